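# Central-difference numerical gradient of a scalar-valued function of a
# matrix, used to validate the autodiff tape.
numerical_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# Analytic gradient of a tape expression w.r.t. an input matrix.
# build(tape, x_node) must return a scalar node.
tape_grad <- function(build, x) {
  tp <- td_tape()
  xn <- td_node(tp, x)
  loss <- build(tp, xn)
  td_backward(loss)
  list(value = as.numeric(loss$value), grad = xn$grad)
}

expect_gradcheck <- function(build, x, tol = 1e-6) {
  ana <- tape_grad(build, x)
  num <- numerical_grad(function(z) {
    tp <- td_tape()
    as.numeric(build(tp, td_node(tp, z))$value)
  }, x)
  expect_lt(max(abs(ana$grad - num)), tol * (1 + max(abs(num))))
}
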