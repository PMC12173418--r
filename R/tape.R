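# Reverse-mode automatic differentiation on dense matrices.
#
# Every value on the tape is a base-R numeric matrix. A node records its value,
# its parent nodes and a backward closure mapping the incoming gradient to one
# gradient per parent. td_backward() walks the tape in reverse creation order.
# This is deliberately minimal: enough operations to express the encoders,
# fusion, gating and losses used by the model, nothing more.

td_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 512L)
  tp$n <- 0L
  tp
}

.td_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node$idx <- n
  node
}

td_node <- function(tape, value, parents = list(), backward = NULL,
                    const = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$backward <- backward
  nd$grad <- NULL
  nd$const <- const
  nd$tape <- tape
  .td_push(tape, nd)
}

#' @noRd
td_const <- function(tape, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  td_node(tape, x, const = TRUE)
}

# Wrap a parameter environment (fields: value, plus optimizer state) as a leaf
# node; the node is stored back on the parameter so its gradient can be read
# after td_backward().
td_param <- function(tape, pe) {
  nd <- td_node(tape, pe$value)
  pe$node <- nd
  nd
}

td_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  tape <- loss$tape
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (p$const || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  invisible(loss)
}

## ---- arithmetic -------------------------------------------------------------

td_add <- function(a, b) {
  td_node(a$tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

td_sub <- function(a, b) {
  td_node(a$tape, a$value - b$value, list(a, b),
          function(g) list(g, -g))
}

td_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  td_node(a$tape, av * bv, list(a, b),
          function(g) list(g * bv, g * av))
}

td_scale <- function(a, s) {
  td_node(a$tape, a$value * s, list(a), function(g) list(g * s))
}

td_addc <- function(a, c) {
  td_node(a$tape, a$value + c, list(a), function(g) list(g))
}

td_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  td_node(a$tape, av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

td_t <- function(a) {
  td_node(a$tape, t(a$value), list(a), function(g) list(t(g)))
}

## ---- broadcasting over rows / columns --------------------------------------

# v is 1 x d, broadcast over the rows of a (n x d)
td_add_rowvec <- function(a, v) {
  n <- nrow(a$value)
  td_node(a$tape, sweep(a$value, 2L, as.numeric(v$value), "+"), list(a, v),
          function(g) list(g, matrix(colSums(g), 1L)))
}

td_sub_rowvec <- function(a, v) {
  td_node(a$tape, sweep(a$value, 2L, as.numeric(v$value), "-"), list(a, v),
          function(g) list(g, matrix(-colSums(g), 1L)))
}

td_mul_rowvec <- function(a, v) {
  av <- a$value; vv <- as.numeric(v$value)
  td_node(a$tape, sweep(av, 2L, vv, "*"), list(a, v),
          function(g) list(sweep(g, 2L, vv, "*"),
                           matrix(colSums(g * av), 1L)))
}

td_div_rowvec <- function(a, v) {
  av <- a$value; vv <- as.numeric(v$value)
  out <- sweep(av, 2L, vv, "/")
  td_node(a$tape, out, list(a, v),
          function(g) list(sweep(g, 2L, vv, "/"),
                           matrix(-colSums(g * sweep(out, 2L, vv, "/")), 1L)))
}

# v is n x 1, broadcast over the columns of a (n x d)
td_mul_colvec <- function(a, v) {
  av <- a$value; vv <- as.numeric(v$value)
  td_node(a$tape, av * vv, list(a, v),
          function(g) list(g * vv, matrix(rowSums(g * av), ncol = 1L)))
}

td_div_colvec <- function(a, v) {
  av <- a$value; vv <- as.numeric(v$value)
  out <- av / vv
  td_node(a$tape, out, list(a, v),
          function(g) list(g / vv, matrix(-rowSums(g * out / vv), ncol = 1L)))
}

## ---- elementwise nonlinearities --------------------------------------------

td_tanh <- function(a) {
  out <- tanh(a$value)
  td_node(a$tape, out, list(a), function(g) list(g * (1 - out^2)))
}

td_sigmoid <- function(a) {
  out <- 1 / (1 + exp(-a$value))
  td_node(a$tape, out, list(a), function(g) list(g * out * (1 - out)))
}

td_relu <- function(a) {
  av <- a$value
  td_node(a$tape, pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

td_exp <- function(a) {
  out <- exp(a$value)
  td_node(a$tape, out, list(a), function(g) list(g * out))
}

td_log <- function(a) {
  av <- a$value
  td_node(a$tape, log(av), list(a), function(g) list(g / av))
}

td_square <- function(a) {
  av <- a$value
  td_node(a$tape, av^2, list(a), function(g) list(2 * g * av))
}

td_pow <- function(a, p) {
  av <- a$value
  td_node(a$tape, av^p, list(a), function(g) list(g * p * av^(p - 1)))
}

# signed square root used by factorized bilinear pooling, smoothed as
# x (eps + |x|)^{-1/2} so the derivative is exact and finite everywhere
# (gradient-based attributions need the backward to be the true derivative)
td_ssqrt <- function(a, eps = 1e-2) {
  av <- a$value
  s <- (eps + abs(av))
  out <- av / sqrt(s)
  td_node(a$tape, out, list(a),
          function(g) list(g * (eps + abs(av) / 2) / s^1.5))
}

## ---- reductions -------------------------------------------------------------

td_sum <- function(a) {
  dm <- dim(a$value)
  td_node(a$tape, matrix(sum(a$value), 1L, 1L), list(a),
          function(g) list(matrix(as.numeric(g), dm[1L], dm[2L])))
}

td_mean <- function(a) {
  dm <- dim(a$value)
  k <- prod(dm)
  td_node(a$tape, matrix(mean(a$value), 1L, 1L), list(a),
          function(g) list(matrix(as.numeric(g) / k, dm[1L], dm[2L])))
}

## ---- row-wise softmax / log-sum-exp ----------------------------------------

td_softmax_rows <- function(a) {
  av <- a$value
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  out <- e / rowSums(e)
  td_node(a$tape, out, list(a),
          function(g) list((g - rowSums(g * out)) * out))
}

td_logsumexp_rows <- function(a) {
  av <- a$value
  m <- apply(av, 1L, max)
  e <- exp(av - m)
  s <- rowSums(e)
  out <- matrix(log(s) + m, ncol = 1L)
  sm <- e / s
  td_node(a$tape, out, list(a),
          function(g) list(as.numeric(g) * sm))
}

## ---- structural -------------------------------------------------------------

td_cbind <- function(nodes) {
  if (length(nodes) == 1L) return(nodes[[1L]])
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  td_node(nodes[[1L]]$tape, do.call(cbind, lapply(nodes, function(n) n$value)),
          nodes,
          function(g) lapply(seq_along(nodes), function(j)
            g[, starts[j]:ends[j], drop = FALSE]))
}

td_slice_cols <- function(a, idx) {
  dm <- dim(a$value)
  td_node(a$tape, a$value[, idx, drop = FALSE], list(a),
          function(g) {
            out <- matrix(0, dm[1L], dm[2L])
            out[, idx] <- g
            list(out)
          })
}
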