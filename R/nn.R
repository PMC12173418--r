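# Fully connected building blocks on top of the autodiff tape: linear layers
# with uniform U(-1/sqrt(k), 1/sqrt(k)) initialization (k = fan-in), batch
# normalization with running statistics, inverted dropout, and Adam.

.new_param <- function(value, name = "") {
  pe <- new.env(parent = emptyenv())
  pe$value <- value
  pe$m <- array(0, dim(value))
  pe$v <- array(0, dim(value))
  pe$name <- name
  pe$node <- NULL
  pe
}

nn_linear <- function(d_in, d_out, name = "lin") {
  bound <- 1 / sqrt(d_in)
  W <- matrix(stats::runif(d_in * d_out, -bound, bound), d_in, d_out)
  b <- matrix(stats::runif(d_out, -bound, bound), 1L, d_out)
  list(type = "linear",
       W = .new_param(W, paste0(name, ".W")),
       b = .new_param(b, paste0(name, ".b")))
}

nn_linear_fwd <- function(tape, layer, x) {
  td_add_rowvec(td_matmul(x, td_param(tape, layer$W)),
                td_param(tape, layer$b))
}

nn_batchnorm <- function(d, name = "bn", momentum = 0.1, eps = 1e-5) {
  bn <- list(type = "batchnorm",
             gamma = .new_param(matrix(1, 1L, d), paste0(name, ".gamma")),
             beta = .new_param(matrix(0, 1L, d), paste0(name, ".beta")),
             eps = eps, momentum = momentum,
             stats = new.env(parent = emptyenv()))
  bn$stats$mean <- matrix(0, 1L, d)
  bn$stats$var <- matrix(1, 1L, d)
  bn
}

nn_batchnorm_fwd <- function(tape, bn, x, train) {
  n <- nrow(x$value)
  if (train && n > 1L) {
    ones <- td_const(tape, matrix(1 / n, 1L, n))
    mu <- td_matmul(ones, x)                       # 1 x d batch mean
    centered <- td_sub_rowvec(x, mu)
    var_ <- td_matmul(ones, td_square(centered))   # biased batch variance
    inv_sd <- td_pow(td_addc(var_, bn$eps), -0.5)
    xhat <- td_mul_rowvec(centered, inv_sd)
    m <- bn$momentum
    bn$stats$mean <- (1 - m) * bn$stats$mean + m * mu$value
    bn$stats$var <- (1 - m) * bn$stats$var + m * var_$value * n / max(n - 1L, 1L)
  } else {
    mu <- td_const(tape, bn$stats$mean)
    inv_sd <- td_const(tape, (bn$stats$var + bn$eps)^(-0.5))
    xhat <- td_mul_rowvec(td_sub_rowvec(x, mu), inv_sd)
  }
  td_add_rowvec(td_mul_rowvec(xhat, td_param(tape, bn$gamma)),
                td_param(tape, bn$beta))
}

nn_dropout_fwd <- function(tape, x, rate, train) {
  if (!train || rate <= 0) return(x)
  keep <- matrix(stats::rbinom(length(x$value), 1L, 1 - rate),
                 nrow(x$value), ncol(x$value)) / (1 - rate)
  td_mul(x, td_const(tape, keep))
}

# Multi-layer perceptron: hidden blocks are linear -> (batch norm) ->
# activation -> dropout; the output layer is plain linear.
nn_mlp <- function(d_in, hidden, d_out, name = "mlp",
                   use_bn = TRUE, activation = "tanh", dropout = 0) {
  dims <- c(d_in, hidden, d_out)
  blocks <- list()
  for (l in seq_len(length(dims) - 1L)) {
    is_out <- l == length(dims) - 1L
    blocks[[l]] <- list(
      linear = nn_linear(dims[l], dims[l + 1L], paste0(name, ".fc", l)),
      bn = if (!is_out && use_bn)
        nn_batchnorm(dims[l + 1L], paste0(name, ".bn", l)),
      is_out = is_out)
  }
  list(type = "mlp", blocks = blocks,
       activation = activation, dropout = dropout)
}

.nn_act <- function(x, activation) {
  switch(activation,
         tanh = td_tanh(x),
         relu = td_relu(x),
         sigmoid = td_sigmoid(x),
         identity = x,
         stop("unknown activation: ", activation))
}

nn_mlp_fwd <- function(tape, mlp, x, train = FALSE) {
  h <- x
  for (blk in mlp$blocks) {
    h <- nn_linear_fwd(tape, blk$linear, h)
    if (blk$is_out) break
    if (!is.null(blk$bn)) h <- nn_batchnorm_fwd(tape, blk$bn, h, train)
    h <- .nn_act(h, mlp$activation)
    h <- nn_dropout_fwd(tape, h, mlp$dropout, train)
  }
  h
}

# Collect parameter environments from a (possibly nested) module list.
nn_params <- function(module) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x) && !is.null(x$value) && !is.null(x$m)) {
      out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(module)
  out
}

## ---- Adam -------------------------------------------------------------------

# Adam with optional decoupled weight decay (AdamW) and per-parameter
# learning-rate scaling via an `lr_scale` field on the parameter environment
# (used to fine-tune pretrained components more gently).
adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weight_decay = 0) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$weight_decay <- weight_decay
  opt$t <- 0L
  opt
}

adam_step <- function(opt) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (pe in opt$params) {
    if (is.null(pe$node) || is.null(pe$node$grad)) next
    g <- pe$node$grad
    lr <- opt$lr * (pe$lr_scale %||% 1)
    pe$m <- b1 * pe$m + (1 - b1) * g
    pe$v <- b2 * pe$v + (1 - b2) * g^2
    pe$value <- pe$value - lr * ((pe$m / corr1) /
      (sqrt(pe$v / corr2) + opt$eps) + opt$weight_decay * pe$value)
    pe$node <- NULL
  }
  invisible(opt)
}

## ---- RNG scoping ------------------------------------------------------------

# Run expr under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
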