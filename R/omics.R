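# Pathway-partitioned multi-omics embedding: each omics source is split by
# gene set and every pathway gets a multi-source variational autoencoder whose
# latent mean/sample is that pathway's zdim embedding. Stacking the P pathway
# embeddings gives the omics bag fed into the fusion stage.

#' Partition omics sources by gene set
#'
#' Splits every source matrix into per-pathway blocks by gene name. Genes of a
#' pathway absent from a source are dropped from that source's block with a
#' warning; a pathway with no genes in any source is an error. Genes in
#' several pathways are duplicated into each of their blocks.
#'
#' @param sources named list of samples x genes matrices.
#' @param sets a [GeneSetCollection-class].
#' @return nested list `blocks[[source]][[pathway]]` of numeric matrices.
#' @export
partitionByPathway <- function(sources, sets) {
  stopifnot(is.list(sources), length(names(sources)) == length(sources))
  pw <- geneSets(sets)
  blocks <- lapply(names(sources), function(s) {
    mat <- sources[[s]]
    lapply(pw, function(genes) {
      have <- intersect(genes, colnames(mat))
      missing <- setdiff(genes, colnames(mat))
      if (length(missing))
        warning(sprintf("source '%s': dropping %d pathway gene(s) absent from it: %s",
                        s, length(missing),
                        paste(utils::head(missing, 5), collapse = ", ")),
                call. = FALSE)
      mat[, have, drop = FALSE]
    })
  })
  names(blocks) <- names(sources)
  empty <- names(pw)[vapply(names(pw), function(p)
    all(vapply(blocks, function(b) ncol(b[[p]]) == 0L, logical(1))), logical(1))]
  if (length(empty))
    stop("pathway(s) with no genes in any source: ",
         paste(empty, collapse = ", "))
  blocks
}

# block-sparse first layer: one linear map per gene group (e.g. chromosome),
# outputs concatenated; strictly fewer parameters than the dense equivalent
# whenever there is more than one group
nn_block_linear <- function(groups, width, name = "blk") {
  sizes <- vapply(groups, length, 1L)
  w <- pmax(1L, round(width * sizes / sum(sizes)))
  lins <- lapply(seq_along(groups), function(j)
    nn_linear(sizes[j], w[j], sprintf("%s.g%d", name, j)))
  list(type = "block_linear", groups = groups, lins = lins,
       width = sum(w))
}

nn_block_linear_fwd <- function(tape, blk, x) {
  td_cbind(lapply(seq_along(blk$groups), function(j)
    nn_linear_fwd(tape, blk$lins[[j]], td_slice_cols(x, blk$groups[[j]]))))
}

nn_param_count <- function(module) {
  sum(vapply(nn_params(module), function(pe) length(pe$value), 1))
}

# per-source sub-encoder: (block-)linear -> BN -> act -> dropout, twice
.new_sub_encoder <- function(g, widths, use_bn, dropout, groups = NULL,
                             name = "sub") {
  first <- if (is.null(groups)) nn_linear(g, widths[1], paste0(name, ".fc1"))
           else nn_block_linear(groups, widths[1], paste0(name, ".fc1"))
  w1 <- if (is.null(groups)) widths[1] else first$width
  list(first = first,
       bn1 = if (use_bn) nn_batchnorm(w1, paste0(name, ".bn1")),
       fc2 = nn_linear(w1, widths[2], paste0(name, ".fc2")),
       bn2 = if (use_bn) nn_batchnorm(widths[2], paste0(name, ".bn2")),
       dropout = dropout, out_dim = widths[2], in_dim = g)
}

.sub_encoder_fwd <- function(tape, sub, x, train) {
  h <- if (identical(sub$first$type, "block_linear"))
    nn_block_linear_fwd(tape, sub$first, x) else nn_linear_fwd(tape, sub$first, x)
  if (!is.null(sub$bn1)) h <- nn_batchnorm_fwd(tape, sub$bn1, h, train)
  h <- td_tanh(h)
  h <- nn_dropout_fwd(tape, h, sub$dropout, train)
  h <- nn_linear_fwd(tape, sub$fc2, h)
  if (!is.null(sub$bn2)) h <- nn_batchnorm_fwd(tape, sub$bn2, h, train)
  h <- td_tanh(h)
  nn_dropout_fwd(tape, h, sub$dropout, train)
}

#' Initialize the variational encoder of one pathway
#'
#' Per-source sub-encoders (two hidden layers, widths `hidden`) feed a central
#' encoder that maps their concatenation to the latent mean and log-variance;
#' per-source decoders reconstruct each block from the latent sample.
#'
#' @param gene_counts named integer vector: genes of this pathway per source.
#' @param zdim latent dimension.
#' @param hidden sub-encoder widths (two layers).
#' @param use_bn batch normalization on hidden layers.
#' @param dropout dropout rate on hidden layers.
#' @param block_groups optional named list (per source) of gene-index groups
#'   (e.g. chromosomes) making the first layer block-sparse.
#' @param name parameter name prefix.
#' @return list of class `PathwayEncoder`.
#' @export
newPathwayEncoder <- function(gene_counts, zdim = 32, hidden = c(128, 64),
                              use_bn = TRUE, dropout = 0,
                              block_groups = NULL, name = "pw") {
  active <- names(gene_counts)[gene_counts > 0]
  sub <- lapply(active, function(s)
    .new_sub_encoder(gene_counts[[s]], hidden, use_bn, dropout,
                     groups = block_groups[[s]],
                     name = sprintf("%s.%s", name, s)))
  names(sub) <- active
  cat_dim <- sum(vapply(sub, function(x) x$out_dim, 1))
  dec <- lapply(active, function(s)
    nn_mlp(zdim, hidden[2], gene_counts[[s]], use_bn = FALSE,
           dropout = 0, name = sprintf("%s.dec.%s", name, s)))
  names(dec) <- active
  structure(list(sub = sub,
                 mu_head = nn_linear(cat_dim, zdim, paste0(name, ".mu")),
                 logvar_head = nn_linear(cat_dim, zdim, paste0(name, ".logvar")),
                 decoders = dec, zdim = zdim, sources = active),
            class = "PathwayEncoder")
}

# tape forward; blocks_p: named list of n x g matrices (or nodes) for this
# pathway; source_scale: n x S matrix multiplying each source's sub-embedding
# (modality dropout: 0 for dropped, 1/(1-p) for survivors; NULL = all ones)
.encode_pathway_fwd <- function(tape, penc, blocks_p, train = FALSE,
                                source_scale = NULL, sample = train) {
  subs <- lapply(penc$sources, function(s) {
    x <- blocks_p[[s]]
    xn <- if (is.environment(x)) x else td_const(tape, x)
    e <- .sub_encoder_fwd(tape, penc$sub[[s]], xn, train)
    if (!is.null(source_scale))
      e <- td_mul_colvec(e, td_const(tape, source_scale[, s, drop = FALSE]))
    e
  })
  names(subs) <- penc$sources
  cat <- td_cbind(subs)
  mu <- nn_linear_fwd(tape, penc$mu_head, cat)
  logvar <- nn_linear_fwd(tape, penc$logvar_head, cat)
  z <- if (sample) {
    eps <- matrix(stats::rnorm(length(mu$value)), nrow(mu$value))
    td_add(mu, td_mul(td_exp(td_scale(logvar, 0.5)), td_const(tape, eps)))
  } else mu
  list(z = z, mu = mu, logvar = logvar, sub = subs)
}

.decode_pathway_fwd <- function(tape, penc, z, train = FALSE) {
  out <- lapply(penc$sources, function(s)
    nn_mlp_fwd(tape, penc$decoders[[s]], z, train))
  names(out) <- penc$sources
  out
}

#' Encode one pathway's multi-source blocks
#'
#' @param penc a [newPathwayEncoder()].
#' @param blocks_p named list (per source) of samples x genes matrices for
#'   this pathway; sources may be missing (masked), but not all of them.
#' @param sample `"eval"` returns the latent mean (deterministic); `"train"`
#'   returns a reparameterized sample.
#' @param source_scale optional n x S scale matrix (modality dropout).
#' @return list with `z` (n x zdim), `mu`, `logvar` matrices.
#' @export
encodePathway <- function(penc, blocks_p, sample = c("eval", "train"),
                          source_scale = NULL) {
  sample <- match.arg(sample)
  present <- intersect(penc$sources, names(blocks_p))
  if (!length(present))
    stop("all sources masked or absent for this pathway")
  if (length(present) < length(penc$sources)) {
    n <- nrow(blocks_p[[present[1]]])
    if (is.null(source_scale))
      source_scale <- matrix(1, n, length(penc$sources),
                             dimnames = list(NULL, penc$sources))
    for (s in setdiff(penc$sources, present)) {
      source_scale[, s] <- 0
      blocks_p[[s]] <- matrix(0, n, penc$sub[[s]]$in_dim)
    }
  }
  tape <- td_tape()
  res <- .encode_pathway_fwd(tape, penc, blocks_p, train = FALSE,
                             source_scale = source_scale,
                             sample = sample == "train")
  list(z = res$z$value, mu = res$mu$value, logvar = res$logvar$value)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variational autoencoder loss
#'
#' Sum over sources of mean squared reconstruction error plus `beta` times
#' the closed-form KL divergence to the standard normal prior, averaged over
#' the batch: `KL_i = 0.5 * sum_d (mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param recon named list of reconstruction matrices.
#' @param target named list of input matrices (same shapes).
#' @param mu,logvar variational statistics (n x zdim).
#' @param beta KL weight.
#' @return scalar loss.
#' @export
vaeLoss <- function(recon, target, mu, logvar, beta = 0.01) {
  stopifnot(identical(names(recon), names(target)))
  rec <- sum(vapply(names(recon), function(s) {
    stopifnot(all(dim(recon[[s]]) == dim(target[[s]])))
    mean((recon[[s]] - target[[s]])^2)
  }, 1))
  kl <- mean(0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar))
  rec + beta * kl
}

# tape version used in training
.vae_loss_fwd <- function(tape, recon, target, mu, logvar, beta) {
  loss <- NULL
  for (s in names(recon)) {
    t_s <- if (is.environment(target[[s]])) target[[s]]
           else td_const(tape, target[[s]])
    term <- td_mean(td_square(td_sub(recon[[s]], t_s)))
    loss <- if (is.null(loss)) term else td_add(loss, term)
  }
  klmat <- td_sub(td_add(td_square(mu), td_exp(logvar)),
                  td_addc(logvar, 1))
  n <- nrow(mu$value)
  kl <- td_scale(td_sum(klmat), 0.5 / n)
  td_add(loss, td_scale(kl, beta))
}

#' Stack per-pathway embeddings into the omics bag
#'
#' Encodes every pathway in collection order (deterministic eval mode) and
#' stacks the embeddings into an n x P x zdim array.
#'
#' @param sources named list of omics matrices.
#' @param sets a [GeneSetCollection-class].
#' @param encoders list of [newPathwayEncoder()], one per pathway in order.
#' @return array `(n, P, zdim)` with dimnames on the pathway axis and a
#'   `source_mask` attribute naming the sources used.
#' @export
buildOmicsBag <- function(sources, sets, encoders) {
  pw <- names(geneSets(sets))
  stopifnot(length(encoders) == length(pw))
  blocks <- suppressWarnings(partitionByPathway(sources, sets))
  n <- nrow(sources[[1]])
  zdim <- encoders[[1]]$zdim
  bag <- array(0, c(n, length(pw), zdim),
               dimnames = list(rownames(sources[[1]]), pw, NULL))
  for (p in seq_along(pw)) {
    bp <- lapply(blocks, function(b) b[[pw[p]]])
    bag[, p, ] <- encodePathway(encoders[[p]], bp, sample = "eval")$z
  }
  attr(bag, "source_mask") <- names(sources)
  bag
}

# initialize one encoder per pathway from partitioned blocks; chrom_maps is
# an optional named list (per source) mapping gene name -> chromosome, which
# makes that source's first layer block-sparse
.new_pathway_encoders <- function(blocks, sets, zdim, hidden, use_bn, dropout,
                                  chrom_maps = NULL, seed = 1) {
  pw <- names(geneSets(sets))
  with_seed(seed, lapply(seq_along(pw), function(p) {
    gc <- vapply(blocks, function(b) ncol(b[[pw[p]]]), 1L)
    bg <- NULL
    if (!is.null(chrom_maps)) {
      bg <- lapply(names(blocks), function(s) {
        if (is.null(chrom_maps[[s]])) return(NULL)
        genes <- colnames(blocks[[s]][[pw[p]]])
        grp <- chrom_maps[[s]][genes]
        grp[is.na(grp)] <- "unknown"
        unname(split(seq_along(genes), grp))
      })
      names(bg) <- names(blocks)
      bg <- bg[!vapply(bg, is.null, logical(1))]
      if (!length(bg)) bg <- NULL
    }
    newPathwayEncoder(gc, zdim = zdim, hidden = hidden, use_bn = use_bn,
                      dropout = dropout, block_groups = bg,
                      name = sprintf("pw%d", p))
  }))
}

# phase-1 pretraining of all pathway VAEs (full batch, Adam); modality
# dropout over omics sources applied at the sub-embedding input layer
.train_omics_phase1 <- function(encoders, blocks, sets, epochs, lr = 1e-3,
                                beta = 0.01, beta_warmup = 10,
                                modality_dropout = 0, seed = 1,
                                train_rows = NULL, val_rows = NULL) {
  pw <- names(geneSets(sets))
  srcs <- names(blocks)
  n <- nrow(blocks[[1]][[1]])
  params <- nn_params(encoders)
  opt <- adam_new(params, lr = lr)
  tr_rows <- if (is.null(train_rows)) {
    if (is.null(val_rows)) seq_len(n) else setdiff(seq_len(n), val_rows)
  } else train_rows
  hist <- data.frame(epoch = seq_len(epochs), train = NA_real_, val = NA_real_)

  eval_loss <- function(rows, beta_ep) {
    tot <- 0
    for (p in seq_along(pw)) {
      tape <- td_tape()
      bp <- lapply(blocks, function(b) b[[pw[p]]][rows, , drop = FALSE])
      res <- .encode_pathway_fwd(tape, encoders[[p]], bp, train = FALSE,
                                 sample = FALSE)
      rec <- .decode_pathway_fwd(tape, encoders[[p]], res$z, train = FALSE)
      loss <- .vae_loss_fwd(tape, rec, bp, res$mu, res$logvar, beta_ep)
      tot <- tot + as.numeric(loss$value)
    }
    tot
  }

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      beta_ep <- beta * min(1, ep / max(beta_warmup, 1))
      scale_mat <- NULL
      if (modality_dropout > 0 && length(srcs) >= 2) {
        keep <- .dropout_mask(length(tr_rows), srcs, modality_dropout)
        scale_mat <- keep / (1 - modality_dropout)
      }
      tot <- 0
      for (p in seq_along(pw)) {
        tape <- td_tape()
        bp <- lapply(blocks, function(b) b[[pw[p]]][tr_rows, , drop = FALSE])
        res <- .encode_pathway_fwd(tape, encoders[[p]], bp, train = TRUE,
                                   source_scale = scale_mat, sample = TRUE)
        rec <- .decode_pathway_fwd(tape, encoders[[p]], res$z, train = TRUE)
        loss <- .vae_loss_fwd(tape, rec, bp, res$mu, res$logvar, beta_ep)
        td_backward(loss)
        adam_step(opt)
        tot <- tot + as.numeric(loss$value)
      }
      hist$train[ep] <- tot
      if (!is.null(val_rows)) hist$val[ep] <- eval_loss(val_rows, beta_ep)
    }
  })
  list(encoders = encoders, history = hist)
}
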