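# Factorized bilinear fusion of region and pathway embeddings into the
# K x P x zdim interaction tensor, and its reduction by the two-phase
# hierarchical mixture of experts: phase 1 gates spatial regions within each
# pathway, phase 2 gates pathways into the patient embedding. Modality
# dropout (training-time removal of whole modalities with inverted-dropout
# rescaling) lives here too.

#' Modality dropout policy
#'
#' @param rate drop probability per modality per sample, in `[0, 1)`.
#' @param modalities optional character vector restricting which modalities
#'   the policy applies to (default: all).
#' @return list of class `DropoutPolicy`.
#' @export
dropoutPolicy <- function(rate = 0.4, modalities = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("dropout rate must lie in [0, 1)")
  structure(list(rate = rate, modalities = modalities),
            class = "DropoutPolicy")
}

# n x M binary keep matrix; rows where every applicable modality would be
# dropped are redrawn so no sample ever loses all modalities
.dropout_mask <- function(n, modalities, rate, applicable = NULL) {
  M <- length(modalities)
  if (is.null(applicable)) applicable <- rep(TRUE, M)
  keep <- matrix(1, n, M, dimnames = list(NULL, modalities))
  if (rate <= 0 || !any(applicable)) return(keep)
  idx <- which(applicable)
  draw <- function(k) matrix(stats::rbinom(k * length(idx), 1L, 1 - rate),
                             k, length(idx))
  keep[, idx] <- draw(n)
  bad <- which(rowSums(keep[, idx, drop = FALSE]) == 0)
  while (length(bad)) {
    keep[bad, idx] <- draw(length(bad))
    bad <- bad[rowSums(keep[bad, idx, drop = FALSE]) == 0]
  }
  keep
}

#' Apply modality dropout to per-modality embedding blocks
#'
#' In train mode each modality of each sample is zeroed independently with
#' probability `rate`; surviving modalities are rescaled by `1 / (1 - rate)`
#' so the expected input is preserved, and a sample never loses all
#' modalities (its mask is redrawn). In eval mode the data pass through
#' unchanged, except that genuinely missing modalities (all-`NA` blocks) are
#' zeroed without rescaling and recorded in the mask.
#'
#' @param inputs named list of n x d matrices, one per modality (rows are
#'   samples). An all-`NA` matrix marks a missing modality.
#' @param policy a [dropoutPolicy()].
#' @param mode `"train"` or `"eval"`.
#' @return list with `inputs` (masked matrices) and `mask` (n x M keep
#'   matrix, 1 = present).
#' @export
applyModalityDropout <- function(inputs, policy, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  if (length(inputs) < 2L) stop("need at least 2 modalities")
  mods <- names(inputs)
  n <- nrow(inputs[[1]])
  missing <- vapply(inputs, function(x) all(is.na(x)), logical(1))
  applicable <- if (is.null(policy$modalities)) rep(TRUE, length(mods))
                else mods %in% policy$modalities
  mask <- matrix(1, n, length(mods), dimnames = list(NULL, mods))
  for (m in which(missing)) {
    inputs[[m]][] <- 0
    mask[, m] <- 0
  }
  if (mode == "train" && policy$rate > 0) {
    keep <- .dropout_mask(n, mods, policy$rate,
                          applicable = applicable & !missing)
    scale <- keep
    scale[, applicable & !missing] <-
      keep[, applicable & !missing] / (1 - policy$rate)
    for (m in seq_along(mods)) {
      if (missing[m]) next
      inputs[[m]] <- inputs[[m]] * scale[, m]
    }
    mask <- mask * keep
  }
  list(inputs = inputs, mask = mask)
}

#' Initialize the factorized bilinear fusion operator
#'
#' Implements low-rank bilinear pooling: for a region embedding `x` and a
#' pathway embedding `o`, `z = SumPool_r(U x * V o)` followed by signed
#' square root and L2 normalization.
#'
#' @param zdim embedding dimension of both inputs (and of the output).
#' @param rank factor rank r (>= 1).
#' @param in_dim input dimension of the factor matrices (defaults to `zdim`;
#'   the training pipeline passes `zdim + 1` because it lifts embeddings to
#'   homogeneous coordinates `[x, 1]` before fusing, so first-order terms
#'   survive the bilinear map).
#' @param init `"random"` (uniform, the plain MFB start) or `"passthrough"`:
#'   with homogeneous inputs (`in_dim = zdim + 1`), the first two rank slots
#'   of each output dimension are initialized to read `x_d * 1` and `1 * o_d`
#'   so the fused block starts as approximately `x + o` (first-order
#'   pass-through) and training rotates the remaining slots toward
#'   interactions; requires `rank >= 2`.
#' @param seed RNG seed for initialization.
#' @return list of class `BilinearFusion`.
#' @export
newFusion <- function(zdim, rank = 4, in_dim = zdim,
                      init = c("random", "passthrough"), seed = 1) {
  if (!is.numeric(rank) || rank < 1 || rank != round(rank))
    stop("rank must be a positive integer")
  init <- match.arg(init)
  if (init == "passthrough" && (in_dim != zdim + 1L || rank < 2))
    stop("passthrough init needs homogeneous inputs (in_dim = zdim + 1) ",
         "and rank >= 2")
  # bias-free factor matrices: the operator is purely bilinear, so an all-zero
  # input on either side annihilates the fused vector
  bound <- 1 / sqrt(in_dim)
  with_seed(seed, {
    U <- .new_param(matrix(stats::runif(in_dim * rank * zdim, -bound, bound),
                           in_dim, rank * zdim), "mfb.U")
    V <- .new_param(matrix(stats::runif(in_dim * rank * zdim, -bound, bound),
                           in_dim, rank * zdim), "mfb.V")
    if (init == "passthrough") {
      U$value <- U$value * 0.1
      V$value <- V$value * 0.1
      for (d in seq_len(zdim)) {
        s1 <- (d - 1L) * rank + 1L
        U$value[, s1] <- 0; U$value[d, s1] <- 1        # x_d ...
        V$value[, s1] <- 0; V$value[in_dim, s1] <- 1   # ... times constant
        U$value[, s1 + 1L] <- 0; U$value[in_dim, s1 + 1L] <- 1
        V$value[, s1 + 1L] <- 0; V$value[d, s1 + 1L] <- 1
      }
    }
  })
  # pooling matrix: output dim d sums slots (d-1)*rank + 1 .. d*rank
  pool <- matrix(0, rank * zdim, zdim)
  for (d in seq_len(zdim)) pool[(d - 1L) * rank + seq_len(rank), d] <- 1
  structure(list(U = U, V = V, pool = pool, zdim = zdim, rank = rank,
                 in_dim = in_dim),
            class = "BilinearFusion")
}

# tape forward for one (k, p) pair on a batch: xa, ob are n x (r*zdim) nodes
.fuse_pair_fwd <- function(tape, fusion, xa, ob, normalize = TRUE) {
  pooled <- td_matmul(td_mul(xa, ob), td_const(tape, fusion$pool))
  if (!normalize) return(pooled)
  s <- td_ssqrt(pooled)
  norm2 <- td_matmul(td_square(s), td_const(tape, matrix(1, fusion$zdim, 1)))
  td_div_colvec(s, td_pow(td_addc(norm2, 1e-12), 0.5))
}

# project a batch matrix through the bias-free factor matrix U or V
.fuse_project <- function(tape, fac, x) td_matmul(x, td_param(tape, fac))

#' Fuse region and pathway embeddings into the interaction tensor
#'
#' @param regions K x zdim region embeddings (one patient).
#' @param omics P x zdim pathway embeddings (same patient).
#' @param fusion a [newFusion()].
#' @param normalize apply the signed-sqrt + L2 normalization (default TRUE);
#'   the normalization of an all-zero vector is defined as zero.
#' @return K x P x zdim array.
#' @export
bilinearFuse <- function(regions, omics, fusion, normalize = TRUE) {
  stopifnot(ncol(regions) == fusion$in_dim, ncol(omics) == fusion$in_dim)
  K <- nrow(regions); P <- nrow(omics)
  tape <- td_tape()
  xa <- .fuse_project(tape, fusion$U, td_const(tape, regions))  # K x r*zdim
  ob <- .fuse_project(tape, fusion$V, td_const(tape, omics))    # P x r*zdim
  out <- array(0, c(K, P, fusion$zdim))
  for (k in seq_len(K)) for (p in seq_len(P)) {
    z <- .fuse_pair_fwd(tape, fusion,
                        td_slice_rows_const(tape, xa, k),
                        td_slice_rows_const(tape, ob, p), normalize)
    out[k, p, ] <- z$value
  }
  out
}

# take one row of a node as a constant 1 x d node (no gradient path needed in
# the plain-evaluation entry points)
td_slice_rows_const <- function(tape, a, i) {
  td_const(tape, a$value[i, , drop = FALSE])
}

#' Initialize the two-phase mixture-of-experts gating networks
#'
#' Phase 1 scores each region's fused vector with a one-hidden-layer gating
#' network (shared across pathways by default) and softmax-normalizes over
#' regions within each pathway; phase 2 gates the pathway embeddings the same
#' way. The softmax realizes the sum-to-one constraint on the gating weights.
#'
#' @param zdim embedding dimension.
#' @param hidden hidden width of each gating network.
#' @param P number of pathways; when `shared = FALSE` (default) each pathway
#'   gets its own phase-1 gating network so the gate can specialize on the
#'   fused blocks of that pathway.
#' @param shared share one phase-1 gating network across pathways (fewer
#'   parameters, weaker specialization).
#' @param seed RNG seed.
#' @return list of class `MoEGates`.
#' @export
newMoEGates <- function(zdim, hidden = 16, P = 1, shared = FALSE, seed = 1) {
  with_seed(seed, {
    g1 <- if (shared) nn_mlp(zdim, hidden, 1, use_bn = FALSE, name = "gate1")
          else lapply(seq_len(P), function(p)
            nn_mlp(zdim, hidden, 1, use_bn = FALSE,
                   name = sprintf("gate1.p%d", p)))
    g2 <- nn_mlp(zdim, hidden, 1, use_bn = FALSE, name = "gate2")
  })
  structure(list(gate1 = g1, gate2 = g2, zdim = zdim, shared = shared,
                 P = if (shared) NA_integer_ else P),
            class = "MoEGates")
}

.gate1_net <- function(gates, p) {
  if (gates$shared) gates$gate1 else gates$gate1[[p]]
}

# phase-1 tape forward: fused is a list [[k]][[p]] of n x zdim nodes;
# region_mask is an n x K 0/1 matrix (1 = region populated). Returns pathway
# embeddings (list of P n x zdim nodes) and region-weight nodes (list of P
# n x K nodes).
.moe_phase1_fwd <- function(tape, gates, fused, region_mask, train = FALSE) {
  K <- length(fused); P <- length(fused[[1]])
  n <- nrow(fused[[1]][[1]]$value)
  pen <- td_const(tape, (region_mask - 1) * 1e30)   # -inf logits when masked
  z_list <- vector("list", P)
  w_list <- vector("list", P)
  for (p in seq_len(P)) {
    g1 <- .gate1_net(gates, p)
    logits <- td_cbind(lapply(seq_len(K), function(k)
      nn_mlp_fwd(tape, g1, fused[[k]][[p]], train)))
    w <- td_softmax_rows(td_add(logits, pen))
    zp <- NULL
    for (k in seq_len(K)) {
      term <- td_mul_colvec(fused[[k]][[p]], td_slice_cols(w, k))
      zp <- if (is.null(zp)) term else td_add(zp, term)
    }
    z_list[[p]] <- zp
    w_list[[p]] <- w
  }
  list(z = z_list, w = w_list)
}

# phase-2 tape forward: z_list is the list of P pathway-embedding nodes.
# Returns the patient embedding (n x zdim), pathway weights (n x P) and the
# per-pathway linear predictions through `pw_head` (if supplied).
.moe_phase2_fwd <- function(tape, gates, z_list, train = FALSE,
                            pw_head = NULL) {
  P <- length(z_list)
  logits <- td_cbind(lapply(z_list, function(z)
    nn_mlp_fwd(tape, gates$gate2, z, train)))
  w <- td_softmax_rows(logits)
  zmoe <- NULL
  for (p in seq_len(P)) {
    term <- td_mul_colvec(z_list[[p]], td_slice_cols(w, p))
    zmoe <- if (is.null(zmoe)) term else td_add(zmoe, term)
  }
  preds <- if (!is.null(pw_head))
    lapply(z_list, function(z) nn_linear_fwd(tape, pw_head, z))
  list(z = zmoe, w = w, pathway_preds = preds)
}

#' Phase-1 gating: pathway embeddings from the fusion tensor (one patient)
#'
#' @param fused K x P x zdim array from [bilinearFuse()].
#' @param gates a [newMoEGates()].
#' @param region_mask logical length-K vector (TRUE = region populated);
#'   masked regions receive zero weight.
#' @return list with `pathway_embeddings` (P x zdim) and `region_weights`
#'   (K x P, each column summing to 1).
#' @export
moePhase1 <- function(fused, gates, region_mask = NULL) {
  K <- dim(fused)[1]; P <- dim(fused)[2]
  if (is.null(region_mask)) region_mask <- rep(TRUE, K)
  if (!any(region_mask)) stop("all regions are masked")
  tape <- td_tape()
  fl <- lapply(seq_len(K), function(k) lapply(seq_len(P), function(p)
    td_const(tape, matrix(fused[k, p, ], 1))))
  res <- .moe_phase1_fwd(tape, gates, fl,
                         matrix(as.numeric(region_mask), 1))
  list(pathway_embeddings = do.call(rbind, lapply(res$z, function(z) z$value)),
       region_weights = t(do.call(rbind, lapply(res$w, function(w) w$value))))
}

#' Phase-2 gating: patient embedding from pathway embeddings (one patient)
#'
#' @param pathway_embeddings P x zdim matrix from [moePhase1()].
#' @param gates a [newMoEGates()].
#' @return list with `patient_embedding` (zdim vector) and `pathway_weights`
#'   (length P, summing to 1).
#' @export
moePhase2 <- function(pathway_embeddings, gates) {
  P <- nrow(pathway_embeddings)
  tape <- td_tape()
  zl <- lapply(seq_len(P), function(p)
    td_const(tape, pathway_embeddings[p, , drop = FALSE]))
  res <- .moe_phase2_fwd(tape, gates, zl)
  list(patient_embedding = as.numeric(res$z$value),
       pathway_weights = as.numeric(res$w$value))
}
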