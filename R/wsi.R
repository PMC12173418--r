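# Whole-slide-image encoder: kernel-based patch merging, K-means region
# assignment, hypergraph construction and an attention-weighted hypergraph
# convolutional encoder pooled into K region embeddings.

#' Kernel parameters for patch similarity
#'
#' The pairwise patch similarity is the product of a morphological and a
#' spatial Gaussian kernel,
#' `kappa(x_i, x_j) = exp(-lambda_h ||h_i - h_j||^2) * exp(-lambda_g ||g_i - g_j||^2)`.
#' `delta_c` is the merge threshold (patches with similarity above it are
#' agglomerated), `delta_h` the hyperedge threshold on the morphological
#' kernel alone.
#'
#' @param lambda_h morphological bandwidth (> 0), or `NULL` for the median
#'   heuristic `1 / median(squared pairwise feature distance)` per slide.
#' @param lambda_g spatial bandwidth (> 0), or `NULL` for the median heuristic
#'   on coordinates.
#' @param delta_c merge threshold in `(0, 1]`.
#' @param delta_h hyperedge threshold in `(0, 1]`.
#' @return a validated list of class `KernelParams`.
#' @export
kernelParams <- function(lambda_h = NULL, lambda_g = NULL,
                         delta_c = 0.9, delta_h = 0.5) {
  for (nm in c("lambda_h", "lambda_g")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v <= 0))
      stop(nm, " must be > 0 (or NULL for the median heuristic)")
  }
  for (nm in c("delta_c", "delta_h")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1)
      stop(nm, " must lie in (0, 1]")
  }
  structure(list(lambda_h = lambda_h, lambda_g = lambda_g,
                 delta_c = delta_c, delta_h = delta_h),
            class = "KernelParams")
}

# median heuristic: 1 / median nonzero squared pairwise distance
.median_bandwidth <- function(mat) {
  d2 <- as.numeric(stats::dist(mat))^2
  d2 <- d2[d2 > 0]
  if (!length(d2)) return(1)
  1 / stats::median(d2)
}

.resolve_bandwidths <- function(params, features, coords) {
  if (is.null(params$lambda_h)) params$lambda_h <- .median_bandwidth(features)
  if (is.null(params$lambda_g)) params$lambda_g <- .median_bandwidth(coords)
  params
}

#' Pairwise patch similarity kernel
#'
#' @param feat_a,feat_b feature vectors of the two patches.
#' @param coord_a,coord_b their spatial coordinates.
#' @param params a [kernelParams()] with explicit bandwidths.
#' @return similarity in `(0, 1]`; 1 iff the patches agree in both features
#'   and coordinates.
#' @export
similarityKernel <- function(feat_a, coord_a, feat_b, coord_b, params) {
  if (!all(is.finite(c(feat_a, coord_a, feat_b, coord_b))))
    stop("non-finite input to similarityKernel")
  if (is.null(params$lambda_h) || is.null(params$lambda_g))
    stop("explicit bandwidths required for a single pair ",
         "(the median heuristic needs a full bag)")
  exp(-params$lambda_h * sum((feat_a - feat_b)^2)) *
    exp(-params$lambda_g * sum((coord_a - coord_b)^2))
}

# full kernel matrices for one bag; resolves NULL bandwidths
.kernel_matrices <- function(features, coords, params) {
  params <- .resolve_bandwidths(params, features, coords)
  Kh <- exp(-params$lambda_h * as.matrix(stats::dist(features))^2)
  Kg <- exp(-params$lambda_g * as.matrix(stats::dist(coords))^2)
  list(Kh = Kh, Kg = Kg, K = Kh * Kg, params = params)
}

#' Merge morphologically and spatially similar patches
#'
#' Average-linkage agglomerative clustering on the distance `1 - kappa`, cut
#' at height `1 - delta_c`; each cluster is replaced by the arithmetic mean of
#' its members' features and coordinates.
#'
#' @param bag a [PatchBag-class].
#' @param params a [kernelParams()].
#' @return list of class `MergedPatchSet` with `reps` (m x d), `centers`
#'   (m x 2), `counts`, the member `assignment`, and `slideId`.
#' @export
mergePatches <- function(bag, params = kernelParams()) {
  stopifnot(is(bag, "PatchBag"))
  feats <- bag@features
  np <- nrow(feats)
  if (np == 1L) {
    cl <- 1L
  } else {
    km <- .kernel_matrices(feats, bag@coords, params)
    hc <- stats::hclust(stats::as.dist(1 - km$K), method = "average")
    cl <- stats::cutree(hc, h = 1 - params$delta_c)
  }
  m <- max(cl)
  reps <- rowsum(feats, cl) / as.numeric(table(cl))
  centers <- rowsum(bag@coords, cl) / as.numeric(table(cl))
  structure(list(reps = unname(reps), centers = unname(centers),
                 counts = as.integer(table(cl)), assignment = cl,
                 slideId = bag@slideId),
            class = "MergedPatchSet")
}

#' Assign merged patches to K spatial regions with K-means
#'
#' K-means (k-means++-style multiple restarts via `nstart = 10`) on the
#' column-standardized merged features; deterministic under the seed.
#'
#' @param merged a [mergePatches()] result.
#' @param K number of regions.
#' @param seed RNG seed.
#' @return integer vector of region ids in `1..K`.
#' @export
assignRegions <- function(merged, K, seed = 1) {
  m <- nrow(merged$reps)
  if (m < K)
    stop("only ", m, " merged patches for K = ", K,
         " regions; lower K or reduce merging (raise delta_c)")
  if (K == 1L) return(rep(1L, m))
  if (K == m) return(seq_len(m))   # saturated: every merged patch its own region
  X <- merged$reps
  sds <- apply(X, 2L, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  X <- scale(X, center = TRUE, scale = sds)
  with_seed(seed, stats::kmeans(X, centers = K, nstart = 10,
                                iter.max = 50)$cluster)
}

#' Build the hypergraph incidence matrix
#'
#' One hyperedge is seeded per merged patch `p_k` and contains every patch
#' `p_j` whose morphological similarity `kappa_h(p_k, p_j)` reaches `delta_h`
#' (the neighborhood uses the morphological kernel only; spatial proximity
#' does not gate membership). `H[j, k] = 1` iff `p_j` belongs to the
#' hyperedge seeded at `p_k`; the diagonal is always 1.
#'
#' @param merged a [mergePatches()] result.
#' @param params a [kernelParams()].
#' @param region_assignment optional region ids from [assignRegions()], stored
#'   alongside the incidence matrix.
#' @return list of class `HypergraphStructure` with binary `incidence`
#'   (m x m) and `region_assignment` (or NULL).
#' @export
buildHypergraph <- function(merged, params = kernelParams(),
                            region_assignment = NULL) {
  p2 <- .resolve_bandwidths(params, merged$reps, merged$centers)
  Kh <- exp(-p2$lambda_h * as.matrix(stats::dist(merged$reps))^2)
  H <- (Kh >= params$delta_h) * 1
  dimnames(H) <- NULL
  structure(list(incidence = H, region_assignment = region_assignment),
            class = "HypergraphStructure")
}

#' Initialize the hypergraph convolutional encoder
#'
#' `L` layers of attention-weighted hypergraph convolution. In each layer,
#' node scores `s = X a` define softmax attention over the members of every
#' hyperedge; hyperedge messages are the attention-weighted member averages
#' and each node aggregates the messages of the hyperedges it belongs to
#' (degree-normalized), followed by a linear map and the activation.
#'
#' @param d input feature dimension.
#' @param zdim embedding dimension.
#' @param L number of convolution layers.
#' @param activation `"tanh"` (default), `"relu"` or `"identity"`.
#' @param seed RNG seed for weight initialization.
#' @return list of class `WsiEncoder`.
#' @export
newWsiEncoder <- function(d, zdim = 32, L = 2, activation = "tanh", seed = 1) {
  with_seed(seed, {
    dims <- c(d, rep(zdim, L))
    layers <- lapply(seq_len(L), function(l) {
      list(linear = nn_linear(dims[l], dims[l + 1L], sprintf("hgc%d", l)),
           attn = .new_param(matrix(stats::runif(dims[l], -0.1, 0.1),
                                    ncol = 1L), sprintf("hgc%d.a", l)))
    })
    structure(list(layers = layers, d = d, zdim = zdim, L = L,
                   activation = activation),
              class = "WsiEncoder")
  })
}

# tape forward of the hypergraph encoder; X is an m x d node, H a plain
# binary matrix. Returns the m x zdim node-embedding node.
.wsi_encode_fwd <- function(tape, enc, X, H) {
  Hc <- td_const(tape, H)
  m <- nrow(H)
  inv_dv <- td_const(tape, matrix(1 / rowSums(H), ncol = 1L))
  ones <- td_const(tape, matrix(1, 1L, m))
  h <- X
  for (layer in enc$layers) {
    s <- td_matmul(h, td_param(tape, layer$attn))        # m x 1 node scores
    es <- td_exp(td_addc(s, -max(s$value)))              # stabilized
    E <- td_mul_colvec(Hc, es)                           # H[j,e] * exp(s_j)
    colsum <- td_matmul(ones, E)                         # 1 x m
    Halpha <- td_div_rowvec(E, colsum)                   # softmax within edge
    msg <- td_matmul(td_t(Halpha), h)                    # per-edge message
    agg <- td_mul_colvec(td_matmul(Hc, msg), inv_dv)     # node aggregation
    h <- nn_linear_fwd(tape, layer$linear, agg)
    h <- .nn_act(h, enc$activation)
  }
  h
}

# region-mean pooling matrix (K x m); empty regions give zero rows
.region_pool_matrix <- function(regions, K) {
  P <- matrix(0, K, length(regions))
  for (k in seq_len(K)) {
    j <- which(regions == k)
    if (length(j)) P[k, j] <- 1 / length(j)
  }
  P
}

#' Encode a merged patch set into K region embeddings
#'
#' Runs the hypergraph convolution and mean-pools node embeddings by region.
#' A region with no merged patches yields a zero row, flagged in the
#' `"region_mask"` attribute, so the output always has exactly K rows.
#'
#' @param merged a [mergePatches()] result.
#' @param hg a [buildHypergraph()] result carrying a region assignment (or
#'   pass `regions`).
#' @param model a [newWsiEncoder()].
#' @param K number of regions.
#' @param regions region assignment overriding `hg$region_assignment`.
#' @return K x zdim matrix with attribute `region_mask` (TRUE = populated).
#' @export
encodeRegions <- function(merged, hg, model, K, regions = NULL) {
  if (is.null(regions)) regions <- hg$region_assignment
  if (is.null(regions)) stop("no region assignment supplied")
  stopifnot(nrow(hg$incidence) == nrow(merged$reps),
            length(regions) == nrow(merged$reps))
  tape <- td_tape()
  X <- td_const(tape, merged$reps)
  nodes <- .wsi_encode_fwd(tape, model, X, hg$incidence)
  P <- .region_pool_matrix(regions, K)
  out <- P %*% nodes$value
  attr(out, "region_mask") <- tabulate(regions, K) > 0
  out
}

# Unsupervised pretraining of the WSI encoder: reconstruct merged-patch
# features from node embeddings through a linear decoder (autoencoding role
# mirroring the omics VAEs). `slides` is a list of list(merged=, hg=).
.train_wsi_phase1 <- function(enc, slides, epochs = 10, lr = 1e-3, seed = 1) {
  dec <- with_seed(seed + 1L, nn_linear(enc$zdim, enc$d, "wsi.dec"))
  opt <- adam_new(c(nn_params(enc$layers), nn_params(dec)), lr = lr)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (sl in slides) {
      tape <- td_tape()
      X <- td_const(tape, sl$merged$reps)
      z <- .wsi_encode_fwd(tape, enc, X, sl$hg$incidence)
      recon <- nn_linear_fwd(tape, dec, z)
      loss <- td_mean(td_square(td_sub(recon, X)))
      td_backward(loss)
      adam_step(opt)
      tot <- tot + as.numeric(loss$value)
    }
    hist[ep] <- tot / length(slides)
  }
  list(encoder = enc, decoder = dec, loss = hist)
}
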