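make_sources <- function(n = 6, P = 3, gpp = 5, S = 2, seed = 1) {
  with_seed(seed, {
    genes <- as.vector(vapply(seq_len(P), function(p)
      sprintf("PATHWAY%d_GENE%d", p, seq_len(gpp)), character(gpp)))
    src <- lapply(seq_len(S), function(s) {
      m <- matrix(rnorm(n * length(genes)), n,
                  dimnames = list(sprintf("s%d", 1:n), genes))
      m
    })
    names(src) <- sprintf("source%d", seq_len(S))
    sets <- GeneSetCollection(setNames(split(genes, rep(seq_len(P), each = gpp)),
                                       sprintf("PATHWAY%d", seq_len(P))))
    list(sources = src, sets = sets)
  })
}

test_that("partitionByPathway splits cleanly and aligns by gene name", {
  d <- make_sources()
  blocks <- partitionByPathway(d$sources, d$sets)
  expect_length(blocks, 2L)
  for (s in names(blocks)) {
    expect_length(blocks[[s]], 3L)
    for (b in blocks[[s]]) expect_identical(ncol(b), 5L)
  }
  # shuffled column order on disk gives identical blocks after alignment
  shuf <- d$sources
  perm <- with_seed(9, sample(ncol(shuf[[1]])))
  shuf[[1]] <- shuf[[1]][, perm]
  blocks2 <- partitionByPathway(shuf, d$sets)
  for (p in 1:3)
    expect_identical(blocks2[[1]][[p]][, colnames(blocks[[1]][[p]])],
                     blocks[[1]][[p]])
})

test_that("partitionByPathway drops missing genes with a warning, errors on empty pathways", {
  d <- make_sources()
  d$sources[[2]] <- d$sources[[2]][, -3]   # drop one gene from source2
  expect_warning(blocks <- partitionByPathway(d$sources, d$sets),
                 "dropping 1 pathway gene")
  expect_identical(ncol(blocks[[2]][[1]]), 4L)
  expect_identical(ncol(blocks[[1]][[1]]), 5L)

  gone <- lapply(make_sources()$sources,
                 function(m) m[, 6:15])             # pathway 1 fully absent
  expect_error(suppressWarnings(partitionByPathway(gone, d$sets)),
               "PATHWAY1")
})

test_that("the KL term follows its closed form and is nonnegative", {
  # prior match: mu = 0, log sigma^2 = 0 -> KL = 0
  z <- matrix(0, 3, 4)
  expect_equal(vaeLoss(list(a = z), list(a = z), mu = z, logvar = z,
                       beta = 1), 0)
  # 1-dim, mu = 1, sigma^2 = 1 -> KL = 0.5(mu^2 + sigma^2 - 1 - log sigma^2) = 0.5
  one <- matrix(1, 1, 1); zero <- matrix(0, 1, 1)
  expect_equal(vaeLoss(list(a = zero), list(a = zero), mu = one,
                       logvar = zero, beta = 1), 0.5)
  # KL >= 0 with equality iff mu = 0, sigma = 1
  set.seed(4)
  for (i in 1:20) {
    mu <- matrix(rnorm(8), 2); lv <- matrix(rnorm(8, sd = 0.5), 2)
    kl <- vaeLoss(list(a = matrix(0, 2, 1)), list(a = matrix(0, 2, 1)),
                  mu, lv, beta = 1)
    expect_gte(kl, 0)
  }
})

test_that("vaeLoss equals hand-computed MSE plus beta KL", {
  set.seed(5)
  x <- matrix(rnorm(12), 4, 3)
  recon <- 0.9 * x
  mu <- matrix(rnorm(8), 4, 2); lv <- matrix(rnorm(8, sd = 0.3), 4, 2)
  by_hand <- mean((0.1 * x)^2) +
    0.01 * mean(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv))
  expect_equal(vaeLoss(list(a = recon), list(a = x), mu, lv, beta = 0.01),
               by_hand)
  # perfect reconstruction leaves only the KL term
  expect_equal(vaeLoss(list(a = x), list(a = x), mu, lv, beta = 0.01),
               0.01 * mean(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv)))
})

test_that("eval-mode encoding is deterministic and the zero-variance limit collapses to mu", {
  d <- make_sources()
  blocks <- partitionByPathway(d$sources, d$sets)
  penc <- with_seed(2, newPathwayEncoder(c(source1 = 5L, source2 = 5L),
                                         zdim = 3, hidden = c(8, 4)))
  bp <- lapply(blocks, function(b) b[[1]])
  e1 <- encodePathway(penc, bp, sample = "eval")
  e2 <- encodePathway(penc, bp, sample = "eval")
  expect_identical(e1$z, e2$z)
  expect_identical(e1$z, e1$mu)

  # force log sigma^2 towards -inf: the reparameterized sample equals mu
  penc$logvar_head$W$value[] <- 0
  penc$logvar_head$b$value[] <- -80
  s <- encodePathway(penc, bp, sample = "train")
  expect_lt(max(abs(s$z - s$mu)), 1e-10)
})

test_that("buildOmicsBag stacks pathway embeddings in order, invariant to source order", {
  d <- make_sources()
  blocks <- partitionByPathway(d$sources, d$sets)
  encs <- with_seed(3, lapply(1:3, function(p)
    newPathwayEncoder(c(source1 = 5L, source2 = 5L), zdim = 3,
                      hidden = c(8, 4), name = sprintf("pw%d", p))))
  bag <- buildOmicsBag(d$sources, d$sets, encs)
  expect_identical(dim(bag), c(6L, 3L, 3L))
  for (p in 1:3) {
    bp <- lapply(blocks, function(b) b[[p]])
    expect_equal(bag[, p, ], encodePathway(encs[[p]], bp)$z,
                 ignore_attr = TRUE)
  }
  rev_bag <- buildOmicsBag(rev(d$sources), d$sets, encs)
  expect_equal(bag, rev_bag, ignore_attr = TRUE)

  # degenerate P = 1
  sets1 <- GeneSetCollection(geneSets(d$sets)[1])
  bag1 <- buildOmicsBag(d$sources, sets1, encs[1])
  bp <- lapply(blocks, function(b) b[[1]])
  expect_equal(bag1[, 1, ], encodePathway(encs[[1]], bp)$z,
               ignore_attr = TRUE)
})

test_that("phase-1 pretraining decreases the validation reconstruction loss", {
  co <- generateCohort(syntheticConfig(n_patients = 40, n_patches = 8,
                                       n_pathways = 2, genes_per_pathway = 6,
                                       seed = 11))
  blocks <- partitionByPathway(co@omics, co@geneSets)
  encs <- with_seed(4, lapply(1:2, function(p)
    newPathwayEncoder(c(source1 = 6L, source2 = 6L), zdim = 4,
                      hidden = c(16, 8), name = sprintf("pw%d", p))))
  res <- .train_omics_phase1(encs, blocks, co@geneSets, epochs = 12,
                             lr = 2e-3, beta = 0, seed = 5,
                             val_rows = 31:40)
  val <- res$history$val
  expect_true(all(diff(val[1:10]) < 0))
  expect_true(all(diff(val) < 1e-6 | diff(val) < 0 | diff(val) <= 1e-6 + 0))
})

test_that("chromosome-blocked first layer has strictly fewer parameters than dense", {
  groups <- list(1:3, 4:6, 7:10)
  blk <- with_seed(6, nn_block_linear(groups, width = 12))
  dense <- with_seed(6, nn_linear(10, 12))
  expect_lt(nn_param_count(blk), nn_param_count(dense))

  # forward agrees with assembling the per-group outputs by hand
  x <- matrix(rnorm(20), 2, 10)
  tp <- td_tape()
  out <- nn_block_linear_fwd(tp, blk, td_const(tp, x))
  by_hand <- do.call(cbind, lapply(seq_along(groups), function(j) {
    lin <- blk$lins[[j]]
    sweep(x[, groups[[j]], drop = FALSE] %*% lin$W$value, 2,
          as.numeric(lin$b$value), "+")
  }))
  expect_equal(out$value, by_hand)

  # wired through the pathway encoder via a gene -> chromosome map
  d <- make_sources()
  blocks <- partitionByPathway(d$sources, d$sets)
  chrom <- setNames(rep(c("chr1", "chr2"), length.out = 15),
                    colnames(d$sources[[1]]))
  encs <- .new_pathway_encoders(blocks, d$sets, zdim = 3, hidden = c(8, 4),
                                use_bn = TRUE, dropout = 0,
                                chrom_maps = list(source1 = chrom), seed = 7)
  expect_identical(encs[[1]]$sub$source1$first$type, "block_linear")
  expect_identical(encs[[1]]$sub$source2$first$type, "linear")
  bp <- lapply(blocks, function(b) b[[1]])
  expect_silent(encodePathway(encs[[1]], bp))
})

test_that("a trained pathway latent aligns with the generative factor (< 30 degrees)", {
  co <- generateCohort(syntheticConfig(n_patients = 60, n_patches = 8,
                                       n_pathways = 2, genes_per_pathway = 8,
                                       seed = 13))
  blocks <- partitionByPathway(co@omics, co@geneSets)
  encs <- .new_pathway_encoders(blocks, co@geneSets, zdim = 4,
                                hidden = c(32, 16), use_bn = TRUE,
                                dropout = 0, seed = 8)
  .train_omics_phase1(encs, blocks, co@geneSets, epochs = 25, lr = 2e-3,
                      beta = 0.01, seed = 9)
  bp <- lapply(blocks, function(b) b[[1]])
  z <- encodePathway(encs[[1]], bp)$mu
  f <- plantedTruth(co)$pathway_factor[, 1]
  r2 <- summary(stats::lm(f ~ z))$r.squared
  # first principal angle < 30 degrees <=> R^2 > cos^2(30deg) = 0.75
  expect_gt(r2, 0.75)
})
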