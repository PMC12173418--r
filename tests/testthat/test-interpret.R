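test_that("expected-gradient attributions: constant and linear model contracts", {
  set.seed(71)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("g1", "g2")))
  bg0 <- matrix(0, 1, 2)

  const_f <- function(tape, xn)
    td_addc(td_matmul(xn, td_const(tape, matrix(0, 2, 1))), 4.2)
  rc <- shapValues(const_f, X, bg0)
  expect_lt(max(abs(rc$shap)), 1e-12)
  expect_equal(rc$base, rep(4.2, 5))

  # y = 3 * g1 with zero background: SHAP(g1) = 3 g1, SHAP(g2) = 0 exactly
  lin_f <- function(tape, xn)
    td_matmul(xn, td_const(tape, matrix(c(3, 0), 2, 1)))
  rl <- shapValues(lin_f, X, bg0)
  expect_equal(rl$shap[, "g1"], 3 * X[, "g1"])
  expect_equal(unname(rl$shap[, "g2"]), rep(0, 5))
  # completeness is exact for a linear model
  expect_equal(rowSums(rl$shap) + rl$base, rl$pred)
})

test_that("attributions satisfy completeness on a nonlinear network", {
  set.seed(72)
  mlp <- with_seed(5, nn_mlp(3, c(8), 1, use_bn = FALSE))
  f <- function(tape, xn) nn_mlp_fwd(tape, mlp, xn)
  X <- matrix(rnorm(15), 5, 3)
  bg <- matrix(rnorm(12, sd = 0.5), 4, 3)
  r <- shapValues(f, X, bg, nsteps = 24)
  rel <- abs(rowSums(r$shap) + r$base - r$pred) /
    (abs(r$pred - r$base) + 1e-8)
  expect_lt(max(rel), 0.05)
})

test_that("PES and MIS are verbatim, pure reads of the gating record", {
  # hand-set gating record for 3 patients, K = 2, P = 3
  w2 <- rbind(c(0.5, 0.3, 0.2), c(0.2, 0.2, 0.6), c(1 / 3, 1 / 3, 1 / 3))
  colnames(w2) <- paste0("PW", 1:3)
  w1 <- array(0.5, c(3, 2, 3))
  gating <- list(region_weights = w1, pathway_weights = w2)

  pes <- extractPES(gating)
  expect_identical(pes$r, w2)
  expect_equal(unname(pes$cohort), colMeans(w2), ignore_attr = TRUE)
  expect_identical(extractPES(gating)$r, pes$r)   # extraction is idempotent
  expect_identical(gating$pathway_weights, w2)    # record untouched

  mis <- extractMIS(gating)
  expect_identical(mis$mis, w1)
  expect_equal(mis$cohort, matrix(0.5, 2, 3))
  for (p in 1:3) expect_equal(colSums(mis$cohort)[p], 1)
})

test_that("normalizeShap applies s_tilde = r * s exactly and checks coverage", {
  gene <- structure(list(
    table = data.frame(patient = c("a", "a", "b"), source = "rna",
                       gene = c("G1", "G2", "G1"),
                       pathway = c("PW1", "PW2", "PW1"),
                       shap = c(2, -1, 4), stringsAsFactors = FALSE),
    sample_ids = c("a", "b")), class = "GeneImportance")
  r <- rbind(a = c(PW1 = 0.25, PW2 = 0.75), b = c(PW1 = 0.1, PW2 = 0.9))
  pes <- structure(list(r = r, cohort = colMeans(r)), class = "PathwayScore")
  out <- normalizeShap(gene, pes)
  expect_equal(out$table$shap_normalized, c(0.25 * 2, 0.75 * -1, 0.1 * 4))

  # doubling r doubles s_tilde (linearity in r)
  pes2 <- pes; pes2$r <- 2 * r
  out2 <- normalizeShap(gene, pes2)
  expect_equal(out2$table$shap_normalized, 2 * out$table$shap_normalized)

  gene$table$pathway[1] <- "PW9"
  expect_error(normalizeShap(gene, pes), "PW9")
})

make_gene_obj <- function(scores, sets) {
  # scores: named per-(gene within pathway) cohort scores (single patient)
  tab <- do.call(rbind, lapply(names(geneSets(sets)), function(p)
    data.frame(patient = "pt1", source = "rna",
               gene = geneSets(sets)[[p]], pathway = p,
               shap = 0,
               shap_normalized = scores[geneSets(sets)[[p]]],
               stringsAsFactors = FALSE)))
  structure(list(table = tab, sample_ids = "pt1"), class = "GeneImportance")
}

test_that("KS enrichment: perfect separation gives D = 1, small sets are skipped", {
  sets <- GeneSetCollection(list(
    hot = sprintf("H%d", 1:10),
    cold = sprintf("C%d", 1:40)))
  scores <- c(stats::setNames(seq(10, 11, length.out = 10), sprintf("H%d", 1:10)),
              stats::setNames(seq(0, 1, length.out = 40), sprintf("C%d", 1:40)))
  res <- ksEnrichment(make_gene_obj(scores, sets), sets)
  expect_equal(res$ks_statistic[res$pathway == "hot"], 1.0)

  tiny <- GeneSetCollection(list(solo = "G1", rest = sprintf("R%d", 1:5)))
  sc <- stats::setNames(rnorm(6), c("G1", sprintf("R%d", 1:5)))
  # both sets are degenerate here (1 gene inside / 1 gene outside)
  w <- testthat::capture_warnings(res <- ksEnrichment(make_gene_obj(sc, tiny),
                                                      tiny))
  expect_true(any(grepl("solo", w)))
  expect_identical(nrow(res), 0L)
})

test_that("KS p-value matches exact enumeration on a hand-built 4 vs 4 case", {
  inside <- c(0.9, 0.7, 0.65, 0.2)
  outside <- c(0.6, 0.4, 0.3, 0.1)
  ks_stat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(v) - stats::ecdf(b)(v)))
  }
  obs <- ks_stat(inside, outside)
  pool <- c(inside, outside)
  combos <- utils::combn(8, 4)
  ge <- vapply(seq_len(ncol(combos)), function(j) {
    a <- pool[combos[, j]]; b <- pool[-combos[, j]]
    ks_stat(a, b) >= obs - 1e-12
  }, logical(1))
  exact_p <- mean(ge)

  sets <- GeneSetCollection(list(inpw = sprintf("I%d", 1:4),
                                 outpw = sprintf("O%d", 1:4)))
  scores <- c(stats::setNames(inside, sprintf("I%d", 1:4)),
              stats::setNames(outside, sprintf("O%d", 1:4)))
  res <- ksEnrichment(make_gene_obj(scores, sets), sets)
  expect_equal(res$p_value[res$pathway == "inpw"], exact_p, tolerance = 1e-10)
})

test_that("KS enrichment p-values are uniform under the null", {
  # gene-set sizes in the asymptotic KS regime: exact small-sample p-values
  # are discrete and cannot be uniform by construction
  sets <- GeneSetCollection(setNames(
    lapply(1:4, function(p) sprintf("P%d_%d", p, 1:60)), paste0("pw", 1:4)))
  genes <- unlist(geneSets(sets))
  pv <- with_seed(73, vapply(1:200, function(i) {
    scores <- stats::setNames(stats::rnorm(240), genes)
    res <- ksEnrichment(make_gene_obj(scores, sets), sets)
    res$p_value[res$pathway == "pw1"]
  }, 1))
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif")$p.value), 0.01)
  expect_gt(mean(pv), 0.35)
  expect_lt(mean(pv), 0.65)
})

test_that("stability analysis: identical folds, null folds, monotone invariance", {
  w <- stats::setNames(runif(10), paste0("p", 1:10))
  res <- stabilityAnalysis(list(w, w, w))
  expect_equal(unname(res$correlations), matrix(1, 3, 3))

  null_means <- with_seed(74, vapply(1:100, function(i)
    stabilityAnalysis(list(stats::rnorm(50), stats::rnorm(50)))$mean, 1))
  expect_lt(abs(mean(null_means)), 0.3)

  a <- runif(12); b <- runif(12)
  r1 <- stabilityAnalysis(list(a, b))$mean
  r2 <- stabilityAnalysis(list(exp(3 * a), b^3))$mean   # monotone transforms
  expect_equal(r1, r2)
  expect_error(stabilityAnalysis(list(a)), "2 folds")
})

test_that("SHAP additivity holds on a trained model and the report is consistent", {
  co <- generateCohort(syntheticConfig(n_patients = 50, n_patches = 16,
                                       feat_dim = 6, n_pathways = 3,
                                       genes_per_pathway = 5, seed = 75))
  m <- trainModel(co, trainConfig("classification", zdim = 6,
                                  hidden = c(16, 8), gate_hidden = 4,
                                  n_regions = 3, phase1_epochs = 5,
                                  wsi_epochs = 2, phase2_epochs = 10,
                                  seed = 4))
  rep_ <- interpretModel(m, co, rows = m@split$test[1:6], n_background = 8,
                         nsteps = 16)
  expect_s4_class(rep_, "InterpretationReport")
  gt <- geneTable(rep_)
  # normalization identity holds row by row
  pr <- predictModel(m, co, rows = m@split$test[1:6])
  r <- pr$gating$pathway_weights
  idx <- cbind(match(gt$patient, rownames(r)), match(gt$pathway, colnames(r)))
  expect_equal(gt$shap_normalized, r[idx] * gt$shap)
  # MIS columns sum to one
  expect_equal(unname(colSums(interactionScores(rep_))), rep(1, 3))

  gene <- computeShap(m, co, rows = m@split$test[1:6], n_background = 8,
                      nsteps = 48)
  # 5% relative to the output scale (per-patient denominators can be ~0)
  rel <- abs(gene$additivity_gap) / mean(abs(gene$pred - gene$base))
  expect_lt(max(rel), 0.05)

  # smoothing switch returns averaged attributions without changing shape
  gene_s <- computeShap(m, co, rows = m@split$test[1:6], n_background = 8,
                        nsteps = 8, smooth_k = 2)
  expect_identical(dim(gene_s$shap), dim(gene$shap))
})

test_that("Kaplan-Meier utility splits at the median and runs a log-rank test", {
  co <- generateCohort(syntheticConfig(n_patients = 100, n_patches = 8,
                                       task = "survival", censor_rate = 0.2,
                                       seed = 76))
  oc <- cohortOutcome(co)
  km <- kmLogrank(plantedTruth(co)$score, oc$time, oc$event)
  expect_lt(km$p_value, 0.01)          # the true score separates risk groups
  expect_identical(levels(km$groups), c("low", "high"))
  expect_equal(sum(km$groups == "high"), 50)
})
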