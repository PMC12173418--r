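# Lazily trained models shared across acceptance blocks: the recovery,
# interpretability and robustness checks all reuse the same five
# classification fits (and five survival fits), so each is trained once per
# test run.

acc_cache <- new.env(parent = emptyenv())

acc_cls_cohort <- function(i) {
  key <- paste0("cls_co_", i)
  if (is.null(acc_cache[[key]]))
    acc_cache[[key]] <- generateCohort(syntheticConfig(
      n_patients = 120, n_patches = 60, feat_dim = 16, n_regions = 4,
      n_pathways = 6, effect_size = 3, seed = 1000 + i))
  acc_cache[[key]]
}

acc_cls_model <- function(i) {
  key <- paste0("cls_m_", i)
  if (is.null(acc_cache[[key]]))
    acc_cache[[key]] <- trainModel(acc_cls_cohort(i),
                                   trainConfig("classification", seed = i))
  acc_cache[[key]]
}

acc_surv_cohort <- function(i) {
  key <- paste0("surv_co_", i)
  if (is.null(acc_cache[[key]]))
    acc_cache[[key]] <- generateCohort(syntheticConfig(
      n_patients = 150, n_patches = 60, feat_dim = 16, effect_size = 3,
      censor_rate = 0.3, task = "survival", seed = 2000 + i))
  acc_cache[[key]]
}

acc_surv_model <- function(i) {
  key <- paste0("surv_m_", i)
  if (is.null(acc_cache[[key]]))
    acc_cache[[key]] <- trainModel(acc_surv_cohort(i),
                                   trainConfig("survival", seed = i))
  acc_cache[[key]]
}

acc_test_auc <- function(i) {
  m <- acc_cls_model(i)
  co <- acc_cls_cohort(i)
  te <- modelSplit(m)$test
  pr <- predictModel(m, co, rows = te)
  aucScore(cohortOutcome(co)$label[te] == "subtypeB", pr$scores[, "subtypeB"])
}

# planted spatial region mapped to the model's global region id: the region
# whose embedding best explains the planted activity
acc_planted_region <- function(i) {
  m <- acc_cls_model(i)
  tr <- plantedTruth(acc_cls_cohort(i))
  a <- tr$region_activity[, tr$signal_region]
  r2 <- vapply(seq_len(dim(m@state$wsi_cache$Xk)[2]), function(k)
    summary(stats::lm(a ~ m@state$wsi_cache$Xk[, k, ]))$r.squared, 1)
  which.max(r2)
}
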