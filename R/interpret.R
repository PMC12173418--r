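# Interpretability: gene-level attributions by expected gradients (a
# gradient-based Shapley approximation against a background sample), pathway
# enrichment scores read from the phase-2 gating weights with KS-test
# enrichment p-values, and the region-by-pathway multimodal interaction score
# read from the phase-1 gating weights.

#' Expected-gradient Shapley attributions of a differentiable function
#'
#' Integrated gradients from each background row to each sample (midpoint
#' rule, `nsteps` steps), averaged over the background — the expected-
#' gradients estimator of Shapley values for a differentiable model. Exact
#' for linear models; satisfies completeness (attributions sum to
#' `f(x) - mean_b f(b)`) up to quadrature error.
#'
#' @param f function `(tape, x_node) -> n x 1 output node` built on the
#'   autodiff tape.
#' @param X n x G input matrix (rows are samples to explain).
#' @param background m x G background matrix.
#' @param nsteps quadrature steps per background row.
#' @return list with `shap` (n x G), `base` (length-n mean background output;
#'   per sample because `f` may condition on fixed per-sample context such as
#'   the slide embeddings) and `pred` (length-n model outputs).
#' @export
shapValues <- function(f, X, background, nsteps = 8) {
  stopifnot(ncol(X) == ncol(background), nrow(background) >= 1)
  n <- nrow(X); G <- ncol(X)
  total <- matrix(0, n, G, dimnames = dimnames(X))
  base <- numeric(n)
  for (bi in seq_len(nrow(background))) {
    b <- background[bi, ]
    diff <- sweep(X, 2L, b)
    avg_grad <- matrix(0, n, G)
    for (t in seq_len(nsteps)) {
      alpha <- (t - 0.5) / nsteps
      tp <- td_tape()
      xn <- td_node(tp, sweep(diff * alpha, 2L, b, "+"))
      td_backward(td_sum(f(tp, xn)))
      avg_grad <- avg_grad + xn$grad
    }
    total <- total + diff * (avg_grad / nsteps)
    tp <- td_tape()
    bmat <- matrix(b, n, G, byrow = TRUE)
    base <- base + as.numeric(f(tp, td_node(tp, bmat))$value)
  }
  tp <- td_tape()
  pred <- as.numeric(f(tp, td_node(tp, X))$value)
  list(shap = total / nrow(background), base = base / nrow(background),
       pred = pred)
}

# forward builder: model output (risk, or logit of the class of interest) as
# a function of the concatenated standardized omics matrix, with the WSI
# embeddings held fixed at the explained samples' values
.shap_builder <- function(model, Xk, region_mask, src_cols, class_idx) {
  st <- model@state
  P <- length(model@meta$pathways)
  function(tape, xn) {
    nrows <- nrow(xn$value)
    blocks <- lapply(names(src_cols), function(s) {
      lapply(model@meta$block_cols[[s]], function(idx)
        td_slice_cols(xn, src_cols[[s]][idx]))
    })
    names(blocks) <- names(src_cols)
    data <- list(Xk = Xk[seq_len(nrows), , , drop = FALSE],
                 region_mask = region_mask[seq_len(nrows), , drop = FALSE],
                 blocks = blocks, source_scale = NULL)
    fw <- .supervised_fwd(tape, st, data, train = FALSE, sample = FALSE)
    if (model@meta$task == "classification")
      td_slice_cols(fw$pred, class_idx)
    else fw$pred
  }
}

#' Gene-level SHAP attributions for a trained model
#'
#' Attributes the task output (the risk score, or the logit of
#' `class_label`) to every standardized gene value of every omics source by
#' expected gradients against a background drawn from the training split.
#' Optionally smooths attributions by averaging over the `k` nearest
#' neighbors in the patient-embedding space ("samples with similar
#' features").
#'
#' @param model a trained [MoEModel-class].
#' @param cohort the cohort the samples come from.
#' @param rows samples to explain (default: the model's test split).
#' @param n_background background size, drawn from the training split with
#'   `seed`.
#' @param nsteps quadrature steps of the expected-gradients estimator.
#' @param class_label class whose logit is attributed (classification only;
#'   default: last class level).
#' @param smooth_k if > 0, average each patient's attributions with its
#'   `smooth_k` nearest neighbors in embedding space.
#' @param seed RNG seed for the background draw.
#' @return list of class `GeneImportance`: `table` (patient, source, gene,
#'   pathway, shap), `shap` matrix, `base`, `pred`, additivity gap.
#' @export
computeShap <- function(model, cohort, rows = NULL, n_background = 20,
                        nsteps = 25, class_label = NULL, smooth_k = 0,
                        seed = 1) {
  stopifnot(is(model, "MoEModel"))
  if (nrow(model@history) == 0 && model@config$phase2_epochs > 0)
    stop("model has no supervised training history; train it first")
  if (is.null(rows)) rows <- model@split$test
  ids <- sampleIds(cohort)
  st <- model@state

  std <- .apply_scalers(cohort@omics[model@meta$sources], st$scalers)
  wide <- do.call(cbind, lapply(names(std), function(s) {
    m <- std[[s]]
    colnames(m) <- paste(s, colnames(m), sep = ":")
    m
  }))
  src_cols <- local({
    widths <- vapply(std, ncol, 1L)
    ends <- cumsum(widths)
    starts <- c(1L, ends[-length(ends)] + 1L)
    out <- lapply(seq_along(std), function(j) starts[j]:ends[j])
    names(out) <- names(std)
    out
  })

  bg_rows <- with_seed(seed, sample(model@split$train,
                                    min(n_background,
                                        length(model@split$train))))
  class_idx <- if (model@meta$task == "classification") {
    lv <- model@meta$class_levels
    if (is.null(class_label)) class_label <- lv[length(lv)]
    match(class_label, lv)
  } else 1L

  # WSI side fixed at the explained samples; background shares sample 1's
  # slide context (attribution is over omics inputs)
  pred_all <- predictModel(model, cohort, rows = rows)
  sel <- match(ids[rows], st$cache_ids)
  if (anyNA(sel)) {
    structs <- .wsi_structures(cohort, model@config)[rows]
    emb <- .wsi_embed_all(structs, st$wsi_encoder, model@config$n_regions,
                          st$region_centroids)
    Xk <- emb$Xk; mask <- emb$mask
  } else {
    Xk <- st$wsi_cache$Xk[sel, , , drop = FALSE]
    mask <- st$wsi_cache$mask[sel, , drop = FALSE]
  }
  f <- .shap_builder(model, Xk, mask, src_cols, class_idx)
  res <- shapValues(f, wide[rows, , drop = FALSE],
                    wide[bg_rows, , drop = FALSE], nsteps = nsteps)

  shap <- res$shap
  if (smooth_k > 0 && length(rows) > smooth_k) {
    emb <- pred_all$embeddings
    d2 <- as.matrix(stats::dist(emb))
    sm <- shap
    for (i in seq_len(nrow(shap))) {
      nb <- order(d2[i, ])[seq_len(smooth_k + 1L)]   # includes self
      sm[i, ] <- colMeans(shap[nb, , drop = FALSE])
    }
    shap <- sm
  }

  pw <- geneSets(cohort@geneSets)
  tab <- do.call(rbind, lapply(names(std), function(s) {
    genes <- colnames(std[[s]])
    do.call(rbind, lapply(names(pw), function(p) {
      g_in <- intersect(pw[[p]], genes)
      if (!length(g_in)) return(NULL)
      cols <- src_cols[[s]][match(g_in, genes)]
      data.frame(patient = rep(ids[rows], each = length(g_in)),
                 source = s,
                 gene = rep(g_in, times = length(rows)),
                 pathway = p,
                 shap = as.vector(t(shap[, cols, drop = FALSE])),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(table = tab, shap = shap, base = res$base, pred = res$pred,
                 rows = rows, sample_ids = ids[rows],
                 additivity_gap = res$pred - (rowSums(res$shap) + res$base)),
            class = "GeneImportance")
}

#' Pathway enrichment scores from the phase-2 gating weights
#'
#' The per-patient ranking score of pathway p is the gating weight `w_{i,p}`
#' verbatim; the cohort-level score is its mean over patients. A pure read of
#' recorded gating state: extraction never changes model outputs.
#'
#' @param gating the `gating` element of a [predictModel()] result (or that
#'   result itself).
#' @return list of class `PathwayScore`: `r` (n x P per-patient scores),
#'   `cohort` (named length-P means).
#' @export
extractPES <- function(gating) {
  if (!is.null(gating$gating)) gating <- gating$gating
  r <- gating$pathway_weights
  structure(list(r = r, cohort = colMeans(r)), class = "PathwayScore")
}

#' Multimodal interaction scores from the phase-1 gating weights
#'
#' `MIS[i, k, p]` is the weight of region k within pathway p for patient i,
#' copied verbatim from the gating record; the cohort aggregate is the mean
#' over patients. Masked (empty) regions carry zero weight.
#'
#' @param gating the `gating` element of a [predictModel()] result (or that
#'   result itself).
#' @return list of class `InteractionScore`: `mis` (n x K x P array),
#'   `cohort` (K x P matrix).
#' @export
extractMIS <- function(gating) {
  if (!is.null(gating$gating)) gating <- gating$gating
  w <- gating$region_weights
  structure(list(mis = w, cohort = apply(w, c(2, 3), mean)),
            class = "InteractionScore")
}

#' Normalize gene SHAP values by pathway importance
#'
#' `s_tilde[i, g] = r[i, p(g)] * s[i, g]`, where p(g) is the pathway under
#' which the attribution was recorded; genes in several pathways receive one
#' normalized value per (gene, pathway) occurrence.
#'
#' @param gene a [computeShap()] result.
#' @param pes an [extractPES()] result for the same patients.
#' @return the `GeneImportance` with a `shap_normalized` column added.
#' @export
normalizeShap <- function(gene, pes) {
  stopifnot(inherits(gene, "GeneImportance"), inherits(pes, "PathwayScore"))
  tab <- gene$table
  missing_pw <- setdiff(unique(tab$pathway), colnames(pes$r))
  if (length(missing_pw))
    stop("no pathway score for: ", paste(missing_pw, collapse = ", "))
  ridx <- cbind(match(tab$patient, gene$sample_ids),
                match(tab$pathway, colnames(pes$r)))
  if (anyNA(ridx[, 1]))
    stop("gene table patients absent from the pathway scores")
  tab$shap_normalized <- pes$r[ridx] * tab$shap
  gene$table <- tab
  gene
}

#' Kolmogorov-Smirnov pathway enrichment on normalized gene scores
#'
#' Aggregates `|shap_normalized|` per (gene, pathway) occurrence as the mean
#' over patients, then tests each pathway's gene scores against all other
#' genes' scores with a two-sided two-sample KS test. Pathways with fewer
#' than 2 genes on either side are skipped with a warning. Benjamini-
#' Hochberg-adjusted p-values are reported alongside the raw ones.
#'
#' @param gene a [normalizeShap()]-ed `GeneImportance`.
#' @param sets the [GeneSetCollection-class] the model was trained with.
#' @return data.frame: pathway, n_genes, mean_score, ks_statistic, p_value,
#'   p_adjusted, ordered by p_value.
#' @export
ksEnrichment <- function(gene, sets) {
  tab <- gene$table
  if (is.null(tab$shap_normalized))
    stop("run normalizeShap() first")
  agg <- stats::aggregate(abs(tab$shap_normalized),
                          by = list(gene = tab$gene, pathway = tab$pathway),
                          FUN = mean)
  names(agg)[3] <- "score"
  pw <- names(geneSets(sets))
  out <- do.call(rbind, lapply(pw, function(p) {
    inside <- agg$score[agg$pathway == p]
    outside <- agg$score[agg$pathway != p]
    if (length(inside) < 2 || length(outside) < 2) {
      warning("skipping pathway '", p, "': too few genes for a KS test",
              call. = FALSE)
      return(NULL)
    }
    ks <- suppressWarnings(stats::ks.test(inside, outside,
                                          alternative = "two.sided"))
    data.frame(pathway = p, n_genes = length(inside),
               mean_score = mean(inside),
               ks_statistic = unname(ks$statistic),
               p_value = ks$p.value, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    return(data.frame(pathway = character(0), n_genes = integer(0),
                      mean_score = numeric(0), ks_statistic = numeric(0),
                      p_value = numeric(0), p_adjusted = numeric(0)))
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}

#' Rank-correlation stability of pathway weights across folds
#'
#' Spearman correlation of the cohort-mean pathway-weight vectors between
#' every pair of trained folds.
#'
#' @param weight_list list (length >= 2) of named length-P cohort-mean
#'   pathway-weight vectors, or of [extractPES()] results.
#' @return list with the pairwise `correlations` matrix, `mean` and `sd` of
#'   the off-diagonal entries.
#' @export
stabilityAnalysis <- function(weight_list) {
  if (length(weight_list) < 2) stop("need >= 2 folds")
  vecs <- lapply(weight_list, function(w)
    if (inherits(w, "PathwayScore")) w$cohort else w)
  M <- do.call(cbind, vecs)
  rho <- stats::cor(M, method = "spearman")
  off <- rho[upper.tri(rho)]
  list(correlations = rho, mean = mean(off), sd = stats::sd(off))
}

#' Full interpretation report for a trained model
#'
#' Runs prediction on the requested samples, extracts PES and MIS from the
#' gating record, computes expected-gradient SHAP values, normalizes them by
#' pathway importance and performs KS enrichment.
#'
#' @param model a trained [MoEModel-class].
#' @param cohort the cohort.
#' @param rows samples to interpret (default: the model's test split).
#' @param ... passed to [computeShap()].
#' @return An [InterpretationReport-class].
#' @export
interpretModel <- function(model, cohort, rows = NULL, ...) {
  if (is.null(rows)) rows <- model@split$test
  pred <- predictModel(model, cohort, rows = rows)
  pes <- extractPES(pred)
  mis <- extractMIS(pred)
  gene <- computeShap(model, cohort, rows = rows, ...)
  gene <- normalizeShap(gene, pes)
  enr <- ksEnrichment(gene, cohort@geneSets)
  enr$mean_r <- pes$cohort[enr$pathway]
  misl <- lapply(seq_along(rows), function(i) mis$mis[i, , ])
  names(misl) <- pred$sample_ids
  new("InterpretationReport",
      geneTable = gene$table,
      pathwayTable = enr[, c("pathway", "n_genes", "mean_r", "mean_score",
                             "ks_statistic", "p_value", "p_adjusted")],
      mis = mis$cohort, misByPatient = misl,
      meta = list(task = model@meta$task,
                  model_hash = configHash(model@config),
                  n_interpreted = length(rows)))
}

#' Kaplan-Meier split and log-rank test for a risk score
#'
#' Utility for survival models: splits patients at the median risk and
#' compares the two Kaplan-Meier curves with a log-rank test.
#'
#' @param risks numeric risk scores.
#' @param time,event survival outcome.
#' @return list with the `survfit` object, the log-rank `p_value` and the
#'   group labels.
#' @export
kmLogrank <- function(risks, time, event) {
  grp <- factor(ifelse(risks > stats::median(risks), "high", "low"),
                levels = c("low", "high"))
  if (nlevels(droplevels(grp)) < 2) stop("all risks on one side of the median")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(fit = survival::survfit(survival::Surv(time, event) ~ grp),
       p_value = p, groups = grp)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical JSON serialization; recorded in every output so any
#' artifact can be traced to the configuration that produced it.
#'
#' @param config a list.
#' @return character MD5 hash.
#' @export
configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tf))
}
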