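# Synthetic multimodal cohorts with a planted region-by-pathway signal.
#
# Patch bags are drawn from spatially clustered Gaussian regions whose feature
# distributions are region specific, so morphological and spatial similarity
# agree on the cluster structure. Omics matrices get within-pathway
# correlation through one latent activity factor per pathway. The outcome
# (class label or hazard) depends on the product of the patient's activity in
# one region and one pathway, so a model must combine both modalities to
# recover the signal.

#' Configuration for the synthetic cohort generator
#'
#' The defaults define the desk-scale study conditions used throughout the
#' test suite: 100 patients, 60 patches per slide, 16-dim patch features, 4
#' spatial regions, 2 omics sources, 6 pathways of 8 genes. Region activity
#' and pathway factors are N(1, 1) (activity-like, positive mean); the planted
#' score is `effect_size * (a_i * b_i - 1)` where `a_i` is the patient's
#' signal-region activity and `b_i` the signal-pathway factor.
#'
#' @param n_patients number of patients.
#' @param n_patches patches per slide.
#' @param feat_dim patch feature dimension (the upstream extractor's width;
#'   any value up to 1024 works, small values keep tests fast).
#' @param n_regions planted spatial cluster count.
#' @param n_sources number of omics sources.
#' @param genes_per_pathway genes per pathway.
#' @param n_pathways number of pathways.
#' @param signal_region 1-based index of the planted region.
#' @param signal_pathway 1-based index of the planted pathway.
#' @param effect_size dimensionless signal strength (0 = no signal).
#' @param censor_rate target censoring fraction in `[0, 1)` (survival task).
#' @param task `"classification"` or `"survival"`.
#' @param seed RNG seed.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_patients = 100, n_patches = 60, feat_dim = 16,
                            n_regions = 4, n_sources = 2,
                            genes_per_pathway = 8, n_pathways = 6,
                            signal_region = 1, signal_pathway = 1,
                            effect_size = 3, censor_rate = 0.3,
                            task = c("classification", "survival"),
                            seed = 1) {
  cfg <- list(n_patients = n_patients, n_patches = n_patches,
              feat_dim = feat_dim, n_regions = n_regions,
              n_sources = n_sources, genes_per_pathway = genes_per_pathway,
              n_pathways = n_pathways, signal_region = signal_region,
              signal_pathway = signal_pathway, effect_size = effect_size,
              censor_rate = censor_rate, task = match.arg(task), seed = seed)
  counts <- c("n_patients", "n_patches", "feat_dim", "n_regions", "n_sources",
              "genes_per_pathway", "n_pathways")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("invalid config: '", f, "' must be a count >= 1", call. = FALSE)
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("invalid config: 'censor_rate' must be in [0, 1)", call. = FALSE)
  if (cfg$signal_region < 1 || cfg$signal_region > cfg$n_regions)
    stop("invalid config: 'signal_region' out of range", call. = FALSE)
  if (cfg$signal_pathway < 1 || cfg$signal_pathway > cfg$n_pathways)
    stop("invalid config: 'signal_pathway' out of range", call. = FALSE)
  if (!is.numeric(cfg$effect_size) || length(cfg$effect_size) != 1L)
    stop("invalid config: 'effect_size' must be a number", call. = FALSE)
  if (cfg$n_patches < 2 * cfg$n_regions)
    stop("invalid config: 'n_patches' must allow >= 2 patches per region",
         call. = FALSE)
  class(cfg) <- "SyntheticConfig"
  cfg
}

# Fixed generator scales (study conditions, not tuning knobs): spatial layout
# on a circle of radius 1000 px with per-region sd 75 px; region feature
# prototypes of norm 3 (well-separated morphology); patch feature noise 0.5;
# omics loadings U(0.5, 1.5) with residual sd 0.6; baseline hazard 0.02.
.syn_scales <- list(spatial_radius = 1000, spatial_sd = 75, proto_norm = 3,
                    feat_sd = 0.5, loading_lo = 0.5, loading_hi = 1.5,
                    omics_sd = 0.6, base_hazard = 0.02)

#' Generate a synthetic multimodal cohort
#'
#' @param config a [syntheticConfig()].
#' @return A [MultiModalCohort-class] whose `truth` slot records the planted
#'   region/pathway, the per-patient region-activity and pathway-factor
#'   matrices, and the planted score.
#' @examples
#' cohort <- generateCohort(syntheticConfig(n_patients = 8, n_patches = 12,
#'                                          seed = 3))
#' cohort
#' @export
generateCohort <- function(config) {
  if (!inherits(config, "SyntheticConfig"))
    stop("config must come from syntheticConfig()")
  sc <- .syn_scales
  with_seed(config$seed, {
    n <- config$n_patients
    K <- config$n_regions
    P <- config$n_pathways
    d <- config$feat_dim
    S <- config$n_sources
    ids <- sprintf("PT%03d", seq_len(n))

    # region geometry and morphology shared by all slides
    ang <- 2 * pi * (seq_len(K) - 1) / K
    centers <- cbind(x = sc$spatial_radius * (1 + cos(ang)),
                     y = sc$spatial_radius * (1 + sin(ang)))
    proto <- matrix(rnorm(K * d), K, d)
    proto <- proto / sqrt(rowSums(proto^2)) * sc$proto_norm
    act_dir <- matrix(rnorm(K * d), K, d)
    act_dir <- act_dir / sqrt(rowSums(act_dir^2))

    # per-patient latents: region activity and pathway factors, N(1, 1)
    u <- matrix(rnorm(n * K, mean = 1), n, K,
                dimnames = list(ids, NULL))
    f <- matrix(rnorm(n * P, mean = 1), n, P,
                dimnames = list(ids, NULL))

    # patch bags
    extra <- config$n_patches - 2L * K
    bags <- vector("list", n)
    names(bags) <- ids
    for (i in seq_len(n)) {
      reg <- c(rep(seq_len(K), 2L),
               sample(seq_len(K), extra, replace = TRUE))
      coords <- centers[reg, , drop = FALSE] +
        matrix(rnorm(2 * length(reg), sd = sc$spatial_sd), ncol = 2)
      feats <- proto[reg, , drop = FALSE] +
        act_dir[reg, , drop = FALSE] * u[i, reg] +
        matrix(rnorm(length(reg) * d, sd = sc$feat_sd), ncol = d)
      colnames(coords) <- c("x", "y")
      bags[[i]] <- PatchBag(feats, coords, ids[i])
    }

    # gene sets and omics sources
    genes <- as.vector(vapply(seq_len(P), function(p)
      sprintf("PATHWAY%d_GENE%d", p, seq_len(config$genes_per_pathway)),
      character(config$genes_per_pathway)))
    sets <- split(genes, rep(seq_len(P), each = config$genes_per_pathway))
    names(sets) <- sprintf("PATHWAY%d", seq_len(P))
    gsc <- GeneSetCollection(sets)

    omics <- list()
    for (s in seq_len(S)) {
      load_s <- runif(length(genes), sc$loading_lo, sc$loading_hi)
      fac <- f[, rep(seq_len(P), each = config$genes_per_pathway),
               drop = FALSE]
      mat <- sweep(fac, 2L, load_s, "*") +
        matrix(rnorm(n * length(genes), sd = sc$omics_sd), n)
      dimnames(mat) <- list(ids, genes)
      omics[[sprintf("source%d", s)]] <- mat
    }

    # planted score and outcome
    a <- u[, config$signal_region]
    b <- f[, config$signal_pathway]
    eta <- config$effect_size * (a * b - 1)
    if (config$task == "classification") {
      y <- rbinom(n, 1L, stats::plogis(eta))
      outcome <- data.frame(sample_id = ids,
                            label = c("subtypeA", "subtypeB")[y + 1L],
                            stringsAsFactors = FALSE)
    } else {
      rate <- sc$base_hazard * exp(eta)
      t_event <- stats::rexp(n, rate)
      if (config$censor_rate > 0) {
        # independent exponential censoring; rate solved so that the expected
        # censoring fraction E[lc / (lc + rate_i)] matches censor_rate
        lam_c <- stats::uniroot(function(lc)
          mean(lc / (lc + rate)) - config$censor_rate,
          lower = 1e-10, upper = 1e6, tol = 1e-12)$root
        t_cens <- stats::rexp(n, lam_c)
      } else {
        t_cens <- rep(Inf, n)
      }
      outcome <- data.frame(sample_id = ids,
                            time = pmax(pmin(t_event, t_cens), 1e-8),
                            event = as.integer(t_event <= t_cens),
                            stringsAsFactors = FALSE)
    }

    new("MultiModalCohort", patchBags = bags, omics = omics, geneSets = gsc,
        outcome = outcome, task = config$task,
        truth = list(signal_region = config$signal_region,
                     signal_pathway = config$signal_pathway,
                     region_activity = u, pathway_factor = f, score = eta,
                     config = config))
  })
}

#' Write a cohort to disk in the formats the pipeline reads
#'
#' Emits one patch table per slide (`patches/<id>.tsv`, columns `x`, `y`,
#' `f0..f{d-1}`), one TSV per omics source (samples x genes, `sample_id`
#' first), a GMT gene-set file, the outcome TSV and a JSON manifest listing
#' every file together with the generator seed.
#'
#' @param cohort a [MultiModalCohort-class].
#' @param directory output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
writeCohort <- function(cohort, directory) {
  dir.create(file.path(directory, "patches"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(directory))
    stop("cannot create output directory: ", directory)

  patch_files <- character(0)
  for (bag in cohort@patchBags) {
    tab <- cbind(bag@coords, bag@features)
    colnames(tab) <- c("x", "y", sprintf("f%d", seq_len(ncol(bag@features)) - 1L))
    fp <- file.path("patches", paste0(bag@slideId, ".tsv"))
    .write_numeric_tsv(tab, file.path(directory, fp), rownames_as = NULL)
    patch_files <- c(patch_files, fp)
  }

  omics_files <- character(0)
  for (s in names(cohort@omics)) {
    fp <- paste0("omics_", s, ".tsv")
    .write_numeric_tsv(cohort@omics[[s]], file.path(directory, fp),
                       rownames_as = "sample_id")
    omics_files <- c(omics_files, fp)
  }

  gmt <- "gene_sets.gmt"
  writeGMT(cohort@geneSets, file.path(directory, gmt))

  outc <- "outcome.tsv"
  utils::write.table(cohort@outcome, file.path(directory, outc),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  seed <- if (length(cohort@truth)) cohort@truth$config$seed else NA
  manifest <- list(format_version = "1.0",
                   n_patients = nrow(cohort@outcome),
                   task = cohort@task,
                   seed = seed,
                   sample_ids = cohort@outcome$sample_id,
                   files = list(patches = patch_files, omics = omics_files,
                                gene_sets = gmt, outcome = outc))
  mf <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

# Write a numeric matrix as TSV at full double precision (17 significant
# digits) so that write -> read round-trips exactly.
.write_numeric_tsv <- function(mat, path, rownames_as = "sample_id") {
  con <- file(path, "w")
  on.exit(close(con))
  header <- colnames(mat)
  if (!is.null(rownames_as)) header <- c(rownames_as, header)
  writeLines(paste(header, collapse = "\t"), con)
  body <- apply(mat, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  if (!is.null(rownames_as)) body <- paste(rownames(mat), body, sep = "\t")
  writeLines(body, con)
}
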