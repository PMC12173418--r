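# Multi-task heads and losses (categorical cross-entropy; Cox negative
# partial log-likelihood with Breslow ties), stratified 60-20-20 splitting,
# and the multiphase trainer: phase 1 pretrains the WSI hypergraph
# autoencoder and the pathway VAEs unsupervised, phase 2 unfreezes the
# central encoders and optimizes the fusion / mixture-of-experts / task head
# under modality dropout.

#' Training configuration
#'
#' @param task `"classification"` or `"survival"`.
#' @param n_regions K, spatial regions per slide.
#' @param zdim shared embedding dimension.
#' @param rank factor rank of the bilinear fusion.
#' @param gate_hidden hidden width of the gating networks.
#' @param hidden sub-encoder widths of the pathway VAEs.
#' @param phase1_epochs unsupervised epochs for the pathway VAEs.
#' @param wsi_epochs unsupervised epochs for the WSI autoencoder.
#' @param phase2_epochs supervised epochs.
#' @param lr Adam learning rate.
#' @param weight_decay decoupled (AdamW-style) weight decay on the
#'   supervised-phase parameters.
#' @param central_lr_scale learning-rate multiplier for the pretrained
#'   central encoders during fine-tuning.
#' @param batch_size supervised minibatch size (>= 2 for survival).
#' @param dropout network dropout rate on hidden layers.
#' @param modality_dropout per-modality drop probability during training.
#' @param beta KL weight of the VAE loss (linear warm-up over `beta_warmup`
#'   epochs).
#' @param beta_warmup warm-up epochs for `beta`.
#' @param aux_weight weight of the auxiliary VAE loss during phase 2.
#' @param pw_loss_weight weight of the pathway-specific prediction loss (the
#'   per-pathway linear predictions are trained against the task, which
#'   drives the gating to identify informative pathways and regions).
#' @param delta_c,delta_h,lambda_h,lambda_g patch kernel parameters (see
#'   [kernelParams()]).
#' @param wsi_layers hypergraph convolution layers.
#' @param shared_gate share one phase-1 gating network across pathways
#'   (default FALSE: per-pathway gates).
#' @param fused_bn batch-normalize each fused block before gating.
#' @param phase2_sample use reparameterized latent samples (TRUE) or the
#'   latent mean (FALSE) during supervised fine-tuning.
#' @param patience early-stopping patience on the validation loss.
#' @param fold which of the 5 stratified folds to train on.
#' @param chrom_maps optional named list (per source) of gene -> chromosome
#'   maps enabling the block-sparse first layer.
#' @param seed master RNG seed; all internal seeds derive from it.
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(task = c("classification", "survival"),
                        n_regions = 4, zdim = 32, rank = 4, gate_hidden = 16,
                        hidden = c(128, 64), phase1_epochs = 30,
                        wsi_epochs = 8, phase2_epochs = 100, lr = 3e-3,
                        weight_decay = 1e-3, central_lr_scale = 0.1,
                        batch_size = 256, dropout = 0,
                        modality_dropout = 0.4, beta = 0.01, beta_warmup = 10,
                        aux_weight = 0.1, pw_loss_weight = 0.3,
                        delta_c = 0.9, delta_h = 0.5,
                        lambda_h = NULL, lambda_g = NULL, wsi_layers = 2,
                        shared_gate = FALSE, fused_bn = TRUE,
                        phase2_sample = FALSE, patience = 10, fold = 1,
                        chrom_maps = NULL, seed = 1) {
  cfg <- list(task = match.arg(task), n_regions = n_regions, zdim = zdim,
              rank = rank, gate_hidden = gate_hidden, hidden = hidden,
              phase1_epochs = phase1_epochs, wsi_epochs = wsi_epochs,
              phase2_epochs = phase2_epochs, lr = lr,
              weight_decay = weight_decay, central_lr_scale = central_lr_scale,
              batch_size = batch_size,
              dropout = dropout, modality_dropout = modality_dropout,
              beta = beta, beta_warmup = beta_warmup,
              aux_weight = aux_weight, pw_loss_weight = pw_loss_weight,
              delta_c = delta_c, delta_h = delta_h,
              lambda_h = lambda_h, lambda_g = lambda_g,
              wsi_layers = wsi_layers, shared_gate = shared_gate,
              fused_bn = fused_bn, phase2_sample = phase2_sample,
              patience = patience, fold = fold,
              chrom_maps = chrom_maps, seed = seed)
  for (f in c("phase1_epochs", "wsi_epochs", "phase2_epochs"))
    if (cfg[[f]] < 0) stop(f, " must be >= 0")
  if (cfg$task == "survival" && cfg$batch_size < 2)
    stop("batch_size must be >= 2 for survival (risk sets need pairs)")
  if (cfg$modality_dropout < 0 || cfg$modality_dropout >= 1)
    stop("modality_dropout must lie in [0, 1)")
  class(cfg) <- "TrainConfig"
  cfg
}

#' Mean categorical cross-entropy
#'
#' @param logits n x C matrix of class scores.
#' @param labels integer class ids in `1..C` or a factor.
#' @return scalar loss.
#' @export
classificationLoss <- function(logits, labels) {
  if (is.factor(labels)) labels <- as.integer(labels)
  C <- ncol(logits)
  if (any(labels < 1 | labels > C)) stop("label out of range 1..", C)
  m <- apply(logits, 1L, max)
  lse <- log(rowSums(exp(logits - m))) + m
  mean(lse - logits[cbind(seq_along(labels), labels)])
}

# Breslow risk-set ingredients: for each event i, the risk set is every
# patient j with T_j >= T_i (tied times share the full tied risk set)
.cox_ingredients <- function(time, event) {
  ev <- which(event == 1)
  if (!length(ev)) stop("batch with zero events: partial likelihood undefined")
  R <- outer(time[ev], time, function(ti, tj) as.numeric(tj >= ti))
  list(ev = ev, R = R)
}

#' Cox negative partial log-likelihood
#'
#' `L = -sum_{i: E_i = 1} (r_i - log sum_{j: T_j >= T_i} exp(r_j))` with the
#' Breslow convention for tied event times and a log-sum-exp stabilized
#' inner sum. Invariant to adding a constant to all risks.
#'
#' @param risks numeric risk scores, one per patient.
#' @param time follow-up times.
#' @param event event indicators (1 = event).
#' @return scalar loss (a sum over events, not a mean).
#' @export
survivalLoss <- function(risks, time, event) {
  stopifnot(length(risks) == length(time), length(time) == length(event))
  ci <- .cox_ingredients(time, event)
  m <- max(risks)
  lse <- log(as.numeric(ci$R %*% exp(risks - m))) + m
  sum(lse - risks[ci$ev])
}

# tape versions ---------------------------------------------------------------

.ce_loss_fwd <- function(tape, logits, labels) {
  n <- nrow(logits$value)
  Y <- matrix(0, n, ncol(logits$value))
  Y[cbind(seq_len(n), labels)] <- 1
  lse <- td_logsumexp_rows(logits)
  td_scale(td_sub(td_sum(lse), td_sum(td_mul(td_const(tape, Y), logits))),
           1 / n)
}

.cox_loss_fwd <- function(tape, risks, time, event, mean_scale = TRUE) {
  ci <- .cox_ingredients(time, event)
  m <- max(risks$value)
  er <- td_exp(td_addc(risks, -m))
  lse <- td_addc(td_log(td_matmul(td_const(tape, ci$R), er)), m)
  sel <- matrix(0, length(ci$ev), length(time))
  sel[cbind(seq_along(ci$ev), ci$ev)] <- 1
  loss <- td_sum(td_sub(lse, td_matmul(td_const(tape, sel), risks)))
  if (mean_scale) td_scale(loss, 1 / length(ci$ev)) else loss
}

#' Stratified 5-fold 60-20-20 split plan
#'
#' Each stratum is shuffled once and divided into 5 near-equal parts; fold f
#' uses part f as the test set, the next part as validation and the remaining
#' three as training, so test sets are disjoint across folds, every fold is
#' a 60-20-20 partition, and stratum proportions are preserved.
#'
#' @param strata factor (class label, or event indicator for survival).
#' @param seed RNG seed.
#' @param n_folds number of folds.
#' @return list of class `SplitPlan` with `folds` (each `train`/`val`/`test`
#'   index vectors) and `strata`.
#' @export
makeSplits <- function(strata, seed = 1, n_folds = 5) {
  strata <- as.factor(strata)
  small <- names(which(table(strata) < n_folds))
  if (length(small))
    stop("stratum too small for ", n_folds, "-fold splitting: ",
         paste(small, collapse = ", "))
  parts <- vector("list", n_folds)
  with_seed(seed, {
    for (lev in levels(strata)) {
      idx <- sample(which(strata == lev))
      grp <- rep(seq_len(n_folds), length.out = length(idx))
      for (f in seq_len(n_folds))
        parts[[f]] <- c(parts[[f]], idx[grp == f])
    }
  })
  folds <- lapply(seq_len(n_folds), function(f) {
    v <- f %% n_folds + 1L
    list(test = sort(parts[[f]]), val = sort(parts[[v]]),
         train = sort(unlist(parts[setdiff(seq_len(n_folds), c(f, v))])))
  })
  structure(list(folds = folds, strata = strata), class = "SplitPlan")
}

## ---- WSI preparation --------------------------------------------------------

.wsi_structures <- function(cohort, config) {
  kp <- kernelParams(config$lambda_h, config$lambda_g,
                     config$delta_c, config$delta_h)
  lapply(patchBags(cohort), function(bag) {
    merged <- mergePatches(bag, kp)
    hg <- buildHypergraph(merged, kp)
    list(merged = merged, hg = hg)
  })
}

# K-means centroids fitted once on the merged patches of the training slides,
# so region ids carry the same (morphological) meaning for every patient;
# per-slide assignment is nearest-centroid in the standardized feature space.
.fit_region_centroids <- function(structs, train_idx, K, seed = 1) {
  reps <- do.call(rbind, lapply(structs[train_idx], function(s) s$merged$reps))
  mu <- colMeans(reps)
  sd <- apply(reps, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  Z <- sweep(sweep(reps, 2L, mu, "-"), 2L, sd, "/")
  km <- with_seed(seed, stats::kmeans(Z, centers = K, nstart = 10,
                                      iter.max = 50))
  list(centers = km$centers, mean = mu, sd = sd, K = K)
}

.assign_regions_global <- function(merged, centroids) {
  Z <- sweep(sweep(merged$reps, 2L, centroids$mean, "-"),
             2L, centroids$sd, "/")
  d2 <- outer(rowSums(Z^2), rowSums(centroids$centers^2), "+") -
    2 * Z %*% t(centroids$centers)
  max.col(-d2, ties.method = "first")
}

.wsi_embed_all <- function(structs, enc, K, centroids) {
  n <- length(structs)
  Xk <- array(0, c(n, K, enc$zdim), dimnames = list(names(structs), NULL, NULL))
  mask <- matrix(0, n, K, dimnames = list(names(structs), NULL))
  for (i in seq_len(n)) {
    st <- structs[[i]]
    regions <- .assign_regions_global(st$merged, centroids)
    emb <- encodeRegions(st$merged, st$hg, enc, K, regions = regions)
    Xk[i, , ] <- emb
    mask[i, ] <- as.numeric(attr(emb, "region_mask"))
  }
  list(Xk = Xk, mask = mask)
}

## ---- omics preparation ------------------------------------------------------

.fit_scalers <- function(sources, rows) {
  lapply(sources, function(m) {
    mu <- colMeans(m[rows, , drop = FALSE])
    sd <- apply(m[rows, , drop = FALSE], 2L, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    list(mean = mu, sd = sd)
  })
}

.apply_scalers <- function(sources, scalers) {
  out <- lapply(names(sources), function(s)
    sweep(sweep(sources[[s]], 2L, scalers[[s]]$mean, "-"),
          2L, scalers[[s]]$sd, "/"))
  names(out) <- names(sources)
  out
}

## ---- supervised forward -----------------------------------------------------

# One supervised forward pass on the tape. `data` carries, for the batch:
#   Xk: n x K x zdim array (WSI dropout already applied)
#   region_mask: n x K numeric (1 = populated)
#   blocks: blocks[[source]][[pathway]] matrices, or nodes when
#           `input_nodes` supplies whole-source matrices for attribution
#   source_scale: n x S omics-source dropout scales (NULL = ones)
# Returns prediction node, gating weight nodes and VAE pieces for the
# auxiliary loss.
.supervised_fwd <- function(tape, st, data, train = FALSE, sample = FALSE,
                            with_aux = FALSE) {
  K <- dim(data$Xk)[2]
  P <- length(st$omics_encoders)
  n_b <- dim(data$Xk)[1]
  ones <- matrix(1, n_b, 1L)
  # homogeneous-coordinate lift [x, 1]: first-order terms survive the pure
  # bilinear map, and a dropped modality ([0, 1]) leaves the other side's
  # linear features in the fused block
  xa <- lapply(seq_len(K), function(k)
    .fuse_project(tape, st$fusion$U,
                  td_const(tape, cbind(matrix(data$Xk[, k, ], n_b), ones))))
  enc_out <- vector("list", P)
  fused <- lapply(seq_len(K), function(k) vector("list", P))
  for (p in seq_len(P)) {
    bp <- lapply(data$blocks, function(b) b[[p]])
    eo <- .encode_pathway_fwd(tape, st$omics_encoders[[p]], bp,
                              train = FALSE, source_scale = data$source_scale,
                              sample = sample)
    enc_out[[p]] <- eo
    ob <- .fuse_project(tape, st$fusion$V,
                        td_cbind(list(eo$z, td_const(tape, ones))))
    for (k in seq_len(K)) {
      z <- .fuse_pair_fwd(tape, st$fusion, xa[[k]], ob)
      # optional batch norm per fused block: after L2 normalization the
      # across-sample variation is small against the block's mean direction,
      # and the gates/head need it on a unit scale
      if (!is.null(st$fused_bn))
        z <- nn_batchnorm_fwd(tape, st$fused_bn[[k]][[p]], z, train)
      fused[[k]][[p]] <- z
    }
  }
  moe1 <- .moe_phase1_fwd(tape, st$gates, fused, data$region_mask, train)
  moe2 <- .moe_phase2_fwd(tape, st$gates, moe1$z, train, st$pw_head)
  pred <- nn_linear_fwd(tape, st$task_head, moe2$z)
  aux <- NULL
  if (with_aux) {
    aux <- lapply(seq_len(P), function(p) {
      rec <- .decode_pathway_fwd(tape, st$omics_encoders[[p]],
                                 enc_out[[p]]$z, train = FALSE)
      list(rec = rec, mu = enc_out[[p]]$mu, logvar = enc_out[[p]]$logvar,
           target = lapply(data$blocks, function(b) b[[p]]))
    })
  }
  list(pred = pred, w1 = moe1$w, w2 = moe2$w, z = moe2$z, aux = aux,
       pathway_preds = moe2$pathway_preds)
}

.phase2_params <- function(st, central_lr_scale = 1) {
  central <- unlist(lapply(st$omics_encoders, function(pe)
    c(nn_params(pe$mu_head), nn_params(pe$logvar_head))))
  for (pe in central) pe$lr_scale <- central_lr_scale
  c(central,
    list(st$fusion$U, st$fusion$V),
    nn_params(st$fused_bn),
    nn_params(st$gates), nn_params(st$task_head), nn_params(st$pw_head))
}

.batch_blocks <- function(blocks, rows) {
  lapply(blocks, function(b) lapply(b, function(m) m[rows, , drop = FALSE]))
}

.task_loss_fwd <- function(tape, cfg, pred, outc, rows) {
  if (cfg$task == "classification") {
    .ce_loss_fwd(tape, pred, outc$y[rows])
  } else {
    .cox_loss_fwd(tape, pred, outc$time[rows], outc$event[rows])
  }
}

## ---- trainer ----------------------------------------------------------------

#' Train the multimodal mixture-of-experts model
#'
#' Phase 1 pretrains the WSI hypergraph autoencoder and the per-pathway
#' multi-source VAEs unsupervised on the training split. Phase 2 freezes the
#' sub-encoders and the WSI encoder, unfreezes the central (mu / log-variance)
#' encoders and trains fusion, gating and task head on the supervised
#' objective plus `aux_weight` times the VAE losses, under modality dropout,
#' with early stopping on the validation loss.
#'
#' @param cohort a [MultiModalCohort-class].
#' @param config a [trainConfig()]; its task must match the cohort's.
#' @return A [MoEModel-class].
#' @export
trainModel <- function(cohort, config = trainConfig(cohortTask(cohort))) {
  stopifnot(is(cohort, "MultiModalCohort"))
  if (config$task != cohortTask(cohort))
    stop("config task '", config$task, "' does not match cohort task '",
         cohortTask(cohort), "'")
  outcome <- cohortOutcome(cohort)
  n <- nrow(outcome)
  sets <- cohort@geneSets
  sources <- cohort@omics
  K <- config$n_regions

  outc <- list()
  if (config$task == "classification") {
    lv <- sort(unique(outcome$label))
    outc$levels <- lv
    outc$y <- match(outcome$label, lv)
  } else {
    outc$time <- outcome$time
    outc$event <- outcome$event
  }
  strata <- if (config$task == "classification") factor(outcome$label)
            else factor(outcome$event)
  splits <- makeSplits(strata, seed = config$seed)
  fold <- splits$folds[[config$fold]]
  if (config$task == "survival" && sum(outc$event[fold$train]) == 0)
    stop("all-censored training set: survival loss undefined")

  with_seed(config$seed, {
    ## ---- phase 1: WSI ----
    structs <- .wsi_structures(cohort, config)
    feat_dim <- ncol(patchFeatures(patchBags(cohort)[[1]]))
    wsi_enc <- newWsiEncoder(feat_dim, zdim = config$zdim,
                             L = config$wsi_layers, seed = config$seed + 11L)
    wsi_hist <- NULL
    if (config$wsi_epochs > 0) {
      ph1 <- .train_wsi_phase1(wsi_enc, structs[fold$train],
                               epochs = config$wsi_epochs, lr = config$lr,
                               seed = config$seed + 12L)
      wsi_hist <- ph1$loss
    }
    centroids <- .fit_region_centroids(structs, fold$train, K,
                                       seed = config$seed + 19L)
    emb <- .wsi_embed_all(structs, wsi_enc, K, centroids)

    ## ---- phase 1: omics VAEs ----
    scalers <- .fit_scalers(sources, fold$train)
    std <- .apply_scalers(sources, scalers)
    blocks <- partitionByPathway(std, sets)
    encs <- .new_pathway_encoders(blocks, sets, zdim = config$zdim,
                                  hidden = config$hidden, use_bn = TRUE,
                                  dropout = config$dropout,
                                  chrom_maps = config$chrom_maps,
                                  seed = config$seed + 13L)
    om_hist <- NULL
    if (config$phase1_epochs > 0) {
      ph1o <- .train_omics_phase1(encs, blocks, sets,
                                  epochs = config$phase1_epochs,
                                  lr = config$lr, beta = config$beta,
                                  beta_warmup = config$beta_warmup,
                                  modality_dropout = config$modality_dropout,
                                  seed = config$seed + 14L,
                                  train_rows = fold$train,
                                  val_rows = fold$val)
      om_hist <- ph1o$history
    }

    ## ---- phase 2: supervised ----
    C_out <- if (config$task == "classification") length(outc$levels) else 1L
    st <- list(omics_encoders = encs,
               fusion = newFusion(config$zdim, config$rank,
                                  in_dim = config$zdim + 1L,
                                  init = "passthrough",
                                  seed = config$seed + 15L),
               gates = newMoEGates(config$zdim, config$gate_hidden,
                                   P = length(geneSets(sets)),
                                   shared = isTRUE(config$shared_gate),
                                   seed = config$seed + 16L),
               fused_bn = if (isTRUE(config$fused_bn))
                 lapply(seq_len(K), function(k)
                   lapply(seq_along(geneSets(sets)), function(p)
                     nn_batchnorm(config$zdim, sprintf("fbn.%d.%d", k, p)))),
               task_head = with_seed(config$seed + 17L,
                                     nn_linear(config$zdim, C_out, "head")),
               pw_head = with_seed(config$seed + 18L,
                                   nn_linear(config$zdim, C_out, "pw_head")))
    params <- .phase2_params(st, config$central_lr_scale)
    opt <- adam_new(params, lr = config$lr,
                    weight_decay = config$weight_decay)
    mods <- c("wsi", names(sources))
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))

    eval_loss <- function(rows) {
      tape <- td_tape()
      data <- list(Xk = emb$Xk[rows, , , drop = FALSE],
                   region_mask = emb$mask[rows, , drop = FALSE],
                   blocks = .batch_blocks(blocks, rows), source_scale = NULL)
      fw <- .supervised_fwd(tape, st, data, train = FALSE, sample = FALSE)
      as.numeric(.task_loss_fwd(tape, config, fw$pred, outc, rows)$value)
    }

    best <- list(val = Inf, params = NULL, epoch = 0L)
    wait <- 0L
    for (ep in seq_len(config$phase2_epochs)) {
      # cosine learning-rate decay over the supervised phase
      opt$lr <- config$lr * 0.5 * (1 + cos(pi * (ep - 1) / config$phase2_epochs))
      ord <- sample(fold$train)
      nb <- ceiling(length(ord) / config$batch_size)
      ep_loss <- 0; ep_n <- 0
      for (b in seq_len(nb)) {
        rows <- ord[((b - 1L) * config$batch_size + 1L):
                      min(b * config$batch_size, length(ord))]
        if (config$task == "survival" && sum(outc$event[rows]) == 0) next
        keep <- if (config$modality_dropout > 0)
          .dropout_mask(length(rows), mods, config$modality_dropout)
        else matrix(1, length(rows), length(mods),
                    dimnames = list(NULL, mods))
        resc <- 1 / (1 - config$modality_dropout)
        Xk_b <- emb$Xk[rows, , , drop = FALSE] * (keep[, "wsi"] * resc)
        src_scale <- keep[, names(sources), drop = FALSE] * resc

        tape <- td_tape()
        data <- list(Xk = Xk_b,
                     region_mask = emb$mask[rows, , drop = FALSE],
                     blocks = .batch_blocks(blocks, rows),
                     source_scale = src_scale)
        # supervised fine-tuning conditions on the latent mean: the posterior
        # sd after pretraining is of the order of the embedding spread, and
        # sampling would drown the task gradient at desk-scale n
        fw <- .supervised_fwd(tape, st, data, train = TRUE,
                              sample = isTRUE(config$phase2_sample),
                              with_aux = config$aux_weight > 0)
        loss <- .task_loss_fwd(tape, config, fw$pred, outc, rows)
        if (config$pw_loss_weight > 0) {
          for (pp in fw$pathway_preds)
            loss <- td_add(loss, td_scale(
              .task_loss_fwd(tape, config, pp, outc, rows),
              config$pw_loss_weight / length(fw$pathway_preds)))
        }
        if (!is.null(fw$aux)) {
          for (ax in fw$aux) {
            vl <- .vae_loss_fwd(tape, ax$rec, ax$target, ax$mu, ax$logvar,
                                config$beta)
            loss <- td_add(loss, td_scale(vl, config$aux_weight))
          }
        }
        td_backward(loss)
        adam_step(opt)
        ep_loss <- ep_loss + as.numeric(loss$value) * length(rows)
        ep_n <- ep_n + length(rows)
      }
      vl <- eval_loss(fold$val)
      history <- rbind(history,
                       data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                  val_loss = vl))
      if (vl < best$val - 1e-6) {
        best <- list(val = vl, params = lapply(params, function(pe) pe$value),
                     epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
    if (!is.null(best$params))
      for (i in seq_along(params)) params[[i]]$value <- best$params[[i]]

    meta <- list(task = config$task, class_levels = outc$levels,
                 pathways = names(geneSets(sets)),
                 sources = names(sources),
                 feat_dim = feat_dim,
                 block_cols = lapply(std, function(m)
                   lapply(geneSets(sets), function(g)
                     match(intersect(g, colnames(m)), colnames(m)))),
                 best_epoch = best$epoch)
    new("MoEModel",
        state = c(st, list(wsi_encoder = wsi_enc, scalers = scalers,
                           region_centroids = centroids, wsi_cache = emb,
                           cache_ids = outcome$sample_id,
                           phase1 = list(wsi = wsi_hist, omics = om_hist))),
        config = unclass(config), history = history,
        split = fold, meta = meta)
  })
}

## ---- prediction -------------------------------------------------------------

#' Predict with a trained model
#'
#' Runs the deterministic (eval-mode) forward pass: latent means instead of
#' samples, no dropout. Modalities listed in `missing` are removed the way
#' genuinely absent data are handled at inference: the WSI region embeddings
#' are zeroed, omics sources are masked to a zero sub-embedding without
#' rescaling.
#'
#' @param model a [MoEModel-class].
#' @param cohort the cohort to predict on.
#' @param rows integer indices of the samples to predict (default: all).
#' @param missing character vector among `c("wsi", <source names>)`.
#' @return list with `scores` (class probabilities or risk vector), `gating`
#'   (list: `region_weights` n x K x P, `pathway_weights` n x P),
#'   `embeddings` (n x zdim) and `sample_ids`.
#' @export
predictModel <- function(model, cohort, rows = NULL, missing = character(0)) {
  stopifnot(is(model, "MoEModel"))
  ids <- sampleIds(cohort)
  if (is.null(rows)) rows <- seq_along(ids)
  cfg <- model@config
  st <- model@state
  bad <- setdiff(missing, c("wsi", model@meta$sources))
  if (length(bad)) stop("unknown modality in `missing`: ",
                        paste(bad, collapse = ", "))

  # WSI embeddings: cached when the cohort matches the training cohort
  if ("wsi" %in% missing) {
    Xk <- array(0, c(length(rows), cfg$n_regions, cfg$zdim))
    mask <- matrix(1, length(rows), cfg$n_regions)
  } else if (all(ids[rows] %in% st$cache_ids)) {
    sel <- match(ids[rows], st$cache_ids)
    Xk <- st$wsi_cache$Xk[sel, , , drop = FALSE]
    mask <- st$wsi_cache$mask[sel, , drop = FALSE]
  } else {
    structs <- .wsi_structures(cohort, cfg)[rows]
    emb <- .wsi_embed_all(structs, st$wsi_encoder, cfg$n_regions,
                          st$region_centroids)
    Xk <- emb$Xk; mask <- emb$mask
  }

  std <- .apply_scalers(cohort@omics[model@meta$sources], st$scalers)
  blocks <- .batch_blocks(partitionByPathway(std, cohort@geneSets), rows)
  src_scale <- matrix(1, length(rows), length(model@meta$sources),
                      dimnames = list(NULL, model@meta$sources))
  for (s in intersect(missing, model@meta$sources)) src_scale[, s] <- 0

  tape <- td_tape()
  data <- list(Xk = Xk, region_mask = mask, blocks = blocks,
               source_scale = src_scale)
  fw <- .supervised_fwd(tape, st, data, train = FALSE, sample = FALSE)

  P <- length(model@meta$pathways)
  K <- cfg$n_regions
  w1 <- array(0, c(length(rows), K, P),
              dimnames = list(ids[rows], NULL, model@meta$pathways))
  for (p in seq_len(P)) w1[, , p] <- fw$w1[[p]]$value
  scores <- if (cfg$task == "classification") {
    pr <- exp(fw$pred$value - apply(fw$pred$value, 1L, max))
    pr <- pr / rowSums(pr)
    colnames(pr) <- model@meta$class_levels
    rownames(pr) <- ids[rows]
    pr
  } else {
    stats::setNames(as.numeric(fw$pred$value), ids[rows])
  }
  list(scores = scores,
       gating = list(region_weights = w1,
                     pathway_weights = {
                       w2 <- fw$w2$value
                       dimnames(w2) <- list(ids[rows], model@meta$pathways)
                       w2
                     }),
       embeddings = fw$z$value,
       sample_ids = ids[rows])
}
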