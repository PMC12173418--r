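#' Bag of patch features for one whole-slide image
#'
#' A `PatchBag` holds the fixed-length feature vectors and spatial centers of
#' the tissue patches extracted from one slide. Feature extraction itself
#' (tiling, tissue masking, the pretrained patch encoder) is upstream of this
#' package: any fixed feature dimension is accepted. Coordinates are patch
#' centers in pixel units at the extraction magnification, x = column,
#' y = row.
#'
#' @slot features numeric matrix, one row per patch (`np x d`).
#' @slot coords numeric matrix, `np x 2`, columns x and y.
#' @slot slideId character scalar identifier.
#'
#' @examples
#' bag <- PatchBag(matrix(rnorm(20), 5), matrix(runif(10, 0, 100), 5), "s1")
#' nPatches(bag)
#' @export
setClass("PatchBag",
  representation(features = "matrix", coords = "matrix", slideId = "character"))

setValidity("PatchBag", function(object) {
  msg <- character(0)
  if (nrow(object@features) < 1L) msg <- c(msg, "need at least one patch")
  if (!all(is.finite(object@features))) msg <- c(msg, "non-finite feature values")
  if (!all(is.finite(object@coords))) msg <- c(msg, "non-finite coordinates")
  if (ncol(object@coords) != 2L) msg <- c(msg, "coords must have 2 columns")
  if (nrow(object@coords) != nrow(object@features))
    msg <- c(msg, "coords and features must be row-aligned")
  if (length(object@slideId) != 1L) msg <- c(msg, "slideId must be a scalar")
  if (length(msg)) msg else TRUE
})

#' Construct a PatchBag
#' @param features numeric matrix, one row per patch.
#' @param coords numeric matrix of patch centers, columns x and y.
#' @param slideId character scalar.
#' @return A [PatchBag-class] object.
#' @export
PatchBag <- function(features, coords, slideId) {
  new("PatchBag", features = as.matrix(features), coords = as.matrix(coords),
      slideId = as.character(slideId))
}

#' Named collection of gene sets
#'
#' Ordered pathways, each a character vector of gene identifiers. Genes may
#' belong to several pathways (overlapping collections such as the MSigDB
#' Hallmarks are the norm); each membership is kept.
#'
#' @slot sets named list of character vectors, one per pathway.
#' @export
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  if (length(object@sets) < 1L) msg <- c(msg, "need at least one gene set")
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "gene sets must have unique names")
  if (any(vapply(object@sets, length, 1L) < 1L))
    msg <- c(msg, "every gene set must be nonempty")
  if (length(msg)) msg else TRUE
})

#' Construct a gene-set collection
#' @param sets named list of character vectors (pathway -> genes). Duplicate
#'   genes within one set are removed.
#' @return A [GeneSetCollection-class] object.
#' @export
GeneSetCollection <- function(sets) {
  new("GeneSetCollection", sets = lapply(sets, unique))
}

#' Multimodal cohort: patch bags, omics matrices, gene sets and outcomes
#'
#' The in-memory container the pipeline trains on. One patch bag and one row
#' per omics source per patient; the outcome table carries either a class
#' label or a (time, event) pair per patient.
#'
#' @slot patchBags list of [PatchBag-class], named by sample id.
#' @slot omics named list of samples x genes matrices, one per omics source.
#' @slot geneSets a [GeneSetCollection-class].
#' @slot outcome data.frame with `sample_id` plus `label` (classification) or
#'   `time`, `event` (survival).
#' @slot task `"classification"` or `"survival"`.
#' @slot truth list; for synthetic cohorts, the planted-signal record
#'   (empty for cohorts read from disk).
#' @export
setClass("MultiModalCohort",
  representation(patchBags = "list", omics = "list",
                 geneSets = "GeneSetCollection", outcome = "data.frame",
                 task = "character", truth = "list"))

setValidity("MultiModalCohort", function(object) {
  msg <- character(0)
  ids <- object@outcome$sample_id
  if (is.null(ids)) return("outcome must contain a sample_id column")
  if (anyDuplicated(ids)) msg <- c(msg, "duplicate sample ids in outcome")
  if (!setequal(names(object@patchBags), ids))
    msg <- c(msg, "patch bags must match outcome sample ids")
  for (s in names(object@omics)) {
    if (!setequal(rownames(object@omics[[s]]), ids))
      msg <- c(msg, sprintf("omics source '%s' rows must match sample ids", s))
  }
  if (!object@task %in% c("classification", "survival"))
    msg <- c(msg, "task must be 'classification' or 'survival'")
  if (object@task == "survival") {
    if (!all(c("time", "event") %in% names(object@outcome)))
      msg <- c(msg, "survival outcome needs time and event columns")
    else {
      if (any(object@outcome$time <= 0)) msg <- c(msg, "times must be > 0")
      if (!all(object@outcome$event %in% c(0, 1)))
        msg <- c(msg, "event must be 0 or 1")
    }
  } else if (!"label" %in% names(object@outcome)) {
    msg <- c(msg, "classification outcome needs a label column")
  }
  if (length(msg)) msg else TRUE
})

#' Trained multimodal mixture-of-experts model
#'
#' Wraps the learned state of the whole pipeline: the hypergraph WSI encoder,
#' the per-pathway multi-source variational autoencoders, the factorized
#' bilinear fusion and the two-phase gating networks, plus the training
#' history and the data split used.
#'
#' @slot state list of module states (parameter environments).
#' @slot config the training configuration (see [trainConfig()]).
#' @slot history data.frame of per-epoch losses.
#' @slot split list with train / val / test index vectors.
#' @slot meta list: task, class levels, gene/pathway bookkeeping, seeds.
#' @export
setClass("MoEModel",
  representation(state = "list", config = "list", history = "data.frame",
                 split = "list", meta = "list"))

#' Interpretation report: gene, pathway and interaction scores
#'
#' @slot geneTable data.frame with per-patient, per-(gene, source, pathway)
#'   SHAP values and pathway-normalized values.
#' @slot pathwayTable data.frame with mean gating weight, KS statistic and
#'   (adjusted) enrichment p-value per pathway.
#' @slot mis cohort-mean region x pathway interaction matrix; per-patient
#'   matrices in `misByPatient`.
#' @slot misByPatient list of per-patient K x P matrices.
#' @slot meta list (task, model hash, cohort id).
#' @export
setClass("InterpretationReport",
  representation(geneTable = "data.frame", pathwayTable = "data.frame",
                 mis = "matrix", misByPatient = "list", meta = "list"))
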