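#' @include AllClasses.R
NULL

#' Accessors for pathMoE classes
#'
#' Small generics to read the central containers without touching slots:
#' patch features and coordinates, gene-set membership, omics matrices,
#' outcome tables and training history.
#'
#' @param x a pathMoE object.
#' @param name for `omicsSource`, the source to extract.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("patchFeatures", function(x) standardGeneric("patchFeatures"))
#' @rdname accessors
#' @export
setMethod("patchFeatures", "PatchBag", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("patchCoords", function(x) standardGeneric("patchCoords"))
#' @rdname accessors
#' @export
setMethod("patchCoords", "PatchBag", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("slideId", function(x) standardGeneric("slideId"))
#' @rdname accessors
#' @export
setMethod("slideId", "PatchBag", function(x) x@slideId)

#' @rdname accessors
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))
#' @rdname accessors
#' @export
setMethod("nPatches", "PatchBag", function(x) nrow(x@features))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
#' @rdname accessors
#' @export
setMethod("geneSets", "MultiModalCohort", function(x) x@geneSets@sets)

#' @rdname accessors
#' @export
setGeneric("nPathways", function(x) standardGeneric("nPathways"))
#' @rdname accessors
#' @export
setMethod("nPathways", "GeneSetCollection", function(x) length(x@sets))
#' @rdname accessors
#' @export
setMethod("nPathways", "MultiModalCohort", function(x) length(x@geneSets@sets))

#' @rdname accessors
#' @export
setGeneric("patchBags", function(x) standardGeneric("patchBags"))
#' @rdname accessors
#' @export
setMethod("patchBags", "MultiModalCohort", function(x) x@patchBags)

#' @rdname accessors
#' @export
setGeneric("omicsSources", function(x) standardGeneric("omicsSources"))
#' @rdname accessors
#' @export
setMethod("omicsSources", "MultiModalCohort", function(x) names(x@omics))

#' @rdname accessors
#' @export
setGeneric("omicsSource", function(x, name) standardGeneric("omicsSource"))
#' @rdname accessors
#' @export
setMethod("omicsSource", "MultiModalCohort", function(x, name) {
  if (!name %in% names(x@omics)) stop("unknown omics source: ", name)
  x@omics[[name]]
})

#' @rdname accessors
#' @export
setGeneric("cohortOutcome", function(x) standardGeneric("cohortOutcome"))
#' @rdname accessors
#' @export
setMethod("cohortOutcome", "MultiModalCohort", function(x) x@outcome)

#' @rdname accessors
#' @export
setGeneric("cohortTask", function(x) standardGeneric("cohortTask"))
#' @rdname accessors
#' @export
setMethod("cohortTask", "MultiModalCohort", function(x) x@task)

#' @rdname accessors
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))
#' @rdname accessors
#' @export
setMethod("plantedTruth", "MultiModalCohort", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "MultiModalCohort", function(x) x@outcome$sample_id)

#' @rdname accessors
#' @export
setGeneric("trainHistory", function(x) standardGeneric("trainHistory"))
#' @rdname accessors
#' @export
setMethod("trainHistory", "MoEModel", function(x) x@history)

#' @rdname accessors
#' @export
setGeneric("modelSplit", function(x) standardGeneric("modelSplit"))
#' @rdname accessors
#' @export
setMethod("modelSplit", "MoEModel", function(x) x@split)

#' @rdname accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setMethod("geneTable", "InterpretationReport", function(x) x@geneTable)

#' @rdname accessors
#' @export
setGeneric("pathwayTable", function(x) standardGeneric("pathwayTable"))
#' @rdname accessors
#' @export
setMethod("pathwayTable", "InterpretationReport", function(x) x@pathwayTable)

#' @rdname accessors
#' @export
setGeneric("interactionScores", function(x) standardGeneric("interactionScores"))
#' @rdname accessors
#' @export
setMethod("interactionScores", "InterpretationReport", function(x) x@mis)

## ---- show methods -----------------------------------------------------------

setMethod("show", "PatchBag", function(object) {
  cat(sprintf("PatchBag '%s': %d patches, %d-dim features\n",
              object@slideId, nrow(object@features), ncol(object@features)))
})

setMethod("show", "GeneSetCollection", function(object) {
  sz <- vapply(object@sets, length, 1L)
  cat(sprintf("GeneSetCollection: %d sets, %d-%d genes each\n",
              length(sz), min(sz), max(sz)))
})

setMethod("show", "MultiModalCohort", function(object) {
  cat(sprintf("MultiModalCohort: %d patients, task '%s'\n",
              nrow(object@outcome), object@task))
  cat(sprintf("  omics sources: %s\n",
              paste(names(object@omics), collapse = ", ")))
  cat(sprintf("  gene sets: %d; planted truth: %s\n",
              length(object@geneSets@sets),
              if (length(object@truth)) "yes" else "no"))
})

setMethod("show", "MoEModel", function(object) {
  cat(sprintf("MoEModel (%s): K=%d regions, P=%d pathways, zdim=%d\n",
              object@meta$task, object@config$n_regions,
              length(object@meta$pathways), object@config$zdim))
  if (nrow(object@history))
    cat(sprintf("  trained %d supervised epochs; final val loss %.4f\n",
                max(object@history$epoch),
                object@history$val_loss[nrow(object@history)]))
})

setMethod("show", "InterpretationReport", function(object) {
  cat(sprintf("InterpretationReport: %d gene rows, %d pathways, MIS %dx%d\n",
              nrow(object@geneTable), nrow(object@pathwayTable),
              nrow(object@mis), ncol(object@mis)))
})
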