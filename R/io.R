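# Readers and writers for the on-disk formats: GMT gene sets, omics TSVs,
# per-slide patch tables, outcome tables and cohort manifests. Readers are
# strict: malformed input is an error with coordinates, never a silent
# coercion.

#' Read a GMT gene-set file
#'
#' Tab-separated, one line per set: name, description, then genes. Duplicate
#' genes within a line are stored once; empty lines are skipped; CRLF and LF
#' endings are both accepted.
#'
#' @param path file path.
#' @return A [GeneSetCollection-class].
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("malformed GMT line %d: need name, description and >= 1 gene",
                   lineno[i]))
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("malformed GMT line %d: no genes", lineno[i]))
    sets[[fields[1]]] <- genes
  }
  GeneSetCollection(sets)
}

#' Write a gene-set collection as GMT
#' @param sets a [GeneSetCollection-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets@sets), function(nm)
    paste(c(nm, "synthetic", sets@sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an omics matrix (samples x genes TSV)
#'
#' Expects a header row of gene names with the sample id in the first column.
#' Non-numeric or missing cells and duplicate sample ids are errors.
#'
#' @param path file path.
#' @param source_name label attached to the matrix.
#' @return numeric matrix with an attribute `source`.
#' @export
readOmics <- function(path, source_name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("omics table needs sample ids plus >= 1 gene column")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | vals == "", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric or missing value in %s at row %d, column '%s'",
                 path, bad[1, 1], colnames(vals)[bad[1, 2]]))
  dimnames(num) <- list(ids, colnames(vals))
  attr(num, "source") <- source_name
  num
}

#' Read a per-slide patch table
#'
#' Columns `x`, `y`, then `f0..f{d-1}`; the feature dimension is inferred from
#' the header and patch order is preserved.
#'
#' @param path file path.
#' @param slideId slide identifier; default: file name without extension.
#' @return A [PatchBag-class].
#' @export
readPatchTable <- function(path, slideId = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("patch table must have x and y columns: ", path)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (!length(fcols)) stop("patch table has no feature columns f0..: ", path)
  expected <- sprintf("f%d", seq_along(fcols) - 1L)
  if (!setequal(fcols, expected))
    stop("inconsistent feature columns in ", path,
         ": expected f0..f", length(fcols) - 1L)
  feats <- as.matrix(df[, expected, drop = FALSE])
  if (!is.numeric(feats) || anyNA(feats))
    stop("non-numeric feature values in ", path)
  PatchBag(feats, as.matrix(df[, c("x", "y")]), slideId)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param directory directory containing a `manifest.json`.
#' @return A [MultiModalCohort-class] (with an empty `truth` slot).
#' @export
readCohort <- function(directory) {
  mf <- file.path(directory, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", directory)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  gsc <- readGMT(file.path(directory, manifest$files$gene_sets))
  outcome <- utils::read.delim(file.path(directory, manifest$files$outcome),
                               stringsAsFactors = FALSE)
  omics <- list()
  for (fp in manifest$files$omics) {
    nm <- sub("^omics_", "", sub("\\.tsv$", "", basename(fp)))
    m <- readOmics(file.path(directory, fp), nm)
    attr(m, "source") <- NULL
    omics[[nm]] <- m
  }
  bags <- lapply(manifest$files$patches, function(fp)
    readPatchTable(file.path(directory, fp)))
  names(bags) <- vapply(bags, slideId, "")
  bags <- bags[outcome$sample_id]
  new("MultiModalCohort", patchBags = bags, omics = omics, geneSets = gsc,
      outcome = outcome,
      task = if ("label" %in% names(outcome)) "classification" else "survival",
      truth = list())
}
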