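#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   rowData colData colData<-
NULL

.PHASE_LEVELS <- c("BC", "HI", "HIp")

#' RamanSpectraSet: a set of Raman spectra with subject/phase metadata
#'
#' S4 container for a collection of Raman spectra sharing one wavenumber
#' grid, built on [SummarizedExperiment::SummarizedExperiment].  The
#' `"intensity"` assay holds one column per spectrum and one row per
#' wavenumber channel; `rowData` carries the wavenumber axis (`cm^-1`,
#' strictly increasing) and `colData` the per-spectrum metadata:
#' `sample_id`, `subject_id`, `phase` (one of `"BC"`, `"HI"`, `"HIp"` —
#' basal condition, hypoxia-ischemia, post-hypoxia-ischemia) and
#' `time_min` (acquisition time in minutes from the start of the
#' experiment).  `metadata()` stores a provenance `log` of applied
#' transforms plus any generator ground truth (timelines, blood gas,
#' injected-artifact flags).
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @seealso [simulateStudy()], [preprocessSpectra()], [readSpectra()]
#' @export
setClass("RamanSpectraSet", contains = "SummarizedExperiment")

.validRamanSpectraSet <- function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  wn <- rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData must contain a 'wavenumber' column")
  } else {
    if (any(!is.finite(wn)))
      msg <- c(msg, "wavenumbers must be finite")
    if (length(wn) > 1L && any(diff(wn) <= 0))
      msg <- c(msg, "wavenumbers must be strictly increasing")
  }
  cd <- colData(object)
  for (col in c("sample_id", "subject_id", "phase", "time_min"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData must contain '%s'", col))
  if ("sample_id" %in% colnames(cd) && anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if ("phase" %in% colnames(cd) &&
      !all(as.character(cd$phase) %in% .PHASE_LEVELS))
    msg <- c(msg, sprintf("phase values must be in {%s}",
                          paste(.PHASE_LEVELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
}

setValidity("RamanSpectraSet", .validRamanSpectraSet)

#' Construct a RamanSpectraSet
#'
#' @param intensity numeric matrix of intensities, wavenumber channels in
#'   rows and spectra in columns.
#' @param wavenumber numeric vector of wavenumbers (cm^-1), strictly
#'   increasing, one per row of `intensity`.
#' @param sampleData `data.frame` (or `DataFrame`) with one row per
#'   spectrum: columns `sample_id`, `subject_id`, `phase`, `time_min`.
#'   Extra columns are kept.
#' @param metadata named list stored in `metadata()`; a character `log`
#'   entry is added if absent.
#'
#' @return A [RamanSpectraSet-class] object.
#' @examples
#' wn <- seq(535, 1715, by = 4)
#' mat <- matrix(rnorm(length(wn) * 3), ncol = 3)
#' sd <- data.frame(sample_id = paste0("s", 1:3), subject_id = "P1",
#'                  phase = "BC", time_min = 0:2)
#' rs <- RamanSpectraSet(mat, wn, sd)
#' @export
RamanSpectraSet <- function(intensity, wavenumber, sampleData,
                            metadata = list()) {
  intensity <- as.matrix(intensity)
  stopifnot(nrow(intensity) == length(wavenumber),
            ncol(intensity) == nrow(sampleData))
  sampleData <- as(sampleData, "DataFrame")
  rownames(sampleData) <- as.character(sampleData$sample_id)
  sampleData$phase <- factor(as.character(sampleData$phase),
                             levels = .PHASE_LEVELS)
  if (is.null(metadata$log)) metadata$log <- character()
  rownames(intensity) <- sprintf("wn_%g", wavenumber)
  colnames(intensity) <- as.character(sampleData$sample_id)
  se <- SummarizedExperiment(
    assays = S4Vectors::SimpleList(intensity = intensity),
    rowData = DataFrame(wavenumber = as.numeric(wavenumber)),
    colData = sampleData,
    metadata = metadata)
  new("RamanSpectraSet", se)
}

# replace the intensity matrix, keeping the existing dimnames
.setIntensity <- function(x, M) {
  dimnames(M) <- dimnames(assay(x, "intensity"))
  SummarizedExperiment::assay(x, "intensity", withDimnames = FALSE) <- M
  x
}

.logStep <- function(x, step) {
  md <- metadata(x)
  md$log <- c(md$log, step)
  metadata(x) <- md
  x
}
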