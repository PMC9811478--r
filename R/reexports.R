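#' Re-exported generics
#'
#' `colData()` and `metadata()` from SummarizedExperiment/S4Vectors are
#' re-exported so that sample metadata and generator ground truth of a
#' [RamanSpectraSet-class] are reachable without attaching those
#' packages.
#'
#' @name reexports
#' @importFrom SummarizedExperiment colData
#' @export colData
#' @importFrom S4Vectors metadata
#' @export metadata
NULL
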