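#' Accessors for RamanSpectraSet
#'
#' `wavenumbers()` returns the shared wavenumber grid (cm^-1);
#' `intensities()` the channels-by-spectra intensity matrix; `phases()`
#' the per-spectrum phase factor (`BC`/`HI`/`HIp`); `subjects()` the
#' subject identifiers; `acquisitionTimes()` the acquisition times in
#' minutes; `processingLog()` the ordered record of transforms applied.
#'
#' @param x a [RamanSpectraSet-class].
#' @return See the individual descriptions.
#' @name RamanSpectraSet-accessors
#' @aliases wavenumbers intensities phases subjects acquisitionTimes
#'   processingLog
NULL

#' @rdname RamanSpectraSet-accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname RamanSpectraSet-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname RamanSpectraSet-accessors
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' @rdname RamanSpectraSet-accessors
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname RamanSpectraSet-accessors
#' @export
setGeneric("acquisitionTimes", function(x) standardGeneric("acquisitionTimes"))

#' @rdname RamanSpectraSet-accessors
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))
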