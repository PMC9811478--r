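#' @rdname RamanSpectraSet-accessors
setMethod("wavenumbers", "RamanSpectraSet",
          function(x) rowData(x)$wavenumber)

#' @rdname RamanSpectraSet-accessors
setMethod("intensities", "RamanSpectraSet",
          function(x) assay(x, "intensity"))

#' @rdname RamanSpectraSet-accessors
setMethod("phases", "RamanSpectraSet",
          function(x) colData(x)$phase)

#' @rdname RamanSpectraSet-accessors
setMethod("subjects", "RamanSpectraSet",
          function(x) as.character(colData(x)$subject_id))

#' @rdname RamanSpectraSet-accessors
setMethod("acquisitionTimes", "RamanSpectraSet",
          function(x) as.numeric(colData(x)$time_min))

#' @rdname RamanSpectraSet-accessors
setMethod("processingLog", "RamanSpectraSet",
          function(x) metadata(x)$log)

setMethod("show", "RamanSpectraSet", function(object) {
  wn <- wavenumbers(object)
  cat(sprintf("RamanSpectraSet: %d spectra x %d channels\n",
              ncol(object), nrow(object)))
  if (length(wn))
    cat(sprintf("  wavenumbers: %g..%g cm^-1 (step %g)\n",
                min(wn), max(wn), if (length(wn) > 1) wn[2] - wn[1] else NA))
  ph <- table(phases(object))
  cat("  phases:", paste(sprintf("%s=%d", names(ph), ph), collapse = " "),
      "\n")
  cat(sprintf("  subjects: %d\n", length(unique(subjects(object)))))
  lg <- processingLog(object)
  if (length(lg))
    cat("  log:", paste(lg, collapse = " -> "), "\n")
  invisible(NULL)
})
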