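#' Read / write spectra tables
#'
#' Plain-text interchange format for spectra sets: a CSV with header
#' `sample_id, subject_id, phase, time_min` followed by one column per
#' wavenumber labelled with its value in cm^-1, one row per spectrum.
#' `writeSpectra()` serializes at full double precision so that
#' `readSpectra(writeSpectra(x))` round-trips exactly.  On reading,
#' phase labels are whitespace-trimmed and case-normalized to
#' `BC`/`HI`/`HIp` (with a warning when normalization was needed);
#' non-increasing wavenumber columns and duplicate sample ids are
#' errors.
#'
#' @param path file path.
#' @return `readSpectra`: a [RamanSpectraSet-class].
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "subject_id", "phase", "time_min")
  if (!all(meta_cols %in% colnames(df)[1:4]))
    stop("malformed header: expected columns ",
         paste(meta_cols, collapse = ", "))
  extra <- setdiff(colnames(df), meta_cols)
  wn <- suppressWarnings(as.numeric(extra))
  if (any(is.na(wn)))
    stop("non-numeric wavenumber column label: ", extra[is.na(wn)][1])
  bad <- which(diff(wn) <= 0)
  if (length(bad))
    stop("wavenumber columns not strictly increasing at column '",
         extra[bad[1] + 1], "'")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1])
  raw <- df$phase
  norm <- trimws(raw)
  norm <- unname(c(bc = "BC", hi = "HI", hip = "HIp")[tolower(norm)])
  if (any(is.na(norm)))
    stop("unknown phase label: ", raw[is.na(norm)][1])
  if (!identical(norm, raw))
    warning("phase labels normalized to BC/HI/HIp")
  sd <- data.frame(sample_id = df$sample_id, subject_id = df$subject_id,
                   phase = unname(norm), time_min = df$time_min,
                   stringsAsFactors = FALSE)
  RamanSpectraSet(t(as.matrix(df[, extra, drop = FALSE])), wn, sd,
                  metadata = list(log = sprintf("read[%s]",
                                                basename(path))))
}

#' @rdname readSpectra
#' @param x a [RamanSpectraSet-class].
#' @export
writeSpectra <- function(x, path) {
  X <- t(intensities(x))
  cd <- as.data.frame(colData(x))
  df <- data.frame(sample_id = cd$sample_id, subject_id = cd$subject_id,
                   phase = as.character(cd$phase),
                   time_min = cd$time_min,
                   stringsAsFactors = FALSE, check.names = FALSE)
  M <- matrix(sprintf("%.17g", X), nrow = nrow(X))
  colnames(M) <- sprintf("%.10g", wavenumbers(x))
  utils::write.csv(cbind(df, as.data.frame(M, stringsAsFactors = FALSE,
                                           check.names = FALSE)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
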