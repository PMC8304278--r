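# HRMS scan sets: full-scan (FS) and data-independent-acquisition (DIA)
# centroid spectra, ordered in time, negative polarity. mzML reading and
# writing is delegated to Bioconductor's mzR; a scan set is a tibble with
# one row per scan and list-columns for the centroid arrays.

#' Construct an HRMS scan set
#'
#' @param scans A tibble with columns `time` (minutes, non-decreasing),
#'   `mode` (`"FS"`/`"DIA"`), `iso_center`, `iso_width` (Th; `NA` for FS),
#'   and list-columns `mz` (ascending per scan) and `intensity`.
#' @param polarity `"negative"` (the only supported polarity).
#' @return A `scan_set` tibble.
#' @export
new_scan_set <- function(scans, polarity = "negative") {
  req <- c("time", "mode", "iso_center", "iso_width", "mz", "intensity")
  if (!all(req %in% names(scans))) {
    stop("scan set needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(scans$time)) {
    stop("scan times must be non-decreasing", call. = FALSE)
  }
  if (!all(scans$mode %in% c("FS", "DIA"))) {
    stop("scan mode must be FS or DIA", call. = FALSE)
  }
  ok <- purrr::map2_lgl(scans$mz, scans$intensity, function(m, i) {
    length(m) == length(i) && !is.unsorted(m)
  })
  if (!all(ok)) {
    stop("per-scan mz arrays must be ascending and match intensities",
         call. = FALSE)
  }
  if (!identical(polarity, "negative")) {
    stop("only negative polarity is supported", call. = FALSE)
  }
  out <- tibble::as_tibble(scans)
  out$scan <- seq_len(nrow(out))
  attr(out, "polarity") <- polarity
  class(out) <- c("scan_set", class(out))
  out
}

#' @export
print.scan_set <- function(x, ...) {
  cat(sprintf("<scan_set: %d scans (%d FS, %d DIA), %.2f-%.2f min, %s mode>\n",
              nrow(x), sum(x$mode == "FS"), sum(x$mode == "DIA"),
              min(x$time), max(x$time), attr(x, "polarity")))
  invisible(x)
}

#' Read a centroided mzML file into a scan set
#'
#' MS1 scans become FS rows; MS2 scans become DIA rows carrying their
#' isolation windows. Retention times are converted from seconds to minutes.
#' Profile-mode spectra are rejected with a pointer to centroiding; missing
#' polarity information produces a warning and is assumed negative.
#'
#' @param path Path to an mzML file.
#' @return A `scan_set`.
#' @export
read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  if (nrow(hd) == 0L) stop("mzML file contains no spectra: ", path,
                           call. = FALSE)
  if (any(!is.na(hd$centroided) & !hd$centroided)) {
    stop("profile-mode spectra found; centroid the data before reading ",
         "(e.g. msconvert with peak picking)", call. = FALSE)
  }
  if (any(is.na(hd$polarity) | hd$polarity < 0)) {
    warning("polarity missing in mzML header; assuming negative mode")
  } else if (any(hd$polarity == 1)) {
    stop("positive-mode scans found; the method acquires negative mode only",
         call. = FALSE)
  }
  pk <- mzR::peaks(fh)
  if (nrow(hd) == 1L) pk <- list(pk)
  scans <- tibble::tibble(
    time = hd$retentionTime / 60,
    mode = ifelse(hd$msLevel >= 2L, "DIA", "FS"),
    iso_center = ifelse(hd$msLevel >= 2L, hd$isolationWindowTargetMZ,
                        NA_real_),
    iso_width = ifelse(
      hd$msLevel >= 2L,
      hd$isolationWindowLowerOffset + hd$isolationWindowUpperOffset,
      NA_real_
    ),
    mz = purrr::map(pk, function(p) as.numeric(p[, 1])),
    intensity = purrr::map(pk, function(p) as.numeric(p[, 2]))
  )
  new_scan_set(scans)
}

#' Write a scan set to mzML
#'
#' @param scanset A `scan_set`.
#' @param path Output path (`.mzML`).
#' @return The path, invisibly.
#' @export
write_mzml <- function(scanset, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package", call. = FALSE)
  }
  n <- nrow(scanset)
  pks <- purrr::map2(scanset$mz, scanset$intensity,
                     function(m, i) cbind(mz = m, intensity = i))
  is_dia <- scanset$mode == "DIA"
  npk <- vapply(pks, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = ifelse(is_dia, 2L, 1L),
    polarity = 0L,  # negative
    peaksCount = npk,
    totIonCurrent = vapply(scanset$intensity, sum, numeric(1)),
    retentionTime = scanset$time * 60,
    basePeakMZ = vapply(pks, function(p)
      if (nrow(p)) p[which.max(p[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(pks, function(p)
      if (nrow(p)) max(p[, 2]) else 0, numeric(1)),
    collisionEnergy = ifelse(is_dia, 10, 0),
    ionisationEnergy = 0,
    lowMZ = vapply(pks, function(p) if (nrow(p)) min(p[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(pks, function(p) if (nrow(p)) max(p[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = ifelse(is_dia, scanset$iso_center, NA_real_),
    precursorCharge = ifelse(is_dia, 1L, 0L),
    precursorIntensity = 0,
    mergedScan = NA_real_, mergedResultScanNum = NA_real_,
    mergedResultStartScanNum = NA_real_, mergedResultEndScanNum = NA_real_,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is_dia, scanset$iso_center, NA_real_),
    isolationWindowLowerOffset = ifelse(is_dia, scanset$iso_width / 2,
                                        NA_real_),
    isolationWindowUpperOffset = ifelse(is_dia, scanset$iso_width / 2,
                                        NA_real_),
    scanWindowLowerLimit = 50, scanWindowUpperLimit = 750,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}
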