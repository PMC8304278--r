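# Targeted HRMS confirmation tier: extracted-ion chromatograms, retention
# time + exact mass + DIA fragment matching, in-source interconversion
# bookkeeping, and the long-chain E452 fingerprint.

#' Extract an ion chromatogram from a scan set
#'
#' For every scan of the requested mode, sums the centroid intensities
#' within `tol_ppm` of the target m/z. For DIA extraction the scans can be
#' restricted to those whose isolation window covers `covering_mz`.
#'
#' @param scanset A `scan_set`.
#' @param target_mz Target m/z, Th.
#' @param tol_ppm Extraction tolerance in ppm (> 0); default 5 ppm, matched
#'   to a 70,000-resolution full scan.
#' @param mode `"FS"` or `"DIA"`.
#' @param covering_mz When extracting from DIA scans, keep only scans whose
#'   isolation window contains this m/z (typically the precursor).
#' @return An XIC `phos_trace`.
#' @export
extract_xic <- function(scanset, target_mz, tol_ppm = 5,
                        mode = c("FS", "DIA"), covering_mz = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) {
    stop("tol_ppm must be > 0", call. = FALSE)
  }
  sel <- scanset$mode == mode
  if (!is.null(covering_mz)) {
    sel <- sel & !is.na(scanset$iso_center) &
      abs(scanset$iso_center - covering_mz) <= scanset$iso_width / 2
  }
  if (!any(sel)) {
    stop("no ", mode, " scans", if (!is.null(covering_mz))
      sprintf(" covering m/z %.4f", covering_mz), " in scan set",
      call. = FALSE)
  }
  dm <- target_mz * tol_ppm * 1e-6
  sub <- scanset[sel, ]
  ints <- purrr::map2_dbl(sub$mz, sub$intensity, function(m, i) {
    sum(i[abs(m - target_mz) <= dm])
  })
  new_trace(sub$time, ints, channel = "XIC",
            sample_id = attr(scanset, "sample_id") %||% NA_character_,
            target_mz = target_mz)
}

# intensity-weighted mean ppm offset of centroids near target within a
# retention-time window
weighted_mass_error <- function(scanset, target_mz, tol_ppm, t_lo, t_hi) {
  sel <- scanset$mode == "FS" & scanset$time >= t_lo & scanset$time <= t_hi
  if (!any(sel)) return(NA_real_)
  dm <- target_mz * tol_ppm * 1e-6
  sub <- scanset[sel, ]
  num <- 0; den <- 0
  for (r in seq_len(nrow(sub))) {
    m <- sub$mz[[r]]; i <- sub$intensity[[r]]
    k <- abs(m - target_mz) <= dm
    num <- num + sum(m[k] * i[k])
    den <- den + sum(i[k])
  }
  if (den == 0) return(NA_real_)
  (num / den - target_mz) / target_mz * 1e6
}

empty_record <- function(name) {
  tibble::tibble(
    species = name, confirmed = FALSE, matched_rt = NA_real_,
    rt_error = NA_real_, mass_error_ppm = NA_real_,
    fragments_confirmed = list(numeric(0)),
    amount = NA_real_, censoring = "ND", note = ""
  )
}

#' Confirm one (poly)phosphate species in an HRMS run
#'
#' A species is confirmed when (a) its deprotonated-precursor XIC shows a
#' peak whose apex lies within `rt_tol` of the expected retention time, and
#' (b) at least one listed confirmation fragment, extracted from DIA scans
#' whose isolation window covers the precursor, co-elutes with it (apex
#' difference at most `rt_tol / 2`). The mass error is the ppm offset of the
#' intensity-weighted precursor centroid across the peak.
#'
#' @param scanset A `scan_set`.
#' @param species Species name or one-row slice of [phosphate_species()].
#' @param rt_tol Retention-time tolerance, minutes.
#' @param tol_ppm Extraction tolerance, ppm.
#' @param min_snr Minimum S/N for the precursor XIC peak.
#' @param baseline_window Baseline window for XIC peak detection, minutes.
#' @return A one-row detection-record tibble: `species`, `confirmed`,
#'   `matched_rt`, `rt_error`, `mass_error_ppm`, `fragments_confirmed`
#'   (list-column), `amount`, `censoring`, `note`.
#' @export
confirm_species <- function(scanset, species, rt_tol = 0.5, tol_ppm = 5,
                            min_snr = 3, baseline_window = 2.0) {
  sp <- resolve_species(species)
  rec <- empty_record(sp$name)
  xic <- extract_xic(scanset, sp$precursor_mz, tol_ppm, mode = "FS")
  pks <- detect_peaks(xic, min_snr = min_snr, min_width = 0.1,
                      baseline_window = baseline_window)
  hit <- pks[abs(pks$apex_time - sp$expected_rt) <= rt_tol, ]
  if (nrow(hit) == 0L) {
    if (nrow(pks) > 0L) {
      rec$note <- sprintf("precursor signal only outside RT window (%.2f min)",
                          pks$apex_time[which.max(pks$height)])
    }
    return(rec)
  }
  hit <- dplyr::arrange(hit, dplyr::desc(height))
  frs <- sp$fragment_mzs[[1]]
  have_dia <- any(scanset$mode == "DIA" & !is.na(scanset$iso_center) &
                    abs(scanset$iso_center - sp$precursor_mz) <=
                    scanset$iso_width / 2)
  # fragment XIC peaks, computed once per fragment
  frag_peaks <- if (length(frs) && have_dia) {
    lapply(frs, function(f) {
      fx <- extract_xic(scanset, f, tol_ppm, mode = "DIA",
                        covering_mz = sp$precursor_mz)
      detect_peaks(fx, min_snr = min_snr, min_width = 0.1,
                   baseline_window = baseline_window)
    })
  } else {
    list()
  }
  # try candidate precursor peaks tallest-first; keep the first that a
  # fragment co-elutes with, else fall back to the tallest
  best <- NULL
  for (r in seq_len(nrow(hit))) {
    conf <- numeric(0)
    for (k in seq_along(frag_peaks)) {
      fp <- frag_peaks[[k]]
      if (nrow(fp) > 0L &&
          any(abs(fp$apex_time - hit$apex_time[r]) <= rt_tol / 2)) {
        conf <- c(conf, frs[k])
      }
    }
    if (is.null(best)) best <- list(row = r, conf = conf)
    if (length(conf)) { best <- list(row = r, conf = conf); break }
  }
  use <- hit[best$row, ]
  rec$matched_rt <- use$apex_time
  rec$rt_error <- use$apex_time - sp$expected_rt
  rec$mass_error_ppm <- weighted_mass_error(
    scanset, sp$precursor_mz, tol_ppm, use$start_time, use$end_time
  )
  rec$fragments_confirmed <- list(best$conf)
  if (length(best$conf) >= 1L) {
    rec$confirmed <- TRUE
    rec$censoring <- "detected"
  } else if (length(frs) == 0L) {
    rec$note <- "no confirmation fragments listed"
  } else if (!have_dia) {
    rec$note <- "no DIA coverage of precursor"
  } else {
    rec$note <- "no fragment co-eluting with precursor"
  }
  rec
}

#' Screen a scan set against the whole species database
#'
#' @inheritParams confirm_species
#' @param db Species database tibble.
#' @return Detection-record tibble, one row per species, in elution order.
#' @export
confirm_all_species <- function(scanset, db = phosphate_species(),
                                rt_tol = 0.5, tol_ppm = 5, min_snr = 3) {
  recs <- purrr::map(seq_len(nrow(db)), function(i) {
    confirm_species(scanset, db[i, ], rt_tol = rt_tol, tol_ppm = tol_ppm,
                    min_snr = min_snr)
  })
  dplyr::bind_rows(recs)
}

#' Annotate in-source interconversion of phosphate anions
#'
#' In the heated ESI source, condensed phosphates partially fragment or
#' recombine, so an ion can show chromatographic peaks at other species'
#' retention times (e.g. the pyrophosphate anion at the ortho- and
#' triphosphate retention times). Detection and quantification use only the
#' peak at the species' own retention time; this pass documents cross-RT
#' signal in the record notes, and marks unconfirmed species whose ion
#' appears only at a longer chain's retention time as in-source fragments.
#'
#' @param records Detection records from [confirm_all_species()].
#' @inheritParams confirm_species
#' @param db Species database tibble.
#' @return The records, with `note` updated.
#' @export
resolve_interconversion <- function(records, scanset,
                                    db = phosphate_species(),
                                    rt_tol = 0.5, tol_ppm = 5, min_snr = 5) {
  for (r in seq_len(nrow(records))) {
    sp <- db[db$name == records$species[r], ]
    if (nrow(sp) != 1L) next
    xic <- extract_xic(scanset, sp$precursor_mz, tol_ppm, mode = "FS")
    pks <- detect_peaks(xic, min_snr = min_snr, min_width = 0.1,
                        baseline_window = 2.0)
    if (nrow(pks) == 0L) next
    others <- db[db$name != sp$name, ]
    cross <- character(0)
    for (o in seq_len(nrow(others))) {
      if (any(abs(pks$apex_time - others$expected_rt[o]) <= rt_tol)) {
        cross <- c(cross, others$name[o])
      }
    }
    if (length(cross) == 0L) next
    msg <- sprintf("ion also at RT of %s (in-source interconversion; excluded)",
                   paste(cross, collapse = ", "))
    if (!records$confirmed[r] &&
        !any(abs(pks$apex_time - sp$expected_rt) <= rt_tol)) {
      longer <- cross[others$n_phosphorus[match(cross, others$name)] >
                        sp$n_phosphorus]
      if (length(longer)) {
        msg <- sprintf("in-source fragment of %s",
                       paste(longer, collapse = ", "))
      }
    }
    records$note[r] <- paste(c(records$note[r][nzchar(records$note[r])], msg),
                             collapse = "; ")
  }
  records
}

#' Long-chain confirmation fingerprint
#'
#' Runs [confirm_species()] for the six long-chain species (tetra-,
#' tetrameta-, penta-, pentameta-, hexa-, hexametaphosphate). The confirmed
#' subset, in elution order, is the E452 treatment fingerprint.
#'
#' @inheritParams confirm_all_species
#' @return Character vector of confirmed long-chain species names, ordered
#'   by expected retention time.
#' @export
fingerprint_longchain <- function(scanset, rt_tol = 0.5, tol_ppm = 5,
                                  min_snr = 3, db = phosphate_species()) {
  lc <- db[db$chain_class %in% c("long_linear", "long_cyclic"), ]
  lc <- lc[order(lc$expected_rt), ]
  recs <- confirm_all_species(scanset, lc, rt_tol = rt_tol,
                              tol_ppm = tol_ppm, min_snr = min_snr)
  recs$species[recs$confirmed]
}
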