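# JSON result reports: per-species detection records, censored quantities,
# P2O5-equivalent totals and the per-sample verdict.

#' Write / read a sample result report
#'
#' Serialises detection records and verdicts to JSON. Quantified amounts are
#' accompanied by their P2O5 equivalents; censored cells keep their symbol
#' (`ND`, `<LOD`, `<LOQ`). The report is bit-stable for fixed inputs.
#'
#' @param records Detection-record tibble (see [confirm_species()]),
#'   optionally with `amount`/`censoring` filled by [quantify_species()].
#' @param verdicts Verdict tibble from [classify_sample()], or `NULL`.
#' @param path Output path.
#' @param sample_id Sample label stored in the report.
#' @return `read_report()` returns a list with `sample_id`, `records`
#'   (tibble) and `verdicts` (tibble or `NULL`).
#' @export
write_report <- function(records, verdicts, path, sample_id = NA_character_) {
  db <- phosphate_species()
  rec_out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    quantified <- identical(r$censoring, "quantified") && !is.na(r$amount)
    p2o5 <- if (quantified && r$species %in%
                db$name[db$n_phosphorus > 0]) {
      p2o5_equivalent(r$amount, r$species)
    } else {
      NULL
    }
    list(
      species = r$species,
      confirmed = r$confirmed,
      matched_rt = r$matched_rt,
      rt_error = r$rt_error,
      mass_error_ppm = r$mass_error_ppm,
      fragments_confirmed = r$fragments_confirmed[[1]],
      result = if (quantified) r$amount else r$censoring,
      p2o5_equivalent = p2o5,
      note = r$note
    )
  })
  quantified <- records$censoring == "quantified" & !is.na(records$amount)
  total <- sum(vapply(which(quantified), function(i) {
    p2o5_equivalent(records$amount[i], records$species[i])
  }, numeric(1)))
  out <- list(
    sample_id = sample_id,
    records = rec_out,
    total_p2o5_equivalent = total,
    verdicts = if (!is.null(verdicts)) verdicts else NULL
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  recs <- dplyr::bind_rows(lapply(x$records, function(r) {
    tibble::tibble(
      species = r$species,
      confirmed = isTRUE(r$confirmed),
      matched_rt = r$matched_rt %||% NA_real_,
      rt_error = r$rt_error %||% NA_real_,
      mass_error_ppm = r$mass_error_ppm %||% NA_real_,
      fragments_confirmed = list(as.numeric(unlist(r$fragments_confirmed))),
      amount = if (is.numeric(r$result)) r$result else NA_real_,
      censoring = if (is.numeric(r$result)) "quantified" else r$result,
      note = r$note %||% ""
    )
  }))
  verd <- if (!is.null(x$verdicts) && length(x$verdicts)) {
    dplyr::bind_rows(lapply(x$verdicts, tibble::as_tibble))
  } else {
    NULL
  }
  list(sample_id = x$sample_id, records = recs,
       total_p2o5_equivalent = x$total_p2o5_equivalent, verdicts = verd)
}
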