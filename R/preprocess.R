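#' Record-selection filters for an imaging cohort
#'
#' Applies, in order: (1) drop records with incomplete metadata, (2) keep
#' frontal views only (AP or PA), (3) within each study keep only the
#' chronologically last record (ties broken by lexicographically greatest
#' `image_ref`), and (4) restrict to the `top_k` most frequent imaging
#' devices, with frequencies computed *after* the preceding filters (ties at
#' rank `top_k` are all included).
#'
#' @param records cohort records data frame (or a `drift_cohort`).
#' @param top_k_devices number of devices to keep (default 10).
#' @return a list with `records` (filtered data frame) and `report`, a
#'   `filter_report` tallying removals per stage, the device whitelist, and
#'   the fraction of post-filter records the whitelist covers.
#' @export
filter_records <- function(records, top_k_devices = 10L) {
  if (inherits(records, "drift_cohort")) records <- records$records
  stopifnot(all(c("view", "device", "study_date", "metadata_complete",
                  "study_id") %in% names(records)))
  n_input <- nrow(records)

  rec <- records[records$metadata_complete, , drop = FALSE]
  n_incomplete <- n_input - nrow(rec)

  keep_frontal <- rec$view %in% c("AP", "PA")
  n_nonfrontal <- sum(!keep_frontal)
  rec <- rec[keep_frontal, , drop = FALSE]

  # last record per study; deterministic tie-break on image_ref
  if (nrow(rec) > 0) {
    ord <- order(rec$study_id, rec$study_date, rec$image_ref)
    rec <- rec[ord, , drop = FALSE]
    last <- !duplicated(rec$study_id, fromLast = TRUE)
  } else {
    last <- logical(0)
  }
  n_dup <- sum(!last)
  rec <- rec[last, , drop = FALSE]

  dev_freq <- sort(table(rec$device), decreasing = TRUE)
  if (length(dev_freq) > top_k_devices) {
    cutoff <- as.integer(dev_freq[top_k_devices])
    whitelist <- names(dev_freq)[as.integer(dev_freq) >= cutoff]
  } else {
    whitelist <- names(dev_freq)
  }
  keep_dev <- rec$device %in% whitelist
  n_rare <- sum(!keep_dev)
  coverage <- if (nrow(rec) > 0) sum(keep_dev) / nrow(rec) else NA_real_
  rec <- rec[keep_dev, , drop = FALSE]

  if (nrow(rec) == 0) warning("all records removed by preprocessing filters")

  report <- structure(list(
    n_input = n_input,
    n_removed_incomplete = n_incomplete,
    n_removed_nonfrontal = n_nonfrontal,
    n_removed_duplicate_study = n_dup,
    n_removed_rare_device = n_rare,
    n_output = nrow(rec),
    device_whitelist = whitelist,
    device_coverage = coverage
  ), class = "filter_report")
  list(records = rec, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> %d -> %d records ",
                     "(incomplete %d, non-frontal %d, duplicate-study %d, ",
                     "rare-device %d); %d devices cover %.1f%%\n"),
              x$n_input, x$n_output, x$n_removed_incomplete,
              x$n_removed_nonfrontal, x$n_removed_duplicate_study,
              x$n_removed_rare_device, length(x$device_whitelist),
              100 * x$device_coverage))
  invisible(x)
}

#' Bin adult ages into three groups
#'
#' Young is `[18, 35)`, middle-aged `[35, 65)`, senior `[65, Inf)`. The
#' half-open convention keeps the three groups a partition of `[18, Inf)`
#' (printed clinical bins typically overlap at the boundaries).
#'
#' @param age_years integer vector of ages, all `>= 18`.
#' @return factor with levels `young`, `middle-aged`, `senior`.
#' @export
bin_age <- function(age_years) {
  if (any(is.na(age_years)) || any(age_years < 18)) {
    stop("ages must be >= 18 and non-missing", call. = FALSE)
  }
  cut(age_years, breaks = c(18, 35, 65, Inf), right = FALSE,
      labels = c("young", "middle-aged", "senior"))
}

#' Normalize free-text institution names via an alias map
#'
#' Lookup is case-insensitive and whitespace-trimmed. Unmapped names pass
#' through unchanged with a warning.
#'
#' @param raw_name character vector of raw institution strings.
#' @param alias_map named character vector: lowercased trimmed alias ->
#'   canonical level.
#' @return character vector of canonical levels.
#' @export
normalize_institution <- function(raw_name, alias_map) {
  key <- tolower(trimws(raw_name))
  out <- unname(alias_map[key])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sprintf("unmapped institution name(s): %s",
                    paste(unique(raw_name[unknown]), collapse = ", ")))
    out[unknown] <- raw_name[unknown]
  }
  out
}
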