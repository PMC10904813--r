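# Source/target pair construction for the two drift designs: stratified
# enrichment (synthetic categorical drift) and rolling temporal windows.

#' Specification of a synthetic enrichment drift
#'
#' The source is a stratified random sample of the cohort; the target is a
#' same-size sample in which a fraction `delta` of the records is drawn
#' exclusively from one category (a covariate level or a positive label),
#' and the remaining `1 - delta` is sampled like the source.
#'
#' @param sample_size records per dataset (source and target each).
#' @param target_category length-2 character vector `(column, level)`, e.g.
#'   `c("sex", "M")` or `c("label_03", "1")`.
#' @param delta enrichment fraction in `[0, 0.5]`.
#' @param strat_columns covariate columns defining the stratification cells
#'   (`age_group` is derived from `age_years` via [bin_age()]).
#' @param n_repetitions number of independent redraws per condition.
#' @param seed integer seed.
#' @return an object of class `enrichment_spec`.
#' @export
enrichment_spec <- function(sample_size = 4000L,
                            target_category = c("sex", "M"),
                            delta = 0.1,
                            strat_columns = c("sex", "institution", "is_icu",
                                              "age_group", "patient_class"),
                            n_repetitions = 10L,
                            seed = 1L) {
  stopifnot(delta >= 0, delta <= 1, sample_size >= 1,
            length(target_category) == 2)
  structure(list(sample_size = as.integer(sample_size),
                 target_category = target_category, delta = delta,
                 strat_columns = strat_columns,
                 n_repetitions = as.integer(n_repetitions),
                 seed = as.integer(seed)),
            class = "enrichment_spec")
}

strat_cells <- function(records, strat_columns) {
  cols <- lapply(strat_columns, function(cn) {
    if (cn == "age_group") as.character(bin_age(records$age_years))
    else as.character(records[[cn]])
  })
  do.call(paste, c(cols, sep = "|"))
}

# proportional allocation over cells with largest-remainder rounding
allocate_cells <- function(cell_counts, n) {
  p <- cell_counts / sum(cell_counts)
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  base
}

sample_stratified_ids <- function(records, n, strat_columns, seed,
                                  available = rep(TRUE, nrow(records))) {
  cells_all <- strat_cells(records, strat_columns)
  # cell proportions follow the full cohort; cells with no available
  # records are dropped with renormalization
  avail_cells <- unique(cells_all[available])
  counts <- table(cells_all[cells_all %in% avail_cells])
  alloc <- allocate_cells(as.numeric(counts), n)
  names(alloc) <- names(counts)
  with_stream(seed, {
    ids <- character(0)
    shortfall <- 0
    for (cell in names(alloc)) {
      if (alloc[[cell]] == 0) next
      pool <- records$study_id[available & cells_all == cell]
      take <- min(alloc[[cell]], length(pool))
      shortfall <- shortfall + alloc[[cell]] - take
      ids <- c(ids, if (length(pool) == 1 && take == 1) pool
                    else sample(pool, take))
    }
    if (shortfall > 0) {
      warning(sprintf("stratified sampling: %d record(s) reallocated across cells",
                      shortfall))
      pool <- records$study_id[available & !(records$study_id %in% ids)]
      if (length(pool) < shortfall) {
        stop("cohort too small for requested stratified sample", call. = FALSE)
      }
      ids <- c(ids, sample(pool, shortfall))
    }
    ids
  })
}

#' Draw the stratified source sample
#'
#' Samples `sample_size` records without replacement whose joint
#' stratification-cell proportions match the cohort's within rounding.
#'
#' @param records cohort records data frame (or a `drift_cohort`).
#' @param spec an [enrichment_spec()].
#' @param rep_seed seed for this repetition's draw.
#' @return character vector of study ids.
#' @export
stratified_source_sample <- function(records, spec, rep_seed = spec$seed) {
  if (inherits(records, "drift_cohort")) records <- records$records
  if (nrow(records) < spec$sample_size) {
    stop("cohort smaller than the requested sample size", call. = FALSE)
  }
  sample_stratified_ids(records, spec$sample_size, spec$strat_columns,
                        derive_seed(rep_seed, "source"))
}

category_members <- function(records, target_category) {
  col <- target_category[1]; lev <- target_category[2]
  as.character(records[[col]]) == lev
}

#' Draw the enriched target sample
#'
#' The target has the same size as the source and is the union of (a) a
#' `1 - delta` fraction sampled with the source's stratified methodology and
#' (b) a `delta` fraction drawn only from members of the target category.
#' Target records are disjoint from the source at both the record and the
#' patient level.
#'
#' @param records cohort records data frame (or a `drift_cohort`).
#' @param spec an [enrichment_spec()].
#' @param source_ids ids returned by [stratified_source_sample()].
#' @param rep_seed seed for this repetition's draw.
#' @return a `sample_pair`: list with `source_ids`, `target_ids`,
#'   `base_ids`, `enriched_ids`, and `provenance`.
#' @export
enrich_target_sample <- function(records, spec, source_ids,
                                 rep_seed = spec$seed) {
  if (inherits(records, "drift_cohort")) records <- records$records
  n_enrich <- round(spec$delta * spec$sample_size)
  n_base <- spec$sample_size - n_enrich

  src_patients <- records$patient_id[records$study_id %in% source_ids]
  avail <- !(records$study_id %in% source_ids) &
    !(records$patient_id %in% src_patients)

  base_ids <- if (n_base > 0) {
    sample_stratified_ids(records, n_base, spec$strat_columns,
                          derive_seed(rep_seed, "target-base"),
                          available = avail)
  } else character(0)

  pool <- records$study_id[avail & category_members(records, spec$target_category) &
                             !(records$study_id %in% base_ids)]
  if (length(pool) < n_enrich) {
    stop(sprintf("enrichment pool exhausted: need %d '%s = %s' records, have %d",
                 n_enrich, spec$target_category[1], spec$target_category[2],
                 length(pool)), call. = FALSE)
  }
  enriched_ids <- if (n_enrich > 0) {
    with_stream(derive_seed(rep_seed, "target-enrich"), sample(pool, n_enrich))
  } else character(0)

  structure(list(source_ids = source_ids,
                 target_ids = c(base_ids, enriched_ids),
                 base_ids = base_ids, enriched_ids = enriched_ids,
                 provenance = list(spec = spec, rep_seed = rep_seed)),
            class = "sample_pair")
}

#' Rolling temporal window plan
#'
#' @param bucket_days length of one date bucket in days.
#' @param source_window_buckets,target_window_buckets initial window widths
#'   in buckets (widened adaptively when volume is low).
#' @param stride_buckets buffer between the source and target windows, in
#'   buckets.
#' @param sample_size records sampled from each window.
#' @param step_days days between successive evaluations.
#' @param seed integer seed for the window draws.
#' @return an object of class `window_plan`.
#' @export
window_plan <- function(bucket_days = 30L, source_window_buckets = 1L,
                        target_window_buckets = 1L, stride_buckets = 1L,
                        sample_size = 500L, step_days = 30L, seed = 1L) {
  stopifnot(bucket_days >= 1, source_window_buckets >= 1,
            target_window_buckets >= 1, stride_buckets >= 1,
            sample_size >= 1, step_days >= 1)
  structure(list(bucket_days = as.integer(bucket_days),
                 source_window_buckets = as.integer(source_window_buckets),
                 target_window_buckets = as.integer(target_window_buckets),
                 stride_buckets = as.integer(stride_buckets),
                 sample_size = as.integer(sample_size),
                 step_days = as.integer(step_days), seed = as.integer(seed)),
            class = "window_plan")
}

#' Build rolling source/target pairs over a dated cohort
#'
#' For each evaluation date `t` (stepping by `step_days`), the target window
#' is `[t, t + target_buckets * bucket_days)` and the source window ends
#' `stride_buckets` buckets earlier. If a window holds fewer than
#' `sample_size` records it is widened by whole buckets (source backwards,
#' target forwards) until sufficient; if even maximal widening is not
#' enough, the evaluation is skipped with a message. Source and target
#' windows never overlap, so the pairs are disjoint by construction.
#'
#' @param records cohort records data frame (or a `drift_cohort`).
#' @param plan a [window_plan()].
#' @return list of `sample_pair` objects; each `provenance` records the
#'   evaluation date and the realized window extents (in buckets and dates).
#' @export
rolling_window_pairs <- function(records, plan) {
  if (inherits(records, "drift_cohort")) records <- records$records
  stopifnot(inherits(plan, "window_plan"))
  bd <- plan$bucket_days
  start <- min(records$study_date)
  end <- max(records$study_date)
  first_eval <- start + bd * (plan$source_window_buckets + plan$stride_buckets)
  eval_dates <- seq(first_eval, end, by = plan$step_days)
  pairs <- list()
  for (t in as.list(eval_dates)) {
    sb <- plan$source_window_buckets
    tb <- plan$target_window_buckets
    in_window <- function(lo, hi) which(records$study_date >= lo &
                                          records$study_date < hi)
    repeat {
      src_lo <- t - bd * (plan$stride_buckets + sb)
      src_hi <- t - bd * plan$stride_buckets
      src <- in_window(src_lo, src_hi)
      if (length(src) >= plan$sample_size || src_lo <= start) break
      sb <- sb + 1L
    }
    if (length(src) < plan$sample_size) {
      message(sprintf("skipping evaluation at %s: insufficient source records (%d)",
                      format(t), length(src)))
      next
    }
    src_ids <- with_stream(derive_seed(plan$seed, "window-src", format(t)),
                           sample(records$study_id[src], plan$sample_size))
    src_patients <- records$patient_id[records$study_id %in% src_ids]
    repeat {
      tgt_hi <- t + bd * tb
      tgt <- in_window(t, tgt_hi)
      tgt <- tgt[!(records$patient_id[tgt] %in% src_patients)]
      if (length(tgt) >= plan$sample_size || tgt_hi > end + 1) break
      tb <- tb + 1L
    }
    if (length(tgt) < plan$sample_size) {
      message(sprintf("skipping evaluation at %s: insufficient target records (%d)",
                      format(t), length(tgt)))
      next
    }
    ids <- list(src = src_ids,
                tgt = with_stream(derive_seed(plan$seed, "window-tgt", format(t)),
                                  sample(records$study_id[tgt], plan$sample_size)))
    pairs[[length(pairs) + 1L]] <- structure(list(
      source_ids = ids$src, target_ids = ids$tgt,
      provenance = list(eval_date = t, source_buckets = sb, target_buckets = tb,
                        source_window = c(src_lo, src_hi),
                        target_window = c(t, tgt_hi), plan = plan)
    ), class = "sample_pair")
  }
  pairs
}

#' Audit non-target composition shifts between target sample and cohort
#'
#' For every covariate level, age group, and label, reports the absolute
#' difference between its proportion in the target sample and in the full
#' source population, flagging entries above `tolerance`. The intended
#' target category itself is excluded from flagging. Correlated categories
#' (e.g. a pathology that co-occurs with the enriched one) show up here.
#'
#' @param records cohort records data frame (or a `drift_cohort`).
#' @param source_ids,target_ids id vectors of the realized pair.
#' @param tolerance flag threshold on the absolute proportion difference.
#' @param target_category the intended `(column, level)` target, excluded
#'   from flagging (optional).
#' @return data frame with columns `variable`, `level`, `reference_prop`,
#'   `target_prop`, `abs_diff`, `flagged`.
#' @export
non_target_shift_audit <- function(records, source_ids, target_ids,
                                   tolerance = 0.05, target_category = NULL) {
  if (inherits(records, "drift_cohort")) records <- records$records
  tgt <- records[records$study_id %in% target_ids, , drop = FALSE]
  vars <- c("sex", "institution", "is_icu", "patient_class", "device", "view")
  rows <- list()
  prop_row <- function(variable, level, ref_p, tgt_p) {
    data.frame(variable = variable, level = as.character(level),
               reference_prop = ref_p, target_prop = tgt_p,
               abs_diff = abs(tgt_p - ref_p), stringsAsFactors = FALSE)
  }
  for (v in vars) {
    ref <- table(as.character(records[[v]]))
    for (lev in names(ref)) {
      rows[[length(rows) + 1L]] <- prop_row(
        v, lev, unname(ref[[lev]]) / nrow(records),
        mean(as.character(tgt[[v]]) == lev))
    }
  }
  ag_ref <- table(bin_age(records$age_years)) / nrow(records)
  ag_tgt <- table(bin_age(tgt$age_years)) / nrow(tgt)
  for (lev in names(ag_ref)) {
    rows[[length(rows) + 1L]] <- prop_row("age_group", lev,
                                          unname(ag_ref[[lev]]),
                                          unname(ag_tgt[[lev]]))
  }
  lcols <- grep("^label_\\d+$", names(records), value = TRUE)
  for (cn in lcols) {
    rows[[length(rows) + 1L]] <- prop_row(cn, "1", mean(records[[cn]] == 1),
                                          mean(tgt[[cn]] == 1))
  }
  out <- do.call(rbind, rows)
  out$flagged <- out$abs_diff > tolerance
  if (!is.null(target_category)) {
    is_target <- out$variable == target_category[1] &
      out$level == as.character(target_category[2])
    out$flagged[is_target] <- FALSE
  }
  out
}

#' Validate a sample pair's disjointness invariants
#'
#' @param pair a `sample_pair`.
#' @param records cohort records (needed for the patient-level check).
#' @return `TRUE` invisibly; errors on violation.
#' @export
check_sample_pair <- function(pair, records = NULL) {
  if (anyDuplicated(pair$source_ids) || anyDuplicated(pair$target_ids)) {
    stop("duplicate ids within a sample", call. = FALSE)
  }
  if (length(intersect(pair$source_ids, pair$target_ids)) > 0) {
    stop("source and target samples share record ids", call. = FALSE)
  }
  if (!is.null(records)) {
    if (inherits(records, "drift_cohort")) records <- records$records
    ps <- records$patient_id[records$study_id %in% pair$source_ids]
    pt <- records$patient_id[records$study_id %in% pair$target_ids]
    if (length(intersect(ps, pt)) > 0) {
      stop("source and target samples share patients", call. = FALSE)
    }
  }
  invisible(TRUE)
}
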