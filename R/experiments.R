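# Experiment harnesses: enrichment magnitude sweeps, sample-size sweeps, and
# rolling temporal monitoring, each contrasting MMD-based drift detection
# (tae / bbsd / tae+bbsd) with aggregate performance monitoring.

#' Sweep configuration
#'
#' @param methods subset of `c("tae", "bbsd", "tae+bbsd", "performance")`.
#' @param delta_grid enrichment fractions to test.
#' @param sample_sizes per-dataset sizes for the sample-size sweep.
#' @param n_repetitions repetitions per cell (each with fresh samples).
#' @param n_permutations MMD permutations per test.
#' @param alpha detection threshold on the p-value.
#' @param seed master seed fanned out to every repetition stream.
#' @return an object of class `sweep_config`.
#' @export
sweep_config <- function(methods = c("tae", "bbsd", "tae+bbsd", "performance"),
                         delta_grid = seq(0.05, 0.5, by = 0.05),
                         sample_sizes = c(500L, 1000L, 2000L, 4000L),
                         n_repetitions = 10L,
                         n_permutations = 1000L,
                         alpha = 0.05,
                         seed = 1L) {
  stopifnot(all(methods %in% c("tae", "bbsd", "tae+bbsd", "performance")),
            all(delta_grid >= 0 & delta_grid <= 0.5), alpha > 0, alpha < 1)
  structure(list(methods = methods, delta_grid = delta_grid,
                 sample_sizes = as.integer(sample_sizes),
                 n_repetitions = as.integer(n_repetitions),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, seed = as.integer(seed)),
            class = "sweep_config")
}

#' Precompute the reduced representations of a whole cohort
#'
#' @param cohort a `drift_cohort` with images.
#' @param models list with `encoder` (an `encoder_model`) and `classifier`
#'   (a `classifier_model`).
#' @return list with `tae` and `bbsd` feature matrices (rows = all records)
#'   and `pixels` (the pixel matrix).
#' @export
compute_representations <- function(cohort, models) {
  X <- images_as_matrix(cohort)
  list(tae = encode_images(models$encoder, X),
       bbsd = reduce_bbsd(models$classifier, X),
       pixels = X)
}

pair_features <- function(reps, pair, method) {
  ids <- c(pair$source_ids, pair$target_ids)
  F <- switch(method,
    "tae" = reps$tae[ids, , drop = FALSE],
    "bbsd" = reps$bbsd[ids, , drop = FALSE],
    "tae+bbsd" = reduce_combined(reps$tae[ids, , drop = FALSE],
                                 reps$bbsd[ids, , drop = FALSE],
                                 source_ids = pair$source_ids),
    stop("unknown method: ", method)
  )
  list(X = F[pair$source_ids, , drop = FALSE],
       Y = F[pair$target_ids, , drop = FALSE])
}

eval_pair <- function(cohort, reps, models, pair, methods, n_permutations,
                      test_seed) {
  out <- list()
  for (method in setdiff(methods, "performance")) {
    ft <- pair_features(reps, pair, method)
    res <- mmd_permutation_test(ft$X, ft$Y, n_permutations = n_permutations,
                                seed = derive_seed(test_seed, method))
    out[[method]] <- data.frame(method = method, p_value = res$p_value,
                                statistic = res$statistic,
                                auroc_source = NA_real_, auroc_target = NA_real_,
                                d_auroc = NA_real_, d_f1 = NA_real_,
                                d_brier = NA_real_, stringsAsFactors = FALSE)
  }
  if ("performance" %in% methods) {
    lcols <- label_cols(models$classifier$n_labels)
    rec <- cohort$records
    rownames(rec) <- rec$study_id
    gsrc <- as.matrix(rec[pair$source_ids, lcols])
    gtgt <- as.matrix(rec[pair$target_ids, lcols])
    psrc <- reps$bbsd[pair$source_ids, , drop = FALSE]
    ptgt <- reps$bbsd[pair$target_ids, , drop = FALSE]
    ms <- compute_metrics(gsrc, psrc)$macro
    mt <- compute_metrics(gtgt, ptgt)$macro
    out[["performance"]] <- data.frame(
      method = "performance", p_value = NA_real_, statistic = NA_real_,
      auroc_source = unname(ms["auroc"]), auroc_target = unname(mt["auroc"]),
      d_auroc = unname(mt["auroc"] - ms["auroc"]),
      d_f1 = unname(mt["f1"] - ms["f1"]),
      d_brier = unname(mt["brier"] - ms["brier"]), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Enrichment-magnitude sweep
#'
#' For each target category, enrichment fraction, and repetition: draw a
#' stratified source and an enriched target sample, reduce both with each
#' requested representation, run the MMD permutation test, and (for the
#' `performance` method) compare source/target macro metrics computed from
#' the classifier outputs against gold labels.
#'
#' @param cohort a `drift_cohort` with images (disjoint from the model
#'   training pool).
#' @param models list with `encoder` and `classifier`.
#' @param targets list of `(column, level)` target categories.
#' @param config a [sweep_config()].
#' @param sample_size per-dataset size (default 4000).
#' @param reps optional precomputed [compute_representations()] output.
#' @return a `sweep_result` data frame, one row per (target, delta,
#'   repetition, method).
#' @export
run_magnitude_sweep <- function(cohort, models, targets = list(c("sex", "M")),
                                config = sweep_config(), sample_size = 4000L,
                                reps = NULL) {
  if (is.null(reps)) reps <- compute_representations(cohort, models)
  rows <- list()
  for (target in targets) {
    tname <- paste(target, collapse = "=")
    for (delta in config$delta_grid) {
      for (r in seq_len(config$n_repetitions)) {
        rep_seed <- derive_seed(config$seed, "mag", tname, delta, r)
        spec <- enrichment_spec(sample_size = sample_size,
                                target_category = target, delta = delta,
                                seed = rep_seed)
        pair <- tryCatch({
          src <- stratified_source_sample(cohort$records, spec, rep_seed)
          enrich_target_sample(cohort$records, spec, src, rep_seed)
        }, error = function(e) {
          message(sprintf("skipping cell (%s, delta=%.2f, rep %d): %s",
                          tname, delta, r, conditionMessage(e)))
          NULL
        })
        if (is.null(pair)) next
        res <- eval_pair(cohort, reps, models, pair, config$methods,
                         config$n_permutations, derive_seed(rep_seed, "test"))
        res$target_category <- tname
        res$delta <- delta
        res$sample_size <- sample_size
        res$repetition <- r
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", class(out))
  out
}

#' Sample-size sweep at fixed drift magnitude
#'
#' @param cohort,models,config,reps as in [run_magnitude_sweep()].
#' @param target single `(column, level)` target category.
#' @param delta fixed enrichment fraction (default 0.4).
#' @return a `sweep_result` data frame, one row per (sample size,
#'   repetition, method).
#' @export
run_sample_size_sweep <- function(cohort, models, target = c("sex", "M"),
                                  config = sweep_config(), delta = 0.4,
                                  reps = NULL) {
  if (is.null(reps)) reps <- compute_representations(cohort, models)
  rows <- list()
  tname <- paste(target, collapse = "=")
  for (n in config$sample_sizes) {
    for (r in seq_len(config$n_repetitions)) {
      rep_seed <- derive_seed(config$seed, "size", tname, n, r)
      spec <- enrichment_spec(sample_size = n, target_category = target,
                              delta = delta, seed = rep_seed)
      pair <- tryCatch({
        src <- stratified_source_sample(cohort$records, spec, rep_seed)
        enrich_target_sample(cohort$records, spec, src, rep_seed)
      }, error = function(e) {
        message(sprintf("skipping cell (n=%d, rep %d): %s", n, r,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(pair)) next
      res <- eval_pair(cohort, reps, models, pair, config$methods,
                       config$n_permutations, derive_seed(rep_seed, "test"))
      res$target_category <- tname
      res$delta <- delta
      res$sample_size <- n
      res$repetition <- r
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sweep_result", class(out))
  out
}

#' Rolling temporal drift monitor
#'
#' Evaluates each rolling source/target window pair with the requested
#' methods, producing a time series of p-values and macro-metric deltas.
#'
#' @param cohort a `drift_cohort` (typically after [apply_regime()]); models
#'   must have been trained on pre-onset data only.
#' @param models list with `encoder` and `classifier`.
#' @param plan a [window_plan()].
#' @param config a [sweep_config()] (supplies methods, permutations, alpha).
#' @param reps optional precomputed representations.
#' @return a data frame with one row per (evaluation date, method):
#'   `eval_date`, `method`, `p_value`, `detected`, macro metric columns, and
#'   the realized window extents.
#' @export
run_temporal_monitor <- function(cohort, models, plan,
                                 config = sweep_config(methods = c("tae+bbsd",
                                                                   "performance")),
                                 reps = NULL) {
  if (is.null(reps)) reps <- compute_representations(cohort, models)
  pairs <- rolling_window_pairs(cohort$records, plan)
  rows <- list()
  for (pair in pairs) {
    t <- pair$provenance$eval_date
    res <- eval_pair(cohort, reps, models, pair, config$methods,
                     config$n_permutations,
                     derive_seed(config$seed, "monitor", format(t)))
    res$eval_date <- t
    res$source_buckets <- pair$provenance$source_buckets
    res$target_buckets <- pair$provenance$target_buckets
    rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$detected <- !is.na(out$p_value) & out$p_value < config$alpha
  out
}

#' Null calibration of the end-to-end drift pipeline
#'
#' Repeatedly draws two identically sampled, patient-disjoint groups from
#' the same cohort (one record per sampled patient, split at random — the
#' no-drift analogue of a window comparison), pushes both through the full
#' representation + MMD pipeline, and records the p-value. Under this
#' exchangeable null the p-values should be (approximately) uniform, so
#' `P(p <= alpha)` estimates the pipeline's false-alarm rate.
#'
#' Note that the *stratified enrichment* design at `delta = 0` is
#' deliberately not used here: fixing the cell composition of both samples
#' makes its p-values conservative (see the package vignette).
#'
#' @param cohort a `drift_cohort` with images.
#' @param models list with `encoder` and `classifier`.
#' @param n_per_group records per group.
#' @param n_repetitions number of independent null draws.
#' @param n_permutations MMD permutations per test.
#' @param method representation to test (default `"tae+bbsd"`).
#' @param seed master seed.
#' @param reps optional precomputed representations.
#' @return data frame with one row per repetition (`repetition`, `p_value`,
#'   `statistic`).
#' @export
run_null_calibration <- function(cohort, models, n_per_group = 200L,
                                 n_repetitions = 200L, n_permutations = 200L,
                                 method = "tae+bbsd", seed = 1L, reps = NULL) {
  if (is.null(reps)) reps <- compute_representations(cohort, models)
  rec <- cohort$records
  by_patient <- split(rec$study_id, rec$patient_id)
  upat <- names(by_patient)
  if (length(upat) < 2 * n_per_group) {
    stop("cohort has too few patients for the requested group size", call. = FALSE)
  }
  out <- vector("list", n_repetitions)
  for (r in seq_len(n_repetitions)) {
    rep_seed <- derive_seed(seed, "null", r)
    pair <- with_stream(rep_seed, {
      pats <- sample(upat, 2 * n_per_group)
      ids <- vapply(by_patient[pats], function(cand) {
        if (length(cand) == 1) cand else sample(cand, 1)
      }, character(1))
      list(source_ids = unname(ids[seq_len(n_per_group)]),
           target_ids = unname(ids[(n_per_group + 1):(2 * n_per_group)]))
    })
    res <- eval_pair(cohort, reps, models, pair, method, n_permutations,
                     derive_seed(rep_seed, "test"))
    out[[r]] <- data.frame(repetition = r, p_value = res$p_value,
                           statistic = res$statistic)
  }
  do.call(rbind, out)
}

#' Summarize sweep rows into per-cell aggregates
#'
#' @param rows a `sweep_result` data frame.
#' @param alpha detection threshold on the p-value.
#' @return data frame with one row per (target, delta, sample size, method):
#'   repetition count, mean/sd of the p-value, detection rate
#'   (`fraction of repetitions with p < alpha`), and mean/sd of the macro
#'   AUROC delta for performance rows.
#' @export
summarize_sweep <- function(rows, alpha = 0.05) {
  key <- interaction(rows$target_category, rows$delta, rows$sample_size,
                     rows$method, drop = TRUE)
  parts <- split(rows, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(
      target_category = d$target_category[1], delta = d$delta[1],
      sample_size = d$sample_size[1], method = d$method[1],
      n_repetitions = nrow(d),
      mean_p = mean(d$p_value), sd_p = stats::sd(d$p_value),
      detection_rate = mean(d$p_value < alpha),
      mean_d_auroc = mean(d$d_auroc), sd_d_auroc = stats::sd(d$d_auroc),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$target_category, out$method, out$sample_size, out$delta), ]
}

#' Write / read sweep rows as CSV
#'
#' @param rows sweep rows data frame.
#' @param path CSV path.
#' @return `write_sweep` returns `path` invisibly; `read_sweep` the data
#'   frame (round-trips exactly up to numeric printing precision).
#' @export
write_sweep <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("eval_date" %in% names(out)) out$eval_date <- as.Date(out$eval_date)
  out
}
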