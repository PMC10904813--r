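#' Configuration for a synthetic imaging cohort
#'
#' Describes a multi-site, multi-device cohort of imaging studies over a
#' multi-year date range: demographic covariates that influence image
#' appearance, binary pathology labels (optionally correlated) that add
#' learnable localized patterns, and the rendering parameters for the
#' grayscale images themselves.
#'
#' The default covariate image effects are small global intensity offsets
#' (plus a fixed per-device pattern and an age-scaled border) sized so that
#' enrichment drifts between 5% and 50% span the range from statistically
#' undetectable to reliably detectable at the sample sizes used in the
#' experiment harnesses. Label effects are localized additive blobs that are
#' independent of the covariates, so a classifier can learn them and
#' aggregate discrimination is insensitive to covariate-only drift.
#'
#' @param n_patients number of patients.
#' @param studies_per_patient mean number of studies per patient (>= 1);
#'   counts are drawn as `1 + Poisson(mean - 1)`.
#' @param date_range length-2 `Date` vector (start, end), start < end.
#' @param covariate_levels named list: covariate name -> named probability
#'   vector over its levels (each summing to 1).
#' @param age_distribution list of mixture components, each
#'   `list(weight, mean, sd)`; ages are truncated to `[18, 100]` and floored
#'   to integer years.
#' @param n_labels number of binary pathology labels.
#' @param label_base_prevalence base prevalence per label, in `[0, 1)`.
#' @param label_correlations data frame with columns `i`, `j`, `or`
#'   (`i < j`): presence of label `i` multiplies the odds of label `j`
#'   by `or`.
#' @param covariate_image_effects named list of per-level global intensity
#'   offsets plus `device_pattern_amplitude` and `age_frame_amplitude`.
#' @param label_image_effects numeric vector of per-label blob amplitudes.
#' @param image_size integer `(H, W)`, at least `(16, 16)`.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @param incomplete_frac fraction of records flagged
#'   `metadata_complete = FALSE`.
#' @param seed master integer seed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 2000,
                          studies_per_patient = 1.2,
                          date_range = as.Date(c("2016-01-01", "2020-12-31")),
                          covariate_levels = default_covariate_levels(),
                          age_distribution = list(
                            list(weight = 0.35, mean = 38, sd = 12),
                            list(weight = 0.65, mean = 68, sd = 13)
                          ),
                          n_labels = 14,
                          label_base_prevalence = default_label_prevalence(n_labels),
                          label_correlations = data.frame(
                            i = c(1L, 4L), j = c(2L, 5L), or = c(3.0, 2.0)
                          ),
                          covariate_image_effects = default_covariate_effects(),
                          label_image_effects = rep(0.30, n_labels),
                          image_size = c(32L, 32L),
                          noise_sd = 0.08,
                          incomplete_frac = 0.02,
                          seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    studies_per_patient = studies_per_patient,
    date_range = as.Date(date_range),
    covariate_levels = covariate_levels,
    age_distribution = age_distribution,
    n_labels = as.integer(n_labels),
    label_base_prevalence = label_base_prevalence,
    label_correlations = label_correlations,
    covariate_image_effects = covariate_image_effects,
    label_image_effects = label_image_effects,
    image_size = as.integer(image_size),
    noise_sd = noise_sd,
    incomplete_frac = incomplete_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_covariate_levels <- function() {
  device_p <- c(0.22, 0.18, 0.14, 0.11, 0.09, 0.075, 0.06, 0.045,
                0.035, 0.025, 0.015, 0.005)
  names(device_p) <- sprintf("d%02d", 1:12)
  list(
    sex = c(M = 0.5, F = 0.5),
    institution = c(site1 = 0.6, site2 = 0.4),
    is_icu = c("FALSE" = 0.85, "TRUE" = 0.15),
    patient_class = c(inpatient = 0.5, outpatient = 0.3, emergency = 0.2),
    device = device_p,
    view = c(AP = 0.55, PA = 0.37, LAT = 0.08)
  )
}

#' @rdname cohort_config
#' @export
default_label_prevalence <- function(n_labels = 14) {
  # prevalences between ~3% and ~25%, decaying with label index
  0.25 * exp(-0.16 * (seq_len(n_labels) - 1)) + 0.02
}

#' @rdname cohort_config
#' @export
default_covariate_effects <- function() {
  list(
    sex = c(M = 0.020, F = 0),
    institution = c(site1 = 0, site2 = 0.030),
    is_icu = c("FALSE" = 0, "TRUE" = 0.050),
    patient_class = c(inpatient = 0.020, outpatient = 0, emergency = 0.035),
    view = c(AP = 0, PA = 0.015, LAT = 0),
    device_pattern_amplitude = 0.030,
    age_frame_amplitude = 0.060
  )
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1, cfg$n_labels >= 1)
  if (!(length(cfg$date_range) == 2 && cfg$date_range[1] < cfg$date_range[2])) {
    stop("date_range start must precede end", call. = FALSE)
  }
  for (nm in names(cfg$covariate_levels)) {
    p <- cfg$covariate_levels[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("level probabilities for '%s' must be >= 0 and sum to 1", nm),
           call. = FALSE)
    }
  }
  if (length(cfg$label_base_prevalence) != cfg$n_labels ||
      any(cfg$label_base_prevalence < 0) || any(cfg$label_base_prevalence >= 1)) {
    stop("label_base_prevalence must be length n_labels with values in [0, 1)",
         call. = FALSE)
  }
  lc <- cfg$label_correlations
  if (nrow(lc) > 0) {
    if (any(lc$or <= 0)) {
      stop("correlation odds multipliers must be positive", call. = FALSE)
    }
    if (any(lc$i >= lc$j) || any(lc$j > cfg$n_labels)) {
      stop("label_correlations must reference i < j <= n_labels", call. = FALSE)
    }
  }
  if (any(cfg$image_size < 16)) stop("image_size must be at least 16x16", call. = FALSE)
  if (cfg$studies_per_patient < 1) stop("studies_per_patient mean must be >= 1", call. = FALSE)
  invisible(cfg)
}

label_cols <- function(n_labels) sprintf("label_%02d", seq_len(n_labels))

# ---- image rendering ---------------------------------------------------

.render_cache <- new.env(parent = emptyenv())

render_assets <- function(size) {
  key <- paste(size, collapse = "x")
  if (!is.null(.render_cache[[key]])) return(.render_cache[[key]])
  H <- size[1]; W <- size[2]
  ys <- (seq_len(H) - 0.5) / H
  xs <- (seq_len(W) - 0.5) / W
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  ellipse <- function(cx, cy, rx, ry) ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
  lungs <- ellipse(0.32, 0.52, 0.17, 0.27) | ellipse(0.68, 0.52, 0.17, 0.27)
  base <- matrix(0.12, H, W)
  base[lungs] <- 0.45
  frame <- matrix(0, H, W)
  frame[c(1, 2, H - 1, H), ] <- 1
  frame[, c(1, 2, W - 1, W)] <- 1
  blob <- function(cx, cy, s) exp(-(((X - cx)^2 + (Y - cy)^2) / (2 * s^2)))
  novel <- blob(0.32, 0.52, 0.10) + blob(0.68, 0.52, 0.10)
  .render_cache[[key]] <- list(X = X, Y = Y, base = base, frame = frame,
                               novel = novel, blob = blob)
  .render_cache[[key]]
}

label_blob <- function(k, assets) {
  # deterministic placement: odd labels in the left lung field, even in the
  # right, stacked vertically within each field
  lung_cx <- if (k %% 2 == 1) 0.32 else 0.68
  t <- (ceiling(k / 2) - 1)
  cy <- 0.32 + 0.40 * ((t %% 7) / 6)
  cx <- lung_cx + 0.05 * (if (t %% 2 == 0) 1 else -1)
  assets$blob(cx, cy, 0.045)
}

device_pattern <- function(device, size) {
  key <- paste("dev", device, paste(size, collapse = "x"), sep = "_")
  if (!is.null(.render_cache[[key]])) return(.render_cache[[key]])
  coarse <- with_stream(derive_seed(0L, "device-pattern", device),
                        matrix(stats::rnorm(16), 4, 4))
  up <- kronecker(coarse, matrix(1, ceiling(size[1] / 4), ceiling(size[2] / 4)))
  .render_cache[[key]] <- up[seq_len(size[1]), seq_len(size[2])]
  .render_cache[[key]]
}

#' Render a grayscale study image from a record
#'
#' Composes a fixed anatomical template (two elliptical lung fields), global
#' per-covariate intensity effects (sex, institution, ICU status, patient
#' class, view), a fixed additive pattern per imaging device, a border frame
#' scaled by patient age, one localized additive Gaussian blob per positive
#' pathology label, an optional bilateral novel-pattern effect, and Gaussian
#' pixel noise. Pixel values are clipped to `[0, 1]`.
#'
#' Label blobs are additive and independent of covariates by construction:
#' conditional on the label vector, the label-driven image component does not
#' depend on the demographic covariates.
#'
#' @param record single study record (list or one-row data frame) with fields
#'   `sex`, `age_years`, `institution`, `is_icu`, `patient_class`, `device`,
#'   `view`, labels `label_01 ...`, and optionally `novel_pattern`.
#' @param effects covariate image effects (see [default_covariate_effects()]).
#' @param label_effects numeric vector of per-label blob amplitudes.
#' @param size image size `(H, W)`, at least `(16, 16)`.
#' @param noise_sd Gaussian pixel noise sd; `0` renders deterministically.
#' @param seed seed for the noise stream (required when `noise_sd > 0`).
#' @param novel_effect amplitude of the bilateral novel pattern.
#' @return an `H x W` numeric matrix with values in `[0, 1]`.
#' @export
render_image <- function(record, effects = default_covariate_effects(),
                         label_effects = rep(0.30, 14),
                         size = c(32L, 32L), noise_sd = 0.08, seed = NULL,
                         novel_effect = 0.10) {
  if (any(size < 16)) stop("image size must be at least 16x16", call. = FALSE)
  assets <- render_assets(size)
  img <- assets$base
  offset <- 0
  for (cov in c("sex", "institution", "is_icu", "patient_class", "view")) {
    lev <- as.character(record[[cov]])
    eff <- effects[[cov]]
    if (!is.null(eff) && lev %in% names(eff)) offset <- offset + eff[[lev]]
  }
  img <- img + offset
  img <- img + effects$device_pattern_amplitude *
    device_pattern(as.character(record$device), size)
  img <- img + effects$age_frame_amplitude *
    ((record$age_years - 18) / 82) * assets$frame
  labs <- which(vapply(label_cols(length(label_effects)),
                       function(cn) isTRUE(record[[cn]] == 1), logical(1)))
  for (k in labs) {
    img <- img + label_effects[k] * label_blob(k, assets)
  }
  if (isTRUE(record$novel_pattern)) {
    img <- img + novel_effect * assets$novel
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0", call. = FALSE)
    img <- img + with_stream(seed,
      matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img), ncol(img)))
  }
  pmin(pmax(img, 0), 1)
}

# ---- cohort generation -------------------------------------------------

draw_level <- function(p) sample(names(p), 1L, prob = p)

draw_labels <- function(base_prev, correlations) {
  L <- length(base_prev)
  labs <- integer(L)
  u <- stats::runif(L)
  for (j in seq_len(L)) {
    p <- base_prev[j]
    if (p <= 0) next
    mult <- 1
    if (nrow(correlations) > 0) {
      rows <- correlations$j == j & labs[correlations$i] == 1L
      if (any(rows)) mult <- prod(correlations$or[rows])
    }
    odds <- p / (1 - p) * mult
    labs[j] <- as.integer(u[j] < odds / (1 + odds))
  }
  labs
}

#' Generate a synthetic imaging cohort
#'
#' Draws patients (sex, age, institution fixed per patient), one or more
#' studies per patient (date, device, view, ICU flag, patient class, labels),
#' and renders one image per study. Each record's random draws come from a
#' private stream keyed by `(seed, study_id)`, so subsetting the cohort never
#' changes the remaining records.
#'
#' @param config a [cohort_config()].
#' @param render_images if `FALSE`, skip image rendering (metadata-only
#'   cohorts are much faster for large statistical checks).
#' @return an object of class `drift_cohort`: a list with `records` (data
#'   frame, one row per study), `images` (named list of matrices keyed by
#'   `image_ref`, or `NULL`), and `config`.
#' @export
generate_cohort <- function(config, render_images = TRUE) {
  validate_cohort_config(config)
  cfg <- config
  seed <- cfg$seed
  lcols <- label_cols(cfg$n_labels)
  n_days <- as.integer(cfg$date_range[2] - cfg$date_range[1])

  rows <- vector("list", cfg$n_patients * 2L)
  nrec <- 0L
  for (p in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%06d", p)
    pat <- with_stream(derive_seed(seed, "pat", pid), {
      comp <- sample(length(cfg$age_distribution), 1L,
                     prob = vapply(cfg$age_distribution, `[[`, numeric(1), "weight"))
      ac <- cfg$age_distribution[[comp]]
      age <- floor(min(max(stats::rnorm(1, ac$mean, ac$sd), 18), 100))
      list(
        sex = draw_level(cfg$covariate_levels$sex),
        institution = draw_level(cfg$covariate_levels$institution),
        age = as.integer(age),
        n_studies = 1L + stats::rpois(1L, max(cfg$studies_per_patient - 1, 0))
      )
    })
    for (s in seq_len(pat$n_studies)) {
      sid <- sprintf("%s-S%02d", pid, s)
      rec <- with_stream(derive_seed(seed, "rec", sid), {
        list(
          patient_id = pid,
          study_id = sid,
          study_date = cfg$date_range[1] + sample.int(n_days + 1L, 1L) - 1L,
          sex = pat$sex,
          age_years = pat$age,
          institution = pat$institution,
          is_icu = draw_level(cfg$covariate_levels$is_icu) == "TRUE",
          patient_class = draw_level(cfg$covariate_levels$patient_class),
          device = draw_level(cfg$covariate_levels$device),
          view = draw_level(cfg$covariate_levels$view),
          labels = draw_labels(cfg$label_base_prevalence, cfg$label_correlations),
          metadata_complete = stats::runif(1) >= cfg$incomplete_frac
        )
      })
      nrec <- nrec + 1L
      rows[[nrec]] <- rec
    }
  }
  rows <- rows[seq_len(nrec)]

  records <- data.frame(
    patient_id = vapply(rows, `[[`, character(1), "patient_id"),
    study_id = vapply(rows, `[[`, character(1), "study_id"),
    study_date = as.Date(vapply(rows, function(r) as.character(r$study_date),
                                character(1))),
    sex = vapply(rows, `[[`, character(1), "sex"),
    age_years = vapply(rows, `[[`, integer(1), "age_years"),
    institution = vapply(rows, `[[`, character(1), "institution"),
    is_icu = vapply(rows, `[[`, logical(1), "is_icu"),
    patient_class = vapply(rows, `[[`, character(1), "patient_class"),
    device = vapply(rows, `[[`, character(1), "device"),
    view = vapply(rows, `[[`, character(1), "view"),
    metadata_complete = vapply(rows, `[[`, logical(1), "metadata_complete"),
    stringsAsFactors = FALSE
  )
  labmat <- t(vapply(rows, `[[`, integer(cfg$n_labels), "labels"))
  colnames(labmat) <- lcols
  records <- cbind(records, as.data.frame(labmat))
  records$novel_pattern <- FALSE
  records$image_ref <- records$study_id

  images <- NULL
  if (render_images) {
    images <- render_cohort_images(records, cfg)
  }
  structure(list(records = records, images = images, config = cfg),
            class = "drift_cohort")
}

render_cohort_images <- function(records, cfg, novel_effect = 0.10) {
  images <- vector("list", nrow(records))
  names(images) <- records$image_ref
  for (i in seq_len(nrow(records))) {
    images[[i]] <- render_image(
      records[i, ], effects = cfg$covariate_image_effects,
      label_effects = cfg$label_image_effects, size = cfg$image_size,
      noise_sd = cfg$noise_sd,
      seed = derive_seed(cfg$seed, "img", records$study_id[i]),
      novel_effect = novel_effect
    )
  }
  images
}

#' @export
print.drift_cohort <- function(x, ...) {
  cat(sprintf("<drift_cohort> %d records, %d patients, %s to %s, images: %s\n",
              nrow(x$records), length(unique(x$records$patient_id)),
              min(x$records$study_date), max(x$records$study_date),
              if (is.null(x$images)) "none" else length(x$images)))
  invisible(x)
}

# ---- temporal regime ---------------------------------------------------

#' Specify a temporal regime change
#'
#' Models the arrival of a novel radiographic pattern: after `onset_date` the
#' probability that a study carries the novel bilateral pattern ramps
#' linearly from 0 to `peak_prevalence` over `ramp_days`, while non-novel
#' encounters are suppressed (dropped) with probability `volume_suppression`,
#' emulating a simultaneous fall in routine imaging volume.
#'
#' @param onset_date `Date` of regime onset.
#' @param ramp_days days over which prevalence ramps to its peak.
#' @param peak_prevalence peak novel-pattern prevalence, in `(0, 1)`.
#' @param volume_suppression post-onset drop probability for non-novel
#'   records, in `[0, 1)`.
#' @param novel_pattern_effect image amplitude of the bilateral pattern.
#' @return an object of class `regime_spec`.
#' @export
regime_spec <- function(onset_date, ramp_days = 30L, peak_prevalence = 0.3,
                        volume_suppression = 0.3, novel_pattern_effect = 0.10) {
  stopifnot(ramp_days >= 1, peak_prevalence >= 0, peak_prevalence < 1,
            volume_suppression >= 0, volume_suppression < 1)
  structure(list(onset_date = as.Date(onset_date), ramp_days = as.integer(ramp_days),
                 peak_prevalence = peak_prevalence,
                 volume_suppression = volume_suppression,
                 novel_pattern_effect = novel_pattern_effect),
            class = "regime_spec")
}

#' Apply a temporal regime change to a cohort
#'
#' @param cohort a `drift_cohort`.
#' @param regime a [regime_spec()].
#' @return a new `drift_cohort` with novel-pattern flags assigned, suppressed
#'   records dropped, and affected images re-rendered.
#' @export
apply_regime <- function(cohort, regime) {
  stopifnot(inherits(cohort, "drift_cohort"), inherits(regime, "regime_spec"))
  rec <- cohort$records
  cfg <- cohort$config
  if (regime$onset_date < min(rec$study_date) ||
      regime$onset_date > max(rec$study_date)) {
    stop("regime onset_date lies outside the cohort date range", call. = FALSE)
  }
  days_post <- as.numeric(rec$study_date - regime$onset_date)
  ramp <- pmin(pmax(days_post / regime$ramp_days, 0), 1)
  p_novel <- ramp * regime$peak_prevalence

  keep <- rep(TRUE, nrow(rec))
  novel <- rep(FALSE, nrow(rec))
  post <- which(days_post >= 0)
  for (i in post) {
    draws <- with_stream(derive_seed(cfg$seed, "regime", rec$study_id[i]),
                         stats::runif(2))
    novel[i] <- draws[1] < p_novel[i]
    if (!novel[i]) keep[i] <- draws[2] >= regime$volume_suppression
  }
  rec$novel_pattern <- novel
  rec <- rec[keep, , drop = FALSE]

  images <- cohort$images
  if (!is.null(images)) {
    images <- images[rec$image_ref]
    for (i in which(rec$novel_pattern)) {
      images[[rec$image_ref[i]]] <- render_image(
        rec[i, ], effects = cfg$covariate_image_effects,
        label_effects = cfg$label_image_effects, size = cfg$image_size,
        noise_sd = cfg$noise_sd,
        seed = derive_seed(cfg$seed, "img", rec$study_id[i]),
        novel_effect = regime$novel_pattern_effect
      )
    }
  }
  structure(list(records = rec, images = images, config = cfg),
            class = "drift_cohort")
}

#' Subset a cohort by study ids
#'
#' @param cohort a `drift_cohort`.
#' @param ids study ids to keep.
#' @return a `drift_cohort` restricted to those records (and their images).
#' @export
subset_cohort <- function(cohort, ids) {
  rec <- cohort$records[cohort$records$study_id %in% ids, , drop = FALSE]
  images <- if (!is.null(cohort$images)) cohort$images[rec$image_ref] else NULL
  structure(list(records = rec, images = images, config = cohort$config),
            class = "drift_cohort")
}

#' Split a cohort into model-training and evaluation pools
#'
#' The split is at the patient level via a deterministic hash of
#' `patient_id`, so no patient appears in both pools; the training pool is
#' reserved for fitting the reducers and is never reused downstream.
#'
#' @param cohort a `drift_cohort`.
#' @param train_frac fraction of patients assigned to the training pool.
#' @param seed integer seed for the hash stream.
#' @return list with `train` and `eval` cohorts.
#' @export
partition_cohort <- function(cohort, train_frac = 0.25, seed = 1L) {
  rec <- cohort$records
  upat <- unique(rec$patient_id)
  h <- vapply(upat, function(p) derive_seed(seed, "pool", p) %% 1000L,
              integer(1))
  train_pat <- upat[h < round(train_frac * 1000)]
  in_train <- rec$patient_id %in% train_pat
  list(train = subset_cohort(cohort, rec$study_id[in_train]),
       eval = subset_cohort(cohort, rec$study_id[!in_train]))
}

# ---- I/O helpers -------------------------------------------------------

#' Stack cohort images into a pixel matrix
#'
#' @param cohort a `drift_cohort` with images.
#' @param ids image refs (default: all records, in record order).
#' @return an `n x (H*W)` matrix with rownames set to the image refs.
#' @export
images_as_matrix <- function(cohort, ids = cohort$records$image_ref) {
  stopifnot(!is.null(cohort$images))
  miss <- setdiff(ids, names(cohort$images))
  if (length(miss) > 0) stop("missing images for some ids", call. = FALSE)
  out <- t(vapply(cohort$images[ids], as.vector,
                  numeric(prod(cohort$config$image_size))))
  rownames(out) <- ids
  out
}

#' Write / read a cohort as plain-text files
#'
#' Records go to `<path>.csv` (ISO-8601 dates); images, if present, to
#' `<path>-images.csv` in long format (`image_ref, pixel, value`).
#'
#' @param cohort a `drift_cohort`.
#' @param path file stem (no extension).
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   `drift_cohort` (with a minimal config recording the image size).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort$records, paste0(path, ".csv"), row.names = FALSE)
  if (!is.null(cohort$images)) {
    n_px <- prod(cohort$config$image_size)
    long <- data.frame(
      image_ref = rep(names(cohort$images), each = n_px),
      pixel = rep(seq_len(n_px), length(cohort$images)),
      value = as.vector(vapply(cohort$images, as.vector, numeric(n_px)))
    )
    utils::write.csv(long, paste0(path, "-images.csv"), row.names = FALSE)
    utils::write.csv(data.frame(H = cohort$config$image_size[1],
                                W = cohort$config$image_size[2]),
                     paste0(path, "-meta.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  rec <- utils::read.csv(paste0(path, ".csv"), stringsAsFactors = FALSE)
  rec$study_date <- as.Date(rec$study_date)
  images <- NULL
  size <- NULL
  if (file.exists(paste0(path, "-images.csv"))) {
    meta <- utils::read.csv(paste0(path, "-meta.csv"))
    size <- c(meta$H[1], meta$W[1])
    long <- utils::read.csv(paste0(path, "-images.csv"), stringsAsFactors = FALSE)
    images <- lapply(split(long$value, factor(long$image_ref, levels = unique(long$image_ref))),
                     function(v) matrix(v, size[1], size[2]))
  }
  cfg <- list(image_size = size)
  structure(list(records = rec, images = images, config = cfg),
            class = "drift_cohort")
}
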