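# Shared fixtures, built once per test run and cached. All data is
# generated in code; sizes are desk-scale so the whole suite stays fast.

fixture_env <- new.env(parent = emptyenv())

# Imaging cohort with trained reducers: the workhorse for representation,
# drift-detection, and experiment tests. ~12.6k records; the filtered cohort
# is split into a model-training pool and an evaluation pool at the patient
# level.
imaging_fixture <- function() {
  if (!is.null(fixture_env$imaging)) return(fixture_env$imaging)
  cfg <- cohort_config(n_patients = 11000, studies_per_patient = 1.15,
                       seed = 42)
  co <- generate_cohort(cfg)
  fl <- filter_records(co)
  parts <- partition_cohort(subset_cohort(co, fl$records$study_id),
                            train_frac = 0.25, seed = 42)
  Xtr <- images_as_matrix(parts$train)
  ae <- train_autoencoder(Xtr, encoder_spec(epochs = 60, seed = 42),
                          size = cfg$image_size)
  clf <- train_classifier(parts$train$records, Xtr,
                          classifier_spec(epochs = 150, seed = 42))
  models <- list(encoder = ae, classifier = clf)
  reps <- compute_representations(parts$eval, models)
  fixture_env$imaging <- list(config = cfg, cohort = co, train = parts$train,
                              eval = parts$eval, models = models, reps = reps)
  fixture_env$imaging
}

# Large metadata-only cohort (no images) for statistical checks on the
# generator and the sampling designs: ~19.5k records, with a strong 4.0
# odds multiplier between labels 1 and 2.
metadata_fixture <- function() {
  if (!is.null(fixture_env$metadata)) return(fixture_env$metadata)
  cfg <- cohort_config(
    n_patients = 17000, studies_per_patient = 1.15, seed = 123,
    label_correlations = data.frame(i = c(1L, 4L), j = c(2L, 5L),
                                    or = c(4.0, 2.0))
  )
  fixture_env$metadata <- generate_cohort(cfg, render_images = FALSE)
  fixture_env$metadata
}

# Dated imaging cohort with a temporal regime change (novel bilateral
# pattern ramping up from 2020-03-01 plus volume suppression), evaluated
# with the drift-free models from imaging_fixture().
temporal_fixture <- function() {
  if (!is.null(fixture_env$temporal)) return(fixture_env$temporal)
  cfg <- cohort_config(n_patients = 8000, studies_per_patient = 1.05,
                       date_range = as.Date(c("2019-01-01", "2020-09-30")),
                       seed = 77)
  co <- generate_cohort(cfg)
  regime <- regime_spec(onset_date = "2020-03-01", ramp_days = 30L,
                        peak_prevalence = 0.3, volume_suppression = 0.3)
  fixture_env$temporal <- list(cohort = apply_regime(co, regime),
                               pre = co, regime = regime)
  fixture_env$temporal
}

# Ten-record preprocessing fixture: 1 incomplete, 2 lateral views, 1
# duplicate within a study, 1 record on a rare device excluded at top_k = 2.
preprocess_fixture <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:10),
    study_id = c("S01", "S02", "S03", "S04", "S05",
                 "S06", "S07", "S08", "S01", "S10"),
    study_date = as.Date("2020-01-01") + c(10, 2, 3, 4, 5, 6, 7, 8, 1, 9),
    view = c("AP", "PA", "AP", "PA", "AP", "LAT", "LAT", "AP", "AP", "AP"),
    device = c("d01", "d01", "d02", "d02", "d01",
               "d01", "d02", "d01", "d01", "d99"),
    metadata_complete = c(rep(TRUE, 7), FALSE, TRUE, TRUE),
    image_ref = sprintf("img%02d", 1:10),
    stringsAsFactors = FALSE
  )
}

# A minimal single record for rendering tests.
template_record <- function(sex = "M", age = 50L, institution = "site1",
                            icu = FALSE, pclass = "inpatient", device = "d01",
                            view = "AP", labels = integer(14),
                            novel = FALSE) {
  rec <- list(sex = sex, age_years = age, institution = institution,
              is_icu = icu, patient_class = pclass, device = device,
              view = view, novel_pattern = novel)
  for (k in seq_along(labels)) rec[[sprintf("label_%02d", k)]] <- labels[k]
  rec
}
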