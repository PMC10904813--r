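test_that("stratified source samples match cohort cell proportions", {
  co <- metadata_fixture()
  spec <- enrichment_spec(sample_size = 4000L, target_category = c("sex", "M"),
                          delta = 0, seed = 21)
  ids <- stratified_source_sample(co$records, spec, rep_seed = 21)
  expect_equal(length(ids), 4000L)
  expect_equal(anyDuplicated(ids), 0L)

  src <- co$records[co$records$study_id %in% ids, ]
  cells_all <- mmdrift:::strat_cells(co$records, spec$strat_columns)
  cells_src <- mmdrift:::strat_cells(src, spec$strat_columns)
  p_all <- table(cells_all) / nrow(co$records)
  p_src <- table(factor(cells_src, levels = names(p_all))) / length(ids)
  # largest-remainder allocation: every cell within one record of target
  expect_lt(max(abs(p_src - p_all)), 2 / 4000)

  # different repetition seeds give different draws, same composition
  ids2 <- stratified_source_sample(co$records, spec, rep_seed = 22)
  expect_false(setequal(ids, ids2))
  src2 <- co$records[co$records$study_id %in% ids2, ]
  p_src2 <- table(factor(mmdrift:::strat_cells(src2, spec$strat_columns),
                         levels = names(p_all))) / length(ids2)
  expect_lt(max(abs(p_src2 - p_src)), 2 / 4000)

  # sample_size = cohort size returns the whole cohort
  tiny <- co$records[1:60, ]
  spec_all <- enrichment_spec(sample_size = 60L, delta = 0, seed = 1)
  expect_setequal(stratified_source_sample(tiny, spec_all), tiny$study_id)
})

test_that("enrichment arithmetic and disjointness match the design", {
  co <- metadata_fixture()
  # 500 images, 10% male enrichment: 450 base + 50 male
  spec <- enrichment_spec(sample_size = 500L, target_category = c("sex", "M"),
                          delta = 0.10, seed = 31)
  src <- stratified_source_sample(co$records, spec, rep_seed = 31)
  pair <- enrich_target_sample(co$records, spec, src, rep_seed = 31)
  expect_equal(length(pair$base_ids), 450L)
  expect_equal(length(pair$enriched_ids), 50L)
  expect_equal(length(pair$target_ids), 500L)
  enr <- co$records[co$records$study_id %in% pair$enriched_ids, ]
  expect_true(all(enr$sex == "M"))
  expect_true(check_sample_pair(pair, co$records))

  # 4000 at 5%: 3800 + 200
  spec2 <- enrichment_spec(sample_size = 4000L, target_category = c("sex", "M"),
                           delta = 0.05, seed = 32)
  src2 <- stratified_source_sample(co$records, spec2, rep_seed = 32)
  pair2 <- enrich_target_sample(co$records, spec2, src2, rep_seed = 32)
  expect_equal(length(pair2$base_ids), 3800L)
  expect_equal(length(pair2$enriched_ids), 200L)

  # delta = 0 is a plain stratified sample with the source's composition
  spec0 <- enrichment_spec(sample_size = 2000L, target_category = c("sex", "M"),
                           delta = 0, seed = 33)
  src0 <- stratified_source_sample(co$records, spec0, rep_seed = 33)
  pair0 <- enrich_target_sample(co$records, spec0, src0, rep_seed = 33)
  expect_equal(length(pair0$enriched_ids), 0L)
  p_src <- mean(co$records$sex[co$records$study_id %in% src0] == "M")
  p_tgt <- mean(co$records$sex[co$records$study_id %in% pair0$target_ids] == "M")
  expect_lt(abs(p_src - p_tgt), 3 * sqrt(0.25 / 2000))

  # exhausting the category errors with a shortfall message
  few <- co$records[co$records$sex == "F" | co$records$study_id %in% src[1:50], ]
  spec_big <- enrichment_spec(sample_size = 40L, target_category = c("sex", "M"),
                              delta = 0.9, seed = 34)
  expect_error(enrich_target_sample(few, spec_big, src[1:50], rep_seed = 34),
               "exhausted")
})

test_that("enriched-level proportion follows (1 - delta) * p0 + delta", {
  co <- metadata_fixture()
  p0 <- mean(co$records$sex == "M")
  for (delta in c(0.05, 0.25, 0.5)) {
    spec <- enrichment_spec(sample_size = 4000L,
                            target_category = c("sex", "M"), delta = delta,
                            seed = 41)
    src <- stratified_source_sample(co$records, spec,
                                    rep_seed = derive_seed(41L, delta))
    pair <- enrich_target_sample(co$records, spec, src,
                                 rep_seed = derive_seed(41L, delta))
    tgt <- co$records[co$records$study_id %in% pair$target_ids, ]
    expected <- (1 - delta) * p0 + delta
    se <- sqrt(expected * (1 - expected) / 4000)
    expect_lt(abs(mean(tgt$sex == "M") - expected), 3 * se,
              label = sprintf("delta=%.2f enriched proportion", delta))
  }
})

test_that("labels can be enrichment targets", {
  co <- metadata_fixture()
  spec <- enrichment_spec(sample_size = 1000L,
                          target_category = c("label_01", "1"), delta = 0.3,
                          seed = 51)
  src <- stratified_source_sample(co$records, spec, rep_seed = 51)
  pair <- enrich_target_sample(co$records, spec, src, rep_seed = 51)
  enr <- co$records[co$records$study_id %in% pair$enriched_ids, ]
  expect_true(all(enr$label_01 == 1))
  expect_equal(length(pair$enriched_ids), 300L)
})

test_that("rolling windows keep their size, widen on thin buckets, and never overlap", {
  # uniform cohort: ~1000 records per 30-day bucket
  n <- 12000
  rec <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    study_id = sprintf("S%05d", seq_len(n)),
    study_date = as.Date("2020-01-01") + ((seq_len(n) - 1) %% 360),
    stringsAsFactors = FALSE
  )
  plan <- window_plan(sample_size = 500L, seed = 61)
  pairs <- rolling_window_pairs(rec, plan)
  expect_gt(length(pairs), 3)
  for (pair in pairs) {
    expect_equal(length(pair$source_ids), 500L)
    expect_equal(length(pair$target_ids), 500L)
    expect_equal(pair$provenance$source_buckets, 1L)
    expect_equal(pair$provenance$target_buckets, 1L)
    expect_true(check_sample_pair(pair, rec))
    expect_lte(pair$provenance$source_window[2],
               pair$provenance$target_window[1])
    src_dates <- rec$study_date[rec$study_id %in% pair$source_ids]
    tgt_dates <- rec$study_date[rec$study_id %in% pair$target_ids]
    expect_lt(max(src_dates), min(tgt_dates))
  }

  # a thin bucket (200 records) forces the source window to widen backwards
  bucket_sizes <- c(1000, 200, 1000, 1000)
  dates <- as.Date("2020-01-01") +
    unlist(lapply(seq_along(bucket_sizes), function(b) {
      30 * (b - 1) + ((seq_len(bucket_sizes[b]) - 1) %% 30)
    }))
  thin <- data.frame(
    patient_id = sprintf("Q%05d", seq_along(dates)),
    study_id = sprintf("T%05d", seq_along(dates)),
    study_date = dates, stringsAsFactors = FALSE
  )
  plan2 <- window_plan(sample_size = 500L, step_days = 30L, seed = 62)
  pairs2 <- rolling_window_pairs(thin, plan2)
  expect_gt(length(pairs2), 1)
  sb <- vapply(pairs2, function(p) p$provenance$source_buckets, integer(1))
  expect_true(any(sb >= 2L))
  for (pair in pairs2) {
    expect_equal(length(pair$source_ids), 500L)
    expect_equal(length(pair$target_ids), 500L)
  }
})

test_that("non-target shift audit flags only real composition changes", {
  co <- metadata_fixture()
  # delta = 0 with a large sample: nothing should drift beyond tolerance
  spec0 <- enrichment_spec(sample_size = 4000L, target_category = c("sex", "M"),
                           delta = 0, seed = 71)
  src0 <- stratified_source_sample(co$records, spec0, rep_seed = 71)
  pair0 <- enrich_target_sample(co$records, spec0, src0, rep_seed = 71)
  audit0 <- non_target_shift_audit(co$records, pair0$source_ids,
                                   pair0$target_ids, tolerance = 0.05)
  expect_false(any(audit0$flagged))

  # enriching label_01 drags the perfectly correlated label_02 along
  rec2 <- co$records
  rec2$label_02 <- rec2$label_01
  spec2 <- enrichment_spec(sample_size = 2000L,
                           target_category = c("label_01", "1"), delta = 0.5,
                           seed = 72)
  src2 <- stratified_source_sample(rec2, spec2, rep_seed = 72)
  pair2 <- enrich_target_sample(rec2, spec2, src2, rep_seed = 72)
  audit2 <- non_target_shift_audit(rec2, pair2$source_ids, pair2$target_ids,
                                   tolerance = 0.05,
                                   target_category = c("label_01", "1"))
  expect_false(any(audit2$flagged[audit2$variable == "label_01"]))
  expect_true(audit2$flagged[audit2$variable == "label_02"])

  # tolerance 1 never flags
  audit3 <- non_target_shift_audit(rec2, pair2$source_ids, pair2$target_ids,
                                   tolerance = 1.0)
  expect_false(any(audit3$flagged))
})
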