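test_that("node stage maps node counts to the three NPI stages", {
  expect_identical(compute_node_stage(0), 1L)
  expect_identical(compute_node_stage(1), 2L)
  expect_identical(compute_node_stage(2), 2L)
  expect_identical(compute_node_stage(3), 2L)
  expect_identical(compute_node_stage(4), 3L)
  expect_identical(compute_node_stage(25), 3L)
  expect_error(compute_node_stage(-1), "non-negative")
  expect_error(compute_node_stage(1.5), "integer")
})

test_that("NPI arithmetic follows 0.2*size + grade + node stage", {
  expect_equal(compute_npi(0, 1, 0)$npi, 2.0)
  expect_equal(compute_npi(2, 2, 2)$npi, 4.4)
  # one extra centimetre adds exactly 0.2 NPI points
  for (size in c(0, 1.3, 2.8, 6)) {
    expect_equal(compute_npi(size + 1, 2, 1)$npi - compute_npi(size, 2, 1)$npi,
                 0.2)
  }
  expect_error(compute_npi(NA, 2, 1), "impute")
  expect_error(compute_npi(2, 2), "impute")
})

test_that("NPI is nondecreasing in each argument", {
  sizes <- seq(0, 8, by = 0.5)
  vals <- vapply(sizes, function(s) compute_npi(s, 2, 1)$npi, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(diff(vapply(1:3, function(g) compute_npi(2, g, 1)$npi,
                              numeric(1))) >= 0))
  expect_true(all(diff(vapply(0:8, function(n) compute_npi(2, 2, n)$npi,
                              numeric(1))) >= 0))
})

test_that("prognostic groups partition [0, Inf) at the Blamey thresholds", {
  expect_identical(assign_prognostic_group(2.4), "EPG")
  expect_identical(assign_prognostic_group(3.4), "GPG")
  expect_identical(assign_prognostic_group(4.4), "MPG I")
  expect_identical(assign_prognostic_group(5.4), "MPG II")
  expect_identical(assign_prognostic_group(6.4), "PPG")
  expect_identical(assign_prognostic_group(6.41), "VPPG")
  expect_identical(assign_prognostic_group(7.0), "VPPG")
  # every value maps to exactly one group; groups appear in order
  grid <- seq(0, 10, by = 0.01)
  gs <- vapply(grid, assign_prognostic_group, character(1))
  expect_true(all(gs %in% prognostic_group_levels()))
  expect_true(!is.unsorted(match(gs, prognostic_group_levels())))
  # adjacent thresholds differ by 1.0
  expect_equal(diff(c(2.4, 3.4, 4.4, 5.4, 6.4)), rep(1, 4))
})

test_that("dNPI imputation fills nodes with 0, grade with 2, size by TNM mode", {
  rec <- make_record()
  rec$tumor_grade <- NA
  rec$n_nodes <- NA
  out <- impute_for_dnpi(rec, list())
  expect_equal(out, list(tumor_size_cm = 2.0, grade = 2L, n_nodes = 0L))

  rec2 <- make_record()
  rec2$tumor_size_cm <- NA
  peers <- lapply(c(2, 2, 3), function(s) {
    r <- make_record(patient_id = paste0("P", s))
    r$tumor_size_cm <- s
    r
  })
  expect_equal(impute_for_dnpi(rec2, peers)$tumor_size_cm, 2)

  # fully observed record is unchanged
  expect_equal(impute_for_dnpi(make_record(), list()),
               list(tumor_size_cm = 2.0, grade = 2L, n_nodes = 1L))

  # all three missing -> unavailable
  rec3 <- make_record()
  rec3$tumor_size_cm <- NA; rec3$tumor_grade <- NA; rec3$n_nodes <- NA
  expect_null(impute_for_dnpi(rec3, peers))

  # missing size with no TNM peers -> unavailable
  rec4 <- make_record()
  rec4$tumor_size_cm <- NA
  rec4$tnm_stage <- "T4"
  expect_null(impute_for_dnpi(rec4, peers))
})

test_that("bio binarization: 1 outside the normal range, 2 inside, closed bounds", {
  spec <- bio_marker_spec("LEUK", 4, 10)
  expect_identical(binarize_bio(12, spec), 1L)
  expect_identical(binarize_bio(3.9, spec), 1L)
  expect_identical(binarize_bio(7, spec), 2L)
  expect_identical(binarize_bio(4, spec), 2L)
  expect_identical(binarize_bio(10, spec), 2L)
  expect_identical(binarize_bio(NA, spec), NA_integer_)
})

test_that("delta tokens divide by ten, round half away from zero, skip zero", {
  spec <- bio_marker_spec("CA15-3", 0, 30)
  expect_identical(delta_token(57, 10, spec), 5L)   # 4.7 -> 5
  expect_identical(delta_token(10, 22, spec), -1L)  # -1.2 -> -1
  expect_identical(delta_token(15, 10, spec), 1L)   # 0.5 rounds away from zero
  expect_identical(delta_token(10, 10, spec), NA_integer_) # zero delta skipped
  expect_identical(delta_token(12, 10, spec), NA_integer_) # rounds to zero
  expect_identical(delta_token(12, NA, spec), NA_integer_) # first observation
  spec5 <- bio_marker_spec("X", 0, 1, delta_unit_divisor = 5)
  expect_identical(delta_token(12, 0, spec5), 2L)
})

test_that("age is rounded to the nearest integer year", {
  birth <- as.Date("1960-01-01")
  expect_identical(discretize_age(birth, as.Date("2010-01-01")), 50L)
  expect_identical(discretize_age(birth, birth + round(49.6 * 365.25)), 50L)
  expect_identical(discretize_age(birth, birth + round(49.4 * 365.25)), 49L)
  expect_identical(discretize_age(NA, as.Date("2010-01-01")), NA_integer_)
})

test_that("delay buckets tile the non-negative day axis exactly once", {
  expect_identical(discretize_delay(5), "W0")
  expect_identical(discretize_delay(0), "W0")
  expect_identical(discretize_delay(7), "W1")
  expect_identical(discretize_delay(27), "W3")
  expect_identical(discretize_delay(28), "M1")
  expect_identical(discretize_delay(100), "M4")
  expect_identical(discretize_delay(364), "M12")
  expect_identical(discretize_delay(365), "LT")
  expect_identical(discretize_delay(400), "LT")
  expect_error(discretize_delay(-1), "non-negative")
  buckets <- vapply(0:1500, discretize_delay, character(1))
  expect_true(all(buckets %in% delay_bucket_levels()))
  expect_true(!is.unsorted(match(buckets, delay_bucket_levels())))
})

test_that("marker missingness filter keeps markers under the 30% threshold", {
  specs <- list(a = bio_marker_spec("a", 0, 1),
                b = bio_marker_spec("b", 0, 1),
                c = bio_marker_spec("c", 0, 1))
  # 20 panel visits: a fully observed, b missing 25%, c missing 35%
  visits <- lapply(1:20, function(i) {
    bio <- list(a = 0.5)
    if (i > 5) bio$b <- 0.5
    if (i > 7) bio$c <- 0.5
    visit_event(as.Date("2016-01-01") + i, department = "laboratoire",
                bio_values = bio)
  })
  rec <- make_record(visits = visits)
  kept <- filter_bio_features(list(rec), specs)
  expect_identical(names(kept), c("a", "b"))
  expect_equal(unname(attr(kept, "missingness")), c(0, 0.25, 0.35))
  expect_error(filter_bio_features(list(), specs), "empty")
  # the reference panel on generated data keeps all five markers
  kept5 <- filter_bio_features(small_cohort_fixture())
  expect_identical(names(kept5), names(default_marker_specs()))
})

test_that("label normalization strips accents/punctuation, merges synonyms, filters rare", {
  syn <- c(anapath = "anatomocytopathologie",
           anatomopathologie = "anatomocytopathologie")
  counts <- c(anatomocytopathologie = 250, radiologie = 99)
  expect_identical(normalize_label("Anapath", syn, counts),
                   "anatomocytopathologie")
  expect_identical(normalize_label("Radiologie", syn, counts), NA_character_)
  expect_identical(normalize_label("anatomocytopathologie", syn, counts),
                   "anatomocytopathologie")
  expect_identical(normalize_label("écho-graphie!", character()),
                   "echo graphie")
  expect_identical(normalize_label(NA), NA_character_)
})
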