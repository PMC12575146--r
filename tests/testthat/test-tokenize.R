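test_that("history window spans diagnosis - 182 days to surgery + 365 days", {
  diag <- as.Date("2016-03-01")
  surg <- as.Date("2016-04-01")
  visits <- list(
    make_visit(diag - 200),        # before the window
    make_visit(diag - 30),         # one month before diagnosis: included
    make_visit(diag - 182),        # boundary: included
    make_visit(surg + 365),        # boundary: included
    make_visit(surg + 730)         # two years after surgery: excluded
  )
  rec <- make_record(visits = visits)
  win <- select_history_window(rec)
  expect_length(win$visits, 3L)
  dates <- vapply(win$visits, function(v) as.character(v$date), character(1))
  expect_true(all(as.Date(dates) >= diag - 182 & as.Date(dates) <= surg + 365))
  rec$visits <- list()
  expect_length(select_history_window(rec)$visits, 0L)
})

test_that("cohort filters exclude pre-index relapse, short follow-up, sparse histories", {
  recs <- list(
    make_record("A", dfs_event = TRUE, followup_days = 200),   # pre-index relapse
    make_record("B", dfs_event = FALSE, followup_days = 800),  # censored early
    make_record("C", dfs_event = FALSE, followup_days = 1200), # kept, event-free
    make_record("D", dfs_event = TRUE, followup_days = 700),   # kept, event
    make_record("E", dfs_event = FALSE, followup_days = 1200,  # too few visits
                visits = list(make_visit(as.Date("2016-03-05")),
                              make_visit(as.Date("2016-03-06"))))
  )
  out <- apply_cohort_filters(recs)
  expect_length(out$kept, 2L)
  expect_equal(nrow(out$exclusions) + length(out$kept), length(recs))
  expect_equal(out$exclusions$reason[out$exclusions$patient_id == "A"],
               "pre_index_relapse")
  expect_equal(out$exclusions$reason[out$exclusions$patient_id == "B"],
               "insufficient_followup")
  expect_equal(out$exclusions$reason[out$exclusions$patient_id == "E"],
               "too_few_visits")
  labels <- vapply(out$kept, `[[`, logical(1), "label")
  names(labels) <- vapply(out$kept, `[[`, character(1), "patient_id")
  expect_false(labels[["C"]])
  expect_true(labels[["D"]])
})

test_that("an event observed beyond the horizon labels the patient event-free", {
  out <- apply_cohort_filters(list(
    make_record("L", dfs_event = TRUE, followup_days = 1200)))
  expect_length(out$kept, 1L)
  expect_false(out$kept[[1]]$label)
})

test_that("a fully populated visit emits exactly 17 (token, modality) pairs", {
  pairs <- tokenize_visit(make_full_visit(), full_visit_context())
  expect_identical(nrow(pairs), 17L)
  expect_identical(anyDuplicated(pairs$modality), 0L)
  expect_true(all(pairs$modality %in% modality_levels()))
  # canonical order: bio, deltas, visit descriptors, age, dNPI, subtype
  expect_match(pairs$token[1], "^bio:MONO=")
  expect_match(pairs$token[6], "^delta:MONO=")
  expect_identical(pairs$modality[11:17],
                   c("department", "procedure", "therapy", "subtherapy",
                     "age", "dnpi", "subtype"))
})

test_that("missing features and zero deltas are skipped, not encoded", {
  ctx <- full_visit_context()
  v <- visit_event(as.Date("2016-04-10"), department = "radiologie")
  ctx$dnpi_group <- NA
  ctx$subtype <- NA
  ctx$birth_date <- NA
  pairs <- tokenize_visit(v, ctx)
  expect_identical(pairs$token, "dept:radiologie")
  # zero delta for one marker drops exactly that delta pair
  ctx2 <- full_visit_context()
  v2 <- make_full_visit()
  v2$bio_values$MONO <- ctx2$prev_bio$MONO  # delta 0
  pairs2 <- tokenize_visit(v2, ctx2)
  expect_identical(nrow(pairs2), 16L)
  expect_false("delta:MONO" %in% pairs2$modality)
  expect_true("bio:MONO" %in% pairs2$modality)
})

test_that("trajectories start with CLS, separate visits with SEP, align layers", {
  rec <- make_record()
  traj <- build_trajectory(select_history_window(rec))
  n <- length(traj$tokens)
  expect_identical(traj$tokens[1], "CLS")
  expect_identical(length(traj$modalities), n)
  expect_identical(length(traj$delays), n)
  expect_identical(traj$positions, 0:(n - 1))
  # one SEP per visit, including the last
  expect_identical(sum(traj$tokens == "SEP"), length(rec$visits))
  expect_identical(traj$tokens[n], "SEP")
  # CLS carries W0; the delay of each visit block is its gap bucket
  expect_identical(traj$delays[1], "W0")
})

test_that("trajectory delay layer buckets the inter-visit gaps", {
  diag <- as.Date("2016-03-01")
  visits <- list(
    make_visit(diag),            # first visit: W0
    make_visit(diag + 10),       # gap 10 d: W1
    make_visit(diag + 110)       # gap 100 d: M4
  )
  rec <- make_record(visits = visits)
  traj <- build_trajectory(rec)
  # each visit: dept, proc, age, dNPI, subtype + SEP = 6 aligned entries
  expect_identical(traj$delays,
                   c("W0", rep("W0", 6), rep("W1", 6), rep("M4", 6)))
  # single-visit record: all W0
  tr1 <- build_trajectory(make_record(visits = visits[1]))
  expect_true(all(tr1$delays == "W0"))
})

test_that("overlong trajectories are truncated to the first 512 tokens", {
  visits <- lapply(0:330, function(i) make_visit(as.Date("2016-03-01") + i))
  rec <- make_record(visits = visits,
                     surgery_date = as.Date("2016-12-01"))
  traj <- build_trajectory(rec)   # 1 + 331*3 tokens before truncation
  expect_identical(length(traj$tokens), 512L)
  expect_identical(length(traj$modalities), 512L)
  expect_identical(length(traj$delays), 512L)
  expect_identical(traj$positions, 0:511)
  expect_identical(traj$tokens[1], "CLS")
  empty <- make_record()
  empty$visits <- list()
  expect_error(build_trajectory(empty), "no visits")
})

test_that("the dNPI token is re-emitted per visit and updates with tumor size", {
  diag <- as.Date("2016-03-01")
  visits <- list(
    visit_event(diag, department = "radiologie", tumor_size_cm = 1.0),
    make_visit(diag + 20),
    visit_event(diag + 40, department = "chirurgie", tumor_size_cm = 9.0)
  )
  rec <- make_record(visits = visits)   # grade 2, 1 node -> stage 2
  traj <- build_trajectory(rec)
  pg <- traj$tokens[traj$modalities == "dnpi"]
  # 0.2*1+2+2 = 4.2 -> MPG I, carried forward, then 0.2*9+2+2 = 5.8 -> PPG
  expect_identical(pg, c("pg:MPG I", "pg:MPG I", "pg:PPG"))
})

test_that("vocabulary ids are dense, special ids reserved, UNK catches novel tokens", {
  rec <- make_record()
  traj <- build_trajectory(select_history_window(rec))
  vocab <- build_vocabulary(list(traj))
  ids <- sort(unname(vocab$token_ids))
  expect_identical(ids, seq_along(ids))      # dense
  expect_identical(unname(vocab$token_ids[names(special_tokens())]),
                   unname(special_tokens()))
  enc <- encode_trajectory(traj, vocab)
  expect_identical(length(enc$token_ids), length(traj$tokens))
  expect_identical(enc$token_ids[1], unname(special_tokens()[["CLS"]]))
  novel <- traj
  novel$tokens[2] <- "dept:never seen"
  expect_identical(encode_trajectory(novel, vocab)$token_ids[2],
                   unname(special_tokens()[["UNK"]]))
  expect_false(special_tokens()[["UNK"]] %in% content_token_ids(vocab))
})

test_that("serialized trajectories round-trip to identical id sequences", {
  cohort <- small_cohort_fixture()[1:8]
  tk <- tokenize_cohort(cohort, max_len = 64)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trajectories_jsonl(tk$trajectories, path)
  back <- read_trajectories_jsonl(path)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$token_ids, tk$trajectories[[i]]$token_ids)
    expect_identical(back[[i]]$modality_ids, tk$trajectories[[i]]$modality_ids)
    expect_identical(back[[i]]$delay_ids, tk$trajectories[[i]]$delay_ids)
    expect_identical(back[[i]]$positions, tk$trajectories[[i]]$positions)
    expect_identical(back[[i]]$label, tk$trajectories[[i]]$label)
  }
  vpath <- withr::local_tempfile(fileext = ".json")
  write_vocabulary(tk$vocab, vpath)
  v2 <- read_vocabulary(vpath)
  expect_identical(v2$token_ids, tk$vocab$token_ids)
})

test_that("cohort CSV/JSONL export round-trips through read_cohort", {
  cohort <- small_cohort_fixture()[1:5]
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_length(back, 5L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$patient_id, cohort[[i]]$patient_id)
    expect_equal(length(back[[i]]$visits), length(cohort[[i]]$visits))
    t1 <- build_trajectory(select_history_window(cohort[[i]]))
    t2 <- build_trajectory(select_history_window(back[[i]]))
    expect_identical(t2$tokens, t1$tokens)
  }
})
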