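test_that("AUC handles perfect separation, ties and monotone transforms", {
  y <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(roc_auc(y, c(6:10, 1:5)), 1)
  expect_equal(roc_auc(y, c(1:5, 6:10)), 0)
  expect_equal(roc_auc(y, rep(1, 10)), 0.5)
  set.seed(4)
  s <- rnorm(100)
  yy <- runif(100) < 0.3
  expect_equal(roc_auc(yy, s), roc_auc(yy, exp(s)))       # rank statistic
  expect_equal(roc_auc(yy, s), roc_auc(yy, 100 + 3 * s))
  expect_error(roc_auc(rep(TRUE, 5), 1:5), "both classes")
})

test_that("AUC matches pROC to 1e-12 on a 50-sample fixture", {
  skip_if_not_installed("pROC")
  set.seed(10)
  y <- runif(50) < 0.4
  y[1:2] <- c(TRUE, FALSE)
  s <- rnorm(50) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
  # with ties
  s2 <- round(s, 1)
  ref2 <- as.numeric(pROC::auc(pROC::roc(y, s2, quiet = TRUE,
                                         direction = "<")))
  expect_equal(roc_auc(y, s2), ref2, tolerance = 1e-12)
})

test_that("bootstrap CI contains the estimate and covers 0.5 under the null", {
  set.seed(5)
  y <- runif(400) < 0.3
  y[1:2] <- c(TRUE, FALSE)
  s <- rnorm(400)                       # independent of labels
  rep_ <- roc_auc_ci(y, s, n_boot = 500, seed = 1)
  expect_s3_class(rep_, "eval_report")
  expect_true(rep_$lower <= rep_$estimate && rep_$estimate <= rep_$upper)
  expect_identical(rep_$n, 400L)
  # reproducible given seed
  rep2 <- roc_auc_ci(y, s, n_boot = 500, seed = 1)
  expect_identical(rep_, rep2)
  # a 95% interval for a label-independent score covers 0.5 in most draws
  cover <- vapply(1:10, function(r) {
    set.seed(900 + r)
    yy <- runif(400) < 0.3
    yy[1:2] <- c(TRUE, FALSE)
    ci <- roc_auc_ci(yy, rnorm(400), n_boot = 300, seed = r)
    ci$lower <= 0.5 && ci$upper >= 0.5
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("average precision matches a naive O(n^2) reference and its edge cases", {
  naive_ap <- function(labels, scores) {
    # independent implementation: precision at each distinct threshold
    th <- sort(unique(scores), decreasing = TRUE)
    prev_r <- 0; ap <- 0; n1 <- sum(labels)
    for (t in th) {
      tp <- 0; fp <- 0
      for (i in seq_along(scores)) {
        if (scores[i] >= t) {
          if (labels[i]) tp <- tp + 1 else fp <- fp + 1
        }
      }
      ap <- ap + (tp / n1 - prev_r) * tp / (tp + fp)
      prev_r <- tp / n1
    }
    ap
  }
  expect_equal(average_precision(c(TRUE, TRUE, FALSE), 3:1), 1)
  set.seed(6)
  for (rep in 1:5) {
    y <- runif(60) < 0.25
    y[1:2] <- c(TRUE, FALSE)
    s <- round(rnorm(60), 1)
    expect_equal(average_precision(y, s), naive_ap(y, s), tolerance = 1e-12)
  }
  # random scores give AP near prevalence
  set.seed(9)
  y <- rep(c(TRUE, FALSE), c(100, 900))
  aps <- vapply(1:30, function(i) average_precision(y, rnorm(1000)),
                numeric(1))
  expect_lt(abs(mean(aps) - 0.1), 0.02)
  expect_error(average_precision(rep(TRUE, 3), 1:3), "both classes")
})

test_that("DeLong test: p = 1 on identical scores, matches pROC, detects separation", {
  set.seed(12)
  y <- runif(120) < 0.4
  y[1:2] <- c(TRUE, FALSE)
  sA <- rnorm(120) + y
  expect_equal(delong_test(y, sA, sA)$p_value, 1)
  skip_if_not_installed("pROC")
  sB <- rnorm(120) + 0.3 * y
  ours <- delong_test(y, sA, sB)
  ref <- pROC::roc.test(pROC::roc(y, sA, quiet = TRUE, direction = "<"),
                        pROC::roc(y, sB, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(abs(ours$statistic), abs(unname(ref$statistic)),
               tolerance = 1e-10)
  # strong vs random predictor is significant in nearly all seeds
  hits <- vapply(1:10, function(s) {
    set.seed(400 + s)
    yy <- runif(500) < 0.3
    yy[1:2] <- c(TRUE, FALSE)
    strong <- yy + rnorm(500, 0, 0.4)
    random <- rnorm(500)
    delong_test(yy, strong, random)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("NPI baseline scores rank risk and feed the AUC", {
  cohort <- small_cohort_fixture()
  scores <- npi_baseline_scores(cohort)
  expect_length(scores, length(cohort))
  expect_true(all(is.na(scores) | scores >= 2))
  labels <- vapply(cohort, `[[`, logical(1), "label")
  ok <- !is.na(scores)
  auc <- roc_auc(labels[ok], scores[ok])
  # the generator plants a positive NPI effect, so NPI must beat chance
  expect_gt(auc, 0.5)
  # ordering invariance under a strictly increasing transform
  expect_equal(roc_auc(labels[ok], scores[ok]^3 + 1), auc)
})

test_that("stratified evaluation scores populated strata and flags sparse ones", {
  set.seed(14)
  y <- runif(300) < 0.3
  y[1:2] <- c(TRUE, FALSE)
  s <- rnorm(300) + y
  strata <- rep(c("node+", "node-"), c(200, 100))
  # make one stratum single-class
  y[strata == "node-"] <- FALSE
  out <- stratified_eval(y, s, strata, n_boot = 200, seed = 2)
  expect_identical(nrow(out), 2L)
  expect_identical(out$status[out$subgroup == "node+"], "ok")
  expect_identical(out$status[out$subgroup == "node-"], "insufficient")
  # a single stratum reproduces the global evaluation
  g <- stratified_eval(y, s, rep("all", 300), n_boot = 200, seed = 2)
  expect_equal(g$estimate, roc_auc(y, s))
})

test_that("random search draws reproducible configs and APS picks the best scores", {
  grid <- list(learning_rate = c(1e-3, 5e-4, 1e-4), n_layers = 2:4)
  draws <- random_search_configs(grid, 6, seed = 3)
  expect_length(draws, 6L)
  expect_identical(draws, random_search_configs(grid, 6, seed = 3))
  expect_true(all(vapply(draws, function(d) {
    d$learning_rate %in% grid$learning_rate && d$n_layers %in% grid$n_layers
  }, logical(1))))
  set.seed(8)
  y <- runif(100) < 0.3
  y[1:2] <- c(TRUE, FALSE)
  good <- y + rnorm(100, 0, 0.3)
  bad <- rnorm(100)
  sel <- select_by_average_precision(y, list(bad, good))
  expect_identical(sel$best, 2L)
  expect_gt(sel$aps[2], sel$aps[1])
})

test_that("learning-curve harness compares the sequence model with a flat baseline", {
  cohort <- small_cohort_fixture()
  tk <- tokenize_cohort(cohort, max_len = 48)
  n <- length(cohort)
  tr_idx <- 1:floor(0.6 * n)
  te_idx <- setdiff(1:n, tr_idx)
  mlm <- train_mlm(tk$trajectories[tr_idx], tk$vocab,
                   tiny_encoder_config(seed = 50, epochs = 2),
                   val_fraction = 0)
  lc <- learning_curve(mlm, tk$trajectories[tr_idx], cohort[tr_idx],
                       tk$trajectories[te_idx], cohort[te_idx],
                       sizes = c(12, 30), seeds = 1:2,
                       config = finetune_config(learning_rate = 1e-3,
                                                epochs = 2, batch_size = 8))
  expect_identical(nrow(lc), 4L)
  expect_true(all(c("size", "seed", "auc_sequence", "auc_flat",
                    "advantage") %in% names(lc)))
  expect_true(all(lc$auc_sequence >= 0 & lc$auc_sequence <= 1))
  expect_equal(lc$advantage, lc$auc_sequence - lc$auc_flat)
})

test_that("bootstrap interval coverage is near nominal in a small calibration", {
  # true AUC of scores = y + N(0, 1) at balanced n = 60 per class
  true_auc <- pnorm(1 / sqrt(2))
  covered <- vapply(1:40, function(r) {
    set.seed(2000 + r)
    y <- rep(c(TRUE, FALSE), each = 60)
    s <- y + rnorm(120)
    ci <- roc_auc_ci(y, s, n_boot = 300, seed = r)
    ci$lower <= true_auc && true_auc <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})
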