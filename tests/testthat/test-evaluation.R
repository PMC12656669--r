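test_that("error metrics reproduce hand arithmetic and the identity case", {
  s <- generate_subject(gait_profile("HEALTHY"), frames = 50, seed = 17)
  em0 <- error_metrics(s, s)
  expect_equal(c(em0$mae, em0$mse, em0$mape), c(0, 0, 0))
  # truth (2, 4) vs prediction (1, 8)
  truth <- gait_sequence(array(c(2, 4), dim = c(1, 17, 2))[, 1:17, , drop = FALSE])
  t2 <- gait_sequence(array(0, dim = c(1, 17, 2)) + rep(c(2, 4), each = 17))
  p2 <- gait_sequence(array(0, dim = c(1, 17, 2)) + rep(c(1, 8), each = 17))
  em <- error_metrics(t2, p2)
  expect_equal(em$mae, 2.5)
  expect_equal(em$mse, 8.5)
  expect_equal(em$mape, 75)
  expect_error(error_metrics(s, truth), "mismatch")
})

test_that("zero-filling obeys the analytic MAPE/MAE/MSE identities", {
  s <- generate_subject(gait_profile("PD"), frames = 50, seed = 18)
  y <- flatten_record(s)
  for (g in names(body_part_groups())) {
    for (k in c(10, 20, 30, 40)) {
      occ <- simulate_missing(s, g, missing_frames = k)
      em <- error_metrics(s, occ)
      m <- 2 * length(body_part_group(g)) * k
      expect_equal(em$mape, 100 * m / 1700, tolerance = 1e-12)
      missing_vals <- y[flatten_record(occ) == 0]
      expect_equal(em$mae, sum(abs(missing_vals)) / 1700, tolerance = 1e-12)
      expect_equal(em$mse, sum(missing_vals^2) / 1700, tolerance = 1e-12)
      # scope consistency: the all-values MAPE is the missing-only MAPE
      # diluted by m/n
      em_miss <- error_metrics(s, occ, scope = "missing")
      expect_equal(em$mape, em_miss$mape * m / 1700, tolerance = 1e-9)
      expect_equal(em_miss$mape, 100)
      expect_equal(em_miss$n_values, m)
    }
  }
})

test_that("classification metrics match their ratio definitions", {
  # unique confusion counts consistent with accuracy 0.8913, precision
  # 0.9286, recall 0.7647 on 92 samples, recovered by brute-force search
  hits <- list()
  for (tp in 0:92) for (fp in 0:(92 - tp)) for (fn in 0:(92 - tp - fp)) {
    tn <- 92 - tp - fp - fn
    if (tp + fp == 0 || tp + fn == 0) next
    if (abs((tp + tn) / 92 - 0.8913) < 5e-5 &&
        abs(tp / (tp + fp) - 0.9286) < 5e-5 &&
        abs(tp / (tp + fn) - 0.7647) < 5e-5) {
      hits[[length(hits) + 1]] <- c(tp = tp, tn = tn, fp = fp, fn = fn)
    }
  }
  expect_length(hits, 1)
  cc <- hits[[1]]
  rep_ <- classification_metrics(cc["tp"], cc["tn"], cc["fp"], cc["fn"])
  expect_equal(cc, c(tp = 26, tn = 56, fp = 2, fn = 8))
  expect_equal(rep_$accuracy, 82 / 92)
  expect_equal(rep_$precision, 26 / 28)
  expect_equal(rep_$recall, 26 / 34)
  # F1 from the printed precision/recall rounds to 0.8387-0.8388
  f1_printed <- 2 * 0.9286 * 0.7647 / (0.9286 + 0.7647)
  expect_equal(rep_$f1, f1_printed, tolerance = 1e-4)
  expect_gte(round(rep_$f1, 4), 0.8387)
  expect_lte(round(rep_$f1, 4), 0.8388)
})

test_that("degenerate confusion counts are handled explicitly", {
  perfect <- classification_metrics(1, 1, 0, 0)
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall,
                 perfect$f1), c(1, 1, 1, 1))
  expect_message(noPD <- classification_metrics(0, 5, 0, 0), "precision")
  expect_equal(noPD$precision, 0)
  expect_equal(noPD$f1, 0)
  expect_error(classification_metrics(0, 0, 0, 0), "zero")
})

test_that("confusion counting matches per-sample comparison", {
  set.seed(91)
  truth <- sample(c("PD", "HEALTHY"), 60, replace = TRUE)
  pred <- ifelse(stats::runif(60) < 0.8, truth,
                 ifelse(truth == "PD", "HEALTHY", "PD"))
  cc <- confusion_counts(truth, pred)
  expect_equal(sum(cc), 60)
  rep_ <- classification_metrics(cc["tp"], cc["tn"], cc["fp"], cc["fn"])
  expect_equal(rep_$accuracy, mean(truth == pred))
})

test_that("sweep tables are keyed, sorted and duplicate-safe", {
  rows <- list()
  for (tech in c("none", "ukf", "gated", "recovgait")) {
    for (g in c("HEAD", "BODY", "HIPS", "LEGS")) {
      rows[[length(rows) + 1]] <- data.frame(
        technique = tech, group = g, missing_frames = 40L, mape = runif(1))
    }
  }
  tab <- sweep_report(rows)
  expect_equal(nrow(tab), 16)
  # stable under permutation of the input
  set.seed(3)
  tab2 <- sweep_report(sample(rows))
  expect_equal(tab2$mape, tab$mape)
  expect_error(sweep_report(c(rows, rows[1])), "duplicate")
  expect_error(sweep_report(rows, keys = c("technique", "seed")), "missing key")
  empty <- sweep_report(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("technique", "group", "missing_frames") %in% names(empty)))
})
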