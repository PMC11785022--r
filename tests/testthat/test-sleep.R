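test_that("scoring features separate the generator's states", {
  ses <- small_session()
  f <- small_features()
  st <- ses$truth$states
  expect_equal(nrow(f), length(st))
  expect_true(all(f$delta >= 0) && all(f$whisk_s >= 0) &&
                all(f$whisk_s <= 5 + 1e-9))
  m <- sapply(split(f, st), colMeans)
  expect_gt(m["delta", "NREM"], m["delta", "Awake"])     # NREM delta elevation
  expect_gt(m["theta", "REM"], m["theta", "Awake"])      # REM theta elevation
  expect_lt(m["emg", "REM"], m["emg", "NREM"])           # atonia
  expect_lt(m["heart_rate", "NREM"], m["heart_rate", "Awake"])
  expect_gt(m["whisk_s", "Awake"], m["whisk_s", "NREM"])
})

test_that("a pure 2 Hz bin loads the delta feature only", {
  fs <- 1000
  n_bins <- 4
  t <- seq(0, n_bins * 5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2 * t)
  ses <- list(channels = list(lfp_cortexL = x, lfp_cortexR = x,
                              lfp_hipp = x * 0, emg = x * 0,
                              whisker = rep(0, n_bins * 5 * 30)),
              fs = list(neural = fs, optical = 30), truth = NULL)
  f <- extract_features(ses)
  expect_gt(min(f$delta), 100 * max(f$beta))
  expect_gt(min(f$delta), 100 * max(f$gamma))
  expect_equal(f$whisk_s, rep(0, n_bins))  # no whisker motion
})

test_that("bagged forest separates constructed classes and reports OOB", {
  set.seed(20)
  n <- 300
  X <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 6), rnorm(n, 6)))
  y <- factor(rep(c("a", "b"), each = n))
  m <- bagged_forest(X, y, n_trees = 64, seed = 1)
  expect_lte(m$oob_error, 0.02)
  expect_equal(as.character(predict(m, cbind(c(-0.5, 6.2), c(0.3, 5.8)))),
               c("a", "b"))
  # single-class input is rejected
  expect_error(bagged_forest(X[1:10, ], factor(rep("a", 10))), "single class")
  # reproducibility under a fixed seed
  m2 <- bagged_forest(X, y, n_trees = 64, seed = 1)
  expect_equal(m$oob_error, m2$oob_error)
})

test_that("shuffled labels give chance-level OOB error", {
  f <- small_features()
  st <- small_session()$truth$states
  set.seed(30)
  sh <- sample(as.character(st))
  m <- train_classifier(f, sh, n_trees = 64, seed = 2)
  chance <- 1 - max(prop.table(table(sh)))
  # deep trees on permuted labels sit between the majority-vote chance rate
  # and the Gini rate; "about chance" here means within a few points above
  expect_gt(m$oob_error, chance - 0.03)
  expect_lt(m$oob_error, chance + 0.08)
})

test_that("classifier accuracy degrades as class separation shrinks", {
  # collapse the state-dependent structure toward uniformity
  shrink <- function(a) {
    bp <- gen_params()$band_power_by_state
    bp <- 1 + a * (bp - 1)
    emg <- 1 + a * (gen_params()$emg_power_by_state - 1)
    hr <- 9 + a * (gen_params()$heart_rate_by_state - 9)
    gen_params(band_power_by_state = bp, emg_power_by_state = emg,
               heart_rate_by_state = hr, seed = 31)
  }
  acc <- vapply(c(1, 0.15, 0), function(a) {
    ses <- simulate_session(shrink(a), duration_s = 1500)
    f <- extract_features(ses)
    if (nlevels(droplevels(ses$truth$states)) < 2) return(NA_real_)
    m <- train_classifier(f, ses$truth$states, n_trees = 48, seed = 3)
    seen <- rowSums(m$oob_votes) > 0
    pred <- m$classes[max.col(m$oob_votes, ties.method = "first")]
    mean(pred[seen] == as.character(ses$truth$states)[seen])
  }, numeric(1))
  acc <- acc[!is.na(acc)]
  expect_true(all(diff(acc) <= 0.05))  # non-increasing up to noise
  expect_gt(acc[1], 0.95)
})

test_that("segmentation rules are enforced exactly", {
  lv <- c("Awake", "NREM", "REM")
  # 85% awake block -> Alert; 85% sleep block -> Asleep; mixed -> Neither
  mk <- function(frac_awake, frac_sleep) {
    na <- round(180 * frac_awake)
    ns <- round(180 * frac_sleep)
    factor(c(rep("Awake", na), rep("NREM", ns), rep("REM", 180 - na - ns)),
           levels = lv)
  }
  lab1 <- segment_periods(mk(0.85, 0.15))
  expect_equal(lab1$blocks$state, "Alert")
  lab2 <- segment_periods(mk(0.15, 0.70))   # 85% NREM+REM
  expect_equal(lab2$blocks$state, "Asleep")
  lab3 <- segment_periods(mk(0.5, 0.5))
  expect_equal(lab3$blocks$state, "Neither")
  # 25 s of NREM (5 bins) is excluded from NREM events; 30 s retained
  s <- factor(c(rep("Awake", 20), rep("NREM", 5), rep("Awake", 20),
                rep("NREM", 6), rep("Awake", 20)), levels = lv)
  lab4 <- segment_periods(s)
  expect_equal(nrow(lab4$nrem_events), 1)
  expect_equal(lab4$nrem_events$duration_s, 30)
  # REM needs 60 s
  s2 <- factor(c(rep("NREM", 10), rep("REM", 11), rep("NREM", 10),
                 rep("REM", 12), rep("NREM", 10)), levels = lv)
  lab5 <- segment_periods(s2)
  expect_equal(nrow(lab5$rem_events), 1)
  expect_equal(lab5$rem_events$duration_s, 60)
  # all-awake motionless session: one rest event spanning it
  s3 <- all_awake(40)
  lab6 <- segment_periods(s3, whisker = rep(0, 40 * 150), force = NULL)
  expect_equal(nrow(lab6$rest_events), 1)
  expect_equal(lab6$rest_events$duration_s, 200)
  # transitions require 30 s purity on both sides, and both halves are pure
  s4 <- factor(c(rep("Awake", 8), rep("NREM", 8), rep("Awake", 3),
                 rep("NREM", 8)), levels = lv)
  lab7 <- segment_periods(s4)
  expect_equal(nrow(lab7$transitions), 1)
  expect_equal(lab7$transitions$from, "Awake")
  expect_equal(lab7$transitions$to, "NREM")
  # segmentation is deterministic and idempotent
  expect_identical(segment_periods(s4), segment_periods(s4))
  # stimulation-period exclusion drops early events
  lab8 <- segment_periods(s3, exclude_first_s = 100)
  expect_equal(lab8$rest_events$onset_s, 100)
})
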