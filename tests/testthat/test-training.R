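test_that("fall-frame threshold follows the 0.87-of-peak rule", {
  cv <- c(0.1, 0.5, 2.0, 1.2)
  expect_equal(fall_frame_threshold(cv), 1.74)
  expect_equal(fall_frame_threshold(cv, factor = 1), 2.0)
  expect_error(fall_frame_threshold(rep(0, 10)), "no fall signature")
})

test_that("trial labeling marks exactly the frames above threshold", {
  set.seed(7)
  f <- data.frame(cv_fast = runif(500, 0, 2))
  thr <- fall_frame_threshold(f$cv_fast)
  lab <- label_trial(f, TRUE, thr)
  expect_equal(lab, ifelse(f$cv_fast > thr, 1L, -1L))
  expect_gte(sum(lab > 0), 1)   # the max frame is always positive
  expect_equal(label_trial(f, FALSE), rep(-1L, 500))
  expect_error(label_trial(f, TRUE), "threshold")
})

test_that("every fall trial yields >= 1 positive, non-fall trials none", {
  p <- small_protocol()
  for (i in seq_len(nrow(p$manifest))) {
    f <- p$features[[p$manifest$path[i]]]
    if (p$manifest$is_fall[i]) {
      lab <- label_trial(f, TRUE, fall_frame_threshold(f$cv_fast))
      expect_gte(sum(lab > 0), 1)
    } else {
      expect_equal(sum(label_trial(f, FALSE) > 0), 0)
    }
  }
})

test_that("training-set assembly selects, counts and reproduces", {
  p <- small_protocol()   # 2 subjects x 21 ADLs x 2 trials
  ts <- assemble_training_set(p$manifest, select = 1, seed = 9,
                              features = p$features, negative_stride = 50)
  expect_equal(ts$n_fall_trials, 2 * 10)
  expect_equal(ts$n_nonfall_trials, 2 * 11)
  expect_equal(ncol(ts$X), 4)
  expect_setequal(unique(ts$D), c(1L, -1L))
  expect_true(all(ts$D[!ts$provenance$adl_id %in% 1:10] == -1L))
  # determinism and row-order invariance
  ts2 <- assemble_training_set(p$manifest, select = 1, seed = 9,
                               features = p$features, negative_stride = 50)
  shuf <- p$manifest[sample(nrow(p$manifest)), ]
  ts3 <- assemble_training_set(trial_manifest(shuf$path, shuf$subject,
                                              shuf$adl_id, shuf$trial),
                               select = 1, seed = 9, features = p$features,
                               negative_stride = 50)
  expect_identical(ts$X, ts2$X)
  expect_identical(ts$X, ts3$X)
  # parameter combinations restrict columns
  ts4 <- assemble_training_set(p$manifest, select = 1, seed = 9,
                               features = p$features, negative_stride = 50,
                               params = c("sv_total", "cv_fast"))
  expect_equal(colnames(ts4$X), c("sv_total", "cv_fast"))
  expect_error(assemble_training_set(p$manifest, select = 0), "select")
  expect_error(assemble_training_set(p$manifest, select = 3,
                                     features = p$features),
               "subject 1, ADL 1")
})

test_that("frame files round-trip", {
  p <- small_protocol()
  ts <- assemble_training_set(p$manifest, select = 1, seed = 9,
                              features = p$features, negative_stride = 200)
  d <- withr::local_tempdir()
  path <- file.path(d, "ts.csv")
  write_frames(ts, path)
  back <- read_frames(path)
  expect_equal(unname(back$X), unname(ts$X), tolerance = 1e-12)
  expect_equal(back$D, ts$D)
  expect_equal(back$params, ts$params)
})

test_that("two-fold splits are disjoint, exhaustive and reproducible", {
  p <- small_protocol()
  h <- split_cv(p$manifest, "by_trial", seed = 4)
  expect_equal(nrow(h$train), nrow(p$manifest) / 2)
  key <- function(m) paste(m$subject, m$adl_id, m$trial)
  expect_length(intersect(key(h$train), key(h$test)), 0)
  expect_setequal(c(key(h$train), key(h$test)), key(p$manifest))
  # per-cell 1/1 for 2 trials per cell
  tab <- table(h$train$subject, h$train$adl_id)
  expect_true(all(tab == 1))
  hs <- split_cv(p$manifest, "by_subject", seed = 4)
  expect_length(intersect(hs$train$subject, hs$test$subject), 0)
  h2 <- split_cv(p$manifest, "by_trial", seed = 4)
  expect_identical(as.data.frame(h$train), as.data.frame(h2$train))
  one <- p$manifest[p$manifest$subject == 1, ]
  expect_error(split_cv(trial_manifest(one$path, one$subject, one$adl_id,
                                       one$trial), "by_subject"),
               ">= 2 subjects")
})
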