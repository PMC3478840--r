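test_that("trial generation is deterministic and device-faithful", {
  a <- generate_trial(8, seed = 5)
  b <- generate_trial(8, seed = 5)
  expect_identical(a$trace, b$trace)
  expect_identical(a$annotation, b$annotation)
  samples <- unlist(a$trace[c("ax", "ay", "az")])
  step <- 4 / 4096
  expect_true(all(abs(samples) <= 2))
  expect_lt(max(abs(samples / step - round(samples / step))), 1e-9)
  expect_error(generate_trial(25), "adl_id")
  expect_error(generate_trial(3, fs = -1), "fs")
})

test_that("fall trials carry free-fall, impact and posture signatures", {
  for (seed in 1:5) {
    g <- generate_trial(3, seed = seed)
    f <- extract_features(g$trace)
    svt <- f$sv_total
    # sustained sub-0.5 g dip (the free-fall phase lasts >= 0.16 s; the
    # magnitude sits below 0.5 g for the deeper part of the ramp)
    dip <- rle(svt < 0.5)
    expect_gte(max(dip$lengths[dip$values], 0), 0.1 * 200)
    # hard impact
    expect_gte(max(f$cv_fast), 1.6)
    # ends lying
    expect_gte(tail(f$phi_z, 1), 60)
    # annotation brackets the dip
    expect_true(nrow(g$annotation) == 1)
    lo <- which(svt < 0.5)[1] / 200
    expect_lte(g$annotation$start_s, lo)
    expect_gte(g$annotation$end_s, lo)
  }
})

test_that("walking never shows a fall signature", {
  for (seed in 1:5) {
    g <- generate_trial(17, seed = seed)
    f <- extract_features(g$trace)
    dip <- rle(f$sv_total < 0.5)
    expect_lt(max(c(0, dip$lengths[dip$values])), 0.15 * 200)
    expect_lt(max(f$cv_fast), 1.7)
    expect_equal(nrow(g$annotation), 0)
  }
})

test_that("severity override moves impact amplitude", {
  soft <- generate_trial(3, seed = 2, severity = "soft")
  hard <- generate_trial(3, seed = 2, severity = "hard")
  expect_lt(max(cv_fast(soft$trace)), max(cv_fast(hard$trace)))
})

test_that("profile catalog respects the class contracts", {
  prof <- adl_profiles()
  expect_length(prof, 21)
  for (p in prof) {
    kinds <- vapply(p$phases, `[[`, "", "kind")
    if (p$is_fall) {
      expect_true(any(kinds %in% c("free_fall", "impact")))
    } else {
      expect_false(any(kinds == "free_fall"))
      bumps <- p$phases[kinds == "impact"]
      for (b in bumps) expect_lt(max(b$amp), 1.2)
    }
  }
  soft_max <- max(unlist(lapply(prof[c(5, 6, 7, 9)], function(p)
    lapply(p$phases[vapply(p$phases, `[[`, "", "kind") == "impact"],
           `[[`, "amp"))))
  hard_min <- min(unlist(lapply(prof[c(3, 4, 8, 10)], function(p)
    lapply(p$phases[vapply(p$phases, `[[`, "", "kind") == "impact"],
           `[[`, "amp"))))
  expect_lt(soft_max, hard_min + 1e-9)  # 1.6 vs 1.7: strictly below
})

test_that("class signatures separate falls from gait, softs overlap sits", {
  # reduced version of the 200-trial signature sweep (full sweep in the
  # acceptance suite): falls clear the walking quantile, soft falls and
  # energetic sit-downs overlap across the subject amplitude spread
  nseed <- 12
  cvmax <- function(id, seed, amp) max(cv_fast(generate_trial(
    id, seed = seed, amp_scale = amp)$trace))
  walk <- vapply(1:nseed, function(s) cvmax(17, s, 1), 0)
  falls <- unlist(lapply(1:10, function(id)
    vapply(1:3, function(s) cvmax(id, 100 + s, 1), 0)))
  expect_gt(min(falls), quantile(walk, 0.9))
  softs <- vapply(1:nseed, function(s)
    cvmax(sample(c(5, 6, 7, 9), 1), 200 + s, 0.85), 0)
  sits <- vapply(1:nseed, function(s)
    cvmax(sample(c(13, 15), 1), 300 + s, 1.25), 0)
  expect_lt(min(softs), max(sits))   # distributions overlap
})

test_that("protocol generation counts, flags and files are right", {
  p <- generate_protocol(1, 1, seed = 3)
  expect_equal(nrow(p$manifest), 21)
  expect_equal(sum(p$manifest$is_fall), 10)
  sp <- small_protocol()
  expect_equal(nrow(sp$manifest), 2 * 21 * 2)
  expect_equal(sum(sp$manifest$is_fall), 40)
  expect_false(anyDuplicated(sp$manifest$path) > 0)
  # files written when out_dir given
  d <- withr::local_tempdir()
  pw <- generate_protocol(1, 1, seed = 3, out_dir = d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_equal(nrow(read_manifest(file.path(d, "manifest.csv"))), 21)
  tr <- read_trace(pw$manifest$path[1], fs = 200)
  expect_gt(nrow(tr), 200)
  expect_error(generate_protocol(0, 1), "counts")
})

test_that("sessions tile activities and annotate embedded falls", {
  s <- generate_session(300, embed_falls = 3, seed = 6)
  expect_equal(nrow(s$annotation), 3)
  expect_true(all(diff(s$annotation$start_s) >= 20))
  expect_true(all(s$annotation$adl_id %in% 1:10))
  # script tiles without overlap
  sc <- s$script[order(s$script$start_s), ]
  expect_true(all(sc$end_s[-nrow(sc)] - sc$start_s[-1] < 1e-9))
  expect_equal(nrow(s$trace), 300 * 200)
  s0 <- generate_session(120, 0, seed = 6)
  expect_equal(nrow(s0$annotation), 0)
  s2 <- generate_session(300, embed_falls = 3, seed = 6)
  expect_identical(s$trace, s2$trace)
  expect_error(generate_session(30), "60")
  expect_error(generate_session(300, embed_falls = 2), "0 or 3")
  expect_error(generate_session(80, embed_falls = 3), "too short")
})
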