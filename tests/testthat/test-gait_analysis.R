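# swing extraction, gait classification, irregularity detection

test_that("swing extraction on elementary traces", {
  expect_error(extract_swings(numeric(0)), "empty trace")

  # permanently in the contact band: no swings
  sw <- extract_swings(rep(31, 500))
  expect_identical(nrow(sw[!is.na(sw$duration), ]), 0L)

  # square wave 31 <-> 55 with 300-ms plateaus: intervals match the plateaus
  beta <- c(rep(c(rep(31, 300), rep(55, 300)), 4), rep(31, 50))
  sw <- extract_swings(beta)
  sw <- sw[!is.na(sw$duration), ]
  expect_identical(nrow(sw), 4L)
  expect_true(all(abs(sw$duration - 300) <= 2)) # within one sample
  # a 10-ms blip is discarded by the minimal-duration rule
  blip <- c(rep(31, 100), rep(55, 10), rep(31, 200))
  expect_identical(nrow(extract_swings(blip)), 0L)
})

test_that("synthetic traces classify back to their requested pattern (closure)", {
  cases <- list(list("tripod", 1200, 0.33), list("tetrapod_B", 1800, 0.25),
                list("tetrapod_C", 1800, 0.25), list("bilateral_sync", 1800, 0.3),
                list("new_pattern", 1600, 0.2))
  for (cs in cases) {
    tr <- synth_traces(cs[[1]], period = cs[[2]], duty = cs[[3]], jitter = 0,
                       seed = 11)
    cl <- classify_gait(step_intervals(tr$beta, tr$times),
                        window = range(tr$times))
    expect_identical(cl$label, cs[[1]])
  }
  expect_error(synth_traces("gallop"), "unknown pattern")
})

test_that("left-right mirroring swaps the tetrapod types and fixes the others", {
  for (cs in list(c("tetrapod_B", "tetrapod_C"), c("tetrapod_C", "tetrapod_B"),
                  c("tripod", "tripod"), c("bilateral_sync", "bilateral_sync"),
                  c("new_pattern", "new_pattern"))) {
    tr <- synth_traces(cs[1], period = 1700, duty = 0.25, seed = 3)
    cl <- classify_gait(step_intervals(mirror_traces(tr$beta), tr$times),
                        window = range(tr$times))
    expect_identical(cl$label, cs[2])
  }
})

test_that("extraction recovers the generated liftoff/touchdown times at zero jitter", {
  tr <- synth_traces("tetrapod_B", period = 1500, duty = 0.3, jitter = 0,
                     seed = 5, dt = 5)
  iv <- step_intervals(tr$beta, tr$times)
  for (l in names(iv)) {
    truth <- tr$true_intervals[[l]]
    got <- iv[[l]][!is.na(iv[[l]]$duration), ]
    truth <- truth[truth$liftoff >= 0 & truth$touchdown <= max(tr$times), ]
    n <- min(nrow(truth), nrow(got))
    expect_gte(n, 4)
    expect_true(all(abs(got$liftoff[1:n] - truth$liftoff[1:n]) <= 5))
    expect_true(all(abs(got$touchdown[1:n] - truth$touchdown[1:n]) <= 5))
  }
})

test_that("heavy jitter makes most trials unclassifiable", {
  n_unclassified <- 0
  for (s in 1:40) {
    tr <- synth_traces("tetrapod_B", period = 1500, duty = 0.3,
                       jitter = 0.3 * 1500, seed = s)
    cl <- classify_gait(step_intervals(tr$beta, tr$times),
                        window = range(tr$times))
    if (cl$label != "tetrapod_B") n_unclassified <- n_unclassified + 1
  }
  expect_gte(n_unclassified / 40, 0.8)
})

test_that("too-short windows are unclassified with a reason", {
  tr <- synth_traces("tripod", period = 1200, duty = 0.33, seed = 1)
  cl <- classify_gait(step_intervals(tr$beta, tr$times), window = c(0, 1300))
  expect_identical(cl$label, "unclassified")
  expect_match(cl$reason, "window too short")
})

test_that("the overlap matrix is symmetric with values in [0, 1]", {
  tr <- synth_traces("tripod", period = 1200, duty = 0.33, seed = 2)
  m <- swing_overlap_matrix(step_intervals(tr$beta, tr$times),
                            window = range(tr$times))
  expect_identical(m, t(m))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("prolonged and permanent lifts are flagged; short swings are not", {
  iv <- list(
    L1 = structure(data.frame(liftoff = c(100, 2000), touchdown = c(1300, 2400),
                              duration = c(1200, 400)),
                   class = c("sw_step_intervals", "data.frame")),
    L2 = structure(data.frame(liftoff = 5000, touchdown = NA_real_,
                              duration = NA_real_),
                   class = c("sw_step_intervals", "data.frame")))
  bad <- detect_prolonged_lift(iv, horizon = 8000)
  expect_identical(nrow(bad), 2L)
  expect_true(1200 %in% bad$duration)               # the 1200-ms swing
  expect_false(400 %in% bad$duration)               # the 400-ms swing
  expect_true(any(bad$permanent & bad$leg == "L2")) # open past the horizon
})

test_that("the recurrence-period estimator recovers a constructed period exactly", {
  flags <- rep(c(TRUE, TRUE, TRUE, FALSE, FALSE), 6) # period 5 samples
  expect_equal(recurrence_period(flags, spacing = 50), 250)
  expect_true(is.na(recurrence_period(rep(TRUE, 10), 50)))
})

test_that("scan input validation", {
  expect_error(scan_transition_starts(default_model(), step = 0),
               "step must be positive")
  expect_error(scan_backward_transitions(default_model(), step = -5),
               "step must be positive")
})
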