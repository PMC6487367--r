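# antagonistic-muscle joint dynamics

test_that("zero activity at the mid-range rest point is an equilibrium", {
  mp <- muscle_pair_params("alpha") # the alpha joint carries no passive bias
  js <- joint_state("alpha", mean(mp$limits))
  for (i in 1:200) js <- joint_step(js, c(0, 0, 0, 0), mp, 1)
  expect_equal(js$angle, mean(mp$limits), tolerance = 1e-8)
  expect_equal(js$velocity, 0, tolerance = 1e-10)
})

test_that("sustained maximal retractor activity converges to 128 degrees", {
  mp <- muscle_pair_params("alpha")
  js <- joint_state("alpha", 60)
  for (i in 1:4000) js <- joint_step(js, c(0, 1, 0, 1), mp, 1)
  expect_equal(js$angle, 128, tolerance = 0.01) # relative: within ~1 degree
  # and protractor-only activation reaches the most protracted value, 28
  expect_equal(pose_equilibrium(c(1, 0, 1, 0), mp), 28, tolerance = 0.01)
})

test_that("balanced activations settle at the range midpoint", {
  mp <- muscle_pair_params("alpha")
  expect_equal(pose_equilibrium(c(0.7, 0.7, 0.7, 0.7), mp), mean(mp$limits))
})

test_that("pose_equilibrium matches long joint_step integration within 0.5 degrees", {
  mp <- muscle_pair_params("beta")
  set.seed(42)
  for (rep in 1:5) {
    a <- runif(4)
    js <- joint_state("beta", 45)
    for (i in 1:10000) js <- joint_step(js, a, mp, 1)
    expect_lt(abs(js$angle - pose_equilibrium(a, mp)), 0.5)
  }
})

test_that("joint limits are never violated under bounded random activity", {
  set.seed(7)
  for (joint in c("alpha", "beta", "gamma")) {
    mp <- muscle_pair_params(joint)
    js <- joint_state(joint, mean(mp$limits))
    for (i in 1:3000) {
      if (i %% 150 == 1) a <- runif(4) # piecewise-constant random drive
      js <- joint_step(js, a, mp, 1)
      expect_gte(js$angle, mp$limits[1] - 1e-6)
      expect_lte(js$angle, mp$limits[2] + 1e-6)
    }
  }
})

test_that("invalid step arguments are rejected", {
  mp <- muscle_pair_params("alpha")
  js <- joint_state("alpha", 78)
  expect_error(joint_step(js, c(0, 0, 0, 0), mp, dt = 0), "dt")
  expect_error(joint_step(js, c(-0.1, 0, 0, 0), mp, dt = 1), "nonnegative")
  expect_error(pose_equilibrium(c(1, 1), mp), "nonnegative|four")
})

test_that("the slow pathway's rise time exceeds the fast one's by the time-constant ratio", {
  # identical step drive through the fast-only vs the slow-only motoneuron
  # pathway: the slow muscle's activation lag lives in the slow motoneuron
  # membrane, so its joint response is slower by about tau_act_slow/tau_act_fast
  p <- sw_params()
  drive <- c(rep(0, 50), rep(0.3, 2500))
  zero <- rep(0, length(drive))
  af <- mn_activity(motoneuron_unit("fast", p), drive, zero)$activity
  as <- mn_activity(motoneuron_unit("slow", p), drive, zero)$activity
  rise <- function(a) {
    a10 <- which(a >= 0.1 * max(a) & seq_along(a) > 50)[1]
    a90 <- which(a >= 0.9 * max(a))[1]
    a90 - a10
  }
  ratio <- rise(as) / max(rise(af), 1)
  expect_gte(ratio, p$mn$tau_act_slow / p$mn$tau_act_fast * 0.5)
  expect_gt(rise(as), rise(af))
})

test_that("the slow-muscle stance ripple never lifts beta into swing", {
  rec <- tetrapod_run()
  b <- beta_traces(rec)
  # during stance (contact band) the baseline oscillation stays below 32
  late <- rec$times > 9000
  for (l in colnames(b)) {
    stance <- late & b[, l] < 32
    expect_gt(sum(stance), 1000)           # stance phases exist
    expect_gte(min(b[late, l]), 30 - 1e-6) # never below the band
  }
})
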