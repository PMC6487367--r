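# single-neuron and half-center dynamics

test_that("a CPG half-center is quiescent without drive and oscillates with it", {
  u <- cpg_unit("ld")
  r0 <- simulate_cpg(u, drive = c(0, 0), duration = 5000)
  expect_false(r0$oscillating)

  p <- sw_params()
  r1 <- simulate_cpg(u, drive = p$gapp$tetrapod$ld, duration = 16000)
  expect_true(r1$oscillating)
  expect_gt(r1$period, 1000)
})

test_that("the oscillation period decreases from the tetrapod to the tripod drive", {
  p <- sw_params()
  u <- cpg_unit("ld")
  drv <- seq(0, 1, length.out = 5)
  pers <- vapply(drv, function(f) {
    d <- (1 - f) * p$gapp$tetrapod$ld + f * p$gapp$tripod$ld
    simulate_cpg(u, d, duration = 16000)$period
  }, numeric(1))
  expect_true(all(is.finite(pers)))
  expect_true(all(diff(pers) < 0))
})

test_that("symmetric drives in the oscillatory range give antiphase plateaus", {
  u <- cpg_unit("ld")
  for (g in c(0.05, 0.06, 0.08)) {
    r <- simulate_cpg(u, drive = c(g, g), duration = 16000)
    expect_true(r$oscillating)
    expect_equal(r$phase_diff, 0.5, tolerance = 0.1) # 0.5 +/- 0.05 absolute
    expect_true(abs(r$phase_diff - 0.5) <= 0.05)
  }
})

test_that("mid-plateau inhibition at contralateral magnitude is blocked; strong or late pulses terminate", {
  p <- sw_params()
  u <- cpg_unit("ld")
  drive <- p$gapp$tetrapod$ld
  mid <- inhibition_response(u, drive,
    pulse = list(onset_frac = 0.3, duration = 80, g = p$contra$g_l2r3),
    duration = 14000)
  expect_identical(mid$outcome, "persists")
  expect_gt(mid$plateau_pulsed, 0.95 * mid$plateau_ref)

  late <- inhibition_response(u, drive,
    pulse = list(onset_frac = 0.93, duration = 80, g = 0.3), duration = 14000)
  expect_identical(late$outcome, "terminated")

  # a null pulse leaves the plateau exactly unperturbed
  null <- inhibition_response(u, drive,
    pulse = list(onset_frac = 0.3, duration = 80, g = 0), duration = 14000)
  expect_equal(null$plateau_pulsed, null$plateau_ref, tolerance = 1e-6)

  # in the terminating branch, stronger pulses never leave a longer plateau
  rem <- vapply(c(0.1, 0.2, 0.4), function(g) {
    inhibition_response(u, drive,
      pulse = list(onset_frac = 0.3, duration = 80, g = g),
      duration = 14000)$plateau_pulsed
  }, numeric(1))
  expect_true(all(rem < 0.95 * mid$plateau_ref))
  expect_true(all(diff(rem) <= 1))
})

test_that("a pulse outside the simulated window is an argument error", {
  u <- cpg_unit("ld")
  expect_error(
    inhibition_response(u, sw_params()$gapp$tetrapod$ld,
      pulse = list(onset_frac = 0.5, duration = 1e6, g = 0.1),
      duration = 12000),
    "outside the simulated window")
})

test_that("motoneuron activity: silencing, adaptation contrast and onset latency", {
  mnf <- motoneuron_unit("fast")
  mns <- motoneuron_unit("slow")
  expect_equal(mns$g_q, 3 * mnf$g_q)

  drive <- c(rep(0, 100), rep(0.3, 1400))
  zero <- rep(0, 1500)
  expect_error(mn_activity(mnf, drive, zero[1:10]), "differ in length")

  # saturating premotor inhibition keeps activity at baseline
  sat <- mn_activity(mnf, drive, rep(0.6, 1500))
  expect_lt(max(sat$activity), 0.05)

  af <- mn_activity(mnf, drive, zero)$activity
  as <- mn_activity(mns, drive, zero)$activity
  ratio <- function(a) mean(a[1300:1500]) / max(a[100:400])
  expect_lt(ratio(as), ratio(af)) # slow MN adapts more strongly
  expect_lt(which(af > 0.5)[1] - 100, 50) # onset latency below 50 ms
})

test_that("the compiled assembly reproduces the deSolve half-center period (dual route)", {
  # with gates and couplings silenced, each LD CPG in the assembly free-runs;
  # its period must match an independent variable-step integration of the
  # same unit equations
  p <- sw_params(gates = list(g_high = c(pr = 0, ld = 0, ef = 0)))
  m <- assemble(p, contralateral_config(FALSE, FALSE, FALSE, FALSE),
                ipsilateral = FALSE)
  rec <- run_model(m, config = sim_config(t_end = 14000,
                                          record_neurons = c(2 * 36 + 12)))
  v <- rec$voltages[, 1]
  on <- which(diff(v > -35) == 1)
  on <- on[rec$times[on] > 5000]
  per_c <- mean(diff(rec$times[on]))

  u <- cpg_unit("ld", p)
  per_r <- simulate_cpg(u, p$gapp$tetrapod$ld, duration = 16000)$period
  expect_equal(per_c, per_r, tolerance = 0.02)
})
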