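# one leg: sensory signals, coordination gates, independent stepping

test_that("ground contact is signalled exactly in the 30-32 degree band", {
  mk <- function(beta) compute_sensory(list(
    alpha = joint_state("alpha", 100),
    beta = joint_state("beta", beta),
    gamma = joint_state("gamma", 105)))
  expect_true(mk(31)$ground_contact)
  expect_false(mk(45)$ground_contact)  # swing
  expect_false(mk(60)$ground_contact)  # maximally lifted
  expect_true(mk(30)$ground_contact)
  expect_false(mk(32)$ground_contact)  # half-open band
})

test_that("gates switch direction-dependently at their thresholds", {
  p <- sw_params()
  sig <- function(beta, dbeta) compute_sensory(list(
    alpha = joint_state("alpha", 100),
    beta = joint_state("beta", beta, dbeta),
    gamma = joint_state("gamma", 105)))
  g0 <- gate_state(pr = "low", ef = "low", time = 0, beta = 35, gamma = 105)
  # beta falling through beta_crit: low -> high
  g1 <- update_gates(sig(32.5, -0.1), g0, p, time = 1)
  expect_identical(g1$pr, "high")
  expect_identical(g1$ef, "high")
  # beta rising through the same value: unchanged
  g2 <- update_gates(sig(32.5, +0.1), g0, p, time = 1)
  expect_identical(g2$pr, "low")
  # out-of-order timestamps are a state error
  expect_error(update_gates(sig(32.5, -0.1), g1, p, time = 0), "temporal order")
})

test_that("one triangular levation cycle yields exactly one switch in each direction", {
  p <- sw_params()
  tt <- seq(0, 2000, by = 5)
  beta <- 45 - 14 * cos(2 * pi * tt / 2000) # 31 <-> 59 cycle, starts grounded
  g <- gate_state(pr = "high", ef = "high", time = -1, beta = beta[1],
                  gamma = 105)
  ups <- 0; downs <- 0
  for (i in seq_along(tt)[-1]) {
    s <- compute_sensory(list(alpha = joint_state("alpha", 100),
      beta = joint_state("beta", beta[i], (beta[i] - beta[i - 1]) / 5),
      gamma = joint_state("gamma", 105)))
    gn <- update_gates(s, g, p, time = tt[i])
    if (g$pr == "low" && gn$pr == "high") ups <- ups + 1
    if (g$pr == "high" && gn$pr == "low") downs <- downs + 1
    g <- gn
  }
  expect_identical(ups, 1)
  expect_identical(downs, 1)
})

test_that("gate conductances map low/high states to the configured values", {
  p <- sw_params()
  g <- gate_state(pr = "high", ld = "low", ef = "high")
  v <- gate_conductances(g, p)
  expect_equal(unname(v["g_beta_pr"]), unname(p$gates$g_high["pr"]))
  expect_equal(unname(v["g_gamma_ld"]), unname(p$gates$g_low["ld"]))
})

test_that("an uncoupled leg steps periodically; tripod drive is faster; no drive, no steps", {
  tr <- simulate_single_leg(10000, "tetrapod")
  sw <- extract_swings(tr$beta, tr$t)
  sw <- sw[!is.na(sw$duration) & sw$liftoff > 2000, ]
  expect_gte(nrow(sw), 4)
  per <- diff(sw$liftoff)
  expect_lt(sd(per) / mean(per), 0.05)

  tr2 <- simulate_single_leg(10000, "tripod")
  sw2 <- extract_swings(tr2$beta, tr2$t)
  sw2 <- sw2[!is.na(sw2$duration) & sw2$liftoff > 2000, ]
  expect_lt(mean(diff(sw2$liftoff)), mean(per))

  # zero drive: silence the CPG drive tables entirely
  p0 <- sw_params(gapp = list(tetrapod = list(pr = c(0, 0), ld = c(0, 0),
                                              ef = c(0, 0))))
  tr0 <- simulate_single_leg(6000, "tetrapod", params = p0)
  sw0 <- extract_swings(tr0$beta, tr0$t)
  expect_identical(nrow(sw0[!is.na(sw0$duration), ]), 0L)
})

test_that("gate automaton shows no chatter on simulated trajectories", {
  rec <- tetrapod_run()
  ev <- rec$events
  for (code in c("gate_pr", "gate_ld", "gate_ef")) {
    for (leg in c("L1", "L2", "L3", "R1", "R2", "R3")) {
      tt <- ev$time[ev$event == code & ev$who == leg]
      if (length(tt) > 1) expect_gt(min(diff(tt)), 10)
    }
  }
})

test_that("intraleg phase order: retraction during stance, protraction during swing", {
  rec <- tetrapod_run()
  late <- rec$times > 9000
  b <- rec$angles[late, "L3_beta"]
  a <- rec$angles[late, "L3_alpha"]
  da <- diff(a)
  stance <- (b < 32)[-1]
  swing <- (b >= 35)[-1]
  expect_gt(mean(da[stance]), 0)  # forward walking: stance = retraction
  expect_lt(mean(da[swing]), 0)   # swing = protraction
})
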