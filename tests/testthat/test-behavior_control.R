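# behaviour-controller rules and schedule validation

legs_df <- function(beta, dbeta) sw_leg_states(beta, dbeta)

test_that("tripod initiation admits only lifted, rising front or hind legs", {
  p <- sw_params()
  # L1 lifted and rising qualifies
  l <- legs_df(c(45, 31, 31, 31, 31, 31), c(0.1, 0, 0, 0, 0, 0))
  expect_identical(try_start_tripod_transition(l, "left", params = p), "L1")
  # a middle leg lifted and rising never qualifies
  l <- legs_df(c(31, 50, 31, 31, 31, 31), c(0, 0.2, 0, 0, 0, 0))
  expect_null(try_start_tripod_transition(l, "left", params = p))
  # all grounded: none
  l <- legs_df(rep(31, 6), rep(0, 6))
  expect_null(try_start_tripod_transition(l, "left", params = p))
  # lifted but descending: none
  l <- legs_df(c(45, 31, 31, 31, 31, 31), c(-0.1, 0, 0, 0, 0, 0))
  expect_null(try_start_tripod_transition(l, "left", params = p))
})

test_that("once one side initiates at a segment, the other side is held to that segment", {
  p <- sw_params()
  # R3 qualifies, but L1 started the transition at the front segment
  l <- legs_df(c(31, 31, 31, 31, 31, 48), c(0, 0, 0, 0, 0, 0.15))
  expect_null(try_start_tripod_transition(l, "right",
                                          initiated_segment = "front",
                                          params = p))
  # R1 qualifying is accepted under the same restriction
  l <- legs_df(c(31, 31, 31, 47, 31, 31), c(0, 0, 0, 0.15, 0, 0))
  expect_identical(try_start_tripod_transition(l, "right",
                                               initiated_segment = "front",
                                               params = p), "R1")
})

test_that("tetrapod initiation needs slow or descending middle and hind legs, per side", {
  p <- sw_params()
  l <- legs_df(rep(35, 6), c(0, -0.05, -0.02, 0, 0.3, 0.3))
  expect_true(try_start_tetrapod_transition(l, "left", p))   # both descending
  expect_false(try_start_tetrapod_transition(l, "right", p)) # both rising fast
})

test_that("stop is accepted only when no right leg is descending", {
  expect_identical(request_stop(legs_df(rep(31, 6), c(0, 0, 0, 0, 0.1, 0))),
                   "accepted")
  expect_identical(request_stop(legs_df(rep(31, 6), rep(0, 6))), "accepted")
  expect_identical(request_stop(legs_df(rep(31, 6), c(0, 0, 0, 0, -0.1, 0))),
                   "deferred")
})

test_that("backward needs a middle leg near maximal levation; rejected during still stand", {
  p <- sw_params()
  l <- legs_df(c(31, 59, 31, 31, 31, 31), c(0, 0.05, 0, 0, 0, 0))
  expect_identical(set_direction_rule(l, "backward", params = p), "accepted")
  l2 <- legs_df(rep(31, 6), rep(0, 6))
  expect_identical(set_direction_rule(l2, "backward", params = p), "deferred")
  expect_identical(set_direction_rule(l, "backward", still = TRUE, params = p),
                   "rejected")
  expect_identical(set_direction_rule(l2, "forward", params = p), "accepted")
})

test_that("schedules validate: search/stop overlap is fine, backward/stop overlap conflicts", {
  ok <- list(mode_command("stop", 1000),
             mode_command("search", 1500, leg = "L1", on = TRUE),
             mode_command("search", 2500, leg = "L1", on = FALSE),
             mode_command("restart", 3000))
  v <- validate_schedule(ok)
  expect_true(v$valid)

  bad <- list(mode_command("stop", 1000),
              mode_command("direction", 1500, target = "backward"),
              mode_command("restart", 3000))
  v2 <- validate_schedule(bad)
  expect_false(v2$valid)
  expect_identical(nrow(v2$conflicts), 1L)
  expect_identical(sort(c(v2$conflicts$i, v2$conflicts$j)), c(1, 2))

  expect_true(validate_schedule(list())$valid) # empty schedule: plain walking
})

test_that("search commands are restricted to the front legs", {
  expect_error(mode_command("search", 100, leg = "L2", on = TRUE),
               "front legs")
})

test_that("a conflicting schedule refuses to start", {
  m <- default_model()
  bad <- list(mode_command("stop", 500),
              mode_command("direction", 800, target = "backward"))
  expect_error(run_model(m, bad, config = sim_config(t_end = 100)),
               "schedule conflict")
})

test_that("still-stand pose targets encode the documented static gate settings", {
  tg <- stop_pose_targets()
  expect_identical(tg$alpha_target, c(28, 128, 128, 28, 128, 128))
  expect_true(all(tg$beta_target >= 30 & tg$beta_target < 32))
  expect_identical(tg$g_beta_pr[tg$segment == "front"], c(0, 0))
  expect_true(all(tg$g_beta_pr[tg$segment != "front"] > 0))
  expect_true(all(tg$g_beta_ef[tg$segment == "hind"] > 0))   # via cross connection
  expect_true(all(tg$g_beta_ef[tg$segment == "middle"] == 0))
})

test_that("restart during walking is a rejected no-op", {
  m <- default_model()
  rec <- run_model(m, list(mode_command("restart", 1000)),
                   config = sim_config(t_end = 2000))
  expect_true("rejected" %in% rec$events$event)
  expect_false("restart" %in% rec$events$event)
})
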