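# six-leg assembly: structure, interleg and contralateral pathways

test_that("the assembled model has the full structural counts", {
  ct <- model_counts(assemble())
  expect_identical(ct$cpgs, 18)
  expect_identical(ct$motoneurons, 72L)
  expect_identical(ct$interneurons, 108L)
  expect_identical(ct$neuronal_odes, 648L)
  expect_identical(ct$muscle_odes, 18L)
  expect_identical(ct$units_per_side, 9)
  expect_identical(ct$per_leg$cpgs, 3)
  expect_identical(ct$per_leg$motoneurons, 12L)
  expect_identical(ct$per_leg$interneurons, 18L)
})

test_that("counts are invariant under disabling the slow muscles", {
  m_off <- assemble(slow_muscles = FALSE)
  expect_identical(model_counts(m_off), model_counts(assemble()))
})

test_that("inconsistent configuration is rejected", {
  expect_error(assemble(slow_motoneurons = FALSE, slow_muscles = TRUE),
               "configuration error")
})

test_that("the assembly summary exports counts and synapse classes as JSON", {
  path <- tempfile(fileext = ".json")
  export_assembly(assemble(), path)
  x <- jsonlite::fromJSON(readLines(path))
  expect_identical(x$counts$neuronal_odes, 648L)
  expect_true("cpg_mutual_inhibition" %in% x$synapse_classes$class)
  expect_true("contralateral_l2_r3" %in% x$synapse_classes$class)
  # the experimental variants are absent from the default wiring
  expect_false("contralateral_l2_r2" %in% x$synapse_classes$class)
})

test_that("the ipsilateral drive follows the quadrant rule and is bounded", {
  p <- sw_params()
  post <- data.frame(beta = c(31, 31, 45, 45, 59),
                     dbeta = c(0, -0.1, 0.2, -0.2, 0.05))
  g <- ipsilateral_drive(post, p, target = "prothoracic")
  expect_true(all(g >= 0 & g <= p$interleg$g_inh3))
  expect_equal(g[1], p$interleg$g_inh3 * p$interleg$tonic) # grounded, tonic
  expect_equal(g[3], p$interleg$g_inh3 * p$interleg$rise)  # lifted rising
  expect_equal(g[4], p$interleg$g_inh3 * p$interleg$fall)  # lifted falling
})

test_that("the ipsilateral drive is periodic over a full posterior step cycle", {
  tr <- simulate_single_leg(10000, "tetrapod", leg = "L2")
  db <- c(0, diff(tr$beta))
  g <- ipsilateral_drive(data.frame(beta = tr$beta, dbeta = db),
                         target = "mesothoracic")
  # compare one late cycle against the next (period from swing extraction)
  sw <- extract_swings(tr$beta, tr$t)
  sw <- sw[!is.na(sw$duration) & sw$liftoff > 3000, ]
  per <- round(mean(diff(sw$liftoff)))
  i0 <- which(tr$t >= sw$liftoff[1])[1]
  seg1 <- g[i0:(i0 + per - 1)]
  seg2 <- g[(i0 + per):(i0 + 2 * per - 1)]
  expect_gt(cor(seg1, seg2), 0.99)
})

test_that("contralateral pair pathways transmit only during tripod transitions", {
  legs <- data.frame(leg = c("L1","L2","L3","R1","R2","R3"),
                     beta = c(31, 55, 31, 31, 31, 31),
                     dbeta = c(0, 0.1, 0, 0, 0, 0))
  # normal walking: only the L2->R3 pathway carries signal
  dn <- contralateral_drive(legs, phase = "normal")
  expect_identical(dn$pathway, "l2_to_r3")
  expect_gt(dn$g[1], 0)
  # transition phase: the active segment's pair pathway joins in
  dt_ <- contralateral_drive(legs, phase = "tripod_transition",
                             active_segment = "hind")
  expect_true(any(grepl("pair_hind", dt_$pathway)))
  expect_false(any(grepl("pair_front", dt_$pathway)))
  # all legs grounded: the pair pathways carry essentially nothing
  legs$beta <- rep(31, 6); legs$dbeta <- 0
  dg <- contralateral_drive(legs, phase = "tripod_transition",
                            active_segment = "hind")
  pair <- dg$g[grepl("pair", dg$pathway)]
  expect_true(all(pair < 0.05 * sw_params()$contra$g_pair |
                  length(pair) == 0))
})

test_that("without contralateral connections identical sides stay identical", {
  m <- uncoupled_model()
  m2 <- assemble(contralateral = contralateral_config(FALSE, FALSE, FALSE, FALSE))
  rec <- run_model(m2, config = sim_config(t_end = 6000))
  b <- beta_traces(rec)
  expect_lt(max(abs(b[, 1:3] - b[, 4:6])), 1e-9)
})
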