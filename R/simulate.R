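#' Simulation configuration
#'
#' @param t_end simulation horizon (ms).
#' @param dt integration step of the fixed-step RK4 solver (ms). The solver
#'   tolerance maps onto this step: halving `dt` should change reported step
#'   periods by well under 1 percent.
#' @param out_dt output sampling interval (ms).
#' @param t0 start time (ms).
#' @param start_gait gait drive table active at start, `"tetrapod"` or
#'   `"tripod"`.
#' @param ic initial-condition spec from [initial_conditions()].
#' @param record_neurons integer vector of neuron ids (0..215) whose membrane
#'   potentials are recorded, or `NULL`.
#' @return A list of class `"sw_sim_config"`.
#' @export
sim_config <- function(t_end = 13000, dt = NULL, out_dt = NULL, t0 = 0,
                       start_gait = c("tetrapod", "tripod"),
                       ic = initial_conditions(), record_neurons = NULL) {
  start_gait <- match.arg(start_gait)
  stopifnot(t_end >= 0)
  if (!is.null(dt)) stopifnot(dt > 0)
  if (!is.null(out_dt)) stopifnot(out_dt > 0)
  structure(list(t_end = t_end, dt = dt, out_dt = out_dt, t0 = t0,
                 start_gait = start_gait, ic = ic,
                 record_neurons = record_neurons),
            class = "sw_sim_config")
}

#' Initial conditions
#'
#' All legs start grounded in a stance pose. The per-leg stepping phase is
#' seeded through the adaptation variable of the levator CPG neurons: a leg
#' whose levator adaptation starts low escapes (lifts off) earlier. The
#' default is identical on both sides with the hind legs leading, so that
#' without contralateral connections the model settles into bilaterally
#' synchronous tetrapod stepping initiated at the hind legs.
#'
#' @param mode `"identical_sides"` or `"per_leg"`.
#' @param lev_q0 levator adaptation start values; length 3 (front, middle,
#'   hind; replicated on both sides) for `"identical_sides"`, length 6
#'   (L1, L2, L3, R1, R2, R3) for `"per_leg"`.
#' @export
initial_conditions <- function(mode = c("identical_sides", "per_leg"),
                               lev_q0 = NULL) {
  mode <- match.arg(mode)
  if (is.null(lev_q0)) lev_q0 <- c(0.55, 0.3, 0.02)
  if (mode == "identical_sides") {
    stopifnot(length(lev_q0) == 3)
    lev_q0 <- rep(lev_q0, 2)
  } else stopifnot(length(lev_q0) == 6)
  structure(list(mode = mode, lev_q0 = lev_q0), class = "sw_ic")
}

# build the 684-element continuous state vector for a cold start
sw_initial_state <- function(model, ic = initial_conditions()) {
  p <- model$params$neuron
  sig <- function(v, th, k) 1 / (1 + exp(-(v - th) / k))
  y <- numeric(684)
  for (l in 0:5) {
    seg <- l %% 3
    for (n in 0:2) {
      for (k in 0:11) {
        id <- l * 36 + n * 12 + k
        V <- p$EL
        m <- sig(V, p$thm, p$km)
        q <- sig(V, p$thq, p$kq)
        if (k == 1L) { # the b neuron (retractor/depressor/flexor) starts active
          V <- -25; m <- 0.8; q <- 0.4
        }
        if (n == 1 && k == 0) { # levator phase seed
          V <- -62; m <- 0.01; q <- ic$lev_q0[l + 1]
        }
        y[3 * id + 1:3] <- c(V, m, q)
      }
      jb <- 648 + (l * 3 + n) * 2
      ang <- switch(n + 1, 100, 31, if (seg == 2) 46 else 105)
      y[jb + 1:2] <- c(ang, 0)
    }
  }
  y
}

# initial discrete state: all legs in stance, gates high, chosen gait table
sw_initial_disc <- function(start_gait = "tetrapod") {
  d <- integer(36)
  d[1:18] <- 1L               # pr, ld, ef gates high (stance)
  g <- if (start_gait == "tripod") 1L else 0L
  d[19:20] <- g
  d[32] <- -1L                # tri_seg
  d[33] <- -1L                # pair_active
  d
}

#' Run the six-leg model
#'
#' Integrates the assembled model (648 neuronal ODEs + 18 second-order joint
#' equations) with a fixed-step RK4 solver while the discrete part of the
#' system -- sensory gates, interleg signal levels and the behavioural-mode
#' controller -- is updated once per step. Mode changes requested by the
#' schedule are applied instantaneously at the step at which their acceptance
#' constraints are met, and every discrete switch is logged with a timestamp.
#'
#' @param model an [assemble()]d model.
#' @param schedule a list of mode commands (see [mode_command()]), or `NULL`
#'   for plain walking. The schedule is validated first; conflicts refuse to
#'   start.
#' @param config a [sim_config()].
#' @param state optional list with elements `y`, `disc`, `search_drive` (as
#'   returned in a record's `final`) to resume a previous run.
#' @return An object of class `"sw_trajectory"`: `times` (ms), `angles`
#'   (matrix with columns `L1_alpha`, `L1_beta`, ..., `R3_gamma`), `events`
#'   (data frame: time, event, leg/side, value), `final` (full continuous +
#'   discrete state for resuming), `status` (0 ok, 1 integration failure at
#'   `tfail`).
#' @export
#' @examples
#' \donttest{
#' m <- assemble()
#' rec <- run_model(m, config = sim_config(t_end = 4000))
#' head(beta_traces(rec))
#' }
run_model <- function(model, schedule = NULL, config = sim_config(),
                      state = NULL) {
  stopifnot(inherits(model, "sw_model"), inherits(config, "sw_sim_config"))
  if (!is.null(schedule)) {
    v <- validate_schedule(schedule)
    if (!isTRUE(v$valid))
      stop("schedule conflict: ", paste(v$conflicts$reason, collapse = "; "))
  }
  p <- model$params
  dt <- if (is.null(config$dt)) p$sim$dt else config$dt
  out_dt <- if (is.null(config$out_dt)) p$sim$out_dt else config$out_dt
  cp <- sw_flatten_params(p, model$config)
  sched <- sw_schedule_matrix(schedule)
  if (is.null(state)) {
    y0 <- sw_initial_state(model, config$ic)
    disc0 <- sw_initial_disc(config$start_gait)
    sd0 <- rep(1, 6)
  } else {
    y0 <- state$y; disc0 <- state$disc; sd0 <- state$search_drive
  }
  rec_n <- if (is.null(config$record_neurons)) integer(0)
           else as.integer(config$record_neurons)
  res <- sw_core_run(cp, sched, config$t0, config$t0 + config$t_end,
                     dt, out_dt, y0, disc0, sd0, rec_n)
  ang <- res$angles
  colnames(ang) <- paste(rep(LEGS, each = 3), rep(JOINTS, 6), sep = "_")
  ev <- sw_decode_events(res$events)
  out <- list(times = res$times, angles = ang, events = ev,
              voltages = if (length(rec_n)) res$voltages else NULL,
              record_neurons = rec_n,
              final = list(y = res$state, disc = res$disc,
                           search_drive = res$search_drive),
              status = res$status, tfail = res$tfail,
              dt = dt, out_dt = out_dt, t0 = config$t0)
  class(out) <- "sw_trajectory"
  out
}

sw_event_names <- c(`1` = "gate_pr", `2` = "gate_ld", `3` = "gate_ef",
                    `10` = "gait_switch", `11` = "tripod_init",
                    `12` = "tetrapod_init", `20` = "stop_accepted",
                    `21` = "restart", `22` = "search_on", `23` = "search_off",
                    `24` = "backward", `25` = "forward", `26` = "rejected",
                    `30` = "integration_failure")

sw_decode_events <- function(evm) {
  if (nrow(evm) == 0)
    return(data.frame(time = numeric(), event = character(),
                      who = character(), value = numeric()))
  code <- as.character(evm[, 2])
  who <- ifelse(evm[, 2] %in% c(1, 2, 3, 11, 22, 23), LEGS[evm[, 3] + 1],
         ifelse(evm[, 2] %in% c(10, 12), c("left", "right")[evm[, 3] + 1], ""))
  data.frame(time = evm[, 1], event = unname(sw_event_names[code]),
             who = who, value = evm[, 4])
}

#' @export
print.sw_trajectory <- function(x, ...) {
  cat(sprintf("sw_trajectory: %d samples, t in [%.0f, %.0f] ms, %d events\n",
              length(x$times), if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA, nrow(x$events)))
  if (x$status != 0)
    cat(sprintf("  INTEGRATION FAILURE at t = %.1f ms (partial record)\n", x$tfail))
  invisible(x)
}

#' Extract the levation-angle traces of all six legs
#'
#' @param rec an `sw_trajectory`.
#' @return Matrix with one column per leg (L1..R3) of beta angles (degrees).
#' @export
beta_traces <- function(rec) {
  stopifnot(inherits(rec, "sw_trajectory"))
  b <- rec$angles[, paste0(LEGS, "_beta"), drop = FALSE]
  colnames(b) <- LEGS
  b
}

#' Export / import a trajectory record
#'
#' The trajectory is written as a flat CSV (`t_ms`, then `L1_alpha` ...
#' `R3_gamma`); the event log and sampling metadata go to a JSON sidecar
#' (`<path>.events.json`). The round trip is lossless at the output sampling
#' resolution.
#'
#' @param rec an `sw_trajectory`.
#' @param path CSV output path.
#' @export
export_trajectories <- function(rec, path) {
  stopifnot(inherits(rec, "sw_trajectory"))
  df <- data.frame(t_ms = rec$times, rec$angles, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(events = rec$events, dt = rec$dt, out_dt = rec$out_dt,
               t0 = rec$t0, status = rec$status,
               tfail = if (is.na(rec$tfail)) NULL else rec$tfail)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA, null = "null"),
             paste0(path, ".events.json"))
  invisible(path)
}

#' @rdname export_trajectories
#' @export
import_trajectories <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t_ms", paste(rep(LEGS, each = 3), rep(JOINTS, 6), sep = "_"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(diff(df$t_ms) <= 0)
  if (length(bad))
    stop(sprintf("parse error at line %d: time column not strictly increasing",
                 bad[1] + 2L)) # header + 1-based offset
  sidecar <- paste0(path, ".events.json")
  ev <- data.frame(time = numeric(), event = character(), who = character(),
                   value = numeric())
  dt <- NA; out_dt <- NA; t0 <- df$t_ms[1]; status <- 0; tfail <- NA
  if (file.exists(sidecar)) {
    side <- jsonlite::fromJSON(readLines(sidecar))
    if (!is.null(side$events) && length(side$events)) ev <- as.data.frame(side$events)
    dt <- side$dt; out_dt <- side$out_dt; t0 <- side$t0
    status <- side$status
    tfail <- if (is.null(side$tfail)) NA else side$tfail
  }
  ang <- as.matrix(df[, need[-1], drop = FALSE])
  out <- list(times = df$t_ms, angles = ang, events = ev, voltages = NULL,
              record_neurons = integer(0), final = NULL,
              status = status, tfail = tfail, dt = dt, out_dt = out_dt, t0 = t0)
  class(out) <- "sw_trajectory"
  out
}

#' Simulate one uncoupled leg
#'
#' Runs the assembled model with all interleg and contralateral pathways
#' disabled, so that every leg steps independently through its intraleg
#' coordination gates alone, and returns the trajectories of one leg.
#'
#' @param duration simulation length (ms).
#' @param drive `"tetrapod"` or `"tripod"` drive table.
#' @param leg which leg to return (default L1).
#' @param params model parameters.
#' @return A data frame with `t`, `alpha`, `beta`, `gamma`.
#' @export
simulate_single_leg <- function(duration = 10000,
                                drive = c("tetrapod", "tripod"),
                                leg = "L1", params = sw_params()) {
  drive <- match.arg(drive)
  stopifnot(leg %in% LEGS)
  m <- assemble(params,
                contralateral = contralateral_config(FALSE, FALSE, FALSE, FALSE),
                ipsilateral = FALSE)
  rec <- run_model(m, config = sim_config(t_end = duration, start_gait = drive))
  if (rec$status != 0)
    stop(sprintf("integration failure at t = %.1f ms", rec$tfail))
  data.frame(t = rec$times,
             alpha = rec$angles[, paste0(leg, "_alpha")],
             beta = rec$angles[, paste0(leg, "_beta")],
             gamma = rec$angles[, paste0(leg, "_gamma")])
}
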