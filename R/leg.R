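# one leg's sensory signal generation and the intraleg coordination gates

#' Sensory signals of one leg
#'
#' Derives the sensory signals that drive the intraleg and interleg
#' coordination from the three joint states: the levation angle beta and its
#' angular velocity, the tibia angle gamma and its velocity, and the binary
#' ground-contact signal (30 <= beta < 32 degrees; beta above 32 means the
#' leg is in swing).
#'
#' @param joints a list with components `alpha`, `beta`, `gamma`, each a
#'   [joint_state()].
#' @return A list of class `"sw_sensory"`: `beta`, `dbeta`, `gamma`,
#'   `dgamma`, `ground_contact`.
#' @export
#' @examples
#' s <- compute_sensory(list(alpha = joint_state("alpha", 100),
#'                           beta = joint_state("beta", 31),
#'                           gamma = joint_state("gamma", 105)))
#' s$ground_contact
compute_sensory <- function(joints) {
  stopifnot(all(c("alpha", "beta", "gamma") %in% names(joints)))
  b <- joints$beta; g <- joints$gamma
  structure(list(beta = b$angle, dbeta = b$velocity,
                 gamma = g$angle, dgamma = g$velocity,
                 ground_contact = b$angle >= 30 && b$angle < 32),
            class = "sw_sensory")
}

#' Intraleg gate state
#'
#' The three binary coordination gates of one leg: g_beta(PR) and g_beta(EF)
#' switch on the levation angle, g_gamma(LD) on the tibia angle. Each gate
#' assumes a low or a high conductance value; switching is
#' direction-dependent (g_beta(PR) goes high only while beta is decreasing
#' through its critical value, shortly before ground contact) with a small
#' release hysteresis that protects the automaton against chatter from the
#' slow-muscle baseline ripple.
#'
#' @param pr,ld,ef initial gate states, `"low"` or `"high"`.
#' @param ef_crossed logical; `TRUE` for a hind leg, whose EF network has the
#'   cross connection between CPG and premotor network, so its stance tibia
#'   posture is extended (low gamma) rather than flexed.
#' @param time timestamp (ms) of the state.
#' @param beta,gamma the angles at `time` (needed for crossing detection).
#' @export
gate_state <- function(pr = "low", ld = "low", ef = "low",
                       ef_crossed = FALSE, time = 0, beta = NA, gamma = NA) {
  lv <- function(x) match.arg(x, c("low", "high"))
  structure(list(pr = lv(pr), ld = lv(ld), ef = lv(ef),
                 ef_crossed = isTRUE(ef_crossed),
                 time = time, beta = beta, gamma = gamma),
            class = "sw_gate_state")
}

#' Update the intraleg gates
#'
#' Advances the gate automaton by one sample. g_beta(PR) and g_beta(EF)
#' switch low to high when beta falls through `beta_crit` (beta decreasing),
#' and high to low when beta rises through `beta_crit + beta_hyst`.
#' g_gamma(LD) follows the analogous rule on gamma at `gamma_crit`, with the
#' crossing direction mirrored for a leg whose EF network is crossed (stance
#' = extended).
#'
#' @param signals an [compute_sensory()] result (current sample).
#' @param prev the previous [gate_state()].
#' @param params model parameters.
#' @param time timestamp of `signals` (ms); must not precede `prev$time`.
#' @return The new [gate_state()].
#' @export
update_gates <- function(signals, prev, params = sw_params(), time = NULL) {
  stopifnot(inherits(signals, "sw_sensory"), inherits(prev, "sw_gate_state"))
  if (is.null(time)) time <- prev$time + 1
  if (time < prev$time)
    stop("state error: gate updates must be applied in temporal order")
  g <- params$gates
  new <- prev
  new$time <- time; new$beta <- signals$beta; new$gamma <- signals$gamma
  if (!is.na(prev$beta)) {
    for (nm in c("pr", "ef")) {
      if (prev[[nm]] == "low" &&
          prev$beta > g$beta_crit && signals$beta <= g$beta_crit &&
          signals$dbeta < 0) {
        new[[nm]] <- "high"
      } else if (prev[[nm]] == "high" &&
                 prev$beta < g$beta_crit + g$beta_hyst &&
                 signals$beta >= g$beta_crit + g$beta_hyst) {
        new[[nm]] <- "low"
      }
    }
  }
  if (!is.na(prev$gamma)) {
    if (prev$ef_crossed) { # stance = extended: gate high as gamma drops
      if (prev$ld == "low" && prev$gamma > g$gamma_crit &&
          signals$gamma <= g$gamma_crit && signals$dgamma < 0) {
        new$ld <- "high"
      } else if (prev$ld == "high" &&
                 prev$gamma < g$gamma_crit + g$gamma_hyst &&
                 signals$gamma >= g$gamma_crit + g$gamma_hyst) {
        new$ld <- "low"
      }
    } else {               # stance = flexed: gate high as gamma rises
      if (prev$ld == "low" && prev$gamma < g$gamma_crit &&
          signals$gamma >= g$gamma_crit && signals$dgamma > 0) {
        new$ld <- "high"
      } else if (prev$ld == "high" &&
                 prev$gamma > g$gamma_crit - g$gamma_hyst &&
                 signals$gamma <= g$gamma_crit - g$gamma_hyst) {
        new$ld <- "low"
      }
    }
  }
  new
}

#' Gate conductance values
#'
#' Maps a [gate_state()] to the conductances (uS) seen by the CPGs.
#'
#' @param state a [gate_state()].
#' @param params model parameters.
#' @return Named numeric vector `g_beta_pr`, `g_gamma_ld`, `g_beta_ef`.
#' @export
gate_conductances <- function(state, params = sw_params()) {
  g <- params$gates
  pick <- function(nm, st) if (st == "high") g$g_high[[nm]] else g$g_low[[nm]]
  c(g_beta_pr = pick("pr", state$pr),
    g_gamma_ld = pick("ld", state$ld),
    g_beta_ef = pick("ef", state$ef))
}
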