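# single-unit neuron dynamics: the R reference implementation of the same
# equations the compiled assembly integrates. Each model neuron carries
# exactly three state variables: membrane potential V, slow activation m of
# the persistent inward current, and adaptation q.

sw_sig <- function(v, th, k) 1 / (1 + exp(-(v - th) / k))

#' CPG half-center unit
#'
#' A central pattern generator of the model: two mutually inhibitory
#' nonspiking neurons, each with a persistent inward current and a slow
#' adaptation current, receiving excitatory drive conductances (g_app). In
#' the oscillatory drive range the two neurons produce alternating plateau
#' phases in antiphase; without drive the unit is quiescent.
#'
#' @param network which local network's parameterization to use: the LD
#'   networks are calibrated as free-running oscillators, the PR and EF
#'   networks as gate-switched pairs with one dominant neuron.
#' @param params model parameters.
#' @return An object of class `"sw_cpg_unit"`.
#' @export
cpg_unit <- function(network = c("ld", "pr", "ef"), params = sw_params()) {
  network <- match.arg(network)
  structure(list(network = network, params = params), class = "sw_cpg_unit")
}

sw_cpg_pars <- function(unit) {
  p <- unit$params
  c(p$neuron,
    list(gq = unname(p$cpg$gq[unit$network]),
         tauq = unname(p$cpg$tauq[unit$network]),
         gc = p$cpg$gc))
}

sw_cpg_rhs <- function(t, y, pars, drive, gext_a, gext_b) {
  p <- pars
  V <- y[c(1, 4)]; m <- y[c(2, 5)]; q <- y[c(3, 6)]
  s <- sw_sig(V, p$ths, p$ks)
  ge <- c(gext_a(t), gext_b(t))
  dV <- (-p$gL * (V - p$EL) - p$gP * m * (V - p$EP) - p$gq * q * (V - p$EK)
         - p$gc * s[2:1] * (V - p$Einh) + drive * (p$Eex - V)
         + ge * (p$Einh - V)) / p$C
  dm <- (sw_sig(V, p$thm, p$km) - m) / p$taum
  dq <- (sw_sig(V, p$thq, p$kq) - q) / p$tauq
  list(c(dV[1], dm[1], dq[1], dV[2], dm[2], dq[2]))
}

sw_check_finite <- function(tr) {
  bad <- !is.finite(tr[, -1, drop = FALSE])
  if (any(bad)) {
    i <- which(rowSums(bad) > 0)[1]
    cond <- structure(
      class = c("sw_integration_failure", "error", "condition"),
      list(message = sprintf("integration failure at t = %.2f ms", tr[i, 1]),
           call = NULL, time = tr[i, 1]))
    stop(cond)
  }
  invisible(tr)
}

#' Simulate a CPG half-center
#'
#' Integrates one two-neuron half-center with the given drive-conductance
#' pair and an optional external inhibitory conductance signal, and measures
#' the oscillation period and the phase difference between the two neurons.
#'
#' @param unit a [cpg_unit()].
#' @param drive length-2 drive conductances (uS) for the two neurons.
#' @param external_inhibition `NULL`, or a function of time (ms) returning an
#'   inhibitory conductance applied to neuron a; or a list of two such
#'   functions (neurons a and b).
#' @param duration simulation length (ms); should cover several expected
#'   periods.
#' @param y0 optional initial state (V, m, q for both neurons). The default
#'   starts the pair asymmetrically.
#' @return A list: `times`, `V` (two-column matrix), `period` (ms, `NA` if
#'   quiescent), `phase_diff` (fraction of a period), `oscillating`.
#' @export
#' @examples
#' u <- cpg_unit("ld")
#' r <- simulate_cpg(u, drive = c(0.030, 0.048), duration = 8000)
#' r$period
simulate_cpg <- function(unit, drive, external_inhibition = NULL,
                         duration = 10000, y0 = NULL) {
  stopifnot(inherits(unit, "sw_cpg_unit"), length(drive) == 2, duration > 0)
  p <- sw_cpg_pars(unit)
  if (is.null(y0)) y0 <- c(-40, 0.5, 0.2, -65, 0.01, 0.01)
  if (is.null(external_inhibition)) {
    ga <- function(t) 0; gb <- function(t) 0
  } else if (is.function(external_inhibition)) {
    ga <- external_inhibition; gb <- function(t) 0
  } else {
    ga <- external_inhibition[[1]]; gb <- external_inhibition[[2]]
  }
  tr <- deSolve::ode(y0, seq(0, duration, by = 1), sw_cpg_rhs, p,
                     drive = drive, gext_a = ga, gext_b = gb,
                     method = "lsoda", rtol = 1e-8, atol = 1e-8)
  sw_check_finite(tr)
  Va <- tr[, 2]; Vb <- tr[, 5]; tt <- tr[, 1]
  per <- sw_period(tt, Va)
  out <- list(times = tt, V = cbind(a = Va, b = Vb), period = per$period,
              phase_diff = NA_real_, oscillating = is.finite(per$period))
  if (out$oscillating) {
    # phase difference from plateau midpoints: 0.5 means strict alternation
    # in antiphase even when the two plateau durations differ
    ma <- sw_plateau_mids(tt, Va); mb <- sw_plateau_mids(tt, Vb)
    if (length(ma) > 1 && length(mb) > 1) {
      d <- vapply(mb, function(t2) {
        t1 <- ma[ma <= t2]
        if (!length(t1)) NA_real_ else (t2 - max(t1)) / per$period
      }, numeric(1))
      out$phase_diff <- mean(d, na.rm = TRUE)
    }
  }
  out
}

# midpoints of the plateau phases (V above threshold)
sw_plateau_mids <- function(times, V, threshold = -35, settle = 0.35) {
  keep <- times >= settle * max(times)
  v <- V[keep]; tt <- times[keep]
  up <- which(diff(v > threshold) == 1)
  dn <- which(diff(v > threshold) == -1)
  mids <- numeric()
  for (i in up) {
    j <- dn[dn > i]
    if (length(j)) mids <- c(mids, (tt[i] + tt[j[1]]) / 2)
  }
  mids
}

# oscillation onsets: upward crossings of the plateau threshold, measured on
# the second half of the trace to skip transients
sw_period <- function(times, V, threshold = -35, settle = 0.35) {
  keep <- times >= settle * max(times)
  v <- V[keep]; tt <- times[keep]
  up <- which(diff(v > threshold) == 1)
  if (length(up) < 2) return(list(period = NA_real_, onsets = numeric()))
  onsets <- tt[up + 1]
  list(period = mean(diff(onsets)), onsets = onsets)
}

#' Response of a plateau to an inhibitory pulse
#'
#' Applies a square inhibitory conductance pulse to one neuron of an
#' oscillating half-center during one of its plateau phases and reports
#' whether the plateau persists or is terminated early. CPG neurons are
#' insensitive to inhibition while strongly depolarized (depolarization
#' block), so a mid-plateau pulse of moderate conductance leaves the plateau
#' essentially intact, while the same pulse near the plateau-to-silent
#' transition ends it early.
#'
#' @param unit a [cpg_unit()].
#' @param drive drive-conductance pair.
#' @param pulse list with `onset_frac` (position inside the plateau, 0..1),
#'   `duration` (ms) and `g` (uS).
#' @param duration total simulated time (ms).
#' @return A list: `plateau_ref` and `plateau_pulsed` (durations in ms of the
#'   perturbed plateau without/with the pulse), `outcome` (`"persists"` or
#'   `"terminated"`), `pulse_window` (ms).
#' @export
inhibition_response <- function(unit, drive, pulse, duration = 12000) {
  stopifnot(inherits(unit, "sw_cpg_unit"),
            all(c("onset_frac", "duration", "g") %in% names(pulse)))
  ref <- simulate_cpg(unit, drive, duration = duration)
  if (!ref$oscillating) stop("unit is not oscillating at this drive")
  # pick a full plateau of neuron a well inside the trace
  act <- ref$V[, "a"] > -35
  on <- which(diff(act) == 1) + 1
  off <- which(diff(act) == -1) + 1
  on <- on[ref$times[on] > 0.4 * duration]
  if (!length(on)) stop("no plateau found inside the simulated window")
  t_on <- ref$times[on[1]]
  t_off <- ref$times[off[off > on[1]][1]]
  if (is.na(t_off)) stop("plateau extends beyond the simulated window")
  p_start <- t_on + pulse$onset_frac * (t_off - t_on)
  p_end <- p_start + pulse$duration
  if (p_end > duration)
    stop("argument error: pulse lies outside the simulated window")
  gext <- function(t) ifelse(t >= p_start & t < p_end, pulse$g, 0)
  per <- simulate_cpg(unit, drive, external_inhibition = gext,
                      duration = duration)
  # effective plateau end: first downward crossing followed by a sustained
  # (>= 150 ms) silent phase, so a transient dip during the pulse from which
  # the plateau recovers does not count as termination
  t_off2 <- sw_plateau_end(per$times, per$V[, "a"], t_on)
  ref_dur <- t_off - t_on
  pul_dur <- t_off2 - t_on
  list(plateau_ref = ref_dur, plateau_pulsed = pul_dur,
       outcome = if (pul_dur < 0.95 * ref_dur) "terminated" else "persists",
       pulse_window = c(p_start, p_end))
}

sw_plateau_end <- function(times, V, t_on, threshold = -35, sustain = 150) {
  act <- V > threshold
  dn <- which(diff(act) == -1) + 1
  dn <- dn[times[dn] > t_on]
  for (i in dn) {
    seg <- act[times >= times[i] & times <= times[i] + sustain]
    if (!any(seg)) return(times[i])
  }
  NA_real_
}

#' Motoneuron unit
#'
#' Fast and slow motoneurons share all membrane properties except the
#' adaptation current, whose maximal conductance g_q is three times as large
#' in the slow motoneurons, and the effective activation time constant of the
#' muscle they drive, which is realized as a capacitance scale on the slow
#' motoneuron membrane.
#'
#' @param speed_class `"fast"` or `"slow"`.
#' @param params model parameters.
#' @export
motoneuron_unit <- function(speed_class = c("fast", "slow"),
                            params = sw_params()) {
  speed_class <- match.arg(speed_class)
  structure(list(speed_class = speed_class, params = params,
                 g_q = if (speed_class == "slow") params$mn$gq_slow
                       else params$mn$gq_fast,
                 g_MN = params$mn$gMN),
            class = "sw_motoneuron")
}

#' Motoneuron activity under central drive and premotor inhibition
#'
#' Integrates one motoneuron receiving an excitatory central-drive
#' conductance signal and an inhibitory premotor conductance signal on a
#' common time grid, and returns its muscle-activation output (the synaptic
#' transfer of its membrane potential, between 0 and 1).
#'
#' @param mn a [motoneuron_unit()].
#' @param cpg_drive numeric vector: excitatory conductance (uS) per sample.
#' @param premotor_inhibition numeric vector, same length: inhibitory
#'   conductance (uS) per sample.
#' @param dt sample spacing (ms).
#' @return A list: `times`, `V`, `activity`.
#' @export
mn_activity <- function(mn, cpg_drive, premotor_inhibition, dt = 1) {
  stopifnot(inherits(mn, "sw_motoneuron"))
  if (length(cpg_drive) != length(premotor_inhibition))
    stop("argument error: drive and inhibition signals differ in length")
  p <- mn$params$neuron
  pm <- mn$params$mn
  Cm <- p$C * if (mn$speed_class == "slow") pm$tau_act_slow / pm$tau_act_fast else 1
  tt <- (seq_along(cpg_drive) - 1) * dt
  fe <- stats::approxfun(tt, cpg_drive, rule = 2)
  fi <- stats::approxfun(tt, premotor_inhibition, rule = 2)
  rhs <- function(t, y, parms) {
    V <- y[1]; q <- y[3]
    dV <- (-p$gL * (V - p$EL) - mn$g_q * q * (V - p$EK)
           + fe(t) * (p$Eex - V) + fi(t) * (p$Einh - V)) / Cm
    list(c(dV, (sw_sig(V, p$thm, p$km) - y[2]) / p$taum,
           (sw_sig(V, p$thq, p$kq) - q) / pm$tauq))
  }
  y0 <- c(p$EL, sw_sig(p$EL, p$thm, p$km), sw_sig(p$EL, p$thq, p$kq))
  tr <- deSolve::ode(y0, tt, rhs, NULL, method = "lsoda",
                     rtol = 1e-8, atol = 1e-8)
  sw_check_finite(tr)
  list(times = tr[, 1], V = tr[, 2],
       activity = sw_sig(tr[, 2], p$ths, p$ks))
}
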