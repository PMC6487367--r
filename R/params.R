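#' Model parameters
#'
#' Builds the full parameter set of the six-leg neuromechanical model as a
#' nested list. All values are expressed in the model's working units:
#' time in ms, voltages in mV, conductances in uS, angles in degrees.
#'
#' The major groups are:
#' \describe{
#'   \item{neuron}{Membrane constants shared by all 216 model neurons:
#'     capacitance \code{C}, leak \code{gL}/\code{EL}, persistent inward
#'     current (\code{gP}, \code{EP}, activation sigmoid \code{thm}/\code{km},
#'     time constant \code{taum}), adaptation reversal \code{EK} and sigmoid
#'     \code{thq}/\code{kq}, synaptic transfer sigmoid \code{ths}/\code{ks},
#'     and synaptic reversal potentials \code{Eex}/\code{Einh}.}
#'   \item{cpg}{Half-center parameters per local network (PR, LD, EF):
#'     adaptation conductance \code{gq} and time constant \code{tauq}, and the
#'     mutual-inhibition conductance \code{gc}. The LD networks are genuine
#'     oscillators; the PR and EF networks have one dominant neuron and are
#'     switched by their sensory gates.}
#'   \item{mn}{Motoneuron parameters. \code{gq_slow = 3 * gq_fast}: the slow
#'     motoneurons adapt three times as strongly as the fast ones. The slow
#'     pathway's longer activation time constant is realized as a capacitance
#'     scale \code{tau_act_slow / tau_act_fast} on the slow motoneuron
#'     membrane, keeping the mechanical system strictly second order.}
#'   \item{gates}{Intraleg coordination gates: switching thresholds
#'     (\code{beta_crit}, \code{gamma_crit}), hysteresis, and the low/high
#'     conductances of g_beta(PR), g_beta(EF) and g_gamma(LD).}
#'   \item{muscle}{Antagonistic-pair joint dynamics: fast/slow force gains
#'     \code{Gf}/\code{Gs}, torque scale \code{Tsc}, stiffness \code{kr},
#'     damping \code{bdamp}, per-joint passive bias and the joint limits
#'     alpha [28, 128], beta [30, 60], gamma [45, 110].}
#'   \item{gapp}{CPG drive-conductance tables per gait (tetrapod, tripod) and
#'     the front-leg EF drive pair used during search movements.}
#'   \item{interleg}{Ipsilateral pathway conductances g_inh3 (onto the
#'     prothoracic levator CPG) and g_inh9 (mesothoracic), and the quadrant
#'     rule factors applied while the posterior leg is lifted-rising,
#'     lifted-falling, or grounded.}
#'   \item{contra}{The four contralateral connections (L2 to R3 excitation,
#'     the L1/R1 and L3/R3 pair pathways with their mutual inhibition) and the
#'     two experimental inhibitory variants.}
#'   \item{control}{Behavioural-mode constraints: \code{beta_min} for tripod
#'     initiation, \code{eps_tet} for tetrapod initiation, \code{beta_back}
#'     (= 60 - delta_back) for backward starts, and the static gate settings
#'     of the still-stand pose.}
#'   \item{sim}{Integration step \code{dt} and output sampling
#'     \code{out_dt}.}
#' }
#'
#' @param ... named overrides, e.g. \code{sw_params(gates = list(beta_crit = 34))}.
#'   Unknown names are an error.
#' @return A nested parameter list of class \code{"sw_params"}.
#' @export
#' @examples
#' p <- sw_params(sim = list(dt = 0.2))
#' p$gates$beta_crit
sw_params <- function(...) {
  p <- list(
    neuron = list(
      C = 1, gL = 0.1, EL = -60, gP = 0.25, EP = 20, EK = -80,
      Eex = 0, Einh = -70,
      thm = -37, km = 4, taum = 20, thq = -35, kq = 6, ths = -30, ks = 4
    ),
    cpg = list(
      gq = c(pr = 0.45, ld = 0.4, ef = 0.3),
      tauq = c(pr = 200, ld = 400, ef = 150),
      gc = 0.25
    ),
    mn = list(
      gMN = 0.3, gq_fast = 0.04, gq_slow = 0.12, tauq = 300, g_pm = 0.5,
      tau_act_fast = 5, tau_act_slow = 40
    ),
    premotor = list(g_ci = 0.4, pm_override = 0.5),
    relay = list(g_rel = 0.4),
    gates = list(
      beta_crit = 33, beta_hyst = 2, gamma_crit = 75, gamma_hyst = 2,
      g_low = c(pr = 0, ld = 0, ef = 0),
      g_high = c(pr = 0.3, ld = 0.05, ef = 0.3),
      w6 = c(pr = 1, ld = 0.3, ef = 1)
    ),
    muscle = list(
      Gf = 1, Gs = 0.3, Tsc = 0.25, kr = 0.01, bdamp = 0.21,
      bias = c(alpha = 0, beta = -0.6, gamma = -0.5),
      limits = list(alpha = c(28, 128), beta = c(30, 60), gamma = c(45, 110))
    ),
    gapp = list(
      tetrapod = list(pr = c(0.15, 0.015), ld = c(0.032, 0.044), ef = c(0.08, 0.015)),
      tripod   = list(pr = c(0.15, 0.015), ld = c(0.052, 0.050), ef = c(0.08, 0.015)),
      search_ef = c(0.03, 0.03)
    ),
    interleg = list(
      g_inh3 = 0.3, g_inh9 = 0.3,
      rise = 1, fall = 1, tonic = 0, beta_lift = 32,
      lev_boost = c(front = 1.1, middle = 1.05, hind = 1),
      seg_tau = c(front = 0.82, middle = 0.90, hind = 1)
    ),
    contra = list(
      g_l2r3 = 0.05, th_lift = 45, k_lift = 4, g_pair = 0.03
    ),
    control = list(
      beta_min = 40, eps_tet = 0.02, delta_back = 2, stop_tol = 0.02,
      stop = list(pr_front = 0, pr_other = 0.5, ld = 0.5,
                  ef_frontmid = 0, ef_hind = 0.5)
    ),
    sim = list(dt = 0.1, out_dt = 1)
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter group(s): ", paste(bad, collapse = ", "))
    for (nm in names(dots)) p[[nm]] <- utils::modifyList(p[[nm]], dots[[nm]])
  }
  class(p) <- "sw_params"
  p
}

#' @export
print.sw_params <- function(x, ...) {
  cat("six-leg walking model parameters\n")
  cat(sprintf("  CPG drives (LD): tetrapod (%.3f, %.3f)  tripod (%.3f, %.3f) uS\n",
              x$gapp$tetrapod$ld[1], x$gapp$tetrapod$ld[2],
              x$gapp$tripod$ld[1], x$gapp$tripod$ld[2]))
  cat(sprintf("  gates: beta_crit %.1f deg (+%.1f hyst), gamma_crit %.1f deg\n",
              x$gates$beta_crit, x$gates$beta_hyst, x$gates$gamma_crit))
  cat(sprintf("  interleg: g_inh3 %.3f, g_inh9 %.3f uS\n",
              x$interleg$g_inh3, x$interleg$g_inh9))
  cat(sprintf("  solver: RK4, dt %.2f ms, output every %.1f ms\n",
              x$sim$dt, x$sim$out_dt))
  invisible(x)
}

# flatten the nested parameter list + assembly config into the flat list the
# compiled core expects
sw_flatten_params <- function(p, config) {
  stopifnot(inherits(p, "sw_params"))
  gapp_vec <- function(g) c(g$pr, g$ld, g$ef)
  list(
    C = p$neuron$C, gL = p$neuron$gL, EL = p$neuron$EL, gP = p$neuron$gP,
    EP = p$neuron$EP, EK = p$neuron$EK, Eex = p$neuron$Eex, Einh = p$neuron$Einh,
    thm = p$neuron$thm, km = p$neuron$km, taum = p$neuron$taum,
    thq = p$neuron$thq, kq = p$neuron$kq, ths = p$neuron$ths, ks = p$neuron$ks,
    gq_cpg = unname(p$cpg$gq), tauq_cpg = unname(p$cpg$tauq), gc = p$cpg$gc,
    gMN = p$mn$gMN, gq_fast = p$mn$gq_fast, gq_slow = p$mn$gq_slow,
    tauq_mn = p$mn$tauq, g_pm = p$mn$g_pm,
    c_slow = p$mn$tau_act_slow / p$mn$tau_act_fast,
    g_ci = p$premotor$g_ci, g_rel = p$relay$g_rel,
    beta_crit = p$gates$beta_crit, beta_hyst = p$gates$beta_hyst,
    gamma_crit = p$gates$gamma_crit, gamma_hyst = p$gates$gamma_hyst,
    g_low = unname(p$gates$g_low), g_high = unname(p$gates$g_high),
    w6 = unname(p$gates$w6),
    Gf = p$muscle$Gf, Gs = p$muscle$Gs, Tsc = p$muscle$Tsc,
    kr = p$muscle$kr, bdamp = p$muscle$bdamp,
    bias = unname(p$muscle$bias),
    lo = c(p$muscle$limits$alpha[1], p$muscle$limits$beta[1], p$muscle$limits$gamma[1]),
    hi = c(p$muscle$limits$alpha[2], p$muscle$limits$beta[2], p$muscle$limits$gamma[2]),
    gapp_tet = gapp_vec(p$gapp$tetrapod), gapp_tri = gapp_vec(p$gapp$tripod),
    search_ef = p$gapp$search_ef,
    g_inh3 = if (config$ipsilateral) p$interleg$g_inh3 else 0,
    g_inh9 = if (config$ipsilateral) p$interleg$g_inh9 else 0,
    il_rise = p$interleg$rise, il_fall = p$interleg$fall,
    il_tonic = p$interleg$tonic, beta_lift = p$interleg$beta_lift,
    lev_boost = unname(p$interleg$lev_boost),
    seg_tau = unname(p$interleg$seg_tau),
    g_l2r3 = p$contra$g_l2r3, th_lift = p$contra$th_lift,
    k_lift = p$contra$k_lift, g_pair = p$contra$g_pair,
    c_l2r3 = as.integer(config$contralateral$l2_to_r3),
    c_front = as.integer(config$contralateral$front_pair),
    c_hind = as.integer(config$contralateral$hind_pair),
    c_mutual = as.integer(config$contralateral$pair_mutual_inhibition),
    c_l2r2 = as.integer(config$contralateral$l2_to_r2_inhibition),
    c_l3r3 = as.integer(config$contralateral$l3_to_r3_inhibition),
    beta_min = p$control$beta_min, eps_tet = p$control$eps_tet,
    beta_back = 60 - p$control$delta_back, stop_tol = p$control$stop_tol,
    stop_pr_front = p$control$stop$pr_front, stop_pr_other = p$control$stop$pr_other,
    stop_ld = p$control$stop$ld, stop_ef_frontmid = p$control$stop$ef_frontmid,
    stop_ef_hind = p$control$stop$ef_hind,
    pm_override = p$premotor$pm_override,
    slow_on = as.integer(config$slow_muscles)
  )
}
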