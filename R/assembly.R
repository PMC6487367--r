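LEGS <- c("L1", "L2", "L3", "R1", "R2", "R3")
NETWORKS <- c("PR", "LD", "EF")
JOINTS <- c("alpha", "beta", "gamma")

#' Contralateral connection configuration
#'
#' The six-leg model contains four contralateral connections: an excitatory
#' pathway from the lifted state of L2 to the levator CPG neuron of R3, two
#' bidirectional excitatory pair pathways between the levator-depressor
#' systems of the contralateral front legs (L1, R1) and hind legs (L3, R3),
#' and a mutual inhibition between those two pair pathways. Two further
#' inhibitory variants (L2 to R2, L3 to R3) reproduce connection schemes under
#' which the transition to tripod fails; they are off by default.
#'
#' @param l2_to_r3,front_pair,hind_pair,pair_mutual_inhibition logical;
#'   the default configuration has all four on.
#' @param l2_to_r2_inhibition,l3_to_r3_inhibition logical; experimental
#'   variants, default off.
#' @return A named list of class \code{"sw_contralateral"}.
#' @export
contralateral_config <- function(l2_to_r3 = TRUE, front_pair = TRUE,
                                 hind_pair = TRUE, pair_mutual_inhibition = TRUE,
                                 l2_to_r2_inhibition = FALSE,
                                 l3_to_r3_inhibition = FALSE) {
  structure(list(l2_to_r3 = l2_to_r3, front_pair = front_pair,
                 hind_pair = hind_pair,
                 pair_mutual_inhibition = pair_mutual_inhibition,
                 l2_to_r2_inhibition = l2_to_r2_inhibition,
                 l3_to_r3_inhibition = l3_to_r3_inhibition),
            class = "sw_contralateral")
}

#' Assemble the six-leg model
#'
#' Builds the full model: six legs, each with three local control networks
#' (PR, LD, EF). Every local network contains a CPG half-center (two mutually
#' inhibitory nonspiking neurons), four motoneurons (fast and slow, one pair
#' per antagonistic muscle), four inhibitory premotor interneurons (one per
#' motoneuron) and two sensory relay interneurons carrying the gated position
#' inputs. Each network drives one joint through an antagonistic muscle pair
#' governed by a second-order equation.
#'
#' @param params model parameters from [sw_params()].
#' @param contralateral a [contralateral_config()].
#' @param ipsilateral logical; enable the ipsilateral interleg pathways
#'   (g_inh3, g_inh9).
#' @param slow_motoneurons,slow_muscles logical; enable the slow motoneurons'
#'   muscle drive. Disabling zeroes the slow-muscle torque contribution but
#'   removes no equations. Slow muscles without their motoneurons is a
#'   configuration error.
#' @return An object of class \code{"sw_model"}.
#' @export
#' @examples
#' m <- assemble()
#' model_counts(m)
assemble <- function(params = sw_params(),
                     contralateral = contralateral_config(),
                     ipsilateral = TRUE,
                     slow_motoneurons = TRUE, slow_muscles = TRUE) {
  stopifnot(inherits(params, "sw_params"), inherits(contralateral, "sw_contralateral"))
  if (slow_muscles && !slow_motoneurons)
    stop("configuration error: slow muscles enabled without slow motoneurons")
  m <- list(params = params,
            config = list(contralateral = unclass(contralateral),
                          ipsilateral = ipsilateral,
                          slow_motoneurons = slow_motoneurons,
                          slow_muscles = slow_muscles),
            neurons = sw_neuron_table(),
            synapses = sw_synapse_table(contralateral, ipsilateral))
  class(m) <- "sw_model"
  m
}

# enumerate all 216 neurons with their roles; the structural counts are
# derived from this table, never hard-coded
sw_neuron_table <- function() {
  roles <- c("cpg_a", "cpg_b", "mn_fast_a", "mn_fast_b", "mn_slow_a",
             "mn_slow_b", "in_pm_fa", "in_pm_fb", "in_pm_sa", "in_pm_sb",
             "in_relay5", "in_relay6")
  df <- expand.grid(role = roles, network = NETWORKS, leg = LEGS,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("leg", "network", "role")]
  df$id <- seq_len(nrow(df)) - 1L
  df$class <- ifelse(grepl("^cpg", df$role), "cpg",
               ifelse(grepl("^mn", df$role), "motoneuron", "interneuron"))
  df$states <- 3L
  df
}

# synapse classes present in the wiring, with signs and counts
sw_synapse_table <- function(contra, ipsilateral) {
  rows <- list(
    list(class = "cpg_mutual_inhibition", sign = "inhibitory", n = 18L * 2L),
    list(class = "cpg_to_premotor", sign = "excitatory", n = 72L),
    list(class = "premotor_to_mn", sign = "inhibitory", n = 72L),
    list(class = "relay_to_cpg_excitatory", sign = "excitatory", n = 18L),
    list(class = "relay_to_cpg_inhibitory", sign = "inhibitory", n = 18L),
    list(class = "mn_central_drive", sign = "excitatory", n = 72L)
  )
  if (ipsilateral)
    rows <- c(rows, list(list(class = "interleg_g_inh3", sign = "inhibitory", n = 2L),
                         list(class = "interleg_g_inh9", sign = "inhibitory", n = 2L)))
  if (contra$l2_to_r3)
    rows <- c(rows, list(list(class = "contralateral_l2_r3", sign = "excitatory", n = 1L)))
  if (contra$front_pair)
    rows <- c(rows, list(list(class = "pair_pathway_front", sign = "excitatory", n = 1L)))
  if (contra$hind_pair)
    rows <- c(rows, list(list(class = "pair_pathway_hind", sign = "excitatory", n = 1L)))
  if (contra$pair_mutual_inhibition)
    rows <- c(rows, list(list(class = "pair_pathway_arbiter", sign = "inhibitory", n = 1L)))
  if (contra$l2_to_r2_inhibition)
    rows <- c(rows, list(list(class = "contralateral_l2_r2", sign = "inhibitory", n = 1L)))
  if (contra$l3_to_r3_inhibition)
    rows <- c(rows, list(list(class = "contralateral_l3_r3", sign = "inhibitory", n = 1L)))
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Structural counts of an assembled model
#'
#' @param model an [assemble()]d model.
#' @return A list with total and per-unit counts: CPGs, motoneurons,
#'   interneurons, first-order neuronal ODEs, second-order muscle ODEs,
#'   neuromuscular units per side and the per-leg tally.
#' @export
model_counts <- function(model) {
  stopifnot(inherits(model, "sw_model"))
  nt <- model$neurons
  n_cpg_neurons <- sum(nt$class == "cpg")
  one_leg <- nt[nt$leg == "L1", ]
  list(
    cpgs = n_cpg_neurons / 2L,
    motoneurons = sum(nt$class == "motoneuron"),
    interneurons = sum(nt$class == "interneuron"),
    neurons = nrow(nt),
    neuronal_odes = sum(nt$states),
    muscle_odes = length(LEGS) * length(JOINTS),
    units_per_side = sum(nt$leg %in% c("L1", "L2", "L3") & nt$class == "cpg") / 2L,
    per_leg = list(
      cpgs = sum(one_leg$class == "cpg") / 2L,
      motoneurons = sum(one_leg$class == "motoneuron"),
      interneurons = sum(one_leg$class == "interneuron")
    )
  )
}

#' Export an assembly summary as JSON
#'
#' Writes unit counts and the synapse-class list for structural inspection.
#'
#' @param model an [assemble()]d model.
#' @param path output file; if `NULL`, the JSON string is returned.
#' @export
export_assembly <- function(model, path = NULL) {
  stopifnot(inherits(model, "sw_model"))
  x <- list(counts = model_counts(model), synapse_classes = model$synapses,
            config = model$config)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @export
print.sw_model <- function(x, ...) {
  ct <- model_counts(x)
  cat("six-leg stick-insect walking model\n")
  cat(sprintf("  %d CPGs, %d motoneurons, %d interneurons (%d neuronal ODEs)\n",
              ct$cpgs, ct$motoneurons, ct$interneurons, ct$neuronal_odes))
  cat(sprintf("  %d antagonistic muscle pairs (second-order joint ODEs)\n",
              ct$muscle_odes))
  on <- names(Filter(isTRUE, x$config$contralateral))
  cat("  contralateral connections:",
      if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  cat(sprintf("  ipsilateral pathways: %s, slow muscles: %s\n",
              x$config$ipsilateral, x$config$slow_muscles))
  invisible(x)
}

#' Ipsilateral coordination signal
#'
#' Computes the inhibitory conductance exerted on the anterior leg's levator
#' CPG neuron by a posterior leg, as a function of that leg's levation angle
#' and its angular velocity (quadrant rule): full conductance while the leg is
#' lifted and rising, a reduced fraction while lifted and descending, and a
#' low tonic level while grounded.
#'
#' @param posterior a data frame with columns `beta` (degrees) and `dbeta`
#'   (deg/ms) on a common time grid.
#' @param params model parameters.
#' @param target `"prothoracic"` (conductance scale g_inh3) or
#'   `"mesothoracic"` (g_inh9).
#' @return Numeric vector of conductances (uS), one per input row.
#' @export
ipsilateral_drive <- function(posterior, params = sw_params(),
                              target = c("prothoracic", "mesothoracic")) {
  target <- match.arg(target)
  stopifnot(is.data.frame(posterior), all(c("beta", "dbeta") %in% names(posterior)))
  il <- params$interleg
  gmax <- if (target == "prothoracic") il$g_inh3 else il$g_inh9
  lifted <- posterior$beta >= il$beta_lift
  lev <- ifelse(lifted, ifelse(posterior$dbeta > 0, il$rise, il$fall), il$tonic)
  gmax * lev
}

#' Contralateral synaptic drive
#'
#' Evaluates the contralateral connections for a set of leg states. The
#' L2-to-R3 excitation follows the lifted state of L2; the bidirectional pair
#' pathways (L1/R1, L3/R3) contribute only while a transition to tripod is
#' being initiated, and the activation of one pair pathway suppresses the
#' other (mutual inhibition).
#'
#' @param legs data frame with rownames (or column `leg`) L1..R3 and columns
#'   `beta`, `dbeta`.
#' @param phase `"normal"` or `"tripod_transition"`.
#' @param active_segment during a transition, the segment (`"front"` or
#'   `"hind"`) whose pair pathway is engaged.
#' @param params model parameters.
#' @param config a [contralateral_config()].
#' @return Data frame of target legs and excitatory conductances (uS); zero
#'   rows when nothing is transmitted.
#' @export
contralateral_drive <- function(legs, phase = c("normal", "tripod_transition"),
                                active_segment = c("hind", "front"),
                                params = sw_params(),
                                config = contralateral_config()) {
  phase <- match.arg(phase)
  active_segment <- match.arg(active_segment)
  if (!is.null(legs$leg)) rownames(legs) <- legs$leg
  stopifnot(all(LEGS %in% rownames(legs)))
  lift <- function(beta) {
    1 / (1 + exp(-(beta - params$contra$th_lift) / params$contra$k_lift))
  }
  out <- list()
  if (config$l2_to_r3) {
    g <- params$contra$g_l2r3 * lift(legs["L2", "beta"])
    out[[length(out) + 1]] <- data.frame(target = "R3", source = "L2",
                                         pathway = "l2_to_r3", g = g)
  }
  if (phase == "tripod_transition") {
    seg <- if (active_segment == "front") c("L1", "R1") else c("L3", "R3")
    enabled <- if (active_segment == "front") config$front_pair else config$hind_pair
    if (enabled) {
      for (i in 1:2) {
        src <- seg[i]; tgt <- seg[3 - i]
        out[[length(out) + 1]] <- data.frame(
          target = tgt, source = src,
          pathway = paste0("pair_", active_segment),
          g = params$contra$g_pair * lift(legs[src, "beta"]))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(target = character(), source = character(),
               pathway = character(), g = numeric())
  # during plain walking the pair pathways transmit nothing
  res[res$g > 1e-12 | res$pathway == "l2_to_r3", , drop = FALSE]
}
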