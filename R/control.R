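#' Behavioural mode commands
#'
#' Constructs a timed mode request for the behaviour controller. Commands are
#' requests: each is held pending until its acceptance constraint is met by
#' the ongoing simulation (see Details), then applied instantaneously.
#'
#' \describe{
#'   \item{set_gait tripod}{accepted per side when a front or hind leg (never
#'     the middle leg) is lifted above `beta_min` and still rising; with the
#'     contralateral pair pathways enabled, once one side has initiated at a
#'     segment, the other side may only initiate at the same segment.}
#'   \item{set_gait tetrapod}{accepted per side, independently, when the
#'     middle and hind legs' levation velocity falls below `eps_tet`.}
#'   \item{stop}{accepted when all three right legs have nonnegative levation
#'     velocity; then the still-stand gate settings are applied statically.}
#'   \item{restart}{no constraint; a restart while walking is a no-op.}
#'   \item{search}{no constraint; only the front legs L1 and R1 can search.}
#'   \item{direction backward}{accepted when L2 or R2 is lifted near its
#'     maximal vertical position (beta >= 60 - delta_back); rejected during
#'     still stand. direction forward has no constraint.}
#' }
#'
#' @param kind one of `"set_gait"`, `"stop"`, `"restart"`, `"search"`,
#'   `"direction"`.
#' @param time requested time (ms).
#' @param gait for `set_gait`: `"tripod"` or `"tetrapod"`.
#' @param leg for `search`: `"L1"` or `"R1"`.
#' @param on for `search`: logical.
#' @param tibia_drive for `search`: scale factor applied to the search EF
#'   drive-conductance pair.
#' @param target for `direction`: `"backward"` or `"forward"`.
#' @return A list of class `"sw_command"`.
#' @export
#' @examples
#' sched <- list(
#'   mode_command("set_gait", 3000, gait = "tripod"),
#'   mode_command("stop", 8000),
#'   mode_command("restart", 10000)
#' )
#' validate_schedule(sched)$valid
mode_command <- function(kind = c("set_gait", "stop", "restart", "search",
                                  "direction"),
                         time, gait = NULL, leg = NULL, on = TRUE,
                         tibia_drive = 1, target = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(time), length(time) == 1, time >= 0)
  cmd <- list(kind = kind, time = time)
  if (kind == "set_gait") {
    cmd$gait <- match.arg(gait, c("tripod", "tetrapod"))
  } else if (kind == "search") {
    if (!leg %in% c("L1", "R1"))
      stop("search movements are available for the front legs L1 and R1 only")
    cmd$leg <- leg; cmd$on <- isTRUE(on); cmd$tibia_drive <- tibia_drive
  } else if (kind == "direction") {
    cmd$target <- match.arg(target, c("backward", "forward"))
  }
  class(cmd) <- "sw_command"
  cmd
}

# schedule list -> numeric matrix (time, kind, a, b, c) for the compiled core
sw_schedule_matrix <- function(schedule) {
  if (is.null(schedule) || length(schedule) == 0)
    return(matrix(numeric(0), 0, 5))
  rows <- lapply(schedule, function(cmd) {
    stopifnot(inherits(cmd, "sw_command"))
    switch(cmd$kind,
      set_gait = c(cmd$time, 1, if (cmd$gait == "tripod") 1 else 0, 0, 0),
      stop = c(cmd$time, 2, 0, 0, 0),
      restart = c(cmd$time, 3, 0, 0, 0),
      search = c(cmd$time, 4, if (cmd$leg == "L1") 0 else 3,
                 as.integer(cmd$on), cmd$tibia_drive),
      direction = c(cmd$time, 5, if (cmd$target == "backward") 1 else 0, 0, 0))
  })
  m <- do.call(rbind, rows)
  m[order(m[, 1]), , drop = FALSE]
}

#' Validate a behavioural schedule
#'
#' Checks a time-sorted command list for incompatible overlaps. Backward
#' walking and still stand cannot overlap (during still stand all legs are
#' grounded, so the backward-start constraint can never be met); search
#' movements are compatible with every other mode and any ordering.
#'
#' Mode intervals are derived from the command times: a still-stand interval
#' runs from a stop command to the next restart; a backward interval from a
#' backward command to the next forward command (open-ended otherwise).
#'
#' @param schedule list of [mode_command()]s.
#' @return A list: `valid` (logical), `conflicts` (data frame with the
#'   indices of both conflicting commands and a reason), and the `schedule`
#'   sorted by time.
#' @export
validate_schedule <- function(schedule) {
  if (is.null(schedule)) schedule <- list()
  stopifnot(all(vapply(schedule, inherits, TRUE, "sw_command")))
  times <- vapply(schedule, `[[`, numeric(1), "time")
  ord <- order(times)
  schedule <- schedule[ord]
  times <- times[ord]
  kinds <- vapply(schedule, `[[`, character(1), "kind")

  interval_of <- function(open_kind, close_kind, open_sel = TRUE) {
    # returns matrix (start_idx, end_time) for each opening command
    res <- NULL
    for (i in seq_along(schedule)) {
      opens <- kinds[i] == open_kind &&
        (open_kind != "direction" || schedule[[i]]$target == "backward")
      if (!opens || !open_sel) next
      end <- Inf
      for (j in seq_along(schedule)) {
        closes <- kinds[j] == close_kind &&
          (close_kind != "direction" || schedule[[j]]$target == "forward")
        if (closes && times[j] > times[i]) { end <- times[j]; break }
      }
      res <- rbind(res, c(i, times[i], end))
    }
    res
  }
  stills <- interval_of("stop", "restart")
  backs <- interval_of("direction", "direction")

  conflicts <- NULL
  if (!is.null(stills) && !is.null(backs)) {
    for (si in seq_len(nrow(stills))) for (bi in seq_len(nrow(backs))) {
      s <- stills[si, ]; b <- backs[bi, ]
      if (b[2] < s[3] && s[2] < b[3]) {
        conflicts <- rbind(conflicts, data.frame(
          i = s[1], j = b[1],
          reason = "backward walking and still stand cannot overlap"))
      }
    }
  }
  list(valid = is.null(conflicts),
       conflicts = if (is.null(conflicts))
         data.frame(i = integer(), j = integer(), reason = character())
       else conflicts,
       schedule = schedule)
}

#' Still-stand pose targets
#'
#' The static gate settings applied when a stop is accepted, and the joint
#' pose they produce: front legs protracted (alpha to 28 degrees), middle and
#' hind legs retracted (alpha to 128), all legs grounded (beta in [30, 32))
#' and stretched (gamma extended). Protraction of the front legs is obtained
#' by reducing g_beta(PR) to zero, which inactivates the retractor CPG neuron
#' and disinhibits the protractor one; retraction by a large static
#' g_beta(PR); ground contact by a large static g_gamma(LD); extension by a
#' very low g_beta(EF) in the front and middle legs and, because of the
#' hind-leg cross connection between CPG and premotor network, by a
#' sufficiently large g_beta(EF) in the hind legs.
#'
#' @param params model parameters.
#' @return A data frame, one row per leg, with the static gate conductances
#'   and the target angles.
#' @export
stop_pose_targets <- function(params = sw_params()) {
  st <- params$control$stop
  seg <- rep(c("front", "middle", "hind"), 2)
  data.frame(
    leg = LEGS, segment = seg,
    g_beta_pr = ifelse(seg == "front", st$pr_front, st$pr_other),
    g_gamma_ld = st$ld,
    g_beta_ef = ifelse(seg == "hind", st$ef_hind, st$ef_frontmid),
    alpha_target = ifelse(seg == "front", 28, 128),
    beta_target = 31, # centre of the ground-contact band [30, 32)
    gamma_target = 45
  )
}

# ---- controller predicates (the same rules the simulation loop applies) ----

#' Leg-state table for the controller predicates
#'
#' @param beta,dbeta numeric length 6 (L1, L2, L3, R1, R2, R3): levation
#'   angles (degrees) and velocities (deg/ms).
#' @return Data frame with columns `leg`, `segment`, `side`, `beta`, `dbeta`.
#' @export
sw_leg_states <- function(beta, dbeta) {
  stopifnot(length(beta) == 6, length(dbeta) == 6)
  data.frame(leg = LEGS, segment = rep(c("front", "middle", "hind"), 2),
             side = rep(c("left", "right"), each = 3),
             beta = beta, dbeta = dbeta)
}

#' Tripod-transition initiation rule
#'
#' Returns the leg at which the transition to tripod may start on the given
#' side, or `NULL`. Only a front or hind leg qualifies -- never the middle
#' leg -- and it must be lifted above `beta_min` and moving upward. When the
#' other side has already initiated at some segment, the pair pathways
#' restrict initiation to the same segment.
#'
#' @param legs data frame from [sw_leg_states()] or with columns `leg`,
#'   `segment`, `side`, `beta`, `dbeta`.
#' @param side `"left"` or `"right"`.
#' @param initiated_segment segment at which the contralateral side already
#'   initiated (`"front"`, `"hind"`), or `NULL`.
#' @param params model parameters.
#' @return The initiating leg name, or `NULL` if no leg qualifies.
#' @export
try_start_tripod_transition <- function(legs, side = c("left", "right"),
                                        initiated_segment = NULL,
                                        params = sw_params()) {
  side <- match.arg(side)
  cand <- legs[legs$side == side & legs$segment %in% c("front", "hind"), ]
  if (!is.null(initiated_segment))
    cand <- cand[cand$segment == initiated_segment, ]
  ok <- cand$beta > params$control$beta_min & cand$dbeta > 0
  if (!any(ok)) return(NULL)
  cand$leg[which(ok)[1]]
}

#' Tetrapod-transition initiation rule
#'
#' A side switches to the tetrapod drive table when both its middle and hind
#' legs move slowly or approach the ground: levation velocity below the small
#' positive bound `eps_tet` (negative velocities qualify). Each side
#' transitions independently; no contralateral signal is involved.
#'
#' @inheritParams try_start_tripod_transition
#' @return `TRUE` (initiated) or `FALSE` (not yet).
#' @export
try_start_tetrapod_transition <- function(legs, side = c("left", "right"),
                                          params = sw_params()) {
  side <- match.arg(side)
  mh <- legs[legs$side == side & legs$segment %in% c("middle", "hind"), ]
  all(mh$dbeta < params$control$eps_tet)
}

#' Stop acceptance rule
#'
#' Still stand can begin only when all right legs have a positive (lifting)
#' or zero (on the ground) levation velocity. In tetrapod, a contralateral
#' pair of legs is always lifted simultaneously, so the state of the right
#' legs reflects that of their left partners and the constraint effectively
#' applies to both sides.
#'
#' @inheritParams try_start_tripod_transition
#' @return `"accepted"` or `"deferred"`.
#' @export
request_stop <- function(legs) {
  right <- legs[legs$side == "right", ]
  if (all(right$dbeta >= 0)) "accepted" else "deferred"
}

#' Backward-transition acceptance rule
#'
#' The transition to backward walking may commence only when one of the
#' middle legs is lifted near to its maximal vertical position (about 60
#' degrees); during still stand the request is rejected outright, since all
#' legs are grounded and backward walking and still stand cannot overlap. The
#' return to forward walking has no constraint.
#'
#' @inheritParams try_start_tripod_transition
#' @param target `"backward"` or `"forward"`.
#' @param still logical; is the model in still stand?
#' @return `"accepted"`, `"deferred"` or `"rejected"`.
#' @export
set_direction_rule <- function(legs, target = c("backward", "forward"),
                               still = FALSE, params = sw_params()) {
  target <- match.arg(target)
  if (target == "forward") return("accepted")
  if (still) return("rejected")
  mid <- legs[legs$segment == "middle", ]
  if (any(mid$beta >= 60 - params$control$delta_back)) "accepted" else "deferred"
}
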