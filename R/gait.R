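# gait-diagram toolkit: swing extraction, coordination-pattern
# classification, irregularity detection and transition-start scans

GAIT_LABELS <- c("tripod", "tetrapod_B", "tetrapod_C", "bilateral_sync",
                 "new_pattern", "unclassified")

# defining leg pairs per coordination pattern
sw_defining_pairs <- function(label) {
  switch(label,
    tripod = list(c("L1", "L3"), c("L1", "R2"), c("L3", "R2"),
                  c("L2", "R1"), c("L2", "R3"), c("R1", "R3")),
    tetrapod_B = list(c("L1", "R2"), c("L2", "R3"), c("L3", "R1")),
    tetrapod_C = list(c("R1", "L2"), c("R2", "L3"), c("R3", "L1")),
    bilateral_sync = list(c("L1", "R1"), c("L2", "R2"), c("L3", "R3")),
    new_pattern = list(c("L1", "R3"), c("L3", "R1")),
    stop("unknown pattern: ", label))
}

#' Extract swing intervals from a levation-angle trace
#'
#' A leg is in swing while its levation angle beta is above the contact band.
#' Liftoff is the upward crossing of `threshold + hysteresis`, touchdown the
#' downward crossing of `threshold`; crossing times are linearly
#' interpolated. Intervals shorter than `min_duration` (contact-band ripple)
#' are discarded. A swing still open at the end of the trace gets
#' `touchdown = NA`.
#'
#' @param beta numeric vector of beta angles (degrees), uniformly sampled.
#' @param times sample times (ms); defaults to `0, 1, 2, ...`.
#' @param threshold swing threshold (degrees).
#' @param hysteresis extra margin on the liftoff crossing (degrees).
#' @param min_duration minimal swing duration kept (ms).
#' @return A data frame of class `"sw_step_intervals"` with columns
#'   `liftoff`, `touchdown` (half-open intervals, ms) and `duration`.
#' @export
extract_swings <- function(beta, times = NULL, threshold = 32,
                           hysteresis = 0, min_duration = 20) {
  if (length(beta) == 0) stop("argument error: empty trace")
  if (is.null(times)) times <- seq_along(beta) - 1
  stopifnot(length(times) == length(beta))
  up_thr <- threshold + hysteresis
  lift <- numeric(); down <- numeric()
  state <- beta[1] > up_thr
  t_on <- if (state) times[1] else NA_real_
  out <- NULL
  for (i in seq_along(beta)[-1]) {
    if (!state && beta[i - 1] <= up_thr && beta[i] > up_thr) {
      state <- TRUE
      t_on <- times[i - 1] + (times[i] - times[i - 1]) *
        (up_thr - beta[i - 1]) / (beta[i] - beta[i - 1])
    } else if (state && beta[i - 1] >= threshold && beta[i] < threshold) {
      state <- FALSE
      t_off <- times[i - 1] + (times[i] - times[i - 1]) *
        (beta[i - 1] - threshold) / (beta[i - 1] - beta[i])
      out <- rbind(out, c(t_on, t_off))
    }
  }
  if (state) out <- rbind(out, c(t_on, NA_real_))
  if (is.null(out)) out <- matrix(numeric(0), 0, 2)
  df <- data.frame(liftoff = out[, 1], touchdown = out[, 2])
  df$duration <- df$touchdown - df$liftoff
  keep <- is.na(df$duration) | df$duration >= min_duration
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sw_step_intervals", "data.frame")
  df
}

#' Swing intervals for all six legs
#'
#' @param rec an `sw_trajectory`, or a matrix of six beta traces with columns
#'   L1..R3.
#' @param times sample times when `rec` is a matrix.
#' @inheritParams extract_swings
#' @return Named list of six [extract_swings()] results.
#' @export
step_intervals <- function(rec, times = NULL, threshold = 32,
                           hysteresis = 0, min_duration = 20) {
  if (inherits(rec, "sw_trajectory")) {
    b <- beta_traces(rec); times <- rec$times
  } else b <- rec
  stopifnot(!is.null(colnames(b)), all(LEGS %in% colnames(b)))
  out <- lapply(LEGS, function(l)
    extract_swings(b[, l], times, threshold, hysteresis, min_duration))
  names(out) <- LEGS
  out
}

# clip a swing table to a window, closing open intervals at the window end
sw_clip <- function(sw, window) {
  td <- ifelse(is.na(sw$touchdown), window[2], sw$touchdown)
  lo <- pmax(sw$liftoff, window[1]); hi <- pmin(td, window[2])
  keep <- hi > lo
  cbind(lo[keep], hi[keep])
}

# intersection-over-minimum swing overlap of two legs within a window
sw_pair_overlap <- function(a, b, window) {
  ia <- sw_clip(a, window); ib <- sw_clip(b, window)
  ta <- sum(ia[, 2] - ia[, 1]); tb <- sum(ib[, 2] - ib[, 1])
  if (ta <= 0 || tb <= 0) return(0)
  inter <- 0
  for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
    inter <- inter + max(0, min(ia[i, 2], ib[j, 2]) - max(ia[i, 1], ib[j, 1]))
  }
  inter / min(ta, tb)
}

#' Pairwise swing-overlap matrix
#'
#' @param intervals a named list of six swing tables (see [step_intervals()]).
#' @param window analysis window `c(t0, t1)` in ms.
#' @return Symmetric 6 x 6 matrix of overlap fractions in [0, 1].
#' @export
swing_overlap_matrix <- function(intervals, window) {
  m <- matrix(0, 6, 6, dimnames = list(LEGS, LEGS))
  for (i in 1:5) for (j in (i + 1):6) {
    v <- sw_pair_overlap(intervals[[LEGS[i]]], intervals[[LEGS[j]]], window)
    m[i, j] <- v; m[j, i] <- v
  }
  diag(m) <- 1
  m
}

#' Classify the interleg coordination pattern
#'
#' Assigns one of the coordination-pattern labels -- tripod, B-type or C-type
#' tetrapod, bilaterally synchronous stepping, or the "new" pattern in which
#' L1-R3 and L3-R1 swing together while the middle legs lift alone -- from
#' the pairwise swing-overlap matrix. A label is assigned when its defining
#' pairs overlap by at least `min_defining` on average while all other pairs
#' stay at or below `max_cross` on average; ties go to the highest mean
#' defining-pair overlap. Windows with fewer than two full cycles are
#' `unclassified`.
#'
#' @param intervals named list of six swing tables, or an `sw_trajectory`.
#' @param window analysis window `c(t0, t1)` (ms).
#' @param min_defining,max_cross classification thresholds.
#' @return A list of class `"sw_gait_label"`: `label`, `overlap` (6 x 6
#'   matrix), `window`, `defining_overlap`, `reason`.
#' @export
classify_gait <- function(intervals, window, min_defining = 0.5,
                          max_cross = 0.25) {
  if (inherits(intervals, "sw_trajectory")) intervals <- step_intervals(intervals)
  stopifnot(length(window) == 2, window[2] > window[1])
  n_cycles <- vapply(intervals, function(sw) {
    nrow(sw_clip(sw, window))
  }, numeric(1))
  m <- swing_overlap_matrix(intervals, window)
  res <- list(label = "unclassified", overlap = m, window = window,
              defining_overlap = NA_real_, reason = NULL)
  class(res) <- "sw_gait_label"
  if (any(n_cycles < 2)) {
    res$reason <- "window too short: fewer than 2 swing cycles for some leg"
    return(res)
  }
  cand <- setdiff(GAIT_LABELS, "unclassified")
  score <- rep(NA_real_, length(cand)); names(score) <- cand
  for (lab in cand) {
    pairs <- sw_defining_pairs(lab)
    defv <- vapply(pairs, function(p) m[p[1], p[2]], numeric(1))
    inpair <- matrix(FALSE, 6, 6, dimnames = dimnames(m))
    for (p in pairs) { inpair[p[1], p[2]] <- TRUE; inpair[p[2], p[1]] <- TRUE }
    crossv <- m[upper.tri(m) & !inpair]
    if (mean(defv) >= min_defining && mean(crossv) <= max_cross)
      score[lab] <- mean(defv)
  }
  if (all(is.na(score))) {
    res$reason <- "no pattern's defining pairs dominate"
    return(res)
  }
  res$label <- names(which.max(score))
  res$defining_overlap <- max(score, na.rm = TRUE)
  res
}

#' @export
print.sw_gait_label <- function(x, ...) {
  cat(sprintf("gait: %s (window [%.0f, %.0f] ms", x$label,
              x$window[1], x$window[2]))
  if (is.finite(x$defining_overlap))
    cat(sprintf(", defining-pair overlap %.2f", x$defining_overlap))
  cat(")\n")
  if (!is.null(x$reason)) cat("  ", x$reason, "\n")
  invisible(x)
}

#' Detect prolonged lifted states
#'
#' Flags swing intervals lasting 1000 ms or longer; a swing still open at the
#' analysis horizon counts as permanently lifted.
#'
#' @param intervals named list of swing tables, or a single table.
#' @param horizon end of the analysed interval (ms).
#' @param threshold minimal flagged duration (ms).
#' @return Data frame: `leg`, `liftoff`, `touchdown`, `duration`,
#'   `permanent`. Zero rows when stepping is regular.
#' @export
detect_prolonged_lift <- function(intervals, horizon, threshold = 1000) {
  if (inherits(intervals, "sw_step_intervals")) intervals <- list(leg = intervals)
  out <- NULL
  for (nm in names(intervals)) {
    sw <- intervals[[nm]]
    if (!nrow(sw)) next
    open <- is.na(sw$touchdown)
    dur <- ifelse(open, horizon - sw$liftoff, sw$duration)
    hit <- dur >= threshold
    if (any(hit))
      out <- rbind(out, data.frame(leg = nm, liftoff = sw$liftoff[hit],
                                   touchdown = sw$touchdown[hit],
                                   duration = dur[hit],
                                   permanent = open[hit] & dur[hit] >= threshold))
  }
  if (is.null(out))
    out <- data.frame(leg = character(), liftoff = numeric(),
                      touchdown = numeric(), duration = numeric(),
                      permanent = logical())
  rownames(out) <- NULL
  out
}

#' Synthetic levation-angle traces
#'
#' Generates six idealized beta traces realizing a requested coordination
#' pattern: square swings of the given period and duty cycle at the
#' pattern's defining phase offsets, on a 31-degree contact baseline with
#' 55-degree swing plateaus. With zero jitter, extraction followed by
#' classification returns the requested pattern (closure property). Jitter
#' perturbs every liftoff and touchdown independently (uniform on
#' +/- jitter).
#'
#' @param pattern one of `"tripod"`, `"tetrapod_B"`, `"tetrapod_C"`,
#'   `"bilateral_sync"`, `"new_pattern"`.
#' @param period step period (ms).
#' @param duty swing fraction of the period, in (0, 1).
#' @param jitter timing jitter amplitude (ms).
#' @param seed RNG seed for the jitter.
#' @param n_cycles number of step cycles generated.
#' @param dt sample spacing (ms).
#' @return A list: `times`, `beta` (matrix, columns L1..R3), `true_intervals`
#'   (the generated liftoff/touchdown times), `pattern`.
#' @export
#' @examples
#' tr <- synth_traces("tetrapod_B", period = 1800, duty = 0.25, seed = 1)
#' classify_gait(step_intervals(tr$beta, tr$times),
#'               window = range(tr$times))$label
synth_traces <- function(pattern, period = 1500, duty = 0.3, jitter = 0,
                         seed = 1, n_cycles = 6, dt = 5) {
  phases <- switch(pattern,
    tripod = c(L1 = 0, L2 = 0.5, L3 = 0, R1 = 0.5, R2 = 0, R3 = 0.5),
    tetrapod_B = c(L1 = 2/3, L2 = 1/3, L3 = 0, R1 = 0, R2 = 2/3, R3 = 1/3),
    tetrapod_C = c(L1 = 0, L2 = 2/3, L3 = 1/3, R1 = 2/3, R2 = 1/3, R3 = 0),
    bilateral_sync = c(L1 = 2/3, L2 = 1/3, L3 = 0, R1 = 2/3, R2 = 1/3, R3 = 0),
    new_pattern = c(L1 = 0, L2 = 0.25, L3 = 0.5, R1 = 0.5, R2 = 0.75, R3 = 0),
    stop("argument error: unknown pattern '", pattern, "'"))
  stopifnot(duty > 0, duty < 1, period > 0)
  set.seed(seed)
  t_end <- n_cycles * period
  times <- seq(0, t_end, by = dt)
  beta <- matrix(31, length(times), 6, dimnames = list(NULL, LEGS))
  truth <- list()
  for (l in LEGS) {
    on <- phases[l] * period + (0:(n_cycles - 1)) * period
    off <- on + duty * period
    if (jitter > 0) {
      on <- on + stats::runif(length(on), -jitter, jitter)
      off <- off + stats::runif(length(off), -jitter, jitter)
    }
    keep <- off > on
    on <- on[keep]; off <- off[keep]
    for (i in seq_along(on))
      beta[times >= on[i] & times < off[i], l] <- 55
    truth[[l]] <- data.frame(liftoff = on, touchdown = off)
  }
  list(times = times, beta = beta, true_intervals = truth, pattern = pattern)
}

#' Mirror a set of traces left-right
#'
#' Swaps the left and right legs of a six-leg beta matrix. Mirroring maps
#' B-type tetrapod onto C-type (and back) and fixes tripod, bilateral
#' synchrony and the new pattern.
#'
#' @param beta matrix with columns L1..R3.
#' @export
mirror_traces <- function(beta) {
  stopifnot(all(LEGS %in% colnames(beta)))
  out <- beta[, c("R1", "R2", "R3", "L1", "L2", "L3"), drop = FALSE]
  colnames(out) <- LEGS
  out
}

#' Recurrence period of a regular/irregular scan map
#'
#' Estimates the dominant recurrence period of a boolean sequence sampled at
#' fixed spacing from the mean distance between rising edges.
#'
#' @param flags logical vector.
#' @param spacing sample spacing (ms).
#' @return Period (ms), or `NA` with fewer than two rising edges.
#' @export
recurrence_period <- function(flags, spacing) {
  edges <- which(diff(c(FALSE, flags)) == 1)
  if (length(edges) < 2) return(NA_real_)
  mean(diff(edges)) * spacing
}

#' Scan transition start times (tripod to tetrapod)
#'
#' Re-runs the model once per start time: the model walks in steady tripod,
#' the transition to tetrapod is requested at the scanned time, and the front
#' legs' behaviour after the transition is classified as regular or irregular
#' (irregular = a prolonged lifted state of 1000 ms or more, or a permanently
#' lifted leg, detected by [detect_prolonged_lift()]).
#'
#' @param model an [assemble()]d model.
#' @param window scan window `c(t0, t1)` (ms).
#' @param step start-time increment (ms).
#' @param which transition scanned; only `"tripod_to_tetrapod"` is defined.
#' @param post length of the analysed post-transition interval (ms).
#' @param settle time of the tripod command in the common lead-in run (ms).
#' @return A list: `map` (data frame `start`, `L1_regular`, `R1_regular`),
#'   `n_regular`, `n_irregular`, `regular_fraction` (both legs pooled), and
#'   the recurrence periods of the per-leg regular patterns.
#' @export
scan_transition_starts <- function(model, window = c(3000, 5000), step = 50,
                                   which = "tripod_to_tetrapod",
                                   post = 4000, settle = 500) {
  which <- match.arg(which, "tripod_to_tetrapod")
  if (step <= 0) stop("argument error: step must be positive")
  starts <- seq(window[1], window[2], by = step)
  lead <- run_model(model, list(mode_command("set_gait", settle, gait = "tripod")),
                    config = sim_config(t_end = starts[1]))
  state <- lead$final
  t_cur <- starts[1]
  L1r <- logical(length(starts)); R1r <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    if (s > t_cur) {
      lead <- run_model(model, NULL,
                        config = sim_config(t_end = s - t_cur, t0 = t_cur),
                        state = state)
      state <- lead$final
      t_cur <- s
    }
    br <- run_model(model, list(mode_command("set_gait", s, gait = "tetrapod")),
                    config = sim_config(t_end = post, t0 = s), state = state)
    iv <- step_intervals(br)
    horizon <- s + post
    for (leg in c("L1", "R1")) {
      bad <- detect_prolonged_lift(iv[leg], horizon)
      if (leg == "L1") L1r[i] <- nrow(bad) == 0 else R1r[i] <- nrow(bad) == 0
    }
  }
  map <- data.frame(start = starts, L1_regular = L1r, R1_regular = R1r)
  n_reg <- sum(L1r) + sum(R1r)
  n_irr <- 2 * length(starts) - n_reg
  list(map = map, n_regular = n_reg, n_irregular = n_irr,
       regular_fraction = n_reg / (2 * length(starts)),
       recurrence = c(L1 = recurrence_period(L1r, step),
                      R1 = recurrence_period(R1r, step)))
}

# shared lead-in: steady B-type tetrapod walking reached through the
# bilateral-sync -> tripod -> tetrapod transition sequence
sw_tetrapod_leadin <- function(model, until) {
  sched <- list(mode_command("set_gait", 3000, gait = "tripod"),
                mode_command("set_gait", 7500, gait = "tetrapod"))
  run_model(model, sched, config = sim_config(t_end = until))
}

#' Scan backward-walking transition starts
#'
#' From steady tetrapod forward walking, a backward-walking request is issued
#' at each scanned start time and held to the acceptance constraint (L2 or R2
#' lifted near its maximal vertical position) unless `constraint = FALSE`. A
#' trial fails when any leg stops proper backward stepping during the
#' backward interval: a prolonged (>= 1000 ms) or permanent lift, or a
#' stance gap longer than `max_gap` without a swing.
#'
#' @param model an [assemble()]d model.
#' @param window scan window for the request times (ms); the default spans
#'   more than one tetrapod step cycle after a common walking lead-in.
#' @param step start-time increment (ms).
#' @param constraint logical; apply the middle-leg lift constraint.
#' @param backward_dur length of the backward interval (ms).
#' @param max_gap largest tolerated interval without a swing (ms).
#' @return A list: `map` (data frame `start`, `accepted_at`, `failed`),
#'   `failed_fraction`.
#' @export
scan_backward_transitions <- function(model, window = c(10500, 12500),
                                      step = 100, constraint = TRUE,
                                      backward_dur = 6000, max_gap = 2600) {
  if (step <= 0) stop("argument error: step must be positive")
  if (!constraint) {
    pars <- model$params
    pars$control$delta_back <- 60 # beta_back = 0: accept immediately
    model <- assemble(pars, do.call(contralateral_config, model$config$contralateral),
                      model$config$ipsilateral, model$config$slow_motoneurons,
                      model$config$slow_muscles)
  }
  starts <- seq(window[1], window[2], by = step)
  lead <- sw_tetrapod_leadin(model, starts[1])
  state <- lead$final
  t_cur <- starts[1]
  acc <- rep(NA_real_, length(starts)); fail <- logical(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    if (s > t_cur) {
      lead <- run_model(model, NULL,
                        config = sim_config(t_end = s - t_cur, t0 = t_cur),
                        state = state)
      state <- lead$final
      t_cur <- s
    }
    br <- run_model(model,
                    list(mode_command("direction", s, target = "backward")),
                    config = sim_config(t_end = backward_dur + 2000, t0 = s),
                    state = state)
    tb <- br$events$time[br$events$event == "backward"]
    if (!length(tb)) { fail[i] <- TRUE; next }
    acc[i] <- tb[1]
    w0 <- tb[1] + 300; w1 <- min(tb[1] + backward_dur, max(br$times))
    iv <- step_intervals(br)
    bad <- nrow(detect_prolonged_lift(iv, w1)) > 0
    if (!bad) {
      for (leg in LEGS) {
        sw <- sw_clip(iv[[leg]], c(w0, w1))
        gaps <- diff(c(w0, as.vector(t(sw)), w1))
        gaps <- gaps[seq(1, length(gaps), by = 2)] # stance gaps only
        if (length(gaps) == 0 || max(gaps) > max_gap) { bad <- TRUE; break }
      }
    }
    fail[i] <- bad
  }
  list(map = data.frame(start = starts, accepted_at = acc, failed = fail),
       failed_fraction = mean(fail))
}

#' Scan forward-restore times after backward walking
#'
#' From steady backward walking, the return to forward walking is requested
#' at each scanned time (no constraint applies). A trial fails when the
#' classifier does not report a tetrapod pattern (B- or C-type) within the
#' post-return window.
#'
#' @inheritParams scan_backward_transitions
#' @param classify_window post-return window `c(offset0, offset1)` relative
#'   to the return time (ms).
#' @return A list: `map` (data frame `start`, `label`, `failed`),
#'   `failed_fraction`.
#' @export
scan_forward_restores <- function(model, window = c(16000, 18000), step = 100,
                                  classify_window = c(1200, 7200)) {
  if (step <= 0) stop("argument error: step must be positive")
  starts <- seq(window[1], window[2], by = step)
  sched <- list(mode_command("set_gait", 3000, gait = "tripod"),
                mode_command("set_gait", 7500, gait = "tetrapod"),
                mode_command("direction", 10500, target = "backward"))
  lead <- run_model(model, sched, config = sim_config(t_end = starts[1]))
  state <- lead$final
  t_cur <- starts[1]
  labs <- character(length(starts))
  for (i in seq_along(starts)) {
    s <- starts[i]
    if (s > t_cur) {
      lead <- run_model(model, NULL,
                        config = sim_config(t_end = s - t_cur, t0 = t_cur),
                        state = state)
      state <- lead$final
      t_cur <- s
    }
    br <- run_model(model,
                    list(mode_command("direction", s, target = "forward")),
                    config = sim_config(t_end = classify_window[2] + 400,
                                        t0 = s),
                    state = state)
    cl <- classify_gait(step_intervals(br), window = s + classify_window)
    labs[i] <- cl$label
  }
  fail <- !labs %in% c("tetrapod_B", "tetrapod_C")
  list(map = data.frame(start = starts, label = labs, failed = fail),
       failed_fraction = mean(fail))
}
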