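# antagonistic-muscle joint dynamics: one second-order equation per muscle
# pair. The net muscle torque sets an activation-dependent equilibrium angle
# inside the joint's working range through a saturating (tanh) mapping, and
# the angle relaxes toward it with near-critical damping, so the limits act
# as saturating restoring terms and velocities stay continuous.

sw_joint_dir <- c(alpha = -1, beta = 1, gamma = -1)

#' Muscle-pair parameters
#'
#' Parameters of one antagonistic muscle pair (fast + slow muscle per side)
#' driving a single leg joint. `Gf` and `Gs` are the fast and slow force
#' gains; `Tsc` the torque scale of the saturating equilibrium mapping; `kr`
#' (stiffness, 1/ms^2) and `bdamp` (viscous damping, 1/ms) set the
#' second-order response; `bias` is a passive torque bias (beta toward
#' ground, gamma toward extension). The fast/slow activation time constants
#' (`tau_act_fast`, `tau_act_slow`; the slow one much longer) parameterize
#' the motoneuron-side activation lag of the two muscle classes.
#'
#' @param joint `"alpha"` (protractor-retractor), `"beta"`
#'   (levator-depressor) or `"gamma"` (extensor-flexor).
#' @param params model parameters.
#' @export
muscle_pair_params <- function(joint = c("alpha", "beta", "gamma"),
                               params = sw_params()) {
  joint <- match.arg(joint)
  mu <- params$muscle
  structure(list(joint = joint, Gf = mu$Gf, Gs = mu$Gs, Tsc = mu$Tsc,
                 kr = mu$kr, bdamp = mu$bdamp,
                 bias = unname(mu$bias[joint]),
                 limits = mu$limits[[joint]],
                 dir = unname(sw_joint_dir[joint]),
                 tau_act_fast = params$mn$tau_act_fast,
                 tau_act_slow = params$mn$tau_act_slow),
            class = "sw_muscle_pair")
}

#' Joint state
#'
#' @param joint joint id (`"alpha"`, `"beta"`, `"gamma"`).
#' @param angle degrees.
#' @param velocity deg/ms.
#' @export
joint_state <- function(joint = c("alpha", "beta", "gamma"), angle,
                        velocity = 0) {
  joint <- match.arg(joint)
  structure(list(joint = joint, angle = angle, velocity = velocity),
            class = "sw_joint_state")
}

# activation-dependent equilibrium angle
sw_joint_eq <- function(activities, mp) {
  a <- activities
  torque <- mp$dir * (mp$Gf * (a[1] - a[2]) + mp$Gs * (a[3] - a[4])) + mp$bias
  mid <- mean(mp$limits); half <- diff(mp$limits) / 2
  mid + half * tanh(torque / mp$Tsc)
}

#' Advance a joint by one time step
#'
#' One RK4 step of the second-order joint equation under four motoneuron
#' activity values (fast/slow x agonist/antagonist, each in [0, 1]).
#'
#' @param state a [joint_state()].
#' @param mn_activities numeric length 4: fast agonist, fast antagonist,
#'   slow agonist, slow antagonist (the agonist is the "a" side: protractor,
#'   levator or extensor).
#' @param mp a [muscle_pair_params()].
#' @param dt step (ms), must be positive.
#' @return The updated [joint_state()].
#' @export
joint_step <- function(state, mn_activities, mp, dt) {
  stopifnot(inherits(state, "sw_joint_state"), inherits(mp, "sw_muscle_pair"))
  if (dt <= 0) stop("argument error: dt must be positive")
  if (length(mn_activities) != 4 || any(mn_activities < 0))
    stop("argument error: four nonnegative activities required")
  teq <- sw_joint_eq(mn_activities, mp)
  f <- function(y) c(y[2], mp$kr * (teq - y[1]) - mp$bdamp * y[2])
  y <- c(state$angle, state$velocity)
  k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  joint_state(state$joint, y[1], y[2])
}

#' Static equilibrium pose of a joint
#'
#' Closed-form long-time limit of the joint equation under constant
#' motoneuron activities: the activation-dependent equilibrium angle of the
#' saturating restoring term. Matches long [joint_step()] integration within
#' a small fraction of a degree.
#'
#' @inheritParams joint_step
#' @return Equilibrium angle (degrees).
#' @export
#' @examples
#' mp <- muscle_pair_params("alpha")
#' pose_equilibrium(c(0, 1, 0, 1), mp) # full retraction: close to 128 degrees
pose_equilibrium <- function(mn_activities, mp) {
  stopifnot(inherits(mp, "sw_muscle_pair"))
  if (length(mn_activities) != 4 || any(mn_activities < 0))
    stop("argument error: four nonnegative activities required")
  sw_joint_eq(mn_activities, mp)
}
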