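#' Agent body and acoustics configuration
#'
#' Circular two-wheeled body of radius 4 length-units, two acoustic
#' sensors on the front perimeter at +-45 degrees from the heading, and an
#' emitter at the body centre. The received signal attenuates with
#' distance and is occluded by the receiver's own body
#' ("self-shadowing"). Both laws are configurable:
#'
#' * `attenuation`: `"inverse_square"` (default), `D(d) = 1/d^2`, or
#'   `"inverse"`, `D(d) = 1/d`; in both, `d` is clamped below at
#'   `min_distance` to avoid singularities while bodies overlap.
#' * `shadow`: `"hard"` (default) multiplies the signal by `occlusion`
#'   whenever the source lies behind the sensor's outward radial
#'   direction (angle > pi/2); `"cosine"` uses the smooth factor
#'   `(1 + cos(psi)) / 2`.
#'
#' @param radius Body radius, length-units (> 0).
#' @param sensor_angles Sensor angles relative to heading, radians.
#' @param attenuation Distance-attenuation law, see Details.
#' @param shadow Self-shadowing model, see Details.
#' @param occlusion Multiplier applied by the hard shadow model when the
#'   source is behind the sensor, in `[0, 1]`.
#' @param min_distance Lower clamp on source-sensor distance.
#' @return An object of class `body_config`.
#' @export
body_config <- function(radius = 4, sensor_angles = c(pi / 4, -pi / 4),
                        attenuation = c("inverse_square", "inverse"),
                        shadow = c("hard", "cosine"),
                        occlusion = 0.1, min_distance = 1) {
  attenuation <- match.arg(attenuation)
  shadow <- match.arg(shadow)
  stopifnot(radius > 0, length(sensor_angles) == 2L,
            occlusion >= 0, occlusion <= 1, min_distance > 0)
  structure(list(radius = radius, sensor_angles = sensor_angles,
                 attenuation = attenuation, shadow = shadow,
                 occlusion = occlusion, min_distance = min_distance),
            class = "body_config")
}

#' Construct a pose
#'
#' @param x,y Position, length-units.
#' @param phi Heading, radians; 0 points along the +x axis ("right").
#'   Wrapped into `[0, 2*pi)`.
#' @return Named numeric vector `c(x, y, phi)`.
#' @export
pose <- function(x = 0, y = 0, phi = 0) {
  c(x = as.numeric(x), y = as.numeric(y), phi = as.numeric(phi) %% (2 * pi))
}

#' Differential-drive kinematics: motor outputs to body velocities
#'
#' The net linear velocity is the average of the two motor outputs; the
#' angular velocity is their difference divided by the body radius.
#'
#' @param left_out,right_out Motor actuator outputs in `[0, 1]`.
#' @param radius Body radius (default 4).
#' @return List with `v` (length-units/s) and `omega` (rad/s).
#' @export
#' @examples
#' motor_to_velocity(0, 1)  # v = 0.5, omega = 0.25
motor_to_velocity <- function(left_out, right_out, radius = 4) {
  list(v = (left_out + right_out) / 2,
       omega = (right_out - left_out) / radius)
}

#' One Euler step of the unicycle pose update
#'
#' Translation uses the pre-step heading; the heading is updated after the
#' translation. The heading is wrapped into `[0, 2*pi)`.
#'
#' @param p A [pose()].
#' @param v Linear velocity, length-units/s.
#' @param omega Angular velocity, rad/s.
#' @param dt Step size, seconds.
#' @return The updated pose.
#' @export
update_pose <- function(p, v, omega, dt = 0.1) {
  pose(p[["x"]] + v * cos(p[["phi"]]) * dt,
       p[["y"]] + v * sin(p[["phi"]]) * dt,
       p[["phi"]] + omega * dt)
}

#' World coordinates of the two acoustic sensors
#'
#' @param p A [pose()].
#' @param body A [body_config()].
#' @return 2 x 2 matrix; rows are sensors 1 and 2, columns `x`, `y`.
#' @export
sensor_positions <- function(p, body = body_config()) {
  ang <- p[["phi"]] + body$sensor_angles
  m <- cbind(x = p[["x"]] + body$radius * cos(ang),
             y = p[["y"]] + body$radius * sin(ang))
  rownames(m) <- c("sensor1", "sensor2")
  m
}

#' Received acoustic intensity at one sensor
#'
#' `intensity = emitter_strength * D(d) * S(psi)` where `d` is the
#' Euclidean distance from the source (the partner's emitter, at its body
#' centre) to the sensor point, `D` the distance-attenuation law and `S`
#' the self-shadowing factor; `psi` is the angle between the sensor's
#' outward radial direction and the direction from the sensor to the
#' source. See [body_config()] for the configurable laws.
#'
#' @param emitter_strength Source emitter output in `[0, 1]`.
#' @param source Source position, numeric `c(x, y)`.
#' @param sensor Sensor position, numeric `c(x, y)`.
#' @param receiver_pose The receiving agent's [pose()] (defines the
#'   sensor's outward radial direction).
#' @param body A [body_config()].
#' @return Non-negative intensity.
#' @export
signal_intensity <- function(emitter_strength, source, sensor,
                             receiver_pose, body = body_config()) {
  if (!is.finite(emitter_strength) || emitter_strength < 0)
    stop("emitter strength must be finite and non-negative")
  dx <- source[[1]] - sensor[[1]]
  dy <- source[[2]] - sensor[[2]]
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) stop("source and sensor coincide")
  dc <- max(d, body$min_distance)
  D <- switch(body$attenuation,
              inverse_square = 1 / dc^2,
              inverse = 1 / dc)
  rx <- sensor[[1]] - receiver_pose[["x"]]
  ry <- sensor[[2]] - receiver_pose[["y"]]
  rn <- sqrt(rx^2 + ry^2)
  cospsi <- if (rn == 0) 1 else (rx * dx + ry * dy) / (rn * d)
  S <- switch(body$shadow,
              hard = if (cospsi >= 0) 1 else body$occlusion,
              cosine = (1 + cospsi) / 2)
  emitter_strength * D * S
}

#' Sensor intensities for one agent in a world
#'
#' Agents never sense their own signal: in a single-agent world (or with
#' `sense_input = FALSE`, the decoupled testing mode) both intensities
#' are 0. In a two-agent world each sensor receives the partner's emitter
#' signal under the configured attenuation and self-shadowing.
#'
#' @param world A world state as built by [world_state()].
#' @param agent Index of the receiving agent.
#' @param body A [body_config()].
#' @param sense_input If `FALSE`, force both intensities to 0.
#' @return Length-2 non-negative vector (sensor 1, sensor 2).
#' @export
sense_world <- function(world, agent, body = body_config(),
                        sense_input = TRUE) {
  if (!sense_input || length(world$poses) < 2L) return(c(0, 0))
  other <- if (agent == 1L) 2L else 1L
  src <- world$poses[[other]][c("x", "y")]
  sp <- sensor_positions(world$poses[[agent]], body)
  vapply(1:2, function(k) {
    signal_intensity(world$emitters[[other]], src, sp[k, ],
                     world$poses[[agent]], body)
  }, numeric(1))
}

#' Construct a world state
#'
#' @param poses List of 1 (solitary) or 2 (social) [pose()]s.
#' @param emitters Emitter strengths in `[0, 1]`, one per agent.
#' @return An object of class `world_state`.
#' @export
world_state <- function(poses, emitters = rep(0, length(poses))) {
  stopifnot(length(poses) %in% 1:2, length(emitters) == length(poses),
            all(emitters >= 0), all(emitters <= 1))
  structure(list(poses = poses, emitters = as.numeric(emitters)),
            class = "world_state")
}

#' Advance the world by one time step
#'
#' Moves every agent synchronously from its actuator outputs and replaces
#' the emitter strengths with the emitter actuator outputs. Bodies may
#' overlap: the arena is open and empty, and no collision handling is
#' applied.
#'
#' @param world A [world_state()].
#' @param actuator_outs List with one length-3 actuator output vector
#'   (left, right, emitter) per agent.
#' @param body A [body_config()].
#' @param dt Step size, seconds.
#' @return The updated `world_state`.
#' @export
world_step <- function(world, actuator_outs, body = body_config(),
                       dt = 0.1) {
  stopifnot(length(actuator_outs) == length(world$poses))
  poses <- vector("list", length(world$poses))
  emitters <- numeric(length(world$poses))
  for (a in seq_along(world$poses)) {
    act <- actuator_outs[[a]]
    vel <- motor_to_velocity(act[[1]], act[[2]], body$radius)
    poses[[a]] <- update_pose(world$poses[[a]], vel$v, vel$omega, dt)
    emitters[[a]] <- act[[3]]
  }
  world_state(poses, emitters)
}
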