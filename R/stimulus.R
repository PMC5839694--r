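#' Rotating-cylinder stimulus specification
#'
#' Kinematic description of the bistable structure-from-motion stimulus: a
#' field of dots revolving about a vertical axis, half black and half white,
#' with luminance tied to horizontal motion direction. Depth is never
#' rendered; which surface is "in front" is a perceptual interpretation, not
#' a property of the kinematics.
#'
#' @param n_dots Number of dots.
#' @param width_deg Cylinder diameter on screen (visual degrees).
#' @param height_deg Cylinder height (visual degrees).
#' @param angular_velocity Angular velocity about the vertical axis (deg/s).
#' @param dot_diameter_deg Dot diameter (metadata only; dots are treated as
#'   points for kinematics).
#' @param black_direction Horizontal direction of the black dots,
#'   `"rightward"` (default) or `"leftward"`.
#' @param luminance_black,luminance_white,background_luminance Luminances in
#'   cd/m^2; must satisfy black < background < white.
#' @param frame_rate Display frame rate in Hz; defines "1 frame" for
#'   speed-increment duration metadata.
#' @return A list of class `cylinder_spec`.
#' @export
cylinder_spec <- function(n_dots = 300, width_deg = 8, height_deg = 14,
                          angular_velocity = 60, dot_diameter_deg = 0.30,
                          black_direction = c("rightward", "leftward"),
                          luminance_black = 0.05, luminance_white = 55,
                          background_luminance = 12.4, frame_rate = 120) {
  black_direction <- match.arg(black_direction)
  stopifnot(n_dots > 0, angular_velocity != 0, width_deg > 0, height_deg > 0)
  if (!(luminance_black < background_luminance &&
        background_luminance < luminance_white)) {
    stop("luminances must satisfy black < background < white", call. = FALSE)
  }
  structure(list(
    n_dots = as.integer(n_dots), width_deg = width_deg,
    height_deg = height_deg, angular_velocity = angular_velocity,
    dot_diameter_deg = dot_diameter_deg, black_direction = black_direction,
    luminance_black = luminance_black, luminance_white = luminance_white,
    background_luminance = background_luminance, frame_rate = frame_rate
  ), class = "cylinder_spec")
}

#' Dot position, speed and luminance tag at time t
#'
#' A dot on the virtual cylinder at initial phase angle `theta0_deg` projects
#' to `x = R sin(theta)` with `theta(t) = theta0 + omega t`; the horizontal
#' (linear) speed follows a cosine profile, `dx/dt = R omega cos(theta)` with
#' omega in rad/s. The luminance tag is determined by the sign of the
#' horizontal velocity and the spec's `black_direction` (rightward = positive
#' x direction).
#'
#' @param spec A [cylinder_spec()].
#' @param theta0_deg Initial phase angle(s), degrees.
#' @param t Time(s), seconds; `t` and `theta0_deg` are recycled.
#' @param y_deg Vertical position(s), carried through unchanged.
#' @param direction Rotation direction sign (+1 or -1) for the assigned
#'   dot group; dots moving opposite directions belong to opposite groups.
#' @return A tibble with `x_deg`, `y_deg`, `h_speed_deg_s`, `luminance`
#'   (`"black"` or `"white"`).
#' @export
dot_state <- function(spec, theta0_deg, t, y_deg = 0, direction = 1) {
  stopifnot(inherits(spec, "cylinder_spec"), all(t >= 0),
            all(direction %in% c(-1, 1)))
  R <- spec$width_deg / 2
  omega_deg <- spec$angular_velocity * direction
  theta <- (theta0_deg + omega_deg * t) * pi / 180
  omega_rad <- omega_deg * pi / 180
  x <- R * sin(theta)
  v <- R * omega_rad * cos(theta)
  rightward <- v > 0
  lum <- ifelse(rightward == (spec$black_direction == "rightward"),
                "black", "white")
  lum[v == 0] <- NA_character_  # silhouette edge: direction undefined
  tibble::tibble(x_deg = x, y_deg = y_deg, h_speed_deg_s = v, luminance = lum)
}

#' Swap the motion directions of the black and white dots
#'
#' Involution: applying twice returns the original spec. Luminances are
#' unchanged; only the direction-to-luminance assignment toggles.
#'
#' @param spec A [cylinder_spec()].
#' @return The spec with `black_direction` toggled.
#' @export
swap_directions <- function(spec) {
  stopifnot(inherits(spec, "cylinder_spec"))
  spec$black_direction <-
    if (spec$black_direction == "rightward") "leftward" else "rightward"
  spec
}

#' Schedule speed-increment events
#'
#' Inter-event gaps are `min_separation` plus an exponential with mean
#' `mean_interval - min_separation`, so gaps average `mean_interval` with a
#' hard minimum separation. Each event is tagged to the black or white dot
#' group with equal probability.
#'
#' @param duration Total scheduling time, seconds.
#' @param mean_interval Mean inter-event interval, seconds.
#' @param min_separation Minimum inter-event separation, seconds.
#' @param magnitude Angular-velocity increment, deg/s (metadata).
#' @param duration_frames Event duration in display frames (metadata).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with `t_s`, `dot_color`, `magnitude`, `duration_frames`.
#' @export
schedule_increments <- function(duration, mean_interval = 3,
                                min_separation = 2, magnitude = 600,
                                duration_frames = 1, seed = NULL) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  stopifnot(mean_interval > min_separation, min_separation > 0)
  run <- function() {
    # upper bound on event count, then trim to duration
    n_max <- ceiling(duration / min_separation) + 10L
    gaps <- min_separation +
      stats::rexp(n_max, rate = 1 / (mean_interval - min_separation))
    times <- cumsum(gaps)
    times <- times[times <= duration]
    tibble::tibble(
      t_s = times,
      dot_color = sample(c("black", "white"), length(times), replace = TRUE),
      magnitude = magnitude,
      duration_frames = as.integer(duration_frames)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
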