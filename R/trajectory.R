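#' Simulate an open-field exploration trajectory
#'
#' Generates a smooth, space-filling random walk emulating tracked rodent
#' exploration. Velocity follows a mean-reverting (Ornstein-Uhlenbeck-style)
#' process with reflective arena walls, so speeds are continuous and the
#' animal progressively covers the enclosure.
#'
#' @param arena An [arena()].
#' @param duration Session length in seconds.
#' @param step Tracker sampling interval in seconds (default 0.025 s = 40 Hz).
#' @param speed_params List with `mean_speed` (target mean running speed,
#'   cm/s) and `tau` (velocity relaxation time constant, s). The stationary
#'   per-component velocity s.d. is chosen so the 2-D speed (Rayleigh
#'   distributed) has mean `mean_speed`. `mean_speed = 0` freezes the walk.
#' @param start Optional starting position `c(x, y)` in cm; defaults to the
#'   arena centre.
#' @param seed Optional integer seed; identical seeds give identical paths.
#' @return A `trajectory`: data frame with columns `t`, `x`, `y`, `speed`,
#'   carrying the arena and step as attributes.
#' @examples
#' tr <- simulate_trajectory(arena("rectangle", 60, 60), duration = 60, seed = 1)
#' range(tr$x)
#' @export
simulate_trajectory <- function(arena, duration, step = 0.025,
                                speed_params = list(mean_speed = 12, tau = 0.7),
                                start = NULL, seed = NULL) {
  if (!inherits(arena, "arena")) stopf("`arena` must be an arena object")
  if (!is.numeric(duration) || length(duration) != 1L || duration < 0)
    stopf("`duration` must be a single non-negative number")
  assert_scalar_pos(step, "step")
  mean_speed <- speed_params$mean_speed %||% 12
  tau <- speed_params$tau %||% 0.7
  if (mean_speed < 0) stopf("`mean_speed` must be >= 0")
  assert_scalar_pos(tau, "tau")

  n <- floor(duration / step)
  empty <- data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      speed = numeric(0))
  if (n == 0L)
    return(structure(empty, class = c("trajectory", "data.frame"),
                     arena = arena, step = step))

  # Rayleigh mean = s * sqrt(pi/2) => per-component stationary sd
  s_comp <- mean_speed / sqrt(pi / 2)
  # OU: dv = -v/tau dt + sig dW, stationary sd = sig * sqrt(tau/2)
  sig <- s_comp * sqrt(2 / tau)

  pos0 <- start %||% arena_centre(arena)
  if (!all(arena_contains(arena, pos0[1], pos0[2])))
    stopf("`start` must lie inside the arena")

  with_seed(seed, {
    x <- numeric(n); y <- numeric(n)
    vx <- 0; vy <- 0
    px <- pos0[1]; py <- pos0[2]
    a <- exp(-step / tau)
    b <- sig * sqrt(tau / 2 * (1 - a^2))
    nx <- stats::rnorm(n); ny <- stats::rnorm(n)
    for (i in seq_len(n)) {
      vx <- a * vx + b * nx[i]
      vy <- a * vy + b * ny[i]
      px2 <- px + vx * step
      py2 <- py + vy * step
      # reflect off the walls; for circles, fold back along the radius
      if (arena$shape == "rectangle") {
        if (px2 < 0) { px2 <- -px2; vx <- -vx }
        if (px2 > arena$width) { px2 <- 2 * arena$width - px2; vx <- -vx }
        if (py2 < 0) { py2 <- -py2; vy <- -vy }
        if (py2 > arena$height) { py2 <- 2 * arena$height - py2; vy <- -vy }
        px2 <- min(max(px2, 0), arena$width)
        py2 <- min(max(py2, 0), arena$height)
      } else {
        r <- arena$diameter / 2
        dx <- px2 - r; dy <- py2 - r
        d <- sqrt(dx^2 + dy^2)
        if (d > r) {
          scl <- (2 * r - d) / d
          px2 <- r + dx * max(scl, 0)
          py2 <- r + dy * max(scl, 0)
          vx <- -vx; vy <- -vy
          d2 <- sqrt((px2 - r)^2 + (py2 - r)^2)
          if (d2 > r) { px2 <- r + (px2 - r) * r / d2; py2 <- r + (py2 - r) * r / d2 }
        }
      }
      px <- px2; py <- py2
      x[i] <- px; y[i] <- py
    }
    tt <- (seq_len(n) - 1) * step
    spd <- c(0, sqrt(diff(x)^2 + diff(y)^2) / step)
    structure(data.frame(t = tt, x = x, y = y, speed = spd),
              class = c("trajectory", "data.frame"),
              arena = arena, step = step)
  })
}

#' Assemble a trajectory from tracked samples
#'
#' Wraps externally supplied position samples (e.g. read from a tracking CSV)
#' in the `trajectory` container used throughout the package.
#'
#' @param t,x,y Numeric vectors: time (s, strictly increasing, uniform step)
#'   and position (cm).
#' @param arena The [arena()] the positions belong to.
#' @return A `trajectory` object.
#' @export
as_trajectory <- function(t, x, y, arena) {
  if (length(t) != length(x) || length(t) != length(y))
    stopf("t, x, y must have equal length")
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0)) stopf("`t` must be strictly increasing")
    step <- stats::median(dt)
  } else step <- NA_real_
  if (!all(arena_contains(arena, x, y)))
    stopf("all positions must lie inside the arena")
  spd <- if (length(t) > 1) c(0, sqrt(diff(x)^2 + diff(y)^2) / diff(t)) else 0
  structure(data.frame(t = t, x = x, y = y, speed = spd),
            class = c("trajectory", "data.frame"),
            arena = arena, step = step)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples, %.1f s @ %.0f Hz\n",
              nrow(x), if (nrow(x)) nrow(x) * attr(x, "step") else 0,
              1 / attr(x, "step")))
  invisible(x)
}

trajectory_duration <- function(tr) nrow(tr) * attr(tr, "step")
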