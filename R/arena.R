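#' Define an exploration arena
#'
#' Arenas are the spatial container for trajectories and place-field models.
#' Rectangular arenas span `[0, width] x [0, height]` cm; circular arenas are
#' centred at `(diameter/2, diameter/2)`.
#'
#' @param shape `"rectangle"` or `"circle"`.
#' @param width,height Rectangle dimensions in cm.
#' @param diameter Circle diameter in cm.
#' @return An object of class `arena`.
#' @examples
#' arena("rectangle", width = 60, height = 60)
#' arena("circle", diameter = 80)
#' @export
arena <- function(shape = c("rectangle", "circle"), width = NULL, height = NULL,
                  diameter = NULL) {
  shape <- match.arg(shape)
  if (shape == "rectangle") {
    assert_scalar_pos(width, "width")
    assert_scalar_pos(height, "height")
    a <- list(shape = shape, width = width, height = height)
  } else {
    assert_scalar_pos(diameter, "diameter")
    a <- list(shape = shape, diameter = diameter)
  }
  structure(a, class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  if (x$shape == "rectangle")
    cat(sprintf("<arena> rectangle %.1f x %.1f cm\n", x$width, x$height))
  else
    cat(sprintf("<arena> circle, diameter %.1f cm\n", x$diameter))
  invisible(x)
}

# Bounding extent (cm) used for binning; circles are gridded over their
# bounding square and masked by occupancy.
arena_extent <- function(a) {
  if (a$shape == "rectangle") c(a$width, a$height) else c(a$diameter, a$diameter)
}

arena_contains <- function(a, x, y, tol = 1e-9) {
  if (a$shape == "rectangle")
    x >= -tol & x <= a$width + tol & y >= -tol & y <= a$height + tol
  else {
    r <- a$diameter / 2
    (x - r)^2 + (y - r)^2 <= (r + tol)^2
  }
}

arena_centre <- function(a) arena_extent(a) / 2
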