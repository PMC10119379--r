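# Circular hue arithmetic and the fixed-luminance CIELab color wheel that
# underlies every stimulus in the package.

#' Unsigned angular distance between two hues
#'
#' Distance on the 360-degree hue circle, i.e. the shorter of the two arcs
#' separating `a` and `b`. This is the metric behind every target-distractor
#' and target-foil separation in the designs.
#'
#' @param a,b Hue angles in degrees (any real values; reduced modulo 360).
#'   Vectorized with the usual recycling.
#' @return Numeric vector of distances in `[0, 180]`.
#' @examples
#' angular_distance(10, 350)  # 20, wraps around 0
#' angular_distance(0, 180)   # 180, antipode
#' @export
angular_distance <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Rotate a hue by a signed offset
#'
#' Positive offsets rotate counterclockwise (increasing hue angle); negative
#' offsets rotate clockwise. The result is reduced to `[0, 360)`.
#'
#' @param h Hue angle(s) in degrees.
#' @param offset Signed offset(s) in degrees.
#' @return Hue angle(s) in `[0, 360)`.
#' @examples
#' rotate_hue(350, 20)  # 10
#' rotate_hue(0, -30)   # 330
#' @export
rotate_hue <- function(h, offset) {
  (h + offset) %% 360
}

#' Build the CIELab color wheel
#'
#' The stimulus set is 360 equally spaced hues on a circle of chroma
#' `radius` in the a*b* plane at fixed luminance `center_L`, centered on
#' `(center_a, center_b)`. Hue 0 points along +a* when `phase = 0`; the
#' absolute phase is a display convention and no analysis depends on it.
#'
#' @param n_colors Number of equally spaced hues (default 360).
#' @param center_L,center_a,center_b Center of the wheel in CIELab.
#' @param radius Chroma of every wheel entry, in CIELab units.
#' @param phase Rotation of the hue-0 anchor in degrees (default 0).
#' @return A data frame with columns `hue`, `L`, `a`, `b`, one row per color.
#' @examples
#' wheel <- color_wheel()
#' nrow(wheel)      # 360
#' wheel[1, ]       # hue 0: L = 54, a = 21.5 + 49, b = 11.5
#' @export
color_wheel <- function(n_colors = 360, center_L = 54, center_a = 21.5,
                        center_b = 11.5, radius = 49, phase = 0) {
  stopifnot(n_colors >= 1, radius >= 0)
  hue <- (seq_len(n_colors) - 1) * 360 / n_colors
  ang <- (hue + phase) * pi / 180
  data.frame(
    hue = hue,
    L = rep(center_L, n_colors),
    a = center_a + radius * cos(ang),
    b = center_b + radius * sin(ang)
  )
}

#' Look up the Lab coordinates of a hue
#'
#' Hues are carried through the package as real-valued degrees so that foil
#' offsets need no rounding; when an actual Lab triple is required the hue is
#' rounded to the nearest wheel entry.
#'
#' @param hue Hue angle(s) in degrees.
#' @param wheel A wheel as returned by [color_wheel()].
#' @return Data frame of `hue`, `L`, `a`, `b` rows (the nearest entries).
#' @export
hue_to_lab <- function(hue, wheel = color_wheel()) {
  n <- nrow(wheel)
  idx <- (round(hue * n / 360) %% n) + 1
  out <- wheel[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
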