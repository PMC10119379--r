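# Simulation of a color-tuned neural population under feature-similarity
# attentional gain, and the representational geometry of its responses.
#
# Each of n_neurons units has a bell-shaped tuning curve on the hue circle
# (von Mises by default, wrapped Gaussian as an alternative of matched
# width). Attention multiplies each unit's response by a feature-similarity
# gain profile peaked at an attended hue; with the gain applied off the true
# target hue the geometry of the stimulus-evoked population patterns warps:
# classical MDS shows local expansion around the attended hue, and the
# target-to-foil distance becomes asymmetric in the toward/away direction.
# Distances are computed between stimulus-evoked population response
# patterns (the reading under which a stimulus-space geometry exists at
# all). The population is deterministic: no response noise.

#' Specification of the color-tuned population
#'
#' @param n_neurons Number of units; preferred hues tile `[0, 360)` evenly.
#' @param kappa Tuning concentration (von Mises kappa). The wrapped-Gaussian
#'   family uses the matched local width `sd = 1/sqrt(kappa)` radians.
#' @param family `"von_mises"` or `"wrapped_gaussian"`.
#' @param scale Peak response in arbitrary units.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_neurons = 180, kappa = 1.25,
                            family = c("von_mises", "wrapped_gaussian"),
                            scale = 1) {
  family <- match.arg(family)
  stopifnot(n_neurons >= 8, kappa > 0, scale > 0)
  structure(list(n_neurons = as.integer(n_neurons), kappa = kappa,
                 family = family, scale = scale,
                 preferred = (seq_len(n_neurons) - 1) * 360 / n_neurons),
            class = "population_spec")
}

#' Feature-similarity attentional gain profile
#'
#' Multiplicative gain `1 + A * exp(kappa_g * (cos(mu - theta_a) - 1))`
#' applied to a unit preferring hue `mu`: maximal (`1 + A`) for units tuned
#' to the attended hue, decaying smoothly to 1 for far-tuned units.
#' `amplitude = 0` is the identity (no attention).
#'
#' The default gain concentration (`kappa_g = 0.4`) is deliberately broader
#' than the default tuning (`kappa = 1.25`): local discriminability at a hue is
#' carried by flank-tuned units about one tuning width away, so a gain
#' profile as narrow as the tuning boosts the wrong units and compresses,
#' rather than expands, the geometry at the attended hue. A broad gain
#' places the expansion maximum at the attended hue, the regime in which an
#' off-target gain reproduces the behavioral repulsion.
#'
#' @param attended_hue Attended hue theta_a in degrees.
#' @param amplitude Gain amplitude `A >= 0`.
#' @param kappa_g Concentration of the gain profile.
#' @return Object of class `gain_profile`.
#' @export
gain_profile <- function(attended_hue = 0, amplitude = 1, kappa_g = 0.4) {
  stopifnot(amplitude >= 0, kappa_g > 0)
  structure(list(attended_hue = attended_hue, amplitude = amplitude,
                 kappa_g = kappa_g),
            class = "gain_profile")
}

.gain_at <- function(gain, mu) {
  1 + gain$amplitude *
    exp(gain$kappa_g * (cos((mu - gain$attended_hue) * pi / 180) - 1))
}

.tuning <- function(spec, theta, mu) {
  d <- (theta - mu) * pi / 180
  if (spec$family == "von_mises") {
    spec$scale * exp(spec$kappa * (cos(d) - 1))
  } else {
    sd <- 1 / sqrt(spec$kappa)  # radians; matched curvature at the peak
    k <- -3:3
    rowSums(vapply(k, function(kk) {
      exp(-((d + 2 * pi * kk)^2) / (2 * sd^2))
    }, numeric(length(d)))) * spec$scale /
      sum(exp(-((2 * pi * k)^2) / (2 * sd^2)))
  }
}

#' Population response to a stimulus hue
#'
#' Deterministic firing-rate vector: unit i responds
#' `gain(mu_i) * f(theta; mu_i, kappa)` with `f` the tuning curve, peaked at
#' the unit's preferred hue.
#'
#' @param theta Stimulus hue in degrees.
#' @param spec [population_spec()].
#' @param gain [gain_profile()]; default no attention (`amplitude = 0`).
#' @return Numeric vector of length `n_neurons`.
#' @export
population_response <- function(theta, spec = population_spec(),
                                gain = gain_profile(amplitude = 0)) {
  stopifnot(inherits(spec, "population_spec"), inherits(gain, "gain_profile"))
  .gain_at(gain, spec$preferred) * .tuning(spec, rep(theta, spec$n_neurons),
                                           spec$preferred)
}

# stimulus-by-neuron response matrix
.response_matrix <- function(grid, spec, gain) {
  g <- .gain_at(gain, spec$preferred)
  m <- vapply(grid, function(th) {
    g * .tuning(spec, rep(th, spec$n_neurons), spec$preferred)
  }, numeric(spec$n_neurons))
  t(m)  # rows = stimuli
}

#' Pairwise distances between stimulus-evoked population patterns
#'
#' @param grid Stimulus hues in degrees.
#' @param spec [population_spec()].
#' @param gain [gain_profile()].
#' @return Symmetric matrix of Euclidean distances, dimnames = hues.
#' @export
distance_matrix <- function(grid, spec = population_spec(),
                            gain = gain_profile(amplitude = 0)) {
  stopifnot(length(grid) >= 1)
  r <- .response_matrix(grid, spec, gain)
  d <- as.matrix(stats::dist(r))
  dimnames(d) <- list(grid, grid)
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix and takes the top
#' eigenvectors (via [stats::cmdscale()]). Because an MDS solution is only
#' defined up to rotation and reflection, the embedding is canonicalized:
#' centered at the origin, rotated so the first point (hue 0 when rows are
#' hue-labelled) lies on the +x axis, and reflected so the point a quarter
#' of the way around has positive y.
#'
#' @param d Symmetric distance matrix.
#' @param dims Embedding dimension (default 2).
#' @return List: `points` (n x dims), `eig` (eigenvalues), `degenerate`
#'   (TRUE when fewer than `dims` positive eigenvalues).
#' @export
classical_mds <- function(d, dims = 2) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), all(abs(d - t(d)) < 1e-8))
  fit <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  degenerate <- sum(fit$eig > 1e-10 * max(abs(fit$eig))) < dims
  x <- fit$points
  x <- sweep(x, 2, colMeans(x))
  if (dims == 2 && !degenerate) {
    a <- atan2(x[1, 2], x[1, 1])
    rot <- matrix(c(cos(-a), -sin(-a), sin(-a), cos(-a)), 2, 2, byrow = TRUE)
    x <- x %*% t(rot)
    q <- max(1L, round(nrow(x) / 4))
    if (x[q, 2] < 0) x[, 2] <- -x[, 2]
  }
  rownames(x) <- rownames(d)
  list(points = x, eig = fit$eig, degenerate = degenerate)
}

#' Representational geometry of the attended population code
#'
#' End-to-end convenience: evaluates population responses on a hue grid,
#' computes the pattern-distance matrix and its 2-D classical MDS embedding,
#' and summarizes the warping: the coefficient of variation of embedding
#' radii (0 for a perfect circle), the hue at which the nearest-neighbor
#' embedded spacing is maximal (the center of the expansion), and a
#' subsampled embedding every `subsample` degrees for plotting.
#'
#' @param spec [population_spec()].
#' @param gain [gain_profile()].
#' @param grid Stimulus hues (default every degree).
#' @param subsample Subsampling step in degrees for the display embedding.
#' @return Object of class `geometry_result`: `grid`, `distances`,
#'   `embedding`, `embedding_subsampled`, `radii_cv`, `expansion_hue`,
#'   `degenerate`.
#' @export
representational_geometry <- function(spec = population_spec(),
                                      gain = gain_profile(amplitude = 0),
                                      grid = 0:359, subsample = 10) {
  d <- distance_matrix(grid, spec, gain)
  mds <- classical_mds(d, dims = 2)
  x <- mds$points
  radii <- sqrt(rowSums(x^2))
  radii_cv <- stats::sd(radii) / mean(radii)
  # nearest-neighbor spacing along the (ordered) grid, wrapped
  nn <- sqrt(rowSums((x - x[c(2:nrow(x), 1), ])^2))
  gap_mid <- rotate_hue(grid, diff(c(grid, grid[1] + 360)) / 2)
  expansion_hue <- gap_mid[which.max(nn)]
  keep <- which(grid %% subsample == 0)
  structure(
    list(grid = grid, distances = d, embedding = x,
         embedding_subsampled = x[keep, , drop = FALSE],
         radii_cv = radii_cv, expansion_hue = expansion_hue,
         degenerate = mds$degenerate),
    class = "geometry_result")
}

#' @export
print.geometry_result <- function(x, ...) {
  cat("Representational geometry on", length(x$grid), "hues:",
      "radii CV =", signif(x$radii_cv, 3),
      "; max expansion near", x$expansion_hue, "deg\n")
  invisible(x)
}

#' Toward/away asymmetry of the target-foil representational distance
#'
#' Ratio of the embedded distance between the target hue and a foil rotated
#' `foil_delta` degrees toward the attended (away-from-distractor) side to
#' the distance to the mirror foil on the distractor side. With gain applied
#' at `attended_hue != target` the expansion near the attended hue makes the
#' away-side distance larger (ratio > 1), mirroring the behavioral repulsion;
#' with `amplitude = 0` the code is homogeneous and the ratio is exactly 1.
#'
#' @param spec [population_spec()].
#' @param gain [gain_profile()]; its `attended_hue` defines the away side
#'   via the sign of its circular offset from the target.
#' @param target Target hue in degrees (default 0).
#' @param foil_delta Foil offset in degrees (default 10).
#' @param space `"mds"` (distance in the 2-D embedding, default) or
#'   `"response"` (distance in the full population pattern space, an
#'   MDS-free cross-check).
#' @param grid Hue grid used for the embedding.
#' @return Scalar ratio d(target, away foil) / d(target, toward foil).
#' @export
asymmetry_index <- function(spec = population_spec(),
                            gain = gain_profile(attended_hue = 20),
                            target = 0, foil_delta = 10,
                            space = c("mds", "response"), grid = 0:359) {
  space <- match.arg(space)
  off <- ((gain$attended_hue - target + 180) %% 360) - 180
  if (gain$amplitude > 0 && off == 0) {
    stop("attended_hue must be off the target for the asymmetry to be defined")
  }
  side <- if (off >= 0) 1 else -1
  h_away <- rotate_hue(target, side * foil_delta)
  h_toward <- rotate_hue(target, -side * foil_delta)
  if (space == "response") {
    r0 <- population_response(target, spec, gain)
    ra <- population_response(h_away, spec, gain)
    rt <- population_response(h_toward, spec, gain)
    return(sqrt(sum((r0 - ra)^2)) / sqrt(sum((r0 - rt)^2)))
  }
  grid <- sort(unique(c(grid %% 360, target %% 360, h_away, h_toward)))
  geo <- representational_geometry(spec, gain, grid = grid,
                                   subsample = max(grid) + 1)
  if (geo$degenerate) stop("degenerate MDS embedding")
  x <- geo$embedding
  i0 <- match(target %% 360, grid)
  ia <- match(h_away, grid)
  it <- match(h_toward, grid)
  sqrt(sum((x[i0, ] - x[ia, ])^2)) / sqrt(sum((x[i0, ] - x[it, ])^2))
}
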