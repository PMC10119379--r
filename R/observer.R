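# Generative signal-detection observer for the 2AFC similarity judgment.
#
# The internal representation of the target hue is displaced by a bias b
# (degrees) in the direction away from the search distractor and corrupted
# by noise of SD sigma. On each 2AFC trial the observer reports whichever
# option (exact target color vs. foil) is closer to a sample from that
# internal distribution; a lapse rate lambda mixes in uniform guessing.
#
# On the locally linearized hue axis (target at 0, away side positive) this
# gives the closed forms
#     P(choose target | away foil)   = (1 - lambda) * Phi((delta/2 - b)/sigma) + lambda/2
#     P(choose target | toward foil) = (1 - lambda) * Phi((delta/2 + b)/sigma) + lambda/2
# so an away foil at delta is chosen as often as the target exactly when
# b = delta/2 -- the chance-point identity used to read the bias off the
# data. A circular variant (wrapped-normal noise, arc-distance decision
# rule) is provided as a check on the linearization.

#' Observer parameters for the generative 2AFC model
#'
#' @param bias Bias `b` in degrees: displacement of the internal target
#'   representation away from the distractor (>= 0 means repulsion).
#' @param noise Noise `sigma` in degrees (> 0): SD of the internal
#'   representation on the hue circle.
#' @param lapse Lapse rate in `[0, 0.5]`: probability of a
#'   stimulus-independent uniform guess.
#' @param bias_by_D Optional named numeric vector mapping target-distractor
#'   distance (as character, e.g. `"30"`) to a bias, overriding `bias`
#'   per condition.
#' @param search_accuracy Optional named numeric vector mapping
#'   target-distractor distance to the probability of a correct visual-search
#'   response (used only to generate the exclusion-filter column). `NULL`
#'   means search is always correct.
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(bias = 5, noise = 8)
#' @export
observer_params <- function(bias = 0, noise = 10, lapse = 0,
                            bias_by_D = NULL, search_accuracy = NULL) {
  stopifnot(is.numeric(noise), length(noise) == 1, noise > 0,
            is.numeric(lapse), length(lapse) == 1, lapse >= 0, lapse <= 0.5,
            is.numeric(bias), length(bias) == 1)
  if (!is.null(bias_by_D)) {
    stopifnot(is.numeric(bias_by_D), !is.null(names(bias_by_D)))
  }
  if (!is.null(search_accuracy)) {
    stopifnot(is.numeric(search_accuracy), !is.null(names(search_accuracy)),
              all(search_accuracy >= 0 & search_accuracy <= 1))
  }
  structure(
    list(bias = bias, noise = noise, lapse = lapse,
         bias_by_D = bias_by_D, search_accuracy = search_accuracy),
    class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("2AFC observer: bias =", x$bias, "deg, noise =", x$noise,
      "deg, lapse =", x$lapse, "\n")
  if (!is.null(x$bias_by_D)) {
    cat("  bias by target-distractor distance:",
        paste0(names(x$bias_by_D), ":", x$bias_by_D, collapse = ", "), "\n")
  }
  invisible(x)
}

# bias applying to a vector of target-distractor distances
.bias_for_D <- function(params, D) {
  if (is.null(params$bias_by_D)) return(rep(params$bias, length(D)))
  key <- as.character(D)
  miss <- setdiff(unique(key[!is.na(key)]), names(params$bias_by_D))
  if (length(miss) > 0) {
    stop("bias_by_D has no entry for target-distractor distance(s): ",
         paste(miss, collapse = ", "))
  }
  unname(params$bias_by_D[key])
}

# P(nearer option is the target) for wrapped-normal noise on the circle
# with an arc-distance decision rule. The set of circle points nearer to
# the target (at 0) than to the foil (at delta_signed) is the half circle
# bounded by the two midpoints delta/2 and delta/2 - 180*sign(delta); the
# wrapped-normal mass over that arc is an exact sum of normal CDF
# differences over wrap copies. (A von Mises of matched circular SD differs
# from the linearized model by up to ~0.007 at sigma = 30 deg purely
# through its shape; the wrapped normal shares the Gaussian shape, keeping
# the circular variant a pure test of the wrap-around geometry.)
.p_target_circular <- function(delta_signed, bias, sigma) {
  lo <- delta_signed / 2 - 180 * sign(delta_signed)
  hi <- delta_signed / 2
  bounds <- sort(c(lo, hi))
  k <- -3:3
  sum(stats::pnorm((bounds[2] + 360 * k - bias) / sigma) -
        stats::pnorm((bounds[1] + 360 * k - bias) / sigma))
}

#' Probability the observer chooses the exact target color
#'
#' Closed-form choice probability of the biased signal-detection observer
#' for a 2AFC between the exact target color and a foil `foil_distance`
#' degrees from it, rotated toward or away from the search distractor.
#'
#' With `model = "linear"` the hue circle is linearized around the target
#' (valid for the small offsets used in the designs); `model = "circular"`
#' wraps the same Gaussian noise onto the circle and replaces the nearer-
#' option rule by arc distance, and agrees with the linear model to within
#' 0.005 for foil distances up to 60 degrees and noise up to 30 degrees.
#'
#' @param foil_distance Foil offset(s) delta in degrees, > 0.
#' @param foil_direction `"toward"` or `"away"` (vectorized).
#' @param params An [observer_params()] object.
#' @param model `"linear"` (default) or `"circular"`.
#' @param D Optional target-distractor distance(s), used only to look up a
#'   condition-specific bias when `params$bias_by_D` is set.
#' @return Vector of probabilities of choosing the target.
#' @examples
#' p <- observer_params(bias = 5, noise = 8)
#' p_choose_target(10, "away", p)    # 0.5: foil and target equidistant
#' p_choose_target(10, "toward", p)  # pnorm(10/8), about 0.894
#' @export
p_choose_target <- function(foil_distance, foil_direction, params,
                            model = c("linear", "circular"), D = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(params, "observer_params"))
  if (any(is.na(foil_distance)) || any(foil_distance <= 0)) {
    stop("foil_distance must be positive")
  }
  foil_direction <- match.arg(foil_direction, .foil_directions,
                              several.ok = TRUE)
  k <- max(length(foil_distance), length(foil_direction))
  foil_distance <- rep_len(foil_distance, k)
  foil_direction <- rep_len(foil_direction, k)
  b <- if (is.null(D)) rep(params$bias, k) else rep_len(.bias_for_D(params, D), k)
  # away foil sits on the same side as the bias (positive axis); toward on
  # the opposite side
  sgn <- ifelse(foil_direction == "away", 1, -1)
  p0 <- if (model == "linear") {
    stats::pnorm((foil_distance / 2 - sgn * b) / params$noise)
  } else {
    mapply(function(d, s, bb) {
      .p_target_circular(s * d, bb, params$noise)
    }, foil_distance, sgn, b)
  }
  (1 - params$lapse) * p0 + params$lapse / 2
}

#' Simulate responses for a trial design
#'
#' Generates 2AFC choices from [p_choose_target()] and visual-search
#' correctness from the observer's `search_accuracy` map, per trial. In E3,
#' choices are generated only on similarity-report trials and search
#' responses only on search-report trials; in E4 the toward/away geometry is
#' defined relative to the salient distractor (already encoded in the
#' design's `foil_direction`).
#'
#' @param design Trial table from [design_experiment()].
#' @param params An [observer_params()] object.
#' @param seed Integer seed; the same seed reproduces the responses exactly.
#' @param subject_id Subject label attached to every row.
#' @param model Choice model passed to [p_choose_target()].
#' @return The design with `subject_id`, `choice` (`"target"`/`"foil"`) and
#'   `search_correct` (0/1) columns appended.
#' @export
simulate_dataset <- function(design, params, seed = 1L, subject_id = "s01",
                             model = c("linear", "circular")) {
  model <- match.arg(model)
  stopifnot(nrow(design) >= 1, inherits(params, "observer_params"))
  withr::with_seed(seed, {
    n <- nrow(design)
    kind <- design$trial_kind
    has_choice <- kind %in% c("combined", "similarity_report")
    has_search <- kind %in% c("combined", "search_report")

    choice <- rep(NA_character_, n)
    if (any(has_choice)) {
      p <- p_choose_target(design$foil_distance[has_choice],
                           design$foil_direction[has_choice],
                           params, model = model,
                           D = design$target_distractor_distance[has_choice])
      choice[has_choice] <- ifelse(stats::rbinom(sum(has_choice), 1, p) == 1,
                                   "target", "foil")
    }

    search_correct <- rep(NA_integer_, n)
    if (any(has_search)) {
      D <- design$target_distractor_distance[has_search]
      p_search <- if (is.null(params$search_accuracy)) {
        rep(1, sum(has_search))
      } else {
        key <- as.character(D)
        miss <- setdiff(unique(key), names(params$search_accuracy))
        if (length(miss) > 0) {
          stop("search_accuracy has no entry for distance(s): ",
               paste(miss, collapse = ", "))
        }
        unname(params$search_accuracy[key])
      }
      search_correct[has_search] <- stats::rbinom(sum(has_search), 1, p_search)
    }

    out <- design
    out$subject_id <- subject_id
    out$choice <- choice
    out$search_correct <- search_correct
    out[, c("subject_id", setdiff(names(out), "subject_id"))]
  })
}

#' Distribution of observer parameters across a simulated cohort
#'
#' Subject-level parameters are drawn independently: bias from a normal
#' truncated at zero (repulsion only), noise from a normal truncated below
#' at `noise_min`, lapse fixed. A `bias_by_D_mean` map makes the bias
#' condition-specific, each entry jittered by `bias_sd` and truncated at 0.
#'
#' @param bias_mean,bias_sd Mean and between-subject SD of the bias (deg).
#' @param noise_mean,noise_sd Mean and SD of the noise (deg).
#' @param lapse Shared lapse rate.
#' @param bias_by_D_mean Optional named vector of per-distance mean biases.
#' @param search_accuracy Passed to each subject's [observer_params()].
#' @param noise_min Lower truncation for noise draws (default 1 deg).
#' @return An object of class `cohort_distribution`.
#' @export
cohort_distribution <- function(bias_mean = 0, bias_sd = 0,
                                noise_mean = 10, noise_sd = 0, lapse = 0,
                                bias_by_D_mean = NULL,
                                search_accuracy = NULL, noise_min = 1) {
  stopifnot(bias_sd >= 0, noise_sd >= 0, noise_mean > 0, noise_min > 0,
            lapse >= 0, lapse <= 0.5)
  structure(
    list(bias_mean = bias_mean, bias_sd = bias_sd, noise_mean = noise_mean,
         noise_sd = noise_sd, lapse = lapse,
         bias_by_D_mean = bias_by_D_mean,
         search_accuracy = search_accuracy, noise_min = noise_min),
    class = "cohort_distribution")
}

.rtrunc_normal <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lower)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Simulate a multi-subject cohort
#'
#' Draws per-subject observer parameters from a [cohort_distribution()] and
#' simulates each subject on (a fresh shuffle of) the given design. With all
#' between-subject SDs at zero every subject shares the same parameters.
#'
#' @param n_observers Number of subjects (>= 1).
#' @param design Trial design; each subject gets an independently sampled
#'   realization when `redesign = TRUE` (default), otherwise the identical
#'   trial list.
#' @param dist A [cohort_distribution()] (an [observer_params()] object is
#'   also accepted and shared by all subjects).
#' @param seed Integer seed for the whole cohort.
#' @param experiment Used with `redesign = TRUE` to regenerate the design;
#'   defaults to the design's own experiment label.
#' @param redesign Resample stimulus hues per subject (as in the real task,
#'   where every participant saw their own random colors).
#' @param model Choice model passed through to [simulate_dataset()].
#' @return Row-bound trial table with per-subject `subject_id`; the drawn
#'   subject parameters are attached as attribute `"subject_params"`.
#' @export
simulate_cohort <- function(n_observers, design, dist, seed = 1L,
                            experiment = NULL, redesign = TRUE,
                            model = c("linear", "circular")) {
  model <- match.arg(model)
  stopifnot(n_observers >= 1)
  if (inherits(dist, "observer_params")) {
    dist <- cohort_distribution(
      bias_mean = dist$bias, noise_mean = dist$noise, lapse = dist$lapse,
      bias_by_D_mean = dist$bias_by_D, search_accuracy = dist$search_accuracy)
  }
  stopifnot(inherits(dist, "cohort_distribution"))
  if (is.null(experiment)) experiment <- design$experiment[1]
  withr::with_seed(seed, {
    subj_seeds <- sample.int(.Machine$integer.max, 2 * n_observers)
    biases <- .rtrunc_normal(n_observers, dist$bias_mean, dist$bias_sd, 0)
    noises <- .rtrunc_normal(n_observers, dist$noise_mean, dist$noise_sd,
                             dist$noise_min)
    bias_maps <- if (is.null(dist$bias_by_D_mean)) {
      replicate(n_observers, NULL, simplify = FALSE)
    } else {
      lapply(seq_len(n_observers), function(i) {
        m <- .rtrunc_normal(length(dist$bias_by_D_mean),
                            dist$bias_by_D_mean, dist$bias_sd, 0)
        names(m) <- names(dist$bias_by_D_mean)
        m
      })
    }
  })
  ids <- sprintf("s%02d", seq_len(n_observers))
  params_list <- lapply(seq_len(n_observers), function(i) {
    observer_params(bias = biases[i], noise = noises[i], lapse = dist$lapse,
                    bias_by_D = bias_maps[[i]],
                    search_accuracy = dist$search_accuracy)
  })
  tabs <- lapply(seq_len(n_observers), function(i) {
    des_i <- if (redesign) {
      design_experiment(experiment, seed = subj_seeds[2 * i - 1])
    } else {
      design
    }
    simulate_dataset(des_i, params_list[[i]], seed = subj_seeds[2 * i],
                     subject_id = ids[i], model = model)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  names(params_list) <- ids
  attr(out, "subject_params") <- params_list
  out
}
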