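# Deterministic generators for the trial designs of the four experiments:
# oddball visual search on the color wheel followed by a 2AFC similarity
# judgment between the exact target color and a nearby foil.
#
# Display constants not needed for any analysis (recorded here for
# completeness, not modelled): placeholders 800 ms; search array 200 ms
# (400 ms in E4); 8 items of 80 px at 260 px eccentricity (7 items in E4);
# 2AFC squares 80 x 80 px left/right of fixation.

.experiments <- c("E1", "E2", "E3", "E4")
.foil_directions <- c("toward", "away")
.distractor_directions <- c("cw", "ccw")

# Condition cells with repetition counts, one row per design cell.
experiment_cells <- function(experiment) {
  switch(experiment,
    E1 = {
      cells <- expand.grid(
        target_distractor_distance = c(15, 30, 45, 60, 90, 180),
        foil_direction = .foil_directions,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
      )
      cells$foil_distance <- 10
      cells$trial_kind <- "combined"
      cells$n_reps <- 25
      cells
    },
    E2 = {
      cells <- expand.grid(
        target_distractor_distance = c(30, 60, 180),
        foil_distance = c(10, 20, 60, 180),
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
      )
      cells$foil_direction <- "away"
      cells$trial_kind <- "combined"
      cells$n_reps <- 36
      cells
    },
    E3 = {
      search <- data.frame(
        target_distractor_distance = c(30, 180),
        foil_distance = NA_real_,
        foil_direction = NA_character_,
        trial_kind = "search_report",
        n_reps = 72
      )
      sim <- expand.grid(
        target_distractor_distance = c(30, 180),
        foil_direction = .foil_directions,
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
      )
      sim$foil_distance <- 10
      sim$trial_kind <- "similarity_report"
      sim$n_reps <- 36
      rbind(search, sim[, names(search)])
    },
    E4 = {
      data.frame(
        target_distractor_distance = 30,
        foil_distance = 10,
        foil_direction = .foil_directions,
        trial_kind = "combined",
        n_reps = 120
      )
    },
    stop("unknown experiment label: ", experiment)
  )
}

# Balanced cw/ccw assignment for n trials. An odd remainder gets `extra`;
# callers alternate `extra` across cells so the full design balances
# exactly even when single cells cannot (e.g. 25 repetitions).
.balanced_directions <- function(n, extra = "cw") {
  half <- n %/% 2
  dirs <- rep(.distractor_directions, c(half, half))
  if (n %% 2 == 1) dirs <- c(dirs, extra)
  sample(dirs)
}

#' Generate the full trial design for one experiment
#'
#' Builds the complete condition crossing with the stated repetition counts,
#' balances the distractor rotation direction (and, for E4, the salient-side
#' direction) within each cell, shuffles trial order, and samples per-trial
#' stimulus colors. The result is reproducible: the same seed yields a
#' bitwise-identical table.
#'
#' The four experiments are:
#' \describe{
#'   \item{E1}{300 trials; target-distractor distance D in
#'     \{15, 30, 45, 60, 90, 180\} degrees crossed with a 10-degree foil
#'     rotated toward or away from the distractor, 25 repetitions per cell.}
#'   \item{E2}{432 trials; D in \{30, 60, 180\} crossed with foil distance
#'     \{10, 20, 60, 180\}, always rotated away, 36 per cell.}
#'   \item{E3}{288 trials; 144 search-report and 144 similarity-report
#'     trials, D in \{30, 180\}; similarity trials cross D with a 10-degree
#'     toward/away foil (36 per cell). Trial kinds are interleaved at random.}
#'   \item{E4}{240 trials; distractors at 30 degrees on *both* sides of the
#'     target (7-item array), one side made salient (balanced cw/ccw); the
#'     10-degree foil is rotated toward or away from the salient distractor,
#'     120 trials per direction.}
#' }
#'
#' @param experiment One of `"E1"`, `"E2"`, `"E3"`, `"E4"`.
#' @param seed Integer seed controlling trial order and stimulus sampling.
#' @return A data frame, one row per trial, with condition columns
#'   (`experiment`, `trial_index`, `target_distractor_distance`,
#'   `distractor_direction`, `foil_distance`, `foil_direction`,
#'   `trial_kind`, `salient_direction`) and stimulus columns
#'   (`target_hue`, `distractor_hue`, `foil_hue`, `target_position`,
#'   `set_size`, `foil_side`).
#' @examples
#' d1 <- design_experiment("E1", seed = 1)
#' nrow(d1)                                   # 300
#' table(d1$target_distractor_distance, d1$foil_direction)  # 25 per cell
#' @export
design_experiment <- function(experiment, seed = 1L) {
  experiment <- match.arg(experiment, .experiments)
  cells <- experiment_cells(experiment)
  withr::with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      cell <- cells[i, ]
      n <- cell$n_reps
      out <- cell[rep(1L, n), setdiff(names(cell), "n_reps"), drop = FALSE]
      extra <- .distractor_directions[(i %% 2) + 1]
      if (experiment == "E4") {
        # distractors appear on both sides; the balanced factor is which
        # side is salient
        out$distractor_direction <- NA_character_
        out$salient_direction <- .balanced_directions(n, extra)
      } else {
        out$distractor_direction <- .balanced_directions(n, extra)
        out$salient_direction <- "none"
      }
      out
    }))
    rows <- rows[sample(nrow(rows)), , drop = FALSE]
    rows$experiment <- experiment
    rows$trial_index <- seq_len(nrow(rows))
    rownames(rows) <- NULL
    sample_trial_colors(rows)
  })
}

#' Sample stimulus colors for a table of trial conditions
#'
#' Draws a uniform target hue from the 360-color wheel for each row, places
#' the distractor at the row's target-distractor distance in its rotation
#' direction, the foil at the foil distance on the toward/away side, and
#' randomizes target position in the array and the 2AFC left/right placement.
#' Consumes the current RNG stream; call inside `withr::with_seed()` (as
#' [design_experiment()] does) for reproducibility.
#'
#' Sign convention: counterclockwise (`"ccw"`) offsets are positive degrees.
#' A `"toward"` foil lies on the same side of the target as the (salient)
#' distractor; `"away"` lies on the opposite side. At D = 180 the two
#' rotation directions are physically identical; the recorded label is the
#' balanced assignment.
#'
#' @param conditions Data frame with at least `experiment`,
#'   `target_distractor_distance`, `distractor_direction`, `foil_distance`,
#'   `foil_direction`, `trial_kind`, `salient_direction`.
#' @return The input with `target_hue`, `distractor_hue`, `foil_hue`,
#'   `target_position`, `set_size`, `foil_side` columns appended.
#' @export
sample_trial_colors <- function(conditions) {
  n <- nrow(conditions)
  stopifnot(n >= 1)
  set_size <- ifelse(conditions$experiment == "E4", 7L, 8L)
  target_hue <- sample(0:359, n, replace = TRUE)
  dir_chr <- ifelse(conditions$experiment == "E4",
                    conditions$salient_direction,
                    conditions$distractor_direction)
  dir_sign <- ifelse(dir_chr == "ccw", 1, -1)
  distractor_hue <- rotate_hue(
    target_hue, dir_sign * conditions$target_distractor_distance)
  foil_sign <- ifelse(conditions$foil_direction == "toward", 1, -1)
  foil_hue <- rotate_hue(
    target_hue, foil_sign * dir_sign * conditions$foil_distance)
  foil_hue[is.na(conditions$foil_distance)] <- NA_real_

  conditions$target_hue <- target_hue
  conditions$distractor_hue <- distractor_hue
  conditions$foil_hue <- foil_hue
  conditions$target_position <-
    vapply(set_size, function(k) sample.int(k, 1), integer(1))
  conditions$set_size <- set_size
  conditions$foil_side <- ifelse(
    is.na(conditions$foil_distance), NA_character_,
    sample(c("left", "right"), n, replace = TRUE))
  conditions[, c(
    "experiment", "trial_index", "trial_kind",
    "target_distractor_distance", "distractor_direction",
    "foil_distance", "foil_direction", "salient_direction",
    "target_hue", "distractor_hue", "foil_hue",
    "target_position", "set_size", "foil_side"
  )]
}
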