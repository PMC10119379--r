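# Analysis stage: d-prime summaries of the 2AFC data, maximum-likelihood
# fitting of the bias model, and the chance-point bias inference.

#' 2AFC sensitivity (d-prime)
#'
#' Standard unbiased-2AFC convention: `sqrt(2) * qnorm(p)` with the observed
#' proportion of target choices clamped to `[1/(2n), 1 - 1/(2n)]` so that
#' perfect cells stay finite. Negative values mean the foil was preferred.
#'
#' @param n_target_chosen Count of trials on which the target was chosen.
#' @param n_trials Total 2AFC trials (>= 1). Vectorized.
#' @return d-prime value(s).
#' @examples
#' dprime_2afc(13, 26)  # 0 at chance
#' dprime_2afc(21, 25)  # sqrt(2) * qnorm(0.84)
#' @export
dprime_2afc <- function(n_target_chosen, n_trials) {
  if (any(n_trials < 1)) stop("n_trials must be >= 1")
  stopifnot(all(n_target_chosen >= 0), all(n_target_chosen <= n_trials))
  p <- n_target_chosen / n_trials
  p <- pmin(pmax(p, 1 / (2 * n_trials)), 1 - 1 / (2 * n_trials))
  sqrt(2) * stats::qnorm(p)
}

.cell_keys <- c("experiment", "target_distractor_distance",
                "foil_distance", "foil_direction")

#' Summarize 2AFC performance by design cell
#'
#' Tabulates, per design cell (target-distractor distance x foil distance x
#' foil direction), the number of similarity trials, the count and
#' proportion of target choices, and d-prime. Search-only rows (E3
#' search-report trials) are not 2AFC observations and do not form cells;
#' cells present in the design whose choices were all removed are reported
#' with `n_trials = 0` and `NA` d-prime rather than dropped. Output order is
#' canonical (sorted by keys), so row order of the input is irrelevant.
#'
#' @param data Trial table in the shared schema (see [read_trials()]), with
#'   `choice` responses.
#' @param by_subject Summarize per subject (`TRUE`) or pooled over subjects
#'   (`FALSE`, the default, mirroring group-level fits).
#' @return Data frame of class `condition_summary` with columns
#'   `subject_id` (or `"pooled"`), the cell keys, `n_trials`,
#'   `n_target_chosen`, `p_target`, `dprime`.
#' @export
condition_summary <- function(data, by_subject = FALSE) {
  need <- c(.cell_keys, "trial_kind", "choice")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  afc <- data[data$trial_kind %in% c("combined", "similarity_report"), ,
              drop = FALSE]
  if (nrow(afc) == 0) stop("no similarity-judgment trials in data")
  afc$subject_id <- if (by_subject) afc$subject_id else "pooled"
  keys <- c("subject_id", .cell_keys)
  answered <- !is.na(afc$choice)
  tab <- data.frame(afc[, keys, drop = FALSE],
                    n_trials = as.integer(answered),
                    n_target_chosen = as.integer(afc$choice %in% "target"))
  agg <- stats::aggregate(cbind(n_trials, n_target_chosen) ~
                            subject_id + experiment +
                            target_distractor_distance + foil_distance +
                            foil_direction,
                          data = tab, FUN = sum, na.action = stats::na.pass)
  agg <- agg[do.call(order, agg[keys]), , drop = FALSE]
  agg$p_target <- ifelse(agg$n_trials > 0,
                         agg$n_target_chosen / agg$n_trials, NA_real_)
  agg$dprime <- NA_real_
  ok <- agg$n_trials > 0
  agg$dprime[ok] <- dprime_2afc(agg$n_target_chosen[ok], agg$n_trials[ok])
  rownames(agg) <- NULL
  class(agg) <- c("condition_summary", "data.frame")
  agg
}

# Stable binomial log-likelihood: k*log(p) + (n-k)*log(1-p) with the
# convention 0 * log(0) = 0; discordant counts at a degenerate p give -Inf.
.binom_ll <- function(k, n, p) {
  ll <- numeric(length(k))
  t1 <- ifelse(k > 0, k * log(p), 0)
  t2 <- ifelse(n - k > 0, (n - k) * log1p(-p), 0)
  ll <- t1 + t2
  ll
}

#' Negative log-likelihood of the bias model on cell summaries
#'
#' Sum over cells of the binomial negative log-likelihood of the observed
#' target-choice counts under [p_choose_target()] evaluated at the given
#' observer parameters. A degenerate predicted probability (0 or 1) with
#' discordant counts yields `Inf`, flagged via attribute `"degenerate"`.
#'
#' @param params [observer_params()]; a `bias_by_D` map makes the bias
#'   condition-specific.
#' @param summaries A [condition_summary()] table (or any data frame with
#'   `target_distractor_distance`, `foil_distance`, `foil_direction`,
#'   `n_trials`, `n_target_chosen`).
#' @param model Choice model.
#' @return Negative log-likelihood in nats.
#' @export
negative_loglik <- function(params, summaries,
                            model = c("linear", "circular")) {
  model <- match.arg(model)
  s <- summaries[summaries$n_trials > 0, , drop = FALSE]
  p <- p_choose_target(s$foil_distance, s$foil_direction, params,
                       model = model, D = s$target_distractor_distance)
  ll <- .binom_ll(s$n_target_chosen, s$n_trials, p)
  out <- -sum(ll)
  if (!is.finite(out)) attr(out, "degenerate") <- TRUE
  out
}

# coerce trial table -> pooled summaries if needed
.as_summaries <- function(data, by_subject = FALSE) {
  if ("choice" %in% names(data) && !"n_trials" %in% names(data)) {
    condition_summary(data, by_subject = by_subject)
  } else {
    stopifnot(all(c("target_distractor_distance", "foil_distance",
                    "foil_direction", "n_trials", "n_target_chosen")
                  %in% names(data)))
    data
  }
}

#' Fit the bias model by maximum likelihood
#'
#' Fits the biased signal-detection observer to pooled 2AFC counts: a bias
#' per target-distractor distance (or one shared bias), a shared noise SD,
#' and an optionally free lapse rate. The optimizer is deterministic: a
#' coarse grid (`b` in `[0, 30]` by 1 degree, `sigma` in `[2, 40]` by 2 —
#' the per-distance bias profile is optimized cell-block by cell-block at
#' each grid `sigma`) seeds a Nelder-Mead refinement on the unconstrained
#' scale (`b` free-signed, `log sigma`, logit lapse).
#'
#' @param data Trial table (pooled internally) or a cell-summary table.
#' @param bias_per_D One bias per target-distractor distance (`TRUE`,
#'   default, with D = 180 free and expected near 0) or a single shared bias.
#' @param lambda Fixed lapse rate used when `lambda_free = FALSE`.
#' @param lambda_free Estimate the lapse rate.
#' @param b_fixed Optional: hold every bias fixed at this value (e.g. 0 for
#'   the null model of a likelihood-ratio test) and fit only the remaining
#'   parameters.
#' @param model Choice model.
#' @param grid_b,grid_sigma Grid-search seeds.
#' @return Object of class `bias_fit`: `estimates` (named `bias[<D>]` or
#'   `bias`, `sigma`, `lambda`), `loglik`, `n_params`, `aic`, `converged`,
#'   `boundary` flag, and `predicted` (per-cell `p_hat`, `dprime_hat`).
#' @examples
#' \donttest{
#' d <- design_experiment("E2", seed = 2)
#' sim <- simulate_dataset(d, observer_params(bias = 10, noise = 9), seed = 3)
#' fit_bias_model(sim)
#' }
#' @export
fit_bias_model <- function(data, bias_per_D = TRUE, lambda = 0,
                           lambda_free = FALSE, b_fixed = NULL,
                           model = c("linear", "circular"),
                           grid_b = seq(0, 30, by = 1),
                           grid_sigma = seq(2, 40, by = 2)) {
  model <- match.arg(model)
  s <- .as_summaries(data)
  s <- s[s$n_trials > 0, , drop = FALSE]
  if (nrow(s) < 2) stop("need at least 2 cells with nonzero trials")

  D_levels <- sort(unique(s$target_distractor_distance))
  n_b <- if (!is.null(b_fixed)) 0L else if (bias_per_D) length(D_levels) else 1L

  mk_params <- function(bvec, sigma, lam) {
    if (!is.null(b_fixed)) {
      observer_params(bias = b_fixed, noise = sigma, lapse = lam)
    } else if (bias_per_D) {
      observer_params(noise = sigma, lapse = lam,
                      bias_by_D = stats::setNames(bvec, D_levels))
    } else {
      observer_params(bias = bvec, noise = sigma, lapse = lam)
    }
  }
  nll_at <- function(bvec, sigma, lam) {
    negative_loglik(mk_params(bvec, sigma, lam), s, model = model)
  }

  # ---- grid seed: the per-D biases separate given sigma -------------------
  lam0 <- lambda
  best <- list(nll = Inf)
  for (sigma in grid_sigma) {
    if (!is.null(b_fixed)) {
      v <- nll_at(NULL, sigma, lam0)
      if (v < best$nll) best <- list(nll = v, b = numeric(0), sigma = sigma)
    } else if (bias_per_D) {
      bvec <- numeric(length(D_levels))
      total <- 0
      for (j in seq_along(D_levels)) {
        sj <- s[s$target_distractor_distance == D_levels[j], , drop = FALSE]
        vals <- vapply(grid_b, function(b) {
          negative_loglik(observer_params(bias = b, noise = sigma,
                                          lapse = lam0),
                          sj, model = model)
        }, numeric(1))
        bvec[j] <- grid_b[which.min(vals)]
        total <- total + min(vals)
      }
      if (total < best$nll) best <- list(nll = total, b = bvec, sigma = sigma)
    } else {
      vals <- vapply(grid_b, function(b) nll_at(b, sigma, lam0), numeric(1))
      if (min(vals) < best$nll) {
        best <- list(nll = min(vals), b = grid_b[which.min(vals)],
                     sigma = sigma)
      }
    }
  }

  # ---- derivative-free refinement ----------------------------------------
  par0 <- c(best$b, log(best$sigma),
            if (lambda_free) stats::qlogis(max(lam0, 0.01)) / 2 else NULL)
  obj <- function(par) {
    bvec <- if (n_b > 0) par[seq_len(n_b)] else numeric(0)
    sigma <- exp(par[n_b + 1])
    lam <- if (lambda_free) stats::plogis(par[n_b + 2]) / 2 else lam0
    v <- nll_at(bvec, sigma, lam)
    if (!is.finite(v)) 1e12 else v
  }
  if (length(par0) == 1) {  # sigma only: 1-D golden-section refinement
    o <- stats::optimize(function(z) obj(z), lower = log(0.5),
                         upper = log(200), tol = 1e-10)
    opt <- list(par = o$minimum, value = o$objective, convergence = 0L)
  } else {
    opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
  }
  converged <- opt$convergence == 0 && opt$value <= best$nll + 1e-6
  if (opt$value > best$nll) {  # fall back to the grid point
    opt$par <- par0
    opt$value <- best$nll
  }
  b_hat <- if (n_b > 0) opt$par[seq_len(n_b)] else numeric(0)
  sigma_hat <- exp(opt$par[n_b + 1])
  lam_hat <- if (lambda_free) stats::plogis(opt$par[n_b + 2]) / 2 else lam0
  boundary <- (n_b > 0 && (any(b_hat <= min(grid_b) - 1e-8) ||
                             any(b_hat >= max(grid_b) - 1e-8))) ||
    sigma_hat <= min(grid_sigma) + 1e-8 || sigma_hat >= max(grid_sigma) - 1e-8

  est <- c(
    if (is.null(b_fixed)) {
      if (bias_per_D) stats::setNames(b_hat, paste0("bias[", D_levels, "]"))
      else c(bias = b_hat)
    } else c(bias_fixed = b_fixed),
    sigma = sigma_hat, lambda = lam_hat)

  params_hat <- mk_params(b_hat, sigma_hat, lam_hat)
  pred <- s[, intersect(c("subject_id", .cell_keys, "n_trials",
                          "n_target_chosen", "p_target", "dprime"),
                        names(s)), drop = FALSE]
  pred$p_hat <- p_choose_target(pred$foil_distance, pred$foil_direction,
                                params_hat, model = model,
                                D = pred$target_distractor_distance)
  # keep reported probabilities (and their d') finite where pnorm saturates
  pred$p_hat <- pmin(pmax(pred$p_hat, 1e-12), 1 - 1e-12)
  pred$dprime_hat <- sqrt(2) * stats::qnorm(pred$p_hat)
  n_params <- n_b + 1L + as.integer(lambda_free)

  structure(
    list(estimates = est, params = params_hat, loglik = -opt$value,
         n_params = n_params, aic = 2 * n_params + 2 * opt$value,
         converged = converged, boundary = boundary,
         predicted = pred, model = model),
    class = "bias_fit")
}

#' @export
print.bias_fit <- function(x, ...) {
  cat("Biased-observer fit (", x$model, " model)\n", sep = "")
  print(round(x$estimates, 3))
  cat("logLik:", round(x$loglik, 2), " AIC:", round(x$aic, 2),
      " converged:", x$converged,
      if (x$boundary) " [boundary estimate]" else "", "\n")
  invisible(x)
}

#' Infer the perceptual bias from a chance-performance condition
#'
#' When the target and an away-rotated foil are chosen equally often, both
#' must be equidistant from the internal target representation, which
#' therefore sits halfway between them: the bias equals half the foil
#' distance. The identity is exact for any symmetric noise distribution and
#' zero lapse, so it holds for both the linear and circular observers.
#'
#' @param foil_distance Foil offset(s) in degrees, >= 0.
#' @return Inferred bias in degrees (`foil_distance / 2`).
#' @examples
#' infer_bias_from_chance(10)  # 5
#' infer_bias_from_chance(20)  # 10
#' @export
infer_bias_from_chance <- function(foil_distance) {
  if (any(foil_distance < 0)) stop("foil_distance must be >= 0")
  foil_distance / 2
}
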