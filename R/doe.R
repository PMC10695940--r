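# Design of experiments over the surgical parameter space, quadratic
# response-surface surrogate, and signed local sensitivities.

#' Optimal space-filling design (maximin Latin hypercube)
#'
#' Emulates an optimal space-filling design: a seeded Latin hypercube start
#' is improved by pairwise coordinate exchanges that increase the minimum
#' pairwise distance in the unit cube, until a full sweep brings no further
#' improvement (capped at `max_sweeps`).  Default design sizes follow the
#' study rule: 25 samples for 4-parameter (two-spring) cases and 27 for
#' 5-parameter (four-spring) cases.
#'
#' @param space a [build_parameter_space()] result.
#' @param n_samples number of design points; default per the 25/27 rule.
#' @param seed integer seed (design is deterministic given the seed).
#' @param max_sweeps cap on exchange-optimization sweeps.
#' @return object of class `doe_design`: `samples` (physical units),
#'   `unit` (optimized unit-cube design), `unit_initial` (the unoptimized
#'   seeded start), `space`, `seed`, `rule`.
#' @export
optimal_space_filling <- function(space, n_samples = NULL, seed = 1L,
                                  max_sweeps = 200L) {
  stopifnot(inherits(space, "parameter_space"))
  k <- nrow(space$bounds)
  if (is.null(n_samples)) n_samples <- if (k >= 5) 27L else 25L
  n_samples <- as.integer(n_samples)
  if (n_samples < k + 1) {
    stop("n_samples must exceed the number of parameters", call. = FALSE)
  }
  unit0 <- with_seed(seed, lhs::randomLHS(n_samples, k))
  unit <- maximin_exchange(unit0, max_sweeps)
  lo <- space$bounds$lower
  hi <- space$bounds$upper
  samples <- sweep(sweep(unit, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(samples) <- space$bounds$name
  colnames(unit) <- colnames(unit0) <- space$bounds$name
  structure(list(samples = samples, unit = unit, unit_initial = unit0,
                 space = space, seed = as.integer(seed),
                 rule = sprintf("maximin-LHS %d x %d", n_samples, k)),
            class = "doe_design")
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("<doe_design> %s (seed %d), min pairwise distance %.3f\n",
              x$rule, x$seed, min_pair_dist(x$unit)))
  invisible(x)
}

min_pair_dist <- function(u) min(stats::dist(u))

# pairwise coordinate-exchange maximin optimization on a unit LHS; swapping
# entries within a column preserves the Latin-hypercube marginals
maximin_exchange <- function(unit, max_sweeps = 200L) {
  n <- nrow(unit)
  D <- as.matrix(stats::dist(unit))
  diag(D) <- Inf
  crit <- min(D)
  for (sweep_i in seq_len(max_sweeps)) {
    improved <- FALSE
    for (col in seq_len(ncol(unit))) {
      for (i in seq_len(n - 1)) {
        for (j in seq((i + 1), n)) {
          cand <- unit
          cand[c(i, j), col] <- cand[c(j, i), col]
          # update only the two affected rows
          Dc <- D
          for (r in c(i, j)) {
            dr <- sqrt(colSums((base::t(cand) - cand[r, ])^2))
            Dc[r, ] <- dr
            Dc[, r] <- dr
          }
          diag(Dc) <- Inf
          if (min(Dc) > crit + 1e-12) {
            unit <- cand
            D <- Dc
            crit <- min(Dc)
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  unit
}

quad_terms <- function(U) {
  k <- ncol(U)
  nm <- colnames(U)
  out <- cbind(`(Intercept)` = rep(1, nrow(U)), U)
  for (i in seq_len(k)) {
    q <- U[, i]^2
    out <- cbind(out, q)
    colnames(out)[ncol(out)] <- paste0(nm[i], "^2")
  }
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq((i + 1), k)) {
        out <- cbind(out, U[, i] * U[, j])
        colnames(out)[ncol(out)] <- paste0(nm[i], ":", nm[j])
      }
    }
  }
  out
}

unit_scale <- function(x, space) {
  lo <- space$bounds$lower
  hi <- space$bounds$upper
  sweep(sweep(x, 2, lo), 2, (hi - lo) / 2, `/`) - 1
}

#' Fit a full quadratic response surface
#'
#' Least-squares fit of a full quadratic polynomial (intercept, linear, pure
#' quadratic and pairwise interaction terms) on parameters scaled to
#' `[-1, 1]`, with leave-one-out R-squared computed from the PRESS residuals.
#'
#' @param design a [optimal_space_filling()] design.
#' @param responses numeric vector of simulated post-expansion ICVs (ml), one
#'   per design row; rows with `NA` responses are dropped from the fit.
#' @return object of class `response_surface` with `coefficients`,
#'   `loo_r2`, `design`, and a `predict()` method.
#' @export
fit_response_surface <- function(design, responses) {
  stopifnot(inherits(design, "doe_design"))
  ok <- is.finite(responses)
  if (length(responses) != nrow(design$samples)) {
    stop("need one response per design row", call. = FALSE)
  }
  U <- unit_scale(design$samples[ok, , drop = FALSE], design$space)
  X <- quad_terms(U)
  y <- responses[ok]
  if (nrow(X) < ncol(X)) {
    stop(sprintf("only %d finite responses for %d quadratic terms",
                 nrow(X), ncol(X)), call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop(sprintf("rank-deficient quadratic basis; collinear terms: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  fitted <- as.numeric(X %*% beta)
  resid <- y - fitted
  hat <- rowSums(qr.Q(qrX)^2)
  press <- resid / pmax(1 - hat, 1e-12)
  tss <- sum((y - mean(y))^2)
  loo_r2 <- if (tss > 0) 1 - sum(press^2) / tss else NA_real_
  structure(list(coefficients = beta, loo_r2 = loo_r2, design = design,
                 responses = responses, n_used = sum(ok)),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> full quadratic, %d terms, %d samples, LOO-R2 = %.4f\n",
              length(x$coefficients), x$n_used, x$loo_r2))
  invisible(x)
}

#' Predict from a response surface
#'
#' @param object a `response_surface`.
#' @param newdata matrix or data frame of parameter values in physical units
#'   (columns in the order of the parameter space).
#' @param ... unused.
#' @return predicted ICV (ml).
#' @export
predict.response_surface <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  U <- unit_scale(newdata, object$design$space)
  colnames(U) <- object$design$space$bounds$name
  as.numeric(quad_terms(U) %*% object$coefficients)
}

#' Signed local sensitivity chart
#'
#' For each surgical parameter, the sensitivity is the predicted ICV change
#' when that parameter traverses its full interval with all others held at
#' the reference configuration, expressed as a percentage of the predicted
#' reference ICV:
#' `S_i = 100 * (yhat(upper_i) - yhat(lower_i)) / yhat(reference)`.
#'
#' @param rs a [fit_response_surface()] result.
#' @param space the [build_parameter_space()] (defaults to the design's).
#' @param reference named vector of parameter values; defaults to the
#'   as-operated baseline stored in the parameter space.
#' @param case_id,procedure optional labels carried into the chart.
#' @return object of class `sensitivity_chart`: data frame `sensitivities`
#'   (parameter, sensitivity_pct) plus the reference used.
#' @export
local_sensitivity <- function(rs, space = NULL, reference = NULL,
                              case_id = NA_character_, procedure = NA_character_) {
  stopifnot(inherits(rs, "response_surface"))
  if (is.null(space)) space <- rs$design$space
  b <- space$bounds
  if (is.null(reference)) reference <- setNames(b$baseline, b$name)
  ref <- reference[b$name]
  if (any(is.na(ref))) stop("reference must cover every parameter", call. = FALSE)
  if (any(ref < b$lower - 1e-9) || any(ref > b$upper + 1e-9)) {
    stop("reference point lies outside the parameter bounds", call. = FALSE)
  }
  y_ref <- predict(rs, matrix(ref, nrow = 1))
  if (!is.finite(y_ref) || y_ref <= 0) {
    stop("predicted reference ICV is not positive; sensitivities undefined",
         call. = FALSE)
  }
  sens <- vapply(seq_len(nrow(b)), function(i) {
    up <- ref; up[i] <- b$upper[i]
    lo <- ref; lo[i] <- b$lower[i]
    100 * (predict(rs, matrix(up, nrow = 1)) - predict(rs, matrix(lo, nrow = 1))) / y_ref
  }, numeric(1))
  structure(list(sensitivities = data.frame(parameter = b$name,
                                            sensitivity_pct = sens,
                                            stringsAsFactors = FALSE),
                 reference = setNames(as.numeric(ref), b$name),
                 y_reference = y_ref,
                 case_id = case_id, procedure = procedure),
            class = "sensitivity_chart")
}

#' @export
print.sensitivity_chart <- function(x, ...) {
  cat(sprintf("<sensitivity_chart> %s %s (reference ICV %.0f ml)\n",
              ifelse(is.na(x$case_id), "", x$case_id),
              ifelse(is.na(x$procedure), "", x$procedure), x$y_reference))
  print(x$sensitivities, row.names = FALSE)
  invisible(x)
}

#' Extreme configurations of a design
#'
#' Identifies the design points with the smallest and largest simulated ICV
#' (ties broken by the lowest row index).
#'
#' @param design a `doe_design`.
#' @param responses simulated ICVs, one per design row.
#' @return list with `min` and `max`, each `list(index =, parameters =,
#'   icv_ml =)`.
#' @export
extreme_configurations <- function(design, responses) {
  stopifnot(inherits(design, "doe_design"))
  if (length(responses) < 1) stop("need at least one response", call. = FALSE)
  imin <- which.min(responses)
  imax <- which.max(responses)
  list(min = list(index = imin, parameters = design$samples[imin, ],
                  icv_ml = responses[imin]),
       max = list(index = imax, parameters = design$samples[imax, ],
                  icv_ml = responses[imax]))
}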