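#' Compare fitted models on the same data
#'
#' Ranks two or more [kin_fit()] results fitted to the same observations by
#' small-sample-corrected Akaike information criterion (AICc), and reports
#' the \eqn{R^2} ordering alongside. The preferred model is the one with the
#' lowest AICc (delta AICc 0).
#'
#' @param ... [kin_fit()] objects, or a single list of them.
#' @return an object of class `kin_model_comparison`: a data frame `ranked`
#'   with columns `model_id`, `r_squared`, `aicc`, `delta_aicc`, plus the
#'   `preferred` model id.
#' @examples
#' x <- c(10, 25, 50, 100, 200, 400, 800, 1600, 2500)
#' y <- rate_hill(x, 4.65, 278, 1.76)
#' compare_models(kin_fit(x, y, "hill"), kin_fit(x, y, "michaelis"))
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "kin_fit"))
    fits <- fits[[1]]
  if (!all(vapply(fits, inherits, logical(1), "kin_fit")))
    stop("all arguments must be kin_fit objects")
  n <- vapply(fits, `[[`, numeric(1), "n_obs")
  if (length(unique(n)) != 1L)
    stop("fits were made on differing numbers of observations")
  ranked <- data.frame(
    model_id = vapply(fits, `[[`, character(1), "model_id"),
    r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE)
  ranked <- ranked[order(ranked$aicc, ranked$model_id), , drop = FALSE]
  ranked$delta_aicc <- ranked$aicc - ranked$aicc[1]
  rownames(ranked) <- NULL
  structure(list(ranked = ranked, preferred = ranked$model_id[1],
                 fits = stats::setNames(
                   fits, vapply(fits, `[[`, character(1), "model_id"))),
            class = "kin_model_comparison")
}

#' @export
print.kin_model_comparison <- function(x, ...) {
  cat("Model comparison (preferred:", x$preferred, ")\n")
  print(x$ranked, digits = 5)
  invisible(x)
}

#' Case-resampling bootstrap confidence intervals
#'
#' Refits the model to `n_boot` case resamples of the data and returns
#' percentile intervals per parameter. Degenerate resamples (too few
#' distinct abscissa values, or a failed refit) are skipped and counted.
#' Deterministic under a fixed seed.
#'
#' @param fit a converged [kin_fit()] result.
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param level confidence level (default 0.9).
#' @param seed integer seed.
#' @return object of class `kin_boot`: matrix `intervals` (rows = parameters,
#'   columns lower/upper), the point `estimates`, the bootstrap `draws`, and
#'   `n_skipped`.
#' @export
bootstrap_ci <- function(fit, n_boot = 500, level = 0.9, seed = 1) {
  stopifnot(inherits(fit, "kin_fit"))
  if (n_boot < 100) stop("n_boot must be >= 100")
  x <- fit$data$x; y <- fit$data$y
  p <- length(fit$estimates)
  draws <- local_seed(seed, {
    idx <- replicate(n_boot, sample.int(length(x), replace = TRUE),
                     simplify = FALSE)
    lapply(idx, function(i) {
      if (length(unique(x[i])) < p + 1) return(NULL)
      f <- tryCatch(
        kin_fit(x[i], y[i], fit$model_id, start = fit$estimates,
                n_starts = 3, seed = 1),
        error = function(e) NULL)
      if (is.null(f) || !f$converged) NULL else f$estimates
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  mat <- do.call(rbind, draws[ok])
  a <- (1 - level) / 2
  ints <- t(apply(mat, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE))
  colnames(ints) <- c("lower", "upper")
  structure(list(intervals = ints, estimates = fit$estimates, draws = mat,
                 n_skipped = sum(!ok), level = level, seed = seed),
            class = "kin_boot")
}

#' @export
print.kin_boot <- function(x, ...) {
  cat(sprintf("Bootstrap %d%% percentile intervals (%d resamples kept, %d skipped)\n",
              round(x$level * 100), nrow(x$draws), x$n_skipped))
  print(cbind(estimate = x$estimates, x$intervals), digits = 4)
  invisible(x)
}

#' Classify cooperativity from a fitted Hill coefficient
#'
#' A reproducible rule for the verbal classification of cooperativity:
#' `"none"` when the estimate lies within two standard errors of 1,
#' otherwise `"positive"` (n > 1) or `"negative"` (n < 1).
#'
#' @param n_estimate fitted Hill coefficient.
#' @param std_error its standard error (>= 0).
#' @return one of `"positive"`, `"none"`, `"negative"`.
#' @examples
#' classify_cooperativity(1.76, 0.19)  # positive
#' classify_cooperativity(0.99, 0.18)  # none
#' @export
classify_cooperativity <- function(n_estimate, std_error) {
  if (is.na(std_error) || std_error < 0) stop("std_error must be >= 0")
  if (abs(n_estimate - 1) <= 2 * std_error) "none"
  else if (n_estimate > 1) "positive" else "negative"
}
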