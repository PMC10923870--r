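#' Fit a kinetic or binding model by bounded multi-start least squares
#'
#' Nonlinear least-squares estimation for any model in [kin_models()],
#' using bounded Levenberg-Marquardt (via \pkg{minpack.lm}) restarted from
#' `n_starts` seeded initial points (the data-driven heuristic start plus
#' log-normal jitters of it). The best converged solution by residual sum of
#' squares is kept. The returned object carries parameter estimates,
#' asymptotic standard errors, \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, AICc,
#' residuals and a convergence flag; an optimiser failure yields
#' `converged = FALSE` rather than an error.
#'
#' @param x abscissa values (concentration in uM, or time in s). Alternatively
#'   a data frame with columns `x` and `y`.
#' @param y observed responses (omit when `x` is a data frame).
#' @param model model id, see [kin_models()].
#' @param start optional named vector of starting values (replaces the
#'   heuristic start; jittered restarts are still added).
#' @param lower,upper optional named vectors overriding default bounds.
#' @param n_starts number of optimiser starts (default 20).
#' @param seed integer seed for the restart jitter (default 1; fitting is
#'   deterministic given the seed).
#' @param weights `"none"` (unweighted sum of squares, the default) or
#'   `"inv_y2"` for \eqn{1/y^2} relative weighting.
#' @return an object of class `kin_fit` with components `model_id`,
#'   `estimates`, `std_errors`, `r_squared`, `aicc`, `residuals`, `fitted`,
#'   `converged`, `n_obs`, `seed`, `data`.
#' @examples
#' x <- c(25, 50, 100, 200, 400, 800, 1600, 2500)
#' y <- rate_hill(x, vmax = 4.65, k_half = 278, n_hill = 1.76)
#' fit <- kin_fit(x, y, "hill")
#' coef(fit)
#' @seealso [compare_models()], [bootstrap_ci()], [classify_cooperativity()]
#' @export
kin_fit <- function(x, y = NULL, model, start = NULL, lower = NULL,
                    upper = NULL, n_starts = 20, seed = 1,
                    weights = c("none", "inv_y2")) {
  weights <- match.arg(weights)
  if (is.data.frame(x)) {
    if (!all(c("x", "y") %in% names(x)))
      stop("data frame input must have columns 'x' and 'y'")
    y <- x$y
    x <- x$x
  }
  m <- get_model(model)
  if (length(x) != length(y)) stop("x and y must have the same length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  p <- length(m$par)
  if (length(x) < p + 1)
    stop(sprintf("need at least %d observations to fit '%s'", p + 1, model))
  if (length(unique(x)) < 2) stop("all x values are identical")
  if (any(x < 0)) stop("x values must be non-negative")

  lo <- m$lower; hi <- m$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  init0 <- m$init(x, y)
  if (!is.null(start)) {
    if (!all(m$par %in% names(start)))
      stop("start must name all parameters: ", paste(m$par, collapse = ", "))
    init0 <- start[m$par]
  }
  init0 <- pmin(pmax(init0, lo), hi)

  wts <- if (weights == "inv_y2") 1 / pmax(abs(y), 1e-12)^2 else rep(1, length(y))
  sw <- sqrt(wts)
  resid_fn <- function(par) {
    par <- stats::setNames(par, m$par)
    r <- sw * (y - m$fn(x, par))
    r[!is.finite(r)] <- 1e10
    r
  }

  starts <- list(init0)
  if (n_starts > 1) {
    jit <- local_seed(seed, {
      lapply(seq_len(n_starts - 1), function(i)
        init0 * exp(stats::rnorm(p, 0, 0.5)))
    })
    starts <- c(starts, lapply(jit, function(s) {
      s <- stats::setNames(s, m$par)
      # signed/baseline parameters jitter additively instead
      neg <- lo < 0
      s[neg] <- init0[neg] + stats::rnorm(sum(neg), 0, abs(init0[neg]) + 1)
      pmin(pmax(s, lo), hi)
    }))
  }

  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = s0, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }

  n <- length(y)
  if (is.null(best)) {
    return(structure(list(model_id = model, estimates = init0,
                          std_errors = rep(NA_real_, p), r_squared = NA_real_,
                          aicc = NA_real_, residuals = rep(NA_real_, n),
                          fitted = rep(NA_real_, n), converged = FALSE,
                          n_obs = n, seed = seed,
                          data = list(x = x, y = y, weights = wts)),
                     class = "kin_fit"))
  }

  est <- stats::setNames(best$par, m$par)
  est <- sort_phases(model, est)
  fitted <- m$fn(x, est)
  resid <- y - fitted
  rss <- sum(wts * resid^2)
  sst <- sum(wts * (y - stats::weighted.mean(y, wts))^2)
  r2 <- 1 - rss / sst
  k <- p + 1  # parameters + error variance
  aicc <- n * log(rss / n) + 2 * k +
    if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf

  # asymptotic SEs from a freshly computed central-difference Jacobian at
  # the solution (the optimiser's internal approximation can be badly
  # scaled on long, well-determined datasets)
  se <- rep(NA_real_, p)
  ok <- tryCatch({
    J <- matrix(0, n, p)
    for (q in seq_len(p)) {
      h <- max(abs(est[q]) * 1e-6, 1e-10)
      up <- est; up[q] <- up[q] + h
      dn <- est; dn[q] <- dn[q] - h
      J[, q] <- sw * (m$fn(x, up) - m$fn(x, dn)) / (2 * h)
    }
    qrJ <- qr(J)
    covm <- chol2inv(qr.R(qrJ)) * rss / max(n - p, 1)
    se <- sqrt(pmax(diag(covm), 0))
    TRUE
  }, error = function(e) FALSE)
  se <- stats::setNames(se, names(est))

  structure(list(model_id = model, estimates = est, std_errors = se,
                 r_squared = r2, aicc = aicc, residuals = resid,
                 fitted = fitted,
                 converged = best$info %in% 1:4, n_obs = n, seed = seed,
                 data = list(x = x, y = y, weights = wts)),
            class = "kin_fit")
}

# canonicalise the two-phase transient: fast phase first
sort_phases <- function(model, est) {
  if (model == "exp2" && est[["k1"]] < est[["k2"]]) {
    est[c("k1", "k2", "amp1", "amp2")] <- est[c("k2", "k1", "amp2", "amp1")]
  }
  est
}

# run expr with a temporary RNG state; restores the caller's state
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("Model '%s' fit (%d observations)%s\n", x$model_id, x$n_obs,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  est <- format(signif(x$estimates, 5))
  se <- format(signif(x$std_errors, 3))
  cat(paste0("  ", names(x$estimates), " = ", est, " (se ", se, ")",
             collapse = "\n"), "\n")
  cat(sprintf("  R-squared = %.4f, AICc = %.2f\n", x$r_squared, x$aicc))
  invisible(x)
}

#' @export
coef.kin_fit <- function(object, ...) object$estimates

#' @export
residuals.kin_fit <- function(object, ...) object$residuals

#' @export
fitted.kin_fit <- function(object, ...) object$fitted

#' @export
predict.kin_fit <- function(object, newdata = NULL, ...) {
  m <- get_model(object$model_id)
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else newdata
  m$fn(x, object$estimates)
}

#' @export
summary.kin_fit <- function(object, ...) {
  out <- object
  sigma <- sqrt(sum(object$residuals^2) /
                max(object$n_obs - length(object$estimates), 1))
  out$sigma <- sigma
  if ("n_hill" %in% names(object$estimates)) {
    out$cooperativity <- classify_cooperativity(
      object$estimates[["n_hill"]], object$std_errors[["n_hill"]])
  }
  class(out) <- c("summary.kin_fit", "kin_fit")
  out
}

#' @export
print.summary.kin_fit <- function(x, ...) {
  print.kin_fit(x)
  cat(sprintf("  residual sigma = %.4g\n", x$sigma))
  if (!is.null(x$cooperativity))
    cat(sprintf("  cooperativity: %s\n", x$cooperativity))
  invisible(x)
}

#' @export
plot.kin_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$x, d$y, xlab = "x", ylab = "response",
                 main = sprintf("'%s' fit", x$model_id), ...)
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  graphics::lines(xs, predict(x, xs), col = "red")
  invisible(x)
}

#' Simulate responses from a fitted model
#'
#' Parametric simulation: draws Gaussian noise with the residual standard
#' deviation around the fitted curve, at the fitted design points.
#'
#' @param object a [kin_fit()] result.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return data frame with `nsim` simulated response columns alongside `x`.
#' @export
simulate.kin_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sigma <- sqrt(sum(object$residuals^2) /
                max(object$n_obs - length(object$estimates), 1))
  sims <- local_seed(if (is.null(seed)) 1 else seed, {
    replicate(nsim, object$fitted + stats::rnorm(object$n_obs, 0, sigma))
  })
  out <- data.frame(x = object$data$x, sims)
  names(out) <- c("x", paste0("sim_", seq_len(nsim)))
  out
}

#' @export
vcov.kin_fit <- function(object, ...) {
  se <- object$std_errors
  diag(se^2, nrow = length(se))
}
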