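# representative generative parameter ranges per model, used for the
# exact-data recovery property
draw_params <- function(model) {
  switch(model,
    michaelis = c(vmax = runif(1, 0.5, 10), km = 10^runif(1, -0.5, 2.5)),
    substrate_inhibition = {
      km <- 10^runif(1, -0.5, 1.5)
      c(vmax = runif(1, 0.5, 10), km = km, ki = km * 10^runif(1, 1.2, 2))
    },
    hill = c(vmax = runif(1, 0.5, 10), k_half = 10^runif(1, 0.5, 2.5),
             n_hill = runif(1, 0.8, 3)),
    exp1 = c(amp1 = runif(1, 0.5, 3), k1 = 10^runif(1, 1, 2.5),
             f_eq = runif(1, -1, 1)),
    exp2 = {
      k2 <- 10^runif(1, 1, 1.7)
      c(amp1 = runif(1, 0.5, 2), k1 = k2 * runif(1, 4, 8),
        amp2 = runif(1, 0.5, 2), k2 = k2, f_eq = runif(1, 0, 1))
    },
    isotherm_one = c(fmax1 = runif(1, 0.3, 1), kd1 = 10^runif(1, -1, 1.5)),
    isotherm_two = {
      kd1 <- 10^runif(1, -1.2, 0)
      c(fmax1 = runif(1, 0.3, 0.7), kd1 = kd1,
        fmax2 = runif(1, 0.3, 0.7), kd2 = kd1 * 10^runif(1, 1.7, 2.5))
    },
    isotherm_two_hill = {
      kd1 <- 10^runif(1, -1.2, 0)
      c(fmax1 = runif(1, 0.3, 0.7), kd1 = kd1, n_step1 = runif(1, 1, 1.8),
        fmax2 = runif(1, 0.3, 0.7), kd2 = kd1 * 10^runif(1, 1.7, 2.5))
    },
    kobs_cs = c(k_minus = runif(1, 10, 80), k_plus = runif(1, 100, 400),
                kd_app = 10^runif(1, -0.5, 0.7)),
    kobs_if = c(k_minus = runif(1, 10, 80), k_plus = runif(1, 100, 400),
                kd_app = 10^runif(1, -0.5, 0.7)))
}

design_grid <- function(model, par) {
  switch(model,
    michaelis = ,
    substrate_inhibition = ,
    hill = {
      scale <- if ("k_half" %in% names(par)) par[["k_half"]] else par[["km"]]
      exp(seq(log(scale / 30), log(scale * 30), length.out = 12))
    },
    exp1 = ,
    exp2 = seq(0, 8 / min(par[grep("^k", names(par))]), length.out = 200),
    isotherm_one = ,
    isotherm_two = ,
    isotherm_two_hill =
      exp(seq(log(par[["kd1"]] / 20),
              log(max(par[["kd1"]], par[c("kd2")] %||na% par[["kd1"]]) * 30),
              length.out = 16)),
    kobs_cs = ,
    kobs_if = exp(seq(log(par[["kd_app"]] / 10), log(par[["kd_app"]] * 25),
                      length.out = 12)))
}

`%||na%` <- function(a, b) {
  v <- tryCatch(a, error = function(e) NA)
  if (all(is.na(v))) b else v
}

test_that("noiseless self-generated data are recovered exactly for every model", {
  set.seed(202)
  for (model in kin_models()) {
    for (draw in 1:6) {
      par <- draw_params(model)
      x <- design_grid(model, par)
      g <- gen_kinetic_dataset(model, as.list(par), x, noise_sd = 0,
                               replicates = 1, seed = draw)
      fit <- kin_fit(g$data$x, g$data$y, model, n_starts = 8, seed = draw)
      expect_true(fit$converged, info = model)
      expect_equal(unname(fit$estimates[names(par)]), unname(par),
                   tolerance = 1e-5,
                   info = sprintf("%s draw %d", model, draw))
      expect_gt(fit$r_squared, 1 - 1e-8)
    }
  }
})

test_that("fitting the Hill model to pure hyperbolic data returns n = 1", {
  x <- exp(seq(log(1), log(2000), length.out = 12))
  y <- rate_michaelis(x, vmax = 4.38, km = 120)
  fit <- kin_fit(x, y, "hill")
  expect_equal(unname(fit$estimates[["n_hill"]]), 1, tolerance = 1e-4)
})

test_that("estimation error in the Hill coefficient grows with noise", {
  mae <- sapply(c(0.01, 0.05, 0.15), function(sd) {
    errs <- sapply(1:25, function(s) {
      g <- gen_kinetic_dataset("hill", ref_hill, grid_tylosin[-1],
                               noise_sd = sd, replicates = 3, seed = s)
      fit <- kin_fit(g$data$x, g$data$y, "hill", n_starts = 5, seed = s)
      abs(fit$estimates[["n_hill"]] - ref_hill$n_hill)
    })
    mean(errs)
  })
  expect_true(all(diff(mae) > 0))
})

test_that("fit input contracts are enforced", {
  expect_error(kin_fit(1:3, c(1, 2, 3), "hill"), "at least")
  expect_error(kin_fit(rep(5, 8), rnorm(8), "hill"), "identical")
  expect_error(kin_fit(1:8, rnorm(8), "no_such_model"), "unknown model")
  expect_error(kin_fit(1:8, rnorm(4), "hill"), "same length")
})

test_that("fit results expose the standard modelling methods", {
  g <- gen_kinetic_dataset("hill", ref_hill, grid_tylosin[-1],
                           noise_sd = 0.03, replicates = 3, seed = 9)
  fit <- kin_fit(g$data, model = "hill")
  expect_s3_class(fit, "kin_fit")
  expect_length(residuals(fit), fit$n_obs)
  expect_equal(fitted(fit) + residuals(fit), g$data$y)
  expect_equal(predict(fit), fitted(fit))
  expect_equal(predict(fit, 278), rate_hill(278, fit$estimates[["vmax"]],
                                            fit$estimates[["k_half"]],
                                            fit$estimates[["n_hill"]]))
  s <- summary(fit)
  expect_true(s$cooperativity %in% c("positive", "none", "negative"))
  sim <- simulate(fit, nsim = 3, seed = 4)
  expect_identical(dim(sim), c(fit$n_obs, 4L))
  expect_identical(simulate(fit, nsim = 2, seed = 4),
                   simulate(fit, nsim = 2, seed = 4))
  expect_output(print(fit), "hill")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("two-phase transient fits report the fast phase first", {
  g <- gen_kinetic_dataset("exp2",
    list(amp1 = 0.5, k1 = 254.6, amp2 = 0.5, k2 = 46.2, f_eq = 0),
    grid_transient[-1], noise_sd = 0.005, noise = "additive",
    replicates = 1, seed = 3)
  fit <- kin_fit(g$data$x, g$data$y, "exp2", seed = 3)
  expect_gt(fit$estimates[["k1"]], fit$estimates[["k2"]])
})

test_that("relative weighting changes the objective but preserves exact fits", {
  x <- grid_tylosin[-1]
  y <- rate_hill(x, 4.65, 278, 1.76)
  f1 <- kin_fit(x, y, "hill", weights = "inv_y2")
  expect_equal(unname(coef(f1)), c(4.65, 278, 1.76), tolerance = 1e-5)
})
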