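test_that("kinetic dataset generation is exact at zero noise and seeded", {
  g0 <- gen_kinetic_dataset("hill", ref_hill, grid_tylosin, noise_sd = 0,
                            replicates = 2, seed = 1)
  expect_equal(g0$data$y,
               rep(rate_hill(grid_tylosin, 4.65, 278, 1.76), 2))
  ga <- gen_kinetic_dataset("hill", ref_hill, grid_tylosin, noise_sd = 0.05,
                            replicates = 3, seed = 99)
  gb <- gen_kinetic_dataset("hill", ref_hill, grid_tylosin, noise_sd = 0.05,
                            replicates = 3, seed = 99)
  expect_identical(ga$data, gb$data)
  expect_false(identical(
    ga$data$y,
    gen_kinetic_dataset("hill", ref_hill, grid_tylosin, noise_sd = 0.05,
                        replicates = 3, seed = 100)$data$y))
  expect_error(gen_kinetic_dataset("hill", list(vmax = 1), grid_tylosin),
               "must provide")
  expect_error(gen_kinetic_dataset("hill", ref_hill, c(1, 1, 2)),
               "increasing")
})

test_that("generated noise has the stated magnitude", {
  x <- exp(seq(log(20), log(2500), length.out = 12))
  g <- gen_kinetic_dataset("hill", ref_hill, x, noise_sd = 0.05,
                           replicates = 3, seed = 12)
  mu <- rep(rate_hill(x, 4.65, 278, 1.76), 3)
  rel <- (g$data$y - mu) / mu
  expect_equal(sd(rel), 0.05, tolerance = 0.2)  # n = 36 moment check
})

test_that("dataset files carry a truth sidecar", {
  f <- tempfile(fileext = ".csv")
  g <- gen_kinetic_dataset("michaelis", list(vmax = 2, km = 10), c(1, 5, 20),
                           noise_sd = 0.01, seed = 3, file = f)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".truth.json")))
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_params$km, 10)
  expect_equal(read.csv(f)$y, g$data$y)
})

test_that("planted ensembles honour their specification", {
  ge <- gen_ensemble(20, 100, seed = 1)
  expect_s3_class(ge$ensemble, "ca_ensemble")
  expect_identical(dim(ge$ensemble$coords), c(100L, 20L, 3L))
  # same seed -> bit-identical
  ge2 <- gen_ensemble(20, 100, seed = 1)
  expect_identical(ge$ensemble$coords, ge2$ensemble$coords)
  expect_error(gen_ensemble(20, 1, seed = 1), "at least 2 frames")
  # impossible correlation structure is rejected with the eigenvalue
  expect_error(gen_ensemble(
    6, 10, correlated_pairs = data.frame(i = c(1, 2, 1), j = c(2, 3, 3),
                                         rho = c(0.95, 0.95, -0.9)),
    seed = 1), "positive definite")
  # planted chains must be geodesics of the backbone contact graph
  expect_error(gen_ensemble(30, 10, planted_chain = c(1, 20), seed = 1),
               "adjacent")
  expect_error(gen_ensemble(30, 10, planted_chain = 1:9, seed = 1),
               "folds back")
})

test_that("endpoint generation round-trips the equilibrium constant", {
  ep <- gen_endpoint(1, tylosin0 = 50, nadph0 = 50)
  expect_equal(unname(ep$endpoint), rep(25, 4))
  ep81 <- gen_endpoint(81, tylosin0 = 50, nadph0 = 50)
  expect_equal(ep81$extent, 45, tolerance = 1e-9)
  expect_equal(do.call(compute_keq, as.list(ep81$endpoint)), 81,
               tolerance = 1e-9)
  # noiseless round trip across random equilibrium constants
  set.seed(40)
  for (k in 10^runif(100, -2, 3)) {
    ep <- gen_endpoint(k, tylosin0 = runif(1, 10, 100),
                       nadph0 = runif(1, 10, 100))
    expect_equal(do.call(compute_keq, as.list(ep$endpoint)), k,
                 tolerance = 1e-9)
  }
  # noise is seeded
  e1 <- gen_endpoint(5, 50, 50, noise_sd = 1, seed = 3)
  e2 <- gen_endpoint(5, 50, 50, noise_sd = 1, seed = 3)
  expect_identical(e1$endpoint, e2$endpoint)
})

test_that("generate-then-fit recovers truth within three standard errors", {
  cases <- list(
    list(model = "hill", params = ref_hill, grid = grid_tylosin[-1],
         noise = "relative", sd = 0.03),
    list(model = "substrate_inhibition", params = ref_si, grid = grid_nadph,
         noise = "relative", sd = 0.03),
    list(model = "isotherm_two_hill", params = ref_isotherm,
         grid = grid_isotherm, noise = "additive", sd = 0.02))
  for (cs in cases) {
    hits <- sapply(1:20, function(s) {
      g <- gen_kinetic_dataset(cs$model, cs$params, cs$grid,
                               noise_sd = cs$sd, noise = cs$noise,
                               replicates = 3, seed = 7000 + s)
      fit <- kin_fit(g$data, model = cs$model, n_starts = 6, seed = s)
      est <- fit$estimates; se <- fit$std_errors
      truth <- unlist(cs$params)
      all(abs(est[names(truth)] - truth) <= 3 * se[names(truth)] + 1e-9)
    })
    expect_gte(mean(hits), 0.9)
  }
})
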