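test_that("Michaelis-Menten identities hold", {
  expect_equal(rate_michaelis(2.98, vmax = 1, km = 2.98), 0.5)
  expect_equal(rate_michaelis(0, vmax = 4.38, km = 2.98), 0)
  expect_equal(rate_michaelis(3, vmax = 4, km = 1), 3.0)
  expect_error(rate_michaelis(-1, vmax = 1, km = 1), "non-negative")
  expect_error(rate_michaelis(1, vmax = 1, km = 0), "km")
})

test_that("substrate inhibition is a continuous unimodal law with the stated peak", {
  expect_equal(rate_substrate_inhibition(0, 1, 2.98, 148.6), 0)
  # numeric 1-D maximisation oracle for the wild-type cofactor parameters
  opt <- optimize(function(s) rate_substrate_inhibition(s, 1, 2.98, 148.6),
                  c(1, 200), maximum = TRUE)
  expect_equal(opt$maximum, sqrt(2.98 * 148.6), tolerance = 1e-4)
  expect_equal(opt$objective, 1 / (1 + 2 * sqrt(2.98 / 148.6)),
               tolerance = 1e-8)
  # continuity of the s = 0 extension
  expect_lt(rate_substrate_inhibition(1e-12, 1, 2.98, 148.6), 1e-9)
  expect_error(rate_substrate_inhibition(1, 1, -2, 10), "km")
})

test_that("Hill law: half-saturation identity and a frozen evaluation", {
  for (n in c(0.3, 0.7, 1, 1.76, 4, 10)) {
    expect_equal(rate_hill(278, vmax = 4.65, k_half = 278, n_hill = n),
                 4.65 / 2, tolerance = 1e-12)
  }
  # frozen high-precision evaluation at the sigmoidal fit parameters
  expect_equal(rate_hill(100, vmax = 1, k_half = 278, n_hill = 1.76),
               0.1419103, tolerance = 1e-6)
  expect_error(rate_hill(1, 1, 278, n_hill = 0), "n_hill")
})

test_that("the three rate laws nest into each other on arbitrary grids", {
  set.seed(11)
  for (rep in 1:20) {
    vmax <- runif(1, 0.5, 10); km <- runif(1, 0.5, 500)
    s <- sort(runif(15, 0, 1000))
    expect_equal(rate_substrate_inhibition(s, vmax, km, Inf),
                 rate_michaelis(s, vmax, km), tolerance = 1e-12)
    expect_equal(rate_hill(s, vmax, km, 1),
                 rate_michaelis(s, vmax, km), tolerance = 1e-12)
  }
})

test_that("exponential transients decay from the summed amplitude to baseline", {
  expect_equal(transient_decay(0, c(1, 1), c(254.6, 46.2), f_eq = 2), 4)
  expect_equal(transient_decay(100, c(1, 1), c(254.6, 46.2), f_eq = 2), 2,
               tolerance = 1e-12)
  # fast-phase half-time by root-finding on the single-phase term
  th <- uniroot(function(t) exp(-254.6 * t) - 0.5, c(0, 1), tol = 1e-12)$root
  expect_equal(th, log(2) / 254.6, tolerance = 1e-9)
  expect_equal(transient_decay(th, 1, 254.6, 0), 0.5, tolerance = 1e-9)
  expect_error(transient_decay(1, c(1, 1), 5), "same length")
  expect_error(transient_decay(1, c(1, 1), c(5, 10)), "descending")
  expect_true(all(diff(transient_decay(seq(0, 0.1, by = 1e-3),
                                       c(1, 1), c(254.6, 46.2), 0)) < 0))
})

test_that("binding isotherms start at zero, nest, and match hand arithmetic", {
  for (m in c("one-step", "two-step", "two-step-hill")) {
    expect_equal(binding_isotherm(0, 0.5, 0.45, 0.5, 53.5, 1.22, model = m), 0)
  }
  l <- exp(seq(log(0.01), log(500), length.out = 30))
  expect_equal(
    binding_isotherm(l, 0.5, 0.45, 0.5, 53.5, n_step1 = 1, model = "two-step-hill"),
    binding_isotherm(l, 0.5, 0.45, 0.5, 53.5, model = "two-step"),
    tolerance = 1e-12)
  expect_equal(
    binding_isotherm(0.45, 0.5, 0.45, 0.5, 53.5, 1.22, model = "two-step-hill"),
    0.25 + 0.5 * 0.45 / 53.95, tolerance = 1e-9)
  expect_error(binding_isotherm(1, 0.5, 0.45, model = "three-step"))
  expect_error(binding_isotherm(1, 0.5, 0.45, model = "two-step"), "fmax2")
})

test_that("binding isotherms are monotone non-decreasing in ligand", {
  set.seed(5)
  l <- exp(seq(log(1e-3), log(1e4), length.out = 60))
  for (rep in 1:25) {
    f1 <- runif(1); f2 <- runif(1)
    kd1 <- 10^runif(1, -2, 2); kd2 <- 10^runif(1, -1, 3)
    n1 <- runif(1, 0.3, 3)
    for (m in c("one-step", "two-step", "two-step-hill")) {
      y <- binding_isotherm(l, f1, kd1, f2, kd2, n1, model = m)
      expect_true(all(diff(y) >= -1e-12))
      expect_lt(max(y), f1 + ifelse(m == "one-step", 0, f2) + 1e-9)
    }
  }
})

test_that("relaxation-rate models have the correct limits and monotonicity", {
  km <- 40; kp <- 250; kd <- 0.79
  cs <- function(l) kobs_model(l, km, kp, kd, "conformational-selection")
  ifit <- function(l) kobs_model(l, km, kp, kd, "induced-fit")
  expect_equal(cs(0), km + kp)
  expect_equal(ifit(0), km)
  expect_equal(cs(1e9), km, tolerance = 1e-6)
  expect_equal(ifit(1e9), km + kp, tolerance = 1e-6)
  expect_equal(cs(kd), km + kp / 2)
  l <- seq(0, 20, length.out = 50)
  expect_true(all(diff(cs(l)) < 0))
  expect_true(all(diff(ifit(l)) > 0))
  expect_error(kobs_model(1, km, kp, kd, "sequential"))
})
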