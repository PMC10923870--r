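#' Published wild-type parameter sets for the tylosin reductase
#'
#' The reported wild-type kinetic and binding constants for the
#' NADPH-dependent tylosin reductase, used as generative ground truth by
#' the parameter-recovery studies: the substrate-inhibition constants for
#' cofactor NADPH (saturating tylosin), the Hill constants for substrate
#' tylosin (saturating, 200 uM NADPH), the two stopped-flow relaxation
#' rates, the two-step-Hill equilibrium-quench constants, the apparent
#' dissociation constant of the conformational-selection fit, and the
#' measured equilibrium constants at three NADPH levels.
#'
#' @return a named list of parameter lists.
#' @export
akr_reference_params <- function() {
  list(
    nadph_si = list(vmax = 4.38, km = 2.98, ki = 148.6),
    tylosin_hill = list(vmax = 4.65, k_half = 278, n_hill = 1.76),
    tylosin_hill_low_nadph = list(vmax = 1.44, k_half = 214.51,
                                  n_hill = 1.76),
    stopped_flow = list(amp1 = 0.5, k1 = 254.6, amp2 = 0.5, k2 = 46.2,
                        f_eq = 0.1),
    quench_isotherm = list(fmax1 = 0.5, kd1 = 0.45, n_step1 = 1.22,
                           fmax2 = 0.5, kd2 = 53.5),
    relaxation_cs = list(k_minus = 40, k_plus = 250, kd_app = 0.79),
    keq_vs_nadph = data.frame(nadph = c(5, 50, 200),
                              keq = c(0.86, 81.37, 0.89))
  )
}

#' Simulate a wild-type assay at published parameters and refit it
#'
#' One seeded realisation of each assay used in the recovery studies:
#' generates synthetic data from the published wild-type parameters under
#' the corresponding noise model, refits the generating model (fitting the
#' competing model too where model preference is part of the analysis), and
#' returns the fit.
#'
#' Assay designs: `"tylosin_rates"` — triplicate initial rates at 12
#' tylosin concentrations spanning 0-2500 uM, 3\% relative noise, Hill fit;
#' `"nadph_rates"` — triplicate rates at 14 log-spaced NADPH concentrations
#' (0.5-200 uM), 3\% relative noise, substrate-inhibition fit;
#' `"stopped_flow"` — one transient of 2000 points over 0-100 ms, additive
#' noise at 1\% of the total amplitude, mono- vs double-exponential fits;
#' `"quench_isotherm"` — octuplicate quench ratios at 16 log-spaced NADPH
#' concentrations (0.01-500 uM), additive noise 0.02, two-step-Hill fit
#' (the zero-ligand quench is structurally 0); `"relaxation"` — triplicate
#' apparent rates at 12 log-spaced NADPH concentrations (0.05-20 uM), 3\%
#' relative noise, conformational-selection vs induced-fit fits. Assays
#' with relative (multiplicative) noise are fitted with 1/y^2 weighting,
#' the efficient estimator for that noise model; additive-noise assays are
#' fitted unweighted.
#'
#' @param assay one of `"tylosin_rates"`, `"nadph_rates"`,
#'   `"stopped_flow"`, `"quench_isotherm"`, `"relaxation"`.
#' @param seed integer seed for data generation and fitting.
#' @return list with `fit` (the [kin_fit()] for the generating model),
#'   `comparison` (a [compare_models()] result, where applicable), `truth`
#'   (generative parameters) and `n_obs`.
#' @export
wt_recovery <- function(assay = c("tylosin_rates", "nadph_rates",
                                  "stopped_flow", "quench_isotherm",
                                  "relaxation"), seed = 1) {
  assay <- match.arg(assay)
  ref <- akr_reference_params()
  out <- switch(assay,
    tylosin_rates = {
      grid <- c(0, 50, 100, 200, 300, 450, 650, 900, 1250, 1650, 2050, 2500)
      g <- gen_kinetic_dataset("hill", ref$tylosin_hill, grid,
                               noise_sd = 0.03, replicates = 3, seed = seed)
      list(fit = kin_fit(g$data, model = "hill", seed = seed,
                         weights = "inv_y2"),
           truth = g$truth)
    },
    nadph_rates = {
      grid <- exp(seq(log(0.5), log(200), length.out = 14))
      g <- gen_kinetic_dataset("substrate_inhibition", ref$nadph_si, grid,
                               noise_sd = 0.03, replicates = 3, seed = seed)
      list(fit = kin_fit(g$data, model = "substrate_inhibition",
                         seed = seed, weights = "inv_y2"),
           truth = g$truth)
    },
    stopped_flow = {
      grid <- seq(0, 0.1, length.out = 2000)
      g <- gen_kinetic_dataset("exp2", ref$stopped_flow, grid,
                               noise_sd = 0.01, noise = "additive",
                               replicates = 1, seed = seed)
      f2 <- kin_fit(g$data, model = "exp2", seed = seed)
      f1 <- kin_fit(g$data, model = "exp1", seed = seed)
      list(fit = f2, comparison = compare_models(f2, f1), truth = g$truth)
    },
    quench_isotherm = {
      grid <- exp(seq(log(0.01), log(500), length.out = 16))
      g <- gen_kinetic_dataset("isotherm_two_hill", ref$quench_isotherm,
                               grid, noise_sd = 0.02, noise = "additive",
                               replicates = 8, seed = seed)
      list(fit = kin_fit(g$data, model = "isotherm_two_hill", seed = seed),
           truth = g$truth)
    },
    relaxation = {
      grid <- exp(seq(log(0.05), log(20), length.out = 12))
      g <- gen_kinetic_dataset("kobs_cs", ref$relaxation_cs, grid,
                               noise_sd = 0.03, replicates = 3, seed = seed)
      fcs <- kin_fit(g$data, model = "kobs_cs", seed = seed,
                     weights = "inv_y2")
      fif <- kin_fit(g$data, model = "kobs_if", seed = seed,
                     weights = "inv_y2")
      list(fit = fcs, comparison = compare_models(fcs, fif),
           truth = g$truth)
    })
  out$n_obs <- out$fit$n_obs
  out
}
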