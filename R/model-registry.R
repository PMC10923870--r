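# Internal registry of fittable models. Each entry carries the model
# function over a named parameter vector, box constraints, the data kind it
# applies to, and an initialisation heuristic computed from the data.
#
# Default bounds follow the package-wide convention: concentrations and
# dissociation/rate constants in [1e-4, 1e6] (uM or s^-1), Hill coefficients
# in [0.2, 5], amplitudes/vmax positive, baselines unbounded below.

.kin_models <- new.env(parent = emptyenv())

register_model <- function(id, fn, par, lower, upper, init, kind) {
  assign(id, list(id = id, fn = fn, par = par, lower = lower, upper = upper,
                  init = init, kind = kind),
         envir = .kin_models)
}

get_model <- function(id) {
  if (!exists(id, envir = .kin_models, inherits = FALSE))
    stop(sprintf("unknown model id '%s'; known: %s", id,
                 paste(sort(ls(.kin_models)), collapse = ", ")),
         call. = FALSE)
  get(id, envir = .kin_models, inherits = FALSE)
}

#' List fittable model identifiers
#'
#' @return character vector of model ids accepted by [kin_fit()].
#' @export
kin_models <- function() sort(ls(.kin_models))

.CONC_LO <- 1e-4
.CONC_HI <- 1e6

# K_0.5 / Km heuristic: abscissa closest to half-maximal response
half_sat_guess <- function(x, y) {
  ymax <- max(y)
  xh <- x[which.min(abs(y - ymax / 2))]
  max(xh, .CONC_LO * 10)
}

register_model(
  "michaelis",
  fn = function(x, p) rate_michaelis(x, p[["vmax"]], p[["km"]]),
  par = c("vmax", "km"),
  lower = c(vmax = .CONC_LO, km = .CONC_LO),
  upper = c(vmax = .CONC_HI, km = .CONC_HI),
  init = function(x, y) c(vmax = max(y) * 1.2, km = half_sat_guess(x, y)),
  kind = "rates"
)

register_model(
  "substrate_inhibition",
  fn = function(x, p) rate_substrate_inhibition(x, p[["vmax"]], p[["km"]],
                                                p[["ki"]]),
  par = c("vmax", "km", "ki"),
  lower = c(vmax = .CONC_LO, km = .CONC_LO, ki = .CONC_LO),
  upper = c(vmax = .CONC_HI, km = .CONC_HI, ki = .CONC_HI),
  init = function(x, y) {
    # peak position ~ sqrt(km*ki); rising-limb half point ~ km
    xpk <- x[which.max(y)]
    km0 <- half_sat_guess(x[x <= xpk], y[x <= xpk])
    ki0 <- max(xpk^2 / km0, km0 * 10)
    c(vmax = max(y) * 1.5, km = km0, ki = min(ki0, .CONC_HI / 10))
  },
  kind = "rates"
)

register_model(
  "hill",
  fn = function(x, p) rate_hill(x, p[["vmax"]], p[["k_half"]], p[["n_hill"]]),
  par = c("vmax", "k_half", "n_hill"),
  lower = c(vmax = .CONC_LO, k_half = .CONC_LO, n_hill = 0.2),
  upper = c(vmax = .CONC_HI, k_half = .CONC_HI, n_hill = 5),
  init = function(x, y) c(vmax = max(y) * 1.2,
                          k_half = half_sat_guess(x, y), n_hill = 1),
  kind = "rates"
)

# time to half total amplitude -> k ~ ln2 / t_half
khalf_time_guess <- function(x, y) {
  amp <- y[which.min(x)] - min(y)
  yh <- min(y) + amp / 2
  th <- x[which.min(abs(y - yh))]
  if (th <= 0) th <- stats::median(x[x > 0])
  log(2) / th
}

register_model(
  "exp1",
  fn = function(x, p) transient_decay(x, p[["amp1"]], p[["k1"]], p[["f_eq"]]),
  par = c("amp1", "k1", "f_eq"),
  lower = c(amp1 = 0, k1 = .CONC_LO, f_eq = -.CONC_HI),
  upper = c(amp1 = .CONC_HI, k1 = .CONC_HI, f_eq = .CONC_HI),
  init = function(x, y) c(amp1 = max(y) - min(y), k1 = khalf_time_guess(x, y),
                          f_eq = min(y)),
  kind = "transient"
)

register_model(
  "exp2",
  fn = function(x, p) {
    # evaluate without the descending-rate constraint; kin_fit sorts phases
    rep(p[["f_eq"]], length(x)) +
      p[["amp1"]] * exp(-p[["k1"]] * x) + p[["amp2"]] * exp(-p[["k2"]] * x)
  },
  par = c("amp1", "k1", "amp2", "k2", "f_eq"),
  lower = c(amp1 = 0, k1 = .CONC_LO, amp2 = 0, k2 = .CONC_LO, f_eq = -.CONC_HI),
  upper = c(amp1 = .CONC_HI, k1 = .CONC_HI, amp2 = .CONC_HI, k2 = .CONC_HI,
            f_eq = .CONC_HI),
  init = function(x, y) {
    k0 <- khalf_time_guess(x, y)
    amp <- max(y) - min(y)
    c(amp1 = amp / 2, k1 = k0 * 4, amp2 = amp / 2, k2 = k0 / 2, f_eq = min(y))
  },
  kind = "transient"
)

register_model(
  "isotherm_one",
  fn = function(x, p) binding_isotherm(x, p[["fmax1"]], p[["kd1"]],
                                       model = "one-step"),
  par = c("fmax1", "kd1"),
  lower = c(fmax1 = 0, kd1 = .CONC_LO),
  upper = c(fmax1 = .CONC_HI, kd1 = .CONC_HI),
  init = function(x, y) c(fmax1 = max(y), kd1 = half_sat_guess(x, y)),
  kind = "isotherm"
)

register_model(
  "isotherm_two",
  fn = function(x, p) binding_isotherm(x, p[["fmax1"]], p[["kd1"]],
                                       p[["fmax2"]], p[["kd2"]],
                                       model = "two-step"),
  par = c("fmax1", "kd1", "fmax2", "kd2"),
  lower = c(fmax1 = 0, kd1 = .CONC_LO, fmax2 = 0, kd2 = .CONC_LO),
  upper = c(fmax1 = .CONC_HI, kd1 = .CONC_HI, fmax2 = .CONC_HI, kd2 = .CONC_HI),
  init = function(x, y) {
    kd <- half_sat_guess(x, y)
    c(fmax1 = max(y) / 2, kd1 = kd / 10, fmax2 = max(y) / 2, kd2 = kd * 10)
  },
  kind = "isotherm"
)

register_model(
  "isotherm_two_hill",
  fn = function(x, p) binding_isotherm(x, p[["fmax1"]], p[["kd1"]],
                                       p[["fmax2"]], p[["kd2"]],
                                       n_step1 = p[["n_step1"]],
                                       model = "two-step-hill"),
  par = c("fmax1", "kd1", "n_step1", "fmax2", "kd2"),
  lower = c(fmax1 = 0, kd1 = .CONC_LO, n_step1 = 0.2, fmax2 = 0,
            kd2 = .CONC_LO),
  upper = c(fmax1 = .CONC_HI, kd1 = .CONC_HI, n_step1 = 5, fmax2 = .CONC_HI,
            kd2 = .CONC_HI),
  init = function(x, y) {
    kd <- half_sat_guess(x, y)
    c(fmax1 = max(y) / 2, kd1 = kd / 10, n_step1 = 1,
      fmax2 = max(y) / 2, kd2 = kd * 10)
  },
  kind = "isotherm"
)

register_model(
  "kobs_cs",
  fn = function(x, p) kobs_model(x, p[["k_minus"]], p[["k_plus"]],
                                 p[["kd_app"]], "conformational-selection"),
  par = c("k_minus", "k_plus", "kd_app"),
  lower = c(k_minus = .CONC_LO, k_plus = .CONC_LO, kd_app = .CONC_LO),
  upper = c(k_minus = .CONC_HI, k_plus = .CONC_HI, kd_app = .CONC_HI),
  init = function(x, y) c(k_minus = max(min(y), .CONC_LO * 10),
                          k_plus = max(max(y) - min(y), .CONC_LO * 10),
                          kd_app = half_sat_guess(x, -y)),
  kind = "kobs-vs-ligand"
)

register_model(
  "kobs_if",
  fn = function(x, p) kobs_model(x, p[["k_minus"]], p[["k_plus"]],
                                 p[["kd_app"]], "induced-fit"),
  par = c("k_minus", "k_plus", "kd_app"),
  lower = c(k_minus = .CONC_LO, k_plus = .CONC_LO, kd_app = .CONC_LO),
  upper = c(k_minus = .CONC_HI, k_plus = .CONC_HI, kd_app = .CONC_HI),
  init = function(x, y) c(k_minus = max(min(y), .CONC_LO * 10),
                          k_plus = max(max(y) - min(y), .CONC_LO * 10),
                          kd_app = half_sat_guess(x, y)),
  kind = "kobs-vs-ligand"
)
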