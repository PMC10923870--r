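#' Steady-state rate laws
#'
#' Evaluate the three steady-state rate laws used for aldo-keto reductase
#' kinetics: the Michaelis-Menten hyperbola, the substrate-inhibition law
#' (velocity falls again at high ligand because a second cofactor molecule
#' occupies the substrate pocket as a dead-end complex), and the Hill
#' equation for cooperative substrate binding.
#'
#' `rate_substrate_inhibition()` computes
#' \deqn{v = V_{max} / (1 + K_m/[S] + [S]/K_i)}
#' which is defined as 0 at \eqn{[S]=0} by continuous extension. It is
#' unimodal with its maximum at \eqn{[S] = \sqrt{K_m K_i}}. `rate_hill()`
#' computes \eqn{v = V_{max}[S]^n / (K_{0.5}^n + [S]^n)}; at \eqn{n=1} it
#' reduces to the Michaelis-Menten form, and `rate_substrate_inhibition()`
#' reduces to it as \eqn{K_i \to \infty}.
#'
#' @param s substrate (or cofactor) concentration, uM; vectorised, must be
#'   non-negative.
#' @param vmax maximal rate (signal s^-1, or s^-1 if normalised by enzyme).
#' @param km Michaelis constant, uM.
#' @param ki inhibition constant, uM (may be `Inf`).
#' @param k_half apparent half-saturation constant K_0.5, uM.
#' @param n_hill Hill coefficient (dimensionless, > 0).
#' @return numeric vector of rates, same length as `s`.
#' @examples
#' rate_michaelis(2.98, vmax = 4.38, km = 2.98)      # half of vmax
#' rate_substrate_inhibition(21, vmax = 4.38, km = 2.98, ki = 148.6)
#' rate_hill(278, vmax = 4.65, k_half = 278, n_hill = 1.76)
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
rate_michaelis <- function(s, vmax, km) {
  check_conc(s)
  check_pos(vmax = vmax, km = km)
  vmax * s / (km + s)
}

#' @rdname rate_laws
#' @export
rate_substrate_inhibition <- function(s, vmax, km, ki) {
  check_conc(s)
  check_pos(vmax = vmax, km = km, ki = ki)
  # written as vmax*s / (s + km + s^2/ki): continuous at s = 0
  vmax * s / (s + km + s * s / ki)
}

#' @rdname rate_laws
#' @export
rate_hill <- function(s, vmax, k_half, n_hill) {
  check_conc(s)
  check_pos(vmax = vmax, k_half = k_half, n_hill = n_hill)
  sn <- (s / k_half)^n_hill
  vmax * sn / (1 + sn)
}

#' Exponential fluorescence transients
#'
#' Mono- or multi-exponential decay of tryptophan fluorescence after
#' stopped-flow mixing with a quenching ligand:
#' \deqn{F(t) = \sum_i \Delta F_i e^{-k_{obs,i} t} + F_{eq}}
#' with `amplitudes` the fluorescence amplitude decreases and `k_obs` the
#' apparent first-order rate constants (sorted descending; one or two phases).
#'
#' @param t time, s (vectorised, non-negative).
#' @param amplitudes numeric vector of phase amplitudes (1 or 2 entries).
#' @param k_obs apparent rate constants, s^-1, same length as `amplitudes`,
#'   strictly descending, all positive.
#' @param f_eq fluorescence at equilibrium.
#' @return fluorescence at each `t`.
#' @examples
#' transient_decay(0.01, amplitudes = c(1, 1), k_obs = c(254.6, 46.2), f_eq = 0)
#' @export
transient_decay <- function(t, amplitudes, k_obs, f_eq = 0) {
  if (any(t < 0)) stop("time must be non-negative")
  if (length(amplitudes) != length(k_obs))
    stop("amplitudes and k_obs must have the same length")
  if (!length(k_obs) %in% c(1L, 2L))
    stop("one or two exponential phases are supported")
  if (any(k_obs <= 0)) stop("all k_obs must be positive")
  if (length(k_obs) == 2L && diff(k_obs) >= 0)
    stop("k_obs must be strictly descending (fast phase first)")
  out <- rep(f_eq, length(t))
  for (i in seq_along(k_obs)) out <- out + amplitudes[i] * exp(-k_obs[i] * t)
  out
}

#' Equilibrium fluorescence-quenching isotherms
#'
#' Quench ratio versus ligand concentration for one-step, two-step, and
#' two-step-with-first-step-Hill binding models. The quench ratio at zero
#' ligand is fixed at 0:
#' \describe{
#'   \item{one-step}{\eqn{F = F_{max1} L / (K_{d1} + L)}}
#'   \item{two-step}{sum of two such hyperbolae}
#'   \item{two-step-hill}{\eqn{F = F_{max1} L^n / (K_{d1}^n + L^n) +
#'     F_{max2} L / (K_{d2} + L)}, with `n_step1` the Hill coefficient of
#'     the first (cooperative, cofactor-site) step.}
#' }
#'
#' @param l ligand concentration, uM (vectorised, non-negative).
#' @param fmax1,fmax2 maximal quench ratios of steps 1 and 2.
#' @param kd1,kd2 dissociation constants, uM.
#' @param n_step1 Hill coefficient of step 1.
#' @param model one of `"one-step"`, `"two-step"`, `"two-step-hill"`.
#' @return quench ratio at each `l`.
#' @examples
#' binding_isotherm(0.45, fmax1 = 0.5, kd1 = 0.45, n_step1 = 1.22,
#'                  fmax2 = 0.5, kd2 = 53.5, model = "two-step-hill")
#' @export
binding_isotherm <- function(l, fmax1, kd1, fmax2 = NULL, kd2 = NULL,
                             n_step1 = 1,
                             model = c("one-step", "two-step", "two-step-hill")) {
  model <- match.arg(model)
  check_conc(l)
  check_pos(kd1 = kd1)
  if (fmax1 < 0) stop("fmax1 must be >= 0")
  step1 <- switch(model,
    "two-step-hill" = {
      check_pos(n_step1 = n_step1)
      ln <- (l / kd1)^n_step1
      fmax1 * ln / (1 + ln)
    },
    fmax1 * l / (kd1 + l)
  )
  if (model == "one-step") return(step1)
  if (is.null(fmax2) || is.null(kd2))
    stop("fmax2 and kd2 are required for two-step models")
  check_pos(kd2 = kd2)
  if (fmax2 < 0) stop("fmax2 must be >= 0")
  step1 + fmax2 * l / (kd2 + l)
}

#' Relaxation-rate models: conformational selection vs induced fit
#'
#' Apparent first-order relaxation rate as a function of ligand
#' concentration for the two limiting two-state binding mechanisms, under
#' rapid ligand binding:
#' \describe{
#'   \item{conformational selection}{\eqn{k_{obs} = k_- + k_+ / (1 + L/K_{d,app})},
#'     monotone decreasing in L (ligand binds a pre-existing conformation and
#'     pulls it out of the conformational equilibrium).}
#'   \item{induced fit}{\eqn{k_{obs} = k_- + k_+ L / (K_{d,app} + L)},
#'     monotone increasing in L (the conformational step follows binding).}
#' }
#' Both are bounded between `k_minus` and `k_minus + k_plus`.
#'
#' @param l ligand concentration, uM (vectorised, non-negative).
#' @param k_minus,k_plus conformational rate constants, s^-1 (> 0).
#' @param kd_app apparent dissociation constant of the rapid binding step, uM.
#' @param mechanism `"conformational-selection"` or `"induced-fit"`.
#' @return k_obs at each `l`, s^-1.
#' @examples
#' kobs_model(0.79, k_minus = 40, k_plus = 250, kd_app = 0.79,
#'            mechanism = "conformational-selection")  # k_minus + k_plus/2
#' @export
kobs_model <- function(l, k_minus, k_plus, kd_app,
                       mechanism = c("conformational-selection", "induced-fit")) {
  mechanism <- match.arg(mechanism)
  check_conc(l)
  check_pos(k_minus = k_minus, k_plus = k_plus, kd_app = kd_app)
  if (mechanism == "conformational-selection")
    k_minus + k_plus / (1 + l / kd_app)
  else
    k_minus + k_plus * l / (kd_app + l)
}
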