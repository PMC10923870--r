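#' Concerted (MWC) saturation function
#'
#' Fractional saturation and R-state fraction of a concerted two-state
#' allosteric unit of `n_sites` protomers. The unliganded tense/relaxed
#' equilibrium is `l0 = [T]/[R]`; ligand binds the R protomer with
#' dissociation constant `kr` and the T protomer with `kr / c`
#' (so `c = kr/kt <= 1` means preferential R binding). With
#' \eqn{\alpha = L/K_R}:
#' \deqn{\bar{y} = \frac{\alpha(1+\alpha)^{N-1} + L_0 c\alpha(1+c\alpha)^{N-1}}
#'                      {(1+\alpha)^N + L_0 (1+c\alpha)^N}}
#' \deqn{f_R = \frac{(1+\alpha)^N}{(1+\alpha)^N + L_0 (1+c\alpha)^N}}
#' Degeneracies: `l0 = 0` or `c = 1` collapse to the simple hyperbola
#' \eqn{\alpha/(1+\alpha)}.
#'
#' @param l ligand concentration, uM (vectorised, non-negative).
#' @param n_sites protomers per allosteric unit (default 4, the tetrameric
#'   allosteric unit of the octameric reductase).
#' @param l0 allosteric constant \eqn{[T]/[R]} of the unliganded unit (>= 0).
#' @param kr dissociation constant for the R protomer, uM.
#' @param c_ratio ratio \eqn{K_R/K_T} in (0, 1].
#' @return list with numeric vectors `y_bar` (fractional saturation) and
#'   `r_fraction` (fraction of units in the R state), both in [0, 1].
#' @examples
#' mwc_saturation(1, n_sites = 4, l0 = 1000, kr = 1, c_ratio = 0.01)
#' @export
mwc_saturation <- function(l, n_sites = 4, l0, kr, c_ratio) {
  check_conc(l)
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (l0 < 0) stop("l0 must be >= 0")
  check_pos(kr = kr)
  if (c_ratio <= 0 || c_ratio > 1) stop("c_ratio must be in (0, 1]")
  a <- l / kr
  ca <- c_ratio * a
  n <- n_sites
  zr <- (1 + a)^n
  zt <- l0 * (1 + ca)^n
  y <- (a * (1 + a)^(n - 1) + l0 * ca * (1 + ca)^(n - 1)) / (zr + zt)
  list(y_bar = y, r_fraction = zr / (zr + zt))
}

#' Three-step cofactor binding scheme
#'
#' Rapid-equilibrium velocity of the dormant/active/cofactor/inhibitor
#' binding scheme: a dormant conformation in equilibrium with an active one
#' (constant `l0 = [dormant]/[active]`), cofactor NADPH binding the active
#' conformation at its cofactor site (`kd_c`), and a second NADPH binding in
#' the substrate pocket as a dead-end inhibitor (`kd_i`). Velocity is
#' proportional to the fraction of the productive (cofactor-only) complex.
#'
#' For `n_sites = 1` the closed form is
#' \deqn{v = k_{cat}\,\frac{x/K_{dc}}{L_0 + 1 + x/K_{dc} + x^2/(K_{dc}K_{di})}}
#' which has exactly the substrate-inhibition shape with apparent
#' \eqn{K_m = K_{dc}(1+L_0)} and \eqn{K_i = K_{di}}. For `n_sites > 1` an
#' independent-sites concerted variant is used: each site of the active unit
#' is empty, productive or inhibited with weights \eqn{1, x/K_{dc},
#' x^2/(K_{dc}K_{di})}, the dormant unit has weight \eqn{L_0}, and velocity
#' is proportional to the mean fraction of productive sites.
#'
#' @param nadph NADPH concentration, uM (vectorised, non-negative).
#' @param l0 dormant/active equilibrium constant (>= 0).
#' @param kd_c cofactor-site dissociation constant, uM.
#' @param kd_i inhibitor-site (substrate pocket) dissociation constant, uM.
#' @param kcat turnover of the productive complex, s^-1.
#' @param n_sites sites per allosteric unit (1 gives the closed form).
#' @return velocity at each `nadph`.
#' @examples
#' # coincides with rate_substrate_inhibition(km = 6, ki = 150):
#' three_step_velocity(10, l0 = 1, kd_c = 3, kd_i = 150, kcat = 1)
#' @export
three_step_velocity <- function(nadph, l0, kd_c, kd_i, kcat = 1, n_sites = 1) {
  check_conc(nadph)
  if (l0 < 0) stop("l0 must be >= 0")
  check_pos(kd_c = kd_c, kd_i = kd_i, kcat = kcat)
  if (n_sites < 1) stop("n_sites must be >= 1")
  a <- nadph / kd_c                    # productive-site weight
  b <- a * nadph / kd_i                # inhibited-site weight
  w <- 1 + a + b                       # per-site partition function
  # mean fraction of productive sites x probability the unit is active
  kcat * (a / w) * (w^n_sites / (l0 + w^n_sites))
}

#' Equilibrium constant from endpoint concentrations
#'
#' K_eq of the reduction tylosin + NADPH <-> relomycin + NADP+ from the
#' equilibrium concentrations of the four species (1:1:1:1 stoichiometry):
#' \deqn{K_{eq} = \frac{[relomycin][NADP^+]}{[tylosin][NADPH]}}
#'
#' @param conc_tylosin,conc_nadph equilibrium reactant concentrations, uM
#'   (must be > 0 for K_eq to be defined).
#' @param conc_relomycin,conc_nadp equilibrium product concentrations, uM
#'   (>= 0).
#' @return dimensionless equilibrium constant.
#' @examples
#' compute_keq(5, 5, 45, 45)   # 81
#' @export
compute_keq <- function(conc_tylosin, conc_nadph, conc_relomycin, conc_nadp) {
  concs <- c(conc_tylosin, conc_nadph, conc_relomycin, conc_nadp)
  if (any(!is.finite(concs)) || any(concs < 0))
    stop("concentrations must be finite and non-negative")
  if (conc_tylosin <= 0 || conc_nadph <= 0)
    stop("K_eq undefined: reactant concentrations must be positive")
  (conc_relomycin * conc_nadp) / (conc_tylosin * conc_nadph)
}
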