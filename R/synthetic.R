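#' Generate a seeded synthetic kinetic dataset
#'
#' Draws noisy realisations of any model in [kin_models()] at known
#' parameters on a stated concentration/time grid, for parameter-recovery
#' studies. Noise is Gaussian, either multiplicative (`y = f(x)(1 + eps)`,
#' the default for rate data, emulating constant relative assay error) or
#' additive (`y = f(x) + eps`, natural for fluorescence signals). A truth
#' record with the generative parameters travels with the data so recovery
#' tests never re-derive ground truth.
#'
#' @param model model id, see [kin_models()].
#' @param true_params named list/vector of generative parameters for the
#'   model function.
#' @param x_grid strictly increasing abscissa grid (uM or s).
#' @param noise_sd noise standard deviation: relative (fraction of the
#'   signal) for `noise = "relative"`, absolute for `noise = "additive"`.
#' @param replicates number of replicates per grid point (>= 1).
#' @param seed integer seed; generation is a pure function of
#'   (spec, seed).
#' @param noise `"relative"` or `"additive"`.
#' @param file optional CSV path; the dataset is written there with a
#'   `<file>.truth.json` sidecar.
#' @return list with `data` (data frame: `x`, `y`, `replicate`) and `truth`
#'   (model, parameters, noise spec, seed).
#' @examples
#' gen_kinetic_dataset("hill",
#'   list(vmax = 4.65, k_half = 278, n_hill = 1.76),
#'   x_grid = c(50, 100, 250, 500, 1000, 2500),
#'   noise_sd = 0.03, replicates = 3, seed = 42)
#' @export
gen_kinetic_dataset <- function(model, true_params, x_grid, noise_sd = 0.03,
                                replicates = 3, seed = 1,
                                noise = c("relative", "additive"),
                                file = NULL) {
  noise <- match.arg(noise)
  m <- get_model(model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.unsorted(x_grid, strictly = TRUE))
    stop("x_grid must be strictly increasing")
  par <- unlist(true_params)[m$par]
  if (anyNA(par))
    stop("true_params must provide: ", paste(m$par, collapse = ", "))
  mu <- m$fn(x_grid, par)
  x <- rep(x_grid, times = replicates)
  rep_id <- rep(seq_len(replicates), each = length(x_grid))
  mu_all <- rep(mu, times = replicates)
  y <- local_seed(seed, {
    eps <- stats::rnorm(length(mu_all), 0, noise_sd)
    if (noise == "relative") mu_all * (1 + eps) else mu_all + eps
  })
  data <- data.frame(x = x, y = y, replicate = rep_id)
  truth <- list(model = model, true_params = as.list(par),
                x_grid = x_grid, noise_sd = noise_sd, noise = noise,
                replicates = replicates, seed = seed)
  if (!is.null(file)) {
    utils::write.csv(data, file, row.names = FALSE)
    jsonlite::write_json(truth, paste0(file, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(data = data, truth = truth)
}

#' Generate a Gaussian C-alpha ensemble with planted correlations
#'
#' Draws ensemble frames from a multivariate normal around a rigid backbone
#' with specified per-residue fluctuation and pairwise motion correlations,
#' including an optional planted high-correlation chain (the ground-truth
#' allosteric "pathway" for recovery tests). Displacements along the three
#' axes are independent draws with a shared residue-residue correlation
#' matrix, so the scalar-product motion covariance converges to that matrix.
#'
#' Backbones: `"snake-grid"` (default) lays residues on a square grid in
#' snake order with `spacing` 6 Angstrom, so sequence neighbours and
#' orthogonal grid neighbours are in contact at the 8 Angstrom cutoff while
#' diagonal and second-sequence neighbours are not — the contact graph is a
#' grid with many alternative routes. `"linear"` is a straight chain with
#' `spacing` 3.8 Angstrom (contacts then reach two residues along the
#' chain).
#'
#' @param n_residues,n_frames ensemble dimensions (`n_frames >= 2`).
#' @param spacing backbone spacing, Angstrom (default 6 for the grid,
#'   use 3.8 for `"linear"`).
#' @param backbone `"snake-grid"` or `"linear"`.
#' @param fluctuation_sd per-axis displacement SD, Angstrom (scalar or one
#'   per residue).
#' @param background_rho baseline correlation between all residue pairs.
#' @param correlated_pairs optional data frame with columns `i`, `j`,
#'   `rho` planting individual pair correlations (residue indices).
#' @param planted_chain optional integer vector of residue indices forming
#'   the planted pathway; consecutive members must be within 8 Angstrom on
#'   the backbone.
#' @param chain_rho correlation within the planted chain (equicorrelated
#'   block; |rho| < 1).
#' @param seed integer seed.
#' @return list with `ensemble` (a [ca_ensemble()]) and `truth`
#'   (the correlation matrix, backbone coordinates, planted chain labels,
#'   seed).
#' @export
gen_ensemble <- function(n_residues, n_frames, spacing = 6,
                         backbone = c("snake-grid", "linear"),
                         fluctuation_sd = 1, background_rho = 0,
                         correlated_pairs = NULL, planted_chain = NULL,
                         chain_rho = 0.9, seed = 1) {
  backbone <- match.arg(backbone)
  if (n_frames < 2) stop("an ensemble requires at least 2 frames")
  if (abs(chain_rho) >= 1) stop("|chain_rho| must be < 1")
  bb <- if (backbone == "linear") {
    cbind(spacing * (seq_len(n_residues) - 1), 0, 0)
  } else {
    ncol_g <- ceiling(sqrt(n_residues))
    row <- (seq_len(n_residues) - 1) %/% ncol_g
    col <- (seq_len(n_residues) - 1) %% ncol_g
    col <- ifelse(row %% 2 == 1, ncol_g - 1 - col, col)  # snake order
    cbind(col * spacing, row * spacing, 0)
  }
  C <- matrix(background_rho, n_residues, n_residues)
  diag(C) <- 1
  if (!is.null(correlated_pairs)) {
    for (k in seq_len(nrow(correlated_pairs))) {
      i <- correlated_pairs$i[k]; j <- correlated_pairs$j[k]
      C[i, j] <- C[j, i] <- correlated_pairs$rho[k]
    }
  }
  if (!is.null(planted_chain)) {
    pc <- as.integer(planted_chain)
    dists <- sqrt(rowSums((bb[pc[-1], , drop = FALSE] -
                           bb[pc[-length(pc)], , drop = FALSE])^2))
    if (any(dists >= 8))
      stop("planted chain members must be adjacent (< 8 A) on the backbone")
    # non-consecutive members must NOT be in contact: the chain is
    # equicorrelated, so any internal contact would be a legitimate
    # shortcut and the ordered chain would not be the unique shortest path
    if (length(pc) > 2) {
      D <- as.matrix(stats::dist(bb[pc, , drop = FALSE]))
      off <- abs(outer(seq_along(pc), seq_along(pc), `-`)) > 1
      if (any(D[off] < 8))
        stop("planted chain folds back on itself: non-consecutive members ",
             "are within the 8 A contact cutoff")
    }
    C[pc, pc] <- chain_rho
    diag(C) <- 1
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop(sprintf("correlation matrix not positive definite (min eigenvalue %.3g)",
                 min(ev)))
  sds <- rep(fluctuation_sd, length.out = n_residues)
  U <- chol(C)
  coords <- local_seed(seed, {
    arr <- array(0, c(n_frames, n_residues, 3))
    for (a in 1:3) {
      Z <- matrix(stats::rnorm(n_frames * n_residues), n_frames)
      disp <- (Z %*% U) * rep(sds, each = n_frames)
      arr[, , a] <- sweep(disp, 2, bb[, a], `+`)
    }
    arr
  })
  labels <- paste0("A", seq_len(n_residues))
  list(ensemble = ca_ensemble(coords, labels),
       truth = list(correlation = C, backbone = bb,
                    planted_chain = if (!is.null(planted_chain))
                      labels[as.integer(planted_chain)] else NULL,
                    chain_rho = chain_rho, fluctuation_sd = sds,
                    seed = seed))
}

#' Generate a synthetic equilibrium endpoint
#'
#' Solves the 1:1:1:1 equilibrium extent of tylosin + NADPH <-> relomycin +
#' NADP+ for a stated true equilibrium constant and initial concentrations,
#' then (optionally) perturbs the measured endpoint concentrations with
#' seeded Gaussian noise. With `noise_sd = 0`, [compute_keq()] on the
#' output returns `keq_true` to machine precision.
#'
#' @param keq_true true equilibrium constant (> 0).
#' @param tylosin0,nadph0,relomycin0,nadp0 initial concentrations, uM.
#' @param noise_sd additive SD applied to each measured concentration, uM.
#' @param seed integer seed.
#' @return list with `endpoint` (named concentrations `conc_tylosin`,
#'   `conc_nadph`, `conc_relomycin`, `conc_nadp`), the reaction `extent`
#'   (uM), and `truth`.
#' @examples
#' ep <- gen_endpoint(81, tylosin0 = 50, nadph0 = 50)
#' do.call(compute_keq, as.list(ep$endpoint))   # 81
#' @export
gen_endpoint <- function(keq_true, tylosin0, nadph0, relomycin0 = 0,
                         nadp0 = 0, noise_sd = 0, seed = 1) {
  check_pos(keq_true = keq_true)
  init <- c(tylosin0, nadph0, relomycin0, nadp0)
  if (any(init < 0)) stop("initial concentrations must be non-negative")
  # extent xi: K = (r0+xi)(q0+xi) / ((t0-xi)(n0-xi)); monotone in xi
  fn <- function(xi) (relomycin0 + xi) * (nadp0 + xi) -
    keq_true * (tylosin0 - xi) * (nadph0 - xi)
  lo <- -min(relomycin0, nadp0); hi <- min(tylosin0, nadph0)
  eps <- 1e-12 * max(1, hi - lo)
  if (hi <= lo || fn(lo + eps) * fn(hi - eps) > 0)
    stop("no physical equilibrium extent for these initial concentrations")
  xi <- stats::uniroot(fn, c(lo + eps, hi - eps), tol = 1e-14)$root
  conc <- c(conc_tylosin = tylosin0 - xi, conc_nadph = nadph0 - xi,
            conc_relomycin = relomycin0 + xi, conc_nadp = nadp0 + xi)
  if (noise_sd > 0) {
    conc <- local_seed(seed, pmax(conc + stats::rnorm(4, 0, noise_sd), 0))
  }
  list(endpoint = conc, extent = xi,
       truth = list(keq_true = keq_true, initial = init,
                    noise_sd = noise_sd, seed = seed))
}
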