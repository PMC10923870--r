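#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolling-probe SASA: each atom's van der Waals sphere is inflated by the
#' probe radius and covered with a deterministic quasi-uniform point set
#' (golden-section spiral); the accessible area is the fraction of points
#' not occluded by any neighbouring inflated sphere, times the sphere area.
#' An isolated atom of radius r therefore has SASA `4*pi*(r + probe)^2`.
#'
#' Van der Waals radii (Bondi): C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
#' H 1.20 Angstrom. Hydrogens are included only if present in the file.
#' Occlusion is computed in the context of the whole structure even when
#' `selection` restricts the atoms reported.
#'
#' @param s a [read_structure()] result.
#' @param selection optional [sel()] restricting the atoms whose area is
#'   reported (default: all atoms).
#' @param probe probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points sphere points per atom (default 960; accuracy improves
#'   roughly with 1/n).
#' @return list with `total` (Angstrom^2) and `per_atom` (one value per
#'   selected atom, with the atom table rows as `atoms`).
#' @export
sasa <- function(s, selection = NULL, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "mol_structure"))
  at <- s$atoms
  radii <- vdw_radii(at$elesy)
  idx <- if (is.null(selection)) seq_len(nrow(at))
         else resolve_selection(s, selection)
  pts <- golden_spiral(n_points)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rp <- radii + probe
  per <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    # neighbours whose inflated sphere can occlude atom i's surface
    dv <- sweep(xyz, 2, xyz[i, ])
    d2 <- rowSums(dv^2)
    nb <- which(d2 < (rp + rp[i])^2 & d2 > 0)
    # orient the point set in a local frame built from the two nearest
    # atoms, so the estimate is exactly equivariant under rigid motion
    sp <- pts %*% t(local_frame(dv, d2, i)) * rp[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (sp[free, 1] - xyz[j, 1])^2 + (sp[free, 2] - xyz[j, 2])^2 +
            (sp[free, 3] - xyz[j, 3])^2
      free[free] <- dj >= rp[j]^2
    }
    per[k] <- 4 * pi * rp[i]^2 * sum(free) / n_points
  }
  list(total = sum(per), per_atom = per, atoms = at[idx, , drop = FALSE],
       probe = probe, n_points = n_points)
}

#' Pocket SASA
#'
#' SASA of a named residue set (a binding pocket), computed in the context
#' of the whole structure: occlusion by atoms outside the pocket counts.
#'
#' @param s a [read_structure()] result.
#' @param pocket integer vector of residue numbers (optionally restricted
#'   to `chain`).
#' @param chain optional chain id.
#' @inheritParams sasa
#' @return total pocket SASA, Angstrom^2 (attribute `per_atom` carries the
#'   breakdown).
#' @export
pocket_sasa <- function(s, pocket, chain = NULL, probe = 1.4,
                        n_points = 960) {
  stopifnot(inherits(s, "mol_structure"))
  if (!length(pocket)) input_error("empty pocket residue list")
  at <- s$atoms
  present <- if (is.null(chain)) unique(at$resno)
             else unique(at$resno[at$chain %in% chain])
  missing <- setdiff(pocket, present)
  if (length(missing))
    input_error("pocket residue(s) absent from structure: %s",
                paste(missing, collapse = ", "))
  res <- sasa(s, sel(chain = chain, resno = pocket), probe = probe,
              n_points = n_points)
  structure(res$total, per_atom = res$per_atom)
}

vdw_radii <- function(elements) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
  el <- toupper(trimws(elements))
  r <- tab[el]
  if (anyNA(r))
    stop("no van der Waals radius configured for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "), call. = FALSE)
  unname(r)
}

# deterministic right-handed frame from the directions to the two nearest
# other atoms (identity when the structure has fewer than 2 other atoms or
# the directions are collinear beyond repair)
local_frame <- function(dv, d2, i) {
  ord <- order(replace(d2, i, Inf))
  u <- dv[ord[1], ]
  if (!is.finite(d2[ord[1]]) || sum(u^2) < 1e-12) return(diag(3))
  u <- u / sqrt(sum(u^2))
  v <- if (length(ord) >= 2 && is.finite(d2[ord[2]])) dv[ord[2], ] else c(1, 0, 0)
  v <- v - sum(v * u) * u
  if (sum(v^2) < 1e-10) {
    v <- c(1, 0, 0) - u[1] * u
    if (sum(v^2) < 1e-10) v <- c(0, 1, 0) - u[2] * u
  }
  v <- v / sqrt(sum(v^2))
  cbind(u, v, c(u[2] * v[3] - u[3] * v[2],
                u[3] * v[1] - u[1] * v[3],
                u[1] * v[2] - u[2] * v[1]))
}

# deterministic quasi-uniform unit-sphere points (golden-section spiral)
golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
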