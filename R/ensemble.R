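#' Construct a C-alpha coordinate ensemble
#'
#' Container for F frames of R C-alpha coordinates with fixed residue
#' labels, the input to superposition, PCA, loop-RMSD clustering and the
#' contact-persistence network workflow. Sources: [gen_ensemble()]
#' (synthetic), [read_ensemble_pdb()] (multi-model PDB), or any reader that
#' yields a frames x residues x 3 array.
#'
#' @param coords numeric array `F x R x 3` (Angstrom), `F >= 2`, `R >= 2`.
#' @param labels character vector of R residue labels (e.g. `"R257"`),
#'   order fixed across frames.
#' @param frame_weights optional non-negative per-frame weights.
#' @return object of class `ca_ensemble`.
#' @export
ca_ensemble <- function(coords, labels = NULL, frame_weights = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be an F x R x 3 array")
  if (dim(coords)[1] < 2L) stop("an ensemble requires at least 2 frames")
  if (dim(coords)[2] < 2L) stop("an ensemble requires at least 2 residues")
  if (any(!is.finite(coords))) stop("coordinates must be finite")
  if (is.null(labels)) labels <- paste0("A", seq_len(dim(coords)[2]))
  if (length(labels) != dim(coords)[2]) stop("one label per residue required")
  if (anyDuplicated(labels)) stop("residue labels must be unique")
  if (!is.null(frame_weights)) {
    if (length(frame_weights) != dim(coords)[1] || any(frame_weights < 0))
      stop("frame_weights must be non-negative, one per frame")
  }
  structure(list(coords = coords, labels = labels,
                 frame_weights = frame_weights),
            class = "ca_ensemble")
}

#' @export
print.ca_ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("C-alpha ensemble: %d frames x %d residues\n", d[1], d[2]))
  invisible(x)
}

n_frames <- function(e) dim(e$coords)[1]
n_residues <- function(e) dim(e$coords)[2]

label_index <- function(e, labels) {
  i <- match(labels, e$labels)
  if (anyNA(i))
    stop("unknown residue label(s): ",
         paste(labels[is.na(i)], collapse = ", "))
  i
}

# resolve a residue selection: integer indices or character labels
resolve_residues <- function(e, sel) {
  if (is.null(sel)) return(seq_len(n_residues(e)))
  if (is.character(sel)) return(label_index(e, sel))
  sel <- as.integer(sel)
  if (any(sel < 1 | sel > n_residues(e))) stop("residue index out of range")
  sel
}

#' Superpose an ensemble onto its iteratively refined mean
#'
#' Least-squares rigid-body (Kabsch) superposition of every frame onto the
#' mean structure over a core residue selection, iterating the mean until
#' convergence. Required before PCA, loop RMSD and motion covariance.
#'
#' @param e a [ca_ensemble()].
#' @param core residue indices or labels defining the superposition core
#'   (default: all residues). Must resolve to >= 3 non-collinear residues.
#' @param max_iter,tol iteration controls for refining the mean.
#' @return the superposed `ca_ensemble`.
#' @export
superpose <- function(e, core = NULL, max_iter = 10, tol = 1e-8) {
  stopifnot(inherits(e, "ca_ensemble"))
  ci <- resolve_residues(e, core)
  if (length(ci) < 3) stop("superposition core must contain >= 3 residues")
  X <- e$coords
  ref <- X[1, ci, , drop = TRUE]
  sv <- svd(scale(ref, scale = FALSE))$d
  if (sv[2] < 1e-6 * max(sv[1], 1e-6))
    stop("degenerate (collinear) superposition core")
  mean_prev <- ref
  nf <- dim(X)[1]; nr <- dim(X)[2]
  for (it in seq_len(max_iter)) {
    # batched Kabsch: cross-covariances for all frames at once, then one
    # 3x3 SVD per frame, then vectorised rotation of all coordinates
    Bc <- scale(mean_prev, scale = FALSE)
    cb <- attr(Bc, "scaled:center")
    camean <- sapply(1:3, function(a) rowMeans(X[, ci, a, drop = FALSE]))
    H <- array(0, c(nf, 3, 3))
    for (a in 1:3) {
      Xc <- X[, ci, a] - camean[, a]
      H[, a, ] <- Xc %*% Bc
    }
    rot <- array(0, c(nf, 3, 3))
    for (f in seq_len(nf)) {
      s <- svd(H[f, , ])
      d <- sign(det(s$v %*% t(s$u)))
      rot[f, , ] <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    }
    Xnew <- array(0, c(nf, nr, 3))
    shift <- matrix(0, nf, 3)
    for (b in 1:3) {
      for (a in 1:3) {
        Xnew[, , b] <- Xnew[, , b] + X[, , a] * rot[, a, b]
        shift[, b] <- shift[, b] - camean[, a] * rot[, a, b]
      }
      Xnew[, , b] <- Xnew[, , b] + (cb[b] + shift[, b])
    }
    X <- Xnew
    mean_new <- apply(X[, ci, , drop = FALSE], c(2, 3), mean)
    if (max(abs(mean_new - mean_prev)) < tol) break
    mean_prev <- mean_new
  }
  e$coords <- X
  e
}

#' Principal component analysis of ensemble coordinates
#'
#' Eigendecomposition of the 3R x 3R covariance matrix of the flattened,
#' mean-centred coordinates of a superposed ensemble. Eigenvalues are
#' returned in descending order with the fraction of total variance each
#' mode explains and per-frame projections.
#'
#' @param e a superposed [ca_ensemble()] with at least 3 frames.
#' @param n_modes number of modes to retain projections for (default 10).
#' @return object of class `ca_pca`: `eigenvalues` (descending),
#'   `explained_fraction`, `modes` (3R x n_modes, orthonormal),
#'   `projections` (F x n_modes).
#' @export
ensemble_pca <- function(e, n_modes = 10) {
  stopifnot(inherits(e, "ca_ensemble"))
  f <- n_frames(e)
  if (f < 3) stop("PCA requires at least 3 frames")
  M <- matrix(e$coords, nrow = f)         # F x 3R (column-major over R then xyz)
  M <- scale(M, scale = FALSE)
  sv <- svd(M)
  ev <- sv$d^2 / (f - 1)
  n_modes <- min(n_modes, length(ev))
  structure(list(eigenvalues = ev,
                 explained_fraction = ev / sum(ev),
                 modes = sv$v[, seq_len(n_modes), drop = FALSE],
                 projections = (sv$u %*% diag(sv$d, length(sv$d)))[
                   , seq_len(n_modes), drop = FALSE]),
            class = "ca_pca")
}

#' @export
print.ca_pca <- function(x, ...) {
  cat("Ensemble PCA\n  explained fraction (first modes):",
      paste(sprintf("%.3f", utils::head(x$explained_fraction, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' Per-frame loop RMSD
#'
#' Root-mean-square deviation of a loop's C-alpha atoms in each frame versus
#' a reference (the ensemble mean, or a chosen frame), computed on an
#' already superposed ensemble. Used as the clustering feature separating
#' inner-folded from out-folded loop conformations.
#'
#' @param e a superposed [ca_ensemble()].
#' @param loop residue indices or labels of the loop.
#' @param reference `"mean"` (default) or a frame index.
#' @param core optional superposition core used upstream; if the loop
#'   overlaps it a warning is raised (the loop signal is then damped).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
loop_rmsd <- function(e, loop, reference = "mean", core = NULL) {
  stopifnot(inherits(e, "ca_ensemble"))
  li <- resolve_residues(e, loop)
  if (!is.null(core) && length(intersect(li, resolve_residues(e, core))))
    warning("loop overlaps the superposition core")
  ref <- if (identical(reference, "mean"))
    apply(e$coords[, li, , drop = FALSE], c(2, 3), mean)
  else e$coords[as.integer(reference), li, , drop = TRUE]
  vapply(seq_len(n_frames(e)), function(f) {
    d <- e$coords[f, li, , drop = TRUE] - ref
    sqrt(mean(rowSums(matrix(d, ncol = 3)^2)))
  }, numeric(1))
}

#' Cluster ensemble frames into conformational states
#'
#' Seeded k-means clustering of per-frame feature vectors (typically the
#' two loop RMSDs), with clusters relabelled in ascending order of the
#' centroid value of the state-defining feature so state 1 is the most
#' inner-folded and state k the most out-folded.
#'
#' @param features numeric matrix (frames x features) or vector.
#' @param k number of states (default 4).
#' @param seed integer seed for the k-means++-style restarts.
#' @param order_by column of `features` whose centroid orders the states
#'   (default: the last column, the state-defining loop).
#' @param nstart k-means restarts (default 50).
#' @param state_names optional character vector of k names, ordered
#'   inner-folded to out-folded; defaults supplied for k = 4.
#' @return object of class `state_clustering`: `labels` (per-frame state),
#'   `occupancy` (fractions summing to 1), `centroids`, `state_names`.
#' @export
cluster_states <- function(features, k = 4, seed = 1, order_by = NULL,
                           nstart = 50, state_names = NULL) {
  features <- as.matrix(features)
  if (nrow(unique(features)) < k)
    stop("k exceeds the number of distinct feature vectors")
  if (is.null(order_by)) order_by <- ncol(features)
  # Lloyd iterations: robust on large, strongly overlapping frame sets
  # where Hartigan-Wong exhausts its transfer stage
  km <- local_seed(seed, stats::kmeans(features, centers = k,
                                       nstart = nstart, iter.max = 200,
                                       algorithm = "Lloyd"))
  ord <- order(km$centers[, order_by])
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  if (is.null(state_names)) {
    state_names <- if (k == 4)
      c("inner-folded", "partly out-folded", "half out-folded",
        "totally out-folded")
    else paste0("state-", seq_len(k))
  }
  occ <- tabulate(labels, nbins = k) / length(labels)
  structure(list(labels = labels, occupancy = occ,
                 centroids = km$centers[ord, , drop = FALSE],
                 state_names = state_names, seed = seed),
            class = "state_clustering")
}

#' @export
print.state_clustering <- function(x, ...) {
  cat("Conformational state clustering\n")
  print(data.frame(state = x$state_names,
                   occupancy = sprintf("%.1f%%", 100 * x$occupancy)))
  invisible(x)
}
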