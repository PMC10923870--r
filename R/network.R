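#' Contact-persistence residue graph
#'
#' Builds the residue graph underlying allosteric-pathway prediction: an
#' undirected edge joins residues i and j (i != j) when their C-alpha
#' distance is below `cutoff` in at least a fraction `persistence` of the
#' ensemble frames. Distances are internal, so no superposition is needed.
#'
#' @param e a [ca_ensemble()].
#' @param cutoff contact distance cutoff, Angstrom (default 8.0; strict
#'   `<`).
#' @param persistence minimum fraction of frames in contact (default 0.75;
#'   closed `>=`).
#' @return object of class `residue_graph`: `nodes` (labels) and an edge
#'   data frame with columns `i`, `j` (labels), `persistence`, and (after
#'   [edge_lengths()]) `c_ij`, `d_ij`.
#' @export
contact_persistence_graph <- function(e, cutoff = 8.0, persistence = 0.75) {
  stopifnot(inherits(e, "ca_ensemble"))
  r <- n_residues(e)
  # fraction of frames with ||ri - rj|| < cutoff, via squared distances;
  # one F x R slab per residue keeps memory flat for large ensembles
  frac <- matrix(0, r, r)
  cut2 <- cutoff^2
  cx <- e$coords[, , 1]; cy <- e$coords[, , 2]; cz <- e$coords[, , 3]
  for (jj in seq_len(r)) {
    d2 <- (cx - cx[, jj])^2 + (cy - cy[, jj])^2 + (cz - cz[, jj])^2
    frac[, jj] <- colMeans(d2 < cut2)
  }
  idx <- which(upper.tri(frac) & frac >= persistence, arr.ind = TRUE)
  edges <- data.frame(i = e$labels[idx[, 1]], j = e$labels[idx[, 2]],
                      persistence = frac[idx], stringsAsFactors = FALSE)
  structure(list(nodes = e$labels, edges = edges,
                 cutoff = cutoff, min_persistence = persistence),
            class = "residue_graph")
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("Residue graph: %d nodes, %d edges (cutoff %.1f A, persistence >= %.2f)%s\n",
              length(x$nodes), nrow(x$edges), x$cutoff, x$min_persistence,
              if ("d_ij" %in% names(x$edges)) ", weighted" else ""))
  invisible(x)
}

#' Inter-residue motion covariance
#'
#' Normalised scalar-product cross-correlation of C-alpha displacements
#' from the mean position of a superposed ensemble:
#' \deqn{c_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j \rangle}
#'   {\sqrt{\langle \Delta r_i^2\rangle \langle \Delta r_j^2\rangle}}}
#' The absolute value is returned by default (anticorrelated motion is
#' treated as communication) and clamped to `[1e-6, 1]` so that edge
#' lengths `-log(c_ij)` are finite; the signed matrix is available with
#' `signed = TRUE` (unclamped).
#'
#' @param e a superposed [ca_ensemble()].
#' @param signed return the signed, unclamped correlation matrix.
#' @return R x R matrix with unit diagonal, residue labels as dimnames.
#' @export
motion_covariance <- function(e, signed = FALSE) {
  stopifnot(inherits(e, "ca_ensemble"))
  f <- n_frames(e)
  cov3 <- 0
  for (a in 1:3) {
    ca <- scale(e$coords[, , a], scale = FALSE)
    cov3 <- cov3 + crossprod(ca) / f
  }
  v <- diag(cov3)
  zero <- v <= 0 | !is.finite(v)
  if (any(zero))
    numerical_error("zero-variance residue(s): %s",
                    paste(e$labels[zero], collapse = ", "))
  cmat <- cov3 / sqrt(outer(v, v))
  dimnames(cmat) <- list(e$labels, e$labels)
  if (signed) return(cmat)
  cmat <- abs(cmat)
  cmat <- pmin(pmax(cmat, 1e-6), 1)
  diag(cmat) <- 1
  cmat
}

#' Assign negative-log-covariance edge lengths
#'
#' Gives every edge of a contact-persistence graph the length
#' \eqn{d_{ij} = -\ln(c_{ij})}: strongly co-moving residue pairs get short
#' edges, so shortest paths trace putative allosteric communication routes.
#' Any logarithm base rescales all lengths uniformly and leaves shortest
#' paths unchanged; the natural log is used.
#'
#' @param g a [contact_persistence_graph()] result.
#' @param cmat covariance matrix from [motion_covariance()] (absolute,
#'   clamped), with dimnames covering all graph nodes.
#' @param base logarithm base (default `exp(1)`).
#' @return the graph with `c_ij` and `d_ij` edge columns filled in.
#' @export
edge_lengths <- function(g, cmat, base = exp(1)) {
  stopifnot(inherits(g, "residue_graph"))
  if (is.null(dimnames(cmat)) ||
      !all(g$nodes %in% rownames(cmat)))
    stop("covariance matrix must have residue labels covering all nodes")
  cij <- cmat[cbind(g$edges$i, g$edges$j)]
  if (any(cij <= 0 | cij > 1))
    stop("c_ij values must lie in (0, 1]; clamp the covariance first")
  g$edges$c_ij <- cij
  g$edges$d_ij <- -log(cij, base = base)
  g
}

#' Shortest allosteric pathway by Dijkstra's algorithm
#'
#' Minimal total-edge-length path between two residues on a weighted
#' contact-persistence graph. Ties are broken deterministically by
#' lexicographic node order. If the target is unreachable an explicit
#' no-path result is returned (`residues = character(0)`,
#' `total_length = Inf`).
#'
#' @param g a weighted residue graph (see [edge_lengths()]).
#' @param source,target residue labels.
#' @return object of class `path_result`: `residues` (ordered node list),
#'   `total_length`, `edge_lengths` (per step), `found`.
#' @export
shortest_pathway <- function(g, source, target) {
  stopifnot(inherits(g, "residue_graph"))
  if (!"d_ij" %in% names(g$edges))
    stop("graph has no edge lengths; call edge_lengths() first")
  nodes <- sort(g$nodes)  # lexicographic order fixes tie-breaks
  for (nm in c(source, target))
    if (!nm %in% nodes) stop(sprintf("unknown node '%s'", nm))
  n <- length(nodes)
  adj <- vector("list", n)
  ii <- match(g$edges$i, nodes); jj <- match(g$edges$j, nodes)
  for (k in seq_along(ii)) {
    adj[[ii[k]]] <- rbind(adj[[ii[k]]], c(jj[k], g$edges$d_ij[k]))
    adj[[jj[k]]] <- rbind(adj[[jj[k]]], c(ii[k], g$edges$d_ij[k]))
  }
  s <- match(source, nodes); t <- match(target, nodes)
  dist <- rep(Inf, n); dist[s] <- 0
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    u <- NA_integer_; du <- Inf
    for (v in seq_len(n))          # linear scan; lowest index wins ties
      if (!done[v] && dist[v] < du) { u <- v; du <- dist[v] }
    if (is.na(u) || u == t) break
    done[u] <- TRUE
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      v <- nb[k, 1]; w <- du + nb[k, 2]
      if (w < dist[v] || (w == dist[v] && !is.na(prev[v]) && u < prev[v])) {
        dist[v] <- w; prev[v] <- u
      }
    }
  }
  if (!is.finite(dist[t])) {
    return(structure(list(residues = character(0), total_length = Inf,
                          edge_lengths = numeric(0), found = FALSE),
                     class = "path_result"))
  }
  path <- t
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  res <- nodes[path]
  steps <- if (length(path) > 1) dist[path[-1]] - dist[path[-length(path)]]
           else numeric(0)
  structure(list(residues = res, total_length = dist[t],
                 edge_lengths = steps, found = TRUE),
            class = "path_result")
}

#' @export
print.path_result <- function(x, ...) {
  if (!x$found) cat("No path found\n")
  else cat(sprintf("Pathway (total length %.4f):\n  %s\n", x$total_length,
                   paste(x$residues, collapse = " -> ")))
  invisible(x)
}

#' Export a residue graph
#'
#' `write_graph_tsv()` writes the edge list (`i`, `j`, `persistence`,
#' `c_ij`, `d_ij`) as tab-separated text; `write_graphml()` writes GraphML
#' readable by igraph/Cytoscape; `write_path_json()` serialises a
#' [shortest_pathway()] result.
#'
#' @param g a residue graph.
#' @param path output file path.
#' @return the file path, invisibly.
#' @export
write_graph_tsv <- function(g, path) {
  stopifnot(inherits(g, "residue_graph"))
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
write_graphml <- function(g, path) {
  stopifnot(inherits(g, "residue_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="persistence" for="edge" attr.name="persistence" attr.type="double"/>')
  w('  <key id="c_ij" for="edge" attr.name="c_ij" attr.type="double"/>')
  w('  <key id="d_ij" for="edge" attr.name="d_ij" attr.type="double"/>')
  w('  <graph id="G" edgedefault="undirected">')
  for (nd in g$nodes) w(sprintf('    <node id="%s"/>', nd))
  has_w <- "d_ij" %in% names(g$edges)
  for (k in seq_len(nrow(g$edges))) {
    w(sprintf('    <edge source="%s" target="%s">',
              g$edges$i[k], g$edges$j[k]))
    w(sprintf('      <data key="persistence">%.17g</data>',
              g$edges$persistence[k]))
    if (has_w) {
      w(sprintf('      <data key="c_ij">%.17g</data>', g$edges$c_ij[k]))
      w(sprintf('      <data key="d_ij">%.17g</data>', g$edges$d_ij[k]))
    }
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' @rdname write_graph_tsv
#' @param p a [shortest_pathway()] result.
#' @export
write_path_json <- function(p, path) {
  stopifnot(inherits(p, "path_result"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
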