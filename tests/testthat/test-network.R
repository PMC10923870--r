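static_ensemble <- function(positions, n_frames = 4) {
  r <- nrow(positions)
  coords <- array(0, c(n_frames, r, 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- positions
  coords
}

test_that("contact edges require the persistence threshold exactly", {
  # two residues at 5 A plus a third drifting across the 8 A cutoff
  pos <- rbind(c(0, 0, 0), c(5, 0, 0), c(100, 0, 0))
  coords <- static_ensemble(pos, n_frames = 100)
  # residue 3 within 8 A of residue 2 in exactly 74 of 100 frames
  coords[, 3, 1] <- ifelse(seq_len(100) <= 74, 12, 100)
  g74 <- contact_persistence_graph(ca_ensemble(coords))
  expect_identical(nrow(g74$edges), 1L)
  expect_equal(g74$edges$persistence, 1.0)  # only the 5 A pair
  coords[, 3, 1] <- ifelse(seq_len(100) <= 75, 12, 100)
  g75 <- contact_persistence_graph(ca_ensemble(coords))
  expect_identical(nrow(g75$edges), 2L)
  expect_equal(sort(g75$edges$persistence), c(0.75, 1.0))
})

test_that("a static chain at 3.8 A spacing connects residues up to two apart", {
  n <- 12
  pos <- cbind((seq_len(n) - 1) * 3.8, 0, 0)
  g <- contact_persistence_graph(ca_ensemble(static_ensemble(pos)))
  # brute-force adjacency oracle
  want <- which(abs(outer(1:n, 1:n, `-`)) %in% 1:2 & upper.tri(diag(n)),
                arr.ind = TRUE)
  got <- cbind(match(g$edges$i, paste0("A", 1:n)),
               match(g$edges$j, paste0("A", 1:n)))
  expect_identical(nrow(g$edges), nrow(want))
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
})

test_that("the contact graph is equivariant under residue relabelling", {
  ge <- gen_ensemble(10, 50, seed = 12)
  g1 <- contact_persistence_graph(ge$ensemble)
  perm <- sample(10)
  e2 <- ca_ensemble(ge$ensemble$coords[, perm, , drop = FALSE],
                    ge$ensemble$labels[perm])
  g2 <- contact_persistence_graph(e2)
  canon <- function(g) {
    k <- ifelse(g$edges$i < g$edges$j, paste(g$edges$i, g$edges$j),
                paste(g$edges$j, g$edges$i))
    sort(paste(k, signif(g$edges$persistence, 12)))
  }
  expect_identical(canon(g1), canon(g2))
})

test_that("motion covariance is normalised, symmetric and PSD", {
  ge <- gen_ensemble(8, 300, background_rho = 0.2, seed = 3)
  e <- superpose(ge$ensemble)
  cm <- motion_covariance(e)
  expect_equal(unname(diag(cm)), rep(1, 8))
  expect_true(all(cm >= 0 & cm <= 1))
  signed <- motion_covariance(e, signed = TRUE)
  expect_equal(signed, t(signed))
  expect_gte(min(eigen(signed, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9)
  # zero-variance residues are named in the error
  coords <- e$coords
  coords[, 4, ] <- 0
  expect_error(motion_covariance(ca_ensemble(coords, e$labels)), "A4")
})

test_that("motion covariance estimates planted correlations", {
  # the generator emits aligned frames (fixed backbone, no rigid motion),
  # so covariance is computed directly; re-superposing a small system would
  # itself induce correlations through the fitted rigid-body parameters
  ge0 <- gen_ensemble(6, 10000, background_rho = 0, seed = 17)
  cm0 <- motion_covariance(ge0$ensemble)
  expect_lt(max(cm0[upper.tri(cm0)]), 0.05)
  gep <- gen_ensemble(6, 5000,
                      correlated_pairs = data.frame(i = 2, j = 5, rho = 0.8),
                      seed = 18)
  cmp <- motion_covariance(gep$ensemble)
  expect_equal(cmp["A2", "A5"], 0.8, tolerance = 0.0625)  # +/- 0.05 absolute
})

test_that("edge lengths are the negative log of covariance", {
  ge <- gen_ensemble(6, 50, seed = 2)
  g <- contact_persistence_graph(ge$ensemble)
  cm <- motion_covariance(superpose(ge$ensemble))
  cm[] <- 1  # c = 1 -> d = 0
  gw <- edge_lengths(g, cm)
  expect_equal(gw$edges$d_ij, rep(0, nrow(gw$edges)))
  cm[] <- exp(-1); diag(cm) <- 1
  expect_equal(edge_lengths(g, cm)$edges$d_ij, rep(1, nrow(g$edges)))
  cm[] <- 0.1; diag(cm) <- 1
  expect_equal(edge_lengths(g, cm)$edges$d_ij[1], log(10), tolerance = 1e-12)
  cm[] <- 1.5
  expect_error(edge_lengths(g, cm), "clamp")
})

test_that("Dijkstra matches exhaustive enumeration and an independent library", {
  for (s in 1:25) {
    rg <- random_graph(s)
    src <- rg$nodes[1]; tgt <- rg$nodes[length(rg$nodes)]
    got <- shortest_pathway(rg$graph, src, tgt)
    oracle <- brute_force_shortest(rg$nodes, rg$edges, src, tgt)
    expect_equal(got$total_length, oracle$len, tolerance = 1e-12)
    ig <- igraph::graph_from_data_frame(
      rg$edges[, c("i", "j")], directed = FALSE,
      vertices = rg$nodes)
    dl <- igraph::distances(ig, v = src, to = tgt,
                            weights = rg$edges$d_ij)[1, 1]
    expect_equal(got$total_length, dl, tolerance = 1e-12)
    expect_equal(sum(got$edge_lengths), got$total_length, tolerance = 1e-12)
  }
})

test_that("pathway results handle trivial and disconnected cases", {
  ge <- gen_ensemble(9, 40, seed = 6)
  g <- edge_lengths(contact_persistence_graph(ge$ensemble),
                    motion_covariance(superpose(ge$ensemble)))
  p0 <- shortest_pathway(g, "A3", "A3")
  expect_identical(p0$residues, "A3")
  expect_equal(p0$total_length, 0)
  expect_error(shortest_pathway(g, "A3", "ZZ"), "unknown")
  # disconnected target
  g2 <- g
  g2$nodes <- c(g2$nodes, "B1")
  p <- shortest_pathway(g2, "A1", "B1")
  expect_false(p$found)
  expect_identical(p$total_length, Inf)
})

test_that("shortest paths are invariant to the logarithm base", {
  ge <- gen_ensemble(16, 200, background_rho = 0.1,
                     planted_chain = 1:4, chain_rho = 0.85, seed = 9)
  cm <- motion_covariance(superpose(ge$ensemble))
  g <- contact_persistence_graph(ge$ensemble)
  p_ln <- shortest_pathway(edge_lengths(g, cm), "A1", "A4")
  p_10 <- shortest_pathway(edge_lengths(g, cm, base = 10), "A1", "A4")
  expect_identical(p_ln$residues, p_10$residues)
  expect_equal(p_ln$total_length, p_10$total_length * log(10),
               tolerance = 1e-9)
})

test_that("graph and path exports are readable round-trips", {
  ge <- gen_ensemble(8, 60, seed = 5)
  g <- edge_lengths(contact_persistence_graph(ge$ensemble),
                    motion_covariance(superpose(ge$ensemble)))
  tsv <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, tsv)
  back <- read.delim(tsv)
  expect_equal(back$d_ij, g$edges$d_ij)
  gml <- tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), 8)
  expect_equal(igraph::gsize(ig), nrow(g$edges))
  expect_equal(sort(igraph::edge_attr(ig, "d_ij")), sort(g$edges$d_ij),
               tolerance = 1e-12)
  pj <- tempfile(fileext = ".json")
  p <- shortest_pathway(g, "A1", "A8")
  write_path_json(p, pj)
  got <- jsonlite::read_json(pj, simplifyVector = TRUE)
  expect_identical(got$residues, p$residues)
  expect_equal(got$total_length, p$total_length)
})

test_that("equal-length path ties break by lexicographic node order", {
  edges <- data.frame(i = c("A", "A", "B", "C"),
                      j = c("B", "C", "D", "D"),
                      persistence = 1, c_ij = exp(-1), d_ij = 1)
  g <- structure(list(nodes = c("A", "B", "C", "D"), edges = edges,
                      cutoff = 8, min_persistence = 0.75),
                 class = "residue_graph")
  p <- shortest_pathway(g, "A", "D")
  expect_identical(p$residues, c("A", "B", "D"))
  expect_equal(p$total_length, 2)
})
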