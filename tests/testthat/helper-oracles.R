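# Independent oracles and fixture builders used across the test files.

# exhaustive shortest-path oracle: enumerates every simple path by DFS
brute_force_shortest <- function(nodes, edges, source, target) {
  adj <- lapply(stats::setNames(seq_along(nodes), nodes), function(i) NULL)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]; w <- edges$d_ij[k]
    adj[[i]] <- rbind(adj[[i]], data.frame(to = j, w = w))
    adj[[j]] <- rbind(adj[[j]], data.frame(to = i, w = w))
  }
  best <- list(len = Inf, path = character(0))
  dfs <- function(node, visited, len, path) {
    if (node == target) {
      if (len < best$len) best <<- list(len = len, path = path)
      return(invisible())
    }
    nb <- adj[[node]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      nxt <- nb$to[k]
      if (nxt %in% visited) next
      dfs(nxt, c(visited, nxt), len + nb$w[k], c(path, nxt))
    }
  }
  dfs(source, source, 0, source)
  best
}

# random connected-ish weighted graph on <= n_max nodes
random_graph <- function(seed, n_max = 10) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < 0.5
  # always keep a spanning path so source/target are connected
  spine <- cbind(seq_len(n - 1), 2:n)
  pick <- unique(rbind(pairs[keep, , drop = FALSE], spine))
  edges <- data.frame(i = nodes[pick[, 1]], j = nodes[pick[, 2]],
                      persistence = 1,
                      c_ij = runif(nrow(pick), 0.05, 1))
  edges$d_ij <- -log(edges$c_ij)
  g <- structure(list(nodes = nodes, edges = edges, cutoff = 8,
                      min_persistence = 0.75),
                 class = "residue_graph")
  list(graph = g, nodes = nodes, edges = edges)
}

# numeric mass-balance solve of the dormant/active/cofactor/inhibitor
# scheme at n_sites = 1: root-find the active fraction from conservation
numeric_three_step <- function(nadph, l0, kd_c, kd_i, kcat = 1) {
  vapply(nadph, function(x) {
    if (x == 0) return(0)
    resid <- function(a_act) {
      a_c <- a_act * x / kd_c
      a_ci <- a_c * x / kd_i
      a_d <- l0 * a_act
      (a_d + a_act + a_c + a_ci) - 1
    }
    a_act <- stats::uniroot(resid, c(0, 1), tol = 1e-14)$root
    kcat * a_act * x / kd_c
  }, numeric(1))
}

# enumeration oracle for the multi-site scheme: sum over site occupancies
enum_three_step <- function(nadph, l0, kd_c, kd_i, kcat = 1, n_sites = 4) {
  vapply(nadph, function(x) {
    a <- x / kd_c; b <- a * x / kd_i
    z <- 0; prod_sum <- 0
    for (kc in 0:n_sites) for (ki in 0:(n_sites - kc)) {
      ke <- n_sites - kc - ki
      wgt <- factorial(n_sites) / (factorial(kc) * factorial(ki) *
                                   factorial(ke)) * a^kc * b^ki
      z <- z + wgt
      prod_sum <- prod_sum + (kc / n_sites) * wgt
    }
    kcat * prod_sum / (l0 + z)
  }, numeric(1))
}

# apparent Hill slope of a saturation curve at half-saturation, by numeric
# differentiation of log(y/(1-y)) against log(l)
apparent_hill <- function(sat_fn, l_half, h = 1e-4) {
  lo <- l_half * exp(-h); hi <- l_half * exp(h)
  f <- function(l) { y <- sat_fn(l); log(y / (1 - y)) }
  (f(hi) - f(lo)) / (2 * h)
}

# minimal PDB text fixture from an atom table
write_toy_pdb <- function(path, atoms) {
  lines <- character(0)
  for (k in seq_len(nrow(atoms))) {
    a <- atoms[k, ]
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      k, a$elety, ifelse(is.null(a$alt) || a$alt == "", " ", a$alt),
      a$resid, a$chain, a$resno, a$x, a$y, a$z,
      if (!is.null(a$o)) a$o else 1, 0, a$elesy))
  }
  writeLines(c(lines, "END"), path)
  path
}

# cube of 8 carbon atoms with unit edge, one per residue
cube_atoms <- function() {
  g <- expand.grid(x = 0:1, y = 0:1, z = 0:1)
  data.frame(elety = "C1", resid = "LIG", chain = "A",
             resno = seq_len(8), x = g$x, y = g$y, z = g$z,
             o = 1, alt = "", elesy = "C", stringsAsFactors = FALSE)
}

# published wild-type parameter sets used as generative truth throughout
ref_hill <- list(vmax = 4.65, k_half = 278, n_hill = 1.76)
ref_si <- list(vmax = 4.38, km = 2.98, ki = 148.6)
ref_transient <- list(amplitudes = c(0.5, 0.5), k_obs = c(254.6, 46.2),
                      f_eq = 0)
ref_isotherm <- list(fmax1 = 0.5, kd1 = 0.45, n_step1 = 1.22,
                     fmax2 = 0.5, kd2 = 53.5)
ref_kobs_cs <- list(k_minus = 40, k_plus = 250, kd_app = 0.79)

# shared generation grids (assay designs used in recovery studies)
grid_tylosin <- c(0, 50, 100, 200, 300, 450, 650, 900, 1250, 1650, 2050, 2500)
grid_nadph <- exp(seq(log(0.5), log(200), length.out = 14))
grid_transient <- seq(0, 0.1, length.out = 2000)
grid_isotherm <- exp(seq(log(0.01), log(500), length.out = 16))
grid_kobs <- exp(seq(log(0.05), log(20), length.out = 12))
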