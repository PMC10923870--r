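#' Pipeline configuration and reports
#'
#' The three `run_*()` stages accept either a configuration list or a path
#' to a YAML/JSON file with the same structure. Every threshold defaults to
#' the workflow's standard value (8 Angstrom contact cutoff, 0.75
#' persistence, k = 4 states, 1.4 Angstrom probe, 4 sites per allosteric
#' unit). Reports embed an md5 hash of the canonicalised configuration plus
#' the seed, so identical config + seed reproduces identical results.
#'
#' @param config list or file path.
#' @return normalised configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) input_error("config file not found: %s", config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) input_error("config must be a list or a YAML/JSON file")
  config
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

make_report <- function(stage, results, config, seed) {
  structure(list(stage = stage, results = results,
                 provenance = list(
                   config_hash = config_hash(config),
                   seed = seed,
                   package_version = as.character(
                     utils::packageVersion("allokin")))),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Run report: stage '%s' (config %s, seed %s)\n", x$stage,
              x$provenance$config_hash, x$provenance$seed))
  for (nm in names(x$results)) {
    cat("--", nm, "--\n")
    print(x$results[[nm]])
  }
  invisible(x)
}

read_kinetic_csv <- function(path) {
  if (!file.exists(path)) input_error("dataset file not found: %s", path)
  d <- tryCatch(utils::read.csv(path),
                error = function(e) input_error("cannot parse %s: %s", path,
                                                conditionMessage(e)))
  if (!nrow(d) || !all(c("x", "y") %in% names(d)))
    input_error("dataset %s must have non-empty columns 'x' and 'y'", path)
  d
}

#' Run the kinetics analysis stage
#'
#' Fits every requested model to each dataset, compares them by AICc,
#' classifies cooperativity where a Hill coefficient was fitted, and
#' tabulates the kinetic constants (K_m or K_0.5, k_cat, k_cat/K_m, K_i,
#' Hill n with its verbal label).
#'
#' Config fields: `datasets` — a list of blocks with `name`, `file` (CSV
#' with columns `x`, `y`) or inline `data`, `models` (character vector of
#' model ids), optional `enzyme_conc` (uM) converting fitted vmax to k_cat;
#' top-level `seed`, `weights`.
#'
#' @param config list or YAML/JSON path (see [load_config()]).
#' @return a `run_report` whose `results` holds, per dataset, the fits,
#'   the model comparison and a parameter `table`.
#' @export
run_kinetics <- function(config) {
  config <- load_config(config)
  seed <- config$seed %||% 1
  weights <- config$weights %||% "none"
  if (is.null(config$datasets)) input_error("config has no 'datasets' block")
  results <- list()
  for (ds in config$datasets) {
    d <- if (!is.null(ds$file)) read_kinetic_csv(ds$file)
         else as.data.frame(ds$data)
    if (!nrow(d)) input_error("dataset '%s' is empty", ds$name %||% "?")
    fits <- lapply(ds$models, function(mid)
      kin_fit(d$x, d$y, mid, seed = seed, weights = weights))
    names(fits) <- ds$models
    bad <- !vapply(fits, `[[`, logical(1), "converged")
    if (all(bad)) numerical_error("no model converged on dataset '%s'",
                                  ds$name %||% "?")
    cmp <- if (length(fits) > 1) compare_models(fits) else NULL
    tab <- do.call(rbind, lapply(fits, kinetic_row))
    results[[ds$name %||% paste0("dataset", length(results) + 1)]] <-
      list(fits = fits, comparison = cmp, table = tab,
           enzyme_conc = ds$enzyme_conc)
  }
  make_report("kinetics", results, config, seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one row of the kinetic-constant table for a fitted model
kinetic_row <- function(fit) {
  est <- fit$estimates; se <- fit$std_errors
  km <- est[["km"]] %||na% est[["k_half"]] %||na% NA_real_
  kcat <- est[["vmax"]] %||na% NA_real_
  n <- est[["n_hill"]] %||na% est[["n_step1"]] %||na% NA_real_
  n_se <- se[["n_hill"]] %||na% se[["n_step1"]] %||na% NA_real_
  data.frame(model = fit$model_id,
             km_or_khalf = km, kcat = kcat,
             kcat_over_km = if (is.na(km) || is.na(kcat)) NA_real_
                            else kcat / km,
             ki = est[["ki"]] %||na% NA_real_,
             hill_n = n,
             cooperativity = if (is.na(n) || is.na(n_se)) NA_character_
                             else classify_cooperativity(n, n_se),
             r_squared = fit$r_squared, aicc = fit$aicc,
             stringsAsFactors = FALSE)
}

`%||na%` <- function(a, b) {
  v <- tryCatch(a, error = function(e) NULL)
  if (is.null(v)) b else v
}

#' Run the ensemble-network analysis stage
#'
#' Executes the full trajectory-analysis workflow on a coordinate ensemble:
#' superposition on a core selection, PCA, loop RMSDs, conformational-state
#' clustering, contact-persistence graph, motion covariance, negative-log
#' edge lengths, and the Dijkstra shortest pathway between the configured
#' source and target residues. Optionally computes the C-alpha pocket SASA
#' per clustered state on a sample of frames.
#'
#' Config fields: `ensemble` (multi-model PDB path, or a `ca_ensemble`),
#' `source`, `target` (residue labels), `core` / `loop1` / `loop2`
#' (residue labels or indices; loops default to the whole-range split),
#' `cutoff` (8), `persistence` (0.75), `k` (4), `seed`, `frame_mask`
#' (optional frame subset, e.g. ligand-bound frames only), `pocket`
#' (optional residue indices for per-state SASA), `output_dir` (optional:
#' writes GraphML, TSV edge list, path JSON, occupancy CSV).
#'
#' @param config list or YAML/JSON path.
#' @return a `run_report` with `pca`, `clustering`, `graph`, `covariance`,
#'   `path`, and optionally `state_sasa`.
#' @export
run_network <- function(config) {
  config <- load_config(config)
  seed <- config$seed %||% 1
  e <- config$ensemble
  if (is.character(e)) e <- read_ensemble_pdb(e)
  if (!inherits(e, "ca_ensemble"))
    input_error("config$ensemble must be a ca_ensemble or a multi-model PDB path")
  if (!is.null(config$frame_mask))
    e <- ca_ensemble(e$coords[config$frame_mask, , , drop = FALSE], e$labels)
  src <- config$source; tgt <- config$target
  if (is.null(src) || is.null(tgt))
    input_error("config must name 'source' and 'target' residues")
  for (nm in c(src, tgt))
    if (!nm %in% e$labels)
      input_error("residue '%s' not in ensemble (known: %s ...)", nm,
                  paste(utils::head(e$labels, 5), collapse = ", "))
  es <- superpose(e, core = config$core)
  # fail fast on degenerate (motionless) residues: the covariance step
  # would be undefined for them
  v <- rowSums(sapply(1:3, function(a)
    apply(es$coords[, , a], 2, stats::var)))
  if (any(v <= 0))
    numerical_error("zero-variance residue(s): %s",
                    paste(es$labels[v <= 0], collapse = ", "))
  pca <- ensemble_pca(es)
  li1 <- config$loop1 %||% seq_len(ceiling(n_residues(e) / 2))
  li2 <- config$loop2 %||% seq(ceiling(n_residues(e) / 2) + 1, n_residues(e))
  feats <- cbind(loop1 = loop_rmsd(es, li1), loop2 = loop_rmsd(es, li2))
  clus <- cluster_states(feats, k = config$k %||% 4, seed = seed)
  g <- contact_persistence_graph(e, cutoff = config$cutoff %||% 8.0,
                                 persistence = config$persistence %||% 0.75)
  cmat <- motion_covariance(es)
  g <- edge_lengths(g, cmat)
  path <- shortest_pathway(g, src, tgt)
  results <- list(pca = pca, clustering = clus, graph = g,
                  covariance = cmat, path = path)
  if (!is.null(config$pocket)) {
    results$state_sasa <- state_pocket_sasa(es, clus, config$pocket,
                                            n_sample = config$n_sample %||% 20,
                                            seed = seed)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_graphml(g, file.path(config$output_dir, "network.graphml"))
    write_graph_tsv(g, file.path(config$output_dir, "network_edges.tsv"))
    write_path_json(path, file.path(config$output_dir, "pathway.json"))
    utils::write.csv(data.frame(state = clus$state_names,
                                occupancy = clus$occupancy),
                     file.path(config$output_dir, "state_occupancy.csv"),
                     row.names = FALSE)
  }
  cfg_hashable <- config
  cfg_hashable$ensemble <- NULL
  make_report("network", results, cfg_hashable, seed)
}

# mean C-alpha pocket SASA per conformational state, sampled frames
state_pocket_sasa <- function(e, clus, pocket, n_sample = 20, seed = 1) {
  k <- length(clus$occupancy)
  out <- local_seed(seed, {
    vapply(seq_len(k), function(s) {
      fr <- which(clus$labels == s)
      if (!length(fr)) return(NA_real_)
      fr <- if (length(fr) > n_sample) sample(fr, n_sample) else fr
      mean(vapply(fr, function(f)
        as.numeric(pocket_sasa(frame_structure(e, f), pocket)), numeric(1)))
    }, numeric(1))
  })
  data.frame(state = clus$state_names, mean_pocket_sasa = out)
}

# minimal mol_structure built from one ensemble frame (C-alpha carbons)
frame_structure <- function(e, frame) {
  at <- data.frame(elety = "CA", elesy = "C",
                   resno = resno_from_labels(e$labels), insert = "",
                   resid = "ALA", chain = "A", alt = "", o = 1,
                   x = e$coords[frame, , 1], y = e$coords[frame, , 2],
                   z = e$coords[frame, , 3], stringsAsFactors = FALSE)
  structure(list(atoms = at, n_models = 1, source = "<frame>"),
            class = "mol_structure")
}

#' Run the structural-measurement stage
#'
#' Evaluates configured named distances and pocket SASAs on a structure.
#'
#' Config fields: `structure` (PDB/mmCIF path), `distances` — list of
#' blocks `name`, `a`, `b` (each a list of [sel()] arguments), optional
#' `mode` (`"single"`/`"min"`); `pockets` — list of blocks `name`,
#' `residues`, optional `chain`; `probe`, `n_points`.
#'
#' @param config list or YAML/JSON path.
#' @return a `run_report` with a `measurements` table.
#' @export
run_structure <- function(config) {
  config <- load_config(config)
  s <- config$structure
  if (is.character(s)) s <- read_structure(s)
  if (!inherits(s, "mol_structure"))
    input_error("config$structure must be a structure path or mol_structure")
  rows <- list()
  for (d in config$distances %||% list()) {
    val <- atom_distance(s, do.call(sel, as.list(d$a)),
                         do.call(sel, as.list(d$b)),
                         mode = d$mode %||% "single")
    rows[[length(rows) + 1]] <- data.frame(
      name = d$name %||% "distance", kind = "distance", value = val,
      units = "Angstrom", stringsAsFactors = FALSE)
  }
  for (p in config$pockets %||% list()) {
    val <- as.numeric(pocket_sasa(s, p$residues, chain = p$chain,
                                  probe = config$probe %||% 1.4,
                                  n_points = config$n_points %||% 960))
    rows[[length(rows) + 1]] <- data.frame(
      name = p$name %||% "pocket", kind = "pocket_sasa", value = val,
      units = "Angstrom^2", stringsAsFactors = FALSE)
  }
  cfg_hashable <- config
  cfg_hashable$structure <- NULL
  make_report("structure",
              list(measurements = do.call(rbind, rows)),
              cfg_hashable, config$seed %||% 1)
}
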