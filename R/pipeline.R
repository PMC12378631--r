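#' Assemble and validate a pipeline configuration
#'
#' Collects every tunable of the contacts -> occupancy -> PLS pipeline with
#' its default. Paths are interpreted relative to the directory the config
#' file lives in (or the working directory for in-memory configs).
#'
#' @param topology Path to the topology PDB.
#' @param trajectories data.frame with columns `path`, `ligand_id`,
#'   `replicate_id`.
#' @param ligand_table Path to the ligand CSV.
#' @param ligand_resname Residue name(s) identifying the ligand (NULL =
#'   HETATM rule).
#' @param carboxylate_atoms,ligand_ring_atoms Group-annotation rules (lists
#'   of ligand atom-name vectors; see [annotate_groups()]).
#' @param candidate_cutoff Heavy-atom candidate threshold, Angstrom.
#' @param ring_candidate_cutoff Ring-centroid candidate threshold, Angstrom.
#' @param stride Candidate-enumeration frame stride (1 = every frame;
#'   occupancy always uses every frame).
#' @param hbond_elements Hydrogen-bond-capable element set.
#' @param cutoffs Named per-contact-type occupancy cutoffs (Angstrom);
#'   partial overrides of the defaults are allowed.
#' @param replicate_policy `"mean"` or `"concat"` (see [build_matrix()]).
#' @param n_components PLS components (NULL = `min(2, n_ligands - 1)`).
#' @param scale Autoscale X in the PLS fit.
#' @param smoothing_window Window (frames) for the exported smoothed trends.
#' @param seed Seed recorded in the run log.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(topology = "topology.pdb",
                            trajectories = NULL,
                            ligand_table = "ligands.csv",
                            ligand_resname = NULL,
                            carboxylate_atoms = list(),
                            ligand_ring_atoms = list(),
                            candidate_cutoff = 4.0,
                            ring_candidate_cutoff = 6.0,
                            stride = 1L,
                            hbond_elements = c("N", "O", "S"),
                            cutoffs = NULL,
                            replicate_policy = "mean",
                            n_components = NULL,
                            scale = TRUE,
                            smoothing_window = 51L,
                            seed = 1L) {
  if (candidate_cutoff <= 0 || ring_candidate_cutoff <= 0)
    stop("candidate cutoffs must be positive")
  if (stride < 1) stop("stride must be >= 1")
  cutoffs <- .merge_cutoffs(cutoffs)
  if (!replicate_policy %in% c("mean", "concat"))
    stop("replicate_policy must be 'mean' or 'concat'")
  structure(list(topology = topology, trajectories = trajectories,
                 ligand_table = ligand_table, ligand_resname = ligand_resname,
                 carboxylate_atoms = carboxylate_atoms,
                 ligand_ring_atoms = ligand_ring_atoms,
                 candidate_cutoff = candidate_cutoff,
                 ring_candidate_cutoff = ring_candidate_cutoff,
                 stride = as.integer(stride),
                 hbond_elements = hbond_elements,
                 cutoffs = cutoffs, replicate_policy = replicate_policy,
                 n_components = n_components, scale = scale,
                 smoothing_window = as.integer(smoothing_window),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.config_to_yaml <- function(config) {
  out <- unclass(config)
  out$cutoffs <- as.list(out$cutoffs)
  if (!is.null(out$trajectories)) out$trajectories <- as.list(out$trajectories)
  out
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML config file (keys as in [pipeline_config()]).
#' @return A `pipeline_config`; the config directory is attached so relative
#'   input paths resolve against it.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$trajectories))
    raw$trajectories <- as.data.frame(raw$trajectories,
                                      stringsAsFactors = FALSE)
  if (!is.null(raw$cutoffs)) raw$cutoffs <- unlist(raw$cutoffs)
  known <- names(formals(pipeline_config))
  config <- do.call(pipeline_config, raw[intersect(names(raw), known)])
  attr(config, "dir") <- dirname(normalizePath(path))
  config
}

#' Run the contact -> occupancy -> PLS analysis on in-memory objects
#'
#' The computational core of the pipeline: enumerates candidate contacts per
#' trajectory (union over all ligands and replicates), filters to
#' hydrogen-bond-capable pairs and ring pi-stacking candidates, collapses
#' equivalent distances, computes occupancy percentages, assembles the
#' ligands x contacts matrix, and fits the PLS model of pIC50 on occupancy.
#'
#' @param topo Topology (annotated or not; annotation rules are taken from
#'   `config`).
#' @param trajs Named list of trajectories.
#' @param ligands Ligand table (data.frame with `ligand_id`, `ic50_nM`).
#' @param config A [pipeline_config()].
#' @param ligand_ids Character vector mapping each trajectory to its ligand.
#' @return A `sar_run`: list with `topology`, `contacts`, `occupancy` (long),
#'   `X` (occupancy matrix), `y`, `model`, `weights`, `coefficients`,
#'   `warnings`, `config`.
#' @export
run_contact_sar <- function(topo, trajs, ligands, config, ligand_ids) {
  warnings <- character(0)
  note <- function(msg) warnings[[length(warnings) + 1L]] <<- msg

  topo <- annotate_groups(topo,
                          carboxylate_atoms = config$carboxylate_atoms,
                          ligand_ring_atoms = config$ligand_ring_atoms)

  atom_pairs <- list(); ring_pairs <- list()
  for (t in seq_along(trajs)) {
    cand <- enumerate_candidates(trajs[[t]], topo,
                                 candidate_cutoff = config$candidate_cutoff,
                                 stride = config$stride)
    fl <- filter_contacts(cand, topo, trajs[[t]],
                          hbond_elements = config$hbond_elements,
                          ring_cutoff = config$ring_candidate_cutoff,
                          stride = config$stride)
    atom_pairs[[t]] <- fl$atom_pairs[c("ligand_atom", "residue_atom")]
    ring_pairs[[t]] <- fl$ring_pairs
  }
  ap <- unique(do.call(rbind, atom_pairs))
  rp <- unique(do.call(rbind, ring_pairs))
  contacts <- collapse_equivalents(
    list(atom_pairs = ap, ring_pairs = rp), topo,
    cutoffs = config$cutoffs,
    provenance = list(candidate_cutoff = config$candidate_cutoff,
                      ring_candidate_cutoff = config$ring_candidate_cutoff,
                      stride = config$stride))
  if (!nrow(contacts)) stop("stage contacts: no contacts survive filtering")

  occ <- compute_occupancy(trajs, topo, contacts, ligand_ids)
  X <- build_matrix(occ, contact_ids = contacts$contact_id,
                    policy = config$replicate_policy)

  keep <- ligands$ligand_id[!is.na(ligands$ic50_nM)]
  if (length(keep) < length(unique(ligand_ids)))
    note(sprintf("%d ligand(s) without IC50 excluded from the PLS fit",
                 length(unique(ligand_ids)) - length(keep)))
  row_lig <- attr(X, "ligand_ids")
  Xfit <- X[row_lig %in% keep, , drop = FALSE]
  yfit <- pic50(ligands$ic50_nM[match(row_lig[row_lig %in% keep],
                                      ligands$ligand_id)])
  if (nrow(Xfit) < 2) stop("stage pls: fewer than 2 ligands with potencies")
  if (length(unique(row_lig[row_lig %in% keep])) <= 4)
    note(paste("small-n: 4 or fewer ligands; the PLS model is severely",
               "underdetermined and coefficients are indicative only"))
  n_comp <- config$n_components
  if (is.null(n_comp)) n_comp <- min(2L, nrow(Xfit) - 1L)
  model <- withCallingHandlers(
    fit_pls(Xfit, yfit, n_components = n_comp, scale = config$scale),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })

  coefficients <- data.frame(contact_id = model$contact_ids,
                             beta_standardized = model$beta_standardized,
                             beta_raw = model$beta_raw,
                             stringsAsFactors = FALSE)
  weights <- do.call(rbind, lapply(seq_len(model$n_components), function(a) {
    w <- contact_weights(model, a)
    w$component <- a
    w[c("contact_id", "component", "weight")]
  }))
  structure(list(topology = topo, contacts = contacts, occupancy = occ,
                 X = X, y = yfit, model = model, weights = weights,
                 coefficients = coefficients, warnings = warnings,
                 config = config),
            class = "sar_run")
}

#' @export
print.sar_run <- function(x, ...) {
  cat(sprintf("<sar_run> %d contact(s), %d ligand row(s), %d PLS component(s)\n",
              nrow(x$contacts), nrow(x$X), x$model$n_components))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Run the full pipeline from files
#'
#' Reads the topology, trajectories and ligand table named in the config,
#' executes [run_contact_sar()], and writes all artifacts to `outdir`:
#' `contacts.csv`, `occupancy_matrix.csv`, `pls_weights.csv`,
#' `pls_coefficients.csv`, `timeseries_trends.json` (smoothed trends and
#' fluctuation bands for the highest-|coefficient| contacts) and
#' `run_log.yaml` (config echo, package version, seed, warnings, applied
#' defaults). Warnings never abort; stage errors abort with the stage name.
#'
#' @param config A `pipeline_config` or path to a YAML config.
#' @param outdir Output directory (created if needed).
#' @param n_trend_contacts How many top contacts get exported trend series.
#' @return The `sar_run`, invisibly.
#' @export
run_all <- function(config, outdir = "sar_out", n_trend_contacts = 3L) {
  if (is.character(config)) config <- read_config(config)
  base <- attr(config, "dir")
  resolve <- function(p) if (!is.null(base)) file.path(base, p) else p

  topo <- read_topology(resolve(config$topology),
                        ligand_resname = config$ligand_resname)
  ligands <- read_ligand_table(resolve(config$ligand_table))
  ti <- config$trajectories
  if (is.null(ti) || !nrow(ti))
    stop("stage input: config lists no trajectories")
  trajs <- list()
  for (j in seq_len(nrow(ti)))
    trajs[[ti$replicate_id[j]]] <- read_trajectory(resolve(ti$path[j]), topo,
                                                   replicate_id = ti$replicate_id[j])
  run <- run_contact_sar(topo, trajs, ligands, config,
                         ligand_ids = ti$ligand_id)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(contact_table(run$contacts),
                   file.path(outdir, "contacts.csv"), row.names = FALSE)
  occ_out <- data.frame(ligand_id = rownames(run$X),
                        as.data.frame(unclass(run$X), check.names = FALSE),
                        check.names = FALSE)
  utils::write.csv(occ_out, file.path(outdir, "occupancy_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(run$weights, file.path(outdir, "pls_weights.csv"),
                   row.names = FALSE)
  utils::write.csv(run$coefficients, file.path(outdir, "pls_coefficients.csv"),
                   row.names = FALSE)

  top <- run$coefficients$contact_id[
    order(abs(run$coefficients$beta_standardized), decreasing = TRUE)]
  top <- utils::head(top, n_trend_contacts)
  trends <- list()
  for (cid in top) {
    ci <- which(run$contacts$contact_id == cid)
    for (t in seq_along(trajs)) {
      ts <- distance_timeseries(trajs[[t]], run$topology,
                                run$contacts[ci, , drop = FALSE])
      window <- min(config$smoothing_window, length(ts$distances))
      sm <- smooth_series(ts, window)
      trends[[paste(cid, trajs[[t]]$replicate_id, sep = "|")]] <-
        list(contact_id = cid, replicate_id = trajs[[t]]$replicate_id,
             cutoff = ts$cutoff, window = window,
             trend = sm$trend, band = sm$band)
    }
  }
  jsonlite::write_json(trends, file.path(outdir, "timeseries_trends.json"),
                       auto_unbox = TRUE, digits = NA)

  log <- list(
    package = "contactsar",
    version = as.character(utils::packageVersion("contactsar")),
    seed = config$seed,
    config = .config_to_yaml(config),
    defaults_applied = list(
      replicate_policy = config$replicate_policy,
      occupancy_cutoffs = as.list(config$cutoffs),
      candidate_cutoff = config$candidate_cutoff,
      ring_candidate_cutoff = config$ring_candidate_cutoff,
      stride = config$stride,
      pls_components = run$model$n_components,
      pls_autoscale = config$scale,
      fluctuation_band = "plus/minus one rolling standard deviation",
      missing_contact_fill = "0 percent (never within the candidate cutoff)"),
    warnings = run$warnings)
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  invisible(run)
}
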