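# Clamp to +/- bound (used to make jitter strictly bounded so programmed
# contacts can never cross their cutoff).
.clamp <- function(x, bound) pmin(pmax(x, -bound), bound)

# Per-atom positional jitter applied to every atom in every frame.
.atom_jitter_sd <- 0.02
.atom_jitter_max <- 4 * .atom_jitter_sd

.frac <- function(x) x - floor(x)

#' Default planted contact programs
#'
#' Four programs spanning every contact template and collapse rule, with the
#' planted potency pattern: the C-terminal-carboxylate/Arg929 salt bridge
#' hurts potency (coefficient -1.5 pIC50 per unit occupancy), an
#' Arg439-guanidinium hydrogen bond helps (+1.5), a Tyr961 pi-stack and a
#' glutamate hydrogen bond are inert controls (0). Per-ligand stationary
#' occupancies are fixed, well-spread design vectors: a linear ramp for the
#' Arg929 program and low-discrepancy (golden-ratio) sequences for the rest,
#' so the occupancy columns are far from collinear at any series size.
#'
#' @param n_ligands Number of ligands in the series.
#' @return List of contact program lists (fields `name`, `template`,
#'   `residue_label`, `target_occupancy`, `d_on`, `d_off`, `beta_true`).
#' @export
default_contact_programs <- function(n_ligands) {
  i <- seq_len(n_ligands)
  spread <- function(phi) 0.05 + 0.9 * .frac(i * phi)
  list(
    list(name = "arg929_salt_bridge", template = "salt_bridge",
         residue_label = "ARG929",
         target_occupancy = seq(0.05, 0.95, length.out = n_ligands),
         d_on = 4.0, d_off = 8.0, beta_true = -1.5),
    list(name = "arg439_hbond", template = "guanidinium_hbond",
         residue_label = "ARG439",
         target_occupancy = spread(0.6180339887),
         d_on = 4.0, d_off = 8.0, beta_true = 1.5),
    list(name = "tyr961_pi", template = "pi_stack",
         residue_label = "TYR961",
         target_occupancy = spread(0.4142135624),
         d_on = 4.7, d_off = 8.5, beta_true = 0),
    list(name = "glu465_hbond", template = "hbond",
         residue_label = "GLU465",
         target_occupancy = spread(0.7548776662),
         d_on = 2.9, d_off = 6.5, beta_true = 0)
  )
}

#' Specification of a synthetic protein-ligand SAR study
#'
#' Defines the study conditions for the generator: a ligand series, replicate
#' MD-like trajectories with two-state (bound/unbound) contact dynamics whose
#' stationary occupancy is programmable per ligand, and a linear
#' occupancy-to-pIC50 affinity model with Gaussian noise.
#'
#' Validation guarantees occupancy identifiability: for every program,
#' `d_on` plus the worst-case jitter must stay below the contact-type cutoff,
#' and `d_off` minus it must stay above, so a frame's state is always read
#' back correctly by the occupancy stage.
#'
#' @param n_ligands Number of ligands (default 8).
#' @param replicates_per_ligand Independent trajectory replicates per ligand
#'   (default 3, as in triplicate MD protocols).
#' @param frames_per_replicate Frames per replicate (default 2000).
#' @param sim_time_ns Nominal simulated time per replicate in ns (default
#'   500); only used for reporting total sampling.
#' @param contact_programs List of contact programs (see
#'   [default_contact_programs()]).
#' @param intercept Affinity model intercept, pIC50 units (default 7.0).
#' @param noise_sd Gaussian noise on pIC50 (default 0.2).
#' @param switching_rate Markov switching-rate scale in (0, 1]: the on->off
#'   probability per frame is `rate * (1 - occupancy)` and off->on is
#'   `rate * occupancy`, giving the programmed stationary occupancy with
#'   contact dwell times of a few frames (default 0.25).
#' @param jitter_sd Gaussian jitter (Angstrom) on the programmed gap
#'   distance, truncated at 4 sd (default 0.08).
#' @param seed Base random seed; every (ligand, replicate) trajectory and the
#'   affinity noise derive their own sub-seed from it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_ligands = 8L, replicates_per_ligand = 3L,
                           frames_per_replicate = 2000L, sim_time_ns = 500,
                           contact_programs = default_contact_programs(n_ligands),
                           intercept = 7.0, noise_sd = 0.2,
                           switching_rate = 0.25, jitter_sd = 0.08,
                           seed = 1L) {
  if (n_ligands < 1 || replicates_per_ligand < 1 || frames_per_replicate < 1)
    stop("n_ligands, replicates_per_ligand and frames_per_replicate must be >= 1")
  if (switching_rate <= 0 || switching_rate > 1)
    stop("switching_rate must be in (0, 1]")
  margin <- 4 * jitter_sd + 2 * .atom_jitter_max
  labels <- vapply(contact_programs, `[[`, character(1), "residue_label")
  if (anyDuplicated(labels))
    stop("contact programs must target distinct residues")
  for (pr in contact_programs) {
    if (length(pr$target_occupancy) != n_ligands)
      stop(sprintf("program %s: need one target occupancy per ligand", pr$name))
    if (any(pr$target_occupancy < 0 | pr$target_occupancy > 1))
      stop(sprintf("program %s: target occupancies must lie in [0, 1]", pr$name))
    cutoff <- .default_cutoffs[[.template_contact_type(pr$template)]]
    if (pr$d_on + margin >= cutoff || pr$d_off - margin <= cutoff)
      stop(sprintf(
        "program %s: jitter too large to guarantee separation (d_on %.2f + %.2f and d_off %.2f - %.2f must bracket cutoff %.2f)",
        pr$name, pr$d_on, margin, pr$d_off, margin, cutoff))
  }
  structure(list(n_ligands = as.integer(n_ligands),
                 replicates_per_ligand = as.integer(replicates_per_ligand),
                 frames_per_replicate = as.integer(frames_per_replicate),
                 sim_time_ns = sim_time_ns,
                 contact_programs = contact_programs,
                 intercept = intercept, noise_sd = noise_sd,
                 switching_rate = switching_rate, jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

.template_contact_type <- function(template) {
  switch(template,
         salt_bridge = "salt_bridge",
         guanidinium_hbond = "collapsed_guanidinium",
         hbond = "hbond",
         pi_stack = "pi_stack",
         stop("unknown contact template: ", template))
}

#' Total sampling per ligand in microseconds
#'
#' Replicates times nominal simulated time; the default 3 x 500 ns protocol
#' gives 1.5 us per ligand.
#'
#' @param spec A `synthetic_spec`.
#' @return Microseconds of sampling per ligand.
#' @export
total_sampling_us <- function(spec) {
  spec$replicates_per_ligand * spec$sim_time_ns / 1000
}

# Local residue geometries per template, relative to the bay origin. The
# residue representative (CZ, OE1 or the ring centroid) sits at the origin;
# the ligand group approaches along +x so the governing distance equals the
# gap d exactly.
.residue_geometry <- function(template, resname, resno) {
  hex <- function(prefix) {
    th <- 2 * pi * (0:5) / 6
    data.frame(atom_name = prefix, x = 0, y = 1.39 * cos(th), z = 1.39 * sin(th))
  }
  geo <- switch(template,
    salt_bridge = ,
    guanidinium_hbond = data.frame(
      atom_name = c("CB", "NE", "CZ", "NH1", "NH2"),
      x = c(-2.50, -1.33, 0, 1.15, 1.15),
      y = c(0, 0, 0, 0.66, -0.66), z = 0),
    hbond = data.frame(
      atom_name = c("CD", "OE1", "OE2"),
      x = c(-1.25, 0, -1.85), y = c(0, 0, 1.07), z = 0),
    pi_stack = hex(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")))
  geo$residue_name <- resname
  geo$residue_number <- resno
  geo
}

# Ligand group geometry per template, relative to the group reference point
# (placed at x = gap). Returns atom names, local offsets, and which atom (or
# centroid) governs the programmed distance.
.ligand_geometry <- function(template, k) {
  switch(template,
    salt_bridge = data.frame(
      atom_name = c(paste0("C", k), paste0("O", k, "A"), paste0("O", k, "B")),
      x = c(0, -0.55, -0.55), y = c(0, 1.12, -1.12), z = 0),
    guanidinium_hbond = data.frame(atom_name = paste0("N", k), x = 0, y = 0, z = 0),
    hbond = data.frame(atom_name = paste0("O", k), x = 0, y = 0, z = 0),
    pi_stack = {
      th <- 2 * pi * (0:5) / 6
      data.frame(atom_name = paste0("C", k, LETTERS[1:6]),
                 x = 0, y = 1.39 * cos(th), z = 1.39 * sin(th))
    })
}

#' Build the schematic pocket topology for a synthetic spec
#'
#' One protein residue per contact program (ARG with a full guanidinium,
#' TYR with its aromatic ring, GLU with a carboxylate as a hydrogen-bond
#' partner) and a single ligand entity carrying the matching groups
#' (carboxylate, amide-like N or O donors/acceptors, a six-membered ring).
#' Each program lives in its own spatial bay 50 Angstrom from the next, so
#' programmed contacts are independent. Geometry is schematic: only
#' inter-group distances carry information.
#'
#' @param spec A `synthetic_spec`.
#' @return An (unannotated) `topology`; the annotation rules it was built
#'   with are attached as attribute `annotation` (`ligand_resname`,
#'   `carboxylate_atoms`, `ligand_ring_atoms`) and the placement geometry as
#'   attribute `geometry`.
#' @export
build_topology <- function(spec) {
  rows <- list()
  geometry <- list()
  carboxylate_atoms <- list()
  ligand_ring_atoms <- list()
  for (k in seq_along(spec$contact_programs)) {
    pr <- spec$contact_programs[[k]]
    bay <- c((k - 1) * 50, 0, 0)
    resname <- sub("[0-9]+$", "", pr$residue_label)
    resno <- as.integer(sub("^[A-Za-z]+", "", pr$residue_label))
    rgeo <- .residue_geometry(pr$template, resname, resno)
    rgeo$x <- rgeo$x + bay[1]; rgeo$y <- rgeo$y + bay[2]; rgeo$z <- rgeo$z + bay[3]
    rgeo$record <- "ATOM"; rgeo$chain_id <- "A"; rgeo$is_ligand <- FALSE
    lgeo <- .ligand_geometry(pr$template, k)
    lloc <- as.matrix(lgeo[, c("x", "y", "z")])
    lgeo$x <- lgeo$x + bay[1] + pr$d_off
    lgeo$y <- lgeo$y + bay[2]; lgeo$z <- lgeo$z + bay[3]
    lgeo$record <- "HETATM"; lgeo$chain_id <- "L"
    lgeo$residue_name <- "LIG"; lgeo$residue_number <- 1L
    lgeo$is_ligand <- TRUE
    rows[[length(rows) + 1L]] <- rgeo
    rows[[length(rows) + 1L]] <- lgeo
    geometry[[k]] <- list(template = pr$template, bay = bay,
                          ligand_atom_names = lgeo$atom_name,
                          ligand_local = lloc,
                          d_on = pr$d_on, d_off = pr$d_off)
    if (pr$template == "salt_bridge")
      carboxylate_atoms[[length(carboxylate_atoms) + 1L]] <- lgeo$atom_name
    if (pr$template == "pi_stack")
      ligand_ring_atoms[[length(ligand_ring_atoms) + 1L]] <- lgeo$atom_name
  }
  atoms <- do.call(rbind, rows)
  # protein first, ligand last, as a deposited complex would list them
  atoms <- atoms[order(atoms$is_ligand), , drop = FALSE]
  atoms$element <- .infer_element(atoms$atom_name, rep("", nrow(atoms)))
  atoms$is_heavy <- atoms$element != "H"
  atoms$atom_index <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  topo <- structure(list(atoms = atoms, rings = list(), groups = list()),
                    class = "topology")
  for (k in seq_along(geometry))
    geometry[[k]]$mobile_idx <-
      match(geometry[[k]]$ligand_atom_names, atoms$atom_name)
  attr(topo, "geometry") <- geometry
  attr(topo, "annotation") <- list(ligand_resname = "LIG",
                                   carboxylate_atoms = carboxylate_atoms,
                                   ligand_ring_atoms = ligand_ring_atoms)
  topo
}

# Two-state Markov chain with stationary P(on) = p_on.
.markov_states <- function(n, p_on, rate) {
  on <- logical(n)
  p_on_off <- rate * (1 - p_on)
  p_off_on <- rate * p_on
  u <- stats::runif(n)
  state <- u[1] < p_on
  on[1] <- state
  for (t in seq_len(n)[-1]) {
    state <- if (state) u[t] >= p_on_off else u[t] < p_off_on
    on[t] <- state
  }
  on
}

.traj_seed <- function(spec, ligand_index, replicate_index) {
  (spec$seed %% 100000L) * 20011L + ligand_index * 211L + replicate_index
}

#' Simulate one replicate trajectory
#'
#' For each contact program, a two-state Markov chain over (bound, unbound)
#' with stationary bound probability equal to the ligand's programmed target
#' occupancy drives the gap distance between the ligand group and its partner
#' residue: approximately `d_on` when bound, `d_off` when unbound, plus
#' truncated Gaussian jitter small enough that the cutoff is never crossed.
#' All atoms additionally receive small bounded positional jitter.
#' Deterministic for a fixed (spec seed, ligand, replicate).
#'
#' @param topo Topology from [build_topology()] (carries the placement
#'   geometry).
#' @param spec The `synthetic_spec`.
#' @param ligand_index Ligand number (1-based).
#' @param replicate_index Replicate number (1-based).
#' @return A `trajectory` with `replicate_id` `"L<ligand>_rep<replicate>"`.
#' @export
simulate_trajectory <- function(topo, spec, ligand_index, replicate_index) {
  geometry <- attr(topo, "geometry")
  if (is.null(geometry))
    stop("topology does not carry synthetic placement geometry")
  n_frames <- spec$frames_per_replicate
  n_atoms <- nrow(topo$atoms)
  set.seed(.traj_seed(spec, ligand_index, replicate_index))
  base <- as.matrix(topo$atoms[, c("x", "y", "z")])
  coords <- aperm(array(base, dim = c(n_atoms, 3, n_frames)), c(3, 1, 2))
  for (k in seq_along(geometry)) {
    g <- geometry[[k]]
    pr <- spec$contact_programs[[k]]
    occ <- pr$target_occupancy[ligand_index]
    on <- .markov_states(n_frames, occ, spec$switching_rate)
    gap <- ifelse(on, pr$d_on, pr$d_off) +
      .clamp(stats::rnorm(n_frames, 0, spec$jitter_sd), 4 * spec$jitter_sd)
    coords[, g$mobile_idx, 1] <-
      outer(gap + g$bay[1], g$ligand_local[, 1], "+")
  }
  coords <- coords + array(.clamp(stats::rnorm(length(coords), 0, .atom_jitter_sd),
                                  .atom_jitter_max),
                           dim = dim(coords))
  structure(list(coords = coords, n_frames = n_frames,
                 replicate_id = sprintf("L%02d_rep%d", ligand_index,
                                        replicate_index),
                 frame_times = NULL),
            class = "trajectory")
}

#' Generate a complete synthetic SAR dataset
#'
#' Produces the topology, all replicate trajectories, a ligand table with
#' potencies drawn from the planted affinity model
#' `pIC50 = intercept + sum_j beta_j * occupancy_j + Normal(0, noise_sd)`,
#' and the ground truth needed to verify downstream recovery. With `dir`
#' given, everything is also written to disk (topology.pdb, one multi-model
#' PDB per replicate, ligands.csv, ground_truth.json, config.yaml) so the
#' file-based pipeline can run on it unchanged.
#'
#' @param spec A `synthetic_spec`.
#' @param dir Optional output directory (created if needed).
#' @return Invisibly, a list: `spec`, `topo`, `trajs` (named list),
#'   `traj_index` (data.frame path/ligand_id/replicate_id), `ligands`
#'   (ligand table), `ground_truth` (planted coefficients, per-ligand target
#'   occupancies, true and observed pIC50, expected collapsed contact ids),
#'   `config` (a ready [pipeline_config()] list), and `dir`.
#' @export
generate_sar_dataset <- function(spec, dir = NULL) {
  topo <- build_topology(spec)
  ligand_ids <- sprintf("L%02d", seq_len(spec$n_ligands))
  occ_target <- do.call(cbind, lapply(spec$contact_programs, `[[`,
                                      "target_occupancy"))
  colnames(occ_target) <- vapply(spec$contact_programs, `[[`, character(1), "name")
  rownames(occ_target) <- ligand_ids
  beta_true <- vapply(spec$contact_programs, `[[`, numeric(1), "beta_true")
  names(beta_true) <- colnames(occ_target)

  set.seed((spec$seed %% 100000L) * 20011L + 9901L)
  pic50_true <- spec$intercept + as.numeric(occ_target %*% beta_true)
  pic50_obs <- pic50_true + stats::rnorm(spec$n_ligands, 0, spec$noise_sd)
  ligands <- data.frame(ligand_id = ligand_ids, formula = "",
                        ic50_nM = ic50_nM(pic50_obs),
                        stringsAsFactors = FALSE)

  trajs <- list()
  traj_index <- data.frame(path = character(0), ligand_id = character(0),
                           replicate_id = character(0))
  for (i in seq_len(spec$n_ligands)) {
    for (r in seq_len(spec$replicates_per_ligand)) {
      tr <- simulate_trajectory(topo, spec, i, r)
      trajs[[tr$replicate_id]] <- tr
      traj_index <- rbind(traj_index, data.frame(
        path = paste0("traj_", tr$replicate_id, ".pdb"),
        ligand_id = ligand_ids[i], replicate_id = tr$replicate_id,
        stringsAsFactors = FALSE))
    }
  }

  templates <- vapply(spec$contact_programs, `[[`, character(1), "template")
  expected_contact_id <- vapply(seq_along(spec$contact_programs), function(k) {
    pr <- spec$contact_programs[[k]]
    switch(pr$template,
           salt_bridge = paste0("C", k, "-", pr$residue_label, ":CZ"),
           guanidinium_hbond = paste0("N", k, "-", pr$residue_label, ":CZ"),
           hbond = paste0("O", k, "-", pr$residue_label, ":OE1"),
           pi_stack = paste0("ring", sum(templates[seq_len(k)] == "pi_stack"),
                             "-", pr$residue_label, ":ring"))
  }, character(1))
  ground_truth <- list(beta_true = beta_true,
                       target_occupancy = occ_target,
                       intercept = spec$intercept, noise_sd = spec$noise_sd,
                       pic50_true = stats::setNames(pic50_true, ligand_ids),
                       pic50_observed = stats::setNames(pic50_obs, ligand_ids),
                       expected_contact_id = stats::setNames(
                         expected_contact_id, names(beta_true)))

  ann <- attr(topo, "annotation")
  config <- pipeline_config(
    topology = "topology.pdb", trajectories = traj_index,
    ligand_table = "ligands.csv", ligand_resname = ann$ligand_resname,
    carboxylate_atoms = ann$carboxylate_atoms,
    ligand_ring_atoms = ann$ligand_ring_atoms,
    seed = spec$seed)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_topology(topo, file.path(dir, "topology.pdb"))
    for (j in seq_len(nrow(traj_index)))
      write_trajectory(trajs[[traj_index$replicate_id[j]]], topo,
                       file.path(dir, traj_index$path[j]))
    utils::write.csv(ligands, file.path(dir, "ligands.csv"), row.names = FALSE)
    gt <- ground_truth
    gt$target_occupancy <- as.data.frame(gt$target_occupancy)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(.config_to_yaml(config), file.path(dir, "config.yaml"))
  }
  invisible(list(spec = spec, topo = topo, trajs = trajs,
                 traj_index = traj_index, ligands = ligands,
                 ground_truth = ground_truth, config = config, dir = dir))
}
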