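test_that("spec validation enforces identifiability of programmed contacts", {
  expect_error(synthetic_spec(n_ligands = 0), ">= 1")
  expect_error(synthetic_spec(switching_rate = 0), "switching_rate")
  bad <- default_contact_programs(8)
  bad[[1]]$target_occupancy[1] <- 1.2
  expect_error(synthetic_spec(contact_programs = bad), "\\[0, 1\\]")
  expect_error(synthetic_spec(jitter_sd = 0.5), "jitter too large")
  dup <- default_contact_programs(8)
  dup[[2]]$residue_label <- dup[[1]]$residue_label
  expect_error(synthetic_spec(contact_programs = dup), "distinct residues")
})

test_that("generated topology carries one ligand and every collapse rule", {
  spec <- synthetic_spec(n_ligands = 2, frames_per_replicate = 10)
  topo <- build_topology(spec)
  lig <- topo$atoms[topo$atoms$is_ligand, ]
  expect_equal(unique(lig$residue_name), "LIG")
  ann <- attr(topo, "annotation")
  topo_a <- annotate_groups(topo, carboxylate_atoms = ann$carboxylate_atoms,
                            ligand_ring_atoms = ann$ligand_ring_atoms)
  types <- vapply(topo_a$groups, `[[`, character(1), "type")
  expect_equal(sum(types == "guanidinium"), 2L)  # ARG929 and ARG439
  expect_equal(sum(types == "carboxylate"), 1L)
  expect_equal(length(topo_a$rings), 2L)         # TYR961 + ligand ring
  # two arginine programs give two guanidinium groups with CZ representatives
  reps <- vapply(topo_a$groups[types == "guanidinium"], function(g)
    topo_a$atoms$atom_name[g$representative], character(1))
  expect_true(all(reps == "CZ"))
})

test_that("generated files round-trip through the structure reader cleanly", {
  spec <- synthetic_spec(n_ligands = 2, replicates_per_ligand = 1,
                         frames_per_replicate = 5, seed = 3)
  dir <- withr::local_tempdir()
  expect_no_warning(ds <- generate_sar_dataset(spec, dir = dir))
  expect_no_warning(topo2 <- read_topology(file.path(dir, "topology.pdb")))
  expect_equal(topo2$atoms$atom_name, ds$topo$atoms$atom_name)
  expect_equal(topo2$atoms$is_ligand, ds$topo$atoms$is_ligand)
  tr <- read_trajectory(file.path(dir, "traj_L01_rep1.pdb"), topo2)
  expect_equal(tr$n_frames, 5L)
  expect_equal(tr$coords, ds$trajs$L01_rep1$coords, tolerance = 1e-3)
})

test_that("programmed occupancy extremes and midpoint are honoured", {
  prog <- list(list(name = "p", template = "guanidinium_hbond",
                    residue_label = "ARG439",
                    target_occupancy = c(1, 0, 0.5),
                    d_on = 4.0, d_off = 8.0, beta_true = 0))
  spec <- synthetic_spec(n_ligands = 3, replicates_per_ligand = 1,
                         frames_per_replicate = 10000,
                         contact_programs = prog, seed = 77)
  topo <- build_topology(spec)
  n1 <- topo$atoms$atom_index[topo$atoms$atom_name == "N1"]
  cz <- topo$atoms$atom_index[topo$atoms$atom_name == "CZ"]
  occ <- vapply(1:3, function(i) {
    tr <- simulate_trajectory(topo, spec, i, 1)
    d <- sqrt(rowSums((tr$coords[, n1, ] - tr$coords[, cz, ])^2))
    100 * mean(d <= 5.0)
  }, numeric(1))
  expect_equal(occ[1], 100)
  expect_equal(occ[2], 0)
  expect_lt(abs(occ[3] - 50), 3)
})

test_that("trajectories are deterministic in (seed, ligand, replicate)", {
  spec <- synthetic_spec(n_ligands = 2, frames_per_replicate = 50, seed = 9)
  topo <- build_topology(spec)
  t1 <- simulate_trajectory(topo, spec, 2, 3)
  t2 <- simulate_trajectory(topo, spec, 2, 3)
  expect_identical(t1$coords, t2$coords)
  t3 <- simulate_trajectory(topo, spec, 2, 2)
  expect_false(identical(t1$coords, t3$coords))
  # byte-identical files for identical specs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_sar_dataset(synthetic_spec(n_ligands = 2, frames_per_replicate = 20,
                                      seed = 9), dir = d1)
  generate_sar_dataset(synthetic_spec(n_ligands = 2, frames_per_replicate = 20,
                                      seed = 9), dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("the affinity model maps occupancy to potency as specified", {
  # zero noise, zero coefficients: every ligand sits at the intercept
  prog <- default_contact_programs(4)
  for (k in seq_along(prog)) prog[[k]]$beta_true <- 0
  spec <- synthetic_spec(n_ligands = 4, replicates_per_ligand = 1,
                         frames_per_replicate = 5, contact_programs = prog,
                         intercept = 7.0, noise_sd = 0, seed = 2)
  ds <- generate_sar_dataset(spec)
  expect_equal(unname(ds$ground_truth$pic50_observed), rep(7, 4))
  # zero occupancy everywhere: IC50 is exactly 10^(9-intercept) = 100 nM
  for (k in seq_along(prog)) prog[[k]]$target_occupancy <- rep(0, 4)
  spec0 <- synthetic_spec(n_ligands = 4, replicates_per_ligand = 1,
                          frames_per_replicate = 5, contact_programs = prog,
                          intercept = 7.0, noise_sd = 0, seed = 2)
  ds0 <- generate_sar_dataset(spec0)
  expect_equal(ds0$ligands$ic50_nM, rep(100, 4))
  # general case: pIC50 = intercept + beta . occupancy (+ noise)
  spec1 <- synthetic_spec(n_ligands = 4, replicates_per_ligand = 1,
                          frames_per_replicate = 5, noise_sd = 0, seed = 2)
  ds1 <- generate_sar_dataset(spec1)
  beta <- ds1$ground_truth$beta_true
  occ <- ds1$ground_truth$target_occupancy
  expect_equal(unname(ds1$ground_truth$pic50_observed),
               unname(7 + as.numeric(occ %*% beta)))
})

test_that("empirical occupancy error shrinks like 1/sqrt(frames)", {
  lens <- c(100, 1000, 10000)
  errs <- vapply(seq_along(lens), function(i) {
    prog <- list(list(name = "p", template = "salt_bridge",
                      residue_label = "ARG929", target_occupancy = 0.7,
                      d_on = 4.0, d_off = 8.0, beta_true = 0))
    spec <- synthetic_spec(n_ligands = 1, replicates_per_ligand = 1,
                           frames_per_replicate = lens[i],
                           contact_programs = prog, seed = 100 + i)
    topo <- build_topology(spec)
    tr <- simulate_trajectory(topo, spec, 1, 1)
    c1 <- topo$atoms$atom_index[topo$atoms$atom_name == "C1"]
    cz <- topo$atoms$atom_index[topo$atoms$atom_name == "CZ"]
    d <- sqrt(rowSums((tr$coords[, c1, ] - tr$coords[, cz, ])^2))
    abs(100 * mean(d <= 5) - 70)
  }, numeric(1))
  # tolerance bands shrinking with length (generous multiples of the
  # Markov-chain standard error)
  expect_lt(errs[1], 25)
  expect_lt(errs[2], 9)
  expect_lt(errs[3], 3)
})
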