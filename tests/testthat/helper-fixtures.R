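# Fixture builders: PDB text assembled in code, never stored on disk.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", element = "") {
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial,
          ifelse(nchar(name) < 4, paste0(" ", name), name),
          resname, chain, resno, x, y, z, 1, 0, element)
}

# 5-atom fixture: 2-atom LIG (HETATM) + 3 protein atoms
five_atom_pdb <- function(coords = NULL) {
  if (is.null(coords))
    coords <- rbind(c(0, 0, 0), c(1.2, 0, 0),
                    c(3, 0, 0), c(3, 4, 0), c(10, 0, 0))
  c(pdb_atom_line(1, "C1", "LIG", "L", 1, coords[1, 1], coords[1, 2], coords[1, 3],
                  record = "HETATM", element = "C"),
    pdb_atom_line(2, "O1", "LIG", "L", 1, coords[2, 1], coords[2, 2], coords[2, 3],
                  record = "HETATM", element = "O"),
    pdb_atom_line(3, "N", "GLY", "A", 10, coords[3, 1], coords[3, 2], coords[3, 3],
                  element = "N"),
    pdb_atom_line(4, "CA", "GLY", "A", 10, coords[4, 1], coords[4, 2], coords[4, 3],
                  element = "C"),
    pdb_atom_line(5, "O", "GLY", "A", 10, coords[5, 1], coords[5, 2], coords[5, 3],
                  element = "O"))
}

multi_model_pdb <- function(frames) {
  # frames: list of 5x3 coordinate matrices
  unlist(lapply(seq_along(frames), function(k) {
    c(sprintf("MODEL     %4d", k), five_atom_pdb(frames[[k]]), "ENDMDL")
  }))
}

# random topology + trajectory pair for property tests: n_lig ligand atoms,
# n_prot protein atoms, mixed elements, coordinates ~ U[0, box]
random_fixture <- function(n_lig, n_prot, n_frames, box = 8) {
  elements <- c("C", "N", "O", "S", "H")
  lig_el <- sample(elements, n_lig, replace = TRUE)
  prot_el <- sample(elements, n_prot, replace = TRUE)
  lines <- c(
    vapply(seq_len(n_lig), function(i)
      pdb_atom_line(i, paste0(lig_el[i], i), "LIG", "L", 1, 0, 0, 0,
                    record = "HETATM", element = lig_el[i]), character(1)),
    vapply(seq_len(n_prot), function(i)
      pdb_atom_line(n_lig + i, paste0(prot_el[i], i), "ALA", "A", i, 0, 0, 0,
                    element = prot_el[i]), character(1)))
  topo <- read_topology(lines)
  n <- n_lig + n_prot
  coords <- array(stats::runif(n_frames * n * 3, 0, box), dim = c(n_frames, n, 3))
  traj <- structure(list(coords = coords, n_frames = n_frames,
                         replicate_id = "rnd", frame_times = NULL),
                    class = "trajectory")
  list(topo = topo, traj = traj)
}

# minimal pocket for collapse tests: one ARG, one GLU, ligand with a
# carboxylate (OD1/OD2/CG), an amide O (O1) and a backbone-like N (N1),
# everything within candidate range in a single frame
collapse_fixture <- function() {
  lines <- c(
    pdb_atom_line(1, "CG", "LIG", "L", 1, 0.0, 0.0, 0, record = "HETATM", element = "C"),
    pdb_atom_line(2, "OD1", "LIG", "L", 1, -0.6, 1.1, 0, record = "HETATM", element = "O"),
    pdb_atom_line(3, "OD2", "LIG", "L", 1, -0.6, -1.1, 0, record = "HETATM", element = "O"),
    pdb_atom_line(4, "O1", "LIG", "L", 1, 0.0, 8.0, 0, record = "HETATM", element = "O"),
    pdb_atom_line(5, "N1", "LIG", "L", 1, 0.0, -8.0, 0, record = "HETATM", element = "N"),
    # ARG929 guanidinium facing the ligand carboxylate
    pdb_atom_line(6, "NE", "ARG", "A", 929, 2.2, 1.0, 0, element = "N"),
    pdb_atom_line(7, "CZ", "ARG", "A", 929, 3.2, 0.0, 0, element = "C"),
    pdb_atom_line(8, "NH1", "ARG", "A", 929, 2.2, -1.0, 0, element = "N"),
    pdb_atom_line(9, "NH2", "ARG", "A", 929, 4.4, 0.0, 0, element = "N"),
    # ARG440 guanidinium near the amide O only
    pdb_atom_line(10, "NE", "ARG", "A", 440, 2.0, 8.5, 0, element = "N"),
    pdb_atom_line(11, "CZ", "ARG", "A", 440, 3.1, 8.0, 0, element = "C"),
    pdb_atom_line(12, "NH1", "ARG", "A", 440, 2.0, 7.5, 0, element = "N"),
    # GLU near the ligand N1
    pdb_atom_line(13, "OE1", "GLU", "A", 100, 2.5, -8.0, 0, element = "O"),
    pdb_atom_line(14, "CD", "GLU", "A", 100, 3.7, -8.0, 0, element = "C"),
    # SER hydroxyl near the carboxylate only (carboxylate-only collapse)
    pdb_atom_line(15, "OG", "SER", "A", 200, -3.0, 1.1, 0, element = "O"))
  topo <- read_topology(lines)
  topo <- annotate_groups(topo, carboxylate_atoms = list(c("OD1", "OD2", "CG")))
  coords <- array(NA_real_, dim = c(1, nrow(topo$atoms), 3))
  coords[1, , ] <- as.matrix(topo$atoms[, c("x", "y", "z")])
  traj <- structure(list(coords = coords, n_frames = 1L,
                         replicate_id = "fix", frame_times = NULL),
                    class = "trajectory")
  list(topo = topo, traj = traj)
}

make_ts <- function(distances, cutoff, id = "c", rep = "r1") {
  structure(list(contact_id = id, replicate_id = rep,
                 distances = distances, cutoff = cutoff),
            class = "distance_timeseries")
}
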