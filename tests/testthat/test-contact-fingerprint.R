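make_two_atom_traj <- function(dists) {
  # ligand O at origin, protein N at distance d along x, per frame
  lines <- c(pdb_atom_line(1, "O1", "LIG", "L", 1, 0, 0, 0,
                           record = "HETATM", element = "O"),
             pdb_atom_line(2, "N", "ALA", "A", 7, 1, 0, 0, element = "N"))
  topo <- read_topology(lines)
  coords <- array(0, dim = c(length(dists), 2, 3))
  coords[, 2, 1] <- dists
  traj <- structure(list(coords = coords, n_frames = length(dists),
                         replicate_id = "r", frame_times = NULL),
                    class = "trajectory")
  list(topo = topo, traj = traj)
}

test_that("candidate enumeration respects the cutoff with <= tie rule", {
  fx <- make_two_atom_traj(c(3.9, 3.9))
  expect_equal(nrow(enumerate_candidates(fx$traj, fx$topo)), 1L)
  fx <- make_two_atom_traj(c(4.1, 4.1))
  expect_equal(nrow(enumerate_candidates(fx$traj, fx$topo)), 0L)
  fx <- make_two_atom_traj(c(4.0, 6.0))
  expect_equal(nrow(enumerate_candidates(fx$traj, fx$topo)), 1L)
  expect_error(enumerate_candidates(list(n_frames = 0), fx$topo), "empty")
})

test_that("enumeration equals the exhaustive brute-force scan on random fixtures", {
  set.seed(101)
  for (i in 1:20) {
    fx <- random_fixture(sample(3:8, 1), sample(5:15, 1), sample(2:6, 1))
    stride <- sample(1:2, 1)
    got <- enumerate_candidates(fx$traj, fx$topo, stride = stride)
    ref <- brute_force_candidates(fx$traj, fx$topo, stride = stride)
    expect_equal(got[c("ligand_atom", "residue_atom")],
                 ref[order(ref$residue_atom, ref$ligand_atom), ],
                 ignore_attr = TRUE)
  }
})

test_that("enumeration is monotone in the candidate cutoff", {
  set.seed(33)
  fx <- random_fixture(5, 10, 4)
  small <- enumerate_candidates(fx$traj, fx$topo, candidate_cutoff = 4.0)
  large <- enumerate_candidates(fx$traj, fx$topo, candidate_cutoff = 4.5)
  key <- function(d) paste(d$ligand_atom, d$residue_atom)
  expect_true(all(key(small) %in% key(large)))
})

test_that("filtering keeps N/O/S pairs and emits ring pi-stack candidates", {
  fx <- collapse_fixture()
  cand <- enumerate_candidates(fx$traj, fx$topo)
  elems <- fx$topo$atoms$element
  fl <- filter_contacts(cand, fx$topo, fx$traj)
  expect_true(all(elems[fl$atom_pairs$ligand_atom] %in% c("N", "O", "S")))
  expect_true(all(elems[fl$atom_pairs$residue_atom] %in% c("N", "O", "S")))
  # C-C candidate pairs existed before filtering
  expect_gt(nrow(cand), nrow(fl$atom_pairs))

  # two hexagons 4.8 apart -> pi candidate; 6.5 apart -> none
  hexa <- function(cx, names, resn, chain, resno, record, el) {
    th <- 2 * pi * (0:5) / 6
    vapply(1:6, function(i)
      pdb_atom_line(i, names[i], resn, chain, resno,
                    cx, 1.39 * cos(th[i]), 1.39 * sin(th[i]),
                    record = record, element = el), character(1))
  }
  for (gap in c(4.8, 6.5)) {
    lines <- c(hexa(0, paste0("C", 1:6, "L"), "LIG", "L", 1, "HETATM", "C"),
               hexa(gap, c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                    "TYR", "A", 961, "ATOM", "C"))
    topo <- annotate_groups(read_topology(lines),
                            ligand_ring_atoms = list(paste0("C", 1:6, "L")))
    coords <- array(NA_real_, dim = c(1, 12, 3))
    coords[1, , ] <- as.matrix(topo$atoms[, c("x", "y", "z")])
    traj <- structure(list(coords = coords, n_frames = 1L, replicate_id = "r",
                           frame_times = NULL), class = "trajectory")
    fl <- filter_contacts(data.frame(ligand_atom = integer(0),
                                     residue_atom = integer(0)), topo, traj)
    expect_equal(nrow(fl$ring_pairs), if (gap < 6) 1L else 0L)
  }
})

test_that("equivalent-distance collapsing merges to representatives", {
  fx <- collapse_fixture()
  cand <- enumerate_candidates(fx$traj, fx$topo)
  fl <- filter_contacts(cand, fx$topo, fx$traj)
  contacts <- collapse_equivalents(fl, fx$topo)
  expect_setequal(contacts$contact_id,
                  c("CG-ARG929:CZ", "CG-SER200:OG", "O1-ARG440:CZ",
                    "N1-GLU100:OE1"))
  tp <- stats::setNames(contacts$contact_type, contacts$contact_id)
  expect_equal(tp[["CG-ARG929:CZ"]], "salt_bridge")
  expect_equal(tp[["CG-SER200:OG"]], "collapsed_carboxylate")
  expect_equal(tp[["O1-ARG440:CZ"]], "collapsed_guanidinium")
  expect_equal(tp[["N1-GLU100:OE1"]], "hbond")
  # collapsing never increases the contact count and the audit map is total
  expect_lte(nrow(contacts), nrow(fl$atom_pairs))
  audit <- attr(contacts, "audit")
  expect_equal(nrow(audit), nrow(fl$atom_pairs))
  expect_true(all(audit$contact_id %in% contacts$contact_id))
  # default cutoffs follow the contact type
  expect_equal(unname(contacts$cutoff[match(c("N1-GLU100:OE1", "CG-ARG929:CZ"),
                                            contacts$contact_id)]),
               c(3.5, 5.0))
})

test_that("ring centroid distance matches the mean-of-vertices definition", {
  hex <- cbind(0, 1.39 * cos(2 * pi * (0:5) / 6), 1.39 * sin(2 * pi * (0:5) / 6))
  coords <- rbind(hex, sweep(hex, 2, c(0, 0, 5), "+"))
  expect_equal(ring_centroid_distance(rbind(hex, hex), 1:6, 7:12), 0)
  expect_equal(ring_centroid_distance(coords, 1:6, 7:12), 5)
  set.seed(9)
  for (i in 1:10) {
    pts <- matrix(stats::rnorm(36), 12, 3)
    ref <- sqrt(sum((colMeans(pts[1:6, ]) - colMeans(pts[7:12, ]))^2))
    expect_equal(ring_centroid_distance(pts, 1:6, 7:12), ref)
  }
  expect_error(ring_centroid_distance(hex, integer(0), 1:3), "non-empty")
})

test_that("distances and contact sets are invariant under rigid motion", {
  set.seed(55)
  fx <- random_fixture(4, 8, 3)
  base <- enumerate_candidates(fx$traj, fx$topo)
  for (i in 1:5) {
    tr <- apply_rigid(fx$traj, random_orthogonal(), stats::rnorm(3, 0, 10))
    moved <- enumerate_candidates(tr, fx$topo)
    expect_equal(moved$ligand_atom, base$ligand_atom)
    expect_equal(moved$residue_atom, base$residue_atom)
    expect_equal(moved$min_distance, base$min_distance, tolerance = 1e-9)
  }
})

test_that("contact sets serialize deterministically", {
  fx <- collapse_fixture()
  build <- function() {
    cand <- enumerate_candidates(fx$traj, fx$topo)
    fl <- filter_contacts(cand, fx$topo, fx$traj)
    tab <- contact_table(collapse_equivalents(fl, fx$topo))
    paste(utils::capture.output(utils::write.csv(tab, row.names = FALSE)),
          collapse = "\n")
  }
  expect_identical(build(), build())
})
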