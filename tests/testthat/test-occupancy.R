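contact_row <- function(type, lig, res, cutoff, id = "c1") {
  df <- data.frame(contact_id = id, contact_type = type, cutoff = cutoff,
                   stringsAsFactors = FALSE)
  df$ligand_sel <- list(lig)
  df$residue_sel <- list(res)
  df
}

two_atom_traj <- function(dists) {
  coords <- array(0, dim = c(length(dists), 2, 3))
  coords[, 2, 1] <- dists
  structure(list(coords = coords, n_frames = length(dists),
                 replicate_id = "r1", frame_times = NULL),
            class = "trajectory")
}

test_that("distance time series match hand and brute-force computation", {
  # 3-4-5 triangle: frame 1 distance 3, frame 2 distance 5
  coords <- array(0, dim = c(2, 2, 3))
  coords[1, 2, ] <- c(3, 0, 0)
  coords[2, 2, ] <- c(3, 4, 0)
  traj <- structure(list(coords = coords, n_frames = 2L, replicate_id = "r",
                         frame_times = NULL), class = "trajectory")
  ts <- distance_timeseries(traj, NULL, contact_row("hbond", 1L, 2L, 3.5))
  expect_equal(ts$distances, c(3, 5))
  # a point against itself is identically zero
  ts0 <- distance_timeseries(traj, NULL, contact_row("hbond", 1L, 1L, 3.5))
  expect_equal(ts0$distances, c(0, 0))
  # random fixture vs direct per-frame recomputation, atom and ring contacts
  set.seed(12)
  fx <- random_fixture(6, 6, 5)
  ts2 <- distance_timeseries(fx$traj, fx$topo, contact_row("hbond", 2L, 9L, 3.5))
  ref <- vapply(1:5, function(k)
    sqrt(sum((fx$traj$coords[k, 2, ] - fx$traj$coords[k, 9, ])^2)), numeric(1))
  expect_equal(ts2$distances, ref)
  tsr <- distance_timeseries(fx$traj, fx$topo,
                             contact_row("pi_stack", 1:3, 7:12, 5.5))
  refr <- vapply(1:5, function(k)
    ring_centroid_distance(fx$traj$coords[k, , ], 1:3, 7:12), numeric(1))
  expect_equal(tsr$distances, refr)
  expect_error(distance_timeseries(fx$traj, fx$topo,
                                   contact_row("hbond", 1L, 99L, 3.5)),
               "out of range")
})

test_that("occupancy is the percent of frames at or below the cutoff", {
  expect_equal(occupancy_percent(make_ts(rep(2, 10), 3.5)), 100)
  expect_equal(occupancy_percent(make_ts(c(1, 2, 9, 9, 9), 3.5)), 40)
  expect_equal(occupancy_percent(make_ts(c(3.5, 4), 3.5)), 50)  # tie counts
  expect_error(occupancy_percent(make_ts(numeric(0), 3.5)), "empty")
})

test_that("occupancy is monotone in cutoff and order-independent", {
  set.seed(3)
  d <- stats::runif(500, 0, 8)
  cuts <- sort(stats::runif(10, 0, 8))
  occ <- vapply(cuts, function(co) occupancy_percent(make_ts(d, co)), numeric(1))
  expect_true(all(diff(occ) >= 0))
  expect_equal(occupancy_percent(make_ts(rev(d), 3.5)),
               occupancy_percent(make_ts(d, 3.5)))
})

test_that("two-state series recover the programmed stationary occupancy", {
  # single-program spec, increasing trajectory lengths, shrinking tolerance
  lens <- c(100, 1000, 10000)
  tols <- c(20, 8, 3)
  prog <- list(list(name = "glu_hb", template = "hbond",
                    residue_label = "GLU465",
                    target_occupancy = 0.5, d_on = 2.9, d_off = 6.5,
                    beta_true = 0))
  for (i in seq_along(lens)) {
    spec <- synthetic_spec(n_ligands = 1, replicates_per_ligand = 1,
                           frames_per_replicate = lens[i],
                           contact_programs = prog, seed = 20 + i)
    topo <- build_topology(spec)
    tr <- simulate_trajectory(topo, spec, 1, 1)
    oe1 <- topo$atoms$atom_index[topo$atoms$atom_name == "OE1"]
    o1 <- topo$atoms$atom_index[topo$atoms$atom_name == "O1"]
    ts <- distance_timeseries(tr, topo, contact_row("hbond", o1, oe1, 3.5))
    expect_lt(abs(occupancy_percent(ts) - 50), tols[i])
  }
})

test_that("matrix assembly honours replicate policy and zero-fill", {
  occ <- data.frame(
    ligand_id = c("A", "A", "A", "B"),
    replicate_id = c("r1", "r2", "r3", "r1"),
    contact_id = c("c1", "c1", "c1", "c2"),
    occupancy = c(60, 80, 100, 10))
  M <- build_matrix(occ, contact_ids = c("c1", "c2"))
  expect_equal(unclass(M)["A", "c1"], 80)
  expect_equal(unclass(M)["B", "c1"], 0)   # contact never seen for B
  expect_equal(unclass(M)["A", "c2"], 0)
  Mc <- build_matrix(occ, contact_ids = c("c1", "c2"), policy = "concat")
  expect_equal(nrow(Mc), 4L)
  # mean matrix equals concat rows averaged by ligand
  expect_equal(unclass(M)["A", ],
               colMeans(unclass(Mc)[attr(Mc, "ligand_ids") == "A", , drop = FALSE]))
  expect_error(build_matrix(rbind(occ, occ[1, ])), "duplicate")
  expect_error(build_matrix(transform(occ, occupancy = occupancy + 100)),
               "\\[0, 100\\]")
})

test_that("concat rows reduce to the mean matrix on a full pipeline run", {
  spec <- synthetic_spec(n_ligands = 3, frames_per_replicate = 150, seed = 4)
  ds <- generate_sar_dataset(spec)
  cfg_mean <- ds$config
  cfg_concat <- ds$config; cfg_concat$replicate_policy <- "concat"
  run_m <- run_contact_sar(ds$topo, ds$trajs, ds$ligands, cfg_mean,
                           ds$traj_index$ligand_id)
  run_c <- run_contact_sar(ds$topo, ds$trajs, ds$ligands, cfg_concat,
                           ds$traj_index$ligand_id)
  lig <- attr(run_c$X, "ligand_ids")
  for (l in unique(lig))
    expect_equal(unclass(run_m$X)[l, ],
                 colMeans(unclass(run_c$X)[lig == l, , drop = FALSE]))
})

test_that("smoothing produces truncated-window rolling mean and sd", {
  expect_equal(smooth_series(make_ts(rep(2.5, 20), 3), 7)$trend, rep(2.5, 20))
  expect_equal(smooth_series(make_ts(rep(2.5, 20), 3), 7)$band, rep(0, 20))
  d <- c(1, 5, 2, 8, 3)
  sm1 <- smooth_series(make_ts(d, 3), 1)
  expect_equal(sm1$trend, d)
  expect_equal(sm1$band, rep(0, 5))
  set.seed(8)
  x <- stats::rnorm(40)
  sm <- smooth_series(make_ts(x, 3), 5)
  ref <- rolling_oracle(x, 5)
  expect_equal(sm$trend, ref$trend)
  expect_equal(sm$band, ref$band)
  expect_error(smooth_series(make_ts(x, 3), 0), "window")
  expect_error(smooth_series(make_ts(x, 3), 41), "window")
})
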