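#' Per-frame distance time series for one contact
#'
#' Atom-atom contacts (and collapsed representative-representative contacts)
#' measure the Euclidean distance between their two selector atoms; pi-stack
#' contacts measure the ring-centroid distance.
#'
#' @param traj A `trajectory`.
#' @param topo The matching `topology`.
#' @param contact One row of a `contact_set` (data.frame of one row).
#' @return A `distance_timeseries`: list with `contact_id`, `replicate_id`,
#'   `distances` (Angstrom, one per frame) and `cutoff`.
#' @export
distance_timeseries <- function(traj, topo, contact) {
  lig <- contact$ligand_sel[[1]]
  res <- contact$residue_sel[[1]]
  n_atoms <- dim(traj$coords)[2]
  if (any(c(lig, res) < 1L) || any(c(lig, res) > n_atoms))
    stop("contact selector out of range for this trajectory")
  if (contact$contact_type == "pi_stack") {
    ca <- apply(traj$coords[, lig, , drop = FALSE], c(1, 3), mean)
    cb <- apply(traj$coords[, res, , drop = FALSE], c(1, 3), mean)
    d <- sqrt(rowSums((ca - cb)^2))
  } else {
    nf <- dim(traj$coords)[1]
    A <- traj$coords[, lig, , drop = FALSE]
    B <- traj$coords[, res, , drop = FALSE]
    dim(A) <- dim(B) <- c(nf, 3L)
    d <- sqrt(rowSums((A - B)^2))
  }
  structure(list(contact_id = contact$contact_id,
                 replicate_id = traj$replicate_id,
                 distances = d, cutoff = contact$cutoff),
            class = "distance_timeseries")
}

#' Percent of trajectory in contact
#'
#' 100 x (number of frames with distance at or below the cutoff) / n_frames.
#' A distance exactly equal to the cutoff counts as in contact.
#'
#' @param ts A `distance_timeseries` (or any list with `distances` and
#'   `cutoff`).
#' @param cutoff Optional override of the series' own cutoff.
#' @return Occupancy percentage in \[0, 100\].
#' @export
occupancy_percent <- function(ts, cutoff = NULL) {
  d <- ts$distances
  if (!length(d)) stop("empty distance series")
  co <- if (is.null(cutoff)) ts$cutoff else cutoff
  100 * mean(d <= co)
}

#' Assemble the ligands x contacts occupancy matrix
#'
#' @param occ Long-format data.frame with columns `ligand_id`,
#'   `replicate_id`, `contact_id`, `occupancy` (percent). Each
#'   (ligand, replicate, contact) combination must be unique.
#' @param contact_ids Column order (defaults to order of appearance). A
#'   contact never observed for a ligand fills as 0 percent: absence from
#'   enumeration means the contact was never formed.
#' @param policy `"mean"` averages replicate occupancies per ligand (one row
#'   per ligand); `"concat"` keeps one row per replicate, labelled
#'   `ligand_id|replicate_id`.
#' @return An `occupancy_matrix`: numeric matrix, rows ligands (or
#'   replicates), columns contacts, values in \[0, 100\], with attributes
#'   `ligand_ids` and `replicate_policy`.
#' @export
build_matrix <- function(occ, contact_ids = NULL, policy = c("mean", "concat")) {
  policy <- match.arg(policy)
  need <- c("ligand_id", "replicate_id", "contact_id", "occupancy")
  if (!all(need %in% names(occ))) stop("occupancy table must have columns ",
                                       paste(need, collapse = ", "))
  if (anyDuplicated(occ[c("ligand_id", "replicate_id", "contact_id")]))
    stop("duplicate (ligand, replicate, contact) occupancy entries")
  if (any(occ$occupancy < 0 | occ$occupancy > 100))
    stop("occupancies must lie in [0, 100]")
  if (is.null(contact_ids)) contact_ids <- unique(occ$contact_id)
  ligands <- unique(occ$ligand_id)

  # per-replicate matrix first; a replicate inherits 0 for unobserved contacts
  reps <- unique(occ[c("ligand_id", "replicate_id")])
  row_key <- paste(reps$ligand_id, reps$replicate_id, sep = "|")
  M <- matrix(0, nrow(reps), length(contact_ids),
              dimnames = list(row_key, contact_ids))
  i <- match(paste(occ$ligand_id, occ$replicate_id, sep = "|"), row_key)
  j <- match(occ$contact_id, contact_ids)
  if (anyNA(j)) stop("occupancy table contains contacts absent from contact_ids")
  M[cbind(i, j)] <- occ$occupancy

  if (policy == "mean") {
    out <- do.call(rbind, lapply(ligands, function(l) {
      colMeans(M[reps$ligand_id == l, , drop = FALSE])
    }))
    rownames(out) <- ligands
  } else {
    out <- M
  }
  structure(out, ligand_ids = if (policy == "mean") ligands else reps$ligand_id,
            replicate_policy = policy, class = c("occupancy_matrix", "matrix"))
}

#' Smoothed trend and fluctuation band of a distance series
#'
#' Centered rolling mean and rolling standard deviation over a window of
#' `window` frames; windows are truncated at the edges. The band is plus or
#' minus one rolling standard deviation. `window = 1` returns the raw series
#' with a zero band.
#'
#' @param ts A `distance_timeseries`.
#' @param window Window length in frames (1 to n_frames).
#' @return A data.frame with `frame`, `distance`, `trend`, `band` (one sd).
#' @export
smooth_series <- function(ts, window) {
  d <- ts$distances
  n <- length(d)
  if (window < 1) stop("window must be >= 1")
  if (window > n) stop("window exceeds series length")
  trend <- zoo::rollapply(d, window, mean, partial = TRUE, align = "center")
  band <- zoo::rollapply(d, window, stats::sd, partial = TRUE, align = "center")
  band[is.na(band)] <- 0
  data.frame(frame = seq_len(n), distance = d,
             trend = as.numeric(trend), band = as.numeric(band))
}

#' Contact occupancies for a set of trajectories
#'
#' Computes, for every (trajectory, contact) combination, the distance time
#' series and its occupancy percentage.
#'
#' @param trajs Named list of `trajectory` objects; names are used as
#'   replicate labels if `ligand_ids` is not given.
#' @param topo The matching annotated `topology`.
#' @param contacts A `contact_set`.
#' @param ligand_ids Character vector (one per trajectory) assigning each
#'   trajectory to a ligand.
#' @return Long-format data.frame with `ligand_id`, `replicate_id`,
#'   `contact_id`, `occupancy` — input for [build_matrix()].
#' @export
compute_occupancy <- function(trajs, topo, contacts, ligand_ids) {
  if (length(ligand_ids) != length(trajs))
    stop("ligand_ids must have one entry per trajectory")
  out <- vector("list", length(trajs) * nrow(contacts))
  k <- 0L
  for (t in seq_along(trajs)) {
    for (ci in seq_len(nrow(contacts))) {
      ts <- distance_timeseries(trajs[[t]], topo, contacts[ci, , drop = FALSE])
      k <- k + 1L
      out[[k]] <- data.frame(ligand_id = ligand_ids[t],
                             replicate_id = trajs[[t]]$replicate_id,
                             contact_id = ts$contact_id,
                             occupancy = occupancy_percent(ts),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
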