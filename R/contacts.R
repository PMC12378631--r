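# Occupancy cutoffs (Angstrom) by contact type. Conventional geometric
# criteria; all overridable through the pipeline config.
.default_cutoffs <- c(hbond = 3.5,
                      collapsed_carboxylate = 5.0,
                      collapsed_guanidinium = 5.0,
                      salt_bridge = 5.0,
                      pi_stack = 5.5)

.frame_cross_dist2 <- function(A, B) {
  # squared distances between two coordinate blocks of one frame
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

#' Enumerate candidate ligand-residue heavy-atom contacts
#'
#' A ligand-atom/protein-atom pair is a candidate iff both atoms are heavy
#' and their distance is at or below `candidate_cutoff` in at least one
#' sampled frame (a distance exactly equal to the cutoff counts as in
#' contact). Frames are sampled every `stride` frames starting at the first.
#'
#' @param traj A `trajectory`.
#' @param topo The matching `topology`.
#' @param candidate_cutoff Candidate distance threshold in Angstrom.
#' @param stride Frame sampling stride (1 = every frame).
#' @return A data.frame with columns `ligand_atom`, `residue_atom` (atom
#'   indices) and `min_distance` (the minimum sampled distance), ordered by
#'   residue atom then ligand atom.
#' @export
enumerate_candidates <- function(traj, topo, candidate_cutoff = 4.0, stride = 1L) {
  if (candidate_cutoff <= 0) stop("candidate_cutoff must be positive")
  if (stride < 1) stop("stride must be >= 1")
  if (is.null(traj$n_frames) || traj$n_frames < 1L) stop("empty trajectory")
  a <- topo$atoms
  lig <- a$atom_index[a$is_ligand & a$is_heavy]
  prot <- a$atom_index[!a$is_ligand & a$is_heavy]
  if (!length(lig) || !length(prot))
    return(data.frame(ligand_atom = integer(0), residue_atom = integer(0),
                      min_distance = numeric(0)))
  frames <- seq(1L, traj$n_frames, by = as.integer(stride))
  mind2 <- matrix(Inf, length(lig), length(prot))
  for (k in frames) {
    A <- traj$coords[k, lig, , drop = FALSE]
    dim(A) <- c(length(lig), 3L)
    B <- traj$coords[k, prot, , drop = FALSE]
    dim(B) <- c(length(prot), 3L)
    mind2 <- pmin(mind2, .frame_cross_dist2(A, B))
  }
  hit <- which(mind2 <= candidate_cutoff^2, arr.ind = TRUE)
  out <- data.frame(ligand_atom = lig[hit[, 1]],
                    residue_atom = prot[hit[, 2]],
                    min_distance = sqrt(pmax(mind2[hit], 0)))
  out[order(out$residue_atom, out$ligand_atom), , drop = FALSE]
}

#' Filter candidate pairs to hydrogen-bond-capable atoms and add ring
#' pi-stacking candidates
#'
#' An atom pair survives iff both atoms' elements are in `hbond_elements`.
#' Additionally, every (annotated ligand ring, annotated residue ring) pair
#' whose centroid distance is at or below `ring_cutoff` in at least one
#' sampled frame is emitted as a pi-stack candidate.
#'
#' @param pairs Candidate pairs from [enumerate_candidates()].
#' @param topo An annotated `topology` (see [annotate_groups()]).
#' @param traj The `trajectory` used for the ring-centroid screen (may be
#'   omitted when the topology has no ring annotations).
#' @param hbond_elements Elements considered hydrogen-bond capable.
#' @param ring_cutoff Ring-centroid candidate threshold in Angstrom.
#' @param stride Frame sampling stride for the ring screen.
#' @return A list with `atom_pairs` (filtered data.frame) and `ring_pairs`
#'   (data.frame of `ligand_ring`, `residue_ring` ring-list indices).
#' @export
filter_contacts <- function(pairs, topo, traj = NULL,
                            hbond_elements = c("N", "O", "S"),
                            ring_cutoff = 6.0, stride = 1L) {
  elem <- topo$atoms$element
  keep <- elem[pairs$ligand_atom] %in% hbond_elements &
    elem[pairs$residue_atom] %in% hbond_elements
  atom_pairs <- pairs[keep, , drop = FALSE]

  lig_rings <- which(vapply(topo$rings, function(r) r$is_ligand, logical(1)))
  res_rings <- which(!vapply(topo$rings, function(r) r$is_ligand, logical(1)))
  ring_pairs <- data.frame(ligand_ring = integer(0), residue_ring = integer(0))
  if (length(lig_rings) && length(res_rings) && !is.null(traj)) {
    frames <- seq(1L, traj$n_frames, by = as.integer(stride))
    for (i in lig_rings) for (j in res_rings) {
      hit <- FALSE
      for (k in frames) {
        d <- ring_centroid_distance(traj$coords[k, , , drop = TRUE],
                                    topo$rings[[i]]$members,
                                    topo$rings[[j]]$members)
        if (d <= ring_cutoff) { hit <- TRUE; break }
      }
      if (hit)
        ring_pairs <- rbind(ring_pairs,
                            data.frame(ligand_ring = i, residue_ring = j))
    }
  }
  list(atom_pairs = atom_pairs, ring_pairs = ring_pairs)
}

#' Ring-centroid distance in one frame
#'
#' Euclidean distance between the arithmetic means of the member coordinates
#' of two atom-index sets.
#'
#' @param frame_coords An n_atoms x 3 coordinate matrix (one frame).
#' @param ringA,ringB Non-empty atom-index vectors.
#' @return Distance in Angstrom.
#' @export
ring_centroid_distance <- function(frame_coords, ringA, ringB) {
  if (!length(ringA) || !length(ringB)) stop("ring atom sets must be non-empty")
  ca <- colMeans(frame_coords[ringA, , drop = FALSE])
  cb <- colMeans(frame_coords[ringB, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

.group_lookup <- function(topo, type, ligand_side) {
  # maps member atom index -> group list index
  map <- integer(0)
  for (g in seq_along(topo$groups)) {
    grp <- topo$groups[[g]]
    if (grp$type == type && grp$is_ligand == ligand_side)
      map[as.character(grp$members)] <- g
  }
  map
}

#' Collapse chemically equivalent distances into contact definitions
#'
#' Applies the equivalent-atom rules: every pair whose ligand atom is a
#' carboxylate oxygen is re-measured from that carboxylate's carboxyl carbon
#' (C_COOH); every pair whose residue atom is a guanidinium nitrogen
#' (NE/NH1/NH2) of an arginine is re-measured to that arginine's CZ. Pairs
#' that after substitution share the same (ligand selector, residue selector)
#' merge into one contact. A pair hit by both rules collapses to a single
#' C_COOH-CZ salt-bridge contact. Untouched pairs become atom-to-atom
#' hydrogen-bond contacts; ring candidate pairs become pi-stack contacts.
#'
#' @param filtered Result of [filter_contacts()].
#' @param topo The annotated `topology`.
#' @param cutoffs Named per-type occupancy cutoff vector (Angstrom); defaults
#'   hbond 3.5, collapsed carboxylate/guanidinium and salt bridge 5.0,
#'   pi-stack ring-centroid 5.5.
#' @param provenance Optional list recorded on the contact set (enumeration
#'   parameters).
#' @return A `contact_set`: data.frame with `contact_id`, `contact_type`,
#'   `cutoff`, plus list-columns `ligand_sel` and `residue_sel` holding atom
#'   index vectors (length one except for rings). The attribute `audit`
#'   maps every input pair to its collapsed `contact_id`.
#' @export
collapse_equivalents <- function(filtered, topo, cutoffs = .default_cutoffs,
                                 provenance = list()) {
  cutoffs <- .merge_cutoffs(cutoffs)
  a <- topo$atoms
  carb <- .group_lookup(topo, "carboxylate", ligand_side = TRUE)
  guan <- .group_lookup(topo, "guanidinium", ligand_side = FALSE)
  pairs <- filtered$atom_pairs
  n <- nrow(pairs)

  lig_sel <- pairs$ligand_atom
  res_sel <- pairs$residue_atom
  lig_collapsed <- logical(n)
  res_collapsed <- logical(n)
  for (i in seq_len(n)) {
    gi <- carb[as.character(pairs$ligand_atom[i])]
    if (!is.na(gi) && length(gi)) {
      lig_sel[i] <- topo$groups[[gi]]$representative
      lig_collapsed[i] <- TRUE
    }
    gj <- guan[as.character(pairs$residue_atom[i])]
    if (!is.na(gj) && length(gj)) {
      res_sel[i] <- topo$groups[[gj]]$representative
      res_collapsed[i] <- TRUE
    }
  }
  key <- paste(lig_sel, res_sel)
  type <- ifelse(lig_collapsed & res_collapsed, "salt_bridge",
          ifelse(lig_collapsed, "collapsed_carboxylate",
          ifelse(res_collapsed, "collapsed_guanidinium", "hbond")))
  # a merged contact inherits the collapsed type; rule application is
  # consistent within a key by construction
  first <- !duplicated(key)
  def <- data.frame(
    contact_id = paste0(trimws(a$atom_name[lig_sel[first]]), "-",
                        residue_label(topo, res_sel[first]), ":",
                        trimws(a$atom_name[res_sel[first]])),
    contact_type = type[first],
    residue_number = a$residue_number[res_sel[first]],
    lig_order = lig_sel[first],
    stringsAsFactors = FALSE)
  def$cutoff <- unname(cutoffs[def$contact_type])
  def$ligand_sel <- as.list(lig_sel[first])
  def$residue_sel <- as.list(res_sel[first])
  audit <- data.frame(ligand_atom = pairs$ligand_atom,
                      residue_atom = pairs$residue_atom,
                      contact_id = def$contact_id[match(key, key[first])],
                      stringsAsFactors = FALSE)

  rp <- filtered$ring_pairs
  if (nrow(rp)) {
    ring_def <- data.frame(
      contact_id = vapply(seq_len(nrow(rp)), function(i) {
        lr <- topo$rings[[rp$ligand_ring[i]]]
        rr <- topo$rings[[rp$residue_ring[i]]]
        paste0(lr$name, "-", rr$name)
      }, character(1)),
      contact_type = "pi_stack",
      residue_number = vapply(seq_len(nrow(rp)), function(i)
        a$residue_number[topo$rings[[rp$residue_ring[i]]]$members[1]], numeric(1)),
      lig_order = vapply(seq_len(nrow(rp)), function(i)
        min(topo$rings[[rp$ligand_ring[i]]]$members), numeric(1)),
      stringsAsFactors = FALSE)
    ring_def$cutoff <- unname(cutoffs["pi_stack"])
    ring_def$ligand_sel <- lapply(seq_len(nrow(rp)), function(i)
      topo$rings[[rp$ligand_ring[i]]]$members)
    ring_def$residue_sel <- lapply(seq_len(nrow(rp)), function(i)
      topo$rings[[rp$residue_ring[i]]]$members)
    def <- rbind(def, ring_def)
  }

  def <- def[order(def$residue_number, def$lig_order), , drop = FALSE]
  def$residue_number <- NULL
  def$lig_order <- NULL
  rownames(def) <- NULL
  if (anyDuplicated(def$contact_id))
    stop("contact_id collision; atom names do not uniquely label contacts")
  structure(def, class = c("contact_set", "data.frame"),
            audit = audit, provenance = provenance)
}

.merge_cutoffs <- function(cutoffs) {
  out <- .default_cutoffs
  if (!is.null(cutoffs)) out[names(cutoffs)] <- cutoffs
  if (any(out <= 0)) stop("cutoffs must be positive")
  out
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set> %d contact(s)\n", nrow(x)))
  print(as.data.frame(x)[, c("contact_id", "contact_type", "cutoff")])
  invisible(x)
}

#' Serialize a contact set to a plain data.frame
#'
#' Selector atom-index vectors become `+`-joined strings, suitable for CSV.
#'
#' @param contacts A `contact_set`.
#' @return A data.frame with `contact_id`, `contact_type`, `ligand_selector`,
#'   `residue_selector`, `cutoff`.
#' @export
contact_table <- function(contacts) {
  data.frame(
    contact_id = contacts$contact_id,
    contact_type = contacts$contact_type,
    ligand_selector = vapply(contacts$ligand_sel, paste, character(1), collapse = "+"),
    residue_selector = vapply(contacts$residue_sel, paste, character(1), collapse = "+"),
    cutoff = contacts$cutoff,
    stringsAsFactors = FALSE)
}
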