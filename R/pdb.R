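# Residue names treated as solvent/ions when assigning the ligand by HETATM.
.solvent_resnames <- c("HOH", "WAT", "TIP3", "TIP4", "SPC", "SOL",
                       "NA", "CL", "K", "MG", "CA", "ZN", "SOD", "CLA", "POT")

# Aromatic side-chain ring templates (standard residue atom names).
.residue_ring_templates <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HID = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HIE = c("CG", "ND1", "CD2", "CE1", "NE2"),
  HIP = c("CG", "ND1", "CD2", "CE1", "NE2")
)

.parse_atom_lines <- function(lines, lineno) {
  # PDB fixed columns: name 13-16, resName 18-21, chain 22, resSeq 23-26,
  # x/y/z 31-54 (8.3 each), element 77-78.
  name <- trimws(substr(lines, 13, 16))
  resn <- trimws(substr(lines, 18, 21))
  chain <- substr(lines, 22, 22)
  resno <- suppressWarnings(as.integer(trimws(substr(lines, 23, 26))))
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  elem <- trimws(substr(lines, 77, 78))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resno) | !nzchar(name))
  if (length(bad))
    stop(sprintf("PDB parse failure at line %d: %s", lineno[bad[1]], lines[bad[1]]))
  data.frame(atom_name = name, residue_name = resn, chain_id = chain,
             residue_number = resno, x = x, y = y, z = z, element = elem,
             stringsAsFactors = FALSE)
}

.infer_element <- function(atom_name, element_col) {
  elem <- toupper(element_col)
  known <- names(.monoisotopic_masses)
  need <- !(elem %in% known)
  if (any(need)) {
    # heuristic fallback: strip leading digits, try two-letter then one-letter
    core <- toupper(sub("^[0-9]*", "", atom_name[need]))
    two <- paste0(substr(core, 1, 1), tolower(substr(core, 2, 2)))
    one <- substr(core, 1, 1)
    guess <- ifelse(two %in% known & !(one %in% c("C", "H", "N", "O", "S", "P")),
                    two, one)
    elem[need] <- toupper(guess)
  }
  # normalise capitalisation ("CL" -> "Cl")
  long <- nchar(elem) == 2
  elem[long] <- paste0(substr(elem[long], 1, 1), tolower(substr(elem[long], 2, 2)))
  elem
}

.pdb_lines <- function(input) {
  if (length(input) == 1L && !grepl("\n", input) && file.exists(input))
    readLines(input)
  else if (length(input) == 1L)
    strsplit(input, "\n", fixed = TRUE)[[1]]
  else
    input
}

#' Read a PDB topology
#'
#' Parses ATOM/HETATM records from fixed-column PDB text (a file path, a
#' single string, or a character vector of lines). The first MODEL block is
#' used when several are present; coordinates of that frame are stored on
#' the topology so a write/read round-trip is exact to PDB precision.
#'
#' Ligand assignment: atoms whose record is HETATM and whose residue name is
#' not a common solvent/ion are the ligand, unless `ligand_resname` names the
#' ligand residue(s) explicitly. Exactly one ligand residue is required.
#'
#' @param input PDB file path, text, or lines.
#' @param ligand_resname Optional character vector of residue names to treat
#'   as the ligand (overrides the HETATM rule).
#' @return A `topology` object: a list with `atoms` (data.frame of
#'   `atom_index` (1-based), `atom_name`, `element`, `residue_name`,
#'   `residue_number`, `chain_id`, `is_ligand`, `is_heavy`, `x`, `y`, `z`),
#'   plus empty `rings` and `groups` slots filled by [annotate_groups()].
#' @export
read_topology <- function(input, ligand_resname = NULL) {
  lines <- .pdb_lines(input)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM") | substr(lines, 1, 4) == "ATOM"
  endmdl <- which(trimws(rec) == "ENDMDL")
  if (length(endmdl)) {
    first_end <- endmdl[1]
    keep <- keep & seq_along(lines) < first_end
  }
  idx <- which(keep)
  if (!length(idx)) stop("no ATOM/HETATM records found")
  atoms <- .parse_atom_lines(lines[idx], idx)
  atoms$record <- ifelse(substr(lines[idx], 1, 6) == "HETATM", "HETATM", "ATOM")
  atoms$element <- .infer_element(atoms$atom_name, atoms$element)
  if (!is.null(ligand_resname)) {
    atoms$is_ligand <- atoms$residue_name %in% ligand_resname
  } else {
    atoms$is_ligand <- atoms$record == "HETATM" &
      !(atoms$residue_name %in% .solvent_resnames)
  }
  atoms$is_heavy <- atoms$element != "H"
  atoms$atom_index <- seq_len(nrow(atoms))
  if (!any(atoms$is_ligand)) stop("no ligand atoms identified")
  if (all(atoms$is_ligand)) stop("no protein atoms identified")
  lig_res <- unique(atoms[atoms$is_ligand, c("residue_name", "residue_number", "chain_id")])
  if (nrow(lig_res) > 1L)
    stop("expected exactly one ligand residue, found ",
         paste(paste0(lig_res$residue_name, lig_res$residue_number), collapse = ", "))
  structure(list(atoms = atoms, rings = list(), groups = list()),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<topology> %d atoms (%d ligand, %d protein), %d ring(s), %d group(s)\n",
              nrow(a), sum(a$is_ligand), sum(!a$is_ligand),
              length(x$rings), length(x$groups)))
  invisible(x)
}

#' Residue label of an atom ("ARG929" style)
#'
#' File residue numbers are preserved verbatim so crystal-structure
#' numbering round-trips into reported contact labels.
#'
#' @param topo A `topology`.
#' @param atom_index Atom index (1-based).
#' @return Character label `residue_name + residue_number`.
#' @export
residue_label <- function(topo, atom_index) {
  a <- topo$atoms
  paste0(a$residue_name[atom_index], a$residue_number[atom_index])
}

#' Read a multi-model PDB trajectory
#'
#' Each MODEL/ENDMDL block must contain the same atoms in file order as the
#' topology; a file without MODEL records is a single-frame trajectory.
#'
#' @param input PDB file path, text, or lines.
#' @param topo The matching [read_topology()] result.
#' @param replicate_id Label stored on the trajectory.
#' @return A `trajectory`: list with `coords` (n_frames x n_atoms x 3 array,
#'   Angstrom), `n_frames`, `replicate_id`, optional `frame_times` (ns).
#' @export
read_trajectory <- function(input, topo, replicate_id = "rep1") {
  lines <- .pdb_lines(input)
  rec6 <- substr(lines, 1, 6)
  is_atom <- rec6 %in% c("ATOM  ", "HETATM")
  model_starts <- which(trimws(rec6) == "MODEL")
  n_atoms <- nrow(topo$atoms)
  if (!length(model_starts)) {
    frames <- list(which(is_atom))
  } else {
    bounds <- c(model_starts, length(lines) + 1L)
    frames <- lapply(seq_along(model_starts), function(k) {
      span <- seq(bounds[k], bounds[k + 1L] - 1L)
      span[is_atom[span]]
    })
  }
  n_frames <- length(frames)
  if (n_frames == 0L || all(lengths(frames) == 0L)) stop("empty trajectory")
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  for (k in seq_len(n_frames)) {
    idx <- frames[[k]]
    if (length(idx) != n_atoms)
      stop(sprintf("model %d: expected %d atoms, got %d", k, n_atoms, length(idx)))
    block <- lines[idx]
    coords[k, , 1] <- as.numeric(substr(block, 31, 38))
    coords[k, , 2] <- as.numeric(substr(block, 39, 46))
    coords[k, , 3] <- as.numeric(substr(block, 47, 54))
  }
  if (anyNA(coords)) stop("unparseable coordinates in trajectory")
  structure(list(coords = coords, n_frames = n_frames,
                 replicate_id = replicate_id, frame_times = NULL),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s: %d frame(s) x %d atoms\n",
              x$replicate_id, x$n_frames, dim(x$coords)[2]))
  invisible(x)
}

.format_pdb_atoms <- function(atoms, xyz) {
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$record, atoms$atom_index,
          ifelse(nchar(atoms$atom_name) < 4, paste0(" ", atoms$atom_name),
                 atoms$atom_name),
          atoms$residue_name, atoms$chain_id, atoms$residue_number,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, toupper(atoms$element))
}

#' Write a topology as a single-frame PDB file
#'
#' @param topo A `topology` with coordinates in its `atoms` slot.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topo, path) {
  a <- topo$atoms
  lines <- c(.format_pdb_atoms(a, cbind(a$x, a$y, a$z)), "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `trajectory`.
#' @param topo The matching `topology` (atom metadata).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, topo, path) {
  a <- topo$atoms
  blocks <- vapply(seq_len(traj$n_frames), function(k) {
    paste(c(sprintf("MODEL     %4d", k),
            .format_pdb_atoms(a, traj$coords[k, , , drop = TRUE]),
            "ENDMDL"), collapse = "\n")
  }, character(1))
  writeLines(c(blocks, "END"), path)
  invisible(path)
}

#' Annotate functional groups and aromatic rings on a topology
#'
#' Applies three rules:
#' \itemize{
#'   \item every arginine (ARG) gains a guanidinium group with members
#'     NE/NH1/NH2 and representative CZ (a warning is issued and the residue
#'     skipped if CZ is absent);
#'   \item each configured ligand carboxylate (a set of atom names containing
#'     exactly one carbon and its oxygens) gains a carboxylate group with the
#'     carboxyl carbon as representative;
#'   \item aromatic rings are detected on protein residues by side-chain
#'     templates (PHE/TYR/TRP/HIS) and on the ligand from configured atom-name
#'     sets.
#' }
#'
#' @param topo A `topology`.
#' @param carboxylate_atoms List of character vectors of ligand atom names,
#'   one vector per carboxylate (e.g. `list(c("OD1","OD2","CG"))`).
#' @param ligand_ring_atoms List of character vectors of ligand atom names,
#'   one per aromatic ring.
#' @return The topology with `groups` and `rings` filled. Group entries carry
#'   `type` ("carboxylate" or "guanidinium"), `members`, `representative`
#'   (atom indices) and a human-readable `label`; ring entries carry `name`,
#'   `members` and `is_ligand`.
#' @export
annotate_groups <- function(topo, carboxylate_atoms = NULL,
                            ligand_ring_atoms = NULL) {
  a <- topo$atoms
  groups <- list()
  rings <- list()

  prot <- a[!a$is_ligand, , drop = FALSE]
  res_key <- paste(prot$chain_id, prot$residue_number, prot$residue_name)
  for (key in unique(res_key)) {
    res <- prot[res_key == key, , drop = FALSE]
    resn <- res$residue_name[1]
    if (resn == "ARG") {
      members <- res$atom_index[res$atom_name %in% c("NE", "NH1", "NH2")]
      cz <- res$atom_index[res$atom_name == "CZ"]
      if (length(cz) != 1L) {
        warning(sprintf("ARG%d is missing CZ; guanidinium group skipped",
                        res$residue_number[1]))
      } else if (length(members)) {
        groups[[length(groups) + 1L]] <- list(
          type = "guanidinium", members = members, representative = cz,
          is_ligand = FALSE,
          label = paste0(resn, res$residue_number[1]))
      }
    }
    tmpl <- .residue_ring_templates[[resn]]
    if (!is.null(tmpl)) {
      ring_idx <- res$atom_index[match(tmpl, res$atom_name)]
      if (!anyNA(ring_idx)) {
        rings[[length(rings) + 1L]] <- list(
          name = paste0(resn, res$residue_number[1], ":ring"),
          members = ring_idx, is_ligand = FALSE)
      }
    }
  }

  lig <- a[a$is_ligand, , drop = FALSE]
  for (k in seq_along(carboxylate_atoms)) {
    nm <- carboxylate_atoms[[k]]
    idx <- lig$atom_index[match(nm, lig$atom_name)]
    if (anyNA(idx))
      stop("configured carboxylate atom(s) absent from ligand: ",
           paste(nm[is.na(idx)], collapse = ", "))
    elem <- a$element[idx]
    carbon <- idx[elem == "C"]
    if (length(carbon) != 1L)
      stop("a carboxylate set must contain exactly one carbon (the carboxyl carbon)")
    groups[[length(groups) + 1L]] <- list(
      type = "carboxylate", members = setdiff(idx, carbon),
      representative = carbon, is_ligand = TRUE,
      label = a$atom_name[carbon])
  }
  for (k in seq_along(ligand_ring_atoms)) {
    nm <- ligand_ring_atoms[[k]]
    idx <- lig$atom_index[match(nm, lig$atom_name)]
    if (anyNA(idx))
      stop("configured ligand ring atom(s) absent: ",
           paste(nm[is.na(idx)], collapse = ", "))
    if (length(idx) < 5L)
      stop("a ring annotation needs at least 5 atoms")
    rings[[length(rings) + 1L]] <- list(
      name = paste0("ring", sum(vapply(rings, function(r) r$is_ligand, logical(1))) + 1L),
      members = idx, is_ligand = TRUE)
  }

  heavy_ok <- vapply(rings, function(r) all(topo$atoms$is_heavy[r$members]), logical(1))
  if (length(rings) && !all(heavy_ok))
    stop("ring annotations must contain heavy atoms only")
  topo$groups <- groups
  topo$rings <- rings
  topo
}
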