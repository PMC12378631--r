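#' Read a ligand table
#'
#' A ligand table is a CSV with header `ligand_id,formula,ic50_nM` (extra
#' columns are preserved). `formula` is the Hill-notation formula of the
#' species whose monoisotopic mass should be reported (for HRMS comparison
#' this is the protonated \[M+H\]+ formula); `formula` and `ic50_nM` cells
#' may be empty.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with at least `ligand_id`, `formula`, `ic50_nM`.
#' @export
read_ligand_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(ligand_id = "character"))
  need <- c("ligand_id", "formula", "ic50_nM")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("ligand table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$ligand_id))
    stop("duplicate ligand_id in ligand table")
  tab$formula <- as.character(tab$formula)
  tab$formula[is.na(tab$formula)] <- ""
  tab$ic50_nM <- suppressWarnings(as.numeric(tab$ic50_nM))
  if (any(!is.na(tab$ic50_nM) & tab$ic50_nM <= 0))
    stop("ic50_nM values must be positive where present")
  tab
}

#' Augment a ligand table with pIC50 and monoisotopic [M+H]+ mass
#'
#' Adds a `pic50` column (where `ic50_nM` is present) and a
#' `monoisotopic_mass_mplus_h` column (where `formula` parses). If the table
#' carries an `expected_mplus_h` column, a logical `mass_ok` column flags
#' agreement with the computed mass to within `tol` Da; rows whose formula
#' is empty or unparseable get `NA` and a note, and processing continues.
#'
#' @param ligands A data.frame as returned by [read_ligand_table()].
#' @param tol Absolute agreement tolerance in Da for `mass_ok`.
#' @return The augmented data.frame, with a `note` column describing any
#'   per-row problem.
#' @export
masscheck <- function(ligands, tol = 5e-4) {
  n <- nrow(ligands)
  mass <- rep(NA_real_, n)
  note <- character(n)
  for (i in seq_len(n)) {
    f <- ligands$formula[i]
    if (is.na(f) || !nzchar(f)) {
      note[i] <- "no formula"
      next
    }
    m <- tryCatch(monoisotopic_mass(f), error = function(e) conditionMessage(e))
    if (is.character(m)) {
      note[i] <- m
    } else {
      mass[i] <- m
    }
  }
  ligands$pic50 <- NA_real_
  has_ic50 <- !is.na(ligands$ic50_nM)
  ligands$pic50[has_ic50] <- pic50(ligands$ic50_nM[has_ic50])
  ligands$monoisotopic_mass_mplus_h <- mass
  ligands$note <- note
  if ("expected_mplus_h" %in% names(ligands)) {
    exp <- suppressWarnings(as.numeric(ligands$expected_mplus_h))
    ligands$mass_ok <- ifelse(is.na(mass) | is.na(exp), NA,
                              abs(mass - exp) <= tol)
    bad <- which(!is.na(mass) & !is.na(exp) & !ligands$mass_ok)
    for (i in bad)
      note[i] <- sprintf("computed %.4f differs from expected %.4f by %+.4f Da",
                         mass[i], exp[i], mass[i] - exp[i])
    ligands$note <- note
  }
  ligands
}
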