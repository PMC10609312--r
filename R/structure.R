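#' C-alpha structures
#'
#' A `ca_structure` is the node set used by every network model in the
#' package: one record per residue carrying the author residue number, the
#' 3-letter residue name, the chain identifier and the C-alpha coordinates
#' in Angstrom. It is a tibble (columns `residue`, `icode`, `resname`,
#' `chain`, `x`, `y`, `z`) so the usual dplyr verbs apply; a `label`
#' attribute names the system (e.g. `"GlnBP-open"`).
#'
#' @param residue integer author residue numbers, ordered as in the file.
#' @param resname character 3-letter residue codes.
#' @param coords N x 3 numeric matrix of C-alpha positions (Angstrom).
#' @param chain single chain identifier.
#' @param icode insertion codes (default none); insertion-coded residues
#'   are kept as distinct residues in file order.
#' @param label system name.
#'
#' @return A `ca_structure` tibble.
#' @export
ca_structure <- function(residue, resname, coords, chain = "A",
                         icode = rep("", length(residue)), label = "structure") {
  assert_coords(coords, n_min = 1)
  n <- length(residue)
  if (nrow(coords) != n || length(resname) != n) {
    abort_allonet("residue ids, residue names and coordinate rows must agree in length.")
  }
  out <- tibble::tibble(
    residue = as.integer(residue),
    icode = as.character(icode),
    resname = as.character(resname),
    chain = rep_len(as.character(chain), n),
    x = coords[, 1], y = coords[, 2], z = coords[, 3]
  )
  # within a chain, author numbering must not decrease (insertion codes may
  # repeat a number)
  if (n > 1 && any(diff(out$residue) < 0)) {
    abort_allonet("residue numbers must be non-decreasing within the chain.")
  }
  attr(out, "label") <- label
  class(out) <- c("ca_structure", class(tibble::tibble()))
  out
}

#' @export
print.ca_structure <- function(x, ...) {
  cat(sprintf("# ca_structure '%s': %d residues, chain %s\n",
              structure_label(x), nrow(x), x$chain[1]))
  NextMethod()
}

#' Coordinate matrix of a structure
#'
#' @param s a `ca_structure`.
#' @return N x 3 numeric matrix in Angstrom.
#' @export
ca_coords <- function(s) {
  m <- cbind(s$x, s$y, s$z)
  rownames(m) <- s$residue
  m
}

#' @rdname ca_coords
#' @export
structure_label <- function(s) attr(s, "label") %||% "structure"

#' Read C-alpha records from a PDB file
#'
#' Parses ATOM/HETATM records of one chain and keeps one node per residue
#' that has a C-alpha atom, in file order. Alternate locations are resolved
#' to the highest occupancy (first record on a tie); residues without a
#' C-alpha are dropped with a warning. Insertion-coded residues are kept as
#' distinct residues.
#'
#' @param path PDB-format file.
#' @param chain chain identifier (default: first chain in the file).
#' @param label system name attached to the result (default: file stem).
#' @return A [ca_structure()].
#' @export
read_pdb_ca <- function(path, chain = NULL, label = NULL) {
  if (!file.exists(path)) abort_allonet(sprintf("PDB file not found: %s", path))
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  at <- pdb$atom
  chains <- unique(at$chain)
  chain <- chain %||% chains[1]
  if (!chain %in% chains) {
    abort_allonet(sprintf("chain '%s' absent from %s (has: %s)",
                          chain, path, paste(chains, collapse = ", ")))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  res_key <- paste(at$resno, at$insert, sep = "|")
  res_order <- unique(res_key)
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) abort_allonet(sprintf("no C-alpha atoms in chain '%s' of %s", chain, path))

  # altloc: highest occupancy wins, first record on ties
  ca_key <- paste(ca$resno, ca$insert, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(ca_key, levels = unique(ca_key))),
                        function(idx) idx[which.max(ca[idx, "o"])]))
  ca <- ca[sort(keep), , drop = FALSE]
  ca_key <- paste(ca$resno, ca$insert, sep = "|")

  missing <- setdiff(res_order, ca_key)
  if (length(missing) > 0) {
    warn_allonet(sprintf("%d residue(s) without a C-alpha dropped in chain '%s': %s",
                         length(missing), chain,
                         paste(utils::head(sub("\\|$", "", missing), 10), collapse = ", ")))
  }

  ca_structure(
    residue = ca$resno,
    resname = ca$resid,
    coords = cbind(ca$x, ca$y, ca$z),
    chain = chain,
    icode = ca$insert,
    label = label %||% sub("\\.(pdb|ent)$", "", basename(path))
  )
}

#' Write a structure back to PDB format
#'
#' Minimal ATOM-record writer (C-alpha only); round-trips coordinates at the
#' PDB's 3-decimal precision.
#'
#' @param s a `ca_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(s, path) {
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(s)), s$resname, s$chain, s$residue,
    ifelse(s$icode == "", " ", s$icode), s$x, s$y, s$z
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# 3-letter -> 1-letter, incl. common modified residues
aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q", GLU = "E",
  GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K", MET = "M", PHE = "F",
  PRO = "P", SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  MSE = "M",  # selenomethionine
  SEC = "U", PYL = "O", HSD = "H", HSE = "H", HSP = "H", CYX = "C", HID = "H",
  HIE = "H", HIP = "H"
)

#' Extract the one-letter sequence of a structure
#'
#' Unknown 3-letter codes become `"X"` with a warning; selenomethionine
#' (`MSE`) maps to `M`.
#'
#' @param s a `ca_structure`.
#' @return A single character string, one letter per residue.
#' @export
extract_sequence <- function(s) {
  one <- unname(aa_three_to_one[toupper(s$resname)])
  unknown <- is.na(one)
  if (any(unknown)) {
    warn_allonet(sprintf("%d unknown residue code(s) mapped to 'X': %s",
                         sum(unknown),
                         paste(unique(s$resname[unknown]), collapse = ", ")))
    one[unknown] <- "X"
  }
  paste(one, collapse = "")
}
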