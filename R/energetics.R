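#' Per-residue binding-energy decomposition tables
#'
#' Reads the five-column MM-GBSA per-residue decomposition layout: van der
#' Waals (`e_vdw`) and electrostatic (`e_ele`) terms in vacuum, polar
#' (`e_gb`) and non-polar (`e_gbsur`) solvation terms, and the total
#' (`e_tot`), all in kJ/mol. Cells may be plain numbers or `value ± sd`;
#' Unicode minus signs are normalized.
#'
#' The packaged reference table
#' (`system.file("extdata", "aabp_substrate_energy_decomposition.tsv",
#' package = "allonet")`) carries the published per-residue decomposition
#' for the GlnBP-Gln, HisJ-His and LAOBP-Lys complexes in consensus
#' numbering.
#'
#' @param path TSV file with columns `system`, `consensus`, `residue`,
#'   `e_vdw`, `e_ele`, `e_gb`, `e_gbsur`, `e_tot`.
#' @return An `energy_table` tibble: `system`, `consensus`, `residue`,
#'   one `<term>` and `<term>_sd` column per energy term.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) abort_allonet(sprintf("energy table not found: %s", path))
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           strip.white = TRUE)
  terms <- c("e_vdw", "e_ele", "e_gb", "e_gbsur", "e_tot")
  if (nrow(raw) == 0) {
    warn_allonet("empty energy table.")
    out <- tibble::tibble(system = character(0), consensus = integer(0),
                          residue = character(0))
    for (tm in terms) {
      out[[tm]] <- numeric(0); out[[paste0(tm, "_sd")]] <- numeric(0)
    }
    class(out) <- c("energy_table", class(tibble::tibble()))
    return(out)
  }
  need <- c("system", "consensus", "residue", terms)
  if (!all(need %in% names(raw))) {
    abort_allonet(sprintf("energy table must have columns: %s", paste(need, collapse = ", ")))
  }
  parse_cell <- function(cell, line) {
    cell <- gsub("−", "-", cell)            # Unicode minus
    parts <- strsplit(cell, "±|\\+/-")[[1]]
    vals <- suppressWarnings(as.numeric(trimws(parts)))
    if (length(vals) < 1 || anyNA(vals)) {
      abort_allonet(sprintf("malformed energy cell '%s' on line %d.", cell, line))
    }
    c(value = vals[1], sd = if (length(vals) > 1) vals[2] else NA_real_)
  }
  out <- tibble::tibble(
    system = raw$system,
    consensus = as.integer(raw$consensus),
    residue = raw$residue
  )
  for (tm in terms) {
    parsed <- t(vapply(seq_len(nrow(raw)),
                       function(r) parse_cell(raw[[tm]][r], r + 1),
                       numeric(2)))
    out[[tm]] <- unname(parsed[, 1])
    out[[paste0(tm, "_sd")]] <- unname(parsed[, 2])
  }
  if (!all(grepl("^[A-Z][0-9]+$", out$residue))) {
    abort_allonet("residue labels must be letter + number (e.g. 'K115').")
  }
  dup <- out |> dplyr::count(.data$system, .data$consensus) |> dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort_allonet("duplicate residue numbers within a system.")
  class(out) <- c("energy_table", class(tibble::tibble()))
  out
}

#' Path of the packaged reference energy table
#' @return File path.
#' @export
aabp_energy_table_path <- function() {
  system.file("extdata", "aabp_substrate_energy_decomposition.tsv",
              package = "allonet", mustWork = TRUE)
}

#' Recompute total binding energies from the components
#'
#' `e_tot_sum = e_vdw + e_ele + e_gb + e_gbsur`, rounded to 2 decimals for
#' comparison against printed totals (published tables round each
#' component, so recomputed and printed totals can differ by a few
#' hundredths of a kJ/mol).
#'
#' @param t an `energy_table`.
#' @return The table with an `e_tot_sum` column appended.
#' @export
compute_etot <- function(t) {
  dplyr::mutate(t, e_tot_sum = round(.data$e_vdw + .data$e_ele +
                                       .data$e_gb + .data$e_gbsur, 2))
}

#' Filter the key substrate-binding residues
#'
#' Residues whose total binding energy is strictly below the threshold
#' (default -1.00 kJ/mol), sorted most favourable first.
#'
#' @param t an `energy_table`.
#' @param threshold kJ/mol cutoff (strict `<`).
#' @return Filtered table ordered by ascending `e_tot` (within system when
#'   several systems are present).
#' @export
key_residues <- function(t, threshold = -1.00) {
  t |>
    dplyr::filter(.data$e_tot < threshold) |>
    dplyr::arrange(.data$system, .data$e_tot)
}
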