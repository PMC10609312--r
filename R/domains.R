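#' The consensus domain partition of amino-acid binding proteins
#'
#' AABPs divide into eight fine segments in consensus numbering 1-238, which
#' roll up into three coarse regions: the Thumb (large lobe), the Index
#' Finger (small lobe) and the Linker hinges. The fine partition is the one
#' used for domain-interaction analysis; the I-Loop (consensus 98-112) is
#' the terminal receiver of the allosteric signal.
#'
#' @return A tibble with columns `domain`, `index` (1-8), `start`, `end`.
#' @export
aabp_domains <- function() {
  out <- tibble::tibble(
    domain = c("T-a", "T-aba", "IT1", "I-b", "I-loop", "I-ba", "I-2ba", "IT2"),
    index = 1:8,
    start = c(1, 18, 61, 92, 98, 113, 157, 186),
    end   = c(17, 60, 91, 97, 112, 156, 185, 238)
  )
  stopifnot(all(out$start[-1] == out$end[-nrow(out)] + 1))
  out
}

#' @rdname aabp_domains
#' @export
aabp_regions <- function() {
  tibble::tibble(
    region = c("Thumb", "Linker", "Index", "Linker", "Thumb"),
    start = c(1, 86, 91, 193, 197),
    end   = c(85, 90, 192, 196, 238)
  )
}

range_label <- function(pos, ranges, value_col) {
  idx <- vapply(pos, function(p) {
    hit <- which(ranges$start <= p & p <= ranges$end)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
  ranges[[value_col]][idx]
}

#' Assign domain labels to the residues of one protein
#'
#' Maps each residue through its consensus position (from a position map,
#' see [build_position_map()]) and labels it with the fine domain and the
#' coarse region it falls in. Residues whose alignment column is a gap
#' inherit the label of the nearest mapped consensus position.
#'
#' @param n_residues residue count of the protein.
#' @param map position map for this protein: tibble with columns `residue`
#'   and `consensus`; `NULL` means identity mapping (already in consensus
#'   numbering).
#' @param domains,regions partition tables; defaults [aabp_domains()] and
#'   [aabp_regions()].
#' @return A tibble with columns `residue`, `consensus`, `domain`,
#'   `domain_index`, `region`.
#' @export
assign_domains <- function(n_residues, map = NULL,
                           domains = aabp_domains(), regions = aabp_regions()) {
  if (is.null(map)) {
    map <- tibble::tibble(residue = seq_len(n_residues),
                          consensus = seq_len(n_residues))
  }
  if (max(map$residue) > n_residues) {
    abort_allonet("position map addresses residues beyond `n_residues`.")
  }
  res <- seq_len(n_residues)
  cons <- map$consensus[match(res, map$residue)]
  if (all(is.na(cons))) abort_allonet("position map shares no residues with the protein.")
  # unmapped residues (alignment gaps): nearest mapped neighbour's consensus
  if (anyNA(cons)) {
    mapped <- which(!is.na(cons))
    for (i in which(is.na(cons))) {
      cons[i] <- cons[mapped[which.min(abs(mapped - i))]]
    }
  }
  # consensus positions beyond the partition clamp to its last segment
  cons_clamped <- pmin(pmax(cons, min(domains$start)), max(domains$end))
  tibble::tibble(
    residue = res,
    consensus = as.integer(cons),
    domain = range_label(cons_clamped, domains, "domain"),
    domain_index = range_label(cons_clamped, domains, "index"),
    region = range_label(pmin(pmax(cons, min(regions$start)), max(regions$end)),
                         regions, "region")
  )
}

#' I-Loop consensus positions
#'
#' The default signal-endpoint set for pathway analysis. The flexible loop
#' spans consensus 98-112; `shifted = TRUE` selects the alternative 97-111
#' reading used in some pathway listings.
#'
#' @param shifted use the 97-111 range instead of 98-112.
#' @return Integer vector of consensus positions.
#' @export
iloop_positions <- function(shifted = FALSE) {
  if (shifted) 97:111 else 98:112
}
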