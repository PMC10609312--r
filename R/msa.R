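# Progressive three-way alignment and the consensus position map.
#
# The closest pair (highest pairwise identity) is aligned first; the third
# sequence is then aligned to the pair's column profile with the same
# affine-gap scheme (Gotoh). MSA columns define consensus numbering.

# affine-gap alignment of one sequence against a gapped profile.
# rows: character vectors (equal length) possibly containing "-".
# Returns list(rows_aligned, seq_aligned, score).
# Column score = mean substitution score over non-gap entries, with gap
# entries contributing -gap_extend. Gap of length L costs open + L*extend.
# Traceback tie-break: match/mismatch > gap-in-sequence > gap-in-profile.
profile_align <- function(rows, s, submat, gap_open = 11, gap_extend = 1) {
  sch <- strsplit(s, "")[[1]]
  n <- length(sch)
  L <- length(rows[[1]])
  col_score <- function(i, r) {
    ent <- vapply(rows, `[[`, character(1), i)
    sc <- ifelse(ent == "-", -gap_extend, NA_real_)
    idx <- ent != "-"
    if (any(idx)) sc[idx] <- submat[cbind(ent[idx], rep(r, sum(idx)))]
    mean(sc)
  }
  NEG <- -1e18
  M <- matrix(NEG, L + 1, n + 1); X <- matrix(NEG, L + 1, n + 1); Y <- matrix(NEG, L + 1, n + 1)
  M[1, 1] <- 0
  if (L > 0) X[2:(L + 1), 1] <- -(gap_open + gap_extend * seq_len(L))
  if (n > 0) Y[1, 2:(n + 1)] <- -(gap_open + gap_extend * seq_len(n))
  # precompute substitution scores for all (column, seq char)
  S <- matrix(0, L, n)
  for (i in seq_len(L)) for (j in seq_len(n)) S[i, j] <- col_score(i, sch[j])
  for (i in seq_len(L)) {
    for (j in seq_len(n)) {
      M[i + 1, j + 1] <- S[i, j] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  # traceback
  i <- L; j <- n
  state <- which.max(c(M[L + 1, n + 1], X[L + 1, n + 1], Y[L + 1, n + 1]))
  score <- c(M[L + 1, n + 1], X[L + 1, n + 1], Y[L + 1, n + 1])[state]
  ops <- character(0)  # "M" consume col+char, "X" col+gap, "Y" gapcol+char
  tol <- 1e-9
  while (i > 0 || j > 0) {
    if (state == 1) {
      ops <- c("M", ops)
      v <- M[i + 1, j + 1] - S[i, j]
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which(abs(prev - v) <= tol)[1]
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      ops <- c("X", ops)
      v <- X[i + 1, j + 1]
      from_m <- abs(M[i, j + 1] - gap_open - gap_extend - v) <= tol
      state <- if (from_m) 1 else 2
      i <- i - 1
    } else {
      ops <- c("Y", ops)
      v <- Y[i + 1, j + 1]
      from_m <- abs(M[i + 1, j] - gap_open - gap_extend - v) <= tol
      state <- if (from_m) 1 else 3
      j <- j - 1
    }
    if (i == 0 && j == 0) break
    if (i == 0 && state != 3) state <- 3
    if (j == 0 && state != 2) state <- 2
  }
  # assemble rows
  out_rows <- lapply(rows, function(r) character(0))
  out_seq <- character(0)
  pi <- 0; pj <- 0
  for (op in ops) {
    if (op == "M") {
      pi <- pi + 1; pj <- pj + 1
      for (k in seq_along(rows)) out_rows[[k]] <- c(out_rows[[k]], rows[[k]][pi])
      out_seq <- c(out_seq, sch[pj])
    } else if (op == "X") {
      pi <- pi + 1
      for (k in seq_along(rows)) out_rows[[k]] <- c(out_rows[[k]], rows[[k]][pi])
      out_seq <- c(out_seq, "-")
    } else {
      pj <- pj + 1
      for (k in seq_along(rows)) out_rows[[k]] <- c(out_rows[[k]], "-")
      out_seq <- c(out_seq, sch[pj])
    }
  }
  list(rows = out_rows, seq = out_seq, score = score)
}

#' Progressive three-way multiple alignment
#'
#' Aligns the closest pair first (highest pairwise identity, ties broken by
#' input order), then aligns the third sequence to the pair's column
#' profile. The resulting columns define the consensus numbering used by
#' all cross-protein analyses.
#'
#' @param a,b,c amino-acid sequences; names taken from argument names of a
#'   named vector via `names`, else `"A","B","C"`.
#' @param names row names for the three sequences.
#' @inheritParams align_global
#' @return A `multiple_alignment`: list with `rows` (named character vector
#'   of equal-length aligned strings, input order), `n_columns`,
#'   `conserved` (logical per column: same residue in all rows, no gap).
#' @export
align_three <- function(a, b, c, names = c("A", "B", "C"),
                        substitution_matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  seqs <- c(a, b, c)
  submat <- resolve_submat(substitution_matrix)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  ids <- vapply(pairs, function(p) {
    align_global(seqs[p[1]], seqs[p[2]], substitution_matrix = submat,
                 gap_open = gap_open, gap_extend = gap_extend)$identity
  }, numeric(1))
  first <- pairs[[which.max(ids)]]  # which.max = first on ties = input order
  third <- setdiff(1:3, first)
  aln <- align_global(seqs[first[1]], seqs[first[2]], substitution_matrix = submat,
                      gap_open = gap_open, gap_extend = gap_extend)
  prof <- list(strsplit(aln$a, "")[[1]], strsplit(aln$b, "")[[1]])
  res <- profile_align(prof, seqs[third], submat, gap_open, gap_extend)
  rows_chr <- character(3)
  rows_chr[first[1]] <- paste(res$rows[[1]], collapse = "")
  rows_chr[first[2]] <- paste(res$rows[[2]], collapse = "")
  rows_chr[third] <- paste(res$seq, collapse = "")
  out <- list(rows = stats::setNames(rows_chr, names),
              n_columns = nchar(rows_chr[1]))
  out$conserved <- msa_conserved_flags(out)
  class(out) <- "multiple_alignment"
  out
}

msa_conserved_flags <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa$rows), ""))
  apply(m, 2, function(col) col[1] != "-" && all(col == col[1]))
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("# multiple_alignment: %d rows x %d columns, %d conserved\n",
              length(x$rows), x$n_columns, sum(x$conserved)))
  invisible(x)
}

#' Fully conserved consensus columns
#'
#' @param msa a `multiple_alignment`.
#' @return Integer vector of consensus column indices where all rows carry
#'   the same residue (gaps disqualify).
#' @export
conserved_positions <- function(msa) {
  which(msa_conserved_flags(msa))
}

#' Residue-to-consensus position map
#'
#' For each protein row of the MSA, maps residue index to consensus column
#' (the MSA column index) and back. Gap cells have no mapping.
#'
#' @param msa a `multiple_alignment`.
#' @return A tibble with columns `protein`, `residue`, `consensus`.
#' @export
build_position_map <- function(msa) {
  purrr::imap_dfr(msa$rows, function(row, nm) {
    ch <- strsplit(row, "")[[1]]
    cols <- which(ch != "-")
    tibble::tibble(protein = nm, residue = seq_along(cols), consensus = cols)
  })
}

#' Restrict a position map to one protein
#'
#' @param map tibble from [build_position_map()].
#' @param protein protein row name.
#' @return Tibble with columns `residue`, `consensus`.
#' @export
position_map_for <- function(map, protein) {
  out <- map[map$protein == protein, c("residue", "consensus")]
  if (nrow(out) == 0) abort_allonet(sprintf("protein '%s' not in position map", protein))
  out
}
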