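#' Global pairwise sequence alignment
#'
#' Optimal global alignment with affine gap penalties, BLOSUM62 scoring and
#' BLAST-default gap costs (open 11, extend 1). Identity and coverage are
#' reported BLAST-style over the trimmed alignment core (terminal gap runs
#' excluded).
#'
#' @param a,b amino-acid sequences (single strings).
#' @param substitution_matrix name of a scoring matrix shipped with
#'   Biostrings, or a numeric matrix.
#' @param gap_open,gap_extend positive gap penalties.
#' @return A `pairwise_alignment` object: list with `a`, `b` (aligned rows
#'   with `-` gaps), `score`, `identity` (%), `coverage` (%).
#' @export
align_global <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  check_aa(a); check_aa(b)
  submat <- resolve_submat(substitution_matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global"
  )
  out <- new_pairwise_alignment(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
  out
}

new_pairwise_alignment <- function(a, b, score) {
  stopifnot(nchar(a) == nchar(b))
  out <- list(a = a, b = b, score = score)
  class(out) <- "pairwise_alignment"
  out$identity <- percent_identity(out)
  out$coverage <- alignment_coverage(out)
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("# pairwise_alignment: score %.1f, identity %.2f%%, coverage %.2f%%\n",
              x$score, x$identity, x$coverage))
  show_n <- min(60, nchar(x$a))
  cat(substr(x$a, 1, show_n), "...\n")
  cat(substr(x$b, 1, show_n), "...\n")
  invisible(x)
}

check_aa <- function(s, arg = deparse(substitute(s))) {
  if (length(s) != 1 || !is.character(s) || nchar(s) == 0) {
    abort_allonet(sprintf("`%s` must be one non-empty sequence string.", arg))
  }
  bad <- setdiff(strsplit(toupper(s), "")[[1]],
                 c(strsplit("ACDEFGHIKLMNPQRSTVWYXBZUO", "")[[1]]))
  if (length(bad) > 0) {
    abort_allonet(sprintf("invalid characters in `%s`: %s", arg,
                          paste(bad, collapse = "")))
  }
  invisible(s)
}

resolve_submat <- function(m) {
  if (is.matrix(m)) return(m)
  e <- new.env()
  utils::data(list = m, package = "Biostrings", envir = e)
  get(m, envir = e)
}

alignment_chars <- function(aln) {
  list(a = strsplit(aln$a, "")[[1]], b = strsplit(aln$b, "")[[1]])
}

# trimmed core: first..last column where both rows carry a residue
core_columns <- function(ca, cb) {
  both <- which(ca != "-" & cb != "-")
  if (length(both) == 0) return(integer(0))
  seq(min(both), max(both))
}

#' Percent identity of an alignment
#'
#' Identities divided by the number of alignment columns after excluding
#' terminal gap runs (the BLAST-like local core), reported to 2 decimals.
#'
#' @param aln a `pairwise_alignment`.
#' @return Percentage in \[0, 100\].
#' @export
percent_identity <- function(aln) {
  ch <- alignment_chars(aln)
  core <- core_columns(ch$a, ch$b)
  if (length(core) == 0) return(0)
  round(100 * sum(ch$a[core] == ch$b[core] & ch$a[core] != "-") / length(core), 2)
}

#' @rdname percent_identity
#' @export
alignment_coverage <- function(aln) {
  ch <- alignment_chars(aln)
  core <- core_columns(ch$a, ch$b)
  qlen <- sum(ch$a != "-")
  round(100 * sum(ch$a[core] != "-") / qlen, 2)
}

#' Read and write FASTA sequence files
#'
#' Thin wrappers over Biostrings returning plain named character vectors.
#'
#' @param path FASTA file.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}
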