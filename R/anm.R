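#' Anisotropic network model of a C-alpha structure
#'
#' Builds the 3N x 3N Hessian of the uniform-spring elastic network and
#' eigendecomposes it. Unlike the Gaussian model, the Hessian's
#' eigenvectors carry per-residue motion directions; the six lowest
#' (zero) modes are the rigid-body translations/rotations and are excluded
#' from all derived quantities.
#'
#' @param s a [ca_structure()] or N x 3 coordinate matrix (Angstrom).
#' @param cutoff contact cutoff in Angstrom (default 15, the community
#'   standard for C-alpha anisotropic networks).
#' @param gamma spring constant (default 1).
#' @return An `anm` object: list with `hessian`, `values` (ascending),
#'   `vectors` (3N x 3N), `n_zero`, `coords`, `params`, `label`, `residues`.
#' @export
anm <- function(s, cutoff = 15, gamma = 1) {
  coords <- if (inherits(s, "ca_structure")) ca_coords(s) else s
  if (cutoff <= 0 || gamma <= 0) abort_allonet("cutoff and gamma must be positive.")
  H <- build_hessian(coords, cutoff = cutoff, gamma = gamma)
  out <- anm_decompose(H)
  out$coords <- unname(coords)
  out$params <- list(cutoff = cutoff, gamma = gamma)
  out$label <- if (inherits(s, "ca_structure")) structure_label(s) else "coords"
  out$residues <- if (inherits(s, "ca_structure")) s$residue else seq_len(nrow(coords))
  out
}

#' Hessian matrix of an anisotropic elastic network
#'
#' For each contact pair (i, j) the 3 x 3 off-diagonal super-element is
#' -(gamma / R_ij^2) (r_j - r_i)(r_j - r_i)^T, the second derivative of the
#' harmonic pair potential at the equilibrium geometry; diagonal blocks are
#' the negative sums of the row's off-diagonal blocks (translation
#' invariance).
#'
#' @param coords N x 3 coordinate matrix.
#' @param cutoff contact cutoff in Angstrom.
#' @param gamma spring constant.
#' @return 3N x 3N symmetric matrix.
#' @export
build_hessian <- function(coords, cutoff = 15, gamma = 1) {
  assert_coords(coords, n_min = 3)
  n <- nrow(coords)
  D <- pair_dists(coords)
  H <- matrix(0, 3 * n, 3 * n)
  idx <- function(i) (3 * (i - 1) + 1):(3 * i)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] <= cutoff && D[i, j] > 0) {
        d <- coords[j, ] - coords[i, ]
        blk <- -(gamma / D[i, j]^2) * tcrossprod(d)
        H[idx(i), idx(j)] <- blk
        H[idx(j), idx(i)] <- blk
        H[idx(i), idx(i)] <- H[idx(i), idx(i)] - blk
        H[idx(j), idx(j)] <- H[idx(j), idx(j)] - blk
      }
    }
  }
  H
}

#' Eigendecomposition of an anisotropic network Hessian
#'
#' @param H symmetric 3N x 3N Hessian.
#' @param zero_tol relative zero-eigenvalue tolerance.
#' @return An `anm` object; warns when more than 6 zero modes indicate a
#'   degenerate (e.g. collinear or disconnected) network.
#' @export
anm_decompose <- function(H, zero_tol = 1e-8) {
  if (!isSymmetric(unname(H), tol = 1e-10)) abort_allonet("Hessian must be symmetric.")
  e <- eigen(H, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  n_zero <- sum(abs(values) < zero_tol * max(abs(values), 1e-300))
  if (n_zero > 6) warn_allonet(sprintf("%d zero modes (> 6): degenerate network.", n_zero))
  if (n_zero < 6) warn_allonet(sprintf("only %d zero modes (< 6): check geometry.", n_zero))
  out <- list(hessian = H, values = values, vectors = vectors, n_zero = n_zero)
  class(out) <- "anm"
  out
}

#' @export
print.anm <- function(x, ...) {
  cat(sprintf("# anm '%s': %d residues, %d zero mode(s), cutoff %.1f A\n",
              x$label %||% "?", nrow(x$hessian) / 3, x$n_zero,
              x$params$cutoff %||% NA))
  invisible(x)
}

#' Per-residue displacement field of one mode
#'
#' Reshapes a Hessian eigenvector into per-residue 3-vectors, normalized to
#' unit total length; the per-residue amplitude is the vector norm.
#'
#' @param r an `anm` object.
#' @param k mode index counted among nonzero (internal) modes: `k = 1` is
#'   the lowest-frequency internal mode.
#' @return A tibble with columns `residue`, `ux`, `uy`, `uz`, `amplitude`.
#' @export
mode_displacements <- function(r, k = 1) {
  n_modes <- length(r$values) - r$n_zero
  if (k < 1 || k > n_modes) {
    abort_allonet(sprintf("mode %d outside the %d internal modes (rigid-body modes excluded).",
                          k, n_modes))
  }
  v <- r$vectors[, r$n_zero + k]
  v <- v / sqrt(sum(v^2))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  tibble::tibble(
    residue = r$residues %||% seq_len(nrow(m)),
    ux = m[, 1], uy = m[, 2], uz = m[, 3],
    amplitude = sqrt(rowSums(m^2))
  )
}

#' Overlap of internal modes with an open-to-closed transition
#'
#' Quantifies how much of the conformational change between two structures
#' is captured by each internal mode: overlap_k = |v_k . dr| / (|v_k||dr|),
#' with dr the closed-minus-open difference vector on shared residues after
#' Kabsch superposition.
#'
#' @param r an `anm` object computed on the open structure (or on any
#'   structure congruent with `open_coords`).
#' @param open_coords,closed_coords N x 3 matrices on shared residues, in
#'   matching row order.
#' @param n_modes number of internal modes to report.
#' @return A tibble with columns `mode`, `eigenvalue`, `overlap`.
#' @export
overlap_with_transition <- function(r, open_coords, closed_coords,
                                    n_modes = min(20, length(r$values) - r$n_zero)) {
  if (nrow(open_coords) < 10) abort_allonet("need at least 10 shared residues.")
  if (!all(dim(open_coords) == dim(closed_coords))) {
    abort_allonet("open and closed coordinate sets must be congruent.")
  }
  fit <- kabsch_superpose(open_coords, closed_coords)
  dr <- as.numeric(t(fit$coords - open_coords))
  dr_n <- sqrt(sum(dr^2))
  if (dr_n < 1e-12) abort_allonet("structures are identical: no transition vector.")
  sel <- r$n_zero + seq_len(n_modes)
  ov <- vapply(sel, function(j) {
    v <- r$vectors[, j]
    abs(sum(v * dr)) / (sqrt(sum(v^2)) * dr_n)
  }, numeric(1))
  tibble::tibble(mode = seq_len(n_modes), eigenvalue = r$values[sel], overlap = ov)
}
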