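#' Gaussian network model of a C-alpha structure
#'
#' Builds the Kirchhoff (connectivity) matrix at the given contact cutoff
#' and eigendecomposes it. Residue pairs closer than the cutoff are coupled
#' by identical springs; mean-square fluctuations and cross-correlations
#' follow from the pseudoinverse restricted to selected modes.
#'
#' @param s a [ca_structure()] or an N x 3 coordinate matrix (Angstrom).
#' @param cutoff contact cutoff in Angstrom (default 7.3).
#' @param gamma spring constant (arbitrary units, default 1).
#' @param kbt thermal factor k_B*T (arbitrary units, default 1).
#' @return A `gnm` object: list with `kirchhoff`, `values` (ascending),
#'   `vectors`, `n_zero` (zero-mode count), `params`, `label`, `residues`.
#' @export
gnm <- function(s, cutoff = 7.3, gamma = 1, kbt = 1) {
  coords <- if (inherits(s, "ca_structure")) ca_coords(s) else s
  if (cutoff <= 0 || gamma <= 0) abort_allonet("cutoff and gamma must be positive.")
  K <- build_kirchhoff(coords, cutoff = cutoff)
  out <- gnm_decompose(K)
  out$params <- list(cutoff = cutoff, gamma = gamma, kbt = kbt)
  out$label <- if (inherits(s, "ca_structure")) structure_label(s) else "coords"
  out$residues <- if (inherits(s, "ca_structure")) s$residue else seq_len(nrow(coords))
  out
}

#' Kirchhoff matrix of a contact network
#'
#' Off-diagonal entries are -1 for residue pairs within the cutoff, 0
#' otherwise; diagonal entries are the negative off-diagonal row sums
#' (contact degrees), so every row sums to zero.
#'
#' @param coords N x 3 coordinate matrix.
#' @param cutoff contact cutoff in Angstrom.
#' @return N x N symmetric matrix.
#' @export
build_kirchhoff <- function(coords, cutoff = 7.3) {
  assert_coords(coords, n_min = 2)
  D <- pair_dists(coords)
  K <- ifelse(D <= cutoff, -1, 0)
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  if (all(K == 0)) {
    warn_allonet("no contacts at this cutoff: Kirchhoff matrix is zero (disconnected).")
  }
  dimnames(K) <- NULL
  K
}

#' Eigendecomposition of a Kirchhoff matrix
#'
#' @param K symmetric Kirchhoff matrix.
#' @param zero_tol relative tolerance below which an eigenvalue counts as a
#'   zero (rigid) mode.
#' @return A `gnm` object (without parameters attached).
#' @export
gnm_decompose <- function(K, zero_tol = 1e-8) {
  if (!isSymmetric(unname(K), tol = 1e-10)) abort_allonet("Kirchhoff matrix must be symmetric.")
  e <- eigen(K, symmetric = TRUE)
  values <- rev(e$values)
  vectors <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  n_zero <- sum(abs(values) < zero_tol * max(abs(values), 1e-300))
  out <- list(kirchhoff = K, values = values, vectors = vectors, n_zero = n_zero)
  class(out) <- "gnm"
  out
}

#' @export
print.gnm <- function(x, ...) {
  cat(sprintf("# gnm '%s': %d residues, %d zero mode(s), cutoff %.2f A\n",
              x$label %||% "?", nrow(x$kirchhoff), x$n_zero,
              x$params$cutoff %||% NA))
  invisible(x)
}

resolve_modes <- function(r, modes, k) {
  n <- length(r$values)
  nz <- setdiff(seq_len(n), seq_len(r$n_zero))
  sel <- switch(modes,
    slow = utils::head(nz, k),
    fast = utils::tail(seq_len(n), k),
    all = nz,
    abort_allonet("`modes` must be 'slow', 'fast' or 'all'.")
  )
  if (length(sel) == 0 || (modes != "all" && length(sel) < k)) {
    abort_allonet(sprintf("requested %d %s modes but only %d available.", k, modes, length(sel)))
  }
  sel
}

selected_pseudoinverse <- function(r, sel) {
  V <- r$vectors[, sel, drop = FALSE]
  V %*% (t(V) / r$values[sel])
}

#' Per-residue mean-square fluctuations from selected modes
#'
#' MSF_i = (3 k_B T / gamma) * sum_k v_ki^2 / lambda_k over the selected
#' modes. `modes = "slow"` selects the k lowest nonzero modes (collective
#' domain motion), `"fast"` the k highest (local packing; minima mark
#' kinetically hot residues), `"all"` every nonzero mode (the full
#' pseudoinverse diagonal).
#'
#' @param r a `gnm` object.
#' @param modes `"slow"`, `"fast"` or `"all"`.
#' @param k number of modes (defaults: slow 2, fast 10).
#' @return A tibble with columns `residue`, `msf`.
#' @export
mode_fluctuations <- function(r, modes = "slow", k = if (modes == "fast") 10 else 2) {
  sel <- resolve_modes(r, modes, k)
  scale <- 3 * (r$params$kbt %||% 1) / (r$params$gamma %||% 1)
  msf <- scale * colSums(t(r$vectors[, sel, drop = FALSE]^2) / r$values[sel])
  tibble::tibble(residue = r$residues %||% seq_along(msf), msf = as.numeric(msf))
}

#' Cross-correlation map from selected modes
#'
#' C_ij from the selected-mode pseudoinverse of the Kirchhoff matrix;
#' normalized maps divide by sqrt(C_ii C_jj) so the diagonal is 1 and
#' off-diagonal values fall in \[-1, 1\].
#'
#' @inheritParams mode_fluctuations
#' @param normalize return normalized correlations (default TRUE).
#' @return N x N matrix.
#' @export
cross_correlation <- function(r, modes = "slow", k = 2, normalize = TRUE) {
  sel <- resolve_modes(r, modes, k)
  C <- selected_pseudoinverse(r, sel)
  if (normalize) {
    d <- sqrt(pmax(diag(C), 1e-300))
    C <- C / tcrossprod(d)
  }
  C
}

#' Detect hot spots and hinges in a fluctuation profile
#'
#' Hot spots are local minima of the fast-mode profile (GNM convention:
#' fast-mode minima are kinetically hot) below a quantile criterion; hinges
#' are local minima of the slow-mode profile (near-zero fluctuation points
#' about which domains rotate).
#'
#' @param profile tibble with columns `residue`, `msf` (or a numeric vector).
#' @param kind `"hotspot"` or `"hinge"` (same extraction; named for intent).
#' @param quantile keep only minima below this profile quantile.
#' @return A tibble with columns `residue`, `msf`, ordered by `msf`.
#' @export
detect_extrema <- function(profile, kind = c("hotspot", "hinge"), quantile = 0.25) {
  kind <- match.arg(kind)
  if (is.numeric(profile)) {
    profile <- tibble::tibble(residue = seq_along(profile), msf = profile)
  }
  v <- profile$msf
  if (length(v) < 3) abort_allonet("profile needs at least 3 residues.")
  if (diff(range(v)) < 1e-12) {
    warn_allonet("flat profile: no extrema.")
    return(profile[0, ])
  }
  # local minima (plateau-tolerant at strict neighbours)
  is_min <- vapply(seq_along(v), function(i) {
    left <- if (i > 1) v[i - 1] else Inf
    right <- if (i < length(v)) v[i + 1] else Inf
    v[i] < left && v[i] <= right
  }, logical(1))
  thr <- stats::quantile(v, quantile)
  out <- profile[is_min & v <= thr, ]
  out[order(out$msf), ]
}

#' Correlation between two residue profiles across proteins
#'
#' Profiles are first mapped onto shared consensus columns via the position
#' map; Pearson correlation is computed over columns mapped in both.
#'
#' @param pa,pb profile tibbles (`residue`, `msf`).
#' @param map_a,map_b per-protein position maps (`residue`, `consensus`);
#'   `NULL` means the profile is already in consensus numbering.
#' @return Pearson correlation coefficient.
#' @export
profile_correlation <- function(pa, pb, map_a = NULL, map_b = NULL) {
  to_consensus <- function(p, map) {
    if (is.null(map)) return(stats::setNames(p$msf, p$residue))
    cons <- map$consensus[match(p$residue, map$residue)]
    stats::setNames(p$msf, cons)[!is.na(cons)]
  }
  va <- to_consensus(pa, map_a)
  vb <- to_consensus(pb, map_b)
  shared <- intersect(names(va), names(vb))
  if (length(shared) < 3) abort_allonet("fewer than 3 shared consensus columns.")
  stats::cor(va[shared], vb[shared])
}
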