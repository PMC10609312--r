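#' Coarse-grained trajectories
#'
#' A `trajectory` stores frames x nodes x 3 coordinates (Angstrom) with
#' optional per-frame velocities (Angstrom per frame) and a timestep in
#' arbitrary units. It is the input container for RMSD/RMSF statistics and
#' for relational-inference features.
#'
#' @param coords numeric array T x N x 3.
#' @param velocities optional array congruent with `coords`.
#' @param dt timestep (arbitrary units).
#' @param label system name.
#' @return A `trajectory` object.
#' @export
trajectory <- function(coords, velocities = NULL, dt = 1, label = "trajectory") {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort_allonet("`coords` must be a T x N x 3 array.")
  }
  if (!all(is.finite(coords))) abort_allonet("`coords` contains non-finite values.")
  if (!is.null(velocities) && !all(dim(velocities) == dim(coords))) {
    abort_allonet("`velocities` must be congruent with `coords`.")
  }
  out <- list(coords = coords, velocities = velocities, dt = dt, label = label)
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("# trajectory '%s': %d frames x %d nodes%s\n",
              x$label, d[1], d[2],
              if (is.null(x$velocities)) "" else " (+velocities)"))
  invisible(x)
}

#' @export
dim.trajectory <- function(x) dim(x$coords)

frame_coords <- function(traj, t) {
  matrix(traj$coords[t, , ], ncol = 3)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `ref` (SVD solution with reflection correction).
#'
#' @param ref,mobile N x 3 coordinate matrices, matched rows.
#' @return List with `coords` (superposed mobile), `rmsd`, `rotation`
#'   (3 x 3), `translation`.
#' @export
kabsch_superpose <- function(ref, mobile) {
  if (!all(dim(ref) == dim(mobile))) abort_allonet("coordinate sets must be congruent.")
  if (nrow(ref) < 3) abort_allonet("need at least 3 points.")
  cr <- colMeans(ref); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  if (sum(A^2) < 1e-20 || sum(B^2) < 1e-20) abort_allonet("degenerate (coincident) coordinates.")
  s <- svd(crossprod(A, B))            # A^T B
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- sweep(A %*% R, 2, cr, FUN = "+")
  list(
    coords = fitted,
    rmsd = sqrt(mean(rowSums((fitted - ref)^2))),
    rotation = R,
    translation = cr - cm %*% R
  )
}

#' Per-frame RMSD to a reference frame
#'
#' Each frame is Kabsch-superposed onto the reference before the deviation
#' is measured, so rigid-body motion does not contribute.
#'
#' @param traj a [trajectory()].
#' @param ref reference frame index (default 1) or an N x 3 matrix.
#' @return A tibble with columns `frame`, `time`, `rmsd`.
#' @export
rmsd_series <- function(traj, ref = 1) {
  refc <- if (is.matrix(ref)) ref else frame_coords(traj, ref)
  T_ <- dim(traj)[1]
  vals <- vapply(seq_len(T_), function(t) {
    kabsch_superpose(refc, frame_coords(traj, t))$rmsd
  }, numeric(1))
  tibble::tibble(frame = seq_len(T_), time = (seq_len(T_) - 1) * traj$dt, rmsd = vals)
}

#' Per-node RMSF profile
#'
#' Frames are superposed onto the mean structure (one iteration: mean of
#' frames superposed on frame 1, then re-superpose on that mean);
#' RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2).
#'
#' @param traj a [trajectory()].
#' @return A tibble with columns `node`, `rmsf`.
#' @export
rmsf_profile <- function(traj) {
  T_ <- dim(traj)[1]; N <- dim(traj)[2]
  if (T_ < 2) abort_allonet("RMSF needs at least 2 frames.")
  ref <- frame_coords(traj, 1)
  aligned <- lapply(seq_len(T_), function(t) kabsch_superpose(ref, frame_coords(traj, t))$coords)
  mean1 <- Reduce(`+`, aligned) / T_
  aligned <- lapply(seq_len(T_), function(t) kabsch_superpose(mean1, frame_coords(traj, t))$coords)
  mean2 <- Reduce(`+`, aligned) / T_
  dev2 <- Reduce(`+`, lapply(aligned, function(m) rowSums((m - mean2)^2))) / T_
  tibble::tibble(node = seq_len(N), rmsf = sqrt(dev2))
}

#' Six-dimensional node features for relational inference
#'
#' Per node and kept frame: position (x, y, z) and velocity (x, y, z).
#' Velocities come from the trajectory when present, else central finite
#' differences (one-sided at the ends). Each of the 6 feature dimensions is
#' standardized to zero mean / unit variance over all nodes and frames,
#' with the transform recorded for exact inversion.
#'
#' @param traj a [trajectory()].
#' @param stride keep every `stride`-th frame.
#' @return List with `features` (array T' x N x 6), `center`, `scale`
#'   (length-6), `stride`.
#' @export
featurize_nri <- function(traj, stride = 1) {
  co <- traj$coords
  T_ <- dim(co)[1]
  keep <- seq(1, T_, by = stride)
  if (length(keep) < 2) abort_allonet("too few frames after striding.")
  if (!is.null(traj$velocities)) {
    ve <- traj$velocities[keep, , , drop = FALSE] * stride
  } else {
    ck <- co[keep, , , drop = FALSE]
    Tk <- length(keep)
    ve <- array(0, dim(ck))
    if (Tk >= 3) {
      ve[2:(Tk - 1), , ] <- (ck[3:Tk, , , drop = FALSE] - ck[1:(Tk - 2), , , drop = FALSE]) / 2
    }
    ve[1, , ] <- ck[2, , ] - ck[1, , ]
    ve[Tk, , ] <- ck[Tk, , ] - ck[Tk - 1, , ]
  }
  feats <- array(0, c(length(keep), dim(co)[2], 6))
  feats[, , 1:3] <- co[keep, , , drop = FALSE]
  feats[, , 4:6] <- ve
  center <- numeric(6); scale <- numeric(6)
  for (d in 1:6) {
    v <- feats[, , d]
    center[d] <- mean(v)
    scale[d] <- stats::sd(v)
    if (scale[d] < 1e-12) scale[d] <- 1
    feats[, , d] <- (v - center[d]) / scale[d]
  }
  list(features = feats, center = center, scale = scale, stride = stride)
}

#' Invert the feature standardization
#'
#' @param f list from [featurize_nri()].
#' @return Array of raw (unstandardized) features.
#' @export
unstandardize_features <- function(f) {
  out <- f$features
  for (d in 1:6) out[, , d] <- out[, , d] * f$scale[d] + f$center[d]
  out
}

#' Read and write multi-frame XYZ trajectory files
#'
#' Plain-text format: per frame, a node-count line, a comment line, then
#' one `name x y z` line per node.
#'
#' @param traj a [trajectory()].
#' @param path file path.
#' @return `write_xyz()`: the path, invisibly; `read_xyz()`: a
#'   [trajectory()].
#' @export
write_xyz <- function(traj, path) {
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(d[1])) {
    writeLines(c(as.character(d[2]), sprintf("frame %d", t)), con)
    m <- frame_coords(traj, t)
    writeLines(sprintf("CA %.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  per <- n + 2
  T_ <- length(lines) %/% per
  co <- array(0, c(T_, n, 3))
  for (t in seq_len(T_)) {
    block <- lines[((t - 1) * per + 3):((t - 1) * per + 2 + n)]
    parts <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    co[t, , ] <- apply(parts[, 2:4, drop = FALSE], 2, as.numeric)
  }
  trajectory(co, label = sub("\\.xyz$", "", basename(path)))
}
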