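# Synthetic inputs: two-lobe hinge structures, elastic-network-sampled
# trajectories, spring-particle systems with known connectivity, and
# synthetic energy tables. Every generator is a pure function of its
# arguments and seed.

# chain of n beads on a sphere shell: dense spherical spiral, walked with
# exact steps of `spacing` (chord length), so consecutive beads are
# `spacing` apart and windings are ~`spacing` apart (self-avoiding,
# globular shell). The radius is inflated until the walk fits; tight polar
# windings make chords consume more arc than their own length.
sphere_chain <- function(n, spacing = 3.8) {
  M <- max(2000, 40 * n)
  h <- seq(-1, 1, length.out = M)
  theta <- acos(h)
  phi <- numeric(M)
  # generalized spiral whose winding count is set by the bead count n (the
  # dense parameter M only smooths the curve), so along-chain and
  # across-winding separations both come out ~`spacing`
  for (k in 2:(M - 1)) {
    phi[k] <- phi[k - 1] + 3.6 * sqrt(n) / (M * sqrt(1 - h[k]^2))
  }
  phi[M] <- phi[M - 1]
  unit <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  L_unit <- sum(sqrt(rowSums((unit[-1, ] - unit[-M, ])^2)))
  r <- (n + 1) * spacing / L_unit
  for (attempt in 1:12) {
    out <- walk_spiral(unit * r, n, spacing, M)
    if (!is.null(out)) return(out)
    r <- r * 1.06
  }
  abort_allonet("infeasible lobe geometry: chain does not fit on the shell.")
}

walk_spiral <- function(pts_dense, n, spacing, M) {
  out <- matrix(0, n, 3)
  out[1, ] <- pts_dense[1, ]
  cur <- 1
  for (i in 2:n) {
    j <- cur
    while (j < M && sqrt(sum((pts_dense[j, ] - out[i - 1, ])^2)) < spacing) j <- j + 1
    if (j >= M) return(NULL)
    a <- pts_dense[j - 1, ]; b <- pts_dense[j, ]
    f <- stats::uniroot(function(t) sqrt(sum((a + t * (b - a) - out[i - 1, ])^2)) - spacing,
                        c(0, 1), tol = 1e-10)$root
    out[i, ] <- a + f * (b - a)
    cur <- j
  }
  out
}

# orthonormal basis of the 6 rigid-body displacement fields (3N space,
# coordinates interleaved x1 y1 z1 x2 ...)
rigid_basis <- function(co0) {
  N <- nrow(co0)
  cen <- sweep(co0, 2, colMeans(co0))
  B <- matrix(0, 3 * N, 6)
  for (ax in 1:3) B[seq(ax, 3 * N, by = 3), ax] <- 1
  rot <- list(c(2, 3), c(3, 1), c(1, 2))         # rotation about x, y, z
  for (r in 1:3) {
    a <- rot[[r]][1]; b <- rot[[r]][2]
    w <- matrix(0, N, 3)
    w[, a] <- -cen[, b]
    w[, b] <- cen[, a]
    B[, 3 + r] <- as.numeric(t(w))
  }
  qr.Q(qr(B))
}

bezier_length <- function(p0, p2) {
  tt <- seq(0, 1, length.out = 200)
  bez <- outer((1 - tt)^2, p0) + outer(tt^2, p2)
  sum(sqrt(rowSums((bez[-1, ] - bez[-nrow(bez), ])^2)))
}

rotation_about_z <- function(angle) {
  matrix(c(cos(angle), -sin(angle), 0,
           sin(angle), cos(angle), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# proper rotation mapping unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (abs(cth + 1) < 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- perp - sum(perp * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

#' Generate a two-lobe hinge structure
#'
#' Builds a coarse-grained protein mimic: two self-avoiding globular lobes
#' (beads walked along a spherical spiral at C-alpha spacing) joined by an
#' extended linker, with the lobe axes meeting at the hinge point at the
#' requested angle (large = open cleft, small = closed). Defaults emulate a
#' 238-residue amino-acid binding protein: 115-residue lobes and an
#' 8-residue linker.
#'
#' @param n_lobe residues per lobe (length-2 vector or scalar).
#' @param linker linker residue count.
#' @param hinge_angle degrees in (0, 180); default 120 (open).
#' @param spacing consecutive C-alpha distance in Angstrom.
#' @param jitter coordinate noise sd in Angstrom.
#' @param seed RNG seed.
#' @param label system name.
#' @return A [ca_structure()] with an extra `region` column
#'   (`lobeA`/`linker`/`lobeB`) and attributes `hinge_point`, `hinge_axis`,
#'   `hinge_angle`, `arc` (per-residue linker arc position).
#' @export
make_two_domain_structure <- function(n_lobe = c(115, 115), linker = 8,
                                      hinge_angle = 120, spacing = 3.8,
                                      jitter = 0.1, seed = 1,
                                      label = "two-domain") {
  n_lobe <- rep_len(n_lobe, 2)
  if (sum(n_lobe) + linker < 30) abort_allonet("need at least 30 residues in total.")
  if (hinge_angle <= 0 || hinge_angle >= 180) abort_allonet("hinge angle must be in (0, 180) degrees.")
  a2 <- hinge_angle * pi / 360
  u1 <- c(cos(a2), sin(a2), 0)
  u2 <- c(cos(a2), -sin(a2), 0)

  lobeA <- sphere_chain(n_lobe[1], spacing)
  lobeB <- sphere_chain(n_lobe[2], spacing)
  rA <- sqrt(sum(lobeA[1, ]^2)); rB <- sqrt(sum(lobeB[1, ]^2))
  # orient chains so lobe A exits, and lobe B enters, facing the hinge
  lobeA <- lobeA %*% t(rotation_between(lobeA[n_lobe[1], ] / rA, -u1))
  lobeB <- lobeB %*% t(rotation_between(lobeB[1, ] / rB, -u2))
  # place the lobes so the hinge-bowed linker curve has the chain's
  # natural length (a few fixed-point iterations on the arm length)
  target <- (linker + 1) * spacing
  D <- max(rA, rB) + target / 2
  for (it in 1:8) {
    arc_len <- bezier_length(D * u1 - rA * u1, D * u2 - rB * u2)
    D <- D + (target - arc_len) / 2
  }
  if (2 * D * sin(a2) < rA + rB + 2) {
    abort_allonet("infeasible geometry: lobes would interpenetrate at this hinge angle.")
  }
  cA <- D * u1; cB <- D * u2
  pA <- sweep(lobeA, 2, cA, "+")
  pB <- sweep(lobeB, 2, cB, "+")

  # linker along a quadratic Bezier bowed through the hinge point, with a
  # small out-of-plane wiggle so no three consecutive beads are collinear
  # (collinear runs would add spurious torsional zero modes to the
  # anisotropic network)
  exitA <- pA[n_lobe[1], ]; entryB <- pB[1, ]
  tt <- seq(0, 1, length.out = 400)
  bez <- outer((1 - tt)^2, exitA) + outer(tt^2, entryB)  # control point = origin
  seg <- sqrt(rowSums((bez[-1, ] - bez[-nrow(bez), ])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  arc <- total * seq_len(linker) / (linker + 1)
  interp <- function(s) {
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    f <- (s - cum[j]) / max(cum[j + 1] - cum[j], 1e-12)
    bez[j, ] + f * (bez[j + 1, ] - bez[j, ])
  }
  pL <- t(vapply(arc, interp, numeric(3)))
  # helical offset (radius 0.8 A) about the curve: stiffens torsion of one
  # lobe about the inter-lobe axis, which a straight linker cannot resist
  ez <- c(0, 0, 1)
  phase <- 2 * pi * arc / (3 * spacing)
  for (q in seq_len(linker)) {
    tang <- interp(min(arc[q] + 0.5, total)) - interp(max(arc[q] - 0.5, 0))
    tang <- tang / max(sqrt(sum(tang^2)), 1e-12)
    n1 <- c(tang[2], -tang[1], 0)
    n1 <- n1 / max(sqrt(sum(n1^2)), 1e-12)
    pL[q, ] <- pL[q, ] + 0.8 * (sin(phase[q]) * ez + cos(phase[q]) * n1)
  }

  coords <- rbind(pA, pL, pB)
  coords <- with_seed(seed, coords + matrix(stats::rnorm(length(coords), 0, jitter),
                                            nrow(coords), 3))
  n <- nrow(coords)
  s <- ca_structure(residue = seq_len(n), resname = rep("ALA", n),
                    coords = coords, chain = "A", label = label)
  s$region <- c(rep("lobeA", n_lobe[1]), rep("linker", linker), rep("lobeB", n_lobe[2]))
  attr(s, "hinge_point") <- c(0, 0, 0)
  attr(s, "hinge_axis") <- c(0, 0, 1)
  attr(s, "hinge_angle") <- hinge_angle
  attr(s, "linker_arc") <- arc
  attr(s, "linker_arm") <- total / 2
  class(s) <- c("ca_structure", class(tibble::tibble()))
  s
}

#' Rotate one lobe to a new hinge angle
#'
#' Rigidly rotates lobe B (and the linker residues past the hinge point)
#' about the hinge axis, leaving lobe-internal geometry untouched; with
#' `new_angle` equal to the current angle this is the identity.
#'
#' @param s structure from [make_two_domain_structure()].
#' @param new_angle degrees in (0, 180).
#' @return The rotated structure (hinge attributes updated).
#' @export
close_hinge <- function(s, new_angle) {
  old <- attr(s, "hinge_angle")
  if (is.null(old)) abort_allonet("structure has no hinge annotation.")
  if (new_angle <= 0 || new_angle >= 180) abort_allonet("hinge angle must be in (0, 180) degrees.")
  delta <- (old - new_angle) * pi / 180
  R <- rotation_about_z(delta)
  move <- s$region == "lobeB"
  lk <- which(s$region == "linker")
  move[lk[attr(s, "linker_arc") >= attr(s, "linker_arm")]] <- TRUE
  co <- ca_coords(s)
  h <- attr(s, "hinge_point")
  co[move, ] <- sweep(sweep(co[move, , drop = FALSE], 2, h) %*% t(R), 2, h, "+")
  s$x <- co[, 1]; s$y <- co[, 2]; s$z <- co[, 3]
  attr(s, "hinge_angle") <- new_angle
  s
}

#' Sample a trajectory from elastic-network modes
#'
#' Desk-scale stand-in for molecular dynamics: frames are the mean
#' structure plus a random superposition of internal elastic-network
#' modes, each mode amplitude drawn with variance `amplitude / lambda_k`
#' (equipartition). A per-residue RMS cap (`rms_cap`) limits the softest
#' modes, mimicking the anharmonic restraints that keep real soft-mode
#' excursions finite. With `ar1` set, amplitudes follow an AR(1) process
#' in time (same stationary variance), which makes finite-difference
#' velocities informative. `source = "anm"` uses directional Hessian
#' modes; `"gnm"` draws isotropic displacements on the Kirchhoff modes.
#'
#' The per-residue mean-square fluctuation implied by the sampled mode
#' variances is attached as attribute `"generating_msf"` (tibble
#' `residue`, `msf`) for parameter-recovery checks.
#'
#' @param s a [ca_structure()].
#' @param n_frames frames to sample.
#' @param amplitude overall fluctuation scale.
#' @param cutoff contact cutoff in Angstrom; default 15 for `"anm"`, 7.3
#'   for `"gnm"`.
#' @param n_modes number of internal modes to superpose (default all).
#' @param ar1 AR(1) coefficient in \[0, 1) or `NULL` for independent
#'   frames; default 0.9.
#' @param rms_cap cap on any single mode's per-residue RMS displacement
#'   (Angstrom).
#' @param source `"anm"` or `"gnm"` mode basis.
#' @param seed RNG seed.
#' @return A [trajectory()] with the `"generating_msf"` attribute.
#' @export
sample_enm_trajectory <- function(s, n_frames = 300, amplitude = 1,
                                  cutoff = NULL, n_modes = NULL, ar1 = 0.9,
                                  rms_cap = 1.5, source = c("anm", "gnm"),
                                  seed = 1) {
  source <- match.arg(source)
  co0 <- ca_coords(s)
  N <- nrow(co0)
  if (source == "anm") {
    a <- anm(s, cutoff = cutoff %||% 15)
    if (a$n_zero > 6) abort_allonet("disconnected or degenerate network: cannot sample modes.")
    n_int <- length(a$values) - a$n_zero
    sel <- a$n_zero + seq_len(min(n_modes %||% n_int, n_int))
    V <- a$vectors[, sel, drop = FALSE]          # 3N x m
    sig <- pmin(sqrt(amplitude / a$values[sel]), rms_cap * sqrt(N))
    n_series <- length(sel)
  } else {
    g <- gnm(s, cutoff = cutoff %||% 7.3)
    if (g$n_zero > 1) abort_allonet("disconnected network: cannot sample modes.")
    n_int <- length(g$values) - g$n_zero
    sel <- g$n_zero + seq_len(min(n_modes %||% n_int, n_int))
    Vg <- g$vectors[, sel, drop = FALSE]         # N x m, isotropic per axis
    m <- length(sel)
    # expand to 3N displacement fields (mode x axis) and project out the
    # rigid-body subspace, which frame superposition would remove anyway
    V <- matrix(0, 3 * N, 3 * m)
    for (ax in 1:3) {
      rows <- seq(ax, 3 * N, by = 3)
      V[rows, (ax - 1) * m + seq_len(m)] <- Vg
    }
    Rb <- rigid_basis(co0)
    V <- V - Rb %*% crossprod(Rb, V)
    sig <- rep(pmin(sqrt(amplitude / g$values[sel]), rms_cap * sqrt(N)), 3)
    n_series <- 3 * m
  }
  amp <- with_seed(seed, {
    eps <- matrix(stats::rnorm(n_frames * n_series), n_frames, n_series)
    if (!is.null(ar1)) {
      for (t in 2:n_frames) eps[t, ] <- ar1 * eps[t - 1, ] + sqrt(1 - ar1^2) * eps[t, ]
    }
    eps
  })
  co <- array(0, c(n_frames, N, 3))
  disp <- sweep(amp, 2, sig, "*") %*% t(V)       # frames x 3N
  for (t in seq_len(n_frames)) {
    co[t, , ] <- co0 + matrix(disp[t, ], ncol = 3, byrow = TRUE)
  }
  msf <- rowSums(matrix(colSums(sig^2 * t(V^2)), ncol = 3, byrow = TRUE))
  out <- trajectory(co, dt = 1, label = paste0(structure_label(s), "-enm"))
  attr(out, "generating_msf") <- tibble::tibble(residue = s$residue %||% seq_len(N),
                                                msf = as.numeric(msf))
  out
}

#' Simulate an interacting spring-particle system
#'
#' Velocity-Verlet integration of unit-mass particles coupled by harmonic
#' springs (zero rest length) on a random graph; the exact adjacency is
#' returned as ground truth for relational inference. A weak tether to
#' the origin (`k_tether`, common to every particle) keeps unbound
#' particles bounded, playing the role of the bounding box in standard
#' relational-inference spring benchmarks, and frames are recorded in the
#' centre-of-mass frame. Optional Gaussian observation noise is added to
#' the recorded positions and velocities only, never to the dynamics.
#' Aborts if total energy grows more than tenfold (unstable timestep).
#'
#' @param n particles (desk scale, <= 20).
#' @param edge_prob probability of a spring between a pair.
#' @param k_spring spring constant.
#' @param k_tether common tether constant (set 0 to disable).
#' @param dt integration step.
#' @param steps integration steps.
#' @param sample_every record every so many steps.
#' @param noise_sd observation noise sd.
#' @param seed RNG seed.
#' @return List with `trajectory` (a [trajectory()] with velocities, in
#'   per-recorded-frame units) and `adjacency` (n x n 0/1).
#' @export
simulate_springs <- function(n = 5, edge_prob = 0.5, k_spring = 1,
                             k_tether = 0.1, dt = 0.005, steps = 80000,
                             sample_every = 40, noise_sd = 0, seed = 1) {
  if (n > 20) abort_allonet("desk-scale simulator: n <= 20.")
  with_seed(seed, {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- stats::rbinom(n * (n - 1) / 2, 1, edge_prob)
    A <- A + t(A)
    x <- matrix(stats::rnorm(n * 3), n, 3)
    v <- matrix(stats::rnorm(n * 3, 0, 0.5), n, 3)
    L <- diag(rowSums(A)) - A                  # graph Laplacian
    force <- function(x) -k_spring * (L %*% x) - k_tether * x
    energy <- function(x, v) {
      pe <- 0.5 * k_tether * sum(x^2)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        if (A[i, j] > 0) pe <- pe + 0.5 * k_spring * sum((x[i, ] - x[j, ])^2)
      }
      0.5 * sum(v^2) + pe
    }
    e0 <- energy(x, v)
    n_rec <- steps %/% sample_every
    co <- array(0, c(n_rec, n, 3)); ve <- array(0, c(n_rec, n, 3))
    f <- force(x)
    rec <- 0
    for (st in seq_len(steps)) {
      v <- v + 0.5 * dt * f
      x <- x + dt * v
      f <- force(x)
      v <- v + 0.5 * dt * f
      if (st %% sample_every == 0) {
        rec <- rec + 1
        co[rec, , ] <- sweep(x, 2, colMeans(x))
        ve[rec, , ] <- sweep(v, 2, colMeans(v)) * dt * sample_every
      }
    }
    e_final <- energy(x, v)
    if (!is.finite(e_final) || e_final > 10 * max(e0, 1e-12)) {
      abort_allonet("unstable timestep: total energy grew more than tenfold.")
    }
    if (noise_sd > 0) {
      co <- co + array(stats::rnorm(length(co), 0, noise_sd), dim(co))
      ve <- ve + array(stats::rnorm(length(ve), 0, noise_sd), dim(ve))
    }
    list(trajectory = trajectory(co, velocities = ve, dt = dt * sample_every,
                                 label = "springs"),
         adjacency = A, energy_initial = e0, energy_final = e_final)
  })
}

#' Generate a synthetic per-residue energy table with planted key residues
#'
#' Draws component energies so that exactly `n_key` rows have a total
#' below -1.00 kJ/mol (the key-residue threshold); the planted set is
#' returned as ground truth.
#'
#' @param n rows.
#' @param n_key planted key residues.
#' @param seed RNG seed.
#' @return List with `table` (an `energy_table`) and `key` (consensus ids
#'   of the planted residues).
#' @export
make_energy_table <- function(n = 20, n_key = 5, seed = 1) {
  if (n_key > n) abort_allonet("n_key cannot exceed n.")
  with_seed(seed, {
    consensus <- sort(sample.int(238, n))
    is_key <- seq_len(n) %in% sample.int(n, n_key)
    target <- ifelse(is_key, stats::runif(n, -6, -1.2), stats::runif(n, -0.9, 0.5))
    e_vdw <- round(stats::rnorm(n, -0.5, 0.4), 2)
    e_ele <- round(stats::rnorm(n, -1, 1), 2)
    e_gbsur <- round(stats::rnorm(n, -0.05, 0.03), 2)
    e_gb <- round(target - e_vdw - e_ele - e_gbsur, 2)
    out <- tibble::tibble(
      system = "synthetic",
      consensus = consensus,
      residue = paste0(sample(LETTERS[c(1, 3:9, 11:14, 16:20, 22, 23, 25)], n, TRUE),
                       consensus),
      e_vdw = e_vdw, e_vdw_sd = round(abs(stats::rnorm(n, 0, 0.2)), 2),
      e_ele = e_ele, e_ele_sd = round(abs(stats::rnorm(n, 0, 0.5)), 2),
      e_gb = e_gb, e_gb_sd = round(abs(stats::rnorm(n, 0, 0.2)), 2),
      e_gbsur = e_gbsur, e_gbsur_sd = round(abs(stats::rnorm(n, 0, 0.02)), 2),
      e_tot = round(e_vdw + e_ele + e_gb + e_gbsur, 2),
      e_tot_sd = round(abs(stats::rnorm(n, 0, 0.3)), 2)
    )
    class(out) <- c("energy_table", class(tibble::tibble()))
    list(table = out, key = consensus[is_key])
  })
}
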