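# shared fixtures and independent oracles, all built in code

# --- independent affine-gap global alignment score (Gotoh, plain loops) ---
# written deliberately simply; used only as an oracle
oracle_align_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + gap_extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + gap_extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- submat[A[i], B[j]] + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend, X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend, Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_seq <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# --- exhaustive simple-path enumeration for shortest-path oracle ---------
oracle_shortest <- function(edges, source, sink) {
  # edges: data.frame from,to,weight (undirected)
  adj <- list()
  for (r in seq_len(nrow(edges))) {
    a <- as.character(edges$from[r]); b <- as.character(edges$to[r])
    adj[[a]] <- rbind(adj[[a]], c(edges$to[r], edges$weight[r]))
    adj[[b]] <- rbind(adj[[b]], c(edges$from[r], edges$weight[r]))
  }
  best <- Inf
  recurse <- function(node, visited, w) {
    if (node == sink) { best <<- min(best, w); return() }
    nb <- adj[[as.character(node)]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (!(v %in% visited)) recurse(v, c(visited, v), w + nb[r, 2])
    }
  }
  recurse(source, source, 0)
  best
}

# --- random geometry ------------------------------------------------------
# helical chain (graded stiffness along the chain)
helix_coords <- function(n, rad = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  t <- 0:(n - 1)
  cbind(rad * cos(t * turn), rad * sin(t * turn), t * rise)
}

# randomly packed globular cluster (burial gradient, like a folded domain)
packed_cluster <- function(n = 80, radius = 12, min_dist = 3.8, seed = 1) {
  set.seed(seed)
  pts <- matrix(0, 0, 3)
  tries <- 0
  while (nrow(pts) < n && tries < 2e5) {
    tries <- tries + 1
    p <- stats::runif(3, -radius, radius)
    if (sqrt(sum(p^2)) > radius) next
    if (nrow(pts) == 0 || min(sqrt(colSums((t(pts) - p)^2))) > min_dist) {
      pts <- rbind(pts, p)
    }
  }
  pts
}

# tiny PDB text fixture
write_tiny_pdb <- function(path, rows) {
  # rows: data.frame resno, resname, x, y, z, optional elety/alt/occ/chain
  lines <- vapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    sprintf("ATOM  %5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
            i,
            sprintf(" %-3s", r$elety %||% "CA"),
            r$alt %||% " ",
            r$resname, r$chain %||% "A", r$resno, r$x, r$y, r$z,
            r$occ %||% 1.00)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# shared expensive fixtures (built once per test run)
two_domain_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- make_two_domain_structure(seed = 7)
      cache <<- list(open = s, closed = close_hinge(s, 60))
    }
    cache
  }
})

# ensemble-trained spring fixture shared across relational-inference tests
spring_ensemble_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sims <- lapply(1:6, function(s) simulate_springs(n = 5, seed = s))
      feats <- lapply(sims, function(sim) featurize_nri(sim$trajectory)$features)
      fit <- train_nri(feats, nri_config(k = 2, hidden = 32, epochs = 60,
                                         window = 20, rollout = 10, seed = 1))
      cache <<- list(sims = sims, feats = feats, fit = fit)
    }
    cache
  }
})

# synthetic stand-in sequence trio emulating the AABP family architecture:
# two close homologues (HisJ/LAOBP-like, 238 aa) and one distant relative
# (GlnBP-like, 226 aa, with a 5-residue deletion after position 187).
# These are synthetic sequences, not the database entries.
synthetic_aabp_sequences <- function(seed = 1) {
  set.seed(seed)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ancestor <- sample(alphabet, 238, replace = TRUE)
  mutate <- function(s, rate) {
    hit <- runif(length(s)) < rate
    s[hit] <- vapply(s[hit], function(ch) sample(setdiff(alphabet, ch), 1), "x")
    s
  }
  hisj <- mutate(ancestor, 0.15)
  laobp <- mutate(ancestor, 0.15)
  glnbp <- mutate(ancestor, 0.60)
  glnbp <- glnbp[-c(188:192, 232:238)]   # 226 residues
  c(GlnBP = paste(glnbp, collapse = ""),
    HisJ = paste(hisj, collapse = ""),
    LAOBP = paste(laobp, collapse = ""))
}

# random-search + refinement oracle for the optimal-superposition RMSD
oracle_kabsch_rmsd <- function(ref, mobile, n0 = 20000) {
  cm <- scale(mobile, scale = FALSE); cr <- scale(ref, scale = FALSE)
  rot_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  rmsd_of <- function(q) sqrt(mean(rowSums((cm %*% t(rot_q(q)) - cr)^2)))
  best_q <- rnorm(4); best <- rmsd_of(best_q)
  for (i in seq_len(n0)) {
    q <- rnorm(4)
    r <- rmsd_of(q)
    if (r < best) { best <- r; best_q <- q }
  }
  for (scale_ in c(0.2, 0.05, 0.01, 0.002)) {
    for (i in 1:2000) {
      q <- best_q / sqrt(sum(best_q^2)) + rnorm(4, 0, scale_)
      r <- rmsd_of(q)
      if (r < best) { best <- r; best_q <- q }
    }
  }
  best
}
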