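test_that("Kirchhoff entries follow the contact rule", {
  two <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(build_kirchhoff(two, cutoff = 7.3),
               matrix(c(1, -1, -1, 1), 2))
  apart <- rbind(c(0, 0, 0), c(8, 0, 0))
  expect_warning(K <- build_kirchhoff(apart, cutoff = 7.3), "disconnected")
  expect_equal(K, matrix(0, 2, 2))
})

test_that("Kirchhoff matches a brute-force pairwise-distance recomputation", {
  set.seed(21)
  co <- matrix(rnorm(60, sd = 6), 20, 3)
  K <- build_kirchhoff(co, cutoff = 7.3)
  for (i in 1:20) for (j in 1:20) {
    if (i == j) next
    d <- sqrt(sum((co[i, ] - co[j, ])^2))
    expect_equal(K[i, j], if (d <= 7.3) -1 else 0)
  }
  expect_equal(unname(rowSums(K)), rep(0, 20))
})

test_that("zero eigenvalues count connected components", {
  chain <- cbind(seq(0, 27, by = 3), 0, 0)
  g <- gnm_decompose(build_kirchhoff(chain, cutoff = 3.5))
  expect_equal(g$n_zero, 1)
  # two separated chains
  two_comp <- rbind(chain, cbind(seq(100, 115, by = 3), 0, 0))
  g2 <- gnm_decompose(build_kirchhoff(two_comp, cutoff = 3.5))
  expect_equal(g2$n_zero, 2)
  # independent check: component count from igraph
  A <- (as.matrix(dist(two_comp)) <= 3.5) * 1; diag(A) <- 0
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(A, "undirected"))
  expect_equal(g2$n_zero, comp$no)
})

test_that("mode-restricted pseudoinverse reproduces the Moore-Penrose inverse", {
  set.seed(2)
  co <- packed_cluster(40, radius = 10, seed = 2)
  g <- gnm(co)
  n_int <- length(g$values) - g$n_zero
  P <- allonet:::selected_pseudoinverse(g, (g$n_zero + 1):length(g$values))
  # independent pseudoinverse via SVD
  sv <- svd(g$kirchhoff)
  keep <- sv$d > 1e-8 * max(sv$d)
  P_oracle <- sv$v[, keep] %*% (t(sv$u[, keep]) / sv$d[keep])
  expect_lt(max(abs(P - P_oracle)), 1e-8)
  # full-mode MSF equals the pseudoinverse diagonal (times 3 kBT/gamma)
  msf <- mode_fluctuations(g, "all")
  expect_equal(msf$msf, 3 * diag(P_oracle), tolerance = 1e-8)
  expect_true(all(msf$msf >= 0))
})

test_that("fluctuations and correlations are rigid-motion invariant", {
  co <- packed_cluster(30, radius = 9, seed = 4)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  co2 <- sweep(co %*% t(R), 2, c(10, -4, 2), "+")
  g1 <- gnm(co); g2 <- gnm(co2)
  expect_equal(mode_fluctuations(g1, "slow", 2)$msf,
               mode_fluctuations(g2, "slow", 2)$msf, tolerance = 1e-8)
  expect_equal(abs(cross_correlation(g1, "slow", 2)),
               abs(cross_correlation(g2, "slow", 2)), tolerance = 1e-7)
})

test_that("normalized correlation maps have unit diagonal and symmetry", {
  g <- gnm(packed_cluster(30, radius = 9, seed = 5))
  C <- cross_correlation(g, "slow", 2)
  expect_equal(unname(diag(C)), rep(1, 30), tolerance = 1e-10)
  expect_equal(C, t(C), tolerance = 1e-10)
  expect_error(cross_correlation(g, "slow", 0), "modes")
})

test_that("two-domain structures show the open-state correlation pattern", {
  fx <- two_domain_fixture()
  s <- fx$open
  iA <- which(s$region == "lobeA"); iB <- which(s$region == "lobeB")
  C <- cross_correlation(gnm(s), "slow", 2)
  expect_lt(mean(C[iA, iB]), 0)           # inter-lobe anticorrelation
  expect_gt(mean(C[iA, iA][upper.tri(C[iA, iA])]), 0)  # intra-lobe coupling
})

test_that("extrema detection finds minima and handles flat profiles", {
  hit <- detect_extrema(c(1, 0, 1), quantile = 0.5)
  expect_equal(hit$residue, 2)
  expect_warning(flat <- detect_extrema(rep(1, 10)), "flat")
  expect_equal(nrow(flat), 0)
  expect_error(detect_extrema(c(1, 2)), "3 residues")
})

test_that("hinge detection lands in the constructed linker", {
  fx <- two_domain_fixture()
  s <- fx$open
  slow <- mode_fluctuations(gnm(s), "slow", 2)
  hinges <- detect_extrema(slow, "hinge")
  linker <- range(which(s$region == "linker"))
  expect_gte(hinges$residue[1], linker[1] - 2)
  expect_lte(hinges$residue[1], linker[2] + 2)
})

test_that("profile correlation maps through consensus positions", {
  p <- tibble::tibble(residue = 1:10, msf = c(5, 3, 1, 2, 4, 6, 8, 9, 7, 5))
  expect_equal(profile_correlation(p, p), 1)
  pn <- p; pn$msf <- -p$msf
  expect_equal(profile_correlation(p, pn), -1)
  # offset numbering reconciled by maps
  p2 <- p; p2$residue <- p$residue + 2
  map2 <- tibble::tibble(residue = p2$residue, consensus = 1:10)
  expect_equal(profile_correlation(p, p2, map_b = map2), 1)
  expect_error(profile_correlation(p, p2, map_b = map2[1:2, ]), "shared")
})
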