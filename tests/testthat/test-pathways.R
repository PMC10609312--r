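ring_graph <- function(weights) {
  n <- length(weights)
  coupling <- matrix(0, n, n); contacts <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    coupling[i, j] <- coupling[j, i] <- weights[i]
    contacts[i, j] <- contacts[j, i] <- 1
  }
  build_graph(coupling, contacts)
}

test_that("edge weights follow the monotone -log coupling rule", {
  coupling <- matrix(c(0, 1, 1, 0), 2)
  contacts <- matrix(c(0, 1, 1, 0), 2)
  g <- build_graph(coupling, contacts, eps = 1e-4)
  expect_equal(g$weight, -log(1 - 1e-9), tolerance = 1e-12)
  g2 <- build_graph(matrix(c(0, 1e-4, 1e-4, 0), 2), contacts, eps = 1e-4)
  expect_equal(g2$weight, -log(1e-4))
  # floor applies below eps too
  g3 <- build_graph(matrix(c(0, 1e-9, 1e-9, 0), 2), contacts, eps = 1e-4)
  expect_equal(g3$weight, -log(1e-4))
  expect_error(build_graph(matrix(0, 2, 2), contacts), "all-zero")
})

test_that("weights decrease monotonically as coupling increases", {
  set.seed(5)
  n <- 12
  coupling <- matrix(runif(n * n), n); coupling <- (coupling + t(coupling)) / 2
  contacts <- matrix(1, n, n) - diag(n)
  g <- build_graph(coupling, contacts)
  ord <- order(g$coupling)
  expect_true(all(diff(g$weight[ord]) <= 1e-12))
})

test_that("a path graph yields the expected path", {
  coupling <- matrix(0, 4, 4); contacts <- matrix(0, 4, 4)
  for (i in 1:3) {
    coupling[i, i + 1] <- coupling[i + 1, i] <- 0.5
    contacts[i, i + 1] <- contacts[i + 1, i] <- 1
  }
  g <- build_graph(coupling, contacts)
  ps <- allosteric_paths(g, sources = 1, sinks = 4)
  expect_equal(ps$path[[1]], c(1, 2, 3, 4))
  expect_equal(ps$weight, 3 * -log(0.5))
  expect_equal(ps$length, 3)
})

test_that("Dijkstra equals exhaustive enumeration on random small graphs", {
  set.seed(77)
  checked <- 0
  for (trial in 1:100) {
    n <- sample(4:8, 1)
    m <- sample(n:14, 1)
    edges <- unique(t(apply(matrix(sample(n, 2 * m, replace = TRUE), ncol = 2),
                            1, sort)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    if (nrow(edges) == 0) next
    coupling <- matrix(0, n, n); contacts <- matrix(0, n, n)
    w <- runif(nrow(edges), 0.05, 0.95)
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      coupling[i, j] <- coupling[j, i] <- w[r]
      contacts[i, j] <- contacts[j, i] <- 1
    }
    g <- build_graph(coupling, contacts)
    src <- sample(n, 1); snk <- sample(setdiff(seq_len(n), src), 1)
    brute <- oracle_shortest(g, src, snk)
    if (!is.finite(brute)) next
    ps <- suppressWarnings(allosteric_paths(g, src, snk))
    expect_equal(ps$weight, brute, tolerance = 1e-9)
    # cross-check against igraph
    ig <- igraph::graph_from_data_frame(g[, c("from", "to")], directed = FALSE,
                                        vertices = data.frame(name = 1:n))
    d_ig <- igraph::distances(ig, v = as.character(src), to = as.character(snk),
                              weights = g$weight)
    expect_equal(ps$weight, as.numeric(d_ig), tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gt(checked, 50)
})

test_that("ties break on hops then lexicographic order, deterministically", {
  # diamond: 1-2-4 and 1-3-4 with equal weights, plus a longer equal path
  coupling <- matrix(0, 5, 5); contacts <- matrix(0, 5, 5)
  link <- function(i, j, c_) {
    coupling[i, j] <<- coupling[j, i] <<- c_
    contacts[i, j] <<- contacts[j, i] <<- 1
  }
  w <- 0.5
  link(1, 2, w); link(2, 4, w); link(1, 3, w); link(3, 4, w)
  link(1, 5, w^1.5); link(5, 4, w^1.5)   # same total weight, still 2 hops
  g <- build_graph(coupling, contacts)
  ps <- allosteric_paths(g, 1, 4)
  expect_equal(ps$path[[1]], c(1, 2, 4))  # lexicographically smallest
})

test_that("unreachable sinks are skipped with a warning", {
  coupling <- matrix(0, 4, 4); contacts <- matrix(0, 4, 4)
  coupling[1, 2] <- coupling[2, 1] <- 0.5; contacts[1, 2] <- contacts[2, 1] <- 1
  coupling[3, 4] <- coupling[4, 3] <- 0.5; contacts[3, 4] <- contacts[4, 3] <- 1
  g <- build_graph(coupling, contacts)
  expect_warning(ps <- allosteric_paths(g, 1, c(2, 4)), "unreachable")
  expect_equal(nrow(ps), 1)
})

test_that("residue frequencies match a brute-force recount", {
  set.seed(8)
  paths <- tibble::tibble(
    source = 1, sink = 9, weight = runif(5), length = 3,
    path = list(c(1, 2, 9), c(1, 3, 9), c(1, 2, 4, 9), c(1, 5, 9), c(1, 2, 9))
  )
  class(paths) <- c("path_set", class(tibble::tibble()))
  freq <- residue_frequency(paths)
  counts <- table(unlist(lapply(paths$path, unique)))
  for (r in freq$residue) {
    expect_equal(freq$count[freq$residue == r], unname(counts[as.character(r)]))
  }
  expect_equal(freq$count[freq$residue == 2], 3)
})

test_that("the top pathway maximizes mean member frequency, order-invariant", {
  # two disjoint paths plus one that overlaps both: the overlap has the
  # higher mean member frequency
  paths <- tibble::tibble(
    source = c(1, 4, 2), sink = c(3, 6, 5), weight = c(1, 1, 2),
    length = c(2, 2, 1),
    path = list(c(1, 2, 3), c(4, 5, 6), c(2, 5))
  )
  class(paths) <- c("path_set", class(tibble::tibble()))
  top <- top_pathway(paths)
  expect_equal(top$path[[1]], c(2, 5))
  perm <- paths[c(3, 1, 2), ]
  class(perm) <- c("path_set", class(tibble::tibble()))
  expect_equal(top_pathway(perm)$path[[1]], top$path[[1]])
  # single path: itself
  one <- paths[1, ]; class(one) <- c("path_set", class(tibble::tibble()))
  expect_equal(top_pathway(one)$path[[1]], c(1, 2, 3))
})

test_that("path weights never increase when an edge gets cheaper", {
  set.seed(12)
  g <- ring_graph(runif(8, 0.2, 0.8))
  base <- allosteric_paths(g, 1, 5)$weight
  g2 <- g
  g2$weight[3] <- g2$weight[3] * 0.5
  expect_lte(allosteric_paths(g2, 1, 5)$weight, base + 1e-12)
})

test_that("a planted strong chain is recovered as the top pathway", {
  fx <- two_domain_fixture()
  s <- fx$open
  co <- ca_coords(s)
  contacts <- contact_adjacency(co, 7.3)
  n <- nrow(co)
  coupling <- matrix(0.1, n, n)
  # plant a high-coupling chain along the backbone from the recognition
  # residue into the I-Loop
  chain <- 117:112
  for (i in seq_len(length(chain) - 1)) {
    coupling[chain[i], chain[i + 1]] <- 0.95
    coupling[chain[i + 1], chain[i]] <- 0.95
  }
  g <- build_graph(coupling * contacts, contacts)
  # the minimum-weight route to the chain's endpoint is the chain itself
  ps_end <- allosteric_paths(g, sources = 117, sinks = 112)
  expect_equal(top_pathway(ps_end)$path[[1]], chain)
  # and across the whole I-Loop sink set the chain members are the
  # highest-frequency relays
  ps_all <- suppressWarnings(
    allosteric_paths(g, sources = 117, sinks = iloop_positions()))
  freq <- residue_frequency(ps_all)
  top_relays <- freq$residue[seq_along(chain)]
  expect_true(all(117:115 %in% top_relays))
})
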