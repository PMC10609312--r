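test_that("block coarse-graining averages contiguous runs", {
  set.seed(1)
  feats <- array(rnorm(20 * 238 * 6), c(20, 238, 6))
  cg <- coarse_grain_blocks(feats, 10)
  expect_equal(nrow(cg$blocks), 24)
  expect_equal(cg$blocks$size[24], 8)
  # brute-force per-dimension averaging
  for (m in c(1, 12, 24)) {
    expect_equal(cg$features[, m, ],
                 apply(feats[, cg$blocks$start[m]:cg$blocks$end[m], , drop = FALSE],
                       c(1, 3), mean),
                 tolerance = 1e-12)
  }
  # block size 1 is the identity
  cg1 <- coarse_grain_blocks(feats[, 1:5, , drop = FALSE], 1)
  expect_equal(cg1$features, feats[, 1:5, ], tolerance = 1e-12)
  expect_error(coarse_grain_blocks(feats[, 1:5, , drop = FALSE], 6), "exceeds")
})

test_that("the ELBO has its closed-form components", {
  cfg <- nri_config(k = 4, sigma2 = 1)
  # equal logits: KL is zero
  e0 <- elbo(matrix(0, 2, 3), matrix(1, 5, 4), cfg)
  expect_equal(e0$kl, 0, tolerance = 1e-12)
  # a certain pair contributes ln K
  e1 <- elbo(matrix(0, 2, 3), rbind(c(1e3, 0, 0, 0)), cfg)
  expect_equal(e1$kl, log(4), tolerance = 1e-9)
  # loop oracle on random tensors
  set.seed(2)
  sq <- matrix(rexp(12), 3)
  lg <- matrix(rnorm(8), 2, 4)
  got <- elbo(sq, lg, cfg)
  recon_o <- 0
  for (v in as.numeric(sq)) recon_o <- recon_o - 0.5 * v - 0.5 * log(2 * pi)
  kl_o <- 0
  for (r in 1:2) {
    p <- exp(lg[r, ]) / sum(exp(lg[r, ]))
    for (k in 1:4) kl_o <- kl_o + p[k] * (log(p[k]) + log(4))
  }
  expect_equal(got$recon, recon_o, tolerance = 1e-8)
  expect_equal(got$kl, kl_o, tolerance = 1e-8)
  expect_equal(got$elbo, recon_o - kl_o, tolerance = 1e-8)
})

test_that("forward passes are deterministic under a fixed seed", {
  set.seed(3)
  feats <- array(rnorm(20 * 4 * 6, sd = 0.5), c(20, 4, 6))
  cfg <- nri_config(k = 3, hidden = 8, window = 10, rollout = 5, seed = 5)
  model <- nri_init(4, cfg)
  xw <- allonet:::make_windows(feats, 10)
  set.seed(99); f1 <- nri_forward(model, xw, "sample")
  set.seed(99); f2 <- nri_forward(model, xw, "sample")
  expect_identical(f1$z, f2$z)
  expect_identical(f1$elbo$elbo, f2$elbo$elbo)
  a1 <- nri_forward(model, xw, "argmax")
  a2 <- nri_forward(model, xw, "argmax")
  expect_identical(a1$z, a2$z)
})

test_that("a zero-initialized decoder predicts persistence", {
  set.seed(4)
  feats <- array(rnorm(10 * 3 * 6), c(10, 3, 6))
  cfg <- nri_config(k = 2, hidden = 8, window = 5, rollout = 4, seed = 2)
  model <- nri_init(3, cfg)
  xw <- allonet:::make_windows(feats, 5)
  fwd <- nri_forward(model, xw, "argmax")
  fl <- allonet:::nri_flatten(xw)
  expect_equal(fwd$pred[[2]], fl$frames[[1]], tolerance = 1e-12)
  expect_equal(fwd$pred[[5]], fl$frames[[1]], tolerance = 1e-12)
})

test_that("training is exactly reproducible and 0 epochs gives the prior fit", {
  sim <- simulate_springs(n = 4, steps = 8000, seed = 9)
  f <- featurize_nri(sim$trajectory)
  cfg <- nri_config(k = 2, hidden = 8, epochs = 3, window = 10, rollout = 5, seed = 4)
  fit1 <- train_nri(f$features, cfg)
  fit2 <- train_nri(f$features, cfg)
  expect_identical(fit1$edge_posterior, fit2$edge_posterior)
  expect_identical(fit1$report, fit2$report)
  fit0 <- train_nri(f$features, nri_config(k = 2, hidden = 8, epochs = 0,
                                           window = 10, seed = 4))
  expect_equal(nrow(fit0$report), 0)
  expect_true(all(abs(apply(fit0$edge_posterior, c(1, 2), sum)[!diag(4)] - 1) < 1e-6))
})

test_that("analytic gradients match central finite differences", {
  cfg <- nri_config(k = 3, hidden = 5, window = 6, rollout = 3, epochs = 0,
                    seed = 3, temperature = 0.7, sigma2 = 1e-3)
  set.seed(11)
  feats <- array(rnorm(12 * 3 * 6, sd = 0.3), c(12, 3, 6))
  xw <- allonet:::make_windows(feats, 6)
  model <- nri_init(3, cfg)
  set.seed(12)
  model$par$Wout <- matrix(rnorm(length(model$par$Wout), 0, 0.05),
                           nrow(model$par$Wout))
  obj <- function(m) { set.seed(99); nri_forward(m, xw, "sample")$elbo$elbo / 2 }
  set.seed(99); fwd <- nri_forward(model, xw, "sample")
  gr <- allonet:::nri_backward(model, fwd)
  set.seed(13)
  for (nm in names(gr)) {
    p <- model$par[[nm]]
    idx <- if (length(p) > 4) sample(length(p), 4) else seq_along(p)
    for (i in idx) {
      m2 <- model; m2$par[[nm]][i] <- m2$par[[nm]][i] + 1e-6
      m3 <- model; m3$par[[nm]][i] <- m3$par[[nm]][i] - 1e-6
      fd <- (obj(m2) - obj(m3)) / 2e-6
      expect_equal(gr[[nm]][i], fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("edge posteriors normalize and domain aggregation is exact", {
  fx <- spring_ensemble_fixture()
  ep <- fx$fit$edge_posterior[[1]]
  sums <- apply(ep, c(1, 2), sum)
  expect_true(all(abs(sums[!diag(5)] - 1) < 1e-6))
  expect_true(all(is.na(diag(sums))))
  # aggregation equals a brute-force double loop
  labels <- c(1, 1, 2, 2, 3)
  agg <- aggregate_domains(ep, labels)
  pe <- edge_probability(ep)
  for (a in 1:3) for (b in 1:3) {
    vals <- c()
    for (i in which(labels == a)) for (j in which(labels == b)) {
      if (i != j) vals <- c(vals, pe[i, j])
    }
    if (length(vals) == 0) {
      expect_true(is.na(agg$matrix[a, b]))
    } else {
      expect_equal(agg$matrix[a, b], mean(vals), tolerance = 1e-12)
    }
  }
})

test_that("uniform posteriors aggregate flat and planted edges dominate", {
  K <- 4
  ep <- array(1 / K, c(6, 6, K))
  for (i in 1:6) ep[i, i, ] <- NA
  agg <- aggregate_domains(ep, rep(1:3, each = 2), threshold = 1 - 1 / K + 1e-6)
  expect_equal(nrow(agg$edges), 0)
  expect_lt(diff(range(agg$matrix)), 1e-12)
  # plant strong edges between groups 2 and 3 only
  ep2 <- array(0, c(6, 6, K)); ep2[, , 1] <- 0.9; ep2[, , 2] <- 0.1
  for (i in 3:4) for (j in 5:6) { ep2[i, j, 1] <- 0.05; ep2[i, j, 2] <- 0.95 }
  for (i in 1:6) ep2[i, i, ] <- NA
  agg2 <- aggregate_domains(ep2, rep(1:3, each = 2))
  off <- !diag(3)
  expect_equal(which.max(agg2$matrix[off]),
               which(row(agg2$matrix)[off] == 2 & col(agg2$matrix)[off] == 3))
})

test_that("spring connectivity is recovered from trained edge posteriors", {
  fx <- spring_ensemble_fixture()
  off <- !diag(5)
  accs <- vapply(1:3, function(s) {
    edge_recovery_accuracy(fx$fit$edge_posterior[[s]], fx$sims[[s]]$adjacency)
  }, numeric(1))
  expect_gte(mean(accs), 0.85)
  # and beats the correlation-threshold baseline on the same data
  bases <- vapply(1:3, function(s) {
    correlation_baseline_accuracy(fx$feats[[s]], fx$sims[[s]]$adjacency)
  }, numeric(1))
  expect_gt(mean(accs), mean(bases))
})

test_that("a trained model scores unseen systems of the same family", {
  fx <- spring_ensemble_fixture()
  sim_new <- simulate_springs(n = 5, seed = 41)
  ep <- infer_edges(fx$fit, featurize_nri(sim_new$trajectory)$features)
  acc <- edge_recovery_accuracy(ep, sim_new$adjacency)
  expect_gt(acc, 0.5)   # clearly above chance on a held-out graph
})

test_that("edge recovery degrades with observation noise", {
  accs <- vapply(c(0, 0.3, 1.5), function(nsd) {
    sims <- lapply(1:6, function(s) {
      simulate_springs(n = 5, noise_sd = nsd, seed = 10 + s)
    })
    feats <- lapply(sims, function(sim) featurize_nri(sim$trajectory)$features)
    fit <- train_nri(feats, nri_config(k = 2, hidden = 32, epochs = 60,
                                       window = 20, rollout = 10, seed = 2))
    mean(vapply(1:5, function(s) {
      edge_recovery_accuracy(fit$edge_posterior[[s]], sims[[s]]$adjacency)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(accs[1] + 0.05, accs[2])
  expect_gte(accs[2] + 0.05, accs[3])
  expect_gt(accs[1], accs[3])
})
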