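# Desk-scale neural relational inference: a variational autoencoder over
# discrete edge types, written directly in base R with hand-derived
# reverse-mode gradients (including backprop through the decoder rollout).
#
# Architecture (deliberately small):
#   encoder  node window (W*6) --tanh--> h_i (H)
#            pair [h_i, h_j]   --tanh--> e_ij (H) --linear--> K logits
#   sampling concrete/Gumbel-softmax relaxation at temperature tau
#   decoder  recursive multi-step rollout: from a ground-truth frame the
#            state is advanced `rollout` steps by its own predictions
#            (teacher forcing at each segment start). Per step and pair:
#            m^k_ij = tanh(Wd_k [f_i, f_j] + bd_k); m_ij = sum_k z_ijk
#            m^k_ij (edge type 1 sends nothing under the no-edge
#            convention); a_j = sum_i m_ij; delta f_j = Wout [a_j, f_j] +
#            bout (zero-initialized, so an untrained decoder predicts
#            persistence). Multi-step prediction is what makes the learned
#            graph identifiable: errors from wrong edges compound over the
#            rollout.
# Objective: ELBO = Gaussian log-likelihood (fixed small variance) of the
# rolled-out features minus KL(q(z|x) || uniform over K), maximized with
# Adam.

#' Configuration for neural relational inference
#'
#' @param k number of discrete edge types (>= 2).
#' @param hidden hidden width of encoder/decoder layers.
#' @param temperature Gumbel-softmax temperature.
#' @param lr Adam learning rate.
#' @param epochs training epochs.
#' @param window window length in frames.
#' @param rollout decoder prediction horizon: within a window the state is
#'   re-anchored to the data every `rollout` steps and advanced by the
#'   model's own predictions in between.
#' @param batch minibatch size in windows.
#' @param block_size residues per coarse-grained block (see
#'   [coarse_grain_blocks()]).
#' @param seed seed fixing every stochastic draw (init, Gumbel noise,
#'   shuffling).
#' @param restarts independent training restarts (seeds derived from
#'   `seed`); the fit with the best ELBO over the final epochs is kept.
#'   Gradient ascent on this objective occasionally lands in a poor local
#'   basin whose ELBO is far below a converged run, so objective-based
#'   restart selection is a cheap, label-free safeguard.
#' @param no_edge treat edge type 1 as "no edge" (sends no message).
#' @param decoder `"linear"` or `"tanh"` message activation. Linear
#'   messages are the right inductive bias for near-harmonic
#'   coarse-grained dynamics and make the graph identifiable from a
#'   single system: a nonlinear message MLP can infer the (fixed)
#'   adjacency from instantaneous pair features, so every pair is
#'   switched on and the posterior carries no information.
#' @param weight_decay decoupled L2 decay applied to weight matrices in
#'   the Adam update. Parsimony pressure on the decoder is what makes the
#'   learned graph identifiable from a single system: without it the
#'   message MLPs can infer the (fixed) adjacency from instantaneous pair
#'   features and every pair is switched on.
#' @param sigma2 fixed variance of the Gaussian reconstruction likelihood
#'   on standardized features. The small default (5e-5, standard practice
#'   for this model family) weights reconstruction strongly against the
#'   KL term; at unit variance the per-pair reconstruction preference is
#'   weaker than the KL pull and the edge posterior collapses to uniform.
#' @return A list of class `nri_config`.
#' @export
nri_config <- function(k = 4, hidden = 64, temperature = 0.5, lr = 5e-3,
                       epochs = 200, window = 20, rollout = 10, batch = 16,
                       block_size = 10, seed = 1, restarts = 1,
                       no_edge = TRUE, decoder = c("linear", "tanh"),
                       weight_decay = 1e-4, sigma2 = 5e-5) {
  decoder <- match.arg(decoder)
  if (restarts < 1) abort_allonet("need at least 1 restart.")
  if (k < 2) abort_allonet("need at least 2 edge types.")
  if (block_size < 1) abort_allonet("block size must be >= 1.")
  if (sigma2 <= 0) abort_allonet("sigma2 must be positive.")
  structure(list(k = k, hidden = hidden, temperature = temperature, lr = lr,
                 epochs = epochs, window = window, rollout = rollout,
                 batch = batch, block_size = block_size, seed = seed,
                 restarts = restarts, no_edge = no_edge, decoder = decoder,
                 weight_decay = weight_decay, sigma2 = sigma2),
            class = "nri_config")
}

msg_types <- function(config) {
  if (config$no_edge) 2:config$k else 1:config$k
}

glorot <- function(nout, nin) {
  matrix(stats::runif(nout * nin, -1, 1) * sqrt(6 / (nin + nout)), nout, nin)
}

#' Initialize an NRI model
#'
#' The decoder output layer starts at zero so the untrained model predicts
#' persistence (zero feature change).
#'
#' @param n_nodes number of (block) nodes.
#' @param config an [nri_config()].
#' @param n_features per-node feature dimension (default 6).
#' @return A list of parameter matrices of class `nri_model`.
#' @export
nri_init <- function(n_nodes, config, n_features = 6) {
  H <- config$hidden; K <- config$k
  din <- config$window * n_features
  with_seed(config$seed, {
    par <- list(
      W1 = glorot(H, din), b1 = numeric(H),
      W2 = glorot(H, 2 * H), b2 = numeric(H),
      W3 = glorot(K, H), b3 = numeric(K),
      Wout = matrix(0, n_features, H + n_features), bout = numeric(n_features)
    )
    for (k in msg_types(config)) {
      par[[paste0("Wd", k)]] <- glorot(H, 2 * n_features)
      par[[paste0("bd", k)]] <- numeric(H)
    }
    par
  }) -> par
  structure(list(par = par, n_nodes = n_nodes, n_features = n_features,
                 config = config), class = "nri_model")
}

# index bookkeeping shared by forward/backward
nri_indices <- function(n_nodes, B) {
  N <- n_nodes
  pr <- expand.grid(j = seq_len(N), i = seq_len(N))[, c("i", "j")]
  pr <- pr[pr$i != pr$j, ]
  pr <- pr[order(pr$i, pr$j), ]
  P <- nrow(pr)
  list(
    N = N, P = P, B = B,
    pi = pr$i, pj = pr$j,
    # pair rows (b-1)*P+p -> node rows (b-1)*N+i
    row_i = rep((seq_len(B) - 1) * N, each = P) + rep(pr$i, B),
    row_j = rep((seq_len(B) - 1) * N, each = P) + rep(pr$j, B)
  )
}

# windows: array B x W x N x F -> encoder input and per-frame state list
nri_flatten <- function(xw) {
  B <- dim(xw)[1]; W <- dim(xw)[2]; N <- dim(xw)[3]; F_ <- dim(xw)[4]
  # encoder input: (B*N) x (W*F), per node all frames of feature 1, then 2, ...
  Xenc <- matrix(0, B * N, W * F_)
  frames <- vector("list", W)            # (B*N) x F state per frame
  for (b in seq_len(B)) {
    m <- matrix(aperm(xw[b, , , , drop = FALSE][1, , , ], c(2, 1, 3)), N, W * F_)
    Xenc[(b - 1) * N + seq_len(N), ] <- m
  }
  for (t in seq_len(W)) {
    Ft <- matrix(0, B * N, F_)
    for (b in seq_len(B)) Ft[(b - 1) * N + seq_len(N), ] <- xw[b, t, , ]
    frames[[t]] <- Ft
  }
  list(Xenc = Xenc, frames = frames, B = B, W = W, N = N, F = F_)
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  E <- exp(L - m)
  E / rowSums(E)
}

# rollout segmentation: start frames and step counts covering 1..W-1
rollout_segments <- function(W, rollout) {
  starts <- seq(1, W - 1, by = rollout)
  lens <- pmin(rollout, W - starts)
  list(starts = starts, lens = lens)
}

#' One forward pass of the NRI network
#'
#' Runs encoder, edge sampling and the multi-step decoder rollout on a
#' batch of feature windows and returns rolled-out predictions, edge
#' logits and the sampled edge assignment. With `mode = "sample"` the
#' Gumbel-softmax relaxation is drawn from the current RNG state (seed it
#' for reproducibility); `"argmax"` uses hard one-hot types; `"mean"` uses
#' the posterior probabilities themselves.
#'
#' @param model an `nri_model`.
#' @param xw window array `B x W x N x F` (or one `W x N x F` window).
#' @param mode `"sample"`, `"argmax"` or `"mean"`.
#' @param z_override optional fixed edge assignment (`P x K` or
#'   `B*P x K` matrix) used instead of the encoder's; lets the decoder be
#'   probed with a known graph (no gradient flows to the encoder).
#' @return List with `pred` (list of `B*N x F` predictions for frames
#'   2..W), `err` (same shape), `logits` (`B*P x K`), `z`, `elbo` (list),
#'   and a `cache` for the backward pass.
#' @export
nri_forward <- function(model, xw, mode = c("sample", "argmax", "mean"),
                        z_override = NULL) {
  mode <- match.arg(mode)
  if (length(dim(xw)) == 3) {
    xw <- array(xw, c(1, dim(xw)))
  }
  if (!all(is.finite(xw))) abort_allonet("non-finite features.")
  par <- model$par; cfg <- model$config
  fl <- nri_flatten(xw)
  ix <- nri_indices(fl$N, fl$B)
  H1 <- tanh(fl$Xenc %*% t(par$W1) + rep(par$b1, each = nrow(fl$Xenc)))
  C <- cbind(H1[ix$row_i, , drop = FALSE], H1[ix$row_j, , drop = FALSE])
  E <- tanh(C %*% t(par$W2) + rep(par$b2, each = nrow(C)))
  L <- E %*% t(par$W3) + rep(par$b3, each = nrow(E))
  if (mode == "sample") {
    G <- -log(-log(matrix(stats::runif(length(L)), nrow(L), ncol(L))))
    Z <- softmax_rows((L + G) / cfg$temperature)
  } else if (mode == "argmax") {
    Z <- matrix(0, nrow(L), ncol(L))
    Z[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))] <- 1
  } else {
    Z <- softmax_rows(L)
  }
  if (!is.null(z_override)) {
    Z <- if (nrow(z_override) == nrow(L)) z_override else
      z_override[rep(seq_len(nrow(z_override)), fl$B), , drop = FALSE]
    mode <- "argmax"                     # no gradient into the encoder
  }
  seg <- rollout_segments(fl$W, cfg$rollout %||% (fl$W - 1))
  steps <- list()        # per decoder step: cache
  pred <- vector("list", fl$W)   # predictions for frames 2..W
  err <- vector("list", fl$W)
  sq_sum <- 0
  for (si in seq_along(seg$starts)) {
    S <- fl$frames[[seg$starts[si]]]
    for (dstep in seq_len(seg$lens[si])) {
      t_out <- seg$starts[si] + dstep
      U <- cbind(S[ix$row_i, , drop = FALSE], S[ix$row_j, , drop = FALSE])
      Msum <- matrix(0, nrow(U), cfg$hidden)
      Mk <- list()
      act <- if ((cfg$decoder %||% "tanh") == "tanh") tanh else identity
      for (k in msg_types(cfg)) {
        Mk[[as.character(k)]] <- act(U %*% t(par[[paste0("Wd", k)]]) +
                                       rep(par[[paste0("bd", k)]], each = nrow(U)))
        Msum <- Msum + Z[, k] * Mk[[as.character(k)]]
      }
      A <- rowsum(Msum, group = ix$row_j)      # (B*N) x H
      dimnames(A) <- NULL
      V <- cbind(A, S)
      Delta <- V %*% t(par$Wout) + rep(par$bout, each = nrow(V))
      S_next <- S + Delta
      e <- S_next - fl$frames[[t_out]]
      pred[[t_out]] <- S_next
      err[[t_out]] <- e
      sq_sum <- sq_sum + sum(e^2)
      steps[[length(steps) + 1]] <- list(U = U, Mk = Mk, A = A, V = V,
                                         S = S, t_out = t_out,
                                         seg_start = dstep == 1)
      S <- S_next
    }
  }
  n_el <- sum(vapply(err, function(e) if (is.null(e)) 0L else length(e), integer(1)))
  el <- elbo_terms(sq_sum, n_el, L, cfg)
  list(pred = pred, err = err, logits = L, z = Z, elbo = el,
       cache = list(fl = fl, ix = ix, H1 = H1, C = C, E = E, L = L, Z = Z,
                    steps = steps, mode = mode))
}

elbo_terms <- function(sq_sum, n_el, logits, config) {
  s2 <- config$sigma2 %||% 1
  recon <- -0.5 * sq_sum / s2 - 0.5 * n_el * log(2 * pi * s2)
  p <- softmax_rows(logits)
  kl <- sum(p * (log(pmax(p, 1e-300)) + log(ncol(logits))))
  list(elbo = recon - kl, recon = recon, kl = kl)
}

#' Evidence lower bound from reconstruction errors and edge logits
#'
#' Reconstruction term: Gaussian log-likelihood with fixed variance
#' `config$sigma2`, `-sum(sq_err) / (2 sigma2) - 0.5 n log(2 pi sigma2)`.
#' KL term: sum over pairs of `KL(softmax(logits) || uniform over K)`.
#' The ELBO is their difference.
#'
#' @param sq_err numeric array/matrix of per-element squared errors.
#' @param logits matrix of per-pair edge-type logits (pairs x K).
#' @param config an [nri_config()] (K and sigma2 are used).
#' @return List with `elbo`, `recon`, `kl`.
#' @export
elbo <- function(sq_err, logits, config) {
  elbo_terms(sum(sq_err), length(sq_err), logits, config)
}

# gradients of mean-per-window ELBO wrt all parameters (ascent direction),
# with backprop through the decoder rollout
nri_backward <- function(model, fwd) {
  par <- model$par; cfg <- model$config
  ca <- fwd$cache; fl <- ca$fl; ix <- ca$ix
  B <- fl$B; H <- cfg$hidden
  scale <- (cfg$sigma2 %||% 1) * B
  gr <- list(Wout = matrix(0, nrow(par$Wout), ncol(par$Wout)),
             bout = numeric(length(par$bout)))
  for (k in msg_types(cfg)) {
    gr[[paste0("Wd", k)]] <- matrix(0, nrow(par[[paste0("Wd", k)]]),
                                    ncol(par[[paste0("Wd", k)]]))
    gr[[paste0("bd", k)]] <- numeric(length(par[[paste0("bd", k)]]))
  }
  dZ <- matrix(0, nrow(ca$Z), ncol(ca$Z))
  dS <- matrix(0, nrow(fl$frames[[1]]), fl$F)
  for (s in rev(seq_along(ca$steps))) {
    st <- ca$steps[[s]]
    dPred <- -fwd$err[[st$t_out]] / scale + dS
    gr$Wout <- gr$Wout + crossprod(dPred, st$V)
    gr$bout <- gr$bout + colSums(dPred)
    dV <- dPred %*% par$Wout
    dA <- dV[, seq_len(H), drop = FALSE]
    dSnew <- dV[, H + seq_len(fl$F), drop = FALSE] + dPred  # identity path
    dM <- dA[ix$row_j, , drop = FALSE]
    dU <- matrix(0, nrow(dM), 2 * fl$F)
    linear_msg <- (cfg$decoder %||% "tanh") == "linear"
    for (k in msg_types(cfg)) {
      Mk <- st$Mk[[as.character(k)]]
      dZ[, k] <- dZ[, k] + rowSums(dM * Mk)
      dSk <- if (linear_msg) dM * ca$Z[, k] else (dM * ca$Z[, k]) * (1 - Mk^2)
      gr[[paste0("Wd", k)]] <- gr[[paste0("Wd", k)]] + crossprod(dSk, st$U)
      gr[[paste0("bd", k)]] <- gr[[paste0("bd", k)]] + colSums(dSk)
      dU <- dU + dSk %*% par[[paste0("Wd", k)]]
    }
    dSnew <- dSnew +
      rowsum(dU[, seq_len(fl$F), drop = FALSE], group = ix$row_i) +
      rowsum(dU[, fl$F + seq_len(fl$F), drop = FALSE], group = ix$row_j)
    dS <- if (st$seg_start) matrix(0, nrow(dS), ncol(dS)) else dSnew
  }
  # through the concrete relaxation (sample mode) or plain softmax (mean)
  if (ca$mode == "argmax") {
    dL <- matrix(0, nrow(ca$L), ncol(ca$L))
  } else {
    dY <- ca$Z * (dZ - rowSums(dZ * ca$Z))
    dL <- if (ca$mode == "sample") dY / cfg$temperature else dY
  }
  # KL gradient (direct function of the logits)
  p <- softmax_rows(ca$L)
  ck <- log(pmax(p, 1e-300)) + log(ncol(ca$L))
  klrow <- rowSums(p * ck)
  dKL <- p * (ck - klrow)
  dL <- dL - dKL / B
  gr$W3 <- crossprod(dL, ca$E)
  gr$b3 <- colSums(dL)
  dEpre <- (dL %*% par$W3) * (1 - ca$E^2)
  gr$W2 <- crossprod(dEpre, ca$C)
  gr$b2 <- colSums(dEpre)
  dC <- dEpre %*% par$W2
  dH1 <- rowsum(rbind(dC[, seq_len(H), drop = FALSE],
                      dC[, H + seq_len(H), drop = FALSE]),
                group = c(ix$row_i, ix$row_j))
  dH1pre <- dH1 * (1 - ca$H1^2)
  gr$W1 <- crossprod(dH1pre, fl$Xenc)
  gr$b1 <- colSums(dH1pre)
  gr
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0), t = 0)
}

adam_step <- function(par, gr, st, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(gr)) {
    g <- -gr[[nm]]                               # minimize -ELBO
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    decay <- if (startsWith(nm, "W")) weight_decay * par[[nm]] else 0
    par[[nm]] <- par[[nm]] - lr * (mhat / (sqrt(vhat) + eps) + decay)
  }
  list(par = par, st = st)
}
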