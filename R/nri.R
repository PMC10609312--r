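#' Coarse-grain node features into contiguous residue blocks
#'
#' Adjacent residues are integrated into blocks of `block_size` (the last
#' block may be short); the block feature is the mean of its members'
#' features. 238 residues at block size 10 give 24 blocks, the last of
#' size 8.
#'
#' @param features array `T x N x F` (e.g. from [featurize_nri()]`$features`).
#' @param block_size residues per block.
#' @return List with `features` (`T x M x F`) and `blocks` (tibble with
#'   `block`, `start`, `end`, `size`).
#' @export
coarse_grain_blocks <- function(features, block_size = 10) {
  N <- dim(features)[2]
  if (block_size > N) abort_allonet("block size exceeds node count.")
  starts <- seq(1, N, by = block_size)
  ends <- pmin(starts + block_size - 1, N)
  M <- length(starts)
  out <- array(0, c(dim(features)[1], M, dim(features)[3]))
  for (m in seq_len(M)) {
    block <- features[, starts[m]:ends[m], , drop = FALSE]
    out[, m, ] <- apply(block, c(1, 3), mean)
  }
  list(features = out,
       blocks = tibble::tibble(block = seq_len(M), start = starts, end = ends,
                               size = ends - starts + 1))
}

# cut a T x N x F feature array into non-overlapping windows -> B x W x N x F
make_windows <- function(features, window) {
  T_ <- dim(features)[1]
  B <- T_ %/% window
  if (B < 2) abort_allonet("need at least 2 full windows; shorten the window or lengthen the trajectory.")
  xw <- array(0, c(B, window, dim(features)[2], dim(features)[3]))
  for (b in seq_len(B)) {
    xw[b, , , ] <- features[((b - 1) * window + 1):(b * window), , , drop = FALSE]
  }
  xw
}

#' Train the relational-inference model on node features
#'
#' Maximizes the ELBO by minibatch Adam ascent; every stochastic draw
#' (initialization, Gumbel noise, shuffling) is fixed by `config$seed`.
#' The edge posterior reported afterwards is the softmax of the encoder
#' logits on the full data (no sampling), averaged over windows.
#'
#' `features` may also be a list of feature arrays from several systems
#' (e.g. spring simulations with different connectivity). Windows from
#' all systems are pooled for training; the interaction graph is inferred
#' per window by the encoder, so the decoder cannot memorize any single
#' system's graph -- training across systems is what makes the learned
#' edges identifiable. The reported `edge_posterior` is then a list, one
#' posterior per system; [infer_edges()] applies a trained model to new
#' trajectories.
#'
#' @param features `T x N x 6` standardized feature array (see
#'   [featurize_nri()]), the list that function returns, or a list of
#'   several such arrays (one per system).
#' @param config an [nri_config()].
#' @return An `nri_fit`: list with `model`, `edge_posterior`
#'   (`N x N x K`, diagonal NA; a list of those when trained on several
#'   systems), `report` (tibble `epoch`, `elbo`, `recon`, `kl`,
#'   per-window means), `config`.
#' @export
train_nri <- function(features, config = nri_config()) {
  if (is.list(features) && !is.null(features$features)) features <- features$features
  multi <- is.list(features)
  if (multi) {
    features <- lapply(features, function(f) {
      if (is.list(f) && !is.null(f$features)) f$features else f
    })
    xw_list <- lapply(features, make_windows, window = config$window)
    xw <- do.call(abind3, xw_list)
  } else {
    xw <- make_windows(features, config$window)
  }
  B_all <- dim(xw)[1]; N <- dim(xw)[3]
  run_once <- function(seed_r) {
    cfg_r <- config; cfg_r$seed <- seed_r
    model <- nri_init(N, cfg_r, n_features = dim(xw)[4])
    st <- adam_state(model$par)
    report <- tibble::tibble(epoch = integer(0), elbo = numeric(0),
                             recon = numeric(0), kl = numeric(0))
    if (config$epochs > 0) {
      with_seed(seed_r + 1, {
        for (ep in seq_len(config$epochs)) {
          ord <- sample.int(B_all)
          batches <- split(ord, ceiling(seq_along(ord) / config$batch))
          tot <- c(elbo = 0, recon = 0, kl = 0)
          for (bt in batches) {
            fwd <- nri_forward(model, xw[bt, , , , drop = FALSE], mode = "sample")
            if (!is.finite(fwd$elbo$elbo)) {
              abort_allonet(sprintf("training diverged (non-finite ELBO) at epoch %d.", ep))
            }
            gr <- nri_backward(model, fwd)
            upd <- adam_step(model$par, gr, st, lr = config$lr,
                             weight_decay = config$weight_decay %||% 0)
            model$par <- upd$par; st <- upd$st
            tot <- tot + c(fwd$elbo$elbo, fwd$elbo$recon, fwd$elbo$kl)
          }
          report <- dplyr::bind_rows(report, tibble::tibble(
            epoch = ep, elbo = tot[["elbo"]] / B_all,
            recon = tot[["recon"]] / B_all, kl = tot[["kl"]] / B_all))
        }
      })
    }
    score <- if (nrow(report) > 0) mean(utils::tail(report$elbo, 5)) else -Inf
    list(model = model, report = report, score = score)
  }
  n_restart <- config$restarts %||% 1
  runs <- lapply(seq_len(n_restart),
                 function(r) run_once(config$seed + 1000L * (r - 1L)))
  scores <- vapply(runs, `[[`, numeric(1), "score")
  best <- if (all(!is.finite(scores))) 1 else which.max(scores)
  model <- runs[[best]]$model
  ep <- if (multi) lapply(xw_list, function(x) edge_posterior(model, x)) else
    edge_posterior(model, xw)
  structure(list(model = model, edge_posterior = ep,
                 report = runs[[best]]$report, config = config,
                 restarts = tibble::tibble(restart = seq_len(n_restart),
                                           elbo = scores,
                                           selected = seq_len(n_restart) == best)),
            class = "nri_fit")
}

# bind window arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(0, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))), d[2], d[3], d[4]))
  at <- 0
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Edge posterior of a trained model on a (new) trajectory
#'
#' Runs the trained encoder on the windows of a feature array and returns
#' the window-averaged edge-type posterior.
#'
#' @param fit an `nri_fit`.
#' @param features `T x N x 6` feature array (or [featurize_nri()] list).
#' @return `N x N x K` posterior array (diagonal NA).
#' @export
infer_edges <- function(fit, features) {
  if (is.list(features) && !is.null(features$features)) features <- features$features
  edge_posterior(fit$model, make_windows(features, fit$config$window))
}

#' @export
print.nri_fit <- function(x, ...) {
  cat(sprintf("# nri_fit: %d nodes, K = %d, %d epochs%s\n",
              x$model$n_nodes, x$config$k, nrow(x$report),
              if (nrow(x$report) > 0)
                sprintf(", final ELBO/window %.2f", x$report$elbo[nrow(x$report)])
              else ""))
  invisible(x)
}

# posterior edge-type probabilities averaged over windows
edge_posterior <- function(model, xw) {
  fwd <- nri_forward(model, xw, mode = "mean")
  ix <- nri_indices(dim(xw)[3], dim(xw)[1])
  P <- ix$P; B <- ix$B; K <- ncol(fwd$logits)
  probs <- softmax_rows(fwd$logits)
  avg <- matrix(0, P, K)
  for (b in seq_len(B)) avg <- avg + probs[(b - 1) * P + seq_len(P), , drop = FALSE]
  avg <- avg / B
  ep <- array(NA_real_, c(ix$N, ix$N, K))
  for (p in seq_len(P)) ep[ix$pi[p], ix$pj[p], ] <- avg[p, ]
  ep
}

#' Probability that a directed pair carries any real edge
#'
#' Under the no-edge convention this is `1 - P(type 1)`; without it, the
#' maximum non-uniform deviation is not defined and the full posterior
#' should be inspected instead.
#'
#' @param ep `N x N x K` edge posterior from an `nri_fit`.
#' @return `N x N` matrix (diagonal NA).
#' @export
edge_probability <- function(ep) {
  1 - ep[, , 1]
}

#' Binary edge-recovery accuracy against a known adjacency
#'
#' A directed pair is called an edge when its any-edge probability exceeds
#' 0.5; accuracy is the fraction of ordered pairs matching the true
#' (symmetric) adjacency.
#'
#' @param fit an `nri_fit` (or an `N x N x K` posterior array).
#' @param adjacency true symmetric 0/1 matrix.
#' @return Accuracy in \[0, 1\].
#' @export
edge_recovery_accuracy <- function(fit, adjacency) {
  ep <- if (inherits(fit, "nri_fit")) fit$edge_posterior else fit
  pe <- edge_probability(ep)
  off <- !diag(nrow(pe))
  mean((pe[off] > 0.5) == (adjacency[off] > 0))
}

#' Correlation-threshold baseline for edge recovery
#'
#' Scores each pair by the maximum absolute correlation between the nodes'
#' coordinate time series and predicts as many edges as the truth contains
#' (an oracle-count baseline, deliberately generous).
#'
#' @param features `T x N x F` array (first 3 feature dims = positions).
#' @param adjacency true symmetric 0/1 matrix.
#' @return Accuracy in \[0, 1\].
#' @export
correlation_baseline_accuracy <- function(features, adjacency) {
  N <- dim(features)[2]
  score <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    cors <- vapply(1:3, function(d) {
      suppressWarnings(stats::cor(features[, i, d], features[, j, d]))
    }, numeric(1))
    score[i, j] <- score[j, i] <- max(abs(cors), na.rm = TRUE)
  }
  ut <- upper.tri(score)
  n_true <- sum(adjacency[ut] > 0)
  thr <- if (n_true == 0) Inf else sort(score[ut], decreasing = TRUE)[n_true]
  pred <- (score >= thr) & ut
  pred <- pred | t(pred)
  off <- !diag(N)
  mean(pred[off] == (adjacency[off] > 0))
}

#' Aggregate a block edge posterior into a domain-interaction map
#'
#' Entry (a, b) is the mean any-edge probability over ordered block pairs
#' with the sender in domain a and the receiver in domain b. The directed
#' edge list keeps entries above `threshold`, with `net` giving the
#' sender-minus-receiver asymmetry (signal direction).
#'
#' @param ep `M x M x K` edge posterior over blocks.
#' @param labels per-block domain index (e.g. 1-8) or name.
#' @param threshold minimum strength for the edge list.
#' @return List with `matrix` (domains x domains) and `edges` (tibble
#'   `from`, `to`, `strength`, `net`).
#' @export
aggregate_domains <- function(ep, labels, threshold = 0) {
  M <- dim(ep)[1]
  if (length(labels) != M || anyNA(labels)) abort_allonet("every block needs a domain label.")
  pe <- edge_probability(ep)
  doms <- unique(labels)
  D <- length(doms)
  out <- matrix(NA_real_, D, D, dimnames = list(doms, doms))
  for (a in seq_len(D)) for (b in seq_len(D)) {
    ia <- which(labels == doms[a]); ib <- which(labels == doms[b])
    vals <- pe[ia, ib, drop = FALSE]
    vals <- vals[is.finite(vals)]
    if (length(vals) > 0) out[a, b] <- mean(vals)
  }
  edges <- tidyr::expand_grid(from = doms, to = doms) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::mutate(
      strength = purrr::map2_dbl(.data$from, .data$to, ~ out[as.character(.x), as.character(.y)]),
      net = purrr::map2_dbl(.data$from, .data$to,
                            ~ out[as.character(.x), as.character(.y)] -
                              out[as.character(.y), as.character(.x)])
    ) |>
    dplyr::filter(.data$strength > threshold) |>
    dplyr::arrange(dplyr::desc(.data$strength))
  list(matrix = out, edges = edges)
}

#' Map coarse-grained blocks to consensus domains
#'
#' Labels each block with the fine domain containing the majority of its
#' residues (consensus numbering).
#'
#' @param blocks tibble from [coarse_grain_blocks()].
#' @param domains partition tibble, default [aabp_domains()].
#' @return Integer vector of domain indices, one per block.
#' @export
block_domain_labels <- function(blocks, domains = aabp_domains()) {
  vapply(seq_len(nrow(blocks)), function(m) {
    res <- blocks$start[m]:blocks$end[m]
    lab <- range_label(pmin(pmax(res, min(domains$start)), max(domains$end)),
                       domains, "index")
    as.integer(names(which.max(table(lab))))
  }, integer(1))
}
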