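#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Gaussian network model
#'
#' One row per residue with the slow- and fast-mode mean-square
#' fluctuation profiles at the default mode counts.
#'
#' @param x a `gnm` object.
#' @param slow_k,fast_k mode counts.
#' @param ... unused.
#' @return A tibble with columns `residue`, `msf_slow`, `msf_fast`.
#' @method tidy gnm
#' @export
tidy.gnm <- function(x, slow_k = 2, fast_k = 10, ...) {
  dplyr::left_join(
    dplyr::rename(mode_fluctuations(x, "slow", slow_k), msf_slow = "msf"),
    dplyr::rename(mode_fluctuations(x, "fast", fast_k), msf_fast = "msf"),
    by = "residue"
  )
}

#' @rdname tidy.gnm
#' @method glance gnm
#' @export
glance.gnm <- function(x, ...) {
  tibble::tibble(
    label = x$label %||% NA_character_,
    n_residues = nrow(x$kirchhoff),
    n_zero = x$n_zero,
    cutoff = x$params$cutoff %||% NA_real_,
    lambda_min_nonzero = x$values[x$n_zero + 1],
    lambda_max = max(x$values)
  )
}

#' Tidy an anisotropic network model
#'
#' One row per internal mode with its eigenvalue; `glance()` summarizes
#' the decomposition.
#'
#' @param x an `anm` object.
#' @param n_modes internal modes to report.
#' @param ... unused.
#' @return A tibble with columns `mode`, `eigenvalue`.
#' @method tidy anm
#' @export
tidy.anm <- function(x, n_modes = min(20, length(x$values) - x$n_zero), ...) {
  tibble::tibble(mode = seq_len(n_modes),
                 eigenvalue = x$values[x$n_zero + seq_len(n_modes)])
}

#' @rdname tidy.anm
#' @method glance anm
#' @export
glance.anm <- function(x, ...) {
  tibble::tibble(
    label = x$label %||% NA_character_,
    n_residues = nrow(x$hessian) / 3,
    n_zero = x$n_zero,
    cutoff = x$params$cutoff %||% NA_real_
  )
}

#' Tidy a relational-inference fit
#'
#' Long edge-posterior table: one row per ordered block pair and edge
#' type. For ensemble fits (several systems) a `system` column indexes
#' the per-system posteriors.
#'
#' @param x an `nri_fit`.
#' @param ... unused.
#' @return A tibble with columns (`system`,) `from`, `to`, `type`, `prob`.
#' @method tidy nri_fit
#' @export
tidy.nri_fit <- function(x, ...) {
  tidy_one <- function(ep) {
    N <- dim(ep)[1]; K <- dim(ep)[3]
    out <- tidyr::expand_grid(from = seq_len(N), to = seq_len(N),
                              type = seq_len(K)) |>
      dplyr::filter(.data$from != .data$to)
    out$prob <- ep[cbind(out$from, out$to, out$type)]
    out
  }
  ep <- x$edge_posterior
  if (is.list(ep)) {
    purrr::imap_dfr(ep, function(e, i) {
      dplyr::mutate(tidy_one(e), system = as.integer(i), .before = 1)
    })
  } else {
    tidy_one(ep)
  }
}

#' @rdname tidy.nri_fit
#' @method glance nri_fit
#' @export
glance.nri_fit <- function(x, ...) {
  last <- if (nrow(x$report) > 0) x$report[nrow(x$report), ] else
    tibble::tibble(elbo = NA_real_, recon = NA_real_, kl = NA_real_)
  tibble::tibble(
    n_nodes = x$model$n_nodes,
    k = x$config$k,
    epochs = nrow(x$report),
    elbo = last$elbo, recon = last$recon, kl = last$kl
  )
}

#' Tidy a path set
#'
#' Unnests each pathway to one row per (path, step) with the residue
#' visited.
#'
#' @param x a `path_set`.
#' @param ... unused.
#' @return A tibble with columns `source`, `sink`, `weight`, `step`,
#'   `residue`.
#' @method tidy path_set
#' @export
tidy.path_set <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x)), function(r) {
    tibble::tibble(source = x$source[r], sink = x$sink[r], weight = x$weight[r],
                   step = seq_along(x$path[[r]]), residue = x$path[[r]])
  })
}
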