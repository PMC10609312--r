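# ggplot2 methods for the result types

#' Plot a fluctuation profile
#'
#' @param x a `gnm` object.
#' @param modes `"slow"` or `"fast"`.
#' @param k mode count (defaults as in [mode_fluctuations()]).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot gnm
#' @export
autoplot.gnm <- function(x, modes = "slow", k = if (modes == "fast") 10 else 2, ...) {
  p <- mode_fluctuations(x, modes, k)
  ggplot2::ggplot(p, ggplot2::aes(x = .data$residue, y = .data$msf)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Residue", y = "Mean-square fluctuation",
                  title = sprintf("%s motion profile (%s)", modes, x$label %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a cross-correlation map
#'
#' @param C correlation matrix from [cross_correlation()].
#' @return A ggplot heat map (warm = correlated, cool = anticorrelated).
#' @export
plot_correlation_map <- function(C) {
  df <- tidyr::expand_grid(i = seq_len(nrow(C)), j = seq_len(ncol(C)))
  df$value <- C[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "Residue", y = "Residue", fill = "C_ij") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot RMSD series and RMSF profile of a trajectory
#'
#' @param x a [trajectory()].
#' @param what `"rmsd"` or `"rmsf"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot trajectory
#' @export
autoplot.trajectory <- function(x, what = c("rmsd", "rmsf"), ...) {
  what <- match.arg(what)
  if (what == "rmsd") {
    df <- rmsd_series(x)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$rmsd)) +
      ggplot2::geom_line(colour = "grey30") +
      ggplot2::labs(x = "Time", y = "RMSD (Å)", title = x$label) +
      ggplot2::theme_minimal()
  } else {
    df <- rmsf_profile(x)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$rmsf)) +
      ggplot2::geom_line(colour = "grey30") +
      ggplot2::labs(x = "Node", y = "RMSF (Å)", title = x$label) +
      ggplot2::theme_minimal()
  }
}

#' Plot a relational-inference fit
#'
#' Training curve (`what = "training"`) or the learned any-edge
#' probability matrix (`what = "edges"`).
#'
#' @param x an `nri_fit`.
#' @param what `"training"` or `"edges"`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot nri_fit
#' @export
autoplot.nri_fit <- function(x, what = c("training", "edges"), ...) {
  what <- match.arg(what)
  if (what == "training") {
    df <- tidyr::pivot_longer(x$report, c("elbo", "recon", "kl"),
                              names_to = "term", values_to = "value")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$term)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Epoch", y = "Per-window value") +
      ggplot2::theme_minimal()
  } else {
    pe <- edge_probability(x$edge_posterior)
    df <- tidyr::expand_grid(from = seq_len(nrow(pe)), to = seq_len(ncol(pe)))
    df$prob <- pe[cbind(df$from, df$to)]
    ggplot2::ggplot(df[is.finite(df$prob), ],
                    ggplot2::aes(x = .data$to, y = .data$from, fill = .data$prob)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
      ggplot2::labs(x = "Receiver block", y = "Sender block", fill = "P(edge)") +
      ggplot2::coord_fixed() +
      ggplot2::theme_minimal()
  }
}

#' Plot residue occurrence frequencies of a path set
#'
#' @param x a `path_set`.
#' @param ... unused.
#' @return A ggplot bar chart.
#' @method autoplot path_set
#' @export
autoplot.path_set <- function(x, ...) {
  freq <- residue_frequency(x)
  ggplot2::ggplot(freq, ggplot2::aes(x = stats::reorder(factor(.data$residue), -.data$count),
                                     y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Residue (consensus)", y = "Pathway occurrences") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
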