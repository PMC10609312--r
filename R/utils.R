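# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_allonet <- function(msg, class = "allonet_error") {
  rlang::abort(msg, class = class)
}

warn_allonet <- function(msg, class = "allonet_warning") {
  rlang::warn(msg, class = class)
}

assert_coords <- function(coords, n_min = 2, arg = "coords") {
  if (!is.matrix(coords) || ncol(coords) != 3) {
    abort_allonet(sprintf("`%s` must be an N x 3 numeric matrix.", arg))
  }
  if (nrow(coords) < n_min) {
    abort_allonet(sprintf("`%s` needs at least %d rows, got %d.", arg, n_min, nrow(coords)))
  }
  if (!all(is.finite(coords))) {
    abort_allonet(sprintf("`%s` contains non-finite values.", arg))
  }
  invisible(coords)
}

# pairwise Euclidean distances, plain and explicit
pair_dists <- function(coords) {
  as.matrix(stats::dist(coords))
}

# seeded RNG scope that restores the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
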