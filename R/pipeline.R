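#' Pipeline configuration
#'
#' A single config drives the end-to-end analysis: structure input (PDB
#' pair or the synthetic hinge generator), elastic-network parameters,
#' trajectory sampling, relational inference, pathway extraction and the
#' energy filter. One global seed propagates to every stochastic stage.
#'
#' @param open_pdb,closed_pdb optional PDB files for an open/closed pair;
#'   when `NULL` the synthetic two-lobe generator supplies the pair.
#' @param chain chain selector for PDB input.
#' @param sequences optional named character vector of three sequences for
#'   the alignment stage (skipped when absent).
#' @param n_lobe,linker,open_angle,closed_angle synthetic-generator
#'   geometry.
#' @param gnm_cutoff,slow_k,fast_k Gaussian-network parameters.
#' @param anm_cutoff anisotropic-network cutoff.
#' @param n_frames,amplitude trajectory sampling.
#' @param nri `TRUE`, `FALSE`, or an [nri_config()]; `TRUE` uses a compact
#'   default sized for the coarse-grained blocks.
#' @param coupling `"nri"` or `"gnm"` edge weights for the pathway graph
#'   (falls back to `"gnm"` when the inference stage is disabled).
#' @param sources,sinks pathway endpoints in consensus numbering.
#' @param energy_table path to a per-residue energy table; default the
#'   packaged reference table.
#' @param energy_threshold key-residue cutoff (kJ/mol).
#' @param seed global seed.
#' @param out_dir optional output directory for per-stage TSV/JSON files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(open_pdb = NULL, closed_pdb = NULL, chain = NULL,
                            sequences = NULL,
                            n_lobe = c(115, 115), linker = 8,
                            open_angle = 120, closed_angle = 60,
                            gnm_cutoff = 7.3, slow_k = 2, fast_k = 10,
                            anm_cutoff = 15,
                            n_frames = 200, amplitude = 1,
                            nri = TRUE, coupling = c("nri", "gnm"),
                            sources = c(11, 117), sinks = iloop_positions(),
                            energy_table = NULL, energy_threshold = -1.00,
                            seed = 1, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full allostery pipeline
#'
#' Executes structure preparation, (optionally) sequence alignment, the
#' Gaussian and anisotropic network models, trajectory sampling and
#' statistics, relational-inference training with domain aggregation,
#' shortest-path signalling analysis and the binding-energy filter, in
#' that order. Every stage's outputs are collected in the returned run
#' object together with a manifest of inputs, parameters and seeds;
#' rerunning with the same config reproduces the numbers exactly.
#'
#' @param config a [pipeline_config()].
#' @return An `allonet_run` list; see components `structures`, `alignment`,
#'   `gnm`, `anm`, `trajectory`, `nri`, `paths`, `energetics`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  coupling <- match.arg(cfg$coupling, c("nri", "gnm"))
  run <- list()
  manifest <- tibble::tibble(stage = character(0), item = character(0),
                             value = character(0))
  note <- function(stage, item, value) {
    manifest <<- dplyr::bind_rows(manifest, tibble::tibble(
      stage = stage, item = item, value = as.character(value)))
  }
  note("config", "seed", cfg$seed)

  # --- structures -----------------------------------------------------
  if (!is.null(cfg$open_pdb)) {
    open <- read_pdb_ca(cfg$open_pdb, chain = cfg$chain, label = "open")
    closed <- read_pdb_ca(cfg$closed_pdb, chain = cfg$chain, label = "closed")
    note("structures", "source", "pdb")
  } else {
    open <- make_two_domain_structure(n_lobe = cfg$n_lobe, linker = cfg$linker,
                                      hinge_angle = cfg$open_angle,
                                      seed = cfg$seed, label = "synthetic-open")
    closed <- close_hinge(open, cfg$closed_angle)
    attr(closed, "label") <- "synthetic-closed"
    note("structures", "source", "synthetic")
    note("structures", "hinge_angles",
         sprintf("%g -> %g deg", cfg$open_angle, cfg$closed_angle))
  }
  run$structures <- list(open = open, closed = closed)
  note("structures", "n_residues", nrow(open))

  # --- alignment (only when sequences are supplied) --------------------
  if (!is.null(cfg$sequences) && length(cfg$sequences) == 3) {
    msa <- align_three(cfg$sequences[1], cfg$sequences[2], cfg$sequences[3],
                       names = names(cfg$sequences))
    run$alignment <- list(msa = msa,
                          conserved = conserved_positions(msa),
                          position_map = build_position_map(msa))
    note("align", "conserved_columns", length(run$alignment$conserved))
  } else {
    note("align", "status", "skipped (no sequences supplied)")
  }

  # --- elastic networks ------------------------------------------------
  run$gnm <- purrr::map(run$structures, function(s) {
    g <- gnm(s, cutoff = cfg$gnm_cutoff)
    list(model = g,
         slow = mode_fluctuations(g, "slow", cfg$slow_k),
         fast = mode_fluctuations(g, "fast", cfg$fast_k),
         correlation = cross_correlation(g, "slow", cfg$slow_k))
  })
  run$gnm$hinges <- detect_extrema(run$gnm$open$slow, "hinge")
  run$gnm$hotspots <- detect_extrema(run$gnm$closed$fast, "hotspot")
  note("gnm", "cutoff_A", cfg$gnm_cutoff)

  run$anm <- list(open = anm(open, cutoff = cfg$anm_cutoff))
  run$anm$overlap <- overlap_with_transition(run$anm$open, ca_coords(open),
                                             ca_coords(closed))
  note("anm", "best_overlap_mode", run$anm$overlap$mode[which.max(run$anm$overlap$overlap)])

  # --- trajectory ------------------------------------------------------
  traj <- sample_enm_trajectory(open, n_frames = cfg$n_frames,
                                amplitude = cfg$amplitude,
                                cutoff = cfg$anm_cutoff, seed = cfg$seed + 1)
  run$trajectory <- list(trajectory = traj,
                         rmsd = rmsd_series(traj),
                         rmsf = rmsf_profile(traj))
  note("trajectory", "n_frames", cfg$n_frames)

  # --- relational inference -------------------------------------------
  nri_on <- !isFALSE(cfg$nri)
  if (nri_on) {
    ncfg <- if (inherits(cfg$nri, "nri_config")) cfg$nri else
      nri_config(k = 4, hidden = 32, epochs = 30, window = 10,
                 block_size = 10, seed = cfg$seed + 2)
    feats <- featurize_nri(traj)
    cg <- coarse_grain_blocks(feats$features, ncfg$block_size)
    fit <- train_nri(cg$features, ncfg)
    labels <- block_domain_labels(cg$blocks)
    run$nri <- list(fit = fit, blocks = cg$blocks, labels = labels,
                    domains = aggregate_domains(fit$edge_posterior, labels))
    note("nri", "final_elbo_per_window",
         sprintf("%.3f", fit$report$elbo[nrow(fit$report)]))
  } else {
    note("nri", "status", "disabled; pathway stage uses GNM coupling")
    coupling <- "gnm"
  }

  # --- pathways --------------------------------------------------------
  contacts <- contact_adjacency(ca_coords(open), cutoff = cfg$gnm_cutoff)
  if (coupling == "nri") {
    pe <- edge_probability(run$nri$fit$edge_posterior)
    blk <- rep(seq_len(nrow(run$nri$blocks)), run$nri$blocks$size)
    C <- matrix(0, nrow(open), nrow(open))
    for (i in seq_len(nrow(open))) {
      C[i, ] <- pe[blk[i], blk]
    }
    C[is.na(C)] <- 0.99                        # intra-block: integrated residues
  } else {
    C <- abs(cross_correlation(gnm(open, cutoff = cfg$gnm_cutoff), "all", normalize = TRUE))
  }
  g <- build_graph(C, contacts)
  run$paths <- list(graph = g,
                    paths = allosteric_paths(g, cfg$sources, cfg$sinks))
  run$paths$frequency <- residue_frequency(run$paths$paths)
  run$paths$top <- top_pathway(run$paths$paths, run$paths$frequency)
  note("paths", "coupling", coupling)
  note("paths", "n_paths", nrow(run$paths$paths))

  # --- energetics ------------------------------------------------------
  et_path <- cfg$energy_table %||% aabp_energy_table_path()
  et <- compute_etot(read_energy_table(et_path))
  run$energetics <- list(table = et,
                         key = key_residues(et, cfg$energy_threshold))
  note("energetics", "table", et_path)
  note("energetics", "n_key", nrow(run$energetics$key))

  # --- outputs ---------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(x, f) utils::write.table(
      x, file.path(cfg$out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    wtsv(run$gnm$open$slow, "gnm_slow_open.tsv")
    wtsv(run$gnm$closed$fast, "gnm_fast_closed.tsv")
    wtsv(run$trajectory$rmsf, "rmsf.tsv")
    wtsv(run$paths$frequency, "path_frequency.tsv")
    wtsv(run$energetics$key[, c("system", "consensus", "residue", "e_tot")],
         "key_residues.tsv")
    jsonlite::write_json(
      list(top_path = run$paths$top$path[[1]],
           overlap = run$anm$overlap,
           manifest = manifest),
      file.path(cfg$out_dir, "run_summary.json"), auto_unbox = TRUE, digits = NA)
    note("output", "dir", cfg$out_dir)
  }
  run$manifest <- manifest
  run$config <- cfg
  class(run) <- "allonet_run"
  run
}

#' @export
print.allonet_run <- function(x, ...) {
  cat("# allonet_run\n")
  print(x$manifest, n = Inf)
  invisible(x)
}
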