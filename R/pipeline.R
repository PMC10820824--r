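#' Default run configuration
#'
#' All tunable pipeline parameters with their standard values: 5000
#' trajectories, a 3-h step input, 1000 parameter sets over a tenfold
#' span, the 250-cell primary and 10-cell alignment windows, 1000
#' (band) and 10,000 (disorder) bootstrap draws, the 200-px analysis
#' radius, 2 h per R8 column, the 30% commitment rule, the 1%
#' threshold percentile and the 60% severity-calibration target.
#'
#' @return Nested named list of defaults, ready to be overridden by a
#'   user configuration.
#' @export
default_config <- function() {
  list(
    rates = unclass(default_rate_params()),
    input = list(onset = 0, duration = 3, amplitude = 1, basal = 0),
    activation = list(auxiliary_stage = "transcript",
                      severity = default_severity("transcript")),
    metabolism = list(label = "normal", scale_eta_G = FALSE,
                      scale_gamma_R = FALSE),
    simulation = list(variant = "linear", n = 5000L, grid_n = 200L),
    sweep = list(n_sets = 1000L, span = 10,
                 conditions = c("normal", "reduced")),
    disorder = list(radius = 200, n_boot = 10000L),
    dynamics = list(window = 250L, align_window = 10L,
                    n_boot = 1000L, hours_per_column = 2,
                    rebase_offset = 10),
    calibration = list(target_raw_failure = 0.60, tol = 0.02)
  )
}

merge_config <- function(user) {
  cfg <- default_config()
  if (is.null(user)) return(cfg)
  for (sec in names(user)) {
    if (is.list(user[[sec]]) && sec %in% names(cfg))
      cfg[[sec]] <- modifyList(cfg[[sec]], user[[sec]])
    else cfg[[sec]] <- user[[sec]]
  }
  cfg
}

config_params <- function(cfg) {
  do.call(rate_params, cfg$rates[setdiff(names(cfg$rates), NULL)])
}

config_input <- function(cfg) {
  do.call(step_input, cfg$input)
}

#' Run one pipeline stage from a configuration
#'
#' Executes the requested stage with the merged configuration (user
#' settings over [default_config()]), writes its artifacts into
#' `out_dir`, and records a manifest (`manifest.json`: configuration
#' snapshot, seed, package version, input checksums, outputs).  The
#' same configuration and seed always produce identical artifacts.
#'
#' @param stage one of `"simulate"`, `"metrics"`, `"sweep"`,
#'   `"disorder"`, `"dynamics"`, `"synth"`.
#' @param config named list of overrides, or the path of a YAML/JSON
#'   configuration file with the same structure; `NULL` for defaults.
#' @param seed master seed for every source of randomness in the
#'   stage.
#' @param out_dir output directory (created if needed).
#' @param input_file stage input table where one is required
#'   (`disorder`: a centroid table; `dynamics`: a cell table).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(stage = c("simulate", "metrics", "sweep",
                                   "disorder", "dynamics", "synth"),
                         config = NULL, seed = 1L, out_dir = ".",
                         input_file = NULL) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("[.]json$", config))
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- merge_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  outputs <- switch(stage,
    simulate = stage_simulate(cfg, seed, out_dir),
    metrics = stage_metrics(cfg, seed, out_dir),
    sweep = stage_sweep(cfg, seed, out_dir),
    disorder = stage_disorder(cfg, seed, out_dir, input_file),
    dynamics = stage_dynamics(cfg, seed, out_dir, input_file),
    synth = stage_synth(cfg, seed, out_dir))
  manifest <- list(
    stage = stage, seed = seed, config = cfg,
    inputs = if (!is.null(input_file))
      list(path = input_file,
           md5 = unname(tools::md5sum(input_file))) else NULL,
    outputs = outputs,
    package_version =
      as.character(utils::packageVersion("flypulse")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

stage_simulate <- function(cfg, seed, out_dir) {
  params <- apply_activation(
    config_params(cfg),
    activation_scheme("full", cfg$activation$auxiliary_stage,
                      cfg$activation$severity))
  params <- scale_for_metabolism(params, cfg$metabolism$label,
                                 cfg$metabolism$scale_eta_G,
                                 cfg$metabolism$scale_gamma_R)
  ens <- simulate_ensemble(cfg$simulation$variant, params,
                           config_input(cfg),
                           n = cfg$simulation$n, seed = seed,
                           grid_n = cfg$simulation$grid_n)
  f <- file.path(out_dir, "ensemble.tsv")
  write_ensemble(ens, f)
  c(ensemble = f, metadata = paste0(f, ".json"))
}

stage_metrics <- function(cfg, seed, out_dir) {
  base <- config_params(cfg)
  input <- config_input(cfg)
  scheme_full <- activation_scheme("full", cfg$activation$auxiliary_stage,
                                   cfg$activation$severity)
  mk <- function(scheme, s) {
    p <- scale_for_metabolism(apply_activation(base, scheme),
                              cfg$metabolism$label,
                              cfg$metabolism$scale_eta_G,
                              cfg$metabolism$scale_gamma_R)
    simulate_ensemble(cfg$simulation$variant, p, input,
                      n = cfg$simulation$n, seed = s,
                      grid_n = cfg$simulation$grid_n)
  }
  full <- mk(scheme_full, seed)
  part <- mk(activation_scheme("partial"), seed + 1L)
  er <- error_report(part, full)
  fE <- file.path(out_dir, "underexpression.tsv")
  write.table(data.frame(t = er$grid, E = er$E_series), fE, sep = "\t",
              quote = FALSE, row.names = FALSE)
  fR <- file.path(out_dir, "error_report.json")
  jsonlite::write_json(
    list(raw_failure = er$raw_failure,
         error_frequency = er$error_frequency,
         tau = er$tau, peak_time = er$peak_time,
         mean_underexpression = er$mean_underexpression,
         theta_peak = er$threshold$theta_peak),
    fR, auto_unbox = TRUE, digits = NA)
  c(error_report = fR, underexpression = fE)
}

stage_sweep <- function(cfg, seed, out_dir) {
  sets <- sample_parameter_sets(cfg$sweep$n_sets,
                                config_params(cfg),
                                span = cfg$sweep$span,
                                severity = cfg$activation$severity,
                                seed = seed)
  sw <- run_sweep(sets, variant = cfg$simulation$variant,
                  ensemble_n = cfg$simulation$n,
                  conditions = cfg$sweep$conditions,
                  input = config_input(cfg), seed = seed,
                  grid_n = cfg$simulation$grid_n,
                  out_dir = file.path(out_dir, "sets"))
  f <- file.path(out_dir, "sweep.tsv")
  write.table(sw$records, f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fs <- file.path(out_dir, "parameter_sets.tsv")
  write.table(as.data.frame(sets), fs, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(sweep = f, parameter_sets = fs)
}

stage_disorder <- function(cfg, seed, out_dir, input_file) {
  if (is.null(input_file))
    stop("disorder stage needs a centroid table (input_file)",
         call. = FALSE)
  cent <- read_centroids(input_file)
  per_omm <- NULL
  summaries <- list()
  for (sid in unique(cent$sample_id)) {
    sub <- cent[cent$sample_id == sid, ]
    lat <- triangulate(data.frame(x = sub$x_px, y = sub$y_px))
    analysis <- restrict_region(lat, cfg$disorder$radius)
    rec <- disorder_metric(lat, analysis)
    boot <- bootstrap_mean(rec$D, cfg$disorder$n_boot, seed = seed)
    per_omm <- rbind(per_omm, data.frame(sample_id = sid, rec))
    summaries[[sid]] <- list(n_analyzed = nrow(rec),
                             mean_D = mean(rec$D),
                             mean_distance =
                               attr(rec, "mean_distance"),
                             bootstrap_mean = boot$mean,
                             bootstrap_sd = boot$sd)
  }
  fo <- file.path(out_dir, "disorder_per_ommatidium.tsv")
  write.table(per_omm, fo, sep = "\t", quote = FALSE, row.names = FALSE)
  fs <- file.path(out_dir, "disorder_summary.json")
  jsonlite::write_json(summaries, fs, auto_unbox = TRUE, digits = NA)
  c(per_ommatidium = fo, summary = fs)
}

stage_dynamics <- function(cfg, seed, out_dir, input_file) {
  if (is.null(input_file))
    stop("dynamics stage needs a cell table (input_file)", call. = FALSE)
  cells <- read_cell_table(input_file)
  cells <- normalize_expression(cells)
  timed <- do.call(rbind, lapply(split(cells, cells$disk_id),
    function(d) furrow_clock(d, cfg$dynamics$hours_per_column)))
  rownames(timed) <- NULL
  al <- align_experiment(timed, seed = seed,
                         window = cfg$dynamics$align_window,
                         rebase_offset = cfg$dynamics$rebase_offset)
  fa <- file.path(out_dir, "aligned_cells.tsv")
  write.table(al$cells, fa, sep = "\t", quote = FALSE,
              row.names = FALSE)
  fl <- file.path(out_dir, "alignment_log.tsv")
  write.table(al$shifts, fl, sep = "\t", quote = FALSE,
              row.names = FALSE)
  trends <- NULL
  for (tr in unique(al$cells$treatment)) {
    prog <- al$cells[al$cells$treatment == tr &
                     al$cells$cell_type == "progenitor", ]
    prog <- prog[order(prog$time), ]
    w <- min(cfg$dynamics$window, nrow(prog))
    ma <- moving_average(prog$time, prog$expression, w)
    band <- bootstrap_band(prog$time, prog$expression, w,
                           n_boot = cfg$dynamics$n_boot, seed = seed)
    trends <- rbind(trends, data.frame(treatment = tr, t = ma$time,
                                       mean = ma$mean, lo = band$lo,
                                       hi = band$hi))
  }
  ft <- file.path(out_dir, "trajectories.tsv")
  write.table(trends, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  c(aligned_cells = fa, alignment_log = fl, trajectories = ft)
}

stage_synth <- function(cfg, seed, out_dir) {
  lat <- do.call(make_hex_lattice,
                 c(cfg$synth$lattice, list(seed = seed)))
  fl <- file.path(out_dir, "centroids.tsv")
  write_centroids(lat, fl)
  disk_cfg <- if (is.null(cfg$synth$disk)) list() else cfg$synth$disk
  disk <- do.call(make_disk, c(disk_cfg, list(seed = seed + 1L)))
  fd <- file.path(out_dir, "cells.tsv")
  write_cell_table(disk, fd)
  jsonlite::write_json(list(lattice = attr(lat, "spec"),
                            disk = attr(disk, "spec")),
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  c(centroids = fl, cells = fd,
    ground_truth = file.path(out_dir, "ground_truth.json"))
}
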