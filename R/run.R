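#' Full run configuration
#'
#' Aggregates the extraction, sonar and simulation configurations with
#' grid-search ranges, so a whole pipeline run is described by one object.
#' All defaults are the study values.
#'
#' @param extraction an [extraction_config()].
#' @param sonar a [sonar_params()].
#' @param sim a [sim_config()].
#' @param A_values,B_values,tau_values grid-search ranges.
#' @param n_pairs ensemble size per grid point.
#' @param seed base seed for every random component.
#' @return an object of class `bsmi_run_config`.
#' @export
run_config <- function(extraction = extraction_config(),
                       sonar = sonar_params(),
                       sim = sim_config(sonar = sonar),
                       A_values = seq(0, 72, by = 8),
                       B_values = seq(-60, 60, by = 10),
                       tau_values = c(0, seq(0.1, 0.5, by = 0.1)),
                       n_pairs = 200, seed = 1) {
  structure(
    list(
      extraction = extraction, sonar = sonar, sim = sim,
      A_values = A_values, B_values = B_values, tau_values = tau_values,
      n_pairs = n_pairs, seed = seed
    ),
    class = "bsmi_run_config"
  )
}

config_fingerprint <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 10, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(as.character(json)) * seq_along(utf8ToInt(as.character(json)))) %% 4294967296)
}

write_manifest <- function(out_dir, what, config, seed, extra = list()) {
  manifest <- c(
    list(
      step = what,
      seed = seed,
      config_fingerprint = config_fingerprint(config),
      package_version = as.character(utils::packageVersion("bsmi")),
      written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    ),
    extra
  )
  jsonlite::write_json(manifest, file.path(out_dir, sprintf("%s_manifest.json", what)),
    auto_unbox = TRUE, digits = NA
  )
}

#' Classify a trajectory file end to end
#'
#' Reads paired trajectories, classifies every pair, and writes the
#' per-pair classification table, the pooled summary (label fractions and
#' delay histogram), the relative-position sample table, and a run
#' manifest.
#'
#' @param input path to a trajectory file readable by
#'   [read_trajectories()].
#' @param out_dir output directory (created if needed).
#' @param config a [run_config()].
#' @param discard_out_of_range drop pairs that never come inside the 0 dB
#'   on-axis sonar range (they are always flagged in the summary).
#' @return invisibly, the list of `bsmi_classified_pair` objects.
#' @export
run_classify <- function(input, out_dir, config = run_config(),
                         discard_out_of_range = FALSE) {
  if (!file.exists(input)) stop(sprintf("input file not found: %s", input))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pairs <- read_trajectories(input)
  if (length(pairs) == 0) stop("input file contains no pairs")
  flagged <- vapply(pairs, beyond_sonar_range, logical(1), params = config$sonar)
  if (discard_out_of_range && any(flagged)) pairs <- pairs[!flagged]
  classified <- lapply(pairs, classify_pair, cfg = config$extraction)
  write_classification(classified, file.path(out_dir, "classification.csv"))
  samples <- do.call(rbind, lapply(classified, relative_samples, seed = config$seed))
  if (!is.null(samples) && nrow(samples) > 0) {
    utils::write.table(samples, file.path(out_dir, "relative_samples.csv"),
      sep = ",", row.names = FALSE, quote = FALSE
    )
  }
  write_manifest(out_dir, "classify", config, config$seed,
    extra = list(
      n_pairs = length(classified),
      flagged_beyond_sonar_range = names(flagged)[flagged]
    )
  )
  invisible(classified)
}

#' Simulate an ensemble and write it in the trajectory exchange format
#'
#' @param out_dir output directory.
#' @param config a [run_config()]; `config$sim` drives the simulation.
#' @param n_pairs ensemble size (defaults to `config$n_pairs`).
#' @return invisibly, the list of `bsmi_sim_pair` objects.
#' @export
run_simulate <- function(out_dir, config = run_config(), n_pairs = config$n_pairs) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sims <- simulate_ensemble(config$sim, n_pairs, seed = config$seed)
  write_trajectories(lapply(sims, `[[`, "pair"), file.path(out_dir, "trajectories.csv"))
  states <- do.call(rbind, lapply(sims, function(s) {
    data.frame(
      pair_id = s$pair$pair_id,
      step = seq_len(nrow(s$interacting)),
      bat1_interacting = s$interacting[, 1],
      bat2_interacting = s$interacting[, 2]
    )
  }))
  utils::write.table(states, file.path(out_dir, "states.csv"),
    sep = ",", row.names = FALSE, quote = FALSE
  )
  write_manifest(out_dir, "simulate", config, config$seed,
    extra = list(n_pairs = n_pairs, tau = config$sim$tau)
  )
  invisible(sims)
}

#' Fit the simulator to an observed relative-position sample table
#'
#' Reads a sample table (as written by [run_classify()]), bins the
#' coordinated-flight samples, runs [grid_search_fit()] over the
#' configured ranges, and writes the RMS surface (one matrix per delay)
#' plus the argmin record.
#'
#' @param samples_file path to a relative-sample table with columns
#'   `label, rel_x, rel_y`.
#' @param out_dir output directory.
#' @param config a [run_config()].
#' @return invisibly, the `bsmi_fit_result`.
#' @export
run_fit <- function(samples_file, out_dir, config = run_config()) {
  if (!file.exists(samples_file)) stop(sprintf("samples file not found: %s", samples_file))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  samples <- utils::read.csv(samples_file, stringsAsFactors = FALSE)
  coord <- samples[samples$label == "coordinated", , drop = FALSE]
  if (nrow(coord) == 0) stop("observed table contains no coordinated samples")
  observed <- bin_density(coord)
  fit <- grid_search_fit(
    observed, config$sim,
    A_values = config$A_values, B_values = config$B_values,
    tau_values = config$tau_values,
    n_pairs = config$n_pairs, seed = config$seed,
    ext_cfg = config$extraction
  )
  for (tv in unique(fit$surface$tau)) {
    sub <- fit$surface[fit$surface$tau == tv, , drop = FALSE]
    m <- stats::reshape(sub[, c("A", "B", "rms")],
      idvar = "A", timevar = "B", direction = "wide"
    )
    utils::write.table(m, file.path(out_dir, sprintf("rms_surface_tau_%g.csv", tv)),
      sep = ",", row.names = FALSE, quote = FALSE
    )
  }
  jsonlite::write_json(
    list(
      best = as.list(fit$best), rms_min = fit$rms_min,
      n_missing = sum(is.na(fit$surface$rms))
    ),
    file.path(out_dir, "fit_best.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_manifest(out_dir, "fit", config, config$seed)
  invisible(fit)
}
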