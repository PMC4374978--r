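#' Classify a paired trajectory into unclassified / coordinated / chase
#'
#' Runs the full per-pair pipeline: smoothing and kinematics, TDDC and TDDS
#' maps, chase-path extraction, coordinated-path extraction anchored to the
#' chase path, and uncertainty bounds. Each lattice time receives a label
#' (chase takes precedence over coordinated) and, where interacting,
#' actor-reactor roles from the sign of the extracted delay: `tau > 0`
#' means bat j is copying bat i's heading tau seconds later, so bat i (the
#' pair's first member) is the actor; `tau < 0` swaps the roles; `tau = 0`
#' is reported as coordinated with unresolved roles.
#'
#' @param pair a `bsmi_paired_trajectory`.
#' @param cfg an [extraction_config()].
#' @param keep_maps keep the TDDC/TDDS maps and paths in the result
#'   (memory-heavy for long recordings; default `FALSE`).
#' @return an object of class `bsmi_classified_pair`: a per-time table
#'   (`$table` with columns `t_idx, t, label, actor, reactor, tau, tau_lo,
#'   tau_hi`) plus `$summary` fractions and the configuration used.
#' @export
classify_pair <- function(pair, cfg = extraction_config(), keep_maps = FALSE) {
  stopifnot(inherits(pair, "bsmi_paired_trajectory"))
  pair <- pair_kinematics(pair, cfg$w)
  degenerate <- FALSE
  res <- tryCatch(
    {
      c_map <- tddc(pair, cfg$w, tau_max = cfg$tau_max %||% Inf)
      r_map <- tdds(pair, cfg$w, tau_max = cfg$tau_max %||% Inf)
      if (all(is.na(c_map$values))) stop("all cells undefined")
      chase <- extract_chase_path(c_map, r_map, cfg)
      coord <- extract_coordinated_path(c_map, cfg, anchor = chase)
      coord <- delay_uncertainty(c_map, coord, cfg, r_map = r_map)
      list(c_map = c_map, r_map = r_map, chase = chase, coord = coord)
    },
    error = function(e) {
      warning(sprintf("pair %s: degenerate pair (%s); all samples unclassified", pair$pair_id, conditionMessage(e)))
      NULL
    }
  )
  if (is.null(res)) {
    degenerate <- TRUE
    tab <- data.frame(
      t_idx = integer(0), t = numeric(0), label = character(0),
      actor = character(0), reactor = character(0),
      tau = numeric(0), tau_lo = numeric(0), tau_hi = numeric(0),
      stringsAsFactors = FALSE
    )
  } else {
    coord <- res$coord
    label <- coord$segment_kind
    label[label == "none"] <- "unclassified"
    tau <- ifelse(label == "unclassified", NA_real_, coord$tau)
    actor <- rep(NA_character_, length(label))
    reactor <- rep(NA_character_, length(label))
    pos <- !is.na(tau) & tau > 0
    neg <- !is.na(tau) & tau < 0
    actor[pos] <- pair$a$bat_id
    reactor[pos] <- pair$b$bat_id
    actor[neg] <- pair$b$bat_id
    reactor[neg] <- pair$a$bat_id
    tab <- data.frame(
      t_idx = coord$t_idx, t = coord$t, label = label,
      actor = actor, reactor = reactor,
      tau = tau, tau_lo = coord$tau_lo, tau_hi = coord$tau_hi,
      stringsAsFactors = FALSE
    )
  }
  n <- max(nrow(tab), 1)
  summary <- list(
    n_times = nrow(tab),
    fraction_unclassified = if (nrow(tab)) mean(tab$label == "unclassified") else 1,
    fraction_coordinated = if (nrow(tab)) mean(tab$label == "coordinated") else 0,
    fraction_chase = if (nrow(tab)) mean(tab$label == "chase") else 0,
    fraction_interacting = if (nrow(tab)) mean(tab$label != "unclassified") else 0
  )
  structure(
    list(
      pair_id = pair$pair_id,
      i_id = pair$a$bat_id,
      j_id = pair$b$bat_id,
      table = tab,
      summary = summary,
      cfg = cfg,
      degenerate = degenerate,
      pair = pair,
      maps = if (keep_maps && !is.null(res)) res else NULL
    ),
    class = "bsmi_classified_pair"
  )
}

#' @export
print.bsmi_classified_pair <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<bsmi_classified_pair> pair %s: %d times; %.1f%% coordinated, %.1f%% chase, %.1f%% unclassified\n",
    x$pair_id, s$n_times, 100 * s$fraction_coordinated,
    100 * s$fraction_chase, 100 * s$fraction_unclassified
  ))
  invisible(x)
}

#' Sensitivity of the interacting fraction to the correlation threshold
#'
#' Re-runs classification for each candidate threshold and reports, per
#' pair and pooled, the fraction of lattice times labelled interacting
#' (coordinated or chase). Stricter thresholds can only shrink the
#' super-threshold region, so the fraction is non-increasing in `v_c`.
#'
#' @param pairs list of `bsmi_paired_trajectory` objects.
#' @param v_c_values numeric vector of thresholds to sweep.
#' @param cfg base [extraction_config()]; `v_c` is overridden per sweep
#'   point.
#' @return data frame `pair_id, v_c, fraction_interacting`, with pooled
#'   rows under `pair_id = "(pooled)"`.
#' @export
sensitivity_sweep <- function(pairs, v_c_values, cfg = extraction_config()) {
  if (inherits(pairs, "bsmi_paired_trajectory")) pairs <- list(pairs)
  stopifnot(length(pairs) >= 1)
  rows <- list()
  for (vc in v_c_values) {
    cfg_vc <- cfg
    cfg_vc$v_c <- vc
    fracs <- numeric(0)
    counts <- numeric(0)
    for (p in pairs) {
      cl <- classify_pair(p, cfg_vc)
      fracs <- c(fracs, cl$summary$fraction_interacting)
      counts <- c(counts, cl$summary$n_times)
      rows[[length(rows) + 1]] <- data.frame(
        pair_id = cl$pair_id, v_c = vc,
        fraction_interacting = cl$summary$fraction_interacting,
        stringsAsFactors = FALSE
      )
    }
    pooled <- if (sum(counts) > 0) sum(fracs * counts) / sum(counts) else 0
    rows[[length(rows) + 1]] <- data.frame(
      pair_id = "(pooled)", v_c = vc, fraction_interacting = pooled,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Randomised-pairing null distribution of same-time separations
#'
#' Draws random pairs of trajectories from different recordings, overlays
#' their time grids from the first sample, and accumulates the same-time
#' separation distances into a histogram. Serves as the null against which
#' observed separation histograms are compared: co-flying animals closer
#' than this null are closer than chance.
#'
#' @param trajectories list of `bsmi_trajectory` objects (>= 2).
#' @param n_draws number of random pairings.
#' @param seed RNG seed.
#' @param breaks histogram break points in metres (default 0.5 m bins up
#'   to just past the largest observed separation).
#' @return list with `breaks`, `counts`, `density` (normalised to unit
#'   mass) and the raw `separations`.
#' @export
randomized_pairing_null <- function(trajectories, n_draws, seed = 1, breaks = NULL) {
  stopifnot(length(trajectories) >= 2)
  set.seed(seed)
  seps <- numeric(0)
  if (n_draws > 0) {
    for (k in seq_len(n_draws)) {
      ij <- sample.int(length(trajectories), 2, replace = FALSE)
      a <- trajectories[[ij[1]]]
      b <- trajectories[[ij[2]]]
      m <- min(nrow(a$xy), nrow(b$xy))
      if (m < 1) stop("trajectories share no overlapping time grid")
      d <- sqrt((a$xy[1:m, 1] - b$xy[1:m, 1])^2 + (a$xy[1:m, 2] - b$xy[1:m, 2])^2)
      seps <- c(seps, d)
    }
  }
  if (is.null(breaks)) {
    top <- if (length(seps)) max(seps) else 1
    breaks <- seq(0, ceiling(top / 0.5) * 0.5 + 0.5, by = 0.5)
  }
  counts <- if (length(seps)) {
    graphics::hist(seps, breaks = breaks, plot = FALSE)$counts
  } else {
    rep(0L, length(breaks) - 1)
  }
  density <- if (sum(counts) > 0) counts / sum(counts) else rep(0, length(counts))
  list(breaks = breaks, counts = counts, density = density, separations = seps)
}

#' Flag pairs flying beyond mutual sonar range
#'
#' A pair whose separation never comes inside the reactor's `level`-dB
#' echo contour (taking the most favourable, on-axis geometry) cannot have
#' interacted acoustically; such recordings are reported so the analyst
#' can exclude them.
#'
#' @param pair a `bsmi_paired_trajectory`.
#' @param params a [sonar_params()].
#' @param level contour level in dB (default 0).
#' @return `TRUE` if the pair never comes within the on-axis `level`-dB
#'   range.
#' @export
beyond_sonar_range <- function(pair, params = sonar_params(), level = 0) {
  d <- sqrt(rowSums((pair$a$xy - pair$b$xy)^2))
  rng <- sonar_isocontour(params, level, n_angles = 3)
  max_range <- max(rng$rho)
  min(d) > max_range
}

#' Export a classification as delimited text plus a pooled JSON summary
#'
#' @param classified a `bsmi_classified_pair` or list of them.
#' @param file output table path; the pooled summary gets `.json`
#'   appended.
#' @param sep field separator.
#' @return `file`, invisibly.
#' @export
write_classification <- function(classified, file, sep = ",") {
  if (inherits(classified, "bsmi_classified_pair")) classified <- list(classified)
  tabs <- lapply(classified, function(cl) cbind(pair_id = cl$pair_id, cl$table))
  df <- do.call(rbind, tabs)
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  delays <- df$tau[!is.na(df$tau)]
  summary <- list(
    n_pairs = length(classified),
    n_times = nrow(df),
    fraction_unclassified = mean(df$label == "unclassified"),
    fraction_coordinated = mean(df$label == "coordinated"),
    fraction_chase = mean(df$label == "chase"),
    delay_histogram = if (length(delays)) {
      h <- graphics::hist(delays, breaks = "Sturges", plot = FALSE)
      list(breaks = h$breaks, counts = h$counts)
    } else {
      NULL
    }
  )
  jsonlite::write_json(summary, paste0(file, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}
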