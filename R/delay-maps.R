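#' Delayed directional correlation of one pair at one (t, tau)
#'
#' The instantaneous alignment measure: the normalised scalar product of
#' bat i's velocity at time t with bat j's velocity at time t + tau, i.e.
#' the cosine of their heading difference. 1 means perfect alignment, 0
#' orthogonal headings, -1 opposite headings. If either sample has zero
#' speed (undefined heading) the value is `NA`.
#'
#' @param pair a `bsmi_paired_trajectory` with kinematics (bat i = `a`,
#'   bat j = `b`).
#' @param t_idx integer sample index for bat i.
#' @param tau_idx integer delay offset in samples (tau = `tau_idx * dt`).
#' @return correlation in `[-1, 1]`, or `NA` for an undefined cell.
#' @export
directional_correlation <- function(pair, t_idx, tau_idx) {
  stopifnot(inherits(pair, "bsmi_paired_trajectory"))
  if (is.null(pair$a$heading)) pair <- pair_kinematics(pair)
  n <- nrow(pair$a$xy)
  j_idx <- t_idx + tau_idx
  if (t_idx < 1 || t_idx > n || j_idx < 1 || j_idx > n) return(NA_real_)
  hi <- pair$a$heading[t_idx]
  hj <- pair$b$heading[j_idx]
  if (is.na(hi) || is.na(hj)) return(NA_real_)
  cos(hi - hj)
}

# Common lattice for both map kinds: t rows are the samples whose whole
# +/-w window has defined kinematics for bat i; tau columns are the offsets
# for which at least one row also has bat j's window defined. Cells outside
# the domain, or touching a zero-speed sample, are NA. tau_max (seconds)
# optionally caps the delay range below its data-driven maximum.
delay_lattice <- function(pair, w, tau_max = Inf) {
  n <- nrow(pair$a$xy)
  # headings defined on (w+2) .. (n-w-1); window of +/-w shrinks each side
  a_lo <- 2 * w + 2
  a_hi <- n - 2 * w - 1
  if (a_hi < a_lo) {
    stop(sprintf("trajectory of %d samples too short for maps with w = %d", n, w))
  }
  t_idx <- a_lo:a_hi
  cap <- a_hi - a_lo
  if (is.finite(tau_max)) {
    cap <- min(cap, as.integer(floor(tau_max / pair$a$dt)))
  }
  tau_idx <- (-cap):cap
  list(t_idx = t_idx, tau_idx = tau_idx)
}

# Window-mean of a per-sample series g over +/-w; NA propagates, which
# implements the domain constraint (every sample of both windows in range).
window_mean <- function(g, w) {
  if (w == 0) return(g)
  as.numeric(stats::filter(g, rep(1 / (2 * w + 1), 2 * w + 1), sides = 2))
}

build_delay_map <- function(pair, w, kind, cell_series, tau_max = Inf) {
  lat <- delay_lattice(pair, w, tau_max)
  t_idx <- lat$t_idx
  tau_idx <- lat$tau_idx
  n <- nrow(pair$a$xy)
  values <- matrix(NA_real_, nrow = length(t_idx), ncol = length(tau_idx))
  a_lo <- t_idx[1]
  a_hi <- t_idx[length(t_idx)]
  for (ci in seq_along(tau_idx)) {
    m <- tau_idx[ci]
    s <- seq_len(n)
    valid <- s + m >= 1 & s + m <= n
    g <- rep(NA_real_, n)
    g[valid] <- cell_series(s[valid], s[valid] + m)
    gm <- window_mean(g, w)
    values[, ci] <- gm[t_idx]
    # both bats' windows must sit on the shared lattice, so correlation
    # and separation maps get identical defined domains
    values[t_idx + m < a_lo | t_idx + m > a_hi, ci] <- NA_real_
  }
  structure(
    list(
      kind = kind,
      values = values,
      t_idx = t_idx,
      tau_idx = tau_idx,
      t0 = pair$a$t0,
      dt = pair$a$dt,
      w = w,
      pair_id = pair$pair_id,
      i_id = pair$a$bat_id,
      j_id = pair$b$bat_id
    ),
    class = "bsmi_delay_map"
  )
}

#' Time-dependent delayed directional correlation (TDDC) map
#'
#' For every lattice cell (t, tau) the map holds the mean of the
#' instantaneous directional correlation over a symmetric window of
#' `2w + 1` samples centred at t, comparing bat i at `t + k dt` with bat j
#' at `t + tau + k dt`. Cells whose windows leave the recording, or touch a
#' zero-speed sample, are `NA`. High values at positive tau mean bat j is
#' copying bat i's heading tau seconds later (bat i acting, bat j
#' reacting).
#'
#' @param pair a `bsmi_paired_trajectory`.
#' @param w averaging half-window in samples (default 2, a five-point
#'   window at 20 ms resolution).
#' @param tau_max optional cap on the explored |tau| in seconds (default
#'   `Inf`, the full data-driven domain).
#' @return a `bsmi_delay_map` with `kind = "correlation"`.
#' @seealso [tdds()], [extract_coordinated_path()]
#' @export
tddc <- function(pair, w = 2, tau_max = Inf) {
  pair <- pair_kinematics(pair, w)
  hi <- pair$a$heading
  hj <- pair$b$heading
  build_delay_map(pair, w, "correlation", function(si, sj) cos(hi[si] - hj[sj]),
    tau_max = tau_max)
}

#' Time-dependent delayed separation (TDDS) map
#'
#' Window-mean Euclidean distance between bat i's smoothed position at
#' `t + k dt` and bat j's at `t + tau + k dt`. A near-zero cell at positive
#' tau means bat j is occupying the positions bat i held tau seconds
#' earlier, the signature of a chase. Computed on the same lattice as
#' [tddc()] so the two maps can be combined cell by cell.
#'
#' @inheritParams tddc
#' @return a `bsmi_delay_map` with `kind = "separation"`.
#' @export
tdds <- function(pair, w = 2, tau_max = Inf) {
  pair <- pair_kinematics(pair, w)
  sa <- pair$a$sxy
  sb <- pair$b$sxy
  build_delay_map(pair, w, "separation", function(si, sj) {
    sqrt((sa[si, 1] - sb[sj, 1])^2 + (sa[si, 2] - sb[sj, 2])^2)
  }, tau_max = tau_max)
}

#' @export
print.bsmi_delay_map <- function(x, ...) {
  cat(sprintf(
    "<bsmi_delay_map> %s, pair %s (i = %s, j = %s): %d x %d lattice, w = %d\n  t in [%.3f, %.3f] s, tau in [%.3f, %.3f] s, %.1f%% of cells defined\n",
    x$kind, x$pair_id, x$i_id, x$j_id, nrow(x$values), ncol(x$values), x$w,
    min(map_t_values(x)), max(map_t_values(x)),
    min(map_tau_values(x)), max(map_tau_values(x)),
    100 * mean(!is.na(x$values))
  ))
  invisible(x)
}

#' Lattice time values of a delay map (seconds)
#' @param map a `bsmi_delay_map`.
#' @return numeric vector, one value per row.
#' @export
map_t_values <- function(map) map$t0 + (map$t_idx - 1) * map$dt

#' Lattice delay values of a delay map (seconds)
#' @param map a `bsmi_delay_map`.
#' @return numeric vector, one value per column.
#' @export
map_tau_values <- function(map) map$tau_idx * map$dt

#' Export a delay map as delimited text plus a JSON sidecar
#'
#' Writes the dense value matrix with a header row of times and a leading
#' column of delays, and a small JSON file describing the lattice.
#'
#' @param map a `bsmi_delay_map`.
#' @param path output path for the matrix; the sidecar gets `.json`
#'   appended.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_delay_map <- function(map, path, sep = ",") {
  m <- t(map$values) # rows = tau, cols = t
  out <- cbind(map_tau_values(map), m)
  colnames(out) <- c("tau", sprintf("%.6g", map_t_values(map)))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    kind = map$kind, pair_id = map$pair_id, i_id = map$i_id, j_id = map$j_id,
    w = map$w, dt = map$dt, t0 = map$t0,
    t_idx_range = range(map$t_idx), tau_idx_range = range(map$tau_idx)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Contour plot of a delay map
#'
#' Renders the (t, tau) lattice as a filled image with optional threshold
#' contour, the visual companion of the extraction functions.
#'
#' @param x a `bsmi_delay_map`.
#' @param threshold optional level to contour (e.g. `v_c` for correlation
#'   maps or `d_c` for separation maps).
#' @param path optional `bsmi_interaction_path` to overlay.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.bsmi_delay_map <- function(x, threshold = NULL, path = NULL, ...) {
  tv <- map_t_values(x)
  tauv <- map_tau_values(x)
  graphics::image(tv, tauv, x$values,
    xlab = "t (s)", ylab = "tau (s)",
    main = sprintf("%s map, pair %s", x$kind, x$pair_id), ...
  )
  if (!is.null(threshold)) {
    graphics::contour(tv, tauv, x$values, levels = threshold, add = TRUE, lwd = 2)
  }
  if (!is.null(path)) {
    keep <- path$segment_kind != "none"
    graphics::points(path$t[keep], path$tau[keep], pch = 20, cex = 0.4)
  }
  invisible(x)
}
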