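#' Extraction configuration
#'
#' Thresholds and penalty controlling interaction-path extraction and
#' behaviour classification.
#'
#' @param v_c correlation threshold at and above which headings count as
#'   aligned (default 0.95, i.e. relative headings within about 18 degrees).
#' @param d_c chase separation threshold in metres (default 0.15, below a
#'   Daubenton's bat wingspan of ~0.25 m).
#' @param q penalty subtracted from a cell's correlation contribution when
#'   the extracted delay changes there (default 0.02); favours persistent,
#'   constant-delay interactions.
#' @param w smoothing / averaging half-window in samples (default 2).
#' @param tau_max optional cap on the explored |tau| in seconds (default
#'   `Inf`, the full data-driven range); delays beyond a second or two
#'   carry no biological meaning for this system and a finite cap speeds
#'   up large ensembles.
#' @return an object of class `bsmi_extraction_config`.
#' @export
extraction_config <- function(v_c = 0.95, d_c = 0.15, q = 0.02, w = 2,
                              tau_max = Inf) {
  if (!(v_c > 0 && v_c <= 1)) stop("v_c must be in (0, 1]")
  if (d_c <= 0) stop("d_c must be positive")
  if (q < 0) stop("q must be >= 0")
  if (tau_max <= 0) stop("tau_max must be positive")
  structure(
    list(v_c = v_c, d_c = d_c, q = q, w = as.integer(w), tau_max = tau_max),
    class = "bsmi_extraction_config"
  )
}

#' @export
print.bsmi_extraction_config <- function(x, ...) {
  cat(sprintf(
    "<bsmi_extraction_config> v_c = %g, d_c = %g m, q = %g, w = %d\n",
    x$v_c, x$d_c, x$q, x$w
  ))
  invisible(x)
}

new_interaction_path <- function(map, dp, segment_kind, kind) {
  tau_idx_path <- map$tau_idx[dp$path]
  structure(
    list(
      kind = kind,
      t_idx = map$t_idx,
      tau_idx_path = tau_idx_path,
      t = map$t0 + (map$t_idx - 1) * map$dt,
      tau = tau_idx_path * map$dt,
      tau_lo = rep(NA_real_, length(map$t_idx)),
      tau_hi = rep(NA_real_, length(map$t_idx)),
      segment_kind = segment_kind,
      score = dp$score,
      n_changes = dp$n_changes,
      cell_contrib = dp$cell_contrib,
      dt = map$dt,
      t0 = map$t0,
      pair_id = map$pair_id,
      i_id = map$i_id,
      j_id = map$j_id
    ),
    class = "bsmi_interaction_path"
  )
}

#' @export
print.bsmi_interaction_path <- function(x, ...) {
  frac <- mean(x$segment_kind != "none")
  cat(sprintf(
    "<bsmi_interaction_path> %s path, pair %s: %d times, %.1f%% classified, score %.4g, %d delay changes\n",
    x$kind, x$pair_id, length(x$t_idx), 100 * frac, x$score, x$n_changes
  ))
  invisible(x)
}

#' Extract the coordinated-flight interaction path from a TDDC map
#'
#' Finds, by dynamic programming over the (t, tau) lattice, the single
#' time-ordered delay path that maximises the cumulative thresholded
#' correlation. Super-threshold cells (`C >= v_c`) contribute their
#' correlation, minus the penalty `q` whenever the delay changes from the
#' previous time step; sub-threshold cells are traversable at zero
#' contribution, which is how the path crosses gaps between disjoint
#' interaction episodes. Transitions obey the time-ordering constraint
#' `dtau/dt >= -1`: the delay may increase by any lattice amount per step
#' but decrease by at most one step, so a reactor's responses keep the
#' order of the actor's actions. Ties are broken towards fewer delay
#' changes, then smaller cumulative |tau|.
#'
#' @param c_map a `bsmi_delay_map` of kind `"correlation"`.
#' @param cfg a [extraction_config()].
#' @param anchor optional chase path from [extract_chase_path()]; the
#'   returned path is forced to coincide with it on every chase-labelled
#'   time.
#' @return a `bsmi_interaction_path` whose `segment_kind` is
#'   `"coordinated"` where the path runs through super-threshold cells and
#'   `"none"` elsewhere (chase anchor times keep the label `"chase"`).
#' @export
extract_coordinated_path <- function(c_map, cfg = extraction_config(), anchor = NULL) {
  stopifnot(inherits(c_map, "bsmi_delay_map"), c_map$kind == "correlation")
  vals <- c_map$values
  super <- !is.na(vals) & vals >= cfg$v_c
  anchor_col <- integer(nrow(vals))
  if (!is.null(anchor)) {
    stopifnot(inherits(anchor, "bsmi_interaction_path"))
    if (!identical(anchor$t_idx, c_map$t_idx)) {
      stop("anchor path and correlation map do not share a lattice")
    }
    on_chase <- anchor$segment_kind == "chase"
    anchor_col[on_chase] <- match(anchor$tau_idx_path[on_chase], c_map$tau_idx)
  }
  dp <- .dp_extract_path(vals, super, abs(c_map$tau_idx), cfg$q, as.integer(anchor_col))
  kind <- ifelse(dp$on_super, "coordinated", "none")
  if (!is.null(anchor)) kind[anchor$segment_kind == "chase"] <- "chase"
  new_interaction_path(c_map, dp, kind, "coordinated")
}

#' Extract the chase interaction path from paired TDDC and TDDS maps
#'
#' Chase flight is the sub-category of coordinated flight in which the
#' follower also occupies the leader's past positions: qualifying cells
#' have `C >= v_c` and delayed separation `R <= d_c`. The extracted path
#' minimises the cumulative delayed separation over qualifying cells (each
#' such cell contributes `d_c - R`, less `q` when the delay changes),
#' under the same time-ordering constraint as the coordinated extraction.
#'
#' @param c_map correlation map.
#' @param r_map separation map on the identical lattice.
#' @param cfg a [extraction_config()].
#' @return a `bsmi_interaction_path` with `segment_kind = "chase"` on
#'   qualifying cells; if no cell qualifies, an empty path (all `"none"`,
#'   score 0) is returned.
#' @export
extract_chase_path <- function(c_map, r_map, cfg = extraction_config()) {
  stopifnot(
    inherits(c_map, "bsmi_delay_map"), c_map$kind == "correlation",
    inherits(r_map, "bsmi_delay_map"), r_map$kind == "separation"
  )
  if (!identical(c_map$t_idx, r_map$t_idx) || !identical(c_map$tau_idx, r_map$tau_idx)) {
    stop("correlation and separation maps do not share a lattice")
  }
  qualifying <- !is.na(c_map$values) & !is.na(r_map$values) &
    c_map$values >= cfg$v_c & r_map$values <= cfg$d_c
  gain <- ifelse(is.na(r_map$values), NA_real_, ifelse(qualifying, cfg$d_c - r_map$values, 0))
  dp <- .dp_extract_path(gain, qualifying, abs(r_map$tau_idx), cfg$q, integer(nrow(gain)))
  kind <- ifelse(dp$on_super, "chase", "none")
  path <- new_interaction_path(r_map, dp, kind, "chase")
  if (!any(qualifying)) {
    path$segment_kind[] <- "none"
    path$score <- 0
  }
  path
}

# contiguous run of TRUE around column j0 in a logical vector
run_around <- function(mask, j0) {
  if (!isTRUE(mask[j0])) return(c(NA_integer_, NA_integer_))
  lo <- j0
  while (lo > 1 && isTRUE(mask[lo - 1])) lo <- lo - 1
  hi <- j0
  while (hi < length(mask) && isTRUE(mask[hi + 1])) hi <- hi + 1
  c(lo, hi)
}

#' Asymmetric uncertainty bounds for an extracted interaction path
#'
#' For each classified time the raw bound is the contiguous super-threshold
#' delay interval containing the path (for chase samples, the contiguous
#' window where both the correlation and separation criteria hold, which is
#' intrinsically narrow). The bounds are then tightened by the
#' time-ordering constraint: a -1-gradient line is propagated forward in
#' time from each per-time minimum delay and backward from each per-time
#' maximum, clipping any raw bound the line undercuts while inside the same
#' classified episode. Straight parallel flight thus keeps wide bounds,
#' while a neighbouring high-curvature episode narrows them.
#'
#' @param c_map correlation map used for the extraction.
#' @param path a `bsmi_interaction_path`.
#' @param cfg a [extraction_config()].
#' @param r_map separation map; required when the path contains chase
#'   samples.
#' @return the path with `tau_lo` and `tau_hi` filled (seconds; `NA` on
#'   unclassified times).
#' @export
delay_uncertainty <- function(c_map, path, cfg = extraction_config(), r_map = NULL) {
  stopifnot(inherits(path, "bsmi_interaction_path"))
  if (!identical(path$t_idx, c_map$t_idx)) stop("path and map do not share a lattice")
  T_len <- length(path$t_idx)
  lo <- rep(NA_real_, T_len)
  hi <- rep(NA_real_, T_len)
  super <- !is.na(c_map$values) & c_map$values >= cfg$v_c
  qual <- NULL
  if (any(path$segment_kind == "chase")) {
    if (is.null(r_map)) stop("r_map is required to bound chase samples")
    qual <- super & !is.na(r_map$values) & r_map$values <= cfg$d_c
  }
  cols <- match(path$tau_idx_path, c_map$tau_idx)
  for (n in seq_len(T_len)) {
    kind <- path$segment_kind[n]
    if (kind == "none") next
    mask <- if (kind == "chase") qual[n, ] else super[n, ]
    rng <- run_around(mask, cols[n])
    lo[n] <- rng[1]
    hi[n] <- rng[2]
  }
  # -1 gradient propagation, restarted at each classified episode
  classified <- path$segment_kind != "none"
  for (n in seq_len(T_len)[-1]) {
    if (classified[n] && classified[n - 1]) {
      lo[n] <- max(lo[n], lo[n - 1] - 1)
    }
  }
  for (n in rev(seq_len(T_len))[-1]) {
    if (classified[n] && classified[n + 1]) {
      hi[n] <- min(hi[n], hi[n + 1] + 1)
    }
  }
  path$tau_lo <- ifelse(is.na(lo), NA_real_, c_map$tau_idx[pmax(lo, 1)] * c_map$dt)
  path$tau_hi <- ifelse(is.na(hi), NA_real_, c_map$tau_idx[pmin(hi, length(c_map$tau_idx))] * c_map$dt)
  path
}

#' Export an interaction path as delimited text
#'
#' Writes columns `t, tau, tau_lo, tau_hi, kind, score_contribution` plus a
#' JSON summary (total score, fraction classified).
#'
#' @param path a `bsmi_interaction_path`.
#' @param file output file path; the summary gets `.json` appended.
#' @param sep field separator.
#' @return `file`, invisibly.
#' @export
write_interaction_path <- function(path, file, sep = ",") {
  df <- data.frame(
    t = path$t,
    tau = path$tau,
    tau_lo = path$tau_lo,
    tau_hi = path$tau_hi,
    kind = path$segment_kind,
    score_contribution = path$cell_contrib,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, file, sep = sep, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      pair_id = path$pair_id, kind = path$kind, score = path$score,
      n_changes = path$n_changes,
      fraction_classified = mean(path$segment_kind != "none")
    ),
    paste0(file, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}
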