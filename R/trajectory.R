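#' Construct a single-bat trajectory
#'
#' A trajectory is a uniformly sampled 2-D path. Positions are given in
#' metres on a regular time grid; headings and speeds are filled in later by
#' [kinematics()] after moving-average smoothing. Times are carried as an
#' integer sample index internally (sample k corresponds to
#' `t0 + (k - 1) * dt`) so the (t, tau) lattice never suffers floating-point
#' drift.
#'
#' @param bat_id identifier of the individual.
#' @param xy two-column numeric matrix of (x, y) positions in metres.
#' @param t0 time of the first sample in seconds.
#' @param dt sampling interval in seconds (default 0.02, i.e. 50 Hz).
#' @return an object of class `bsmi_trajectory`.
#' @seealso [kinematics()], [paired_trajectory()]
#' @export
trajectory <- function(bat_id, xy, t0 = 0, dt = 0.02) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2) stop("xy must have two columns (x, y)")
  if (!is.numeric(xy) || anyNA(xy)) stop("positions must be numeric and complete")
  if (nrow(xy) < 2) stop("a trajectory needs at least 2 samples")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  structure(
    list(
      bat_id = as.character(bat_id),
      t0 = as.numeric(t0),
      dt = as.numeric(dt),
      xy = unname(xy),
      sxy = NULL,
      heading = NULL,
      speed = NULL,
      w = NULL
    ),
    class = "bsmi_trajectory"
  )
}

#' @export
print.bsmi_trajectory <- function(x, ...) {
  cat(sprintf(
    "<bsmi_trajectory> bat %s: %d samples, dt = %g s, t0 = %g s%s\n",
    x$bat_id, nrow(x$xy), x$dt, x$t0,
    if (is.null(x$heading)) "" else sprintf(", kinematics (w = %d)", x$w)
  ))
  invisible(x)
}

#' Number of samples in a trajectory
#' @param traj a `bsmi_trajectory`.
#' @return integer sample count.
#' @export
n_samples <- function(traj) nrow(traj$xy)

#' Time stamps of a trajectory
#' @param traj a `bsmi_trajectory`.
#' @return numeric vector of times in seconds.
#' @export
time_values <- function(traj) traj$t0 + (seq_len(nrow(traj$xy)) - 1) * traj$dt

#' Moving-average smoothing of a position sequence
#'
#' Each interior point becomes the unweighted mean of the `2w + 1`
#' surrounding raw points, per coordinate. The default `w = 2` (a five-point
#' window) suppresses the high-frequency jitter that pixel-level tracking
#' introduces. The first and last `w` samples have no complete window and
#' are returned as `NA`; downstream kinematics exclude them.
#'
#' @param xy two-column numeric matrix of positions.
#' @param w half-window sample count (window width `2w + 1`).
#' @return matrix of the same shape with `NA` rows at both ends.
#' @export
#' @examples
#' smooth_positions(cbind(c(0, 1, 4, 9, 16), 0), w = 2)[3, 1] # 6
smooth_positions <- function(xy, w = 2) {
  xy <- as.matrix(xy)
  w <- as.integer(w)
  if (w < 0) stop("w must be >= 0")
  n <- nrow(xy)
  if (n < 2 * w + 1) {
    stop(sprintf("sequence of length %d is shorter than the smoothing window 2w+1 = %d", n, 2 * w + 1))
  }
  if (w == 0) return(xy)
  kern <- rep(1 / (2 * w + 1), 2 * w + 1)
  out <- apply(xy, 2, function(col) as.numeric(stats::filter(col, kern, sides = 2)))
  unname(out)
}

#' Fill headings and speeds of a trajectory
#'
#' Smooths the raw positions with [smooth_positions()] and differentiates
#' the smoothed track by central differences: the velocity at sample k is
#' `(p[k+1] - p[k-1]) / (2 dt)`. The symmetric difference matches the
#' symmetric smoothing window. Headings are `atan2` of the velocity, wrapped
#' to (-pi, pi]; a zero-speed sample gets an `NA` heading. Samples within
#' `w + 1` of either end carry no heading or speed.
#'
#' @param traj a `bsmi_trajectory`.
#' @param w smoothing half-window (default 2).
#' @return the trajectory with `sxy`, `heading` and `speed` filled.
#' @export
kinematics <- function(traj, w = 2) {
  stopifnot(inherits(traj, "bsmi_trajectory"))
  n <- nrow(traj$xy)
  w <- as.integer(w)
  if (n < 2 * w + 2 || n < 3) {
    stop(sprintf("need at least %d samples for kinematics with w = %d", max(2 * w + 2, 3), w))
  }
  sxy <- smooth_positions(traj$xy, w)
  vx <- rep(NA_real_, n)
  vy <- rep(NA_real_, n)
  idx <- 2:(n - 1)
  vx[idx] <- (sxy[idx + 1, 1] - sxy[idx - 1, 1]) / (2 * traj$dt)
  vy[idx] <- (sxy[idx + 1, 2] - sxy[idx - 1, 2]) / (2 * traj$dt)
  speed <- sqrt(vx^2 + vy^2)
  heading <- ifelse(!is.na(speed) & speed > 0, atan2(vy, vx), NA_real_)
  heading[!is.na(heading)] <- wrap_angle(heading[!is.na(heading)])
  traj$sxy <- sxy
  traj$heading <- heading
  traj$speed <- speed
  traj$w <- w
  traj
}

#' Construct a paired trajectory
#'
#' Both members must share the same start time, sampling interval and
#' length, so the pair lives on a single common time grid.
#'
#' @param pair_id identifier of the pair.
#' @param a,b `bsmi_trajectory` objects for the two bats.
#' @return an object of class `bsmi_paired_trajectory`.
#' @export
paired_trajectory <- function(pair_id, a, b) {
  stopifnot(inherits(a, "bsmi_trajectory"), inherits(b, "bsmi_trajectory"))
  if (!isTRUE(all.equal(a$t0, b$t0)) || !isTRUE(all.equal(a$dt, b$dt))) {
    stop(sprintf("pair %s: members disagree on time grid (t0/dt)", pair_id))
  }
  if (nrow(a$xy) != nrow(b$xy)) {
    stop(sprintf("pair %s: members have different lengths (%d vs %d)", pair_id, nrow(a$xy), nrow(b$xy)))
  }
  structure(
    list(pair_id = as.character(pair_id), a = a, b = b),
    class = "bsmi_paired_trajectory"
  )
}

#' @export
print.bsmi_paired_trajectory <- function(x, ...) {
  cat(sprintf(
    "<bsmi_paired_trajectory> pair %s: bats %s, %s; %d samples at dt = %g s\n",
    x$pair_id, x$a$bat_id, x$b$bat_id, nrow(x$a$xy), x$a$dt
  ))
  invisible(x)
}

#' Ensure both members of a pair carry kinematics
#'
#' @param pair a `bsmi_paired_trajectory`.
#' @param w smoothing half-window.
#' @return the pair with kinematics filled on both members.
#' @export
pair_kinematics <- function(pair, w = 2) {
  stopifnot(inherits(pair, "bsmi_paired_trajectory"))
  if (is.null(pair$a$heading) || !identical(pair$a$w, as.integer(w))) {
    pair$a <- kinematics(pair$a, w)
  }
  if (is.null(pair$b$heading) || !identical(pair$b$w, as.integer(w))) {
    pair$b <- kinematics(pair$b, w)
  }
  pair
}

#' Read paired trajectories from a delimited text file
#'
#' Expects a header row `pair_id,bat_id,t,x,y` (comma or tab separated),
#' with `t` in seconds and `x`, `y` in metres. Rows are grouped by
#' `pair_id`; each pair must contain exactly two bats sampled on an
#' identical uniform time grid.
#'
#' @param path file path.
#' @param dt expected sampling interval; if `NULL` (default) it is inferred
#'   from the data.
#' @return named list of `bsmi_paired_trajectory` objects.
#' @export
read_trajectories <- function(path, dt = NULL) {
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  needed <- c("pair_id", "bat_id", "t", "x", "y")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing columns: %s", paste(missing_cols, collapse = ", ")))
  }
  out <- list()
  for (pid in unique(df$pair_id)) {
    rows <- df[df$pair_id == pid, , drop = FALSE]
    bats <- unique(rows$bat_id)
    if (length(bats) != 2) {
      stop(sprintf("pair %s has %d bat ids; exactly 2 required", pid, length(bats)))
    }
    trajs <- lapply(bats, function(bid) {
      sub <- rows[rows$bat_id == bid, , drop = FALSE]
      sub <- sub[order(sub$t), , drop = FALSE]
      dts <- diff(sub$t)
      if (length(dts) == 0) stop(sprintf("pair %s bat %s has a single sample", pid, bid))
      step <- if (is.null(dt)) stats::median(dts) else dt
      bad <- which(abs(dts - step) > 1e-6)
      if (length(bad) > 0) {
        stop(sprintf(
          "pair %s bat %s: non-uniform time grid at t = %g s (step %g, expected %g)",
          pid, bid, sub$t[bad[1]], dts[bad[1]], step
        ))
      }
      trajectory(bid, cbind(sub$x, sub$y), t0 = sub$t[1], dt = step)
    })
    out[[as.character(pid)]] <- paired_trajectory(pid, trajs[[1]], trajs[[2]])
  }
  out
}

#' Write paired trajectories to delimited text
#'
#' Inverse of [read_trajectories()]. With `audit = TRUE`, trajectories that
#' carry kinematics also get `heading` and `speed` columns.
#'
#' @param pairs list of `bsmi_paired_trajectory` objects (or a single one).
#' @param path output file path.
#' @param sep field separator (default comma).
#' @param audit include heading/speed columns where available.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(pairs, path, sep = ",", audit = FALSE) {
  if (inherits(pairs, "bsmi_paired_trajectory")) pairs <- list(pairs)
  rows <- lapply(pairs, function(p) {
    do.call(rbind, lapply(list(p$a, p$b), function(tr) {
      # %.17g keeps doubles exact through a write/read cycle
      df <- data.frame(
        pair_id = p$pair_id,
        bat_id = tr$bat_id,
        t = sprintf("%.17g", time_values(tr)),
        x = sprintf("%.17g", tr$xy[, 1]),
        y = sprintf("%.17g", tr$xy[, 2]),
        stringsAsFactors = FALSE
      )
      if (audit && !is.null(tr$heading)) {
        df$heading <- sprintf("%.17g", tr$heading)
        df$speed <- sprintf("%.17g", tr$speed)
      }
      df
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
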