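#' Relative geometry of one pair at one time
#'
#' Rotates and translates the actor's same-time position into the
#' reactor's frame: the reactor sits at the origin with its heading along
#' +y, and +x points to the reactor's right. Returns the separation
#' distance `d`, the relative heading `phi_rel` (angular difference of the
#' two velocity vectors), and the exposure angle `theta_exp` (signed angle
#' of the actor's position off the reactor's heading axis, in (-pi, pi]).
#' The extracted delay is used only for the role assignment upstream;
#' geometry here is instantaneous.
#'
#' @param pair a `bsmi_paired_trajectory` with kinematics.
#' @param t_idx integer sample index.
#' @param actor,reactor bat ids naming the roles at this time.
#' @return one-row data frame with `d, phi_rel, theta_exp, rel_x, rel_y`,
#'   or `NULL` if a heading is undefined at `t_idx`.
#' @export
relative_sample <- function(pair, t_idx, actor, reactor) {
  stopifnot(inherits(pair, "bsmi_paired_trajectory"))
  if (is.null(pair$a$heading)) pair <- pair_kinematics(pair)
  ids <- c(pair$a$bat_id, pair$b$bat_id)
  if (!(actor %in% ids) || !(reactor %in% ids) || actor == reactor) {
    stop("actor and reactor must name the two distinct members of the pair")
  }
  tr_a <- if (actor == pair$a$bat_id) pair$a else pair$b
  tr_r <- if (reactor == pair$a$bat_id) pair$a else pair$b
  h_r <- tr_r$heading[t_idx]
  h_a <- tr_a$heading[t_idx]
  if (is.na(h_r) || is.na(h_a)) return(NULL)
  delta <- tr_a$xy[t_idx, ] - tr_r$xy[t_idx, ]
  # reactor frame: +y along heading, +x to the right of it
  rel_y <- delta[1] * cos(h_r) + delta[2] * sin(h_r)
  rel_x <- delta[1] * sin(h_r) - delta[2] * cos(h_r)
  data.frame(
    d = sqrt(rel_x^2 + rel_y^2),
    phi_rel = angle_diff(h_a, h_r),
    theta_exp = atan2(rel_x, rel_y),
    rel_x = rel_x,
    rel_y = rel_y
  )
}

#' Relative-position samples for a classified pair
#'
#' One row per usable lattice time. For interacting times the reactor is
#' centred and the actor plotted; for unclassified times the centred bat is
#' picked at random once per pair (seed-controlled), since no role is
#' defined. Coordinated times with an unresolved role (`tau = 0`) use the
#' same random choice.
#'
#' @param classified a `bsmi_classified_pair` from [classify_pair()].
#' @param seed RNG seed for the random centre choice.
#' @return data frame with columns `pair_id, t_idx, t, label, d, phi_rel,
#'   theta_exp, rel_x, rel_y`.
#' @export
relative_samples <- function(classified, seed = 1) {
  stopifnot(inherits(classified, "bsmi_classified_pair"))
  pair <- pair_kinematics(classified$pair, classified$cfg$w)
  tab <- classified$table
  if (nrow(tab) == 0) {
    return(data.frame(
      pair_id = character(0), t_idx = integer(0), t = numeric(0),
      label = character(0), d = numeric(0), phi_rel = numeric(0),
      theta_exp = numeric(0), rel_x = numeric(0), rel_y = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  set.seed(derive_seed(seed, nrow(tab)))
  centre_first <- stats::runif(1) < 0.5
  default_reactor <- if (centre_first) pair$a$bat_id else pair$b$bat_id
  default_actor <- if (centre_first) pair$b$bat_id else pair$a$bat_id
  rows <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    actor <- tab$actor[k]
    reactor <- tab$reactor[k]
    if (is.na(actor) || is.na(reactor)) {
      actor <- default_actor
      reactor <- default_reactor
    }
    geom <- relative_sample(pair, tab$t_idx[k], actor, reactor)
    if (is.null(geom)) next
    rows[[k]] <- cbind(
      data.frame(
        pair_id = classified$pair_id, t_idx = tab$t_idx[k], t = tab$t[k],
        label = tab$label[k], stringsAsFactors = FALSE
      ),
      geom
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Normalised histograms of separation, |relative heading| and exposure
#' angle
#'
#' Builds, per behaviour label, unit-mass frequency histograms of the
#' separation distance, the absolute relative heading (folded to [0, pi])
#' and the signed exposure angle (wrapped on (-pi, pi]).
#'
#' @param samples data frame from [relative_samples()] (possibly several
#'   pairs row-bound together).
#' @param d_breaks breaks for the separation histogram in metres.
#' @param n_angle_bins number of angular bins (default 18, i.e. 10-degree
#'   resolution on the folded axis).
#' @return nested list: `result[[label]]$d / $abs_phi_rel / $theta_exp`,
#'   each with `breaks`, `counts`, `density` summing to 1.
#' @export
histogram_set <- function(samples, d_breaks = NULL, n_angle_bins = 18) {
  stopifnot(nrow(samples) > 0)
  if (is.null(d_breaks)) {
    d_breaks <- seq(0, ceiling(max(samples$d) / 0.5) * 0.5 + 0.5, by = 0.5)
  }
  phi_breaks <- seq(0, pi, length.out = n_angle_bins + 1)
  theta_breaks <- seq(-pi, pi, length.out = 2 * n_angle_bins + 1)
  one <- function(x, breaks) {
    counts <- graphics::hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE)$counts
    dens <- if (sum(counts) > 0) counts / sum(counts) else rep(0, length(counts))
    list(breaks = breaks, counts = counts, density = dens)
  }
  out <- list()
  for (lab in unique(samples$label)) {
    sub <- samples[samples$label == lab, , drop = FALSE]
    theta <- wrap_angle(sub$theta_exp)
    theta[theta == pi] <- pi - 1e-12 # keep the closed upper bin edge inside
    out[[lab]] <- list(
      d = one(sub$d, d_breaks),
      abs_phi_rel = one(abs(sub$phi_rel), phi_breaks),
      theta_exp = one(theta, theta_breaks),
      n = nrow(sub)
    )
  }
  out
}

#' Scatter plot of relative positions with optional sound-field contours
#'
#' Plots actor positions in the reactor frame (reactor at the origin,
#' heading up), coloured by behaviour label, optionally overlaying
#' isocontours of the reactor's echo-amplitude field.
#'
#' @param samples data frame from [relative_samples()].
#' @param params optional [sonar_params()]; when given, contours at
#'   `levels` are drawn.
#' @param levels contour levels in dB.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `samples`.
#' @export
plot_relative_positions <- function(samples, params = NULL, levels = c(0, 10, 20, 40), ...) {
  cols <- c(chase = "blue", coordinated = "darkgreen", unclassified = "grey60")
  graphics::plot(samples$rel_x, samples$rel_y,
    col = cols[samples$label], pch = 20, cex = 0.5, asp = 1,
    xlab = "x relative to reactor (m)", ylab = "y along reactor heading (m)", ...
  )
  if (!is.null(params)) {
    for (lv in levels) {
      contour <- sonar_isocontour(params, lv)
      graphics::lines(contour$x, contour$y, col = "red")
    }
  }
  invisible(samples)
}
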