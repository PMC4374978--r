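#' Specification of a synthetic ground-truth pair
#'
#' Describes one generated bat pair with known interaction structure, so
#' every stage of the analysis pipeline can be validated without field
#' data. Scenarios:
#' \describe{
#'   \item{independent}{two unrelated correlated random walks.}
#'   \item{coordinated}{the follower copies the leader's heading at the
#'     given lag, with narrow von Mises noise, drawing its own speeds.}
#'   \item{chase}{the follower occupies the leader's past positions at the
#'     given lag, plus optional positional noise.}
#'   \item{role_swap}{coordinated with leader and follower exchanging at
#'     the midpoint.}
#'   \item{piecewise_lag}{coordinated with the lag stepping through
#'     `lags` at evenly spaced change points.}
#'   \item{parallel_straight}{two straight, parallel, constant-speed
#'     tracks offset laterally; every delay is equally consistent.}
#'   \item{curved_then_parallel}{a deterministic winding phase followed by
#'     straight flight, the fixture for uncertainty-propagation checks.}
#' }
#'
#' @param scenario one of the scenario names above.
#' @param lag reaction lag in seconds (multiple of `dt`).
#' @param lags lag sequence for `piecewise_lag`.
#' @param kappa von Mises turning concentration of the leader's walk
#'   (default 557, as fitted to independent flight).
#' @param kappa_follow heading-noise concentration of the follower
#'   (default 2473, as fitted to chases).
#' @param speed_mu,speed_sigma Rician speed parameters in m/s.
#' @param constant_speed if non-`NULL`, use this fixed speed instead of
#'   Rician draws.
#' @param noise_sd positional measurement noise SD in metres (pixelation
#'   mimic; default 0).
#' @param offset follower's initial lateral offset in metres.
#' @param duration,dt time grid (seconds).
#' @param seed RNG seed.
#' @return an object of class `bsmi_synth_spec`.
#' @export
synth_spec <- function(scenario = c(
                         "independent", "coordinated", "chase", "role_swap",
                         "piecewise_lag", "parallel_straight", "curved_then_parallel"
                       ),
                       lag = 0.3, lags = c(0.1, 0.3), kappa = 557,
                       kappa_follow = 2473, speed_mu = 4.81, speed_sigma = 2.18,
                       constant_speed = NULL, noise_sd = 0, offset = 1.5,
                       duration = 10, dt = 0.02, seed = 1) {
  scenario <- match.arg(scenario)
  all_lags <- if (scenario == "piecewise_lag") lags else lag
  steps <- all_lags / dt
  if (any(abs(steps - round(steps)) > 1e-9)) stop("lags must be multiples of dt")
  if (duration < max(all_lags) + 1) stop("duration must be at least lag + 1 s")
  structure(
    list(
      scenario = scenario, lag = lag, lags = lags, kappa = kappa,
      kappa_follow = kappa_follow, speed_mu = speed_mu,
      speed_sigma = speed_sigma, constant_speed = constant_speed,
      noise_sd = noise_sd, offset = offset,
      duration = duration, dt = dt, seed = seed
    ),
    class = "bsmi_synth_spec"
  )
}

draw_speeds <- function(spec, n) {
  if (!is.null(spec$constant_speed)) rep(spec$constant_speed, n) else rrician(n, spec$speed_mu, spec$speed_sigma)
}

# correlated-random-walk heading series of length n from a start heading
crw_headings <- function(n, start, kappa) {
  out <- numeric(n)
  out[1] <- start
  for (k in 2:n) out[k] <- rvonmises(1, out[k - 1], kappa)
  out
}

integrate_track <- function(start, headings, speeds, dt) {
  dx <- speeds * dt * cos(headings)
  dy <- speeds * dt * sin(headings)
  cbind(start[1] + cumsum(dx) - dx[1], start[2] + cumsum(dy) - dy[1])
}

#' Generate a ground-truth-labelled synthetic pair
#'
#' Builds the leader as a correlated random walk (von Mises turning,
#' Rician speed) extended far enough into the past that lagged copies are
#' exact on the sample lattice, then derives the follower per scenario.
#' Heading-copy followers draw their own speeds (coordination couples
#' headings, not speeds); position-copy followers re-trace the leader's
#' track. Returns the per-time true label, lag and roles.
#'
#' @param spec a [synth_spec()].
#' @return list with `$pair` (a `bsmi_paired_trajectory`, bat ids
#'   `leader`/`follower`), `$truth` (data frame `t_idx, label, lag,
#'   actor`) and `$spec`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "bsmi_synth_spec"))
  set.seed(spec$seed)
  dt <- spec$dt
  n <- as.integer(round(spec$duration / dt))
  max_lag <- as.integer(round(max(if (spec$scenario == "piecewise_lag") spec$lags else spec$lag) / dt))
  sc <- spec$scenario

  truth_label <- rep(sc, n)
  truth_lag <- rep(spec$lag, n)
  truth_actor <- rep("leader", n)

  if (sc %in% c("parallel_straight", "curved_then_parallel")) {
    speed <- spec$constant_speed %||% spec$speed_mu
    L <- as.integer(round(spec$lag / dt))
    if (sc == "parallel_straight") {
      h_ext <- rep(0, n + max_lag)
    } else {
      # winding first half (heading oscillates), straight second half
      half <- floor((n + max_lag) / 2)
      tgrid <- seq_len(n + max_lag)
      h_ext <- c(
        1.2 * sin(2 * pi * tgrid[seq_len(half)] / 75),
        rep(1.2 * sin(2 * pi * half / 75), n + max_lag - half)
      )
    }
    h_lead <- h_ext[(max_lag + 1):(max_lag + n)]
    h_follow <- h_ext[(max_lag + 1 - L):(max_lag + n - L)]
    lead_xy <- integrate_track(c(0, 0), h_lead, rep(speed, n), dt)
    follow_xy <- integrate_track(c(0, spec$offset), h_follow, rep(speed, n), dt)
    truth_label[] <- "coordinated"
    truth_lag[] <- spec$lag
  } else if (sc == "independent") {
    h1 <- crw_headings(n, stats::runif(1, -pi, pi), spec$kappa)
    h2 <- crw_headings(n, stats::runif(1, -pi, pi), spec$kappa)
    lead_xy <- integrate_track(c(0, 0), h1, draw_speeds(spec, n), dt)
    follow_xy <- integrate_track(c(spec$offset, spec$offset), h2, draw_speeds(spec, n), dt)
    truth_label[] <- "independent"
    truth_lag[] <- NA_real_
    truth_actor[] <- NA_character_
  } else if (sc %in% c("coordinated", "chase", "piecewise_lag")) {
    h_ext <- crw_headings(n + max_lag, stats::runif(1, -pi, pi), spec$kappa)
    v_ext <- draw_speeds(spec, n + max_lag)
    xy_ext <- integrate_track(c(0, 0), h_ext, v_ext, dt)
    lead_xy <- xy_ext[(max_lag + 1):(max_lag + n), , drop = FALSE]
    if (sc == "chase") {
      L <- as.integer(round(spec$lag / dt))
      follow_xy <- xy_ext[(max_lag + 1 - L):(max_lag + n - L), , drop = FALSE]
      if (spec$noise_sd > 0) {
        follow_xy <- follow_xy + matrix(stats::rnorm(2 * n, 0, spec$noise_sd), n, 2)
      }
      truth_label[] <- "chase"
    } else {
      lag_steps <- if (sc == "piecewise_lag") {
        k <- length(spec$lags)
        bounds <- floor(seq(0, n, length.out = k + 1))
        rep(as.integer(round(spec$lags / dt)), times = diff(bounds))
      } else {
        rep(as.integer(round(spec$lag / dt)), n)
      }
      idx <- (max_lag + seq_len(n)) - lag_steps
      h_follow <- h_ext[idx] + rvonmises(n, 0, spec$kappa_follow)
      follow_xy <- integrate_track(lead_xy[1, ] + c(0, spec$offset), h_follow, draw_speeds(spec, n), dt)
      truth_label[] <- "coordinated"
      truth_lag <- lag_steps * dt
    }
  } else if (sc == "role_swap") {
    L <- as.integer(round(spec$lag / dt))
    mid <- floor(n / 2)
    # phase 1: a leads, b copies; phase 2: b leads on, a copies
    h_a <- numeric(n)
    h_b <- numeric(n)
    h_a[1:mid] <- crw_headings(mid, stats::runif(1, -pi, pi), spec$kappa)
    for (k in seq_len(mid)) {
      src <- max(k - L, 1)
      h_b[k] <- h_a[src] + rvonmises(1, 0, spec$kappa_follow)
    }
    for (k in (mid + 1):n) h_b[k] <- rvonmises(1, h_b[k - 1], spec$kappa)
    for (k in (mid + 1):n) h_a[k] <- h_b[k - L] + rvonmises(1, 0, spec$kappa_follow)
    lead_xy <- integrate_track(c(0, 0), h_a, draw_speeds(spec, n), dt)
    follow_xy <- integrate_track(c(0, spec$offset), h_b, draw_speeds(spec, n), dt)
    truth_label[] <- "coordinated"
    truth_actor <- rep(c("leader", "follower"), c(mid, n - mid))
  }

  a <- trajectory("leader", lead_xy, t0 = 0, dt = dt)
  b <- trajectory("follower", follow_xy, t0 = 0, dt = dt)
  if (spec$noise_sd > 0 && sc != "chase") {
    a <- add_observation_noise(a, spec$noise_sd, seed = spec$seed + 101L)
    b <- add_observation_noise(b, spec$noise_sd, seed = spec$seed + 202L)
  }
  list(
    pair = paired_trajectory(sprintf("synth_%s_%d", sc, spec$seed), a, b),
    truth = data.frame(
      t_idx = seq_len(n), label = truth_label, lag = truth_lag,
      actor = truth_actor, stringsAsFactors = FALSE
    ),
    spec = spec
  )
}

#' Add isotropic Gaussian observation noise to a trajectory
#'
#' Mimics pixelation and measurement error of video tracking: independent
#' Gaussian jitter per sample and coordinate. The moving-average smoothing
#' of the analysis pipeline is designed to suppress exactly this kind of
#' white noise.
#'
#' @param traj a `bsmi_trajectory`.
#' @param sd noise standard deviation in metres (>= 0).
#' @param seed RNG seed.
#' @return the trajectory with jittered raw positions (kinematics, if
#'   present, are dropped and must be recomputed).
#' @export
add_observation_noise <- function(traj, sd, seed = 1) {
  stopifnot(inherits(traj, "bsmi_trajectory"), sd >= 0)
  if (sd == 0) return(traj)
  set.seed(seed)
  n <- nrow(traj$xy)
  traj$xy <- traj$xy + matrix(stats::rnorm(2 * n, 0, sd), n, 2)
  traj$sxy <- NULL
  traj$heading <- NULL
  traj$speed <- NULL
  traj$w <- NULL
  traj
}
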