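# Independent brute-force oracle for the time-ordered path extraction:
# exhaustively enumerates every path over the lattice that satisfies the
# time-ordering constraint (delay may drop by at most one column per row),
# accumulating the same lexicographic objective the extractor optimises
# (max score, then min delay changes, then min cumulative |tau|).
# Tractable only on small lattices; deliberately shares no code with the
# dynamic programme.
oracle_best_value <- function(gain, super, abs_tau, q, anchor = integer(nrow(gain))) {
  T_ <- nrow(gain)
  J <- ncol(gain)
  best <- NULL
  lex_gt <- function(a, b) {
    if (a[1] != b[1]) return(a[1] > b[1])
    if (a[2] != b[2]) return(a[2] < b[2])
    a[3] < b[3]
  }
  rec <- function(n, j_prev, score, changes, sumabs) {
    if (n > T_) {
      val <- c(score, changes, sumabs)
      if (is.null(best) || lex_gt(val, best)) best <<- val
      return(invisible(NULL))
    }
    for (j in seq_len(J)) {
      if (is.na(gain[n, j])) next
      if (anchor[n] > 0 && anchor[n] != j) next
      if (n > 1 && j < j_prev - 1) next
      changed <- n > 1 && j != j_prev
      contrib <- if (super[n, j]) gain[n, j] - (if (changed) q else 0) else 0
      rec(n + 1, j, score + contrib, changes + as.integer(changed), sumabs + abs_tau[j])
    }
  }
  rec(1L, NA_integer_, 0, 0L, 0)
  best
}

# random DP instance on a small lattice; a fraction of cells is blocked
random_dp_instance <- function(T_, J, seed, na_prob = 0.08, v_c = 0.9) {
  set.seed(seed)
  gain <- matrix(stats::runif(T_ * J, 0.6, 1), T_, J)
  gain[stats::runif(T_ * J) < na_prob] <- NA_real_
  super <- !is.na(gain) & gain >= v_c
  abs_tau <- abs(seq_len(J) - ceiling(J / 2))
  list(gain = gain, super = super, abs_tau = as.numeric(abs_tau), q = 0.02)
}

# deterministic constant-speed fixtures used by several test files
make_straight_pair <- function(n = 200, speed = 5, offset = 1, heading = 0, dt = 0.02) {
  steps <- (seq_len(n) - 1) * speed * dt
  a <- trajectory("leader", cbind(steps * cos(heading), steps * sin(heading)), dt = dt)
  b <- trajectory(
    "follower",
    cbind(steps * cos(heading) - offset * sin(heading), steps * sin(heading) + offset * cos(heading)),
    dt = dt
  )
  paired_trajectory("parallel", a, b)
}

# closed-form Rician mean via the Laguerre half polynomial
rician_mean_exact <- function(mu, sigma) {
  x <- -mu^2 / (2 * sigma^2)
  l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) - x * besselI(-x / 2, 1))
  sigma * sqrt(pi / 2) * l_half
}
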