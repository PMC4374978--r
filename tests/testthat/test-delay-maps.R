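test_that("directional correlation matches the cosine of the heading difference", {
  n <- 60
  dt <- 0.02
  mk <- function(ang) {
    steps <- (seq_len(n) - 1) * 5 * dt
    trajectory("x", cbind(steps * cos(ang), steps * sin(ang)), dt = dt)
  }
  for (ang in c(0, pi / 2, pi / 6, 2)) {
    p <- pair_kinematics(paired_trajectory("p", mk(0), mk(ang)))
    expect_equal(directional_correlation(p, 30, 0), cos(ang), tolerance = 1e-9)
  }
  expect_equal(directional_correlation(pair_kinematics(paired_trajectory("p", mk(0), mk(pi / 6))), 30, 0),
    cos(pi / 6),
    tolerance = 1e-9
  ) # 30 degrees apart -> 0.8660
})

test_that("TDDC of parallel straight flight is 1 on every defined cell", {
  p <- make_straight_pair(n = 80)
  cm <- tddc(p)
  expect_true(all(abs(cm$values[!is.na(cm$values)] - 1) < 1e-12))
  expect_true(all(cm$values >= -1 - 1e-12 & cm$values <= 1 + 1e-12, na.rm = TRUE))
})

test_that("a heading-copy follower lights up the TDDC column at the true lag", {
  g <- generate_pair(synth_spec("coordinated", lag = 0.2, duration = 5, seed = 5))
  cm <- tddc(g$pair)
  col <- which(cm$tau_idx == 10) # 0.2 s / 0.02 s
  vals <- cm$values[, col]
  expect_gt(mean(vals[!is.na(vals)] >= 0.999), 0.95)
})

test_that("TDDS vanishes at the true lag of an exact position copy and respects geometry", {
  g <- generate_pair(synth_spec("chase", lag = 0.2, duration = 5, seed = 5))
  rm_ <- tdds(g$pair)
  col <- which(rm_$tau_idx == 10)
  vals <- rm_$values[, col]
  expect_lt(max(vals[!is.na(vals)]), 1e-10)
  expect_true(all(rm_$values >= 0, na.rm = TRUE))

  # parallel tracks offset 1 m: separations never dip below the offset,
  # with equality at the matched delay
  p <- make_straight_pair(n = 80, offset = 1)
  rm2 <- tdds(p)
  expect_true(all(rm2$values >= 1 - 1e-9, na.rm = TRUE))
  col0 <- which(rm2$tau_idx == 0)
  expect_equal(min(rm2$values[, col0], na.rm = TRUE), 1, tolerance = 1e-9)
})

test_that("swap symmetry holds: the (i,j) map equals the (j,i) map under t -> t + tau, tau -> -tau", {
  g <- generate_pair(synth_spec("coordinated", lag = 0.1, duration = 3, seed = 8, noise_sd = 0.01))
  swapped <- paired_trajectory("sw", g$pair$b, g$pair$a)
  for (fn in list(tddc, tdds)) {
    m_ij <- fn(g$pair)
    m_ji <- fn(swapped)
    for (ri in seq(1, length(m_ij$t_idx), by = 7)) {
      for (ci in seq(1, length(m_ij$tau_idx), by = 11)) {
        v <- m_ij$values[ri, ci]
        if (is.na(v)) next
        a <- m_ij$t_idx[ri]
        m <- m_ij$tau_idx[ci]
        ri2 <- match(a + m, m_ji$t_idx)
        ci2 <- match(-m, m_ji$tau_idx)
        expect_equal(m_ji$values[ri2, ci2], v, tolerance = 1e-9)
      }
    }
  }
})

test_that("window means never exceed the window maximum and widening w shrinks the domain", {
  g <- generate_pair(synth_spec("coordinated", lag = 0.1, duration = 3, seed = 2))
  cm2 <- tddc(g$pair, w = 2)
  cm4 <- tddc(g$pair, w = 4)
  expect_true(all(cm2$values <= 1 + 1e-12, na.rm = TRUE))
  expect_lt(sum(!is.na(cm4$values)), sum(!is.na(cm2$values)))
  # w = 4 domain is a subset of the w = 2 domain (on the shared sub-lattice)
  common_t <- intersect(cm4$t_idx, cm2$t_idx)
  common_tau <- intersect(cm4$tau_idx, cm2$tau_idx)
  def4 <- !is.na(cm4$values[match(common_t, cm4$t_idx), match(common_tau, cm4$tau_idx)])
  def2 <- !is.na(cm2$values[match(common_t, cm2$t_idx), match(common_tau, cm2$tau_idx)])
  expect_true(all(!def4 | def2))
})

test_that("zero-speed samples poison their map cells as undefined, not zero", {
  n <- 60
  dt <- 0.02
  xy <- cbind(c(seq(0, 2, length.out = 30), rep(2, 10), seq(2, 4, length.out = 20)), 0)
  a <- trajectory("stop", xy, dt = dt)
  steps <- (seq_len(n) - 1) * 5 * dt
  b <- trajectory("go", cbind(steps, 0), dt = dt)
  cm <- tddc(paired_trajectory("p", a, b))
  col0 <- which(cm$tau_idx == 0)
  stopped_rows <- which(cm$t_idx %in% 33:37) # deep inside the stationary stretch
  expect_true(all(is.na(cm$values[stopped_rows, col0])))
})

test_that("delay maps export to text with a JSON sidecar", {
  p <- make_straight_pair(n = 40)
  cm <- tddc(p)
  f <- tempfile(fileext = ".csv")
  write_delay_map(cm, f)
  expect_true(file.exists(f))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$kind, "correlation")
  expect_equal(side$w, 2)
})
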