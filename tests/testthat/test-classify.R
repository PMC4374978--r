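test_that("a heading-copy pair is labelled coordinated with the leader as actor", {
  g <- generate_pair(synth_spec("coordinated", lag = 0.3, duration = 8, seed = 42))
  cl <- classify_pair(g$pair)
  expect_gt(cl$summary$fraction_interacting, 0.8)
  tab <- cl$table[cl$table$label != "unclassified", ]
  expect_gt(mean(tab$actor == "leader", na.rm = TRUE), 0.8)
  # the per-pair median delay pins the true lag to one sample; individual
  # samples wander within their (wide, straight-flight) uncertainty bands
  expect_lte(abs(median(tab$tau) - 0.3), 0.02 + 1e-9)
  expect_gt(mean(abs(tab$tau - 0.3) <= 0.02 + 1e-9), 0.6)
})

test_that("an exact position copy is labelled chase, a subset of the coordination criterion", {
  g <- generate_pair(synth_spec("chase", lag = 0.2, duration = 6, seed = 7))
  cl <- classify_pair(g$pair, keep_maps = TRUE)
  expect_gt(cl$summary$fraction_chase, 0.8)
  # every chase (and coordinated) sample satisfies C >= v_c at the
  # extracted delay; chase samples additionally satisfy R <= d_c
  cm <- cl$maps$c_map
  rm_ <- cl$maps$r_map
  tab <- cl$table
  for (k in which(tab$label != "unclassified")) {
    row <- match(tab$t_idx[k], cm$t_idx)
    col <- match(round(tab$tau[k] / cm$dt), cm$tau_idx)
    expect_gte(cm$values[row, col], cl$cfg$v_c)
    if (tab$label[k] == "chase") {
      expect_lte(rm_$values[row, col], cl$cfg$d_c)
    }
  }
})

test_that("an independent pair stays essentially unclassified", {
  g <- generate_pair(synth_spec("independent", duration = 6, seed = 3))
  cl <- classify_pair(g$pair)
  expect_lt(cl$summary$fraction_interacting, 0.1)
})

test_that("a mid-recording leader swap flips the extracted roles", {
  g <- generate_pair(synth_spec("role_swap", lag = 0.2, duration = 10, seed = 12))
  cl <- classify_pair(g$pair)
  tab <- cl$table[!is.na(cl$table$actor), ]
  n <- nrow(cl$table)
  early <- tab[tab$t_idx < cl$table$t_idx[1] + 0.35 * n, ]
  late <- tab[tab$t_idx > cl$table$t_idx[1] + 0.65 * n, ]
  expect_gt(nrow(early), 20)
  expect_gt(nrow(late), 20)
  expect_gt(mean(early$actor == "leader"), 0.8)
  expect_gt(mean(late$actor == "follower"), 0.8)
})

test_that("role assignment is antisymmetric under swapping the pair order", {
  g <- generate_pair(synth_spec("coordinated", lag = 0.2, duration = 5, seed = 6))
  cl_ab <- classify_pair(g$pair)
  cl_ba <- classify_pair(paired_trajectory("sw", g$pair$b, g$pair$a))
  on <- cl_ab$table$label != "unclassified" & cl_ba$table$label != "unclassified" &
    !is.na(cl_ab$table$actor) & !is.na(cl_ba$table$actor)
  expect_gt(sum(on), 50)
  expect_gt(mean(cl_ab$table$actor[on] == cl_ba$table$actor[on]), 0.95)
})

test_that("a too-short recording degrades to an all-unclassified result with a warning", {
  xy <- cbind(seq(0, 0.2, length.out = 10), 0)
  p <- paired_trajectory("tiny", trajectory("a", xy), trajectory("b", xy + 0.5))
  expect_warning(cl <- classify_pair(p), "degenerate")
  expect_equal(cl$summary$fraction_interacting, 0)
  expect_true(cl$degenerate)
})

test_that("interacting fraction is non-increasing in the correlation threshold", {
  g <- generate_pair(synth_spec("coordinated", lag = 0.2, duration = 5, seed = 17, kappa_follow = 300))
  sweep <- sensitivity_sweep(g$pair, v_c_values = c(0.85, 0.9, 0.95, 0.99))
  pooled <- sweep[sweep$pair_id == "(pooled)", ]
  expect_true(all(diff(pooled$fraction_interacting) <= 1e-12))
  expect_gte(pooled$fraction_interacting[1], pooled$fraction_interacting[3])

  # a noiseless copy is insensitive to the threshold in this range
  perfect <- make_straight_pair(n = 150)
  sweep2 <- sensitivity_sweep(perfect, v_c_values = c(0.85, 0.95, 0.99))
  fr <- sweep2[sweep2$pair_id == "(pooled)", "fraction_interacting"]
  expect_equal(fr[1], fr[2])
  expect_equal(fr[2], fr[3])
})

test_that("randomised pairing null reflects the geometry of its inputs", {
  # a trajectory paired with its own laterally shifted copy
  steps <- seq(0, 8, by = 0.1)
  a <- trajectory("a", cbind(steps, 0))
  b <- trajectory("b", cbind(steps, 3))
  null <- randomized_pairing_null(list(a, b), n_draws = 5, seed = 1)
  expect_true(all(null$separations >= 3 - 1e-12))

  # zero draws give an empty histogram
  null0 <- randomized_pairing_null(list(a, b), n_draws = 0, seed = 1)
  expect_equal(sum(null0$counts), 0)

  # two clusters 50 m apart dominate the null at ~50 m
  near <- lapply(1:3, function(k) trajectory(paste0("n", k), cbind(steps + k * 0.1, 0)))
  far <- lapply(1:3, function(k) trajectory(paste0("f", k), cbind(steps + k * 0.1, 50)))
  set.seed(2)
  null2 <- randomized_pairing_null(c(near, far), n_draws = 40, seed = 2)
  mids <- (null2$breaks[-1] + null2$breaks[-length(null2$breaks)]) / 2
  heavy <- sum(null2$density[mids > 45 & mids < 55])
  expect_gt(heavy, 0.4)
})

test_that("pairs flying beyond sonar range are flagged", {
  steps <- seq(0, 8, by = 0.1)
  near <- paired_trajectory(
    "near", trajectory("a", cbind(steps, 0)),
    trajectory("b", cbind(steps, 2))
  )
  far <- paired_trajectory(
    "far", trajectory("a", cbind(steps, 0)),
    trajectory("b", cbind(steps, 100))
  )
  expect_false(beyond_sonar_range(near))
  expect_true(beyond_sonar_range(far))
})
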