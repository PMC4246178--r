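test_that("maximum leaf elongation follows the two-branch thermal response", {
  p <- params_with(T_b = 6.8, T_opt = 28, a_Elmax = 0.10, b_Elmax = -0.02)
  # zero at the base temperature
  expect_equal(leaf_elongation_max(6.8, 1, p), 0)
  expect_equal(leaf_elongation_max(4, 1, p), 0)
  # (25 - 6.8) * (0.10 - 0.02 * 1)
  expect_equal(leaf_elongation_max(25, 1, p), 1.456)
  # supra-optimal branch mirrors the sub-optimal one about T_opt
  expect_equal(leaf_elongation_max(31, 1, p), leaf_elongation_max(25, 1, p))
  # far above the optimum the mirrored branch clamps at zero
  expect_equal(leaf_elongation_max(60, 1, p), 0)
})

test_that("bell-shaped thermal-time response has unit peak and e^-0.5 shoulders", {
  expect_equal(bell_effect(200, 200, 50), 1)
  expect_equal(bell_effect(250, 200, 50), exp(-0.5))
  expect_equal(bell_effect(150, 200, 50), exp(-0.5))
  ts <- seq(200, 600, by = 25)
  expect_true(all(diff(bell_effect(ts, 200, 50)) < 0))
  expect_error(bell_effect(1, 1, 0), "width")
})

test_that("rank effect peaks at R_max and freezes above rank 13", {
  p <- params_with(R_max = 9, h = 4)
  expect_equal(rank_effect(9, p), 1)
  expect_equal(rank_effect(5, p), exp(-0.5))
  expect_equal(rank_effect(20, p), rank_effect(13, p))
  expect_error(rank_effect(0, p), "rank")
})

test_that("leaf elongation is the product of its three factors", {
  p <- params_with(T_b = 6.8, T_opt = 28, a_Elmax = 0.10, b_Elmax = -0.02,
                   TS_lmax = 200, h_l = 50, R_max = 9, h = 4)
  expect_equal(leaf_elongation(6.8, 1, 200, 9, p), 0)
  # unit factors at the bell centre and peak rank
  expect_equal(leaf_elongation(25, 1, 200, 9, p), leaf_elongation_max(25, 1, p))
  # product of the component worked examples
  expect_equal(leaf_elongation(25, 1, 250, 5, p), 1.456 * exp(-0.5) * exp(-0.5),
               tolerance = 1e-12)
})

test_that("leaf area follows the power law", {
  p <- params_with(a_Al = 0.3, g = 1.8)
  expect_equal(leaf_area(0, p), 0)
  expect_equal(leaf_area(10, p), 0.3 * 10^1.8)
  expect_equal(leaf_area(20, p) / leaf_area(10, p), 2^1.8)
})

test_that("leaf appearance rate is logarithmic, capped at 30 C and continuous", {
  p <- params_with(a_r = 1.0, b_r = 2.5)
  expect_equal(leaf_appearance_rate(20, p), log(20) - 2.5)
  expect_equal(leaf_appearance_rate(32, p), leaf_appearance_rate(30, p))
  expect_equal(leaf_appearance_rate(30 - 1e-9, p), leaf_appearance_rate(30 + 1e-9, p),
               tolerance = 1e-9)
  expect_equal(leaf_appearance_rate(p$T_b, p), 0)
})

test_that("leaf angle saturates at its asymptote", {
  p <- params_with(a_theta = 100, b_theta = 0.05)
  expect_equal(leaf_angle(0, p), 0)
  expect_equal(leaf_angle(20, p), 100 * (1 - exp(-1)))
  expect_lt(abs(leaf_angle(50 / 0.05, p) - 100), 1e-6)
})

test_that("leaf curvature is piecewise linear, continuous and non-negative", {
  p <- params_with(a_Cl = 120, b_Cl = 1.0, b1_Cl = 0.5)
  expect_equal(leaf_curvature(30, p), 90)
  expect_lt(abs(leaf_curvature(50, p) - leaf_curvature(50 + 1e-9, p)), 1e-6)
  expect_true(all(leaf_curvature(seq(0, 400, by = 10), p) >= 0))
})

test_that("internode elongation and diameter follow their closed forms", {
  p <- params_with(T_bi = 8, a_Eimax = 0.08, b_Eimax = 1e-4,
                   TS_imax = 150, h_i = 60)
  expect_equal(internode_elongation(8, 400, 150, p), 0)
  expect_equal(internode_elongation(24, 400, 150, p), 16 * 0.04)
  # strictly decreasing in PAR while positive
  vals <- internode_elongation(24, c(0, 200, 400, 600), 150, p)
  expect_true(all(diff(vals) < 0))
  p2 <- params_with(a_Di = 0.3, b_Di = 0.001)
  expect_equal(internode_diameter(0, p2), 0.3)
  expect_equal(internode_diameter(200, p2), 0.5)
  expect_equal(internode_diameter(400, p2) - internode_diameter(200, p2),
               internode_diameter(200, p2) - internode_diameter(0, p2))
})

test_that("a day at the base temperatures changes nothing", {
  p <- params_with(T_bi = 6.8)
  st <- new_plant_state(p)
  rec <- data.frame(day = 1, T = 6.8, VPD = 1, PAR = 400, Q0_daily = 0)
  st2 <- advance_plant(st, rec, p)
  expect_equal(st2$leaves$TS, st$leaves$TS)
  expect_equal(st2$leaves$length, st$leaves$length)
  expect_equal(st2$internodes$length, st$internodes$length)
  expect_equal(nrow(st2$leaves), nrow(st$leaves))
})

test_that("a new leaf and internode appear when the accumulator crosses an integer", {
  # constant appearance rate of 0.2 leaves per day
  p <- params_with(a_r = 0, b_r = -0.2)
  st <- new_plant_state(p)
  st$leaf_accumulator <- nrow(st$leaves) + 0.9
  rec <- data.frame(day = 1, T = 20, VPD = 1, PAR = 400, Q0_daily = 0)
  st2 <- advance_plant(st, rec, p)
  expect_equal(nrow(st2$leaves), nrow(st$leaves) + 1)
  expect_equal(nrow(st2$internodes), nrow(st$internodes) + 1)
  expect_equal(st2$leaves$TS[nrow(st2$leaves)], 0)
  expect_equal(st2$leaves$length[nrow(st2$leaves)], 0)
})

test_that("organ sizes are non-decreasing and area tracks the power law over a noisy climate", {
  p <- default_parameters()
  cl <- synthesize_climate("LT", 40, seed = 7)
  g <- grow_plant(p, cl)
  for (r in c(1, 5, 8)) {
    lv <- g$leaves[g$leaves$rank == r, ]
    expect_true(all(diff(lv$length) >= 0))
    expect_equal(lv$area, leaf_area(lv$length, p))
    iv <- g$internodes[g$internodes$rank == r, ]
    expect_true(all(diff(iv$length) >= 0))
    expect_true(all(diff(iv$diameter) >= 0))
  }
  expect_true(all(diff(g$daily$height_cm) >= 0))
  expect_true(all(diff(g$daily$leaf_area_cm2) >= 0))
})

test_that("warmer series produce at least as many leaves, senescence is absorbing", {
  p <- params_with(TS_lsen = 150)
  lt <- grow_plant(p, synthesize_climate("LT", 60, seed = 3))
  ht <- grow_plant(p, synthesize_climate("HT", 60, seed = 3))
  expect_true(all(ht$daily$leaf_number >= lt$daily$leaf_number))
  lv1 <- lt$leaves[lt$leaves$rank == 1, ]
  expect_true(any(lv1$senescent))
  first <- min(which(lv1$senescent))
  expect_true(all(lv1$senescent[first:nrow(lv1)]))
  expect_true(all(lv1$TS[lv1$senescent] > p$TS_lsen))
  # senescent leaves keep their area
  expect_true(all(lv1$area[lv1$senescent] > 0))
})

test_that("constant-climate trajectories match an independent cumulative-sum oracle", {
  p <- default_parameters()
  cl <- tiny_climate(77, T = 22, VPD = 1, PAR = 400, p = p)
  g <- grow_plant(p, cl)

  # independent day-by-day recomputation with plain arithmetic
  rate <- p$a_r * log(22) - p$b_r
  acc <- p$initial_leaf_number
  leaves_TS <- rep(0, p$initial_leaf_number)
  leaves_len <- rep(0, p$initial_leaf_number)
  int_TS <- rep(0, p$initial_leaf_number)
  int_len <- rep(0, p$initial_leaf_number)
  for (d in 1:77) {
    leaves_TS <- leaves_TS + (22 - p$T_b)
    r <- seq_along(leaves_len)
    el <- (22 - p$T_b) * (p$a_Elmax + p$b_Elmax * 1) *
      exp(-0.5 * ((leaves_TS - p$TS_lmax) / p$h_l)^2) *
      exp(-0.5 * ((pmin(r, 13) - p$R_max) / p$h)^2)
    leaves_len <- leaves_len + pmax(0, el)
    int_TS <- int_TS + (22 - p$T_bi)
    ei <- (22 - p$T_bi) * (p$a_Eimax - p$b_Eimax * 400) *
      exp(-0.5 * ((int_TS - p$TS_imax) / p$h_i)^2)
    int_len <- int_len + pmax(0, ei)
    n_new <- floor(acc + rate) - floor(acc)
    acc <- acc + rate
    if (n_new > 0) {
      leaves_TS <- c(leaves_TS, rep(0, n_new))
      leaves_len <- c(leaves_len, rep(0, n_new))
      int_TS <- c(int_TS, rep(0, n_new))
      int_len <- c(int_len, rep(0, n_new))
    }
  }
  final <- g$states[[77]]
  expect_equal(length(leaves_len), nrow(final$leaves))
  expect_equal(final$leaves$length, leaves_len, tolerance = 1e-9)
  expect_equal(final$leaves$TS, leaves_TS, tolerance = 1e-9)
  expect_equal(final$internodes$length, int_len, tolerance = 1e-9)
  expect_equal(plant_height(final), sum(int_len), tolerance = 1e-9)
})
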