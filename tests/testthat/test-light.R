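test_that("a black horizontal leaf intercepts all vertical light; ground below stays dark", {
  leaf <- rect_tris(0, 1, 0, 1, 0.5)
  ground <- rect_tris(0, 1, 0, 1, 0)
  sc <- scene_from_triangles(rbind(leaf, ground), c(1, 1, 2, 2),
                             rbind(c(0, 0, 0, 0), c(0.8, 0, 0, 0)),
                             c("leaf", "ground"))
  r <- trace(sc, sky_model("collimated", n_rays = 20000,
                           emitter_margin_m = 0, seed = 2), Q0_daily = 1)
  expect_equal(r$absorbed[1], 1, tolerance = 0.01)
  expect_equal(r$absorbed[2], 0)
  expect_equal(r$absorbed_total + r$escaped, r$emitted, tolerance = 1e-9)
})

test_that("adaxial optics absorb 90.3% of intercepted flux on first contact", {
  p <- default_parameters()
  leaf <- rect_tris(0, 1, 0, 1, 0.5)
  optics <- matrix(c(p$leaf_reflectance_adaxial, p$leaf_transmittance_adaxial,
                     p$leaf_reflectance_abaxial, p$leaf_transmittance_abaxial), 1)
  sc <- scene_from_triangles(leaf, c(1, 1), optics, "leaf")
  r <- trace(sc, sky_model("collimated", n_rays = 20000,
                           emitter_margin_m = 0, seed = 2), Q0_daily = 1)
  # 1 - 0.073 - 0.024 of the unit incident flux; no return path to the leaf
  expect_equal(r$absorbed[1], 0.903, tolerance = 1e-9)
})

test_that("bare reflective ground absorbs 20% and reflects the rest to the sky", {
  g <- rect_tris(0, 2, 0, 2, 0)
  sc <- scene_from_triangles(g, c(1, 1), matrix(c(0.8, 0, 0, 0), 1), "ground")
  r <- trace(sc, sky_model("collimated", n_rays = 30000,
                           emitter_margin_m = 0, seed = 3), Q0_daily = 1)
  expect_equal(r$absorbed_total / r$emitted, 0.2, tolerance = 1e-9)
  expect_equal(r$escaped / r$emitted, 0.8, tolerance = 1e-9)
})

test_that("sensor transmission is 1 under open sky and 0 under an opaque slab", {
  sens <- rect_tris(0, 1, 0, 1, 0)
  sc <- scene_from_triangles(sens, c(1, 1), matrix(0, 1, 4), "sensor")
  r <- trace(sc, sky_model("collimated", n_rays = 10000,
                           emitter_margin_m = 0, seed = 4), Q0_daily = 1)
  expect_equal(sensor_transmission(r), 1, tolerance = 1e-9)

  slab <- rect_tris(-1, 2, -1, 2, 0.5)
  sc2 <- scene_from_triangles(rbind(slab, sens), c(1, 1, 2, 2),
                              rbind(c(0, 0, 0, 0), c(0, 0, 0, 0)),
                              c("leaf", "sensor"))
  r2 <- trace(sc2, sky_model("collimated", n_rays = 10000,
                             emitter_margin_m = 0, seed = 4), Q0_daily = 1)
  expect_equal(sensor_transmission(r2), 0)
  r_nosens <- r2
  r_nosens$sensor_idx <- integer(0)
  expect_error(sensor_transmission(r_nosens), "no sensors")
})

test_that("extinction coefficient inverts Beer-Lambert's law", {
  expect_equal(estimate_k(1, 2), 0)
  expect_equal(estimate_k(exp(-1), 2), 0.5)
  # printed canopy state: transmission 0.67 with k 0.71 implies LAI 0.564
  lai <- -log(0.67) / 0.71
  expect_equal(lai, 0.5640, tolerance = 1e-4)
  expect_equal(estimate_k(0.67, lai), 0.71, tolerance = 1e-12)
  expect_error(estimate_k(0, 1), "> 0")
  expect_error(estimate_k(0.5, 0), "LAI")
})

test_that("tracing is bit-reproducible for a fixed seed and differs across seeds", {
  p <- default_parameters()
  st <- grow_plant(p, tiny_climate(20))$states[[20]]
  sc <- build_canopy(rep(list(st), 16), p, as.list(1:16), sensors = TRUE)
  r1 <- trace(sc, sky_model(n_rays = 5000, seed = 9), 1e6)
  r2 <- trace(sc, sky_model(n_rays = 5000, seed = 9), 1e6)
  expect_identical(r1, r2)
  r3 <- trace(sc, sky_model(n_rays = 5000, seed = 10), 1e6)
  expect_false(identical(r1$absorbed, r3$absorbed))
  # energy accounting closes
  expect_equal(r1$absorbed_total + r1$escaped, r1$emitted, tolerance = 1e-6)
  # both samplers work and agree within Monte-Carlo error on totals
  r4 <- trace(sc, sky_model(n_rays = 5000, seed = 9, sampler = "low_discrepancy"), 1e6)
  expect_equal(r4$absorbed_total / r4$emitted, r1$absorbed_total / r1$emitted,
               tolerance = 0.05)
})

test_that("adding leaf area above the sensors never increases transmission", {
  sens <- rect_tris(0.5, 1.5, 0.5, 1.5, 0)
  optics_leaf <- matrix(c(0.073, 0.024, 0.127, 0.025), 1)
  qts <- sapply(c(0, 1, 2), function(nl) {
    v <- sens
    surf <- c(1L, 1L)
    kinds <- "sensor"
    optics <- matrix(0, 1, 4)
    if (nl >= 1) {
      v <- rbind(v, rect_tris(0.4, 1.1, 0.4, 1.1, 0.6))
      surf <- c(surf, 2L, 2L)
      kinds <- c(kinds, "leaf")
      optics <- rbind(optics, optics_leaf)
    }
    if (nl >= 2) {
      v <- rbind(v, rect_tris(0.9, 1.6, 0.9, 1.6, 0.8))
      surf <- c(surf, 3L, 3L)
      kinds <- c(kinds, "leaf")
      optics <- rbind(optics, optics_leaf)
    }
    sc <- scene_from_triangles(v, surf, optics, kinds)
    sensor_transmission(trace(sc, sky_model("collimated", n_rays = 20000,
                                            emitter_margin_m = 0, seed = 5), 1))
  })
  expect_true(all(diff(qts) < 0))
})

test_that("doubling the ray budget shrinks the Monte-Carlo standard error", {
  p <- default_parameters()
  st <- grow_plant(p, tiny_climate(20))$states[[20]]
  sc <- build_canopy(rep(list(st), 16), p, as.list(1:16), sensors = TRUE)
  se_at <- function(n) {
    r <- trace(sc, sky_model(n_rays = n, seed = 21), 1e6)
    mean(r$sensor_se)
  }
  ratio <- se_at(16000) / se_at(4000)
  # expect roughly 1/2 (factor-4 budget), loosely bounded for MC noise
  expect_lt(ratio, 0.85)
})
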