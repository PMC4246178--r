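leaf_row <- function(length, p, scenario = NULL) {
  data.frame(rank = 8, appearance_day = 0, TS = 0, length = length,
             area = leaf_area(length, p), angle = leaf_angle(length, p),
             curvature = leaf_curvature(length, p), senescent = FALSE)
}

test_that("a leaf mesh has seven rhombus leaflets whose areas realize the reference fractions", {
  p <- default_parameters()
  lf <- leaf_row(40, p)
  m <- build_leaf(lf, p)
  expect_equal(nrow(m$lamina), 14 * 3)  # 7 rhombi, 2 triangles each
  a <- triangle_areas(m$lamina)
  # total lamina area equals the leaf area (cm2 -> m2) exactly up to float
  expect_equal(sum(a), lf$area * 1e-4, tolerance = 5e-3)
  # terminal rhombus (last two triangles) carries 16% of the lamina
  expect_equal(sum(a[13:14]) / sum(a), 0.16, tolerance = 1e-9)
  expect_equal(nrow(build_leaf(leaf_row(0, p), p)$lamina), 0)
})

test_that("an unbent leaf lies along a single direction", {
  p <- default_parameters()
  lf <- leaf_row(40, p)
  lf$angle <- 90   # horizontal insertion
  lf$curvature <- 0
  m <- build_leaf(lf, p)
  # all lamina vertices at the same height, leaflet pairs balance about the rachis
  expect_lt(diff(range(m$lamina[, 3])), 1e-9)
  rhombus_cent <- sapply(1:7, function(r) colMeans(m$lamina[6 * r - 5:0, ]))
  pair_y <- rhombus_cent[2, c(1, 3, 5)] + rhombus_cent[2, c(2, 4, 6)]
  expect_lt(max(abs(pair_y)), 1e-12)
  expect_lt(abs(rhombus_cent[2, 7]), 1e-12)  # terminal leaflet on the midrib plane
})

test_that("phyllotaxis steps are exact without jitter and the mesh is seed-deterministic", {
  p <- default_parameters()
  cl <- tiny_climate(30)
  st <- grow_plant(p, cl)$states[[30]]
  m0 <- build_plant(st, NULL, p)
  # with jitter disabled consecutive leaves differ by exactly 144 degrees;
  # the lamina centroid lies in each leaf's vertical plane, so its azimuth
  # is the leaf azimuth
  leaf_sids <- which(m0$surfaces$kind == "leaf")
  az <- sapply(leaf_sids, function(s) {
    vv <- m0$v[rep(m0$surface == s, each = 3), , drop = FALSE]
    if (!nrow(vv)) return(NA_real_)
    cent <- colMeans(vv)
    atan2(cent[2], cent[1]) * 180 / pi
  })
  az <- az[!is.na(az)]
  steps <- diff(az) %% 360
  expect_true(all(abs(steps - 144) < 1e-6))
  m1 <- build_plant(st, 42, p)
  m2 <- build_plant(st, 42, p)
  expect_identical(m1, m2)
  expect_false(isTRUE(all.equal(m1$v, m0$v)))
})

test_that("plant mesh height equals the summed internode lengths", {
  p <- default_parameters()
  st <- grow_plant(p, tiny_climate(30))$states[[30]]
  st$leaves$length <- 0  # bare stem: the mesh top is the last cylinder
  m <- build_plant(st, NULL, p)
  expect_equal(max(m$v[, 3]), plant_height(st) * 0.01, tolerance = 1e-9)
})

test_that("canopy assembly is additive, tags the focal centre and places four unit sensors", {
  p <- params_with(stem_facets = 4)
  st <- grow_plant(p, tiny_climate(15))$states[[15]]
  pm <- build_plant(st, NULL, p)
  sc <- build_canopy(rep(list(st), 16), p, NULL, sensors = TRUE)
  n_plant_tris <- nrow(pm$v) / 3
  expect_equal(nrow(sc$v) / 3, 16 * n_plant_tris + 2 + 8)
  expect_error(build_canopy(rep(list(st), 9), p), "16 plants")
  # focal plants are the 2x2 centre of the 4x4 grid
  focal_plants <- unique(sc$surfaces$plant[sc$surfaces$focal])
  pos <- (focal_plants - 1) %% 4 + 1
  row <- (focal_plants - 1) %/% 4 + 1
  expect_setequal(pos, c(2, 3))
  expect_setequal(row, c(2, 3))
  sens <- sc$surfaces[sc$surfaces$kind == "sensor", ]
  expect_equal(nrow(sens), 4)
  expect_equal(sens$area_m2, rep(1, 4), tolerance = 1e-9)
  # no sensors unless requested
  sc0 <- build_canopy(rep(list(st), 16), p, NULL, sensors = FALSE)
  expect_equal(sum(sc0$surfaces$kind == "sensor"), 0)
})

test_that("canopy lamina area matches the growth state within tessellation tolerance", {
  p <- default_parameters()
  st <- grow_plant(p, synthesize_climate("LT", 40, 2))$states[[40]]
  sc <- build_canopy(rep(list(st), 16), p, as.list(1:16))
  per_plant <- tapply(sc$surfaces$area_m2[sc$surfaces$kind == "leaf"],
                      sc$surfaces$plant[sc$surfaces$kind == "leaf"], sum)
  expect_equal(as.numeric(per_plant), rep(plant_leaf_area(st) * 1e-4, 16),
               tolerance = 5e-3)
})

test_that("scenario multipliers act on the geometry exactly", {
  p <- default_parameters()
  lf <- leaf_row(35, p)
  m_scaled <- build_leaf(lf, p, scenario_spec(angle_mult = 1.3))
  lf2 <- lf
  lf2$angle <- lf$angle * 1.3
  m_direct <- build_leaf(lf2, p)
  expect_equal(m_scaled, m_direct)
  # internode multiplier stretches the stem without touching growth state
  st <- grow_plant(p, tiny_climate(20))$states[[20]]
  st$leaves$length <- 0  # bare stem isolates the cylinder stack
  m1 <- build_plant(st, NULL, p)
  m2 <- build_plant(st, NULL, p, scenario_spec(internode_mult = 1.3))
  expect_equal(max(m2$v[, 3]) / max(m1$v[, 3]), 1.3, tolerance = 1e-9)
})

test_that("mesh exporters write valid OBJ and PLY", {
  p <- default_parameters()
  st <- grow_plant(p, tiny_climate(10))$states[[10]]
  m <- build_plant(st, NULL, p)
  f_obj <- withr::local_tempfile(fileext = ".obj")
  write_obj(m, f_obj)
  lines <- readLines(f_obj)
  expect_equal(sum(startsWith(lines, "v ")), nrow(m$v))
  expect_equal(sum(startsWith(lines, "f ")), nrow(m$v) / 3)
  f_ply <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, f_ply)
  lines <- readLines(f_ply)
  expect_equal(lines[1], "ply")
  expect_equal(sum(grepl("^3 ", lines)), nrow(m$v) / 3)
})
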