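# Triangle-soup geometry. A mesh is a list(v, surface):
#   v       - numeric matrix (3 * n_tri) x 3, rows 3i-2..3i are triangle i
#   surface - integer per triangle, indexing a surface table
# The winding defines the front side: front normal = (v2-v1) x (v3-v1).
# Leaves are wound so the front is the adaxial (upper) side. Scene
# coordinates are metres, right-handed, z up, ground plane z = 0.

CM <- 0.01  # growth-model lengths (cm) to scene metres

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# two triangles for a rhombus: base at `base`, long diagonal d_l along unit
# `axis`, short diagonal d_w along unit `wdir`; front normal = axis x wdir
rhombus_tris <- function(base, axis, wdir, d_l, d_w) {
  tip <- base + d_l * axis
  mid <- base + (d_l / 2) * axis
  r <- mid + (d_w / 2) * wdir
  l <- mid - (d_w / 2) * wdir
  rbind(base, r, tip, base, tip, l)
}

# open cylinder (no caps) from `base` along unit `axis`; returns 2*facets tris
cylinder_tris <- function(base, axis, length, radius, facets) {
  tpl <- cylinder_template(facets)
  u <- perp_unit(axis)
  v <- cross3(axis, u)
  # columns of tpl: (cx, cy, z01) in unit-cylinder coordinates
  matrix(base, nrow(tpl), 3, byrow = TRUE) +
    radius * outer(tpl[, 1], u) + radius * outer(tpl[, 2], v) +
    outer(length * tpl[, 3], axis)
}

cylinder_template <- local({
  cache <- list()
  function(facets) {
    key <- as.character(facets)
    if (!is.null(cache[[key]])) return(cache[[key]])
    th <- 2 * pi * (0:facets) / facets
    x <- cos(th); y <- sin(th)
    tris <- vector("list", facets)
    for (i in seq_len(facets)) {
      a0 <- c(x[i], y[i], 0); a1 <- c(x[i + 1], y[i + 1], 0)
      b0 <- c(x[i], y[i], 1); b1 <- c(x[i + 1], y[i + 1], 1)
      tris[[i]] <- rbind(a0, a1, b1, a0, b1, b0)
    }
    out <- do.call(rbind, tris)
    cache[[key]] <<- out
    out
  }
})

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

perp_unit <- function(a) {
  u <- if (abs(a[1]) < 0.9) cross3(a, c(1, 0, 0)) else cross3(a, c(0, 1, 0))
  u / sqrt(sum(u^2))
}

#' Triangle areas of a mesh, m2
#' @param v Vertex matrix of a triangle soup ((3 n) x 3).
#' @return Numeric vector of per-triangle areas.
#' @export
triangle_areas <- function(v) {
  n <- nrow(v) / 3
  i1 <- 3 * seq_len(n) - 2
  e1 <- v[i1 + 1, , drop = FALSE] - v[i1, , drop = FALSE]
  e2 <- v[i1 + 2, , drop = FALSE] - v[i1, , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Build the 3D mesh of one leaf
#'
#' The leaf is built in its local frame: insertion at the origin, parent
#' stem along +z, the leaf extending towards +x. A four-segment rachis
#' polyline leaves the stem at the insertion angle theta from the stem axis
#' and bends by the three curvature angles alpha1..alpha3 (base to tip,
#' curvature split by `curvature_ratio`) at the lateral-leaflet nodes. Seven
#' flat rhombus leaflets (three opposite pairs at the nodes plus a terminal
#' leaflet at the tip) carry the lamina: leaflet i receives
#' `leaflet_area_fractions[i]` of the leaf area per side, with
#' length:width = `leaflet_lw_ratio`, so the lamina mesh area equals the
#' leaf area exactly. The rachis is rendered as thin cylinders.
#'
#' @param leaf One row of a `plant_state$leaves` frame (length, area, angle,
#'   curvature in growth units).
#' @param p Parameter set.
#' @param scenario Optional [scenario_spec()] whose geometry multipliers
#'   (leaf angle, curvature, leaflet shape) are applied to the organ-model
#'   outputs at build time.
#' @param insertion_z_m Height of the insertion point above the ground,
#'   metres. When finite, rachis segments that would droop below the ground
#'   are rotated up just enough to rest on it — a rigid, area-preserving
#'   adjustment (leaves trail along the ground instead of passing through
#'   it). `Inf` (the default) disables the adjustment.
#' @return List with `lamina` and `rachis` vertex matrices (metres); a leaf
#'   of zero length yields empty matrices.
#' @export
build_leaf <- function(leaf, p, scenario = NULL, insertion_z_m = Inf) {
  L <- leaf$length * CM
  if (L <= 0) return(list(lamina = matrix(0, 0, 3), rachis = matrix(0, 0, 3)))
  A <- leaf$area * CM^2
  theta <- leaf$angle
  Cl <- leaf$curvature
  ratio <- p$curvature_ratio
  fr <- p$leaflet_area_fractions
  lw <- p$leaflet_lw_ratio
  if (!is.null(scenario)) {
    theta <- min(179, max(0, theta * scenario$angle_mult))
    Cl <- max(0, Cl * scenario$curvature_mult)
    if (!is.null(scenario$curvature_ratio)) ratio <- scenario$curvature_ratio
    if (!is.null(scenario$leaflet_fractions)) {
      fr <- scenario$leaflet_fractions
      fr <- fr / (2 * sum(fr[1:3]) + fr[4])
    }
    if (!is.null(scenario$lw_ratio)) lw <- scenario$lw_ratio
  }
  alphas <- Cl * ratio / sum(ratio)
  seg_len <- p$rachis_fractions * L
  # rachis polyline: pitch from +z axis, bending at nodes 1..3
  pitch <- pmin(theta + c(0, cumsum(alphas)), 180)  # per segment, degrees
  floor_m <- 2e-3
  if (is.finite(insertion_z_m)) {
    z <- insertion_z_m
    for (s in 1:4) {
      min_cos <- (floor_m - z) / seg_len[s]
      if (cos(pitch[s] * pi / 180) < min_cos)
        pitch[s] <- acos(max(-1, min(1, min_cos))) * 180 / pi
      z <- z + seg_len[s] * cos(pitch[s] * pi / 180)
    }
  }
  dirs <- cbind(sin(pitch * pi / 180), 0, cos(pitch * pi / 180))
  nodes <- apply(dirs * seg_len, 2, cumsum)      # 4 x 3, end of each segment
  nodes <- rbind(c(0, 0, 0), nodes)
  rachis <- vector("list", 4)
  for (s in 1:4) {
    rachis[[s]] <- cylinder_tris(nodes[s, ], dirs[s, ], seg_len[s],
                                 p$petiole_radius_cm * CM, p$stem_facets)
  }
  lam <- vector("list", 7)
  k <- 0
  for (j in 1:3) {
    Aj <- fr[j] * A
    d_l <- sqrt(2 * Aj * lw); d_w <- d_l / lw
    t <- dirs[j + 1, ]                            # tangent past the node
    node_z <- if (is.finite(insertion_z_m)) insertion_z_m + nodes[j + 1, 3] else Inf
    for (s in c(1, -1)) {
      side <- c(0, s, 0)
      # front normal = axis x wdir; choose wdir so the normal has +z
      wdir <- if (s > 0) -t else t
      # tilt the rhombus up about its (horizontal) axis if it would dip
      # below the ground: rigid rotation, area preserved
      max_wz <- 2 * (node_z - floor_m) / d_w
      if (is.finite(max_wz) && abs(wdir[3]) > max_wz) {
        wz <- sign(wdir[3]) * max(0, min(1, max_wz))
        wx <- (if (wdir[1] != 0) sign(wdir[1]) else -s) * sqrt(1 - wz^2)
        wdir <- c(wx, 0, wz)
      }
      k <- k + 1
      lam[[k]] <- rhombus_tris(nodes[j + 1, ], side, wdir, d_l, d_w)
    }
  }
  At <- fr[4] * A
  d_l <- sqrt(2 * At * lw); d_w <- d_l / lw
  tdir <- dirs[4, ]
  if (is.finite(insertion_z_m)) {
    tip_z <- insertion_z_m + nodes[5, 3]
    min_az <- -max(0, min(1, (tip_z - floor_m) / d_l))
    if (tdir[3] < min_az) tdir <- c(sqrt(1 - min_az^2), 0, min_az)
  }
  k <- k + 1
  lam[[k]] <- rhombus_tris(nodes[5, ], tdir, c(0, 1, 0), d_l, d_w)
  list(lamina = do.call(rbind, lam), rachis = do.call(rbind, rachis))
}

#' Build the 3D mesh of one plant
#'
#' Internode cylinders (length `L_i`, diameter `D_i`) stack along +z from
#' the origin; leaf k is inserted at the top of internode k with azimuth
#' `azimuth(k-1) + phyllotaxis + jitter_k`, jitter uniform in +- the
#' configured jitter width. Identical seeds give bit-identical meshes.
#'
#' @param state A `plant_state`.
#' @param phyllotaxis_seed Integer seed for the azimuth jitter; `NULL`
#'   disables jitter (exact 144 degree steps).
#' @param p Parameter set.
#' @param scenario Optional [scenario_spec()]; the internode-length
#'   multiplier rescales cylinder lengths (and leaf insertion heights) at
#'   build time without touching the growth state.
#' @param leaf_cache Optional precomputed list of [build_leaf()] outputs by
#'   rank (shared across plants whose growth states are identical).
#' @return List of class `plant_mesh`: `v`, per-triangle `surface`, and a
#'   `surfaces` data frame (kind = "leaf"/"stem", rank).
#' @export
build_plant <- function(state, phyllotaxis_seed = NULL, p = default_parameters(),
                        scenario = NULL, leaf_cache = NULL) {
  n <- nrow(state$leaves)
  imult <- if (is.null(scenario)) 1 else scenario$internode_mult
  ilen <- state$internodes$length * CM * imult
  tops <- cumsum(ilen)
  bases <- tops - ilen
  jitter <- if (is.null(phyllotaxis_seed)) rep(0, n) else
    with_seed(phyllotaxis_seed,
              stats::runif(n, -p$phyllotaxis_jitter_deg, p$phyllotaxis_jitter_deg))
  azimuth <- cumsum(p$phyllotaxis_deg + jitter)
  blocks <- vector("list", 2 * n)
  surface <- vector("list", 2 * n)
  for (k in seq_len(n)) {
    stem_tris <- if (ilen[k] > 0)
      cylinder_tris(c(0, 0, bases[k]), c(0, 0, 1), ilen[k],
                    state$internodes$diameter[k] / 2 * CM, p$stem_facets)
    else matrix(0, 0, 3)
    leafm <- if (!is.null(leaf_cache)) leaf_cache[[k]] else
      build_leaf(state$leaves[k, ], p, scenario, insertion_z_m = tops[k])
    R <- rot_z(azimuth[k])
    lam <- leafm$lamina %*% t(R)
    rac <- leafm$rachis %*% t(R)
    lam[, 3] <- lam[, 3] + tops[k]
    rac[, 3] <- rac[, 3] + tops[k]
    blocks[[2 * k - 1]] <- lam
    surface[[2 * k - 1]] <- rep.int(2 * k - 1, nrow(lam) / 3)
    blocks[[2 * k]] <- rbind(stem_tris, rac)
    surface[[2 * k]] <- rep.int(2 * k, (nrow(stem_tris) + nrow(rac)) / 3)
  }
  surfaces <- data.frame(kind = rep(c("leaf", "stem"), n),
                         rank = rep(seq_len(n), each = 2))
  out <- list(v = do.call(rbind, blocks),
              surface = unlist(surface),
              surfaces = surfaces)
  class(out) <- "plant_mesh"
  out
}

#' Assemble a canopy scene
#'
#' Places plants on a square grid (default 4 x 4 at 1 m spacing) over a
#' white ground rectangle (80% reflectance, no transmittance). The four
#' central grid positions are tagged focal; optionally four 1 m2 virtual
#' sensor rectangles (no reflectance, no transmittance) are laid just above
#' the ground in the middle of the focal plants. Leaf vertices that a
#' strongly drooping leaf would push below ground are clamped just above it.
#'
#' @param plants List of `plant_state`s, one per grid cell (`canopy_grid`^2).
#' @param p Parameter set.
#' @param phyllotaxis_seeds Integer vector (one per plant) or `NULL` for
#'   jitter-free construction.
#' @param sensors Logical: add the virtual transmission sensors.
#' @param scenario Optional [scenario_spec()].
#' @return A `canopy_scene`: `v`, `surface`, `surfaces` (id, kind, plant,
#'   rank, focal, area_m2), `optics` (per surface: refl_front, trans_front,
#'   refl_back, trans_back), and the scene extent.
#' @export
build_canopy <- function(plants, p = default_parameters(),
                         phyllotaxis_seeds = NULL, sensors = FALSE,
                         scenario = NULL) {
  grid <- p$canopy_grid
  n_pl <- grid^2
  if (length(plants) != n_pl)
    stop("need exactly ", n_pl, " plants for a ", grid, "x", grid, " canopy",
         call. = FALSE)
  if (is.null(phyllotaxis_seeds)) phyllotaxis_seeds <- rep(list(NULL), n_pl)
  spacing <- p$plant_spacing_m
  L <- grid * spacing
  shared <- length(unique(vapply(plants, function(s) s$day, numeric(1)))) == 1
  leaf_cache <- NULL
  if (shared && n_pl > 1) {
    # all plants share one growth state: build each rank's leaf once
    st <- plants[[1]]
    imult <- if (is.null(scenario)) 1 else scenario$internode_mult
    tops <- cumsum(st$internodes$length * CM * imult)
    leaf_cache <- lapply(seq_len(nrow(st$leaves)), function(k)
      build_leaf(st$leaves[k, ], p, scenario, insertion_z_m = tops[k]))
  }
  blocks <- vector("list", n_pl + 2)
  surface <- vector("list", n_pl + 2)
  surf_tabs <- vector("list", n_pl + 2)
  sid0 <- 0
  centre_idx <- c(2, 3)  # focal rows/cols of the 4x4 grid (scaled for others)
  if (grid != 4) centre_idx <- unique(pmin(pmax(round(grid / 2) + c(0, 1), 1), grid))
  for (i in seq_len(n_pl)) {
    gx <- (i - 1) %% grid + 1
    gy <- (i - 1) %/% grid + 1
    pm <- build_plant(plants[[i]], phyllotaxis_seeds[[i]], p, scenario, leaf_cache)
    off <- c((gx - 0.5) * spacing, (gy - 0.5) * spacing, 0)
    v <- sweep(pm$v, 2, off, "+")
    blocks[[i]] <- v
    surface[[i]] <- pm$surface + sid0
    tab <- pm$surfaces
    tab$plant <- i
    tab$focal <- gx %in% centre_idx && gy %in% centre_idx
    surf_tabs[[i]] <- tab
    sid0 <- sid0 + nrow(tab)
  }
  # ground
  ground_v <- rbind(c(0, 0, 0), c(L, 0, 0), c(L, L, 0),
                    c(0, 0, 0), c(L, L, 0), c(0, L, 0))
  sid0 <- sid0 + 1
  blocks[[n_pl + 1]] <- ground_v
  surface[[n_pl + 1]] <- rep.int(sid0, 2)
  surf_tabs[[n_pl + 1]] <- data.frame(kind = "ground", rank = NA_integer_,
                                      plant = NA_integer_, focal = FALSE)
  # sensors
  if (sensors) {
    cx <- L / 2
    centres <- expand.grid(x = cx + c(-0.5, 0.5), y = cx + c(-0.5, 0.5))
    sv <- vector("list", 4)
    for (s in 1:4) {
      x0 <- centres$x[s] - 0.5; x1 <- centres$x[s] + 0.5
      y0 <- centres$y[s] - 0.5; y1 <- centres$y[s] + 0.5
      z <- 2e-4
      sv[[s]] <- rbind(c(x0, y0, z), c(x1, y0, z), c(x1, y1, z),
                       c(x0, y0, z), c(x1, y1, z), c(x0, y1, z))
    }
    blocks[[n_pl + 2]] <- do.call(rbind, sv)
    surface[[n_pl + 2]] <- rep(sid0 + 1:4, each = 2)
    surf_tabs[[n_pl + 2]] <- data.frame(kind = "sensor", rank = NA_integer_,
                                        plant = NA_integer_, focal = FALSE)[rep(1, 4), ]
  }
  v <- do.call(rbind, blocks)
  surface <- unlist(surface)
  surfaces <- do.call(rbind, surf_tabs)
  rownames(surfaces) <- NULL
  surfaces$id <- seq_len(nrow(surfaces))
  # keep drooping leaves above the ground plane (and above the sensors)
  low <- v[, 3] < 1e-3
  kind_per_tri <- surfaces$kind[surface]
  tri_fixable <- kind_per_tri %in% c("leaf", "stem")
  low <- low & rep(tri_fixable, each = 3)
  v[low, 3] <- 1e-3
  areas <- triangle_areas(v)
  surfaces$area_m2 <- as.numeric(tapply(areas, factor(surface, levels = surfaces$id), sum))
  surfaces$area_m2[is.na(surfaces$area_m2)] <- 0
  optics <- matrix(0, nrow(surfaces), 4,
                   dimnames = list(NULL, c("refl_front", "trans_front",
                                           "refl_back", "trans_back")))
  is_leaf <- surfaces$kind == "leaf"
  optics[is_leaf, ] <- matrix(c(p$leaf_reflectance_adaxial, p$leaf_transmittance_adaxial,
                                p$leaf_reflectance_abaxial, p$leaf_transmittance_abaxial),
                              sum(is_leaf), 4, byrow = TRUE)
  is_stem <- surfaces$kind == "stem"
  optics[is_stem, c(1, 3)] <- p$leaf_reflectance_adaxial
  optics[surfaces$kind == "ground", 1] <- p$ground_reflectance
  scene <- list(v = v, surface = surface, surfaces = surfaces, optics = optics,
                extent = L, spacing = spacing, grid = grid)
  class(scene) <- "canopy_scene"
  validate_scene(scene)
  scene
}

validate_scene <- function(scene) {
  if (!all(is.finite(scene$v))) stop("scene contains non-finite vertices", call. = FALSE)
  if (any(scene$v[, 3] < -1e-12)) stop("scene has triangles below the ground plane", call. = FALSE)
  if (any(scene$optics[, 1] + scene$optics[, 2] >= 1) ||
      any(scene$optics[, 3] + scene$optics[, 4] >= 1))
    stop("surface reflectance + transmittance must be < 1 per side", call. = FALSE)
  invisible(scene)
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat("<canopy_scene> ", nrow(x$v) / 3, " triangles, ",
      nrow(x$surfaces), " surfaces (",
      sum(x$surfaces$kind == "leaf"), " leaves, ",
      sum(x$surfaces$kind == "sensor"), " sensors), extent ",
      x$extent, " m\n", sep = "")
  invisible(x)
}

#' Build a scene from raw triangles
#'
#' Low-level constructor used for light-engine oracles (isolated leaves,
#' random 'Poisson' canopies): supply triangle soups and per-surface optics
#' directly.
#'
#' @param v Vertex matrix ((3 n) x 3), metres.
#' @param surface Integer surface id per triangle.
#' @param optics Matrix (n_surfaces x 4): refl_front, trans_front,
#'   refl_back, trans_back.
#' @param kind Character vector of surface kinds (e.g. "leaf", "ground",
#'   "sensor").
#' @return A `canopy_scene`.
#' @export
scene_from_triangles <- function(v, surface, optics, kind = rep("leaf", nrow(optics))) {
  surfaces <- data.frame(id = seq_len(nrow(optics)), kind = kind,
                         rank = NA_integer_, plant = NA_integer_, focal = FALSE)
  areas <- triangle_areas(v)
  surfaces$area_m2 <- as.numeric(tapply(areas, factor(surface, levels = surfaces$id), sum))
  surfaces$area_m2[is.na(surfaces$area_m2)] <- 0
  scene <- list(v = v, surface = as.integer(surface), surfaces = surfaces,
                optics = optics, extent = max(v[, 1:2]), spacing = NA, grid = NA)
  class(scene) <- "canopy_scene"
  validate_scene(scene)
  scene
}

#' Export a scene as a Wavefront OBJ file
#'
#' Faces are grouped by surface kind (adaxial lamina, stem, ground, sensor)
#' via `usemtl` statements so downstream viewers can colour them.
#'
#' @param scene A `canopy_scene` or `plant_mesh`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_obj <- function(scene, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- scene$v
  writeLines("# tomcan triangle soup", con)
  writeLines(sprintf("v %.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  kinds <- if (!is.null(scene$surfaces)) scene$surfaces$kind[scene$surface]
           else rep("mesh", nrow(v) / 3)
  n <- nrow(v) / 3
  idx <- 3 * seq_len(n)
  lines <- character(0)
  last <- ""
  for (i in seq_len(n)) {
    if (kinds[i] != last) {
      lines <- c(lines, paste("usemtl", kinds[i]))
      last <- kinds[i]
    }
    lines <- c(lines, sprintf("f %d %d %d", idx[i] - 2, idx[i] - 1, idx[i]))
  }
  writeLines(lines, con)
  invisible(path)
}

#' Export a scene as an ASCII PLY file
#'
#' Each face carries an integer material id (index into the surface kinds).
#'
#' @inheritParams write_obj
#' @return Invisibly `path`.
#' @export
write_ply <- function(scene, path) {
  v <- scene$v
  n <- nrow(v) / 3
  kinds <- if (!is.null(scene$surfaces)) scene$surfaces$kind[scene$surface]
           else rep("mesh", n)
  mat <- as.integer(factor(kinds)) - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", n),
               "property list uchar int vertex_indices",
               "property int material_id",
               "end_header"), con)
  writeLines(sprintf("%.6f %.6f %.6f", v[, 1], v[, 2], v[, 3]), con)
  i0 <- 3 * seq_len(n) - 3
  writeLines(sprintf("3 %d %d %d %d", i0, i0 + 1, i0 + 2, mat), con)
  invisible(path)
}
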