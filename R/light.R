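#' Sky and sampling model for the light engine
#'
#' @param mode `"overcast_diffuse"` (cosine-weighted downwelling radiance,
#'   the default for daily-integrated greenhouse light) or `"collimated"`
#'   (a single sun direction, used by the engine oracles).
#' @param zenith,azimuth Sun direction for `"collimated"`, degrees
#'   (zenith 0 = straight down).
#' @param n_rays Ray budget per trace (>= 1).
#' @param sampler `"stratified"` (jittered grid over the emitter plane) or
#'   `"low_discrepancy"` (scrambled Halton).
#' @param seed Integer seed; identical seed and budget give bit-identical
#'   results.
#' @param max_bounces Maximum scattering events per path.
#' @param weight_floor Paths lighter than this fraction of their initial
#'   weight stop; the residual is booked as escaped.
#' @param emitter_margin_m Horizontal margin of the emitter plane beyond the
#'   scene bounding box, metres. The default 1 m lets slanted diffuse rays
#'   reach the canopy edge; oracle tests use 0 for exact closed forms.
#' @param n_batches Number of ray batches used for Monte-Carlo standard
#'   errors.
#' @return A `sky_model` list.
#' @export
sky_model <- function(mode = c("overcast_diffuse", "collimated"),
                      zenith = 0, azimuth = 0, n_rays = 20000,
                      sampler = c("stratified", "low_discrepancy"),
                      seed = 1, max_bounces = 5, weight_floor = 1e-3,
                      emitter_margin_m = 1, n_batches = 16) {
  mode <- match.arg(mode)
  sampler <- match.arg(sampler)
  if (n_rays < 1) stop("ray budget must be >= 1", call. = FALSE)
  if (zenith < 0 || zenith >= 90) stop("zenith must be in [0, 90)", call. = FALSE)
  structure(list(mode = mode, zenith = zenith, azimuth = azimuth,
                 n_rays = as.integer(n_rays), sampler = sampler,
                 seed = as.integer(seed), max_bounces = as.integer(max_bounces),
                 weight_floor = weight_floor,
                 emitter_margin_m = emitter_margin_m,
                 n_batches = as.integer(n_batches)),
            class = "sky_model")
}

#' Trace light through a canopy scene
#'
#' Launches the sky model's ray budget from an emitter plane above the
#' scene. At each hit the ray deposits `1 - R - T` of its weight on the
#' struck surface (side-dependent optics) and continues by ideal-diffuse
#' reflection or transmission until it escapes, is extinguished, or reaches
#' the bounce limit; residual weight at termination is booked as escaped, so
#' emitted = absorbed + escaped holds to numerical precision.
#'
#' @param scene A `canopy_scene`.
#' @param sky A [sky_model()].
#' @param Q0_daily Incident daily light integral on a horizontal surface,
#'   J m-2 d-1 (any per-area unit propagates linearly).
#' @return A `light_result`: per-surface absorbed energy (J d-1), per-leaf
#'   absorbed flux `I_abs` (J m-2 d-1, absorbed / lamina mesh area),
#'   per-sensor absorption, totals, and batch-based Monte-Carlo standard
#'   errors.
#' @export
trace <- function(scene, sky = sky_model(), Q0_daily = 1) {
  if (nrow(scene$v) == 0) stop("empty scene", call. = FALSE)
  m <- sky$emitter_margin_m
  x0 <- min(scene$v[, 1]) - m; x1 <- max(scene$v[, 1]) + m
  y0 <- min(scene$v[, 2]) - m; y1 <- max(scene$v[, 2]) + m
  ztop <- max(scene$v[, 3]) + 0.5
  mode <- if (sky$mode == "collimated") 1L else 0L
  zr <- sky$zenith * pi / 180; ar <- sky$azimuth * pi / 180
  sun <- c(sin(zr) * cos(ar), sin(zr) * sin(ar), -cos(zr))
  raw <- .trace_cpp(scene$v, as.integer(scene$surface), scene$optics,
                    Q0_daily, c(x0, x1, y0, y1, ztop), sky$n_rays, sky$seed,
                    mode, sun, sky$max_bounces,
                    sky$weight_floor * Q0_daily * (x1 - x0) * (y1 - y0) / sky$n_rays,
                    sky$n_batches,
                    if (sky$sampler == "low_discrepancy") 1L else 0L)
  surfaces <- scene$surfaces
  absorbed <- raw$absorbed
  nb <- sky$n_batches
  batch_se <- function(x_b) sqrt(nb) * stats::sd(x_b)
  leaf_idx <- which(surfaces$kind == "leaf" & surfaces$area_m2 > 0)
  I_abs <- rep(NA_real_, nrow(surfaces))
  I_abs[leaf_idx] <- absorbed[leaf_idx] / surfaces$area_m2[leaf_idx]
  sensor_idx <- which(surfaces$kind == "sensor")
  res <- list(
    surfaces = surfaces,
    absorbed = absorbed,
    I_abs = I_abs,
    Q0_per_m2 = Q0_daily,
    sensor_idx = sensor_idx,
    sensor_absorbed = absorbed[sensor_idx],
    sensor_area_m2 = surfaces$area_m2[sensor_idx],
    sensor_se = if (length(sensor_idx))
      apply(raw$absorbed_batch[, sensor_idx, drop = FALSE], 2, batch_se)
      else numeric(0),
    absorbed_total = sum(absorbed),
    absorbed_total_se = batch_se(rowSums(raw$absorbed_batch)),
    escaped = raw$escaped,
    escaped_se = batch_se(raw$escaped_batch),
    emitted = raw$emitted,
    emitter_area_m2 = raw$emitter_area,
    n_rays = sky$n_rays
  )
  class(res) <- "light_result"
  res
}

#' @export
print.light_result <- function(x, ...) {
  cat("<light_result> emitted ", signif(x$emitted, 4), " J, absorbed ",
      signif(x$absorbed_total, 4), " (", round(100 * x$absorbed_total / x$emitted, 1),
      "%), escaped ", signif(x$escaped, 4), ", ", x$n_rays, " rays\n", sep = "")
  invisible(x)
}

#' Canopy light transmission from the virtual sensors
#'
#' Mean absorbed flux per square metre over the ground sensors divided by
#' the incident flux per square metre.
#'
#' @param result A `light_result` from a scene traced with sensors.
#' @return `Q_t / Q_0`, dimensionless in \[0, 1\].
#' @export
sensor_transmission <- function(result) {
  if (!length(result$sensor_idx)) stop("no sensors in the traced scene", call. = FALSE)
  mean(result$sensor_absorbed / result$sensor_area_m2) / result$Q0_per_m2
}

#' Beer-Lambert extinction coefficient
#'
#' Inverts `Q_t/Q_0 = exp(-k * LAI)`.
#'
#' @param Qt_over_Q0 Transmitted fraction, in (0, 1\].
#' @param LAI Leaf area index, m2 m-2 (> 0).
#' @return Extinction coefficient `k` (dimensionless).
#' @export
estimate_k <- function(Qt_over_Q0, LAI) {
  if (any(Qt_over_Q0 <= 0)) stop("transmitted fraction must be > 0", call. = FALSE)
  if (any(LAI <= 0)) stop("LAI must be > 0", call. = FALSE)
  -log(Qt_over_Q0) / LAI
}

#' Random horizontal-leaf test canopy
#'
#' Builds the classical Beer-Lambert limiting case: small horizontal black
#' (fully absorbing) square leaves with centres uniformly scattered over the
#' domain and heights uniform in \[0.2, 1\] m, above a fully absorbing
#' ground-level sensor covering the domain. Under collimated vertical light
#' the gap fraction is Poisson, so the fitted extinction coefficient
#' approaches 1.
#'
#' @param LAI Target leaf area index.
#' @param domain_m Side length of the square domain, metres.
#' @param leaf_m Side length of each square leaf, metres.
#' @param seed Integer seed for leaf placement.
#' @return A `canopy_scene` whose single sensor surface reports transmission.
#' @export
poisson_canopy_scene <- function(LAI, domain_m = 2, leaf_m = 0.05, seed = 1) {
  # centres are scattered over the domain expanded by one leaf width so that
  # coverage is uniform inside the domain; the count is scaled to the
  # expanded area so the interior leaf-area density equals the target LAI
  n <- round(LAI * (domain_m + leaf_m)^2 / leaf_m^2)
  pos <- with_seed(seed, matrix(stats::runif(3 * n), n, 3))
  cx <- pos[, 1] * (domain_m + leaf_m) - leaf_m / 2
  cy <- pos[, 2] * (domain_m + leaf_m) - leaf_m / 2
  cz <- 0.2 + 0.8 * pos[, 3]
  h <- leaf_m / 2
  v <- matrix(0, 6 * n + 6, 3)
  for (i in seq_len(n)) {
    r <- 6 * (i - 1)
    v[r + 1, ] <- c(cx[i] - h, cy[i] - h, cz[i])
    v[r + 2, ] <- c(cx[i] + h, cy[i] - h, cz[i])
    v[r + 3, ] <- c(cx[i] + h, cy[i] + h, cz[i])
    v[r + 4, ] <- c(cx[i] - h, cy[i] - h, cz[i])
    v[r + 5, ] <- c(cx[i] + h, cy[i] + h, cz[i])
    v[r + 6, ] <- c(cx[i] - h, cy[i] + h, cz[i])
  }
  D <- domain_m
  v[6 * n + 1:6, ] <- rbind(c(0, 0, 0), c(D, 0, 0), c(D, D, 0),
                            c(0, 0, 0), c(D, D, 0), c(0, D, 0))
  surface <- c(rep(1L, 2 * n), 2L, 2L)
  optics <- matrix(0, 2, 4)
  scene_from_triangles(v, surface, optics, kind = c("leaf", "sensor"))
}
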