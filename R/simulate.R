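#' Architectural trait scenario
#'
#' Describes how a canopy's architecture is perturbed relative to the
#' reference plant. Multipliers act on the *outputs* of the organ shape
#' models at geometry-build time (leaf insertion angle, midrib curvature,
#' internode length), so growth states, leaf areas and production per unit
#' absorbed light stay comparable across scenarios; the categorical
#' variants swap the curvature-angle ratio or the leaflet area arrangement.
#'
#' @param angle_mult Leaf-angle multiplier in \[0.5, 1.5\].
#' @param curvature_mult Curvature multiplier in \[0.5, 1.5\].
#' @param internode_mult Internode-length multiplier in \[0.5, 1.5\].
#' @param lw_ratio Leaflet length:width override in \[0.5, 2\], or `NULL`
#'   for the reference 1.33.
#' @param curvature_variant One of `"reference"` (1:2:2), `"MC1"` (1:1:1),
#'   `"MC2"` (1:1:2), `"MC3"` (1:2:3), `"MC4"` (2:1:1).
#' @param leaflet_variant One of `"reference"` (0.12:0.17:0.13:0.16),
#'   `"ML1"` (0.143:0.143:0.143:0.142), `"ML2"` (0.2:0.15:0.11:0.08),
#'   `"ML3"` (0.08:0.15:0.17:0.2).
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(angle_mult = 1, curvature_mult = 1, internode_mult = 1,
                          lw_ratio = NULL,
                          curvature_variant = c("reference", "MC1", "MC2", "MC3", "MC4"),
                          leaflet_variant = c("reference", "ML1", "ML2", "ML3")) {
  curvature_variant <- match.arg(curvature_variant)
  leaflet_variant <- match.arg(leaflet_variant)
  chk <- function(x, lo, hi, nm) {
    if (x < lo || x > hi)
      stop(nm, " must be in [", lo, ", ", hi, "]", call. = FALSE)
  }
  chk(angle_mult, 0.5, 1.5, "angle_mult")
  chk(curvature_mult, 0.5, 1.5, "curvature_mult")
  chk(internode_mult, 0.5, 1.5, "internode_mult")
  if (!is.null(lw_ratio)) chk(lw_ratio, 0.5, 2, "lw_ratio")
  curvature_ratio <- switch(curvature_variant,
    reference = NULL, MC1 = c(1, 1, 1), MC2 = c(1, 1, 2),
    MC3 = c(1, 2, 3), MC4 = c(2, 1, 1))
  leaflet_fractions <- switch(leaflet_variant,
    reference = NULL,
    ML1 = c(0.143, 0.143, 0.143, 0.142),
    ML2 = c(0.2, 0.15, 0.11, 0.08),
    ML3 = c(0.08, 0.15, 0.17, 0.2))
  structure(list(angle_mult = angle_mult, curvature_mult = curvature_mult,
                 internode_mult = internode_mult, lw_ratio = lw_ratio,
                 curvature_variant = curvature_variant,
                 curvature_ratio = curvature_ratio,
                 leaflet_variant = leaflet_variant,
                 leaflet_fractions = leaflet_fractions),
            class = "scenario_spec")
}

is_reference_scenario <- function(s) {
  s$angle_mult == 1 && s$curvature_mult == 1 && s$internode_mult == 1 &&
    is.null(s$lw_ratio) && s$curvature_variant == "reference" &&
    s$leaflet_variant == "reference"
}

#' Run the full canopy simulation
#'
#' Daily loop over the climate series: advance the (shared) growth state,
#' rebuild the 3D canopy of `canopy_grid`^2 plants with per-plant
#' phyllotaxis jitter, trace the sky light, and accrue dry-mass production
#' on the focal plants from their per-leaf absorbed light. Virtual
#' transmission sensors are present only on the configured sensor days
#' (they would otherwise shade the ground). The run is a pure function of
#' (parameters, climate, scenario, seed, replicate).
#'
#' @param p Parameter set.
#' @param climate A `climate_series`.
#' @param scenario A [scenario_spec()].
#' @param seed Master seed. Named substreams are derived from it so that
#'   replicates can vary only the phyllotaxis jitter while the sky sampler
#'   stays fixed.
#' @param replicate Replicate index (selects the phyllotaxis substream).
#' @param n_rays Ray budget per daily trace.
#' @param use_temperature_factor Apply the temperature response of
#'   light-use efficiency (`TRUE` for evaluation runs, `FALSE` for trait
#'   analyses).
#' @param light Set `FALSE` to skip light and production (growth only).
#' @return List of class `canopy_run`: `daily` (day, leaf_number,
#'   height_cm, leaf_area_cm2, Ws_mean, Qt_over_Q0, k, LAI), `Ws_plant`
#'   (final cumulative per focal plant), `production` (long per-day
#'   per-plant table), `growth` (from [grow_plant()]), and the inputs.
#' @export
run_simulation <- function(p, climate, scenario = scenario_spec(), seed = 1,
                           replicate = 1, n_rays = 20000,
                           use_temperature_factor = TRUE, light = TRUE) {
  n_days <- nrow(climate)
  growth <- grow_plant(p, climate)
  daily <- growth$daily
  daily$Ws_mean <- rep(NA_real_, n_days)
  daily$Qt_over_Q0 <- rep(NA_real_, n_days)
  daily$k <- rep(NA_real_, n_days)
  daily$LAI <- (daily$leaf_area_cm2 * 1e-4) / p$plant_spacing_m^2
  n_pl <- p$canopy_grid^2
  phyl_base <- substream_seed(seed, 200L + as.integer(replicate))
  plant_seeds <- lapply(seq_len(n_pl), function(i) substream_seed(phyl_base, i))
  W_p <- NULL
  production <- vector("list", n_days)
  if (light && n_days > 0) {
    for (i in seq_len(n_days)) {
      state <- growth$states[[i]]
      day <- climate$day[i]
      scene <- build_canopy(rep(list(state), n_pl), p, plant_seeds,
                            sensors = day %in% p$sensor_days, scenario)
      sky <- sky_model(n_rays = n_rays, seed = substream_seed(seed, 300L + i))
      res <- trace(scene, sky, climate$Q0_daily[i])
      focal <- which(scene$surfaces$kind == "leaf" & scene$surfaces$focal)
      focal_plants <- sort(unique(scene$surfaces$plant[focal]))
      if (is.null(W_p)) W_p <- stats::setNames(numeric(length(focal_plants)),
                                               focal_plants)
      prod_rows <- vector("list", length(focal_plants))
      for (jp in seq_along(focal_plants)) {
        pid <- focal_plants[jp]
        idx <- focal[scene$surfaces$plant[focal] == pid]
        ranks <- scene$surfaces$rank[idx]
        I_abs <- res$I_abs[idx]
        I_abs[is.na(I_abs)] <- 0
        lv <- state$leaves[match(ranks, state$leaves$rank), , drop = FALSE]
        W_l <- leaf_daily_dry_mass(lv, I_abs, climate$T[i], p,
                                   use_temperature_factor)
        W_p[jp] <- W_p[jp] + sum(W_l)
        prod_rows[[jp]] <- data.frame(day = day, plant = pid, rank = ranks,
                                      I_abs = I_abs, W_l = W_l)
      }
      production[[i]] <- do.call(rbind, prod_rows)
      daily$Ws_mean[i] <- mean(shoot_dry_mass(W_p, p))
      if (day %in% p$sensor_days) {
        daily$Qt_over_Q0[i] <- sensor_transmission(res)
        daily$k[i] <- estimate_k(max(daily$Qt_over_Q0[i], 1e-12), daily$LAI[i])
      }
    }
  }
  out <- list(daily = daily,
              Ws_plant = if (is.null(W_p)) numeric(0) else shoot_dry_mass(W_p, p),
              production = do.call(rbind, production),
              growth = growth, scenario = scenario, seed = seed,
              replicate = replicate, n_rays = n_rays,
              use_temperature_factor = use_temperature_factor)
  class(out) <- "canopy_run"
  out
}

#' @export
print.canopy_run <- function(x, ...) {
  n <- nrow(x$daily)
  cat("<canopy_run> ", n, " days", sep = "")
  if (n) {
    cat(": final leaf number ", x$daily$leaf_number[n],
        ", height ", round(x$daily$height_cm[n], 1), " cm, W_s ",
        round(x$daily$Ws_mean[n], 1), " g", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Replicate runs varying only the phyllotaxis jitter
#'
#' Repeats [run_simulation()] `n` times; only the phyllotaxis-jitter
#' substream changes between replicates (climate, growth and the sky
#' sampler are shared), mirroring the replicate protocol of randomized
#' 144 +- 10 degree phyllotaxis.
#'
#' @inheritParams run_simulation
#' @param n Number of replicates (>= 2).
#' @return List of class `canopy_replicates`: `runs` (the individual
#'   `canopy_run`s) and `summary` (per-quantity replicate mean, SE and
#'   SE as percent of mean for final-day shoot dry mass and total leaf
#'   area).
#' @export
run_replicates <- function(p, climate, scenario = scenario_spec(), seed = 1,
                           n = 5, n_rays = 20000,
                           use_temperature_factor = TRUE) {
  if (n < 2) stop("need at least 2 replicates", call. = FALSE)
  runs <- lapply(seq_len(n), function(i)
    run_simulation(p, climate, scenario, seed, replicate = i, n_rays = n_rays,
                   use_temperature_factor = use_temperature_factor))
  last <- nrow(climate)
  final_Ws <- vapply(runs, function(r) r$daily$Ws_mean[last], numeric(1))
  final_Ap <- vapply(runs, function(r) r$daily$leaf_area_cm2[last], numeric(1))
  se <- function(x) stats::sd(x) / sqrt(length(x))
  summary <- data.frame(
    quantity = c("final_Ws_g", "final_leaf_area_cm2"),
    mean = c(mean(final_Ws), mean(final_Ap)),
    se = c(se(final_Ws), se(final_Ap))
  )
  summary$se_pct_of_mean <- 100 * summary$se / summary$mean
  out <- list(runs = runs, summary = summary, n = n, seed = seed)
  class(out) <- "canopy_replicates"
  out
}

#' Rank-resolved leaf-length trajectories of replicate runs
#'
#' @param reps A `canopy_replicates` object.
#' @param rank Leaf rank to extract.
#' @return Matrix days x replicates of leaf length (cm); days before the
#'   leaf appears are 0.
#' @export
replicate_leaf_lengths <- function(reps, rank = 8) {
  days <- reps$runs[[1]]$daily$day
  out <- matrix(0, length(days), reps$n,
                dimnames = list(days, paste0("rep", seq_len(reps$n))))
  for (j in seq_len(reps$n)) {
    lv <- reps$runs[[j]]$growth$leaves
    lv <- lv[lv$rank == rank, ]
    out[match(lv$day, days), j] <- lv$length
  }
  out
}

#' Architectural trait sweep
#'
#' Runs the canopy simulation for a set of scenarios (which must include a
#' reference) with the light-use-efficiency temperature factor disabled,
#' and reports final-day shoot dry mass normalized to the reference
#' (= 100%), plus sensor-day transmission and extinction coefficients.
#'
#' @inheritParams run_simulation
#' @param scenarios Named list of [scenario_spec()]s including one named
#'   `"reference"` (or any entry that is the reference scenario).
#' @return List of class `trait_sweep`: `table` (scenario, final_Ws_g,
#'   Ws_pct) and `sensors` (scenario, day, Qt_over_Q0, k).
#' @export
run_trait_sweep <- function(p, climate, scenarios, seed = 1, n_rays = 20000) {
  is_ref <- vapply(scenarios, is_reference_scenario, logical(1))
  if (!any(is_ref))
    stop("scenario grid must include the reference scenario", call. = FALSE)
  runs <- lapply(scenarios, function(s)
    run_simulation(p, climate, s, seed, n_rays = n_rays,
                   use_temperature_factor = FALSE))
  last <- nrow(climate)
  final_Ws <- vapply(runs, function(r) r$daily$Ws_mean[last], numeric(1))
  ref_Ws <- final_Ws[which(is_ref)[1]]
  table <- data.frame(scenario = names(scenarios), final_Ws_g = final_Ws,
                      Ws_pct = if (isTRUE(ref_Ws > 0)) 100 * final_Ws / ref_Ws
                               else NA_real_,
                      row.names = NULL)
  sensors <- do.call(rbind, lapply(names(runs), function(nm) {
    d <- runs[[nm]]$daily
    d <- d[!is.na(d$Qt_over_Q0), c("day", "Qt_over_Q0", "k")]
    if (nrow(d)) cbind(scenario = nm, d) else NULL
  }))
  out <- list(table = table, sensors = sensors, runs = runs, seed = seed)
  class(out) <- "trait_sweep"
  out
}

#' Agreement statistics between measured and simulated series
#'
#' Root mean square deviation, bias (measured minus simulated) and
#' accuracy `1 - RMSD / mean(measured)` expressed in percent.
#'
#' @param measured,simulated Equal-length numeric vectors.
#' @return List with `rmsd`, `bias`, `accuracy_pct`.
#' @export
eval_stats <- function(measured, simulated) {
  if (length(measured) != length(simulated))
    stop("measured and simulated series differ in length", call. = FALSE)
  if (length(measured) < 1) stop("need at least one observation", call. = FALSE)
  m <- mean(measured)
  if (m == 0) stop("mean of measured series is zero; accuracy undefined",
                   call. = FALSE)
  d <- measured - simulated
  rmsd <- sqrt(mean(d^2))
  list(rmsd = rmsd, bias = mean(d), accuracy_pct = 100 * (1 - rmsd / m))
}
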