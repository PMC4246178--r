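#' Maximum leaf elongation rate from temperature and VPD
#'
#' Linear thermal response above the base temperature `T_b`, modulated by
#' vapour pressure deficit; above the optimum `T_opt` the rate declines at
#' the same rate as it rises below it (mirror about `T_opt`). Negative
#' values (temperature below base, or far above optimum) clamp to zero.
#'
#' @param T Air temperature, C (vectorized).
#' @param VPD Vapour pressure deficit, kPa (>= 0).
#' @param p Parameter set.
#' @return Elongation rate, cm d-1.
#' @export
leaf_elongation_max <- function(T, VPD, p) {
  eff_T <- ifelse(T <= p$T_opt, T - p$T_b, 2 * p$T_opt - T - p$T_b)
  out <- eff_T * (p$a_Elmax + p$b_Elmax * VPD)
  out[T < p$T_b] <- 0
  pmax(0, out)
}

#' Bell-shaped thermal-time response
#'
#' `exp(-0.5 * ((TS - centre)/width)^2)`: 1 at the centre, `exp(-0.5)` at
#' one width either side. Shared by the leaf and internode elongation
#' ontogeny terms.
#'
#' @param TS Temperature sum, Cd (vectorized).
#' @param centre Centre of the bell, Cd.
#' @param width Width (> 0), Cd.
#' @return Dimensionless factor in (0, 1].
#' @export
bell_effect <- function(TS, centre, width) {
  if (width <= 0) stop("bell width must be > 0", call. = FALSE)
  exp(-0.5 * ((TS - centre) / width)^2)
}

#' Normalized rank effect on leaf elongation
#'
#' Bell-shaped in rank up to rank 13; leaves above rank 13 behave like
#' rank-13 leaves (rank effects were only measurable up to rank 13).
#'
#' @param r Leaf rank, integer >= 1 (vectorized).
#' @param p Parameter set (`R_max`, `h`).
#' @return Dimensionless factor in (0, 1].
#' @export
rank_effect <- function(r, p) {
  if (any(r < 1)) stop("rank must be >= 1", call. = FALSE)
  bell_effect(pmin(r, 13), p$R_max, p$h)
}

#' Daily leaf elongation rate
#'
#' Product of the temperature/VPD maximum rate, the thermal-time bell and
#' the normalized rank effect.
#'
#' @inheritParams leaf_elongation_max
#' @param TS Leaf temperature sum since appearance, Cd.
#' @param r Leaf rank.
#' @return Elongation rate, cm d-1 (>= 0).
#' @export
leaf_elongation <- function(T, VPD, TS, r, p) {
  leaf_elongation_max(T, VPD, p) *
    bell_effect(TS, p$TS_lmax, p$h_l) *
    rank_effect(r, p)
}

#' Leaf area from leaf length
#'
#' Cultivar-specific power law `A_l = a_Al * L_l^g`.
#'
#' @param L_l Leaf length, cm (>= 0, vectorized).
#' @param p Parameter set.
#' @return Leaf area, cm2.
#' @export
leaf_area <- function(L_l, p) p$a_Al * L_l^p$g

#' Leaf appearance rate from temperature
#'
#' Logarithmic in temperature up to 30 C and capped above it; the cap equals
#' the rate at 30 C (continuity). Zero at or below the base temperature.
#'
#' @param T Air temperature, C (vectorized).
#' @param p Parameter set.
#' @return Appearance rate, leaf d-1 (>= 0).
#' @export
leaf_appearance_rate <- function(T, p) {
  out <- ifelse(T > 30, p$R_lmax, p$a_r * log(pmax(T, 1e-12)) - p$b_r)
  out[T <= p$T_b] <- 0
  pmax(0, out)
}

#' Leaf insertion angle from leaf length
#'
#' Saturating response `a_theta * (1 - exp(-b_theta * L_l))`: 0 for a new
#' leaf, approaching `a_theta` degrees for long leaves.
#'
#' @param L_l Leaf length, cm (vectorized).
#' @param p Parameter set.
#' @return Angle between stem and petiole, degrees.
#' @export
leaf_angle <- function(L_l, p) p$a_theta * (1 - exp(-p$b_theta * L_l))

#' Leaf midrib curvature from leaf length
#'
#' Piecewise linear with a junction at 50 cm; the upper-branch intercept is
#' derived at parameter load time so the two branches meet continuously.
#' The curvature is the sum of the three midrib bending angles
#' alpha1 + alpha2 + alpha3 and is clamped at zero.
#'
#' @param L_l Leaf length, cm (vectorized).
#' @param p Parameter set.
#' @return Curvature, degrees (>= 0).
#' @export
leaf_curvature <- function(L_l, p) {
  out <- ifelse(L_l <= 50, p$a_Cl - p$b_Cl * L_l, p$a1_Cl + p$b1_Cl * L_l)
  pmax(0, out)
}

#' Internode elongation rate
#'
#' Maximum rate linear in temperature above the internode base temperature
#' and decreasing in PAR, modulated by a thermal-time bell.
#'
#' @param T Air temperature, C.
#' @param PAR Daily mean PAR, micromol m-2 s-1 (>= 0).
#' @param TS_i Internode temperature sum, Cd.
#' @param p Parameter set.
#' @return Elongation rate, cm d-1 (>= 0).
#' @export
internode_elongation <- function(T, PAR, TS_i, p) {
  pmax(0, (T - p$T_bi) * (p$a_Eimax - p$b_Eimax * PAR)) *
    bell_effect(TS_i, p$TS_imax, p$h_i)
}

#' Internode diameter from internode age
#'
#' Linear in the internode temperature sum: `D_i = a_Di + b_Di * TS_i`.
#'
#' @param TS_i Internode temperature sum, Cd (>= 0).
#' @param p Parameter set.
#' @return Diameter, cm.
#' @export
internode_diameter <- function(TS_i, p) p$a_Di + p$b_Di * TS_i

#' Fresh plant state
#'
#' A plant starts with `initial_leaf_number` just-appeared leaves (and their
#' subtending internodes) of zero length and zero thermal age.
#'
#' @param p Parameter set.
#' @param day Starting day (DAFLA), default 0.
#' @return A `plant_state` list.
#' @export
new_plant_state <- function(p, day = 0) {
  n0 <- as.integer(p$initial_leaf_number)
  if (n0 < 1) stop("initial_leaf_number must be >= 1", call. = FALSE)
  state <- list(
    day = day,
    leaf_accumulator = n0,
    leaves = data.frame(
      rank = seq_len(n0), appearance_day = rep(day, n0),
      TS = 0, length = 0, area = 0, angle = 0,
      curvature = leaf_curvature(0, p), senescent = FALSE
    ),
    internodes = data.frame(
      rank = seq_len(n0), TS = 0, length = 0,
      diameter = internode_diameter(0, p)
    )
  )
  class(state) <- "plant_state"
  state
}

#' @export
print.plant_state <- function(x, ...) {
  cat("<plant_state> day ", x$day, ": ", nrow(x$leaves), " leaves (",
      sum(x$leaves$senescent), " senescent), height ",
      round(plant_height(x), 1), " cm, leaf area ",
      round(plant_leaf_area(x), 0), " cm2\n", sep = "")
  invisible(x)
}

#' Plant height (sum of internode lengths), cm
#' @param state A `plant_state`.
#' @export
plant_height <- function(state) sum(state$internodes$length)

#' Total plant leaf area (senescent leaves included), cm2
#' @param state A `plant_state`.
#' @export
plant_leaf_area <- function(state) sum(state$leaves$area)

#' Advance a plant by one day
#'
#' Applies one day of climate: every leaf accrues thermal time
#' (`max(T - T_b, 0)`) and elongates by the daily elongation rate (shape
#' descriptors recomputed from the new length); every internode accrues
#' thermal time with its own base temperature and elongates; leaves whose
#' thermal age exceeds the senescence threshold are flagged senescent
#' (absorbing; geometry and area are retained). Finally the leaf-appearance
#' accumulator is integrated and, on crossing an integer, a new leaf and its
#' subtending internode are emitted with zero thermal age.
#'
#' @param state A `plant_state`.
#' @param day_record One row of a `climate_series` (day, T, VPD, PAR).
#' @param p Parameter set.
#' @return The advanced `plant_state`.
#' @export
advance_plant <- function(state, day_record, p) {
  T <- day_record$T; VPD <- day_record$VPD; PAR <- day_record$PAR
  lv <- state$leaves
  if (nrow(lv)) {
    lv$TS <- lv$TS + max(T - p$T_b, 0)
    lv$length <- lv$length + leaf_elongation(T, VPD, lv$TS, lv$rank, p)
    lv$area <- leaf_area(lv$length, p)
    lv$angle <- leaf_angle(lv$length, p)
    lv$curvature <- leaf_curvature(lv$length, p)
    lv$senescent <- lv$senescent | (lv$TS > p$TS_lsen)
  }
  iv <- state$internodes
  if (nrow(iv)) {
    iv$TS <- iv$TS + max(T - p$T_bi, 0)
    iv$length <- iv$length + internode_elongation(T, PAR, iv$TS, p)
    iv$diameter <- internode_diameter(iv$TS, p)
  }
  acc <- state$leaf_accumulator + leaf_appearance_rate(T, p)
  n_new <- floor(acc) - floor(state$leaf_accumulator)
  if (n_new > 0) {
    ranks <- nrow(lv) + seq_len(n_new)
    lv <- rbind(lv, data.frame(
      rank = ranks, appearance_day = day_record$day, TS = 0, length = 0,
      area = 0, angle = 0, curvature = leaf_curvature(0, p), senescent = FALSE
    ))
    iv <- rbind(iv, data.frame(
      rank = ranks, TS = 0, length = 0, diameter = internode_diameter(0, p)
    ))
  }
  state$leaves <- lv
  state$internodes <- iv
  state$leaf_accumulator <- acc
  state$day <- day_record$day
  state
}

#' Run the growth model over a climate series
#'
#' Growth is driven by climate only (light interception feeds production,
#' not morphology), so one trajectory serves every plant in a canopy.
#'
#' @param p Parameter set.
#' @param climate A `climate_series`.
#' @param state Initial `plant_state` (default: fresh plant).
#' @return List with `states` (one `plant_state` per day, named by day),
#'   `daily` (data frame: day, leaf_number, height_cm, leaf_area_cm2),
#'   `leaves` and `internodes` (long per-day per-organ tables).
#' @export
grow_plant <- function(p, climate, state = new_plant_state(p)) {
  n <- nrow(climate)
  states <- vector("list", n)
  daily <- data.frame(day = climate$day, leaf_number = rep(NA_real_, n),
                      height_cm = rep(NA_real_, n), leaf_area_cm2 = rep(NA_real_, n))
  leaves <- vector("list", n)
  internodes <- vector("list", n)
  for (i in seq_len(n)) {
    state <- advance_plant(state, climate[i, ], p)
    states[[i]] <- state
    daily$leaf_number[i] <- nrow(state$leaves)
    daily$height_cm[i] <- plant_height(state)
    daily$leaf_area_cm2[i] <- plant_leaf_area(state)
    leaves[[i]] <- cbind(day = climate$day[i], state$leaves)
    internodes[[i]] <- cbind(day = climate$day[i], state$internodes)
  }
  names(states) <- climate$day
  list(states = states, daily = daily,
       leaves = do.call(rbind, leaves),
       internodes = do.call(rbind, internodes))
}
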