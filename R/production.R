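#' Light-use efficiency as a function of absorbed light
#'
#' Empirical saturating form
#' `eps(I) = eps_min + (eps_max - eps_min) * exp(-I / I_c)`: efficiency is
#' highest at low absorbed flux and declines monotonically towards
#' `eps_min` as leaves light-saturate. The constants are documented
#' placeholders (the published curve for this cultivar is cited from
#' literature, not printed) and are fully overridable.
#'
#' @param I_abs Absorbed flux, J m-2 d-1 (>= 0, vectorized).
#' @param p Parameter set (`eps_max`, `eps_min`, `I_c`, `co2_to_dm`).
#' @return Efficiency, g J-1.
#' @export
light_use_efficiency <- function(I_abs, p) {
  if (any(I_abs < 0)) stop("I_abs must be >= 0", call. = FALSE)
  p$co2_to_dm * (p$eps_min + (p$eps_max - p$eps_min) * exp(-I_abs / p$I_c))
}

#' Temperature factor of light-use efficiency
#'
#' Concave parabola `1 - kappa * (T - T_star)^2`, peaking at 1 at the
#' optimum `T_star` and clamped at zero.
#'
#' @param T Air temperature, C (vectorized).
#' @param p Parameter set (`kappa`, `T_star`).
#' @return Dimensionless factor in \[0, 1\].
#' @export
temperature_factor <- function(T, p) pmax(0, 1 - p$kappa * (T - p$T_star)^2)

#' Daily dry-mass production of one leaf
#'
#' `W_l = I_abs * eps(I_abs) * f_T * A_l` with the leaf area in m2.
#' Senescent leaves keep shading the canopy but no longer produce dry mass.
#' The temperature factor can be disabled (as it is for the architectural
#' trait analyses).
#'
#' @param leaf One row of a `plant_state$leaves` frame (area in cm2,
#'   `senescent` flag).
#' @param I_abs Absorbed flux on that leaf, J m-2 d-1.
#' @param T Air temperature of the day, C.
#' @param p Parameter set.
#' @param use_temperature_factor Logical; `FALSE` fixes `f_T = 1`.
#' @return Dry mass, g d-1.
#' @export
leaf_daily_dry_mass <- function(leaf, I_abs, T, p, use_temperature_factor = TRUE) {
  if (any(leaf$senescent)) {
    out <- numeric(nrow(leaf))
    alive <- !leaf$senescent
    if (any(alive))
      out[alive] <- leaf_daily_dry_mass(leaf[alive, , drop = FALSE],
                                        I_abs[alive], T, p,
                                        use_temperature_factor)
    return(out)
  }
  f_T <- if (use_temperature_factor) temperature_factor(T, p) else 1
  I_abs * light_use_efficiency(I_abs, p) * f_T * (leaf$area * 1e-4)
}

#' Shoot dry mass from plant dry mass
#'
#' Fixed partitioning of whole-plant dry mass to above-ground organs:
#' `W_s = mu * W_p`.
#'
#' @param W_p Plant dry mass, g (>= 0).
#' @param p Parameter set (`mu` in (0, 1]).
#' @return Shoot dry mass, g.
#' @export
shoot_dry_mass <- function(W_p, p) p$mu * W_p
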