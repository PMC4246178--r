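#' Load a daily climate series from CSV
#'
#' Columns `day,T,VPD,PAR` and optionally `Q0_daily`. `day` is the simulation
#' clock in days after first-true-leaf appearance (DAFLA); `T` the daily mean
#' air temperature (C); `VPD` the daily mean vapour pressure deficit (kPa);
#' `PAR` the daily mean daytime photosynthetic photon flux
#' (micromol m-2 s-1). When `Q0_daily` (the incident daily PAR integral,
#' J m-2 d-1) is absent it is computed as
#' `PAR * par_to_energy * daylight_hours * 3600`.
#'
#' @param path CSV path (UTF-8, '.' decimal).
#' @param p Parameter set supplying `par_to_energy` and `daylight_hours`.
#' @return A `climate_series` data frame.
#' @export
load_climate <- function(path, p = default_parameters()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("day", "T", "VPD", "PAR")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("climate CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"Q0_daily" %in% names(x))
    x$Q0_daily <- x$PAR * p$par_to_energy * p$daylight_hours * 3600
  climate_series(x[c("day", "T", "VPD", "PAR", "Q0_daily")])
}

#' Construct and validate a climate series
#'
#' @param x Data frame with columns `day,T,VPD,PAR,Q0_daily`.
#' @return The validated `climate_series`.
#' @export
climate_series <- function(x) {
  if (nrow(x) > 1 && any(diff(x$day) != 1))
    stop("climate days must be strictly increasing and contiguous (non-contiguous)",
         call. = FALSE)
  if (any(x$VPD < 0)) stop("negative VPD in climate series", call. = FALSE)
  if (any(x$PAR < 0)) stop("negative PAR in climate series", call. = FALSE)
  if (any(x$Q0_daily < 0)) stop("negative Q0_daily in climate series", call. = FALSE)
  class(x) <- c("climate_series", "data.frame")
  x
}

#' Write a climate series to CSV
#'
#' Inverse of [load_climate()]: `load_climate(write_climate(x, f))`
#' reproduces `x` field for field.
#'
#' @param x A `climate_series`.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_climate <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synthesize a greenhouse climate series
#'
#' Generates the packaged stand-in for measured greenhouse weather under two
#' day/night temperature regimes: `"LT"` (22/18 C set points) and `"HT"`
#' (32/28 C). The daily mean temperature is the 16 h day / 8 h night weighted
#' set-point mean plus seeded ventilation noise bounded in +-2 C; VPD is
#' bounded in \[0.5, 2.5\] kPa; PAR follows a seasonal ramp with bounded
#' noise and is identical for both regimes under the same seed (both
#' greenhouses receive the same light). Deterministic for a fixed seed, and
#' the HT series is strictly warmer than the LT series day by day for the
#' same seed because the noise substream does not depend on the regime.
#'
#' @param regime `"LT"` or `"HT"`.
#' @param n_days Number of days (>= 1), starting at day 1 (DAFLA).
#' @param seed Integer seed.
#' @param p Parameter set (for the PAR-to-energy conversion).
#' @return A `climate_series` of length `n_days`.
#' @export
synthesize_climate <- function(regime, n_days, seed, p = default_parameters()) {
  if (!regime %in% c("LT", "HT")) stop("unknown regime: ", regime, call. = FALSE)
  if (n_days < 1) stop("n_days must be >= 1", call. = FALSE)
  set_points <- switch(regime, LT = c(day = 22, night = 18), HT = c(day = 32, night = 28))
  base_T <- (16 * set_points[["day"]] + 8 * set_points[["night"]]) / 24
  day <- seq_len(n_days)
  # regime-independent noise substreams so LT/HT share weather fluctuations
  t_noise   <- with_seed(substream_seed(seed, 101L), stats::runif(n_days, -2, 2))
  vpd_noise <- with_seed(substream_seed(seed, 102L), stats::runif(n_days, -0.5, 0.5))
  par_noise <- with_seed(substream_seed(seed, 103L), stats::runif(n_days, -50, 50))
  vpd_base <- switch(regime, LT = 1.0, HT = 1.5)
  vpd <- pmin(2.5, pmax(0.5, vpd_base + vpd_noise))
  par <- pmax(50, 250 + 150 * day / max(n_days, 1) + par_noise)
  climate_series(data.frame(
    day = day,
    T = base_T + t_noise,
    VPD = vpd,
    PAR = par,
    Q0_daily = par * p$par_to_energy * p$daylight_hours * 3600
  ))
}

#' Packaged synthetic climate fixtures
#'
#' The frozen 77-day greenhouse weather series used by the packaged
#' evaluation runs: [synthesize_climate()] with seed 1. Both regimes share
#' the same fluctuation and light substreams, so they differ only in their
#' temperature (and humidity base) levels.
#'
#' @param regime `"LT"` (22/18 C) or `"HT"` (32/28 C).
#' @return A 77-day `climate_series`.
#' @export
packaged_climate <- function(regime = c("LT", "HT")) {
  synthesize_climate(match.arg(regime), 77, seed = 1)
}

# --- seeded substreams -------------------------------------------------------
# Named substreams keep the replicate protocol honest: the phyllotaxis jitter
# can be varied while the sky sampler and climate stay fixed. Derived seeds
# stay below 2^31 - 1.

substream_seed <- function(master, stream_id) {
  as.integer((as.numeric(master) * 7919 + as.numeric(stream_id) * 104729) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
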