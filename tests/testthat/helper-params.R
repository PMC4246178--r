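# parameter set with overrides applied and derived fields re-finalized
params_with <- function(...) {
  p <- default_parameters()
  o <- list(...)
  for (k in names(o)) p[[k]] <- o[[k]]
  tomcan:::finalize_parameters(p)
}

# small square-plate scene helpers for light-engine oracles
rect_tris <- function(x0, x1, y0, y1, z) {
  rbind(c(x0, y0, z), c(x1, y0, z), c(x1, y1, z),
        c(x0, y0, z), c(x1, y1, z), c(x0, y1, z))
}

# a quick low-resolution climate for structural tests
tiny_climate <- function(n = 5, T = 22, VPD = 1, PAR = 400,
                         p = default_parameters()) {
  climate_series(data.frame(
    day = seq_len(n), T = T, VPD = VPD, PAR = PAR,
    Q0_daily = PAR * p$par_to_energy * p$daylight_hours * 3600
  ))
}
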