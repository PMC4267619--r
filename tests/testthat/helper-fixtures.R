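# Shared fixtures: the two study titration schedules and tiny text files.

schedule_methylated <- function() {
  injection_schedule(n_injections = 45L, injection_volume = 6e-6,
                     cell_volume = 1.4e-3, cell_conc = 10e-6,
                     syringe_conc = 125e-6, temperature = 293.15)
}

schedule_unmethylated <- function() {
  injection_schedule(n_injections = 45L, injection_volume = 6e-6,
                     cell_volume = 1.4e-3, cell_conc = 14e-6,
                     syringe_conc = 410e-6, temperature = 293.15)
}

write_sparky_fixture <- function(lines) {
  path <- tempfile(fileext = ".list")
  writeLines(c("      Assignment         w1         w2", lines), path)
  path
}

# Bound fraction via an independent root of the mass-balance quadratic
# x^2 - (P + L + Kd) x + P L = 0 (complex concentration x), solved with
# polyroot rather than the closed form under test.
fraction_bound_oracle <- function(P, L, Kd) {
  if (L == 0) return(0)
  r <- Re(polyroot(c(P * L, -(P + L + Kd), 1)))
  x <- r[r >= -1e-12 & r <= min(P, L) + 1e-12][1]
  x / P
}

# Per-injection heats in the infinite-affinity limit: every injected mole
# binds until the cell macromolecule is saturated (same perfusion-cell
# dilution convention as the forward model, including the displaced-volume
# mean-value term).
stoichiometric_heats <- function(dH, n_sites, schedule) {
  v <- cumsum(schedule$injection_volume)
  V0 <- schedule$cell_volume
  d <- 1 + v / (2 * V0)
  Mt <- schedule$cell_conc * (1 - v / (2 * V0)) / d
  Xt <- schedule$syringe_conc * (v / V0) / d
  bound <- pmin(Xt, n_sites * Mt)
  Q <- bound * dH * 1000 * V0
  Qprev <- c(0, Q[-length(Q)])
  (Q - Qprev + (schedule$injection_volume / V0) * (Q + Qprev) / 2) * 1e6
}
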