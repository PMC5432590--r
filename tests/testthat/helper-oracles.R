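# Independent oracles used across test files.

# Step-by-step, fully unit-annotated Hagen-Poiseuille computation for one
# vessel set: every conversion is spelled out so the vectorized
# implementation can be checked against it.
oracle_kt <- function(diameters_um, extrapolate_half = FALSE) {
  rho_kg_per_m3 <- 1000
  eta_mpa_s <- 1e-9
  molar_mass_kg_per_mol <- 0.018015
  total <- 0
  for (d_um in diameters_um) {
    d_m <- d_um / 1e6                      # um -> m
    d4_m4 <- d_m * d_m * d_m * d_m          # m^4
    # mass-flow conductivity of this conduit: kg m s^-1 MPa^-1
    k_kg <- (pi * rho_kg_per_m3 / (128 * eta_mpa_s)) * d4_m4
    k_mol <- k_kg / molar_mass_kg_per_mol   # mol m s^-1 MPa^-1
    k_mmol <- k_mol * 1000                  # mmol m s^-1 MPa^-1
    total <- total + k_mmol
  }
  if (extrapolate_half) total <- total + total
  total
}

# Brute-force psi-class histogram: explicit interval membership test for
# half-open classes (-(i+1)*w, -i*w] anchored at 0.
oracle_bin_counts <- function(psi, w, imax = 50) {
  counts <- integer(0)
  for (i in 0:imax) {
    lo <- -(i + 1) * w
    hi <- -i * w
    counts[as.character(i)] <- sum(psi > lo & psi <= hi)
  }
  counts[counts > 0]
}
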