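# Shared fixtures and independent oracles, built in code at test time.

# Small two-domain ensemble reused across structural tests.
tiny_dumbbell <- function(n_conformers = 5, seed = 11, dispersion = 25) {
  make_dumbbell_ensemble(n_conformers = n_conformers, domain_size = 10,
                         linker_length = 5, linker_dispersion = dispersion,
                         seed = seed)
}

# Random traceless symmetric Saupe matrix of typical weak-alignment
# magnitude.
random_saupe <- function(scale = 3e-4) {
  v <- runif(5, -scale, scale)
  matrix(c(v[1], v[3], v[4],
           v[3], v[2], v[5],
           v[4], v[5], -v[1] - v[2]), 3, 3)
}

# Rotation matrix from an axis and angle (degrees).
rotation_matrix <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Independent PRE oracle: direct one-line evaluation of the stated
# transverse-enhancement expression (r in Angstrom, tauc in ns).
oracle_gamma2 <- function(r, tauc_ns, field_mhz, K = 1.23e16) {
  K / r^6 * (4 * tauc_ns * 1e-9 +
               3 * tauc_ns * 1e-9 /
                 (1 + (2 * pi * field_mhz * 1e6)^2 * (tauc_ns * 1e-9)^2))
}
oracle_pre_ratio <- function(r, tauc_ns, r2_dia, field_mhz, t_inept_ms) {
  g <- oracle_gamma2(r, tauc_ns, field_mhz)
  r2_dia * exp(-g * t_inept_ms * 1e-3) / (r2_dia + g)
}

# Standard ITC ladder used throughout: peptide in the cell at 30 uM,
# tandem in the syringe at 450 uM, 26 injections of 1.5 uL (0.4 uL
# first) into a 200 uL cell.
standard_schedule <- function(cell_species = "peptide",
                              syringe_species = "WW12") {
  injection_schedule(cell_volume = 200, injections = c(0.4, rep(1.5, 25)),
                     spacing = 150, cell_conc = 30, syringe_conc = 450,
                     cell_species = cell_species,
                     syringe_species = syringe_species)
}
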