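# Internal polypeptide backbone builder (natural extension reference
# frame): places atoms from bond length, bond angle and torsion with
# respect to three previously placed atoms.  Used by the synthetic
# ensemble generator; idealised geometry, one CB per residue.

GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231, b_ca_cb = 1.530,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  a_ca_c_o = 120.8, a_n_ca_cb = 110.5, omega = 180
)

# Place atom D given A-B-C, |C-D|, angle(B,C,D) and torsion(A,B,C,D).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle); tor <- deg2rad(torsion)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + cbind(bc, m, n) %*% d2
}

# Build an n-residue backbone (N, CA, C, O, CB per residue) from phi/psi
# torsion vectors (degrees).  phi[1] is unused (no preceding carbonyl);
# psi[n] fixes the terminal O orientation.  Returns a list with an atoms
# data.frame and an (5n) x 3 coordinate matrix.
build_backbone <- function(phi, psi, chain = "A", first_resid = 1L,
                           resname = "ALA") {
  n <- length(phi)
  if (length(psi) != n) stopf("phi and psi lengths differ")
  coords <- matrix(NA_real_, nrow = 5L * n, ncol = 3L)
  idx <- function(i, atom) (i - 1L) * 5L + match(atom, c("N", "CA", "C", "O", "CB"))
  g <- GEOM
  # seed residue 1 in a canonical frame
  coords[idx(1, "N"), ] <- c(0, 0, 0)
  coords[idx(1, "CA"), ] <- c(g$b_n_ca, 0, 0)
  ang <- deg2rad(180 - g$a_n_ca_c)
  coords[idx(1, "C"), ] <- coords[idx(1, "CA"), ] +
    g$b_ca_c * c(cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    N <- coords[idx(i, "N"), ]; CA <- coords[idx(i, "CA"), ]
    C <- coords[idx(i, "C"), ]
    if (i < n) {
      Nn <- place_atom(N, CA, C, g$b_c_n, g$a_ca_c_n, psi[i])
      coords[idx(i + 1, "N"), ] <- Nn
      CAn <- place_atom(CA, C, Nn, g$b_n_ca, g$a_c_n_ca, g$omega)
      coords[idx(i + 1, "CA"), ] <- CAn
      coords[idx(i + 1, "C"), ] <- place_atom(C, Nn, CAn, g$b_ca_c,
                                              g$a_n_ca_c, phi[i + 1])
      # carbonyl O anti to the next N across the C
      coords[idx(i, "O"), ] <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o,
                                          psi[i] + 180)
    } else {
      coords[idx(i, "O"), ] <- place_atom(N, CA, C, g$b_c_o, g$a_ca_c_o,
                                          psi[i] + 180)
    }
    coords[idx(i, "CB"), ] <- place_atom(C, N, CA, g$b_ca_cb, g$a_n_ca_cb,
                                         122.5)
  }
  atoms <- data.frame(
    chain = chain,
    resid = rep(first_resid + seq_len(n) - 1L, each = 5L),
    resname = resname,
    elety = rep(c("N", "CA", "C", "O", "CB"), n),
    stringsAsFactors = FALSE)
  list(atoms = atoms, coords = coords)
}

# Rigid transform mapping three source points onto three target points
# (exact when both triples share internal geometry; least-squares
# otherwise).  Returns a function applying the transform to an n x 3
# matrix.
frame_transform <- function(src, dst) {
  f <- kabsch_superpose(src, dst)
  function(x) apply_superposition(x, list(rotation = f$rotation,
                                          translation = f$translation,
                                          center = f$center))
}
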