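# Saupe tensor SVD fitting, back-calculation, Q factors, comparisons.

test_that("noiseless RDCs refit to the generating Saupe tensor exactly", {
  ens <- tiny_dumbbell()
  set.seed(5)
  for (k in 1:5) {
    s <- random_saupe()
    rd <- make_rdc_set(ens, s, conformer = 1, noise_sd = 0, seed = 50 + k)
    fit <- svd_fit(ens, rd)
    expect_lt(max(abs(fit$tensor$saupe - s)), 1e-12)
    expect_lt(fit$q_factor, 1e-9)
    expect_lt(fit$rmsd_hz, 1e-9)
  }
})

test_that("SVD solution agrees with brute-force normal equations", {
  ens <- tiny_dumbbell()
  set.seed(17)
  for (k in 1:20) {
    s <- random_saupe()
    rd <- make_rdc_set(ens, s, conformer = 1, noise_sd = 0.5, seed = 200 + k)
    fit <- svd_fit(ens, rd)
    # independent solve: rebuild the design matrix from geometry and use
    # the normal equations
    hp <- amide_h_positions(ens, 1)
    idx <- match(rd$residue, hp$resid)
    v <- cbind(hp$hx - hp$nx, hp$hy - hp$ny, hp$hz - hp$nz)[idx, ]
    v <- v / sqrt(rowSums(v^2))
    A <- dmax_nh() * t(apply(v, 1, function(u) {
      c(u[1]^2 - u[3]^2, u[2]^2 - u[3]^2,
        2 * u[1] * u[2], 2 * u[1] * u[3], 2 * u[2] * u[3])
    }))
    ne <- solve(crossprod(A), crossprod(A, rd$d_obs))
    S_ne <- matrix(c(ne[1], ne[3], ne[4], ne[3], ne[2], ne[5],
                     ne[4], ne[5], -ne[1] - ne[2]), 3, 3)
    expect_equal(fit$tensor$saupe, S_ne, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("zero tensor back-calculates to zero; axial vector gives 2*Da", {
  ens <- tiny_dumbbell()
  z <- back_calculate(matrix(0, 3, 3), ens)
  expect_true(all(abs(z$d_obs) < 1e-15))
  # axially symmetric tensor: vector along the unique axis reads 2*Da
  szz <- 4e-4
  s_ax <- diag(c(-szz / 2, -szz / 2, szz))
  t_ax <- alignment_tensor(s_ax)
  d_along_z <- dmax_nh() * szz  # forward equation for v = z
  expect_equal(d_along_z, 2 * t_ax$da, tolerance = 1e-12)
  expect_equal(t_ax$rhombicity, 0, tolerance = 1e-12)
})

test_that("fit-then-back-calculate is idempotent at zero noise", {
  ens <- tiny_dumbbell()
  s <- random_saupe()
  rd <- make_rdc_set(ens, s, conformer = 1, noise_sd = 0, seed = 31)
  fit <- svd_fit(ens, rd)
  back <- back_calculate(fit$tensor, ens)
  m <- match(rd$residue, back$residue)
  expect_equal(back$d_obs[m], rd$d_obs, tolerance = 1e-9)
})

test_that("doubling observed couplings doubles Da, preserves orientation", {
  ens <- tiny_dumbbell()
  set.seed(77)
  s <- random_saupe()
  rd <- make_rdc_set(ens, s, conformer = 1, noise_sd = 0, seed = 7)
  rd2 <- rd; rd2$d_obs <- 2 * rd$d_obs
  f1 <- svd_fit(ens, rd); f2 <- svd_fit(ens, rd2)
  expect_equal(f2$tensor$da / f1$tensor$da, 2, tolerance = 1e-9)
  expect_equal(f2$tensor$rhombicity, f1$tensor$rhombicity, tolerance = 1e-9)
  cmp <- compare_domain_tensors(f1, f2)
  expect_true(all(cmp$axis_angles < 1e-6))
})

test_that("parallel N-H vectors are rejected as degenerate geometry", {
  # straight artificial chain: every N-H vector identical
  n <- 8
  atoms <- data.frame(chain = "A", resid = rep(1:n, each = 3),
                      resname = "ALA",
                      elety = rep(c("N", "CA", "C"), n))
  coords <- matrix(0, 3 * n, 3)
  for (i in 1:n) {
    base <- (i - 1) * 3.8
    coords[(i - 1) * 3 + 1, ] <- c(base, 0, 0)        # N
    coords[(i - 1) * 3 + 2, ] <- c(base + 1.4, 0, 0)  # CA
    coords[(i - 1) * 3 + 3, ] <- c(base + 2.5, 0, 0)  # C
  }
  # add explicit parallel H atoms
  atoms_h <- data.frame(chain = "A", resid = 1:n, resname = "ALA", elety = "H")
  coords_h <- coords[seq(1, 3 * n, by = 3), ] + matrix(rep(c(0, 1.02, 0), n),
                                                       ncol = 3, byrow = TRUE)
  ens <- structure_ensemble(rbind(atoms, atoms_h),
                            matrix(as.numeric(t(rbind(coords, coords_h))),
                                   nrow = 1))
  rd <- rdc_set(1:n, rnorm(n), d_err = 0.5)
  expect_error(svd_fit(ens, rd), "degenerate")
})

test_that("Q factor and couplings are invariant under joint rotation", {
  ens <- tiny_dumbbell()
  s <- random_saupe()
  rd <- make_rdc_set(ens, s, conformer = 1, noise_sd = 0.8, seed = 12)
  fit <- svd_fit(ens, rd)
  rot <- rotation_matrix(c(1, 2, 0.5), 63)
  ens_rot <- ens
  xyz <- conformer_coords(ens, 1) %*% t(rot)
  ens_rot$xyz[1, ] <- as.numeric(t(xyz))
  # rotating structure and tensor together leaves back-calculation fixed
  s_rot <- rot %*% s %*% t(rot)
  d0 <- back_calculate(s, ens)
  d1 <- back_calculate(s_rot, ens_rot)
  expect_equal(d1$d_obs, d0$d_obs, tolerance = 1e-9)
  fit_rot <- svd_fit(ens_rot, rd)
  expect_equal(fit_rot$q_factor, fit$q_factor, tolerance = 1e-9)
  expect_equal(fit_rot$rmsd_hz, fit$rmsd_hz, tolerance = 1e-9)
})

test_that("tensor parameters round-trip to the same Saupe matrix", {
  set.seed(23)
  for (k in 1:10) {
    s <- random_saupe()
    t1 <- alignment_tensor(s)
    # rebuild from eigen decomposition: S = V diag(vals) V'
    s_back <- t1$axes %*% diag(t1$eigvals) %*% t(t1$axes)
    expect_equal(s_back, s, tolerance = 1e-10, ignore_attr = TRUE)
    expect_gte(t1$rhombicity, 0)
    expect_lte(t1$rhombicity, 2 / 3 + 1e-12)
  }
})

test_that("identical tensors compare as identity; mobile domains diverge", {
  ens <- tiny_dumbbell()
  s <- random_saupe()
  rd <- make_rdc_set(ens, s, conformer = 1, noise_sd = 0, seed = 3)
  dom <- attr(ens, "domains")
  sel1 <- selection(data.frame(chain = "A", start = dom$domain1[1],
                               end = dom$domain1[2]))
  sel2 <- selection(data.frame(chain = "A", start = dom$domain2[1],
                               end = dom$domain2[2]))
  f1 <- suppressWarnings(svd_fit(ens, rd, sel1))
  self_cmp <- compare_domain_tensors(f1, f1)
  expect_equal(self_cmp$da_ratio, 1)
  expect_equal(self_cmp$rhombicity_diff, 0)
  expect_lt(max(self_cmp$axis_angles), 1e-5)
  # rigid conformer: both domains report the same (global) tensor
  f2 <- suppressWarnings(svd_fit(ens, rd, sel2))
  rigid_cmp <- compare_domain_tensors(f1, f2)
  expect_true(all(rigid_cmp$axis_angles < 1))
  expect_equal(rigid_cmp$da_ratio, 1, tolerance = 1e-6)
  # mobile ensemble: per-conformer tensors fitted on re-oriented domain-2
  # data disagree in orientation
  rd_other <- make_rdc_set(ens, s, conformer = 3, noise_sd = 0, seed = 3)
  f2_mobile <- suppressWarnings(svd_fit(ens, rd_other, sel2, conformer = 1))
  mobile_cmp <- compare_domain_tensors(f1, f2_mobile)
  expect_gt(max(mobile_cmp$axis_angles), 5)
})

test_that("Monte-Carlo tensor errors are seeded, vanish and scale with d_err", {
  ens <- tiny_dumbbell()
  s <- random_saupe()
  rd <- make_rdc_set(ens, s, conformer = 1, noise_sd = 0, seed = 40)
  rd$d_err <- 0.05  # small-error (linear) regime
  e1 <- mc_errors(ens, rd, n_draws = 100, seed = 6)
  e1b <- mc_errors(ens, rd, n_draws = 100, seed = 6)
  expect_identical(e1$sds, e1b$sds)
  rd_small <- rd; rd_small$d_err <- 1e-6
  e_small <- mc_errors(ens, rd_small, n_draws = 100, seed = 6)
  expect_true(all(e_small$sds < 1e-3 * max(e1$sds)))
  rd_double <- rd; rd_double$d_err <- 0.1
  e2 <- mc_errors(ens, rd_double, n_draws = 100, seed = 6)
  expect_equal(unname(e2$sds["da"] / e1$sds["da"]), 2, tolerance = 0.05)
})
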