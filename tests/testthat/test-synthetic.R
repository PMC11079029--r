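# Ground-truth generators: determinism, postconditions, round trips.

test_that("every generator regenerates byte-identically under a fixed seed", {
  t1 <- make_titration(seed = 7); t2 <- make_titration(seed = 7)
  expect_identical(t1, t2)
  r1 <- make_relaxation_series(rate = 2, seed = 7)
  r2 <- make_relaxation_series(rate = 2, seed = 7)
  expect_identical(r1, r2)
  e1 <- make_dumbbell_ensemble(n_conformers = 20, domain_size = 6,
                               linker_length = 4, seed = 7)
  e2 <- make_dumbbell_ensemble(n_conformers = 20, domain_size = 6,
                               linker_length = 4, seed = 7)
  expect_identical(e1, e2)
  expect_equal(n_conformers(e1), 20L)
  s <- random_saupe()
  d1 <- make_rdc_set(e1, s, seed = 7); d2 <- make_rdc_set(e2, s, seed = 7)
  expect_identical(d1, d2)
  sched <- standard_schedule()
  m <- binding_model("one_site", 1, kd = 1.4, dh = -8)
  i1 <- make_itc_isotherm(m, sched, seed = 7)
  i2 <- make_itc_isotherm(m, sched, seed = 7)
  expect_identical(i1, i2)
  p1 <- make_pre_set(e1, label_site(3), seed = 7)
  p2 <- make_pre_set(e1, label_site(3), seed = 7)
  expect_identical(p1, p2)
})

test_that("titration generator postconditions hold in both regimes", {
  # no perturbation: every CSP stays within the noise floor
  quiet <- make_titration(n_residues = 25, interface = 3:6, max_csp = 0,
                          noise_sd = 0.002, ratios = c(1, 2), seed = 5)
  tab <- series_csp(quiet$series[[2]], quiet$free)
  expect_true(all(tab$csp[tab$flag == "measured"] <= 3 * 0.002 * 2))
  # noiseless saturating ladder: endpoint CSP equals max_csp exactly
  exact <- make_titration(n_residues = 20, interface = c(2, 9, 15),
                          max_csp = 0.3, ratios = c(0.5, 1, 2, 4),
                          noise_sd = 0, seed = 5)
  tab2 <- series_csp(exact$series[[4]], exact$free)
  expect_equal(tab2$csp[tab2$residue %in% c(2, 9, 15)], rep(0.3, 3),
               tolerance = 1e-12)
  # fast exchange moves linearly in bound fraction
  half <- series_csp(exact$series[[1]], exact$free)  # ratio 0.5
  expect_equal(half$csp[half$residue %in% c(2, 9, 15)], rep(0.15, 3),
               tolerance = 1e-12)
  # slow exchange: free peak fades, bound peak grows at the endpoint
  slow <- make_titration(n_residues = 10, interface = 2:4, max_csp = 0.3,
                         ratios = c(0.25, 0.75, 1.5), regime = "slow",
                         noise_sd = 0, seed = 5)
  pk <- slow$series[[2]]$peaks  # ratio 0.75
  expect_equal(unique(pk$intensity[pk$atom == "HN_free"]), 0.25)
  expect_equal(unique(pk$intensity[pk$atom == "HN_bound"]), 0.75)
  pk_sat <- slow$series[[3]]$peaks
  expect_equal(unique(pk_sat$intensity[pk_sat$atom == "HN_free"]), 0)
  # inconsistent requests are rejected
  expect_error(make_titration(interface = integer(0), max_csp = 0.2, seed = 1),
               "inconsistent")
  expect_error(make_titration(ratios = c(2, 1), seed = 1), "ascending")
})

test_that("dumbbell ensembles honour rigidity, clash and retry contracts", {
  rigid <- make_dumbbell_ensemble(n_conformers = 3, domain_size = 6,
                                  linker_length = 3, linker_dispersion = 0,
                                  seed = 4)
  # rigid limit: conformers are identical outright
  expect_equal(max(abs(sweep(rigid$xyz, 2, rigid$xyz[1, ]))), 0)
  # atom inventory: N, CA, C, O, CB per residue
  expect_identical(unique(rigid$atoms$elety), c("N", "CA", "C", "O", "CB"))
  # an impossible geometry request fails with a clear error
  expect_error(make_dumbbell_ensemble(n_conformers = 2, domain_size = 8,
                                      linker_length = 1,
                                      linker_dispersion = 170, seed = 1,
                                      clash_dist = 30, max_retries = 3),
               "clash-free")
})

test_that("noiseless generator outputs invert exactly through the fitters", {
  # relaxation
  s <- make_relaxation_series(rate = 7.5, i0 = 2, noise_sd = 0, seed = 2)
  expect_equal(fit_exponential(s)$rate, 7.5, tolerance = 1e-9)
  # RDC
  ens <- tiny_dumbbell(seed = 19)
  saupe <- random_saupe()
  rd <- make_rdc_set(ens, saupe, noise_sd = 0, seed = 2)
  expect_lt(max(abs(svd_fit(ens, rd)$tensor$saupe - saupe)), 1e-12)
  # ITC
  sched <- standard_schedule()
  m <- binding_model("one_site", n_sites = 1, kd = 1.4, dh = -8)
  fit <- fit_isotherm(make_itc_isotherm(m, sched, noise_sd = 0, seed = 2))
  expect_equal(coef(fit)[["kd"]], 1.4, tolerance = 1e-6)
  expect_equal(coef(fit)[["n_sites"]], 1, tolerance = 1e-6)
  expect_equal(coef(fit)[["dh"]], -8, tolerance = 1e-6)
})

test_that("zero-tensor RDC sets are pure noise around zero", {
  ens <- tiny_dumbbell(seed = 19)
  rd <- make_rdc_set(ens, matrix(0, 3, 3), noise_sd = 0.5, seed = 44)
  expect_lt(max(abs(rd$d_obs)), 5 * 0.5)
  expect_gt(sd(rd$d_obs), 0.2)
})

test_that("ground-truth records accompany generated data", {
  tt <- make_titration(seed = 3)
  expect_s3_class(tt$truth, "ground_truth")
  expect_identical(tt$truth$kind, "titration")
  expect_identical(tt$truth$seed, 3)
  e <- make_itc_isotherm(binding_model("one_site", 1, 1.4, -8),
                         standard_schedule(), seed = 3)
  expect_identical(attr(e, "truth")$parameters$kd, 1.4)
})
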