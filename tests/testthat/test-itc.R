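# ITC forward model, fitting, and the autoinhibition competition model.

test_that("forward model conserves mass through the dilution recursion", {
  sched <- standard_schedule()
  m <- binding_model("one_site", n_sites = 1, kd = 1.4, dh = -8)
  fw <- wwtandem:::itc_forward(m, sched)
  v0 <- sched$cell_volume
  # track totals independently
  mt <- sched$cell_conc; xt <- 0
  for (i in seq_along(sched$injections)) {
    f <- 1 - sched$injections[i] / v0
    mt <- mt * f
    xt <- xt * f + sched$syringe_conc * sched$injections[i] / v0
    expect_equal(fw$ledger[i, "cell_uM"], mt, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(fw$ledger[i, "titrant_uM"], xt, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_lte(fw$ledger[i, "bound_uM"], min(mt, xt) + 1e-12)
  }
})

test_that("degenerate forward cases: zero enthalpy and the tight-binding step", {
  sched <- standard_schedule()
  zero <- simulate_isotherm(binding_model("one_site", 1, kd = 1, dh = 0), sched)
  expect_true(all(zero$heats == 0))
  # very tight binding: constant heat per injection until molar ratio 1
  tight <- simulate_isotherm(binding_model("one_site", 1, kd = 1e-6, dh = -10),
                             sched)
  pre_sat <- which(tight$molar_ratio < 0.8)[-1]
  expect_lt(diff(range(tight$heats[pre_sat])), 1e-3)
  post <- which(tight$molar_ratio > 1.3)
  expect_true(all(abs(tight$heats[post]) < 1e-3))
  # total heat ~ dH x initial moles of the limiting (cell) species;
  # slightly less because perfusion displaces some unbound material
  # before the titration saturates
  total_ucal <- sum(tight$heats)
  limit_ucal <- -10 * sched$cell_conc * sched$cell_volume * 1e-3
  expect_equal(total_ucal, limit_ucal, tolerance = 0.05)
  expect_gt(total_ucal, limit_ucal)  # |heat| bounded by the limiting moles
})

test_that("noiseless isotherms round-trip (N, Kd, dH) across the study grid", {
  sched <- standard_schedule()
  for (kd in c(0.5, 1.4, 8.8, 10, 30)) {
    for (n in c(0.33, 1, 3)) {
      for (dh in c(-2, -10)) {
        m <- binding_model("one_site", n_sites = n, kd = kd, dh = dh)
        fit <- suppressWarnings(fit_isotherm(simulate_isotherm(m, sched)))
        expect_equal(fit$model$n_sites, n, tolerance = 1e-6)
        expect_equal(fit$model$kd, kd, tolerance = 1e-6)
        expect_equal(fit$model$dh, dh, tolerance = 1e-6)
      }
    }
  }
})

test_that("fits tolerate realistic heat noise", {
  sched <- standard_schedule()
  m <- binding_model("one_site", 1, kd = 1.4, dh = -8)
  kds <- vapply(1:10, function(k) {
    e <- make_itc_isotherm(m, sched, noise_sd = 0.1, seed = 900 + k)
    fit_isotherm(e)$model$kd
  }, 1.0)
  expect_equal(mean(kds), 1.4, tolerance = 0.1)
})

test_that("flat isotherms and short schedules are rejected", {
  sched <- standard_schedule()
  flat <- simulate_isotherm(binding_model("one_site", 1, kd = 1, dh = 0), sched)
  expect_error(fit_isotherm(flat), "flat isotherm")
  short <- injection_schedule(injections = c(0.4, rep(1.5, 5)),
                              cell_conc = 30, syringe_conc = 450)
  e <- simulate_isotherm(binding_model("one_site", 1, kd = 1.4, dh = -8), short)
  expect_error(fit_isotherm(e), ">= 8 informative")
})

test_that("autoinhibited model with k_closed = 0 reduces to one-site", {
  sched <- standard_schedule()
  a <- simulate_isotherm(binding_model("one_site", 1, kd = 2, dh = -6), sched)
  b <- simulate_isotherm(binding_model("autoinhibited", 1, kd = 2, dh = -6,
                                       k_closed = 0), sched)
  expect_equal(a$heats, b$heats, tolerance = 1e-12)
})

test_that("closed-form apparent Kd matches the numerical equilibrium solver", {
  # three-species solver satisfies its equilibrium and mass balances
  for (kd in c(0.5, 1.4, 10)) {
    for (k in c(0, 0.3, 5.2857142857, 20)) {
      for (rt in c(5, 30, 200)) {
        for (lt in c(1, 25, 300)) {
          sp <- solve_equilibrium(rt, lt, kd, k)
          expect_equal(sp[["open"]] * (1 + k) + sp[["bound"]], rt,
                       tolerance = 1e-10 * rt)
          expect_equal(sp[["free_ligand"]] + sp[["bound"]], lt,
                       tolerance = 1e-10 * lt)
          if (sp[["open"]] > 0) {
            expect_equal(sp[["closed"]] / sp[["open"]], k, tolerance = 1e-8)
            expect_equal(sp[["open"]] * sp[["free_ligand"]] / sp[["bound"]],
                         kd, tolerance = 1e-8 * kd)
          }
          # the same bound concentration arises from the one-site
          # quadratic with Kd_app = Kd (1 + k_closed)
          b_closed_form <- wwtandem:::bound_quadratic(rt, lt,
                                                      kd_apparent(kd, k))
          expect_equal(sp[["bound"]], b_closed_form, tolerance = 1e-8)
        }
      }
    }
  }
  expect_equal(kd_apparent(1.4, 0), 1.4)
  expect_equal(kd_apparent(1.4, 8.8 / 1.4 - 1), 8.8, tolerance = 1e-12)
})

test_that("numerical solver agrees with a brute-force free-ligand scan", {
  set.seed(55)
  for (k in 1:10) {
    rt <- runif(1, 1, 100); lt <- runif(1, 1, 100)
    kd <- runif(1, 0.1, 20); kc <- runif(1, 0, 10)
    sp <- solve_equilibrium(rt, lt, kd, kc)
    l_grid <- seq(0, lt, length.out = 2e5)
    fval <- abs(l_grid + rt * l_grid / (kd * (1 + kc) + l_grid) - lt)
    l_brute <- l_grid[which.min(fval)]
    expect_equal(sp[["free_ligand"]], l_brute, tolerance = 1e-3)
  }
  # boundary: no ligand
  sp0 <- solve_equilibrium(10, 0, 1, 4)
  expect_equal(sp0[["bound"]], 0)
  expect_equal(sp0[["open"]], 2)
  expect_equal(sp0[["closed"]], 8)
})

test_that("the N-terminal extension lowers the apparent affinity as Kd(1+k)", {
  sched <- standard_schedule()
  kd0 <- 1.4
  k_closed <- 8.8 / 1.4 - 1
  auto <- simulate_isotherm(binding_model("autoinhibited", 1, kd = kd0,
                                          dh = -8, k_closed = k_closed),
                            sched)
  fit <- fit_isotherm(auto, variant = "one_site")
  expect_equal(fit$model$kd, kd_apparent(kd0, k_closed), tolerance = 1e-4)
  expect_equal(fit$model$n_sites, 1, tolerance = 1e-5)
})

test_that("stoichiometry interpretation converts fitted N by titration role", {
  # multivalent peptide construct in the syringe, tandem in the cell:
  # each peptide engages 3 tandems so sites-per-tandem is 1/3
  sched <- standard_schedule(cell_species = "WW12",
                             syringe_species = "SF1_Cterm")
  m <- binding_model("one_site", n_sites = 1 / 3, kd = 1.4, dh = -8)
  fit <- fit_isotherm(simulate_isotherm(m, sched))
  expect_equal(tandems_per_peptide(fit, tandem_in = "cell"), 3,
               tolerance = 1e-5)
  # peptide in the cell: fitted N counts tandems per peptide directly
  expect_equal(tandems_per_peptide(binding_model("one_site", 3, 1, -8),
                                   tandem_in = "syringe"), 3)
})

test_that("first-injection exclusion and the Wiseman warning behave", {
  sched <- standard_schedule()
  m <- binding_model("one_site", 1, kd = 1.4, dh = -8)
  e <- simulate_isotherm(m, sched)
  # corrupt the small first injection: the default fit must not care
  e_bad <- e
  e_bad$heats[1] <- e$heats[1] + 5
  fit <- fit_isotherm(e_bad)
  expect_equal(fit$model$kd, 1.4, tolerance = 1e-6)
  # weak binding far outside the informative c range warns
  weak <- simulate_isotherm(binding_model("one_site", 1, kd = 4000, dh = -8),
                            sched)
  expect_warning(try(fit_isotherm(weak), silent = TRUE), "Wiseman|informative")
})

test_that("ITC text files round-trip schedule and heats", {
  sched <- standard_schedule()
  e <- simulate_isotherm(binding_model("one_site", 1, kd = 1.4, dh = -8), sched)
  tf <- tempfile(fileext = ".tsv")
  write_itc(e, tf)
  back <- read_itc(tf)
  expect_equal(back$heats, e$heats, tolerance = 1e-9)
  expect_equal(back$schedule$cell_conc, 30)
  expect_equal(back$schedule$injections, sched$injections)
  fit <- fit_isotherm(back)
  expect_equal(fit$model$kd, 1.4, tolerance = 1e-6)
  unlink(tf)
})
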