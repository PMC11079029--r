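# Ensemble I/O, Kabsch superposition and r.m.s.d. statistics.

test_that("multi-MODEL PDB writing and reading round-trips", {
  ens <- tiny_dumbbell(n_conformers = 4, seed = 3)
  tf <- tempfile(fileext = ".pdb")
  write_ensemble(ens, tf)
  back <- read_ensemble(tf)
  expect_equal(n_conformers(back), 4L)
  expect_equal(back$atoms$resid, ens$atoms$resid)
  expect_equal(back$atoms$elety, ens$atoms$elety)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3 + 1e-9)  # PDB precision
  # selections resolve identically on the re-read ensemble
  sel <- selection(data.frame(chain = "A", start = 3, end = 9), "backbone")
  expect_equal(resolve_selection(back, sel), resolve_selection(ens, sel))
  unlink(tf)
})

test_that("lenient reading intersects inconsistent MODEL inventories", {
  ens <- tiny_dumbbell(n_conformers = 2, seed = 3)
  tf <- tempfile(fileext = ".pdb")
  write_ensemble(ens, tf)
  lines <- readLines(tf)
  # drop one atom line from MODEL 2 only
  i2 <- grep("^MODEL", lines)[2]
  atom_lines <- grep("^ATOM", lines)
  drop <- atom_lines[atom_lines > i2][1]
  writeLines(lines[-drop], tf)
  expect_warning(back <- read_ensemble(tf, lenient = TRUE), "differ")
  expect_equal(nrow(back$atoms), nrow(ens$atoms) - 1L)
  unlink(tf)
})

test_that("superposition: identity on self, exact on rigid copies", {
  ens <- tiny_dumbbell(n_conformers = 1, seed = 5)
  x <- conformer_coords(ens, 1)
  f_self <- kabsch_superpose(x, x)
  expect_equal(f_self$rmsd, 0, tolerance = 1e-10)
  expect_equal(f_self$rotation, diag(3), tolerance = 1e-9)
  rot <- rotation_matrix(c(0.3, -1, 2), 117)
  y <- x %*% t(rot) + matrix(c(5, -3, 8), nrow(x), 3, byrow = TRUE)
  f <- kabsch_superpose(y, x)
  expect_lt(f$rmsd, 1e-9)
  expect_equal(det(f$rotation), 1, tolerance = 1e-12)
})

test_that("superposition is optimal against a rotation-grid brute force", {
  set.seed(33)
  toy <- matrix(rnorm(15), 5, 3)
  target <- matrix(rnorm(15), 5, 3)
  best <- kabsch_superpose(toy, target)$rmsd
  # brute force: random proper rotations, optimal translation for each
  tc <- sweep(target, 2, colMeans(target))
  mc <- sweep(toy, 2, colMeans(toy))
  grid_best <- min(vapply(1:4000, function(k) {
    r <- rotation_matrix(rnorm(3), runif(1, 0, 360))
    sqrt(mean(rowSums((mc %*% t(r) - tc)^2)))
  }, 1.0))
  expect_lte(best, grid_best + 1e-12)
  expect_lt(grid_best - best, 0.15)  # grid comes close to the optimum
})

test_that("superposition rmsd agrees with an independent implementation", {
  ens <- tiny_dumbbell(n_conformers = 2, seed = 9)
  a <- conformer_coords(ens, 1); b <- conformer_coords(ens, 2)
  ours <- kabsch_superpose(a, b)$rmsd
  ref <- bio3d::rmsd(as.numeric(t(b)), as.numeric(t(a)), fit = TRUE)
  expect_equal(ours, ref, tolerance = 1e-3)
})

test_that("superposition rmsd is symmetric and rigid-transform invariant", {
  ens <- tiny_dumbbell(n_conformers = 2, seed = 9)
  a <- conformer_coords(ens, 1); b <- conformer_coords(ens, 2)
  r1 <- kabsch_superpose(a, b)$rmsd
  r2 <- kabsch_superpose(b, a)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  rot <- rotation_matrix(c(1, 1, 1), 40)
  a_moved <- a %*% t(rot) + 7
  expect_equal(kabsch_superpose(a_moved, b)$rmsd, r1, tolerance = 1e-9)
})

test_that("ensemble rmsd: zero for identical conformers, modes ordered", {
  rigid <- make_dumbbell_ensemble(n_conformers = 4, domain_size = 8,
                                  linker_length = 4, linker_dispersion = 0,
                                  seed = 1)
  r0 <- ensemble_rmsd(rigid, selection(), "to_mean")
  expect_equal(unname(r0), c(0, 0), tolerance = 1e-9)
  # pairwise >= to_mean across many generated ensembles
  for (k in 1:25) {
    e <- make_dumbbell_ensemble(n_conformers = 3, domain_size = 5,
                                linker_length = 4, linker_dispersion = 30,
                                seed = 700 + k)
    tm <- ensemble_rmsd(e, selection(), "to_mean")
    pw <- ensemble_rmsd(e, selection(), "pairwise")
    expect_gte(pw[["backbone_rmsd"]] + 1e-9, tm[["backbone_rmsd"]])
    expect_gte(pw[["heavy_rmsd"]] + 1e-9, tm[["heavy_rmsd"]])
  }
})

test_that("ensemble rmsd is invariant to conformer order and rigid moves", {
  ens <- tiny_dumbbell(n_conformers = 5, seed = 13)
  base <- ensemble_rmsd(ens, selection(), "to_mean")
  perm <- ens
  ord <- c(3, 1, 5, 2, 4)
  perm$xyz <- ens$xyz[ord, ]
  expect_equal(ensemble_rmsd(perm, selection(), "to_mean"), base,
               tolerance = 1e-9)
  moved <- ens
  rot <- rotation_matrix(c(2, 0, 1), 75)
  x <- conformer_coords(ens, 2) %*% t(rot) + 12
  moved$xyz[2, ] <- as.numeric(t(x))
  expect_equal(ensemble_rmsd(moved, selection(), "to_mean"), base,
               tolerance = 1e-9)
})

test_that("per-domain rigidity holds while the two-domain rmsd is large", {
  ens <- tiny_dumbbell(n_conformers = 5, seed = 11)
  dom <- attr(ens, "domains")
  for (d in dom) {
    sel <- selection(data.frame(chain = "A", start = d[1], end = d[2]))
    r <- ensemble_rmsd(ens, sel, "to_mean")
    expect_lt(r[["backbone_rmsd"]], 1e-9)
    expect_lt(r[["heavy_rmsd"]], 1e-9)
  }
  expect_gt(ensemble_rmsd(ens, selection(), "to_mean")[["backbone_rmsd"]],
            0.5)
})

test_that("selection parsing handles multi-range author numbering", {
  sel <- parse_selection("A:146-221,B:575-582,B:586-590", atoms = "backbone")
  expect_equal(nrow(sel$ranges), 3L)
  expect_identical(sel$ranges$chain, c("A", "B", "B"))
  expect_identical(sel$ranges$start, c(146L, 575L, 586L))
  expect_error(parse_selection("A:146"), "cannot parse")
})
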