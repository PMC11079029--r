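# Synthetic-data generators: every input class of the pipeline with
# known ground truth, so each fitting stage can be validated without
# experimental downloads.  All generators are pure functions of their
# parameters and a mandatory seed, and share the forward-model code
# paths the fitting stages invert.

#' Ground-truth record attached to generated data
#' @param kind One of titration, relaxation, ensemble, rdc, pre, itc.
#' @param parameters Named list of generating parameters.
#' @param seed Seed used.
#' @return Object of class \code{ground_truth}.
#' @export
ground_truth <- function(kind, parameters, seed) {
  kind <- match.arg(kind, c("titration", "relaxation", "ensemble",
                            "rdc", "pre", "itc"))
  structure(list(kind = kind, parameters = parameters, seed = seed),
            class = "ground_truth")
}

#' Generate a synthetic NMR titration
#'
#' Produces a free-state peak list and one peak list per ligand:protein
#' ratio.  Interface residues shift by a weighted CSP of exactly
#' \code{max_csp} at the saturated endpoint; non-interface residues are
#' perturbed only by noise.  In the fast-exchange regime a single peak
#' moves linearly in the bound fraction (tight-binding approximation:
#' bound fraction = min(ratio, 1)); in slow exchange the free peak
#' loses intensity while a bound peak grows at the endpoint position.
#'
#' @param n_residues Number of residues.
#' @param interface Integer set of interface residues (subset of
#'   1..n_residues).
#' @param max_csp Endpoint weighted CSP of interface residues (ppm).
#' @param ratios Non-negative ascending ligand:protein molar ratios.
#' @param regime "fast" or "slow".
#' @param noise_sd Per-peak 1H-equivalent shift noise (ppm).
#' @param seed RNG seed (mandatory).
#' @return List with \code{free} (a \code{titration_series} at ratio
#'   0), \code{series} (list of \code{titration_series}), and
#'   \code{truth} (a \code{ground_truth}).
#' @export
make_titration <- function(n_residues = 60, interface = c(10:14, 40:44),
                           max_csp = 0.2, ratios = c(0.25, 0.5, 1, 2),
                           regime = c("fast", "slow"), noise_sd = 0.002,
                           seed) {
  regime <- match.arg(regime)
  if (is.unsorted(ratios, strictly = TRUE) || any(ratios < 0)) {
    stopf("ratios must be non-negative and ascending")
  }
  if (!all(interface %in% seq_len(n_residues))) {
    stopf("interface residues outside 1..n_residues")
  }
  if (length(interface) == 0L && max_csp > 0) {
    stopf("empty interface with max_csp > 0 is inconsistent")
  }
  with_seed(seed, {
    res <- seq_len(n_residues)
    free_h <- runif(n_residues, 7.5, 9.5)
    free_n <- runif(n_residues, 105, 130)
    # endpoint shift direction per interface residue, scaled so the
    # weighted CSP equals max_csp exactly
    dh <- dn <- numeric(n_residues)
    if (length(interface)) {
      ang <- runif(length(interface), 0, 2 * pi)
      dh[interface] <- max_csp * sqrt(2) * cos(ang)
      dn[interface] <- max_csp * sqrt(2) * sin(ang) / sqrt(CSP_WEIGHTS[["N15"]])
    }
    noise <- function(n) rnorm(n, 0, noise_sd)
    free <- titration_series(0, peak_list(
      residue = res, shift_h = free_h, shift_x = free_n,
      intensity = 1), label = "free")
    series <- lapply(ratios, function(r) {
      fb <- min(r, 1)
      if (regime == "fast") {
        titration_series(r, peak_list(
          residue = res,
          shift_h = free_h + fb * dh + noise(n_residues),
          shift_x = free_n + fb * dn + noise(n_residues) / sqrt(CSP_WEIGHTS[["N15"]]),
          intensity = 1), label = sprintf("ratio %.3g", r))
      } else {
        # two co-existing peak sets: decaying free, growing bound
        pk_free <- peak_list(
          residue = res, atom = "HN_free",
          shift_h = free_h + noise(n_residues),
          shift_x = free_n + noise(n_residues) / sqrt(CSP_WEIGHTS[["N15"]]),
          intensity = 1 - fb)
        pk_bound <- peak_list(
          residue = res, atom = "HN_bound",
          shift_h = free_h + dh + noise(n_residues),
          shift_x = free_n + dn + noise(n_residues) / sqrt(CSP_WEIGHTS[["N15"]]),
          intensity = fb)
        titration_series(r, rbind(pk_free, pk_bound),
                         label = sprintf("ratio %.3g", r))
      }
    })
    list(free = free, series = series,
         truth = ground_truth("titration",
                              list(interface = interface, max_csp = max_csp,
                                   regime = regime, noise_sd = noise_sd),
                              seed))
  })
}

#' Generate a synthetic relaxation decay series
#'
#' I(t) = i0 * exp(-rate * t) plus fractional Gaussian noise; one delay
#' is measured twice (independent noise) for error estimation.
#'
#' @param rate Decay rate (1/s, > 0).
#' @param i0 Intensity at zero delay.
#' @param delays Delays in seconds (> 0, or 0 permitted).
#' @param duplicate_index Index into \code{delays} measured twice.
#' @param noise_sd Noise as a fraction of i0.
#' @param seed RNG seed.
#' @return A \code{relaxation_series} with attached ground truth in
#'   attribute "truth".
#' @export
make_relaxation_series <- function(rate, i0 = 1,
                                   delays = c(0.02, 0.06, 0.1, 0.15, 0.2,
                                              0.3, 0.4, 0.6, 0.8, 1.2),
                                   duplicate_index = 3L, noise_sd = 0.02,
                                   seed) {
  if (rate <= 0) stopf("rate must be positive")
  if (any(delays < 0)) stopf("delays must be non-negative")
  all_delays <- c(delays, delays[duplicate_index])
  with_seed(seed, {
    y <- i0 * exp(-rate * all_delays) + rnorm(length(all_delays), 0,
                                              noise_sd * i0)
    s <- relaxation_series(all_delays, y)
    attr(s, "truth") <- ground_truth("relaxation",
                                     list(rate = rate, i0 = i0,
                                          noise_sd = noise_sd), seed)
    s
  })
}

#' Generate a two-rigid-domain ("dumbbell") conformer ensemble
#'
#' Two internally rigid domains (identical internal coordinates across
#' conformers, enforced by rigid-body attachment of a fixed template)
#' joined by a linker whose backbone torsions are resampled per
#' conformer.  Atoms are N, CA, C, O, CB per residue.  Conformers with
#' interdomain steric overlap below \code{clash_dist} are resampled.
#'
#' @param n_conformers Number of conformers (>= 1).
#' @param domain_size Residues per rigid domain.
#' @param linker_length Linker residues.
#' @param linker_dispersion SD (degrees) of the per-conformer linker
#'   torsion resampling around an extended conformation; 0 gives a
#'   fully rigid molecule.
#' @param seed RNG seed.
#' @param clash_dist Interdomain clash cutoff (Angstrom).
#' @param max_retries Resampling attempts per conformer before failing.
#' @return A \code{structure_ensemble} with attributes "truth" and
#'   "domains" (list of residue ranges for the two rigid units).
#' @export
make_dumbbell_ensemble <- function(n_conformers = 20, domain_size = 12,
                                   linker_length = 6, linker_dispersion = 20,
                                   seed, clash_dist = 2.0, max_retries = 50) {
  if (n_conformers < 1L) stopf("need at least one conformer")
  n_total <- 2L * domain_size + linker_length
  # fixed torsions: beta-like domain 1, helix-like domain 2, extended linker
  phi <- rep(-135, n_total); psi <- rep(135, n_total)
  d2 <- (domain_size + linker_length + 1L):n_total
  phi[d2] <- -60; psi[d2] <- -45
  link <- (domain_size + 1L):(domain_size + linker_length)
  dom1_idx <- 1:(5L * domain_size)
  template <- build_backbone(phi, psi)  # reference chain, linker at base torsions
  dom2_atoms_idx <- (5L * (domain_size + linker_length) + 1L):(5L * n_total)
  # rigid domain-2 template in its own frame
  dom2_template <- template$coords[dom2_atoms_idx, , drop = FALSE]
  anchor_atoms <- function(coords) {
    # first residue of domain 2: N, CA, C rows within the domain block
    coords[1:3, , drop = FALSE]
  }
  with_seed(seed, {
    xyz <- matrix(NA_real_, n_conformers, 3L * nrow(template$atoms))
    for (ic in seq_len(n_conformers)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        ph <- phi; ps <- psi
        if (linker_dispersion > 0) {
          ph[link] <- phi[link] + rnorm(linker_length, 0, linker_dispersion)
          ps[link] <- psi[link] + rnorm(linker_length, 0, linker_dispersion)
        }
        chain <- build_backbone(ph, ps)
        coords <- chain$coords
        # replace the built domain-2 block by the rigidly moved template
        built_anchor <- anchor_atoms(coords[dom2_atoms_idx, , drop = FALSE])
        tmpl_anchor <- anchor_atoms(dom2_template)
        tf <- frame_transform(tmpl_anchor, built_anchor)
        coords[dom2_atoms_idx, ] <- tf(dom2_template)
        # domain 1 is the template's own block: identical in all conformers
        coords[dom1_idx, ] <- template$coords[dom1_idx, , drop = FALSE]
        d1 <- coords[dom1_idx, , drop = FALSE]
        d2c <- coords[dom2_atoms_idx, , drop = FALSE]
        mind <- min(sqrt(outer(rowSums(d1^2), rowSums(d2c^2), "+") -
                           2 * d1 %*% t(d2c)))
        if (linker_dispersion == 0 || mind >= clash_dist) { ok <- TRUE; break }
      }
      if (!ok) stopf("could not place domains clash-free after %d retries",
                     max_retries)
      xyz[ic, ] <- as.numeric(t(coords))
    }
    ens <- structure_ensemble(template$atoms, xyz)
    attr(ens, "domains") <- list(domain1 = c(1L, domain_size),
                                 domain2 = c(domain_size + linker_length + 1L,
                                             n_total))
    attr(ens, "truth") <- ground_truth("ensemble",
                                       list(domain_size = domain_size,
                                            linker_length = linker_length,
                                            linker_dispersion = linker_dispersion),
                                       seed)
    ens
  })
}

#' Generate a synthetic RDC set from a known alignment tensor
#'
#' Applies the forward dipolar equation (the \code{back_calculate}
#' code path) to the N-H vectors of one conformer, then adds noise.
#'
#' @param ens A \code{structure_ensemble}.
#' @param tensor An \code{alignment_tensor} or 3x3 Saupe matrix.
#' @param conformer Conformer index.
#' @param sel Optional \code{selection}.
#' @param noise_sd Gaussian noise (Hz).
#' @param seed RNG seed.
#' @return An \code{rdc_set} with d_err = max(noise_sd, 0.1) and
#'   attribute "truth".
#' @export
make_rdc_set <- function(ens, tensor, conformer = 1L, sel = NULL,
                         noise_sd = 0.5, seed) {
  clean <- back_calculate(tensor, ens, sel, conformer)
  with_seed(seed, {
    d <- clean$d_obs + if (noise_sd > 0) rnorm(nrow(clean), 0, noise_sd) else 0
    out <- rdc_set(clean$residue, d, d_err = max(noise_sd, 0.1),
                   chain = clean$chain)
    saupe <- if (inherits(tensor, "alignment_tensor")) tensor$saupe else tensor
    attr(out, "truth") <- ground_truth("rdc",
                                       list(saupe = saupe,
                                            noise_sd = noise_sd), seed)
    out
  })
}

#' Generate a synthetic PRE data set from a labeled ensemble
#'
#' Ensemble-mean back-calculated ratios (the \code{predict_profile}
#' code path) plus Gaussian noise.
#'
#' @param ens A \code{structure_ensemble}.
#' @param site A \code{label_site}.
#' @param params A \code{pre_params}.
#' @param noise_sd Gaussian noise on the ratios.
#' @param seed RNG seed.
#' @return A \code{pre_set} with attribute "truth".
#' @export
make_pre_set <- function(ens, site, params = pre_params(), noise_sd = 0.05,
                         seed) {
  prof <- predict_profile(ens, site, params)
  prof <- prof[prof$flag == "measured", ]
  with_seed(seed, {
    r <- prof$ratio_mean + if (noise_sd > 0)
      rnorm(nrow(prof), 0, noise_sd) else 0
    out <- pre_set(prof$resid, r, ratio_err = max(noise_sd, 1e-3),
                   chain = prof$chain)
    attr(out, "truth") <- ground_truth("pre",
                                       list(site = site$residue_id,
                                            tauc = params$tauc,
                                            noise_sd = noise_sd), seed)
    out
  })
}

#' Generate a synthetic ITC isotherm
#'
#' Forward model of \code{\link{simulate_isotherm}} plus Gaussian heat
#' noise, with the generating model recorded as ground truth.
#'
#' @param model A \code{binding_model}.
#' @param schedule An \code{injection_schedule}.
#' @param noise_sd Heat noise (ucal).
#' @param seed RNG seed.
#' @return An \code{itc_experiment} with attribute "truth".
#' @export
make_itc_isotherm <- function(model, schedule, noise_sd = 0.1, seed) {
  exp_ <- simulate_isotherm(model, schedule, noise_sd = noise_sd, seed = seed)
  attr(exp_, "truth") <- ground_truth("itc",
                                      list(n_sites = model$n_sites,
                                           kd = model$kd, dh = model$dh,
                                           k_closed = model$k_closed,
                                           noise_sd = noise_sd), seed)
  exp_
}
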