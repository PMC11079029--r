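# Isothermal titration calorimetry: forward model of one-site
# (identical sites) and autoinhibited (open/closed receptor) binding
# isotherms, nonlinear least-squares fitting, the apparent-affinity
# closed form, and a numerical three-species equilibrium solver.

#' Injection schedule for an ITC experiment
#'
#' The default mirrors the common protocol for this system: 26
#' injections of 1.5 uL (0.4 uL for the first) into a 200 uL cell,
#' 150 s apart.
#'
#' @param cell_volume Working cell volume (uL).
#' @param injections Injection volumes (uL), in order.
#' @param spacing Delay between injections (s; metadata only).
#' @param cell_conc,syringe_conc Concentrations (uM).
#' @param cell_species,syringe_species Labels recording which molecule
#'   sits where (e.g. "peptide" in the cell, "WW12" in the syringe).
#' @return Object of class \code{injection_schedule}.
#' @export
injection_schedule <- function(cell_volume = 200,
                               injections = c(0.4, rep(1.5, 25)),
                               spacing = 150,
                               cell_conc, syringe_conc,
                               cell_species = "cell",
                               syringe_species = "syringe") {
  if (any(injections <= 0)) stopf("injection volumes must be positive")
  if (cell_conc <= 0 || syringe_conc <= 0) stopf("concentrations must be positive")
  structure(list(cell_volume = cell_volume, injections = injections,
                 spacing = spacing, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, cell_species = cell_species,
                 syringe_species = syringe_species),
            class = "injection_schedule")
}

#' Binding model description
#'
#' \code{n_sites} counts binding sites per molecule of the *cell*
#' species (the macromolecule role); each site binds one molecule of
#' the titrant.  The autoinhibited variant adds a pre-equilibrium in
#' which a fraction k_closed/(1+k_closed) of the unbound receptor is in
#' a closed state inaccessible to the ligand.
#'
#' @param variant "one_site" or "autoinhibited".
#' @param n_sites Sites per cell-species molecule (> 0).
#' @param kd Intrinsic per-site dissociation constant (uM).
#' @param dh Binding enthalpy (kcal/mol of sites filled).
#' @param k_closed Closed/open equilibrium constant of the unbound
#'   receptor (dimensionless, >= 0; autoinhibited only).
#' @return Object of class \code{binding_model}.
#' @export
binding_model <- function(variant = c("one_site", "autoinhibited"),
                          n_sites = 1, kd, dh, k_closed = 0) {
  variant <- match.arg(variant)
  if (kd <= 0) stopf("kd must be positive")
  if (n_sites <= 0) stopf("n_sites must be positive")
  if (k_closed < 0) stopf("k_closed must be non-negative")
  structure(list(variant = variant, n_sites = n_sites, kd = kd, dh = dh,
                 k_closed = k_closed),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("binding_model (%s): N %.4g, Kd %.4g uM, dH %.4g kcal/mol%s\n",
              x$variant, x$n_sites, x$kd, x$dh,
              if (x$variant == "autoinhibited")
                sprintf(", k_closed %.4g", x$k_closed) else ""))
  invisible(x)
}

# Bound-site concentration (uM) for site total s_t, ligand total l_t and
# effective dissociation constant kd_eff, from the identical-sites
# quadratic.
bound_quadratic <- function(s_t, l_t, kd_eff) {
  b <- s_t + l_t + kd_eff
  disc <- b^2 - 4 * s_t * l_t
  0.5 * (b - sqrt(pmax(disc, 0)))
}

#' Numerically solve the open/closed/bound receptor equilibrium
#'
#' Species: receptor sites that are open (ligand-accessible), closed
#' (inaccessible, pre-equilibrium [closed]/[open] = k_closed among the
#' unbound receptor) or bound; plus free ligand.  Solved by bracketing
#' the free-ligand concentration.
#'
#' @param receptor_total,ligand_total Total concentrations (uM, >= 0).
#' @param kd Intrinsic dissociation constant of the open state (uM).
#' @param k_closed Closed/open constant (>= 0).
#' @return Named vector: open, closed, bound, free_ligand (uM).
#' @export
solve_equilibrium <- function(receptor_total, ligand_total, kd, k_closed = 0) {
  if (receptor_total < 0 || ligand_total < 0) stopf("totals must be non-negative")
  r_t <- receptor_total; l_t <- ligand_total
  if (l_t == 0 || r_t == 0) {
    open <- r_t / (1 + k_closed)
    return(c(open = open, closed = r_t - open, bound = 0, free_ligand = l_t))
  }
  kd_eff <- kd * (1 + k_closed)
  bound_of_l <- function(l) r_t * l / (kd_eff + l)
  f <- function(l) l + bound_of_l(l) - l_t
  scale <- max(r_t, l_t, kd_eff)
  sol <- uniroot(f, lower = 0, upper = l_t, tol = 1e-14 * scale,
                 maxiter = 2000)
  l <- sol$root
  b <- bound_of_l(l)
  open <- (r_t - b) / (1 + k_closed)
  c(open = open, closed = k_closed * open, bound = b, free_ligand = l)
}

#' Apparent dissociation constant under autoinhibition
#'
#' For a receptor whose unbound form pre-equilibrates between an open
#' state (binding with intrinsic Kd) and a closed state inaccessible to
#' ligand, the apparent constant measured by a one-site fit is
#' Kd_app = Kd * (1 + k_closed).
#'
#' @param kd_intrinsic Intrinsic Kd (uM).
#' @param k_closed Closed/open equilibrium constant.
#' @return Apparent Kd (uM).
#' @export
kd_apparent <- function(kd_intrinsic, k_closed) {
  if (any(kd_intrinsic <= 0)) stopf("kd must be positive")
  if (any(k_closed < 0)) stopf("k_closed must be non-negative")
  kd_intrinsic * (1 + k_closed)
}

# Core forward recursion over injections.  Returns per-injection heats
# (ucal) plus the concentration ledger.  The dilution convention:
# cell-resident amounts are scaled by (1 - dV/V0), then the injected
# moles are added; the same convention is used by the fitter.
itc_forward <- function(model, schedule, numerical = FALSE) {
  v0 <- schedule$cell_volume
  dv <- schedule$injections
  n_inj <- length(dv)
  m <- schedule$cell_conc      # cell (macromolecule) concentration, uM
  x <- 0                       # titrant concentration in cell, uM
  b_prev <- 0
  heats <- numeric(n_inj)
  ledger <- matrix(NA_real_, n_inj, 4,
                   dimnames = list(NULL, c("cell_uM", "titrant_uM",
                                           "bound_uM", "molar_ratio")))
  use_numerical <- model$variant == "autoinhibited" &&
    (numerical || model$k_closed > 0)
  for (i in seq_len(n_inj)) {
    f <- 1 - dv[i] / v0
    m <- m * f
    x <- x * f + schedule$syringe_conc * dv[i] / v0
    s_t <- model$n_sites * m
    b <- if (use_numerical) {
      unname(solve_equilibrium(s_t, x, model$kd, model$k_closed)["bound"])
    } else {
      kd_eff <- model$kd * (1 + model$k_closed)
      bound_quadratic(s_t, x, kd_eff)
    }
    # heat evolved by this injection (ucal): V0[uL] * dH[kcal/mol] *
    # d(bound uM) * 1e-3
    heats[i] <- v0 * model$dh * 1e-3 * (b - b_prev * f)
    b_prev <- b
    ledger[i, ] <- c(m, x, b, x / m)
  }
  list(heats = heats, ledger = ledger)
}

#' Simulate an ITC isotherm
#'
#' Forward model of the per-injection heats for a binding model and
#' injection schedule, with optional Gaussian noise.  The same forward
#' code path is inverted by \code{\link{fit_isotherm}}.
#'
#' @param model A \code{binding_model}.
#' @param schedule An \code{injection_schedule}.
#' @param noise_sd Gaussian noise on each heat (ucal); 0 for noiseless.
#' @param seed RNG seed (required when noise_sd > 0).
#' @return Object of class \code{itc_experiment}: schedule, heats
#'   (ucal), molar_ratio, blank_subtracted flag, model (the ground
#'   truth used for generation).
#' @export
simulate_isotherm <- function(model, schedule, noise_sd = 0, seed = NULL) {
  fw <- itc_forward(model, schedule)
  heats <- fw$heats
  if (noise_sd > 0) {
    heats <- with_seed(seed, heats + rnorm(length(heats), 0, noise_sd))
  }
  structure(list(schedule = schedule, heats = heats,
                 molar_ratio = fw$ledger[, "molar_ratio"],
                 blank_subtracted = TRUE, model = model),
            class = "itc_experiment")
}

#' @export
print.itc_experiment <- function(x, ...) {
  cat(sprintf("itc_experiment: %d injections, cell %s %.4g uM, syringe %s %.4g uM\n",
              length(x$heats), x$schedule$cell_species, x$schedule$cell_conc,
              x$schedule$syringe_species, x$schedule$syringe_conc))
  invisible(x)
}

#' Fit a binding model to an ITC isotherm
#'
#' Nonlinear least squares over (N, Kd, dH) plus an optional constant
#' per-injection heat-of-dilution offset (fitted by default).  The
#' first injection is excluded by default (the small-first-injection
#' convention).  Standard errors come from the fit covariance; the
#' Wiseman c value (N * cell_conc / Kd) is reported and a warning is
#' emitted outside [1, 1000].
#'
#' @param experiment An \code{itc_experiment}.
#' @param variant Model variant to fit ("one_site" fits the apparent
#'   constant; "autoinhibited" requires k_closed fixed via \code{fix}).
#' @param fix Named list pinning parameters (n_sites, kd, dh, offset,
#'   k_closed) at fixed values.
#' @param exclude_first Drop the first injection from the residuals.
#' @param fit_offset Fit the constant heat offset (default TRUE).
#' @param start Optional named starting values.
#' @return Object of class \code{itc_fit}.
#' @export
fit_isotherm <- function(experiment, variant = c("one_site", "autoinhibited"),
                         fix = list(), exclude_first = TRUE,
                         fit_offset = TRUE, start = NULL) {
  variant <- match.arg(variant)
  sched <- experiment$schedule
  heats <- experiment$heats
  n_inj <- length(heats)
  use <- if (exclude_first) 2:n_inj else 1:n_inj
  if (length(use) < 8L) stopf("need >= 8 informative injections")
  if (max(abs(heats[use])) < 1e-12) stopf("flat isotherm: nothing to fit")
  k_closed <- fix$k_closed %||% 0
  # dH and the constant offset enter the heats linearly, so they are
  # profiled out by linear least squares at every step (variable
  # projection); the nonlinear search runs only over log N and log Kd
  nl_names <- c(if (is.null(fix$n_sites)) "log_n",
                if (is.null(fix$kd)) "log_kd")
  dh_free <- is.null(fix$dh)
  off_free <- fit_offset && is.null(fix$offset)
  fixed_off <- fix$offset %||% 0
  y <- heats[use]
  base_at <- function(n, kd) {
    itc_forward(binding_model(variant, n_sites = n, kd = kd, dh = 1,
                              k_closed = k_closed), sched)$heats[use]
  }
  eval_at <- function(p) {
    n <- if (is.null(fix$n_sites)) exp(p[["log_n"]]) else fix$n_sites
    kd <- if (is.null(fix$kd)) exp(p[["log_kd"]]) else fix$kd
    b <- base_at(n, kd)
    x <- cbind(if (dh_free) b, if (off_free) rep(1, length(use)))
    target <- y - (if (dh_free) 0 else fix$dh * b) -
      (if (off_free) 0 else fixed_off)
    if (is.null(x)) {
      beta <- numeric(0); res <- target
    } else {
      beta <- qr.coef(qr(x), target)
      res <- as.numeric(target - x %*% beta)
    }
    list(res = res, n = n, kd = kd,
         dh = if (dh_free) beta[[1]] else fix$dh,
         offset = if (off_free) beta[[length(beta)]] else fixed_off)
  }
  resid_fn <- function(p) {
    names(p) <- nl_names
    eval_at(p)$res
  }
  # initial values: N from the molar ratio where the heat magnitude
  # halves (the isotherm inflection), Kd from the cell concentration
  ratio <- cumsum(sched$syringe_conc * sched$injections) /
    (sched$cell_conc * sched$cell_volume)  # approximate molar ratio ladder
  absq <- abs(heats)
  n0 <- start$n_sites %||% {
    drop_idx <- which(absq[use] < 0.5 * max(absq[use]))
    if (length(drop_idx)) max(ratio[use][drop_idx[1]], 0.05) else 1
  }
  kd0 <- start$kd %||% max(sched$cell_conc / 10, 1e-3)
  base_par <- c(log_n = log(n0), log_kd = log(kd0))[nl_names]
  if (length(nl_names) == 0L) {
    sol <- eval_at(numeric(0))
    deviance <- sum(sol$res^2)
  } else {
    best <- NULL
    nudges <- c(0, 0.7, -0.7)  # deterministic restart offsets
    for (trial in 1:3) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = base_par + nudges[trial], fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             ftol = 1e-15, ptol = 1e-15, maxiter = 1000)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
        best <- fit
      }
      if (!is.null(best) &&
          best$deviance < 1e-18 * max(sum(y^2), 1)) break
    }
    if (is.null(best)) stopf("isotherm fit failed to converge")
    # polish from the optimum so the numerical-Jacobian step size is
    # re-centred on the solution
    ref <- tryCatch(
      minpack.lm::nls.lm(par = best$par, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-15, ptol = 1e-15, maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(ref) && ref$deviance <= best$deviance) best <- ref
    p <- best$par; names(p) <- nl_names
    # final Gauss-Newton refinement with central differences: the
    # variable-projection residual is smooth in the two log parameters,
    # so a few steps reach solver precision
    dev <- sum(resid_fn(p)^2)
    hgn <- 1e-7
    for (step in 1:8) {
      r0 <- resid_fn(p)
      jac_nl <- vapply(seq_along(p), function(k) {
        pp <- p; pm <- p
        pp[k] <- pp[k] + hgn; pm[k] <- pm[k] - hgn
        (resid_fn(pp) - resid_fn(pm)) / (2 * hgn)
      }, numeric(length(r0)))
      delta <- tryCatch(qr.coef(qr(jac_nl), r0), error = function(e) NULL)
      if (is.null(delta) || anyNA(delta)) break
      cand <- p - delta  # residual Jacobian: step opposes qr solution
      dev_cand <- sum(resid_fn(cand)^2)
      if (!is.finite(dev_cand) || dev_cand >= dev) break
      p <- cand; dev <- dev_cand
    }
    sol <- eval_at(p)
    deviance <- sum(sol$res^2)
  }
  fitted_model <- binding_model(variant, n_sites = sol$n, kd = sol$kd,
                                dh = sol$dh, k_closed = k_closed)
  # standard errors from the full-model Jacobian at the solution
  b0 <- base_at(sol$n, sol$kd)
  h <- 1e-6
  jcols <- list()
  if (is.null(fix$n_sites)) {
    jcols$log_n <- sol$dh * (base_at(sol$n * exp(h), sol$kd) - b0) / h
  }
  if (is.null(fix$kd)) {
    jcols$log_kd <- sol$dh * (base_at(sol$n, sol$kd * exp(h)) - b0) / h
  }
  if (dh_free) jcols$dh <- b0
  if (off_free) jcols$offset <- rep(1, length(use))
  jac <- do.call(cbind, jcols)
  dof <- max(length(use) - ncol(jac), 1L)
  s2 <- deviance / dof
  cv <- tryCatch(solve(crossprod(jac)) * s2, error = function(e)
    matrix(NA_real_, ncol(jac), ncol(jac),
           dimnames = list(names(jcols), names(jcols))))
  dimnames(cv) <- list(names(jcols), names(jcols))
  se_of <- function(nm) if (nm %in% names(jcols)) sqrt(abs(cv[nm, nm])) else 0
  ses <- c(n_sites = sol$n * se_of("log_n"),
           kd = sol$kd * se_of("log_kd"),
           dh = se_of("dh"),
           offset = se_of("offset"))
  c_value <- fitted_model$n_sites * sched$cell_conc / fitted_model$kd
  if (c_value < 1 || c_value > 1000) {
    warnf("Wiseman c = %.3g outside [1, 1000]: isotherm poorly informative",
          c_value)
  }
  pred <- itc_forward(fitted_model, sched)$heats + sol$offset
  out <- list(model = fitted_model, offset = sol$offset, se = ses,
              c_value = c_value, residual_ss = deviance,
              fitted = pred, heats = heats, used = use,
              schedule = sched, variant = variant)
  class(out) <- "itc_fit"
  out
}

#' @export
print.itc_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf(paste0("itc_fit (%s): N %.4g +/- %.2g, Kd %.4g +/- %.2g uM, ",
                     "dH %.4g +/- %.2g kcal/mol\n  offset %.3g ucal, ",
                     "Wiseman c %.3g, RSS %.3g\n"),
              x$variant, m$n_sites, x$se[["n_sites"]], m$kd, x$se[["kd"]],
              m$dh, x$se[["dh"]], x$offset, x$c_value, x$residual_ss))
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(n_sites = object$model$n_sites, kd = object$model$kd,
    dh = object$model$dh, offset = object$offset)
}

#' @export
predict.itc_fit <- function(object, ...) object$fitted

#' @export
residuals.itc_fit <- function(object, ...) {
  (object$heats - object$fitted)[object$used]
}

#' Stoichiometry interpretation: tandem equivalents per peptide
#'
#' The fitted \code{n_sites} counts titrant molecules bound per
#' cell-species molecule.  When the multivalent peptide construct is
#' the titrant (syringe) and the WW tandem sits in the cell, a fitted
#' N < 1 means each peptide engages 1/N tandems; when the peptide is in
#' the cell, N itself counts tandems per peptide.
#'
#' @param fit An \code{itc_fit} (or \code{binding_model}).
#' @param tandem_in "cell" or "syringe": where the WW tandem construct
#'   was placed.
#' @return Tandem equivalents bound per peptide molecule.
#' @export
tandems_per_peptide <- function(fit, tandem_in = c("cell", "syringe")) {
  tandem_in <- match.arg(tandem_in)
  n <- if (inherits(fit, "itc_fit")) fit$model$n_sites else fit$n_sites
  if (tandem_in == "cell") 1 / n else n
}
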