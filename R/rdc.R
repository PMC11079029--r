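# Residual dipolar coupling analysis: Saupe alignment tensor fitting by
# SVD, back-calculation, quality factors, per-domain tensor comparison
# and Monte-Carlo parameter errors.
#
# Convention: D_i = Dmax * t(v_i) %*% S %*% v_i with S the symmetric
# traceless Saupe matrix and v_i the N-H unit vector.  In the tensor
# eigenframe D = Da * (3 cos^2 theta - 1 + 1.5 R sin^2 theta cos 2phi)
# with Da = Dmax * Szz / 2 and rhombicity R = (2/3)(Sxx - Syy)/Szz,
# eigenvalues ordered |Szz| >= |Syy| >= |Sxx| so that R in [0, 2/3].

#' Static dipolar interaction constant for the N-H vector
#'
#' Dmax such that D = Dmax * t(v) S v, computed from physical constants
#' for the given N-H bond length.
#'
#' @param r_nh N-H distance in Angstrom (1.02 by convention).
#' @return Constant in Hz.
#' @export
dmax_nh <- function(r_nh = 1.02) {
  mu0 <- 4e-7 * pi          # T m / A
  h <- 6.62607015e-34       # J s
  g_h <- 2.6752218744e8     # rad / s / T
  g_n <- -2.7126180436e7    # rad / s / T (15N, negative)
  -(mu0 * h * g_h * g_n) / (16 * pi^3 * (r_nh * 1e-10)^3)
}

#' Construct an RDC data set
#' @param residue Residue ids.
#' @param d_obs Observed 1D(NH) couplings (Hz).
#' @param d_err Measurement errors (Hz, > 0).
#' @param chain Chain id the residues live on.
#' @return data.frame of class \code{rdc_set}.
#' @export
rdc_set <- function(residue, d_obs, d_err = 0.5, chain = "A") {
  if (any(d_err <= 0)) stopf("d_err must be positive")
  if (anyDuplicated(residue)) stopf("duplicate residues in RDC set")
  s <- data.frame(chain = chain, residue = as.integer(residue),
                  d_obs = d_obs, d_err = d_err, stringsAsFactors = FALSE)
  class(s) <- c("rdc_set", "data.frame")
  s
}

# Pack/unpack the 5 independent Saupe elements (Sxx, Syy, Sxy, Sxz, Syz)
saupe_from_vec <- function(s) {
  m <- matrix(c(s[1], s[3], s[4],
                s[3], s[2], s[5],
                s[4], s[5], -s[1] - s[2]), 3, 3)
  m
}
saupe_to_vec <- function(m) c(m[1, 1], m[2, 2], m[1, 2], m[1, 3], m[2, 3])

#' Derived alignment-tensor parameters from a Saupe matrix
#'
#' Eigen-decomposes the (traceless, symmetric) Saupe matrix, orders the
#' eigenvalues by |Szz| >= |Syy| >= |Sxx| (choosing axes so that the
#' rhombicity is non-negative), and reports the axial magnitude
#' Da = Dmax*Szz/2, rhombicity R = (2/3)(Sxx-Syy)/Szz in [0, 2/3], and
#' ZYZ Euler angles of the principal axis frame.
#'
#' @param saupe 3x3 symmetric traceless matrix.
#' @param r_nh N-H bond length used for Dmax.
#' @return Object of class \code{alignment_tensor}: saupe, eigvals
#'   (Sxx, Syy, Szz), axes (columns x, y, z), da (Hz), rhombicity,
#'   euler_zyz (degrees).
#' @export
alignment_tensor <- function(saupe, r_nh = 1.02) {
  if (abs(sum(diag(saupe))) > 1e-9 * max(1, max(abs(saupe)))) {
    stopf("Saupe matrix must be traceless")
  }
  e <- eigen((saupe + t(saupe)) / 2, symmetric = TRUE)
  ord <- order(abs(e$values))            # |Sxx| <= |Syy| <= |Szz|
  vals <- e$values[ord]; vecs <- e$vectors[, ord, drop = FALSE]
  # enforce R >= 0: need (Sxx - Syy)/Szz >= 0, i.e. label the two minor
  # axes so the one with the larger magnitude is y
  if ((vals[1] - vals[2]) / vals[3] < 0) {
    vals <- vals[c(2, 1, 3)]; vecs <- vecs[, c(2, 1, 3), drop = FALSE]
  }
  # right-handed frame, z axis in the positive hemisphere
  if (vecs[3, 3] < 0) vecs[, 3] <- -vecs[, 3]
  if (vecs[1, 1] < 0) vecs[, 1] <- -vecs[, 1]
  vecs[, 2] <- vcross(vecs[, 3], vecs[, 1])
  dm <- dmax_nh(r_nh)
  da <- dm * vals[3] / 2
  rh <- if (abs(vals[3]) < 1e-15) 0 else (2 / 3) * (vals[1] - vals[2]) / vals[3]
  # ZYZ Euler angles of the rotation taking lab to principal frame
  rzyz <- euler_zyz_from_matrix(vecs)
  structure(list(saupe = saupe, eigvals = c(sxx = vals[1], syy = vals[2],
                                            szz = vals[3]),
                 axes = vecs, da = da, rhombicity = rh, euler_zyz = rzyz,
                 r_nh = r_nh),
            class = "alignment_tensor")
}

euler_zyz_from_matrix <- function(r) {
  beta <- acos(min(1, max(-1, r[3, 3])))
  if (abs(sin(beta)) < 1e-10) {
    alpha <- atan2(r[2, 1], r[1, 1]); gamma <- 0
  } else {
    alpha <- atan2(r[2, 3], r[1, 3])
    gamma <- atan2(r[3, 2], -r[3, 1])
  }
  rad2deg(c(alpha = alpha, beta = beta, gamma = gamma))
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat(sprintf("alignment_tensor: Da %.4g Hz, rhombicity %.4f\n",
              x$da, x$rhombicity))
  invisible(x)
}

# N-H unit vectors for residues of a conformer within a selection.
nh_unit_vectors <- function(ens, conformer, sel = NULL) {
  hp <- amide_h_positions(ens, conformer)
  if (!is.null(sel) && !is.null(sel$ranges)) {
    keep <- rep(FALSE, nrow(hp))
    for (k in seq_len(nrow(sel$ranges))) {
      r <- sel$ranges[k, ]
      keep <- keep | (hp$chain == r$chain & hp$resid >= r$start &
                        hp$resid <= r$end)
    }
    hp <- hp[keep, , drop = FALSE]
  }
  v <- cbind(hp$hx - hp$nx, hp$hy - hp$ny, hp$hz - hp$nz)
  v <- v / sqrt(rowSums(v^2))
  list(chain = hp$chain, resid = hp$resid, v = v)
}

rdc_design_row <- function(v) {
  cx <- v[1]; cy <- v[2]; cz <- v[3]
  c(cx^2 - cz^2, cy^2 - cz^2, 2 * cx * cy, 2 * cx * cz, 2 * cy * cz)
}

#' Fit a Saupe alignment tensor to one conformer by SVD
#'
#' Solves the linear least-squares problem
#' D_i = Dmax * sum_kl S_kl cos(theta_k) cos(theta_l) for the 5
#' independent Saupe elements via singular value decomposition, and
#' reports the tensor with quality diagnostics.  Amide protons are
#' built from backbone geometry when absent.
#'
#' @param ens A \code{structure_ensemble}.
#' @param rdcs An \code{rdc_set}.
#' @param sel Optional \code{selection} restricting residues.
#' @param conformer Conformer index to fit against.
#' @param r_nh N-H bond length (Angstrom) fixing Dmax.
#' @param max_condition Condition-number threshold above which the
#'   vector geometry is declared degenerate.
#' @param q_norm "obs" for Q = rms(D_obs - D_calc)/rms(D_obs)
#'   (the common convention), or "da" to normalise by
#'   Da*sqrt(2 + 1.5 R^2).
#' @return Object of class \code{tensor_fit}: tensor
#'   (\code{alignment_tensor}), q_factor, rmsd_hz, n_used,
#'   condition_number, and the per-residue observed/calculated table.
#' @export
svd_fit <- function(ens, rdcs, sel = NULL, conformer = 1L, r_nh = 1.02,
                    max_condition = 1e6, q_norm = c("obs", "da")) {
  q_norm <- match.arg(q_norm)
  nh <- nh_unit_vectors(ens, conformer, sel)
  key_nh <- paste(nh$chain, nh$resid)
  key_d <- paste(rdcs$chain, rdcs$residue)
  idx <- match(key_d, key_nh)
  ok <- !is.na(idx)
  if (sum(ok) < nrow(rdcs)) {
    warnf("%d RDCs without resolvable N-H vectors skipped", sum(!ok))
  }
  n_used <- sum(ok)
  if (n_used < 5L) stopf("need >= 5 residues with RDC and N-H vector, have %d",
                         n_used)
  v <- nh$v[idx[ok], , drop = FALSE]
  d <- rdcs$d_obs[ok]
  dm <- dmax_nh(r_nh)
  a <- dm * t(apply(v, 1, rdc_design_row))
  s <- svd(a)
  cond <- s$d[1] / s$d[5]
  if (!is.finite(cond) || cond > max_condition) {
    stopf("degenerate N-H vector geometry (condition number %.3g)", cond)
  }
  coefs <- s$v %*% ((t(s$u) %*% d) / s$d)
  saupe <- saupe_from_vec(as.numeric(coefs))
  tensor <- alignment_tensor(saupe, r_nh)
  d_calc <- as.numeric(a %*% coefs)
  res <- d - d_calc
  rmsd <- sqrt(mean(res^2))
  q <- switch(q_norm,
              obs = rmsd / sqrt(mean(d^2)),
              da = rmsd / (abs(tensor$da) *
                             sqrt(2 + 1.5 * tensor$rhombicity^2)))
  out <- list(tensor = tensor, q_factor = q, rmsd_hz = rmsd, n_used = n_used,
              condition_number = cond,
              table = data.frame(chain = rdcs$chain[ok],
                                 residue = rdcs$residue[ok],
                                 d_obs = d, d_calc = d_calc),
              q_norm = q_norm)
  class(out) <- "tensor_fit"
  out
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf(paste0("tensor_fit: n = %d, Da %.4g Hz, R %.4f, ",
                     "Q %.4g, rmsd %.4g Hz\n"),
              x$n_used, x$tensor$da, x$tensor$rhombicity, x$q_factor,
              x$rmsd_hz))
  invisible(x)
}

#' @export
coef.tensor_fit <- function(object, ...) {
  c(saupe_to_vec(object$tensor$saupe),
    da = object$tensor$da, rhombicity = object$tensor$rhombicity)
}

#' Back-calculate RDCs from an alignment tensor and a conformer
#'
#' @param tensor An \code{alignment_tensor} (or 3x3 Saupe matrix).
#' @param ens A \code{structure_ensemble}.
#' @param sel Optional \code{selection}.
#' @param conformer Conformer index.
#' @param r_nh N-H bond length (Angstrom).
#' @return An \code{rdc_set} with the predicted couplings in d_obs
#'   (d_err set to 0-width placeholder 1e-6).
#' @export
back_calculate <- function(tensor, ens, sel = NULL, conformer = 1L,
                           r_nh = 1.02) {
  saupe <- if (inherits(tensor, "alignment_tensor")) tensor$saupe else tensor
  check_finite(saupe, "Saupe matrix")
  nh <- nh_unit_vectors(ens, conformer, sel)
  dm <- dmax_nh(r_nh)
  d <- dm * apply(nh$v, 1, function(v) as.numeric(t(v) %*% saupe %*% v))
  rdc_set(nh$resid, d, d_err = 1e-6, chain = nh$chain)
}

#' Compare two fitted alignment tensors
#'
#' Reports the Da ratio, rhombicity difference, and the angle between
#' each pair of principal axes, folded into [0, 90] degrees to absorb
#' the axis sign ambiguity.  Similar tensors (ratio near 1, small
#' angles) indicate the two domains share one alignment frame, i.e.
#' behave rigidly; divergent tensors indicate interdomain mobility.
#'
#' @param fit_a,fit_b \code{tensor_fit} objects (or
#'   \code{alignment_tensor}s).
#' @return List with da_ratio, rhombicity_diff and axis_angles
#'   (degrees, named x/y/z).
#' @export
compare_domain_tensors <- function(fit_a, fit_b) {
  ta <- if (inherits(fit_a, "tensor_fit")) fit_a$tensor else fit_a
  tb <- if (inherits(fit_b, "tensor_fit")) fit_b$tensor else fit_b
  ang <- vapply(1:3, function(k) {
    d <- abs(sum(ta$axes[, k] * tb$axes[, k]))
    rad2deg(acos(min(1, d)))
  }, 1.0)
  list(da_ratio = ta$da / tb$da,
       rhombicity_diff = ta$rhombicity - tb$rhombicity,
       axis_angles = setNames(ang, c("x", "y", "z")))
}

#' Monte-Carlo parameter errors for a tensor fit
#'
#' Refits on n_draws noise realisations D_obs + N(0, d_err) and reports
#' the standard deviations of the five Saupe elements, Da and the
#' rhombicity over the (converged) draws.
#'
#' @param ens,rdcs,sel,conformer As in \code{\link{svd_fit}}.
#' @param n_draws Number of draws (>= 100).
#' @param seed RNG seed (mandatory).
#' @return List with sds (named vector), n_failed.
#' @export
mc_errors <- function(ens, rdcs, sel = NULL, conformer = 1L,
                      n_draws = 200L, seed) {
  if (n_draws < 100L) stopf("n_draws must be >= 100")
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      r <- rdcs
      r$d_obs <- r$d_obs + rnorm(nrow(r), 0, r$d_err)
      tryCatch(coef(svd_fit(ens, r, sel, conformer)), error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, TRUE)
  m <- do.call(rbind, draws[ok])
  list(sds = apply(m, 2, sd), n_failed = sum(!ok))
}
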