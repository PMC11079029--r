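# Paramagnetic relaxation enhancement (PRE): the r^-6 Solomon-
# Bloembergen transverse enhancement, back-calculation of para/dia
# intensity ratios across a labeled conformer ensemble, and comparison
# with measured ratios.

#' PRE back-calculation parameters
#'
#' Defaults follow the free-state convention (tauc 5 ns, 1H R2 of
#' 50 1/s); the bound state uses 8 ns / 55 1/s.
#'
#' @param tauc Rotational correlation time (ns).
#' @param r2_dia Diamagnetic 1H transverse rate (1/s).
#' @param field_1h 1H spectrometer frequency (MHz).
#' @param t_inept Total 1H transverse evolution in the HSQC (ms).
#' @param k_const Electron-1H interaction constant (Angstrom^6 / s^2);
#'   default is the nitroxide value 1.23e16.
#' @return List of class \code{pre_params}.
#' @export
pre_params <- function(tauc = 5, r2_dia = 50, field_1h = 600,
                       t_inept = 10, k_const = 1.23e16) {
  p <- list(tauc = tauc, r2_dia = r2_dia, field_1h = field_1h,
            t_inept = t_inept, k_const = k_const)
  if (any(unlist(p) <= 0)) stopf("all PRE parameters must be positive")
  class(p) <- "pre_params"
  p
}

#' Transverse PRE rate at a given electron-proton distance
#'
#' Gamma2 = K * r^-6 * (4 tauc + 3 tauc / (1 + omegaH^2 tauc^2)),
#' the point-dipole Solomon-Bloembergen form.
#'
#' @param r Electron-proton distance in Angstrom (> 0; vectorised).
#' @param params A \code{pre_params}.
#' @return Gamma2 in 1/s.
#' @export
gamma2 <- function(r, params = pre_params()) {
  if (any(r <= 0)) stopf("distances must be positive (corrupt coordinates?)")
  tau <- params$tauc * 1e-9
  om <- 2 * pi * params$field_1h * 1e6
  params$k_const * r^-6 * (4 * tau + 3 * tau / (1 + om^2 * tau^2))
}

pre_ratio_from_gamma <- function(g2, params) {
  params$r2_dia * exp(-g2 * params$t_inept * 1e-3) / (params$r2_dia + g2)
}

#' Back-calculate PRE intensity ratios from a labeled ensemble
#'
#' Per conformer and per amide proton the para/dia intensity ratio is
#' R2_dia * exp(-Gamma2 * t_inept) / (R2_dia + Gamma2); the profile
#' reports the mean and the min/max envelope across conformers
#' (amides missing in any conformer are flagged, not averaged over
#' partial data).
#'
#' @param ens A \code{structure_ensemble}.
#' @param site A \code{label_site}.
#' @param params A \code{pre_params}.
#' @return data.frame of class \code{pre_profile}: chain, resid,
#'   ratio_mean, ratio_min, ratio_max, flag.
#' @export
predict_profile <- function(ens, site, params = pre_params()) {
  d <- label_distances(ens, site, targets = "H")
  d$ratio <- NA_real_
  ok <- !is.na(d$distance)
  d$ratio[ok] <- pre_ratio_from_gamma(gamma2(d$distance[ok], params), params)
  key <- paste(d$chain, d$resid)
  nc <- n_conformers(ens)
  out <- do.call(rbind, lapply(unique(key), function(k) {
    sub <- d[key == k, ]
    complete <- nrow(sub) == nc && !anyNA(sub$ratio)
    data.frame(chain = sub$chain[1], resid = sub$resid[1],
               ratio_mean = if (complete) mean(sub$ratio) else NA_real_,
               ratio_min = if (complete) min(sub$ratio) else NA_real_,
               ratio_max = if (complete) max(sub$ratio) else NA_real_,
               flag = if (complete) "measured" else "missing",
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chain, out$resid), ]
  rownames(out) <- NULL
  class(out) <- c("pre_profile", "data.frame")
  out
}

#' Construct an observed PRE data set
#' @param residue Residue ids.
#' @param ratio_obs Para/dia intensity ratios.
#' @param ratio_err Errors (>= 0).
#' @param chain Chain id.
#' @return data.frame of class \code{pre_set}.
#' @export
pre_set <- function(residue, ratio_obs, ratio_err = 0.05, chain = "A") {
  if (any(ratio_err < 0)) stopf("ratio errors must be non-negative")
  s <- data.frame(chain = chain, residue = as.integer(residue),
                  ratio_obs = ratio_obs, ratio_err = ratio_err,
                  stringsAsFactors = FALSE)
  class(s) <- c("pre_set", "data.frame")
  s
}

#' Score observed PRE ratios against a back-calculated profile
#'
#' Reports the r.m.s. deviation between observation and ensemble mean
#' over the overlapping residues, and flags residues whose observation
#' falls outside the conformer envelope by more than its error.
#' Observations *below* the envelope are the transient-contact
#' candidates (broadening beyond what the ensemble explains).
#'
#' @param observed A \code{pre_set}.
#' @param predicted A \code{pre_profile}.
#' @return List with rmsd, n_overlap, n_outside, flags (data.frame of
#'   flagged residues with the side of the violation).
#' @export
pre_compare <- function(observed, predicted) {
  key_o <- paste(observed$chain, observed$residue)
  key_p <- paste(predicted$chain, predicted$resid)
  idx <- match(key_o, key_p)
  ok <- !is.na(idx) & predicted$flag[idx] == "measured" &
    !is.na(observed$ratio_obs)
  if (sum(ok) == 0L) stopf("no overlapping residues: mismatched numbering?")
  if (sum(ok) < 10L) warnf("only %d overlapping residues", sum(ok))
  obs <- observed[ok, ]; prd <- predicted[idx[ok], ]
  dev <- obs$ratio_obs - prd$ratio_mean
  below <- obs$ratio_obs < prd$ratio_min - obs$ratio_err
  above <- obs$ratio_obs > prd$ratio_max + obs$ratio_err
  flags <- data.frame(chain = obs$chain, residue = obs$residue,
                      ratio_obs = obs$ratio_obs,
                      ratio_mean = prd$ratio_mean,
                      side = ifelse(below, "below", "above"),
                      stringsAsFactors = FALSE)[below | above, , drop = FALSE]
  rownames(flags) <- NULL
  list(rmsd = sqrt(mean(dev^2)), n_overlap = sum(ok),
       n_outside = nrow(flags), flags = flags)
}
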