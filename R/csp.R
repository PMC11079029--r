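# Weighted chemical shift perturbation (CSP) analysis of NMR
# titrations: the weighted combined-shift formula, series comparison
# into CSP tables, and interface-residue calling.

CSP_WEIGHTS <- c(N15 = 0.14, C13 = 0.3)

#' Construct a peak list
#'
#' @param residue Integer residue ids (author numbering).
#' @param atom_group One of "HN" (backbone amide), "HC_methyl"
#'   (methyl 1H-13C) or "sidechain_NE_HE" (tryptophan Ne-He).
#' @param shift_h 1H chemical shifts (ppm).
#' @param shift_x 15N or 13C chemical shifts (ppm).
#' @param nucleus_x "N15" or "C13" per entry.
#' @param atom Atom name distinguishing multiple correlations within a
#'   residue/group (defaults to the group name).
#' @param intensity Optional peak intensities.
#' @return data.frame of class \code{peak_list}.
#' @export
peak_list <- function(residue, atom_group = "HN", shift_h, shift_x,
                      nucleus_x = "N15", atom = NULL, intensity = NA_real_) {
  pl <- data.frame(residue = as.integer(residue),
                   atom_group = atom_group,
                   atom = atom %||% atom_group,
                   shift_h = shift_h, shift_x = shift_x,
                   nucleus_x = nucleus_x, intensity = intensity,
                   stringsAsFactors = FALSE)
  check_finite(pl$shift_h, "shift_h"); check_finite(pl$shift_x, "shift_x")
  if (!all(pl$atom_group %in% c("HN", "HC_methyl", "sidechain_NE_HE"))) {
    stopf("unknown atom_group")
  }
  if (!all(pl$nucleus_x %in% names(CSP_WEIGHTS))) stopf("unknown nucleus_x")
  key <- paste(pl$residue, pl$atom_group, pl$atom)
  if (anyDuplicated(key)) stopf("duplicate (residue, atom_group, atom) peaks")
  class(pl) <- c("peak_list", "data.frame")
  pl
}

#' One titration point
#'
#' @param ratio Ligand:protein molar ratio (0 = free state).
#' @param peaks A \code{peak_list}.
#' @param label Free-text label.
#' @return Object of class \code{titration_series}.
#' @export
titration_series <- function(ratio, peaks, label = "") {
  if (ratio < 0) stopf("molar ratio must be non-negative")
  structure(list(ratio = ratio, peaks = peaks, label = label),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series '%s': ratio %.3g, %d peaks\n",
              x$label, x$ratio, nrow(x$peaks)))
  invisible(x)
}

#' Weighted chemical shift perturbation of one correlation
#'
#' Computes sqrt(0.5 * (dH^2 + w * dX^2)) with w = 0.14 for 15N and
#' w = 0.3 for 13C; symmetric in the sign of both shift differences.
#'
#' @param delta_h 1H shift difference (ppm).
#' @param delta_x 15N or 13C shift difference (ppm).
#' @param nucleus_x "N15" or "C13" (vectorised).
#' @return CSP in ppm (1H scale).
#' @export
csp_value <- function(delta_h, delta_x, nucleus_x = "N15") {
  check_finite(delta_h, "delta_h"); check_finite(delta_x, "delta_x")
  w <- unname(CSP_WEIGHTS[nucleus_x])
  if (anyNA(w)) stopf("nucleus_x must be one of %s",
                      paste(names(CSP_WEIGHTS), collapse = ", "))
  sqrt(0.5 * (delta_h^2 + w * delta_x^2))
}

#' CSP table between two titration points
#'
#' Matches peaks by (residue, atom_group, atom) and evaluates the
#' weighted CSP of the shift differences.  Works for free-vs-bound
#' (reference ratio 0) and bound-vs-bound comparisons alike; peaks
#' present in only one list are flagged missing, never imputed as 0.
#'
#' @param reference,other \code{titration_series} objects sharing a
#'   residue/atom namespace.
#' @return data.frame of class \code{csp_table} with residue,
#'   atom_group, atom, csp (ppm) and flag ("measured"/"missing").
#' @export
series_csp <- function(reference, other) {
  a <- reference$peaks; b <- other$peaks
  ka <- paste(a$residue, a$atom_group, a$atom)
  kb <- paste(b$residue, b$atom_group, b$atom)
  common <- intersect(ka, kb)
  if (length(common) == 0L) stopf("no shared peaks: mismatched assignments?")
  all_keys <- union(ka, kb)
  ia <- match(all_keys, ka); ib <- match(all_keys, kb)
  src <- ifelse(is.na(ia), ib, ia)
  from_a <- !is.na(ia)
  out <- data.frame(
    residue = ifelse(from_a, a$residue[ia], b$residue[ib]),
    atom_group = ifelse(from_a, a$atom_group[ia], b$atom_group[ib]),
    atom = ifelse(from_a, a$atom[ia], b$atom[ib]),
    csp = NA_real_, flag = "missing", stringsAsFactors = FALSE)
  meas <- !is.na(ia) & !is.na(ib)
  if (any(meas)) {
    out$csp[meas] <- csp_value(a$shift_h[ia[meas]] - b$shift_h[ib[meas]],
                               a$shift_x[ia[meas]] - b$shift_x[ib[meas]],
                               a$nucleus_x[ia[meas]])
    out$flag[meas] <- "measured"
  }
  out <- out[order(out$residue, out$atom_group, out$atom), ]
  rownames(out) <- NULL
  class(out) <- c("csp_table", "data.frame")
  out
}

#' Call interface residues from a CSP table
#'
#' Residues with multiple correlations (e.g. methyls) are collapsed to
#' their maximum CSP before thresholding.  The default rule flags
#' residues whose CSP exceeds mean + 1 SD over the measured entries.
#'
#' @param table A \code{csp_table} with >= 5 measured entries.
#' @param method "mean_plus_sd" or "fixed_threshold".
#' @param threshold CSP cutoff in ppm (fixed_threshold only).
#' @return data.frame with residue, csp and margin (ppm above the
#'   cutoff) for each called residue.
#' @export
interface_residues <- function(table, method = c("mean_plus_sd", "fixed_threshold"),
                               threshold = NULL) {
  method <- match.arg(method)
  meas <- table[table$flag == "measured" & !is.na(table$csp), , drop = FALSE]
  if (nrow(meas) == 0L) stopf("CSP table has no measured entries")
  if (nrow(meas) < 5L) stopf("need >= 5 measured CSP entries, have %d", nrow(meas))
  per_res <- aggregate(csp ~ residue, data = meas, FUN = max)
  cut <- switch(method,
                mean_plus_sd = mean(meas$csp) + sd(meas$csp),
                fixed_threshold = {
                  if (is.null(threshold)) stopf("fixed_threshold needs a threshold")
                  threshold
                })
  hit <- per_res[per_res$csp > cut, , drop = FALSE]
  hit$margin <- hit$csp - cut
  hit <- hit[order(hit$residue), ]
  rownames(hit) <- NULL
  attr(hit, "cutoff") <- cut
  hit
}
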