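# Proline-rich motif analysis: maximal proline-run decomposition, the
# deterministic four-class peptide taxonomy for tandem-WW ligands, and
# a sequence scanner for WW-ligand motifs and proline-rich regions.
#
# Class rationale (affinity-ranked taxonomy of 16-mer ligands):
#   pplp_bridge_polyP - a PPLP motif bridged to a downstream polyproline
#     run (the highest-affinity architecture, engaging both WW domains);
#   two_stretches - two polyproline runs of >= 3;
#   broken_stretch - one run of >= 3 interrupted/flanked by further
#     scattered prolines;
#   spaced - only isolated prolines (lowest/no affinity).

check_sequence <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stopf("empty sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seq)) {
    stopf("non-standard residue characters in sequence")
  }
  seq
}

#' Decompose a sequence into maximal proline runs
#'
#' @param seq Amino-acid string (standard residues; X tolerated and
#'   never matches P).
#' @return Object of class \code{proline_decomposition}: sequence,
#'   runs (data.frame with 1-based inclusive start, length),
#'   proline_fraction.
#' @export
proline_runs <- function(seq) {
  seq <- check_sequence(seq)
  m <- gregexpr("P+", seq)[[1]]
  if (m[1] == -1L) {
    runs <- data.frame(start = integer(0), length = integer(0))
  } else {
    runs <- data.frame(start = as.integer(m),
                       length = attr(m, "match.length"))
  }
  structure(list(sequence = seq, runs = runs,
                 proline_fraction = sum(runs$length) / nchar(seq)),
            class = "proline_decomposition")
}

#' @export
print.proline_decomposition <- function(x, ...) {
  cat(sprintf("proline_decomposition: %d run(s), P fraction %.2f\n",
              nrow(x$runs), x$proline_fraction))
  invisible(x)
}

#' Classify a proline-rich peptide into the four-ligand taxonomy
#'
#' Deterministic priority classification:
#' \enumerate{
#'   \item \code{pplp_bridge_polyP}: a PPLP match with a downstream
#'     proline run of >= \code{polyp_min}, separated by at most
#'     \code{bridge_gap} non-proline residues;
#'   \item \code{two_stretches}: >= 2 runs of length >= \code{run_min};
#'   \item \code{broken_stretch}: exactly one run >= \code{run_min}
#'     plus >= 2 additional prolines outside it;
#'   \item \code{spaced}: everything else.
#' }
#'
#' @param seq Amino-acid string (length >= 8 recommended; shorter
#'   sequences warn).
#' @param run_min Minimum length of a polyproline "stretch".
#' @param bridge_gap Maximum non-proline residues between the PPLP and
#'   the downstream run.
#' @param polyp_min Minimum downstream run length for the bridge class.
#' @return Object of class \code{peptide_class}: class, rationale.
#' @export
classify_peptide <- function(seq, run_min = 3L, bridge_gap = 4L,
                             polyp_min = 4L) {
  seq <- check_sequence(seq)
  if (nchar(seq) < 8L) warnf("sequence shorter than 8 residues")
  dec <- proline_runs(seq)
  runs <- dec$runs
  cls <- NULL; why <- NULL
  # (1) PPLP bridged to a downstream polyP run
  pplp <- gregexpr("PPLP", seq)[[1]]
  if (pplp[1] != -1L) {
    for (p0 in as.integer(pplp)) {
      p_end <- p0 + 3L
      cand <- runs[runs$start > p_end & runs$length >= polyp_min, , drop = FALSE]
      for (k in seq_len(nrow(cand))) {
        gap_seq <- substr(seq, p_end + 1L, cand$start[k] - 1L)
        non_p <- nchar(gsub("P", "", gap_seq))
        if (non_p <= bridge_gap) {
          cls <- "pplp_bridge_polyP"
          why <- sprintf("PPLP at %d bridged (%d non-P) to %d-proline run at %d",
                         p0, non_p, cand$length[k], cand$start[k])
          break
        }
      }
      if (!is.null(cls)) break
    }
  }
  long_runs <- runs[runs$length >= run_min, , drop = FALSE]
  if (is.null(cls) && nrow(long_runs) >= 2L) {
    cls <- "two_stretches"
    why <- sprintf("%d proline runs of length >= %d", nrow(long_runs), run_min)
  }
  if (is.null(cls) && nrow(long_runs) == 1L &&
      sum(runs$length) - long_runs$length[1] >= 2L) {
    cls <- "broken_stretch"
    why <- sprintf("one %d-run plus %d scattered prolines",
                   long_runs$length[1], sum(runs$length) - long_runs$length[1])
  }
  if (is.null(cls)) {
    cls <- "spaced"
    why <- "no polyproline stretch architecture"
  }
  structure(list(class = cls, rationale = why, sequence = seq),
            class = "peptide_class")
}

#' @export
print.peptide_class <- function(x, ...) {
  cat(sprintf("peptide_class: %s (%s)\n", x$class, x$rationale))
  invisible(x)
}

MOTIF_PATTERNS <- list(
  PPLP = "PPLP",
  polyP_run = "P{4,}",
  bridge_PPxAP = "PP[A-Z]AP",
  PPxP = "PP[^P]P|P[^P]{1,2}PP"
)

#' Scan sequences for WW-ligand motifs and proline-rich regions
#'
#' Motif kinds: PPLP (the high-affinity core), polyP_run (>= 4
#' consecutive prolines), bridge_PPxAP (PPxAP bridges such as PPGAP),
#' and PPxP (the interrupted-triplet family, covering PPxP and PxxPP
#' arrangements such as PPVP and PALPP).  A proline-rich region is a
#' window with at least \code{min_p} prolines in \code{window}
#' residues; overlapping qualifying windows are merged.
#'
#' @param records Named character vector of amino-acid sequences.
#' @param window Window length for the region scan (residues).
#' @param min_p Minimum prolines per window.
#' @return List with \code{motifs} (data.frame: record, kind, start,
#'   end, match) and \code{regions} (data.frame: record, start, end);
#'   records with invalid characters are skipped with a warning.
#' @export
scan_sequences <- function(records, window = 16L, min_p = 8L) {
  if (length(records) == 0L) stopf("no records")
  if (is.null(names(records)) || any(names(records) == "")) {
    names(records) <- paste0("seq", seq_along(records))
  }
  motifs <- list(); regions <- list()
  for (nm in names(records)) {
    seq <- tryCatch(check_sequence(records[[nm]]), error = function(e) NULL)
    if (is.null(seq)) { warnf("record '%s' skipped: invalid characters", nm); next }
    for (kind in names(MOTIF_PATTERNS)) {
      m <- gregexpr(MOTIF_PATTERNS[[kind]], seq, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      st <- as.integer(m); ln <- attr(m, "match.length")
      motifs[[length(motifs) + 1L]] <- data.frame(
        record = nm, kind = kind, start = st, end = st + ln - 1L,
        match = substring(seq, st, st + ln - 1L), stringsAsFactors = FALSE)
    }
    # proline-rich windows
    n <- nchar(seq)
    if (n >= window) {
      isp <- as.integer(strsplit(seq, "")[[1]] == "P")
      cs <- c(0L, cumsum(isp))
      counts <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
      hit <- which(counts >= min_p)
      if (length(hit)) {
        iv <- data.frame(start = hit, end = hit + window - 1L)
        merged <- iv[1, , drop = FALSE]
        for (k in seq_len(nrow(iv))[-1]) {
          if (iv$start[k] <= merged$end[nrow(merged)] + 1L) {
            merged$end[nrow(merged)] <- max(merged$end[nrow(merged)], iv$end[k])
          } else merged <- rbind(merged, iv[k, ])
        }
        regions[[length(regions) + 1L]] <- cbind(record = nm, merged)
      }
    }
  }
  list(motifs = if (length(motifs)) do.call(rbind, motifs) else
    data.frame(record = character(0), kind = character(0),
               start = integer(0), end = integer(0), match = character(0)),
    regions = if (length(regions)) do.call(rbind, regions) else
      data.frame(record = character(0), start = integer(0), end = integer(0)))
}

#' The nine 16-mer ligand peptides used in the binding taxonomy
#'
#' Named vector of the SF1-derived 16-mer sequences (author residue
#' ranges in the names); \code{SF1_575_590} is the high-affinity
#' tandem-spanning site, also known as the WW binding site peptide.
#'
#' @return Named character vector of length 9.
#' @export
sf1_peptides <- function() {
  c(SF1_342_357 = "SAPRPAAPANNPPPPS",
    SF1_387_402 = "PGGPGGGPHSFPHPLP",
    SF1_425_440 = "MQPPPPPMNQGPHPPG",
    SF1_470_485 = "MPPPPMGMMPPPPPPP",
    SF1_478_493 = "MPPPPPPPSGQPPPPP",
    SF1_565_580 = "TMVPLPPGVQPPLPPG",
    SF1_575_590 = "PPLPPGAPPPPPPPPP",
    SF1_596_611 = "MYAPPPPPPPPMDPSN",
    SF1_623_638 = "MPPFGMPPAPPPPPPQ")
}
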