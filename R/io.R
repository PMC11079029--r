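# Delimited-text I/O for every data class the analysis stages consume:
# peak lists, CSP tables, relaxation series, RDC and PRE sets, ITC
# isotherms (header block + per-injection rows) and FASTA sequences.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read / write peak lists
#'
#' Columns: residue, atom_group, atom, shift_h, shift_x, nucleus_x,
#' intensity (tab-delimited with header).
#'
#' @param path File path.
#' @return \code{read_peak_list} returns a \code{peak_list}.
#' @export
read_peak_list <- function(path) {
  d <- read_tsv(path)
  peak_list(residue = d$residue, atom_group = d$atom_group,
            shift_h = d$shift_h, shift_x = d$shift_x,
            nucleus_x = d$nucleus_x, atom = d$atom,
            intensity = d$intensity %||% NA_real_)
}

#' @rdname read_peak_list
#' @param peaks A \code{peak_list}.
#' @export
write_peak_list <- function(peaks, path) write_tsv(as.data.frame(peaks), path)

#' Read / write relaxation series (columns: delay_s, intensity)
#' @param path File path.
#' @param experiment "R1" or "R2".
#' @param residue Residue id.
#' @return A \code{relaxation_series}.
#' @export
read_relaxation_series <- function(path, experiment = "R1",
                                   residue = NA_integer_) {
  d <- read_tsv(path)
  relaxation_series(d$delay_s, d$intensity, residue = residue,
                    experiment = experiment)
}

#' @rdname read_relaxation_series
#' @param series A \code{relaxation_series}.
#' @export
write_relaxation_series <- function(series, path) {
  write_tsv(data.frame(delay_s = series$delay, intensity = series$intensity),
            path)
}

#' Read / write RDC sets (columns: chain, residue, d_hz, err_hz)
#' @param path File path.
#' @return An \code{rdc_set}.
#' @export
read_rdc <- function(path) {
  d <- read_tsv(path)
  rdc_set(d$residue, d$d_hz, d$err_hz, chain = d$chain %||% "A")
}

#' @rdname read_rdc
#' @param rdcs An \code{rdc_set}.
#' @export
write_rdc <- function(rdcs, path) {
  write_tsv(data.frame(chain = rdcs$chain, residue = rdcs$residue,
                       d_hz = rdcs$d_obs, err_hz = rdcs$d_err), path)
}

#' Read / write observed PRE sets (columns: chain, residue, ratio, err)
#' @param path File path.
#' @return A \code{pre_set}.
#' @export
read_pre <- function(path) {
  d <- read_tsv(path)
  pre_set(d$residue, d$ratio, d$err, chain = d$chain %||% "A")
}

#' @rdname read_pre
#' @param pre A \code{pre_set}.
#' @export
write_pre <- function(pre, path) {
  write_tsv(data.frame(chain = pre$chain, residue = pre$residue,
                       ratio = pre$ratio_obs, err = pre$ratio_err), path)
}

#' Read / write ITC experiments
#'
#' Format: '#'-prefixed header lines (key = value: cell_volume_uL,
#' cell_conc_uM, syringe_conc_uM, cell_species, syringe_species,
#' spacing_s) followed by tab-delimited rows with columns
#' injection_volume_uL and heat_ucal.
#'
#' @param path File path.
#' @return An \code{itc_experiment}.
#' @export
read_itc <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+)$", h))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^#", lines)]
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(body, tf)
  d <- read_tsv(tf)
  sched <- injection_schedule(
    cell_volume = as.numeric(kv$cell_volume_uL %||% 200),
    injections = d$injection_volume_uL,
    spacing = as.numeric(kv$spacing_s %||% 150),
    cell_conc = as.numeric(kv$cell_conc_uM),
    syringe_conc = as.numeric(kv$syringe_conc_uM),
    cell_species = kv$cell_species %||% "cell",
    syringe_species = kv$syringe_species %||% "syringe")
  structure(list(schedule = sched, heats = d$heat_ucal,
                 molar_ratio = cumsum(sched$syringe_conc * sched$injections) /
                   (sched$cell_conc * sched$cell_volume),
                 blank_subtracted = TRUE, model = NULL),
            class = "itc_experiment")
}

#' @rdname read_itc
#' @param experiment An \code{itc_experiment}.
#' @export
write_itc <- function(experiment, path) {
  s <- experiment$schedule
  hdr <- c(sprintf("# cell_volume_uL = %g", s$cell_volume),
           sprintf("# cell_conc_uM = %g", s$cell_conc),
           sprintf("# syringe_conc_uM = %g", s$syringe_conc),
           sprintf("# cell_species = %s", s$cell_species),
           sprintf("# syringe_species = %s", s$syringe_species),
           sprintf("# spacing_s = %g", s$spacing))
  body <- c("injection_volume_uL\theat_ucal",
            sprintf("%g\t%.10g", s$injections, experiment$heats))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Lowercase letters are accepted and uppercased.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  toupper(unlist(seqs))
}
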