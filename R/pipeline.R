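# Configuration-driven orchestration of the analysis stages into three
# workflows: apo-tandem validation (RDC + PRE agreement with an
# ensemble), complex validation (ensemble precision + optional RDC),
# and autoinhibition quantification (paired ITC fits -> k_closed).
# Stages are isolated: a failing stage is recorded and its dependents
# skipped while independent stages still run.

#' Parse a flat key-value run configuration
#'
#' Format: '[section]' headers with 'key = value' lines; '#' comments.
#' Keys are returned namespaced as section$key.  Unknown sections or
#' keys are rejected.
#'
#' @param path Config file path.
#' @return Nested named list of class \code{run_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list(); section <- "run"
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z_0-9.]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stopf("cannot parse config line: '%s'", ln)
    cfg[[section]][[m[2]]] <- trimws(m[3])
  }
  validate_run_config(cfg)
}

KNOWN_CONFIG_KEYS <- list(
  run = c("workflow", "seed", "out_dir"),
  ensemble = c("pdb", "select", "lenient"),
  rdc = c("file", "select_domain1", "select_domain2", "conformer"),
  pre = c("file", "site", "tauc", "r2", "field", "t_inept"),
  itc = c("file_intrinsic", "file_extended", "tandem_in")
)

validate_run_config <- function(cfg) {
  bad_sec <- setdiff(names(cfg), names(KNOWN_CONFIG_KEYS))
  if (length(bad_sec)) stopf("unknown config section(s): %s",
                             paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), KNOWN_CONFIG_KEYS[[sec]])
    if (length(bad)) stopf("unknown key(s) in [%s]: %s", sec,
                           paste(bad, collapse = ", "))
  }
  wf <- cfg$run$workflow %||% stopf("config must set run.workflow")
  if (!wf %in% c("apo_validate", "complex_validate", "autoinhibition")) {
    stopf("unknown workflow '%s'", wf)
  }
  for (sec in c("ensemble", "rdc", "pre", "itc")) {
    for (key in intersect(names(cfg[[sec]]),
                          c("pdb", "file", "file_intrinsic", "file_extended"))) {
      if (!file.exists(cfg[[sec]][[key]])) {
        stopf("[%s] %s: file not found: %s", sec, key, cfg[[sec]][[key]])
      }
    }
  }
  class(cfg) <- "run_config"
  cfg
}

log_msg <- function(con, level, fmt, ...) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

run_stage <- function(name, log, results, expr) {
  out <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  if (out$ok) log_msg(log, "INFO", "stage %s: ok", name)
  else log_msg(log, "ERROR", "stage %s: %s", name, out$value)
  results[[name]] <- out
  results
}

#' Run a configured analysis workflow
#'
#' Executes only the stages named by the workflow, writes
#' machine-readable tables plus a plain-text summary into the output
#' directory, and echoes all seeds and parameters into the report.
#'
#' @param config A \code{run_config} (from \code{read_run_config}) or
#'   a path to a config file.
#' @return Invisibly, a list of per-stage results; element \code{ok}
#'   is FALSE only on hard failure of every requested stage.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  wf <- config$run$workflow
  out_dir <- config$run$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con))
  log_msg(log_con, "INFO", "workflow %s (seed %s)", wf,
          config$run$seed %||% "none")
  results <- list()
  summary_lines <- c(sprintf("workflow: %s", wf),
                     sprintf("seed: %s", config$run$seed %||% "none"))
  ens <- NULL
  if (!is.null(config$ensemble$pdb)) {
    results <- run_stage("read_ensemble", log_con, results, {
      read_ensemble(config$ensemble$pdb,
                    lenient = isTRUE(config$ensemble$lenient == "true"))
    })
    if (results$read_ensemble$ok) ens <- results$read_ensemble$value
  }
  if (wf %in% c("apo_validate", "complex_validate") && !is.null(ens) &&
      !is.null(config$rdc$file)) {
    results <- run_stage("rdc_fit", log_con, results, {
      rdcs <- read_rdc(config$rdc$file)
      conf <- as.integer(config$rdc$conformer %||% "1")
      f1 <- svd_fit(ens, rdcs, parse_selection(config$rdc$select_domain1),
                    conformer = conf)
      f2 <- svd_fit(ens, rdcs, parse_selection(config$rdc$select_domain2),
                    conformer = conf)
      cmp <- compare_domain_tensors(f1, f2)
      tab <- data.frame(domain = c(1, 2),
                        da = c(f1$tensor$da, f2$tensor$da),
                        rhombicity = c(f1$tensor$rhombicity,
                                       f2$tensor$rhombicity),
                        q_factor = c(f1$q_factor, f2$q_factor),
                        rmsd_hz = c(f1$rmsd_hz, f2$rmsd_hz))
      write_tsv(tab, file.path(out_dir, "rdc_fit.tsv"))
      list(fits = list(f1, f2), comparison = cmp)
    })
    if (results$rdc_fit$ok) {
      cmp <- results$rdc_fit$value$comparison
      summary_lines <- c(summary_lines,
                         sprintf("rdc: Da ratio %.3f, max axis angle %.1f deg",
                                 cmp$da_ratio, max(cmp$axis_angles)))
    }
  }
  if (wf == "apo_validate" && !is.null(ens) && !is.null(config$pre$file)) {
    results <- run_stage("pre_compare", log_con, results, {
      obs <- read_pre(config$pre$file)
      params <- pre_params(
        tauc = as.numeric(config$pre$tauc %||% 5),
        r2_dia = as.numeric(config$pre$r2 %||% 50),
        field_1h = as.numeric(config$pre$field %||% 600),
        t_inept = as.numeric(config$pre$t_inept %||% 10))
      site <- label_site(as.integer(config$pre$site))
      prof <- predict_profile(ens, site, params)
      write_tsv(as.data.frame(prof), file.path(out_dir, "pre_profile.tsv"))
      cmp <- pre_compare(obs, prof)
      list(profile = prof, comparison = cmp)
    })
    if (results$pre_compare$ok) {
      cmp <- results$pre_compare$value$comparison
      summary_lines <- c(summary_lines,
                         sprintf("pre: rmsd %.4f over %d residues, %d outside envelope",
                                 cmp$rmsd, cmp$n_overlap, cmp$n_outside))
    }
  }
  if (wf == "complex_validate" && !is.null(ens)) {
    results <- run_stage("ensemble_rmsd", log_con, results, {
      sel <- if (!is.null(config$ensemble$select))
        parse_selection(config$ensemble$select) else selection()
      tm <- ensemble_rmsd(ens, sel, "to_mean")
      pw <- ensemble_rmsd(ens, sel, "pairwise")
      tab <- data.frame(mode = c("to_mean", "pairwise"),
                        backbone_rmsd = c(tm[["backbone_rmsd"]],
                                          pw[["backbone_rmsd"]]),
                        heavy_rmsd = c(tm[["heavy_rmsd"]],
                                       pw[["heavy_rmsd"]]))
      write_tsv(tab, file.path(out_dir, "ensemble_rmsd.tsv"))
      tab
    })
    if (results$ensemble_rmsd$ok) {
      tab <- results$ensemble_rmsd$value
      summary_lines <- c(summary_lines,
                         sprintf("rmsd(to_mean): backbone %.2f A, heavy %.2f A",
                                 tab$backbone_rmsd[1], tab$heavy_rmsd[1]))
    }
  }
  if (wf == "autoinhibition") {
    results <- run_stage("autoinhibition", log_con, results, {
      fit_a <- fit_isotherm(read_itc(config$itc$file_intrinsic))
      fit_b <- fit_isotherm(read_itc(config$itc$file_extended))
      kd_i <- fit_a$model$kd; kd_app <- fit_b$model$kd
      k_closed <- kd_app / kd_i - 1
      tab <- data.frame(quantity = c("kd_intrinsic_uM", "kd_apparent_uM",
                                     "k_closed"),
                        value = c(kd_i, kd_app, k_closed))
      write_tsv(tab, file.path(out_dir, "autoinhibition.tsv"))
      list(fit_intrinsic = fit_a, fit_extended = fit_b, k_closed = k_closed)
    })
    if (results$autoinhibition$ok) {
      v <- results$autoinhibition$value
      summary_lines <- c(summary_lines,
                         sprintf("itc: Kd intrinsic %.3g uM, apparent %.3g uM, k_closed %.3g",
                                 v$fit_intrinsic$model$kd,
                                 v$fit_extended$model$kd, v$k_closed))
    }
  }
  any_ok <- any(vapply(results, function(r) r$ok, TRUE))
  summary_lines <- c(summary_lines,
                     sprintf("stages ok: %d / %d",
                             sum(vapply(results, function(r) r$ok, TRUE)),
                             length(results)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  log_msg(log_con, "INFO", "workflow complete")
  invisible(c(results, list(ok = any_ok)))
}
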