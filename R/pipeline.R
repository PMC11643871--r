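# End-to-end orchestration: a small stage runner (synth -> analyze ->
# report) driven by a YAML config, with checksummed outputs and a
# machine-readable JSON report.  Identical config + seed gives a
# byte-identical report.

.stage_types <- c("synth_vt", "dnmr", "synth_potential", "scan", "formula")

config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("rotabar_config_error",
                                             "error", "condition")))
}

validate_config <- function(cfg) {
  if (!is.list(cfg)) config_error("config must be a list / YAML mapping")
  if (is.null(cfg$stages) || length(cfg$stages) == 0)
    config_error("config must declare a non-empty 'stages' list")
  names_seen <- character(0)
  for (i in seq_along(cfg$stages)) {
    st <- cfg$stages[[i]]
    if (is.null(st$name) || is.null(st$type))
      config_error("stage ", i, " must have 'name' and 'type'")
    if (!st$type %in% .stage_types)
      config_error("stage '", st$name, "': unknown type '", st$type,
                   "' (supported: ", paste(.stage_types, collapse = ", "), ")")
    if (st$name %in% names_seen)
      config_error("duplicate stage name '", st$name, "'")
    # referenced upstream artifacts must exist or be produced earlier
    ref <- c(st$params$manifest, st$params$profile)
    if (!is.null(ref) && !ref %in% names_seen && !file.exists(ref))
      config_error("stage '", st$name, "' references '", ref,
                   "', which is neither an earlier stage nor an existing file")
    names_seen <- c(names_seen, st$name)
  }
  invisible(cfg)
}

seq_from_spec <- function(x) {
  if (is.list(x)) do.call(seq, lapply(x[c("from", "to", "by")], as.numeric))
  else as.numeric(x)
}

log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

run_stage <- function(st, out_dir, artifacts) {
  p <- st$params
  resolve <- function(ref) {
    if (!is.null(artifacts[[ref]])) artifacts[[ref]] else ref
  }
  switch(st$type,
    synth_vt = {
      sys <- exchange_system(p$nuA, p$nuB,
                             pA = if (is.null(p$pA)) 0.5 else p$pA,
                             T2 = if (is.null(p$T2)) 0.05 else p$T2)
      vt <- make_vt_series(p$dG, sys, temps = seq_from_spec(p$temps),
                           noise_sd = if (is.null(p$noise_sd)) 0 else p$noise_sd)
      dir <- file.path(out_dir, st$name)
      manifest <- write_vt_series(vt, dir)
      list(outputs = manifest,
           summary = list(n_temperatures = length(vt$temperatures),
                          delta_nu = sys$delta_nu))
    },
    dnmr = {
      vt <- read_vt_series(resolve(p$manifest))
      res <- barrier_from_vt(vt)
      path <- file.path(out_dir, paste0(st$name, ".json"))
      jsonlite::write_json(
        list(Tc = res$Tc, delta_nu = res$delta_nu, k_c = res$k_c,
             dG = res$dG, dG_legacy = res$dG_legacy,
             constant_used = res$constant_used),
        path, auto_unbox = TRUE, digits = 10)
      list(outputs = path,
           summary = list(Tc = res$Tc, dG = res$dG))
    },
    synth_potential = {
      pot <- if (!is.null(p$barrier))
        two_well_potential(p$barrier,
                           if (is.null(p$delta)) 1.5 else p$delta)
      else fourier_potential(unlist(p$n), unlist(p$A),
                             if (is.null(p$phi)) 0 else unlist(p$phi))
      mk <- make_potential(pot,
                           start = if (is.null(p$start)) 0 else p$start,
                           step = if (is.null(p$step)) 15 else p$step)
      path <- file.path(out_dir, paste0(st$name, ".csv"))
      write_profile(mk$profile, path)
      truth_path <- file.path(out_dir, paste0(st$name, "_truth.json"))
      jsonlite::write_json(mk$truth, truth_path, digits = 10,
                           dataframe = "columns")
      list(outputs = c(path, truth_path),
           summary = list(n_points = length(mk$profile$angle),
                          n_minima = nrow(mk$truth$minima)))
    },
    scan = {
      prof <- load_profile(resolve(p$profile))
      method <- if (is.null(p$method)) "spline" else p$method
      sp <- stationary_points(prof, method = method)
      barriers <- label_path(prof, labeler = function(a) sprintf("min@%.0f", a),
                             method = method)
      path <- file.path(out_dir, paste0(st$name, ".json"))
      jsonlite::write_json(list(minima = sp$minima, maxima = sp$maxima,
                                transitions = barriers),
                           path, digits = 10, dataframe = "columns")
      list(outputs = path,
           summary = list(n_minima = nrow(sp$minima),
                          max_barrier = if (nrow(barriers)) max(barriers$barrier)
                                        else NA))
    },
    formula = {
      rows <- lapply(p$formulas, function(fs) {
        f <- parse_formula(fs)
        ea <- round_half_up(elemental_analysis(f), 2)
        data.frame(formula = fs,
                   element = names(ea), percent = as.numeric(ea),
                   monoisotopic = round_half_up(monoisotopic_mass(f), 4),
                   mz_M_Na = round_half_up(adduct_mz(f, "[M+Na]+"), 4))
      })
      path <- file.path(out_dir, paste0(st$name, ".csv"))
      utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
      list(outputs = path,
           summary = list(n_formulas = length(p$formulas)))
    }
  )
}

#' Run a configured analysis pipeline
#'
#' Executes a list of stages (`synth_vt`, `dnmr`, `synth_potential`, `scan`,
#' `formula`) in order, writing each stage's outputs under `out_dir` and a
#' checksummed JSON report at `out_dir/report.json`.  Stage parameters that
#' name an earlier stage (`manifest:`, `profile:`) are resolved to that
#' stage's output.  The run is deterministic: identical config and seed give
#' a byte-identical report.  Progress is logged to stderr; results go to
#' files only.
#'
#' @param config path to a YAML config, or an equivalent list.  Top-level
#'   keys: `seed` (integer), `out_dir` (optional; defaults to `"rotabar_run"`
#'   next to the config), `stages` (list of `name`/`type`/`params` blocks).
#' @param out_dir optional override of the config's output directory.
#' @return The report, invisibly: list with `seed`, `status` (`"ok"` or
#'   `"failed"`) and per-stage `status`, `outputs` (paths + md5), `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  validate_config(config)
  if (is.null(out_dir)) {
    out_dir <- if (!is.null(config$out_dir)) config$out_dir else "rotabar_run"
    if (!grepl("^(/|~)", out_dir)) out_dir <- file.path(base, out_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  set.seed(seed)
  artifacts <- list()
  stages_report <- list()
  failed <- FALSE
  for (st in config$stages) {
    if (failed) {
      stages_report[[st$name]] <- list(type = st$type, status = "skipped")
      next
    }
    log_msg("stage '", st$name, "' (", st$type, ")")
    res <- tryCatch(run_stage(st, out_dir, artifacts), error = identity)
    if (inherits(res, "error")) {
      log_msg("stage '", st$name, "' FAILED: ", conditionMessage(res))
      stages_report[[st$name]] <- list(type = st$type, status = "failed",
                                       error = conditionMessage(res))
      failed <- TRUE
    } else {
      artifacts[[st$name]] <- res$outputs[1]
      md5 <- unname(tools::md5sum(res$outputs))
      stages_report[[st$name]] <- list(
        type = st$type, status = "ok",
        outputs = lapply(seq_along(res$outputs), function(i)
          list(path = basename(res$outputs[i]), md5 = md5[i])),
        summary = res$summary)
    }
  }
  report <- list(seed = seed,
                 status = if (failed) "failed" else "ok",
                 stages = stages_report)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
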