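#' Read and validate a pipeline run configuration
#'
#' Configuration is a YAML or JSON file (or an equivalent named list)
#' parameterizing the five-step interpretation procedure: load and
#' coarse-grain the structure, align the pulling axis, compute ENM
#' modes on the full and each truncated form, analyse and select
#' domain-separating modes, deform and track buried volume.
#' Unknown keys are rejected.
#'
#' Top-level keys: `structure` (`path`, optional `chains`, `model`),
#' `pulling` (`attach_a`, `attach_b`, optional `axis`), `domains`
#' (named residue-range map), optional `truncations` (named map of
#' range-string vectors to remove, each analysed as an extra variant),
#' `enm` (`cutoff_rc`, `gamma`, `n_modes`), `selection` (see
#' [mode_selection_criteria()]), `deformation` (`target_rmsd`,
#' `ramp_targets`, `n_conformations`, `n_per_step`, `weighting`),
#' `burial` (see [burial_params()]), `output_dir`, `seed`, `plots`.
#'
#' @param config Path to a YAML/JSON file, or a named list.
#' @return A validated config object of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("structure", "pulling", "domains", "truncations", "enm",
             "selection", "deformation", "burial", "output_dir", "seed",
             "plots")
  extra <- setdiff(names(config), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  for (req in c("structure", "pulling", "domains", "output_dir"))
    if (is.null(config[[req]])) stop("config key '", req, "' is required")
  if (is.null(config$structure$path))
    stop("config key 'structure.path' is required")
  for (req in c("attach_a", "attach_b"))
    if (is.null(config$pulling[[req]]))
      stop("config key 'pulling.", req, "' is required")
  if (is.null(names(config$domains)) || length(config$domains) < 1L)
    stop("'domains' must be a named map of residue ranges")

  cfg <- list(
    structure = list(path = config$structure$path,
                     chains = config$structure$chains,
                     model = config$structure$model %||% 1L),
    pulling = pulling_geometry(config$pulling$attach_a,
                               config$pulling$attach_b,
                               config$pulling$axis %||% c(0, 0, 1)),
    domains = config$domains,
    truncations = config$truncations %||% list(),
    enm = do.call(enm_params, as.list(config$enm %||% list())),
    selection = do.call(mode_selection_criteria,
                        as.list(config$selection %||% list())),
    deformation = list(
      target_rmsd = config$deformation$target_rmsd %||% 12,
      ramp_targets = config$deformation$ramp_targets %||%
        c(2, 4, 6, 8, 10, 12),
      n_conformations = config$deformation$n_conformations %||% 500L,
      n_per_step = config$deformation$n_per_step %||% 100L,
      weighting = config$deformation$weighting %||% "inverse_lambda"),
    burial = do.call(burial_params, as.list(config$burial %||% list())),
    output_dir = config$output_dir,
    seed = as.integer(config$seed %||% 1L),
    plots = isTRUE(config$plots))
  if (length(cfg$truncations) &&
      (is.null(names(cfg$truncations)) ||
         any(!nzchar(names(cfg$truncations)))))
    stop("'truncations' entries must be named")
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_table <- function(df, dir, name, manifest) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  c(manifest, path)
}

#' Run the five-step interpretation pipeline
#'
#' Executes, for the full structure and every configured truncation:
#' (1) coarse-graining and a static buried-core survey, (2) rotation
#' of the tether vector onto the pulling axis, (3) ENM normal modes
#' (all modes, so stiffness is exact), (4) square fluctuations,
#' stiffness, collectivity, per-mode axis components and
#' domain-separating-mode selection, (5) stochastic target-RMSD
#' ensembles plus an RMSD ramp, ensemble buried-volume statistics and
#' a domain integrity ranking (lowest mean buried volume = lowest
#' structural integrity, i.e. expected to come apart first).  All
#' tables are written as CSV under the output directory together with
#' a JSON manifest; identical config + seed reproduces every number.
#'
#' @param config A `run_config` (or path / list accepted by
#'   [read_run_config()]).
#' @param model Optional pre-built [coarse_model()]; when supplied,
#'   `structure.path` is ignored (used by the synthetic-fixture tests
#'   and the CLI).
#' @return An object of class `run_report` (invisible): per-variant
#'   results (`modes` summary, `fluctuations`, `stiffness`,
#'   `selection`, `ensemble_stats`, `ramp_stats`, `integrity_ranking`),
#'   plus `files`, `warnings`, `timings`, `config`.
#' @export
run_pipeline <- function(config, model = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  files <- character()
  timings <- c()
  report <- list(config = config, variants = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- withCallingHandlers(expr, warning = note)
    list(val = val, dt = proc.time()[["elapsed"]] - t0)
  }

  ## stage 1: load, coarse-grain, static burial survey
  st <- t_stage({
    m <- if (is.null(model))
      read_coarse_pdb(config$structure$path,
                      chains = config$structure$chains,
                      model_index = config$structure$model)
    else model
    dm <- domain_map(m, config$domains)
    rep0 <- classify_buried(m, params = config$burial, domains = dm)
    list(model = m, domains = dm, survey = rep0)
  })
  timings["load_and_survey"] <- st$dt
  full_model <- st$val$model
  files <- write_table(st$val$survey$residues, config$output_dir,
                       "static_burial.csv", files)
  report$static_burial <- st$val$survey

  variants <- c(list(full = character()), config$truncations)
  for (vi in seq_along(variants)) {
    vname <- names(variants)[vi]
    vdir <- file.path(config$output_dir, vname)
    dir.create(vdir, showWarnings = FALSE)
    st <- t_stage(analyse_variant(full_model, variants[[vi]], config,
                                  vname, vdir,
                                  seed = config$seed + 101L * (vi - 1L)))
    timings[vname] <- st$dt
    files <- c(files, st$val$files)
    st$val$files <- NULL
    report$variants[[vname]] <- st$val
  }

  report$files <- files
  report$warnings <- warnings_log
  report$timings <- timings
  manifest <- list(
    package_version = as.character(utils::packageVersion("fsnma")),
    seed = config$seed,
    enm = config$enm[c("cutoff_rc", "gamma")],
    burial = config$burial[c("probe_radius", "n_sphere_points",
                             "exposure_threshold")],
    deformation = config$deformation,
    variants = names(variants),
    files = files,
    warnings = warnings_log,
    timings_sec = as.list(round(timings, 3)))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(report) <- "run_report"
  invisible(report)
}

analyse_variant <- function(full_model, removals, config, vname, vdir,
                            seed) {
  files <- character()
  m <- if (length(removals))
    apply_selection(full_model, residue_selection(removals, "remove"))
  else full_model

  ## step 2: align pulling axis (attachments must survive truncation)
  al <- align_pulling_axis(m, config$pulling)
  m <- al$model
  write_coarse_pdb(m, file.path(vdir, "aligned.pdb"))
  files <- c(files, file.path(vdir, "aligned.pdb"))

  ## domains that still resolve on this variant
  dm_spec <- Filter(function(sp) {
    ok <- tryCatch({domain_map(m, structure(list(sp), names = "x")); TRUE},
                   error = function(e) FALSE)
    ok
  }, config$domains)
  if (length(dm_spec) < length(config$domains))
    warning("variant '", vname, "': domain(s) ",
            paste(setdiff(names(config$domains), names(dm_spec)),
                  collapse = ", "),
            " do not resolve after truncation and were dropped")
  dm <- if (length(dm_spec)) domain_map(m, dm_spec) else NULL

  ## step 3: modes (all, so stiffness is available)
  modes <- enm_modes(m, config$enm, n_modes = "all")

  ## step 4: per-residue and per-mode analyses
  fluct <- square_fluctuations(modes,
                               m_modes = min(100L, length(modes$values)))
  stiff <- residue_stiffness(modes)
  res_tab <- data.frame(chain_id = m$chain_id,
                        residue_seq = m$residue_seq,
                        residue_name = m$residue_name,
                        square_fluctuation = fluct,
                        stiffness = stiff)
  files <- write_table(res_tab, vdir, "residue_profiles.csv", files)

  n_report <- min(50L, length(modes$values))
  mode_tab <- data.frame(mode = seq_len(n_report),
                         eigenvalue = modes$values[seq_len(n_report)],
                         collectivity = collectivity(modes,
                                                     seq_len(n_report)))
  sel <- NULL
  if (!is.null(dm) && length(dm) == 2L) {
    sel <- select_separating_modes(modes, dm,
                                   axis = config$pulling$target_axis,
                                   criteria = config$selection)
    files <- write_table(sel$report, vdir, "mode_selection.csv", files)
  }
  files <- write_table(mode_tab, vdir, "mode_table.csv", files)

  ## step 5: ensembles, ramp, burial statistics, integrity ranking
  ens_stats <- ramp_stats <- ranking <- NULL
  if (!is.null(sel) && length(sel$selected)) {
    spec <- deformation_spec(sel$selected,
                             config$deformation$target_rmsd,
                             config$deformation$n_conformations,
                             seed = seed,
                             weighting = config$deformation$weighting)
    ens <- sample_ensemble(modes, spec)
    write_coarse_pdb(ens, file.path(vdir, "ensemble.pdb"))
    files <- c(files, file.path(vdir, "ensemble.pdb"))
    coef_tab <- data.frame(frame = seq_len(nrow(ens$coefficients)),
                           achieved_rmsd = ens$achieved_rmsd,
                           ens$coefficients, check.names = FALSE)
    files <- write_table(coef_tab, vdir, "ensemble_coefficients.csv",
                         files)
    eb <- ensemble_burial(ens, dm, config$burial)
    ens_stats <- eb$stats
    files <- write_table(ens_stats, vdir, "ensemble_burial.csv", files)

    ramp <- rmsd_ramp(modes, sel$selected,
                      config$deformation$ramp_targets,
                      n_per_step = config$deformation$n_per_step,
                      seed = seed,
                      weighting = config$deformation$weighting)
    ramp_stats <- do.call(rbind, lapply(seq_along(ramp), function(s) {
      st <- ensemble_burial(ramp[[s]], dm, config$burial)$stats
      cbind(target_rmsd = config$deformation$ramp_targets[s], st)
    }))
    files <- write_table(ramp_stats, vdir, "ramp_burial.csv", files)

    ranking <- ens_stats$domain[order(ens_stats$mean)]
  }
  if (config$plots)
    files <- c(files, variant_plots(vdir, res_tab, sel, ramp_stats))

  list(variant = vname, n_sites = m$n_sites,
       transform = al$transform,
       modes = list(n_nonzero = length(modes$values),
                    n_zero = modes$n_zero_modes,
                    eigenvalues = modes$values[seq_len(n_report)]),
       fluctuations = fluct, stiffness = stiff, mode_table = mode_tab,
       selection = sel, ensemble_stats = ens_stats,
       ramp_stats = ramp_stats, integrity_ranking = ranking,
       files = files)
}

variant_plots <- function(vdir, res_tab, sel, ramp_stats) {
  out <- character()
  p1 <- file.path(vdir, "residue_profiles.png")
  grDevices::png(p1, width = 900, height = 600)
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  graphics::plot(res_tab$residue_seq, res_tab$square_fluctuation,
                 type = "l", xlab = "residue",
                 ylab = "square fluctuation (1/gamma)")
  graphics::plot(res_tab$residue_seq, res_tab$stiffness, type = "l",
                 xlab = "residue", ylab = "stiffness (gamma)")
  grDevices::dev.off()
  out <- c(out, p1)
  if (!is.null(ramp_stats)) {
    p2 <- file.path(vdir, "ramp_burial.png")
    grDevices::png(p2, width = 900, height = 500)
    doms <- unique(ramp_stats$domain)
    graphics::matplot(
      unique(ramp_stats$target_rmsd),
      sapply(doms, function(d)
        ramp_stats$mean[ramp_stats$domain == d]),
      type = "b", pch = 16, lty = 1,
      xlab = "target RMSD (A)", ylab = "mean buried volume (A^3)")
    graphics::legend("topright", legend = doms, col = seq_along(doms),
                     lty = 1, pch = 16)
    grDevices::dev.off()
    out <- c(out, p2)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> variants:", paste(names(x$variants), collapse = ", "),
      "\n")
  for (v in x$variants) {
    cat("-- ", v$variant, ": N = ", v$n_sites, ", ",
        v$modes$n_nonzero, " non-zero modes", sep = "")
    if (!is.null(v$selection))
      cat("; separating modes: ",
          paste(v$selection$selected, collapse = ", "))
    if (!is.null(v$integrity_ranking))
      cat("; integrity ranking (weakest first): ",
          paste(v$integrity_ranking, collapse = " < "))
    cat("\n")
  }
  if (length(x$warnings))
    cat(length(x$warnings), "warning(s); see manifest.json\n")
  invisible(x)
}
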