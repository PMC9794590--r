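# Configuration-driven runs: a YAML config resolves to package objects, a
# task is executed, and tidy CSV outputs plus a JSON manifest (package
# version, seed, config hash) are written. This is the file-level surface
# behind the inst/cli/schaftosim.R script.

#' Read / write a run configuration
#'
#' Configurations are plain YAML mappings; see [pbpk_run()] for the
#' recognised fields. Round-trips losslessly for scalar fields.
#'
#' @param path File path.
#' @return `read_pbpk_config()`: a named list.
#' @export
read_pbpk_config <- function(path) {
  assert_that(file.exists(path), paste("config file not found:", path))
  yaml::read_yaml(path)
}

#' @rdname read_pbpk_config
#' @param config A named list to serialise.
#' @export
write_pbpk_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

resolve_model_inputs <- function(config) {
  species <- config$species %||% "human"
  calibrated <- isTRUE(config$calibrated %||% TRUE)
  if (calibrated) {
    cal <- if (species == "rat") calibrate_rat_model() else
      calibrate_human_model()
    ind <- cal$individual; cmp <- cal$compound; form <- cal$formulation
    kp_scale <- cal$kp_scale
  } else {
    defs <- schaftoside_defaults()
    cmp <- defs$compound
    form <- if (species == "rat") defs$formulation_rat else
      defs$formulation_human
    ind <- if (species == "rat") {
      build_reference_individual("rat", 0.12, "male", 0.21)
    } else {
      build_reference_individual("human", 28, "male", 56.35, 162.1)
    }
    kp_scale <- 1
  }
  stage <- config$ckd_stage %||% "healthy"
  if (!identical(stage, "healthy")) {
    ind <- apply_ckd_stage(ind, ckd_scaling(stage))
  }
  reg <- if (is.character(config$regimen %||% "human_0p6")) {
    regs <- build_study_regimens()
    nm <- config$regimen %||% "human_0p6"
    assert_that(nm %in% names(regs),
                paste0("unknown regimen '", nm, "'; available: ",
                       paste(names(regs), collapse = ", ")))
    regs[[nm]]
  } else {
    regimen(as_tibble(config$regimen$events), config$regimen$duration)
  }
  list(ind = ind, cmp = cmp, form = form, reg = reg, kp_scale = kp_scale)
}

write_manifest <- function(out_dir, config, seed, extra = list()) {
  manifest <- c(list(
    package = "schaftosim",
    version = as.character(utils::packageVersion("schaftosim")),
    seed = seed,
    config_hash = rlang::hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  ), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Execute a configuration-driven run
#'
#' Tasks:
#' * `simulate` — simulate a (calibrated by default) model over a named or
#'   inline regimen; writes `timecourse.csv` and `pk_parameters.csv`.
#' * `nca` — non-compartmental analysis of `input` (CSV: time, conc);
#'   writes `nca.csv`.
#' * `evaluate` — fold-error qualification of `predicted` against
#'   `observed` CSVs; writes `evaluation_points.csv`,
#'   `evaluation_summary.csv`.
#' * `sensitivity` — local sensitivity of the calibrated human model;
#'   writes `sensitivity.csv`.
#' * `popsim` — population simulation; writes `population_summary.csv` and
#'   `population_band.csv`.
#' * `synth` — synthetic one-compartment profiles (`dose_mg`, `v_L`,
#'   `ke_per_h`, `schedule`, error fields); writes `synthetic_profiles.csv`.
#' * `fixtures` — writes the six packaged study tables.
#'
#' Common fields: `task`, `species`, `regimen`, `ckd_stage`, `calibrated`,
#' `seed`, `rtol`, `atol`. Every run writes a `manifest.json` recording the
#' package version, seed and config hash.
#'
#' @param config A config list or path to a YAML file.
#' @param out_dir Output directory (created if missing).
#' @return The output directory, invisibly.
#' @export
pbpk_run <- function(config, out_dir) {
  if (is.character(config)) config <- read_pbpk_config(config)
  assert_that(is.list(config) && !is.null(config$task),
              "config must be a list (or YAML path) with a `task` field")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  set.seed(seed)
  task <- config$task

  if (task == "simulate") {
    m <- resolve_model_inputs(config)
    sim <- simulate_pbpk(m$ind, m$cmp, m$form, m$reg,
                         kp_scale = m$kp_scale,
                         rtol = config$rtol %||% 1e-8,
                         atol = config$atol %||% 1e-10)
    readr::write_csv(sim$timecourse, file.path(out_dir, "timecourse.csv"))
    readr::write_csv(glance(sim), file.path(out_dir, "pk_parameters.csv"))
    write_manifest(out_dir, config, seed,
                   list(dose_mg = sim$dose_mg,
                        species = m$ind$species))
  } else if (task == "nca") {
    assert_that(!is.null(config$input) && file.exists(config$input),
                paste("input file not found:", config$input %||% "<missing>"))
    prof <- readr::read_csv(config$input, show_col_types = FALSE)
    res <- compute_nca(prof, dose = config$dose_mg,
                       lloq = config$lloq %||% 0,
                       tau = config$tau)
    readr::write_csv(res, file.path(out_dir, "nca.csv"))
    write_manifest(out_dir, config, seed)
  } else if (task == "evaluate") {
    for (f in c(config$predicted, config$observed)) {
      assert_that(!is.null(f) && file.exists(f),
                  paste("input file not found:", f %||% "<missing>"))
    }
    ev <- evaluate_model(readr::read_csv(config$predicted,
                                         show_col_types = FALSE),
                         readr::read_csv(config$observed,
                                         show_col_types = FALSE),
                         lloq = config$lloq %||% 0)
    readr::write_csv(ev$points, file.path(out_dir, "evaluation_points.csv"))
    readr::write_csv(ev$summary, file.path(out_dir, "evaluation_summary.csv"))
    write_manifest(out_dir, config, seed,
                   list(afe = ev$summary$afe, aafe = ev$summary$aafe))
  } else if (task == "sensitivity") {
    m <- resolve_model_inputs(config)
    sens <- local_sensitivity(
      m$ind, m$cmp, m$form, m$reg,
      parameters = config$parameters %||% sensitivity_paths(),
      perturbation = config$perturbation %||% 0.1,
      metrics = config$metrics %||% c("cmax_day1", "auc_day1"),
      kp_scale = m$kp_scale,
      output_times = seq(0, attr(m$reg, "duration"),
                         by = config$dt %||% 0.05))
    readr::write_csv(rank_parameters(sens),
                     file.path(out_dir, "sensitivity.csv"))
    write_manifest(out_dir, config, seed)
  } else if (task == "popsim") {
    # the sampler applies CKD scaling itself, so resolve a healthy base
    m <- resolve_model_inputs(utils::modifyList(as.list(config),
                                                list(ckd_stage = "healthy")))
    spec <- population_spec(n = config$n %||% 100,
                            fraction_male = config$fraction_male %||% 0.5,
                            age_range = unlist(config$age_range %||%
                                                 c(18, 40)),
                            ckd_stage = config$ckd_stage %||% "healthy",
                            seed = seed)
    pop <- simulate_population(spec, m$ind, m$cmp, m$form, m$reg,
                               kp_scale = m$kp_scale)
    readr::write_csv(population_summary(pop),
                     file.path(out_dir, "population_summary.csv"))
    readr::write_csv(pop$band, file.path(out_dir, "population_band.csv"))
    write_manifest(out_dir, config, seed,
                   list(n = spec$n, failures = length(pop$failures)))
  } else if (task == "synth") {
    sched <- config$schedule %||% "human"
    times <- if (is.character(sched)) study_schedules()[[sched]] else
      as.numeric(sched)
    ke <- config$ke_per_h %||% 0.3
    c0 <- (config$dose_mg %||% 100) / (config$v_L %||% 10) * 1000
    err <- error_model(config$proportional_cv %||% 0.1,
                       config$additive_sd, config$lloq %||% 0.05,
                       seed = seed)
    prof <- generate_profile(function(t) c0 * exp(-ke * t), times, err,
                             n_subjects = config$n %||% 1,
                             truth = list(c0 = c0, ke = ke))
    readr::write_csv(prof, file.path(out_dir, "synthetic_profiles.csv"))
    write_manifest(out_dir, config, seed)
  } else if (task == "fixtures") {
    fx <- load_study_tables()
    for (nm in names(fx)) {
      readr::write_csv(fx[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
    write_manifest(out_dir, config, seed, list(tables = length(fx)))
  } else {
    abort(paste0("unknown task '", task, "'"))
  }
  invisible(out_dir)
}
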