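#' Run the full estimation pipeline
#'
#' Orchestrates simulate (optional) -> classify -> fit -> aggregate ->
#' report. Writes, to the output directory: the input tables (when
#' simulated), the classification audit trail (every datum with its path
#' through the decision logic or its exclusion reason), the indicator
#' tables per requested level with point estimates and 80%/95% intervals,
#' MCMC diagnostics, and a run manifest with input digests. A failure in
#' any stage aborts with the stage name.
#'
#' @param config Run configuration: a YAML file path or an equivalent list.
#'   Keys: `seed`; `simulate` (arguments of [world_config()] and
#'   [obs_config()]) or `inputs` (paths: `women`, `births`, `abortion`,
#'   `intention`, optionally `birth_records`, plus `countries` records for
#'   the model); `model` (`sampler`, `bound_softness`, `covariate_names`,
#'   `priors`); `report` (`levels`, `suppress_data_free`).
#' @param output_dir Output directory (created if missing).
#' @param seed Optional override of the configuration seed.
#' @param stages Stages to run, a subset of
#'   `c("simulate", "classify", "fit", "report")` (earlier stages are
#'   always implied by later ones).
#' @param log_level `"info"` or `"quiet"`.
#' @return The output directory, invisibly; the fitted posterior is
#'   attached as attribute `"posterior"` when the fit stage ran.
#' @export
run_pipeline <- function(config, output_dir = "upaest_out", seed = NULL,
                         stages = c("simulate", "classify", "fit", "report"),
                         log_level = "info") {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) {
    if (identical(log_level, "info")) message("[upaest] ", ...)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  inputs <- stage("simulate", {
    if (!is.null(cfg$simulate) || is.null(cfg$inputs)) {
      log_msg("simulating synthetic world (seed ", cfg$seed, ")")
      sim_args <- cfg$simulate
      wc <- do.call(world_config, c(
        sim_args[intersect(names(sim_args), names(formals(world_config)))],
        list(seed = cfg$seed)))
      truth <- generate_world(wc)
      oc <- do.call(obs_config, c(
        sim_args[intersect(names(sim_args), names(formals(obs_config)))],
        list(seed = cfg$seed + 1L)))
      raw <- generate_observations(truth, oc)
      write_exposure(truth$exposure, file.path(output_dir, "women.tsv"),
                     file.path(output_dir, "births.tsv"))
      utils::write.table(raw$abortion,
                         file.path(output_dir, "abortion_data.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE, na = "")
      utils::write.table(raw$intention,
                         file.path(output_dir, "intention_data.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE, na = "")
      if (!is.null(raw$birth_records)) {
        utils::write.table(raw$birth_records,
                           file.path(output_dir, "birth_records.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE,
                           na = "")
      }
      list(exposure = truth$exposure, abortion = raw$abortion,
           intention = raw$intention, birth_records = raw$birth_records,
           countries = truth$countries, covariates = truth$X,
           regions_with_underreporting = raw$regions_with_underreporting,
           truth = truth)
    } else {
      log_msg("reading inputs")
      ip <- cfg$inputs
      periods <- as.integer(unlist(cfg$periods %||% default_periods()))
      exposure <- read_exposure(ip$women, ip$births, periods = periods)
      countries <- do.call(rbind, lapply(ip$countries, function(r) {
        data.frame(country = r$country, modeling_group = r$modeling_group,
                   region = r$region, stringsAsFactors = FALSE)
      }))
      list(exposure = exposure,
           abortion = read_abortion_data(ip$abortion),
           intention = read_intention_data(ip$intention),
           birth_records = if (!is.null(ip$birth_records)) {
             utils::read.delim(ip$birth_records, na.strings = "")
           },
           countries = countries, covariates = NULL,
           regions_with_underreporting =
             as.character(ip$regions_with_underreporting %||% character(0)),
           truth = NULL)
    }
  })
  if (!any(c("classify", "fit", "report") %in% stages)) {
    return(invisible(output_dir))
  }
  class_cfg <- do.call(classification_config,
                       cfg$classification %||% list())
  obs <- stage("classify", {
    log_msg("classifying ", nrow(inputs$abortion), " abortion and ",
            nrow(inputs$intention), " intention datums")
    bind_observations(
      classify_abortion_data(inputs$abortion,
                             inputs$regions_with_underreporting, class_cfg),
      classify_intention_data(inputs$intention, inputs$birth_records,
                              class_cfg))
  })
  write_observations(obs, file.path(output_dir, "observations.tsv"))
  audit_ok <- all(c(inputs$abortion$datum_id, inputs$intention$datum_id)
                  %in% obs$datum_id)
  if (!audit_ok) stop("stage 'classify' failed: audit trail lost a datum")
  if (!any(c("fit", "report") %in% stages)) return(invisible(output_dir))
  post <- stage("fit", {
    mc_args <- cfg$model %||% list()
    mc <- model_config(
      countries = inputs$countries, covariates = inputs$covariates,
      covariate_names = mc_args$covariate_names,
      priors = mc_args$priors %||% default_priors(),
      bound_softness = mc_args$bound_softness %||% 0.15,
      sampler = mc_args$sampler %||% list(),
      seed = cfg$seed)
    model <- build_model(obs, inputs$exposure, mc)
    log_msg("fitting (", model$config$sampler$chains, " chains x ",
            model$config$sampler$iter, " iterations)")
    fit(model)
  })
  writeLines(diagnostics_text(post), file.path(output_dir, "diagnostics.txt"))
  if ("report" %in% stages) {
    stage("report", {
      rp <- cfg$report %||% list()
      levels <- rp$levels %||% c("country", "region", "global")
      suppress <- character(0)
      if (isTRUE(rp$suppress_data_free)) {
        with_data <- unique(obs$country[!obs$excluded])
        suppress <- setdiff(inputs$exposure$countries, with_data)
      }
      for (lv in levels) {
        tab <- report_indicators(post, lv,
                                 suppress = if (lv == "country") suppress
                                 else character(0))
        utils::write.table(tab,
                           file.path(output_dir,
                                     paste0("indicators_", lv, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE)
      }
      log_msg("report written")
    })
  }
  write_manifest(cfg, output_dir)
  out <- invisible(output_dir)
  attr(out, "posterior") <- post
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

diagnostics_text <- function(post) {
  dg <- post$diagnostics
  lines <- c(sprintf("draws: %d  chains: %d", nrow(post$draws),
                     coda::nchain(post$samples)),
             sprintf("converged: %s", dg$converged))
  if (!is.null(dg$rhat)) {
    lines <- c(lines, sprintf("max_rhat: %.4f", max(dg$rhat, na.rm = TRUE)))
  }
  if (!is.null(dg$ess)) {
    lines <- c(lines, sprintf("min_ess: %.1f", min(dg$ess, na.rm = TRUE)))
  }
  lines
}

#' Write the run manifest
#'
#' Records the configuration hash, seed, digests of every tabular output
#' in the directory, the package version and a timestamp. Two runs with
#' identical manifests (timestamps aside) produce bit-identical outputs.
#'
#' @param cfg Run configuration list.
#' @param output_dir Output directory.
#' @return Path of `manifest.json`, invisibly.
#' @export
write_manifest <- function(cfg, output_dir) {
  cfg_file <- file.path(output_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_file)
  files <- sort(setdiff(list.files(output_dir),
                        c("manifest.json")))
  digests <- tools::md5sum(file.path(output_dir, files))
  names(digests) <- files
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    file_digests = as.list(digests),
    package_version = as.character(utils::packageVersion("upaest")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(output_dir, "manifest.json"))
}
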