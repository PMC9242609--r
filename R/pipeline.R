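# End-to-end pipeline and command-line front end.

#' Pipeline run configuration
#'
#' Paths may be `NULL` where optional. When `microdata_dir` is given, rates
#' are re-estimated from the microdata and `rates_path` is ignored for the
#' ACTUAL modes.
#'
#' @param catalog_path incentive catalog (JSON/CSV).
#' @param demo_path demographic rates CSV.
#' @param rates_path rate set CSV (optional when `microdata_dir` given).
#' @param microdata_dir directory written by [write_microdata()] (optional).
#' @param payments_path observed per-category payments CSV (optional).
#' @param series_path series completion distributions CSV (optional; needed
#'   for relaxation fits).
#' @param incentive_payments_path CSV with columns `incentive_id`,
#'   `observed_inr`: observed mean monthly payments for individual series
#'   incentives (optional; enables relaxation fits).
#' @param catchment_population catchment size (default 1,000).
#' @param rounding_mode `"FULL_PRECISION"` or `"PAPER_ROUNDING"`.
#' @param inr_per_usd exchange rate for USD presentation (default 71.7).
#' @param out_dir output directory.
#' @param verbose print progress.
#' @return object of class `run_config`.
#' @export
run_config <- function(catalog_path, demo_path, rates_path = NULL,
                       microdata_dir = NULL, payments_path = NULL,
                       series_path = NULL, incentive_payments_path = NULL,
                       catchment_population = 1000,
                       rounding_mode = "FULL_PRECISION",
                       inr_per_usd = 71.7, out_dir = tempfile("chwearn-run-"),
                       verbose = TRUE) {
  for (p in c(catalog_path, demo_path, rates_path, payments_path, series_path,
              incentive_payments_path)) {
    if (!is.null(p) && !file.exists(p)) {
      chw_abort(sprintf("input path does not exist: %s", p))
    }
  }
  if (!is.null(microdata_dir) && !dir.exists(microdata_dir)) {
    chw_abort(sprintf("microdata directory does not exist: %s", microdata_dir))
  }
  if (is.null(rates_path) && is.null(microdata_dir)) {
    chw_abort("need either `rates_path` or `microdata_dir`")
  }
  if (catchment_population <= 0) chw_abort("catchment_population must be > 0")
  structure(
    list(catalog_path = catalog_path, demo_path = demo_path,
         rates_path = rates_path, microdata_dir = microdata_dir,
         payments_path = payments_path, series_path = series_path,
         incentive_payments_path = incentive_payments_path,
         catchment_population = catchment_population,
         rounding_mode = rounding_mode, inr_per_usd = inr_per_usd,
         out_dir = out_dir, verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

pipeline_log <- function(con, config, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
  writeLines(line, con)
  if (config$verbose) message(line)
}

input_hashes <- function(config) {
  paths <- Filter(Negate(is.null),
                  config[c("catalog_path", "demo_path", "rates_path",
                           "payments_path", "series_path",
                           "incentive_payments_path")])
  vapply(paths, function(p) unname(tools::md5sum(p)), character(1))
}

#' Run the full analysis pipeline
#'
#' Stages: load and validate inputs; (optionally) re-estimate rates from
#' microdata; project all four scenarios; build the gap report against
#' observed payments; fit relaxed completion thresholds for series
#' incentives with observed per-incentive payments; summarize the CHW
#' questionnaire. Writes CSV/JSON outputs plus a human-readable
#' `summary.txt` under `out_dir`, logging every stage with input hashes.
#' Stage failures abort with the failing stage named.
#'
#' @param config a [run_config()].
#' @return the report bundle (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  stage <- "init"
  bundle <- list()
  withCallingHandlers(
    {
      for (h in input_hashes(config)) pipeline_log(log_con, config, "inputs", h)

      stage <- "load"
      catalog <- load_catalog(config$catalog_path)
      demo <- load_demographic_rates(config$demo_path)
      catch <- catchment(config$catchment_population)
      pipeline_log(log_con, config, stage,
                   sprintf("%d incentives, %d demographic rates",
                           length(catalog), nrow(demo)))

      stage <- "rates"
      micro <- NULL
      if (!is.null(config$microdata_dir)) {
        micro <- read_microdata(config$microdata_dir)
        rates <- estimate_rates(micro$households, catalog, micro$chw_months)
        pipeline_log(log_con, config, stage,
                     sprintf("estimated %d rates from microdata", length(rates)))
      } else {
        rates <- load_rate_set(config$rates_path)
        pipeline_log(log_con, config, stage,
                     sprintf("loaded %d rates", length(rates)))
      }
      missing <- validate_against_rates(catalog, rates)
      if (length(missing)) {
        chw_config_error(sprintf("rate set does not cover the catalog: %s",
                                 paste(missing, collapse = ", ")))
      }

      stage <- "projection"
      projections <- project_scenarios(catalog, rates, demo, catch,
                                       config$rounding_mode)
      proj_df <- do.call(rbind, lapply(names(projections), function(code) {
        p <- projections[[code]]
        data.frame(scenario = code, incentive_id = names(p$per_incentive),
                   category = categories(catalog),
                   inr_per_month = as.numeric(p$per_incentive),
                   stringsAsFactors = FALSE)
      }))
      utils::write.csv(proj_df, file.path(config$out_dir, "projections.csv"),
                       row.names = FALSE)
      pipeline_log(log_con, config, stage, sprintf(
        "totals pp=%.1f pa=%.1f ap=%.1f aa=%.1f",
        projections$pp$total, projections$pa$total,
        projections$ap$total, projections$aa$total))
      bundle$projections <- projections

      stage <- "gaps"
      observed <- NULL
      if (!is.null(config$payments_path)) {
        observed <- load_observed_payments(config$payments_path)
      }
      report <- gap_report(projections, observed)
      utils::write.csv(as.data.frame(report),
                       file.path(config$out_dir, "gap_report.csv"),
                       row.names = FALSE)
      bundle$gap_report <- report
      pipeline_log(log_con, config, stage,
                   if (is.null(observed)) "no observed payments; implementation gap omitted"
                   else "gap report with observed payments")

      stage <- "relaxation"
      bundle$relaxation <- NULL
      if (!is.null(config$series_path) &&
          !is.null(config$incentive_payments_path)) {
        dists <- load_series_distributions(config$series_path)
        obs_inc <- utils::read.csv(config$incentive_payments_path,
                                   stringsAsFactors = FALSE)
        fits <- list()
        for (i in seq_len(nrow(obs_inc))) {
          id <- obs_inc$incentive_id[i]
          inc <- catalog[[id]]
          if (is.null(inc) || is.null(inc$series) || is.null(dists[[id]])) next
          contact_keys <- if (length(inc$behavior_keys)) inc$action_keys else character()
          incidence <- beneficiary_incidence(inc, demo, catch) *
            effective_rate("ACTUAL", contact_keys, rates)
          fits[[id]] <- fit_relaxation(inc, dists[[id]], incidence,
                                       obs_inc$observed_inr[i])
        }
        if (length(fits)) {
          relax_df <- do.call(rbind, lapply(fits, function(f)
            data.frame(incentive_id = f$incentive_id,
                       fitted_threshold = f$fitted_threshold,
                       expected_inr = f$expected_payment,
                       observed_inr = f$observed_payment,
                       discrepancy_inr = f$discrepancy)))
          utils::write.csv(relax_df, file.path(config$out_dir, "relaxation.csv"),
                           row.names = FALSE)
          bundle$relaxation <- fits
          pipeline_log(log_con, config, stage,
                       sprintf("fitted %d series incentives", length(fits)))
        }
      } else {
        pipeline_log(log_con, config, stage, "skipped (no series/payment inputs)")
      }

      stage <- "survey"
      if (!is.null(micro) && !is.null(micro$chws) && nrow(micro$chws)) {
        bundle$claim_experience <- claim_experience_summary(micro$chws)
        bundle$awareness <- awareness_summary(micro$chws)
        utils::write.csv(bundle$claim_experience,
                         file.path(config$out_dir, "claim_experience.csv"),
                         row.names = FALSE)
        utils::write.csv(bundle$awareness,
                         file.path(config$out_dir, "awareness.csv"),
                         row.names = FALSE)
        pipeline_log(log_con, config, stage, "survey summaries written")
      } else {
        pipeline_log(log_con, config, stage, "skipped (no questionnaire microdata)")
      }

      stage <- "summary"
      tot <- report[report$scope == "TOTAL", ]
      usd <- function(x) if (is.na(x)) "NA" else
        sprintf("%s (US$%d)", format(round_rupee(x), big.mark = ","),
                convert_currency(x, config$inr_per_usd))
      lines <- c(
        "Monthly CHW earnings, INR (USD at configured rate)",
        sprintf("  potential (perfect CHW-perfect household): %s", usd(tot$potential)),
        sprintf("  achievable (perfect CHW-actual household): %s", usd(tot$achievable)),
        sprintf("  modeled actual (actual-actual):            %s", usd(tot$modeled_actual)),
        sprintf("  observed payments:                         %s", usd(tot$observed)),
        sprintf("  design_gap:         %s", usd(tot$design_gap)),
        sprintf("  lost_opportunity:   %s", usd(tot$lost_opportunity)),
        sprintf("  implementation_gap: %s", usd(tot$implementation_gap))
      )
      writeLines(lines, file.path(config$out_dir, "summary.txt"))
      bundle$summary <- lines
      jsonlite::write_json(
        list(totals = as.list(tot[, -1, drop = FALSE]),
             rounding_mode = config$rounding_mode,
             catchment_population = config$catchment_population),
        file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
      pipeline_log(log_con, config, stage, "done")
    },
    error = function(e) {
      pipeline_log(log_con, config, stage,
                   paste("FAILED:", conditionMessage(e)))
      stop(structure(
        class = c("chwearn_stage_error", class(e)),
        list(message = sprintf("pipeline stage '%s' failed: %s",
                               stage, conditionMessage(e)),
             call = conditionCall(e))))
    }
  )
  invisible(bundle)
}

cli_usage <- "usage: chwearn <simulate|project|gaps|relax-fit|survey-summary|run> [options]"

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic microdata), `project` (scenario
#' projection), `gaps` (gap report), `relax-fit` (threshold fitting),
#' `survey-summary` (questionnaire descriptives), `run` (full pipeline, JSON
#' config). Returns (and, in a script, should be used as) an exit status:
#' 0 success, 2 validation/configuration failure, 1 runtime failure.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return integer exit status, invisibly.
#' @export
chwearn_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) { message(cli_usage); return(invisible(2L)) }
    cmd <- args[[1]]
    rest <- args[-1]
    switch(cmd,
      simulate = cli_simulate(rest),
      project = cli_project(rest),
      gaps = cli_gaps(rest),
      `relax-fit` = cli_relax_fit(rest),
      `survey-summary` = cli_survey_summary(rest),
      run = cli_run(rest),
      { message(cli_usage); return(invisible(2L)) }
    )
    0L
  },
  chwearn_validation_error = function(e) { message("validation error: ", conditionMessage(e)); 2L },
  chwearn_config_error = function(e) { message("configuration error: ", conditionMessage(e)); 2L },
  chwearn_contract_error = function(e) { message("contract error: ", conditionMessage(e)); 2L },
  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}

cli_parse <- function(args, option_list, usage) {
  parser <- optparse::OptionParser(usage = usage, option_list = option_list)
  optparse::parse_args(parser, args = args)
}

cli_simulate <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON generator config (optional)"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--n-chw", dest = "n_chw", type = "integer", default = 100L),
    optparse::make_option("--months", type = "integer", default = 12L),
    optparse::make_option("--out", type = "character", default = "microdata")
  ), "chwearn simulate [options]")
  base <- if (!is.null(opt$config)) jsonlite::fromJSON(opt$config) else list()
  config <- generator_config(
    seed = base$seed %||% opt$seed,
    n_chw = base$n_chw %||% opt$n_chw,
    months = base$months %||% opt$months,
    catchment_population = base$catchment_population %||% 1000,
    n_questionnaire = base$n_questionnaire %||% 1502L
  )
  sim <- generate_microdata(config)
  write_microdata(sim, opt$out)
  message(sprintf("wrote microdata for %d CHWs x %d months to %s",
                  config$n_chw, config$months, opt$out))
}

cli_common_inputs <- function(opt) {
  list(catalog = load_catalog(opt$catalog),
       demo = load_demographic_rates(opt$demo),
       rates = load_rate_set(opt$rates))
}

cli_project <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--catalog", type = "character", default = chwearn_extdata("catalog.json")),
    optparse::make_option("--demo", type = "character", default = chwearn_extdata("demographic_rates.csv")),
    optparse::make_option("--rates", type = "character", default = chwearn_extdata("rates.csv")),
    optparse::make_option("--scenario", type = "character", default = "pp",
                          help = "pp, pa, ap or aa"),
    optparse::make_option("--catchment", type = "double", default = 1000),
    optparse::make_option("--paper-rounding", dest = "paper_rounding",
                          action = "store_true", default = FALSE),
    optparse::make_option("--out", type = "character", default = NULL)
  ), "chwearn project [options]")
  inp <- cli_common_inputs(opt)
  proj <- project_all(inp$catalog, opt$scenario, inp$rates, inp$demo,
                      catchment(opt$catchment),
                      if (opt$paper_rounding) "PAPER_ROUNDING" else "FULL_PRECISION")
  print(proj)
  if (!is.null(opt$out)) {
    utils::write.csv(
      data.frame(incentive_id = names(proj$per_incentive),
                 inr_per_month = as.numeric(proj$per_incentive)),
      opt$out, row.names = FALSE)
  }
}

cli_gaps <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--catalog", type = "character", default = chwearn_extdata("catalog.json")),
    optparse::make_option("--demo", type = "character", default = chwearn_extdata("demographic_rates.csv")),
    optparse::make_option("--rates", type = "character", default = chwearn_extdata("rates.csv")),
    optparse::make_option("--payments", type = "character", default = chwearn_extdata("observed_payments.csv")),
    optparse::make_option("--catchment", type = "double", default = 1000)
  ), "chwearn gaps [options]")
  inp <- cli_common_inputs(opt)
  projections <- project_scenarios(inp$catalog, inp$rates, inp$demo,
                                   catchment(opt$catchment))
  print(gap_report(projections, load_observed_payments(opt$payments)))
}

cli_relax_fit <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--catalog", type = "character", default = chwearn_extdata("catalog.json")),
    optparse::make_option("--demo", type = "character", default = chwearn_extdata("demographic_rates.csv")),
    optparse::make_option("--rates", type = "character", default = chwearn_extdata("rates.csv")),
    optparse::make_option("--series", type = "character", default = chwearn_extdata("series_distributions.csv")),
    optparse::make_option("--incentive", type = "character"),
    optparse::make_option("--observed", type = "double")
  ), "chwearn relax-fit --incentive ID --observed VALUE")
  if (is.null(opt$incentive) || is.null(opt$observed)) {
    chw_abort("relax-fit needs --incentive and --observed")
  }
  inp <- cli_common_inputs(opt)
  inc <- inp$catalog[[opt$incentive]]
  if (is.null(inc)) chw_config_error(sprintf("unknown incentive '%s'", opt$incentive))
  dists <- load_series_distributions(opt$series)
  if (is.null(dists[[inc$id]])) {
    chw_config_error(sprintf("no series distribution for '%s'", inc$id))
  }
  contact_keys <- if (length(inc$behavior_keys)) inc$action_keys else character()
  incidence <- beneficiary_incidence(inc, inp$demo, catchment()) *
    effective_rate("ACTUAL", contact_keys, inp$rates)
  print(fit_relaxation(inc, dists[[inc$id]], incidence, opt$observed))
}

cli_survey_summary <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--microdata", type = "character"),
    optparse::make_option("--out", type = "character", default = NULL)
  ), "chwearn survey-summary --microdata dir/")
  if (is.null(opt$microdata)) chw_abort("survey-summary needs --microdata")
  micro <- read_microdata(opt$microdata)
  ce <- claim_experience_summary(micro$chws)
  aw <- awareness_summary(micro$chws)
  print(ce); print(aw)
  if (!is.null(opt$out)) {
    utils::write.csv(rbind(ce, aw[names(ce)]), opt$out, row.names = FALSE)
  }
}

cli_run <- function(args) {
  opt <- cli_parse(args, list(
    optparse::make_option("--config", type = "character"),
    optparse::make_option("--out", type = "character", default = NULL)
  ), "chwearn run --config cfg.json [--out dir]")
  if (is.null(opt$config)) chw_abort("run needs --config")
  raw <- jsonlite::fromJSON(opt$config)
  config <- run_config(
    catalog_path = raw$catalog_path, demo_path = raw$demo_path,
    rates_path = raw$rates_path, microdata_dir = raw$microdata_dir,
    payments_path = raw$payments_path, series_path = raw$series_path,
    incentive_payments_path = raw$incentive_payments_path,
    catchment_population = raw$catchment_population %||% 1000,
    rounding_mode = raw$rounding_mode %||% "FULL_PRECISION",
    inr_per_usd = raw$inr_per_usd %||% 71.7,
    out_dir = opt$out %||% raw$out_dir %||% "chwearn-report",
    verbose = TRUE
  )
  bundle <- run_pipeline(config)
  writeLines(bundle$summary)
}
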