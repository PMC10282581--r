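#' Derive a stage seed from the master seed
#'
#' Stable string hash of the stage name folded into the master seed, kept
#' below 2^31 so the result is always a valid integer seed.
#'
#' @param master_seed integer master seed.
#' @param stage stage name.
#' @return Integer seed, deterministic in both arguments.
#' @export
derive_seed <- function(master_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(master_seed) * 7919 + h) %% (2^31 - 1))
}

#' Run configuration for the full synthetic study
#'
#' @param master_seed integer; deterministically derives every stage seed.
#' @param n_per_group participants per group.
#' @param model generative model for the synthetic study, `"ddm"` or
#'   `"logistic"` (the diffusion-model stages require `"ddm"` data).
#' @param gen optional generative parameter list (see [simulate_study()]).
#' @param mcmc list of MCMC settings: `chains`, `draws`, `burnin`, `thin`.
#' @param out_dir optional output directory; when given, the trial table,
#'   the selection table and a JSON run summary are written there.
#' @param verbose print stage progress?
#' @return A `run_config` list.
#' @export
run_config <- function(master_seed = 1, n_per_group = 30, model = "ddm",
                       gen = NULL,
                       mcmc = list(chains = 2, draws = 1000, burnin = 500,
                                   thin = 1),
                       out_dir = NULL, verbose = TRUE) {
  structure(list(master_seed = master_seed, n_per_group = n_per_group,
                 model = model, gen = gen, mcmc = mcmc, out_dir = out_dir,
                 verbose = verbose),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @param config a [run_config()] object.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the complete study pipeline on synthetic data
#'
#' Executes, in order: study simulation, quality filtering, the confirmatory
#' and manipulation-check mixed models, hierarchical DDM fits of the
#' five-model space, DIC model selection, the posterior hypothesis tests,
#' and the trait correlations. Every stage draws its seed deterministically
#' from the master seed, so a rerun with the same configuration reproduces
#' the identical trial table and traces. A stage failure aborts with the
#' stage name; results of completed stages are kept in the error condition's
#' `partial` field.
#'
#' @param config a [run_config()].
#' @return A `study_report` list: `trials`, `participants`, `qc`,
#'   `glmm` (confirmatory + manipulation tables), `fits`, `selection`,
#'   `hypotheses`, `trait_cor`, `seeds`, `config`.
#' @export
run_full_study <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = config, seeds = list())
  say <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    say("stage %s ...", name)
    tryCatch(expr, error = function(e) {
      cond <- simpleError(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)))
      cond$partial <- report
      stop(cond)
    })
  }

  report$seeds$simulate <- derive_seed(config$master_seed, "simulate")
  study <- stage("simulate", simulate_study(
    n_per_group = config$n_per_group, model = config$model, gen = config$gen,
    seed = report$seeds$simulate))
  report$trials <- study$trials
  report$participants <- study$participants
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials(study$trials, file.path(config$out_dir, "trials.csv"))
  }

  qc <- stage("quality_filter", apply_quality_filters(study$trials))
  report$qc <- qc$qc
  clean <- qc$data

  report$glmm <- stage("glmm", {
    list(confirmatory = fit_confirmatory_glmm(clean),
         manipulation = fit_manipulation_glmms(clean))
  })

  ddm_data <- clean[clean$partner == "fairness_partner", ]
  space <- build_model_space()
  fits <- stage("hddm_fits", {
    lapply(space, function(spec) {
      sd <- derive_seed(config$master_seed, paste0("fit_", spec$name))
      report$seeds[[paste0("fit_", spec$name)]] <<- sd
      fit_hddm(ddm_data, spec, chains = config$mcmc$chains,
               draws = config$mcmc$draws, burnin = config$mcmc$burnin,
               thin = config$mcmc$thin, seed = sd)
    })
  })
  report$fits <- fits

  report$selection <- stage("model_selection", select_model(fits))
  report$hypotheses <- stage("hypotheses", {
    set.seed(derive_seed(config$master_seed, "hypotheses"))
    evaluate_hypotheses(report$selection)
  })
  report$trait_cor <- stage("trait_correlations",
                            trait_correlations(study$participants))

  if (!is.null(config$out_dir)) {
    for (nm in names(fits)) {
      write_traces(fits[[nm]],
                   file.path(config$out_dir, paste0("traces_", nm, ".csv")))
    }
    write.csv(report$selection$table,
              file.path(config$out_dir, "selection.csv"), row.names = FALSE)
    summ <- list(
      master_seed = config$master_seed, seeds = report$seeds,
      n_per_group = config$n_per_group, model = config$model,
      mcmc = config$mcmc,
      dic = setNames(report$selection$table$dic,
                     report$selection$table$model),
      winners = report$selection$winners,
      max_rhat = max(vapply(fits, function(f) max(f$rhat$rhat), numeric(1))),
      hypotheses = report$hypotheses
    )
    jsonlite::write_json(summ, file.path(config$out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(report) <- "study_report"
  report
}

#' @exportS3Method base::print
print.study_report <- function(x, ...) {
  cat("Synthetic study report\n")
  cat(sprintf("  participants: %d (%d excluded by QC)\n",
              nrow(x$participants), sum(x$qc$excluded)))
  print(x$selection)
  print(x$hypotheses, row.names = FALSE, digits = 3)
  invisible(x)
}
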