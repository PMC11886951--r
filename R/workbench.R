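# Cohort I/O, experiment configuration and end-to-end orchestration:
# simulate -> fit ensemble -> features -> nested stacking -> evaluation,
# with a results directory that is reproducible from config + seeds.

#' Write / load a cohort as delimited text plus a JSON manifest
#'
#' `write_cohort` stores one CSV matrix per subject, a `manifest.json`
#' (ids, families, per-subject file and length, channel count), and CSV
#' tables for traits and confounds.  `load_cohort` reads a manifest back
#' into the ordered structures the pipeline consumes, validating
#' dimensions and ids; subjects with a missing value for a given trait
#' are reported in `trait_n` so callers can drop them per trait.
#'
#' @param cohort List with `timeseries`, `ids`, `families`, `confounds`
#'   (as produced by [generate_cohort]); `traits` optional (`N x P`
#'   matrix or data frame).
#' @param dir Output directory (created if needed).
#' @param traits Optional trait table to store alongside.
#' @export
write_cohort <- function(cohort, dir, traits = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  N <- length(cohort$timeseries)
  files <- sprintf("data_%s.csv", cohort$ids)
  for (n in seq_len(N)) {
    write.csv(cohort$timeseries[[n]], file.path(dir, files[n]),
              row.names = FALSE)
  }
  manifest <- list(
    n_subjects = N,
    n_channels = ncol(cohort$timeseries[[1]]),
    subjects = data.frame(id = cohort$ids, file = files,
                          family = cohort$families,
                          T_len = vapply(cohort$timeseries, nrow, 0L)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  if (!is.null(cohort$confounds)) {
    cf <- as.data.frame(cohort$confounds)
    names(cf) <- sprintf("confound%02d", seq_len(ncol(cf)))
    write.csv(cbind(id = cohort$ids, cf), file.path(dir, "confounds.csv"),
              row.names = FALSE)
  }
  if (!is.null(traits)) {
    write.csv(cbind(id = cohort$ids, as.data.frame(traits)),
              file.path(dir, "traits.csv"), row.names = FALSE)
  }
  invisible(file.path(dir, "manifest.json"))
}

#' @rdname write_cohort
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_cohort].
#' @return `load_cohort` returns a list: `timeseries`, `ids`, `families`,
#'   `confounds`, `traits` (or `NULL`), `trait_n` (non-missing subject
#'   count per trait).
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  dir <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  subj <- as.data.frame(man$subjects)
  if (anyDuplicated(subj$id))
    stop("duplicate subject id(s) in manifest: ",
         paste(unique(subj$id[duplicated(subj$id)]), collapse = ", "))
  ts <- vector("list", nrow(subj))
  for (n in seq_len(nrow(subj))) {
    f <- file.path(dir, subj$file[n])
    if (!file.exists(f))
      stop("missing timeseries file for subject ", subj$id[n], ": ", f)
    X <- as.matrix(read.csv(f, check.names = FALSE))
    if (ncol(X) != man$n_channels)
      stop("subject ", subj$id[n], " in ", f, " has ", ncol(X),
           " channels; manifest declares ", man$n_channels)
    ts[[n]] <- unname(X)
  }
  read_table <- function(name) {
    f <- file.path(dir, name)
    if (!file.exists(f)) return(NULL)
    tab <- read.csv(f, check.names = FALSE)
    if (!identical(as.character(tab$id), as.character(subj$id)))
      stop(name, " subject ids do not match the manifest order")
    as.matrix(tab[, setdiff(names(tab), "id"), drop = FALSE])
  }
  confounds <- read_table("confounds.csv")
  traits <- read_table("traits.csv")
  trait_n <- if (!is.null(traits)) colSums(!is.na(traits)) else NULL
  list(timeseries = ts, ids = as.character(subj$id),
       families = subj$family, confounds = confounds, traits = traits,
       trait_n = trait_n)
}

# ---- experiment configuration ----------------------------------------

config_defaults <- function() list(
  preset = "ukb_like",
  cohort = NULL,            # overrides for cohort_spec / manifest path
  ensemble = list(K = c(3, 4, 5), delta = c(10, 100), n_fixed_runs = 0),
  include_static = TRUE,
  model_mean = TRUE,
  batch_size = NULL,
  max_iter = 30,
  prior_strength = NULL,
  features = list(a = NULL, use_precision = TRUE, include_means = TRUE,
                  include_transitions = TRUE),
  lambda_grid = default_lambda_grid(),
  n_folds = 10,
  inner_folds = 10,
  repetitions = 1,
  trait = list(coupling = c(tangent = 1, means = 0.5, transitions = 0.5,
                            static = 0.5),
               noise_sd = 1.5, confound_effect = 0.3, n_traits = 2),
  seed = 1,
  output_dir = NULL)

#' Read and validate an experiment configuration
#'
#' Accepts a YAML or JSON file (or an R list) and merges it over the
#' package defaults.  Unknown top-level keys are rejected so that typos
#' fail before any computation.
#'
#' @param config Path to a `.yaml`/`.json` config, or a named list.
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) {
    stopifnot(file.exists(config))
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is needed to read YAML configs")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config)
  stopifnot(out$n_folds >= 2, out$inner_folds >= 2, out$repetitions >= 1)
  class(out) <- "run_config"
  out
}

log_line <- function(con, stage, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, msg)
  if (!is.null(con)) writeLines(line, con)
  invisible(line)
}

# Build the base-model feature sets for a cohort under a config: one
# dual-estimated HMM feature set per ensemble member plus optionally the
# static-FC set.
build_feature_sets <- function(cohort, cfg, logf = NULL) {
  ens <- expand.grid(K = cfg$ensemble$K, delta = cfg$ensemble$delta)
  if (!is.null(cfg$ensemble$n_fixed_runs) && cfg$ensemble$n_fixed_runs > 0) {
    fixed <- data.frame(K = rep(6, cfg$ensemble$n_fixed_runs),
                        delta = rep(10, cfg$ensemble$n_fixed_runs))
    ens <- rbind(ens, fixed)
  }
  feature_sets <- list()
  for (i in seq_len(nrow(ens))) {
    hseed <- child_seed(cfg$seed, 100 + i)
    ctl <- hmm_control(K = ens$K[i], delta = ens$delta[i],
                       model_mean = cfg$model_mean,
                       max_iter = cfg$max_iter,
                       batch_size = cfg$batch_size)
    log_line(logf, "fit-hmm",
             sprintf("ensemble member %d: K=%d delta=%g seed=%d",
                     i, ens$K[i], ens$delta[i], hseed))
    fit <- suppressWarnings(
      fit_group_hmm(cohort$timeseries, ctl, seed = hseed))
    subj <- lapply(cohort$timeseries, function(X)
      dual_estimate(fit$params, X, cfg$prior_strength))
    tag <- sprintf("hmm_K%d_d%g_r%d", ens$K[i], ens$delta[i], i)
    feature_sets[[tag]] <- assemble_features(
      subj, a = cfg$features$a,
      use_precision = cfg$features$use_precision,
      include_means = cfg$features$include_means,
      include_transitions = cfg$features$include_transitions)
  }
  if (isTRUE(cfg$include_static)) {
    log_line(logf, "features", "static FC feature set")
    feature_sets[["static"]] <- static_fc_features(
      cohort$timeseries, a = if (is.null(cfg$features$a)) 0.1 else
        cfg$features$a)
  }
  feature_sets
}

#' Run a full stacking experiment
#'
#' End-to-end orchestration: obtain a cohort (simulated from a preset or
#' loaded from a manifest), fit the HMM ensemble, dual-estimate subject
#' parameters, assemble feature sets (plus static FC), run repeated
#' nested stacking per trait, and evaluate.  When `output_dir` is set in
#' the config, per-trait prediction tables, stacking-weight tables, an
#' evaluation summary, a JSON run manifest and a timestamped log are
#' written there; re-running the same config reproduces all numeric
#' outputs exactly.
#'
#' @param config Path to a YAML/JSON config, or a named list (see
#'   [load_config]).
#' @return List of class `experiment_result`: per-trait
#'   `repetition_scores`, the feature-set tags, trait oracle R-squared
#'   values, and the config used.
#' @export
run_experiment <- function(config = list()) {
  cfg <- load_config(config)
  logf <- NULL
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    logf <- file(file.path(cfg$output_dir, "run.log"), open = "wt")
    on.exit(close(logf), add = TRUE)
  }
  stage <- "simulate"
  result <- tryCatch({
    log_line(logf, stage, sprintf("seed=%d preset=%s", cfg$seed, cfg$preset))
    if (is.character(cfg$cohort)) {
      loaded <- load_cohort(cfg$cohort)
      cohort <- loaded
      traits <- loaded$traits
      oracle_r2 <- rep(NA_real_, ncol(traits))
    } else {
      spec <- do.call(cohort_preset,
                      c(list(name = cfg$preset, seed = cfg$seed),
                        cfg$cohort))
      group <- generate_group_params(spec)
      cohort <- generate_cohort(group, spec)
      ts <- do.call(trait_spec, as.list(cfg$trait))
      gen <- generate_traits(cohort, ts, seed = child_seed(cfg$seed, 2))
      traits <- gen$traits
      oracle_r2 <- gen$oracle_r2
    }

    stage <- "features"
    feature_sets <- build_feature_sets(cohort, cfg, logf)

    stage <- "stack"
    per_trait <- list()
    for (p in seq_len(ncol(traits))) {
      tname <- colnames(traits)[p]
      keep <- !is.na(traits[, p])
      fs <- lapply(feature_sets, function(fm) fm$values[keep, , drop = FALSE])
      log_line(logf, stage,
               sprintf("trait %s: %d subjects, %d base models, R=%d",
                       tname, sum(keep), length(fs), cfg$repetitions))
      per_trait[[tname]] <- repeated_cv_evaluate(
        fs, traits[keep, p],
        confounds = if (!is.null(cohort$confounds))
          cohort$confounds[keep, , drop = FALSE] else NULL,
        groups = cohort$families[keep],
        n_folds = cfg$n_folds, R = cfg$repetitions,
        grid = cfg$lambda_grid, seed = child_seed(cfg$seed, 3 + p),
        inner_folds = cfg$inner_folds)
    }

    stage <- "evaluate"
    summary_tab <- do.call(rbind, lapply(names(per_trait), function(tn) {
      sc <- per_trait[[tn]]$scores
      data.frame(trait = tn, method = colnames(sc),
                 mean_r2 = colMeans(sc),
                 var_r2 = apply(sc, 2, var), row.names = NULL)
    }))
    out <- structure(list(per_trait = per_trait, summary = summary_tab,
                          model_tags = names(feature_sets),
                          oracle_r2 = oracle_r2, config = cfg),
                     class = "experiment_result")

    if (!is.null(cfg$output_dir)) {
      for (tn in names(per_trait)) {
        write.csv(per_trait[[tn]]$scores,
                  file.path(cfg$output_dir,
                            sprintf("scores_%s.csv", tn)),
                  row.names = FALSE)
      }
      write.csv(summary_tab, file.path(cfg$output_dir, "evaluation.csv"),
                row.names = FALSE)
      cfg_plain <- unclass(cfg)
      jsonlite::write_json(
        list(config = cfg_plain,
             model_tags = names(feature_sets),
             oracle_r2 = oracle_r2,
             package_version = as.character(utils::packageVersion("statestack"))),
        file.path(cfg$output_dir, "run_manifest.json"),
        digits = NA, auto_unbox = TRUE, null = "null")
      log_line(logf, stage, "results written")
    }
    out
  }, error = function(e) {
    log_line(logf, stage, paste("FAILED:", conditionMessage(e)))
    stop("experiment failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result:", length(x$per_trait), "trait(s),",
      length(x$model_tags), "base models\n")
  agg <- stats::aggregate(mean_r2 ~ method, x$summary, mean)
  for (m in c("stacked", "averaged", "static")) {
    if (m %in% agg$method)
      cat(sprintf("  %s: mean R^2 %.4f\n", m,
                  agg$mean_r2[agg$method == m]))
  }
  invisible(x)
}
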