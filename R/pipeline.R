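# Pipeline orchestration -------------------------------------------------
#
# A single JSON-serializable config drives the full reproducible chain:
# simulate-images -> analyze-images -> simulate-cohort -> diagnose.
# Every output embeds the package version, the seed and a hash of the
# config, and identical config + seed gives byte-identical outputs.

#' Default pipeline configuration
#'
#' Nested configuration blocks for every stage; see [field_spec()],
#' [segmentation_params()], [positivity_params()], [cohort_spec()].
#'
#' @param seed Integer master seed recorded in every output.
#' @return Named list of class `run_config` with blocks `field`
#'   (plus `n_fields`), `segmentation`, `positivity`, `cohort` and
#'   `diagnostics` (`cutoff` NULL = Youden, `cv_k`, `use_covariates`).
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    n_fields = 3L,
    field = unclass(field_spec(seed = seed)),
    segmentation = unclass(segmentation_params()),
    positivity = unclass(positivity_params()),
    cohort = list(n_healthy = 50L, n_hcc = 136L, seed = seed),
    diagnostics = list(cutoff = NULL, cv_k = 5L, use_covariates = FALSE)
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param config List as from [default_config()] (possibly read from
#'   JSON).
#' @return Invisibly the normalized config; missing blocks raise an
#'   error naming them.
#' @export
validate_config <- function(config) {
  need <- c("seed", "n_fields", "field", "segmentation", "positivity",
            "cohort", "diagnostics")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stopf("config is missing block(s): %s", paste(missing, collapse = ", "))
  }
  invisible(config)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}

pipeline_meta <- function(config) {
  list(package = "sevtools",
       version = as.character(utils::packageVersion("sevtools")),
       seed = config$seed,
       config_hash = config_hash(unclass(config)))
}

config_field_spec <- function(config) {
  fs <- config$field
  fs$combination_freqs <- as.numeric(unlist(fs$combination_freqs))
  fs$crosstalk <- matrix(as.numeric(unlist(fs$crosstalk)), 4L, 4L)
  do.call(field_spec, fs)
}

#' Run the full pipeline
#'
#' Executes the requested stages in order, writing all artifacts under
#' `out_dir`. Stage outputs: `field_<i>.tif` (+ truth/spec sidecars),
#' `coexpression.csv` + `marginals.csv`, `cohort.csv`, `roc.csv`,
#' `summary.json`, `cv.json`. Every JSON output embeds the package
#' version, seed and config hash; identical config and seed give
#' byte-identical outputs. A failing stage raises an error prefixed
#' with the stage name.
#'
#' @param config A `run_config` (or list, or path to a JSON config).
#' @param out_dir Output directory (created if absent).
#' @param stages Subset of
#'   `c("simulate-images", "analyze-images", "simulate-cohort",
#'   "diagnose")`.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         stages = c("simulate-images", "analyze-images",
                                    "simulate-cohort", "diagnose")) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- pipeline_meta(config)
  artifacts <- list()
  stage_try <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage %s failed: %s", name, conditionMessage(e))
    })
  }

  if ("simulate-images" %in% stages) stage_try("simulate-images", {
    for (i in seq_len(config$n_fields)) {
      fld <- simulate_field(config_field_spec(config),
                            seed = child_seed(config$seed, 100L + i))
      p <- file.path(out_dir, sprintf("field_%d.tif", i))
      write_field(fld, p)
      artifacts[[sprintf("field_%d", i)]] <- p
    }
  })

  if ("analyze-images" %in% stages) stage_try("analyze-images", {
    seg <- do.call(segmentation_params, config$segmentation)
    pos <- do.call(positivity_params, config$positivity)
    meas <- lapply(seq_len(config$n_fields), function(i) {
      p <- file.path(out_dir, sprintf("field_%d.tif", i))
      if (!file.exists(p)) stopf("missing %s (run simulate-images first)", p)
      fld <- read_field(p)
      measure_evs(fld, segment_field(fld, seg), pos)
    })
    tab <- coexpression_table(meas)
    cp <- file.path(out_dir, "coexpression.csv")
    mp <- file.path(out_dir, "marginals.csv")
    write_coexpression(tab, cp, mp)
    artifacts$coexpression <- cp
    artifacts$marginals <- mp
  })

  if ("simulate-cohort" %in% stages) stage_try("simulate-cohort", {
    cs <- do.call(cohort_spec, config$cohort)
    cohort <- derive_index(simulate_cohort(cs))
    cp <- file.path(out_dir, "cohort.csv")
    write_cohort(cohort, cp)
    artifacts$cohort <- cp
  })

  if ("diagnose" %in% stages) stage_try("diagnose", {
    cp <- file.path(out_dir, "cohort.csv")
    if (!file.exists(cp)) stopf("missing %s (run simulate-cohort first)", cp)
    cohort <- derive_index(read_cohort(cp))
    dg <- evaluate_diagnostics(cohort, cutoff = config$diagnostics$cutoff)
    rp <- file.path(out_dir, "roc.csv")
    utils::write.csv(data.frame(
      threshold = dg$roc$thresholds,
      sensitivity = dg$roc$sensitivity,
      one_minus_specificity = dg$roc$one_minus_specificity
    ), rp, row.names = FALSE)
    feats <- if (isTRUE(config$diagnostics$use_covariates)) {
      cbind(index = cohort$cd98_index, age = cohort$age,
            male = as.numeric(cohort$sex == "M"),
            smoking = as.numeric(cohort$smoking),
            alcohol = as.numeric(cohort$alcohol))
    } else {
      matrix(cohort$cd98_index, ncol = 1,
             dimnames = list(NULL, "index"))
    }
    cv <- logistic_cv(feats, cohort$group,
                      k = config$diagnostics$cv_k %||% 5L,
                      seed = config$seed)
    sp <- file.path(out_dir, "summary.json")
    jsonlite::write_json(c(meta, list(
      auc = dg$roc$auc,
      cutoff = dg$cutoff,
      youden_j = dg$youden$J,
      sensitivity = dg$confusion$sensitivity,
      specificity = dg$confusion$specificity,
      welch_t = dg$welch$statistic,
      welch_p = dg$welch$p_value,
      cv_mean_auc = cv$mean_auc,
      cv_mean_accuracy = cv$mean_accuracy
    )), sp, auto_unbox = TRUE, digits = NA, null = "null")
    vp <- file.path(out_dir, "cv.json")
    jsonlite::write_json(c(meta, list(
      k = cv$k, seed = cv$seed, folds = cv$folds,
      fold_auc = cv$fold_auc, fold_accuracy = cv$fold_accuracy,
      separated = cv$separated,
      coefficients = apply(cv$coefficients, 1, as.list)
    )), vp, digits = NA, auto_unbox = TRUE)
    artifacts$roc <- rp
    artifacts$summary <- sp
    artifacts$cv <- vp
  })

  invisible(artifacts)
}

#' Command-line entry point
#'
#' Thin argument parser behind the `exec/sevtools` script. Subcommands:
#' `simulate-images`, `analyze-images`, `simulate-cohort`, `diagnose`,
#' `run-all`; common flags `--seed <int>`, `--config <json>`,
#' `--out-dir <dir>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
ev_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sevtools <simulate-images|analyze-images|simulate-cohort|",
    "                 diagnose|run-all> [--seed N] [--config FILE]",
    "                 [--out-dir DIR]", sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[[1]]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) == 1L && i < length(args)) args[[i + 1L]] else default
  }
  seed <- as.integer(opt("--seed", "1"))
  out_dir <- opt("--out-dir", "sevtools-out")
  cfg_path <- opt("--config", NA)
  config <- if (!is.na(cfg_path)) {
    jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  } else {
    default_config(seed)
  }
  config$seed <- seed
  stages <- switch(cmd,
    "simulate-images" = "simulate-images",
    "analyze-images" = "analyze-images",
    "simulate-cohort" = "simulate-cohort",
    "diagnose" = "diagnose",
    "run-all" = c("simulate-images", "analyze-images", "simulate-cohort",
                  "diagnose"),
    { message("unknown subcommand: ", cmd, "\n", usage)
      return(invisible(2L)) })
  run_pipeline(config, out_dir, stages)
  message("wrote artifacts to ", out_dir)
  invisible(0L)
}
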