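# Synthetic patient cohort ----------------------------------------------
#
# The diagnostics stage needs subject-level tables (per-well EV counts
# on antibody-coated discs with PBS negative-control wells, a total EV
# concentration from particle tracking, and clinical covariates). No
# patient data are deposited, so a generator reproduces the cohort's
# statistical structure from published median/IQR summaries: the
# per-subject CD98+ EV index is log-normal within group, well counts
# are Poisson around the latent rate implied by the index, and
# covariates are drawn at the published group frequencies.

#' Log-normal parameters from a median/IQR summary
#'
#' Finds `(mu, sigma)` of a log-normal distribution with the given
#' median and interquartile range. `mu = log(median)` exactly; `sigma`
#' solves `exp(mu) * (exp(z * sigma) - exp(-z * sigma)) = iqr` with
#' `z = qnorm(0.75)`, by bracketed root finding refined to
#' `|f| < 1e-10`.
#'
#' @param median,iqr Positive target median and interquartile range.
#' @return Named numeric vector `c(mu, sigma)`.
#' @examples
#' p <- lognormal_from_median_iqr(3.548, 3.821)
#' qlnorm(0.5, p["mu"], p["sigma"])                      # 3.548
#' diff(qlnorm(c(0.25, 0.75), p["mu"], p["sigma"]))      # 3.821
#' @export
lognormal_from_median_iqr <- function(median, iqr) {
  if (!(is.numeric(median) && median > 0)) stopf("`median` must be > 0")
  if (!(is.numeric(iqr) && iqr > 0)) stopf("`iqr` must be > 0")
  z <- stats::qnorm(0.75)
  mu <- log(median)
  f <- function(sigma) median * (exp(z * sigma) - exp(-z * sigma)) - iqr
  upper <- 1
  while (f(upper) < 0) {
    upper <- upper * 2
    if (upper > 1e6) stopf("no positive sigma reproduces this median/IQR")
  }
  root <- stats::uniroot(f, c(0, upper), tol = 1e-14)$root
  # polish by bisection until |f| < 1e-10
  lo <- max(root - 1e-8, 0); hi <- root + 1e-8
  if (f(lo) > 0 || f(hi) < 0) { lo <- 0; hi <- upper }
  while (abs(f(root)) >= 1e-10) {
    if (f(root) > 0) hi <- root else lo <- root
    root <- (lo + hi) / 2
  }
  c(mu = mu, sigma = root)
}

group_defaults <- function() {
  list(
    healthy = list(
      n = 50L, index_median = 3.548, index_iqr = 3.821,
      age_median = 38.5, age_iqr = 11.25,
      p_male = 0.56, p_smoking = 0.34, p_alcohol = 0.20, p_cirrhosis = 0.02
    ),
    hcc = list(
      n = 136L, index_median = 9.761, index_iqr = 16.405,
      age_median = 66, age_iqr = 4.75,
      p_male = 0.801, p_smoking = 0.478, p_alcohol = 0.441, p_cirrhosis = 0.30,
      afp_meanlog = log(20), afp_sdlog = 2.5,
      tumor_size_meanlog = log(4), tumor_size_sdlog = 0.7,
      p_stage1 = 0.55
    )
  )
}

#' Specification of a synthetic diagnostic cohort
#'
#' Holds every generator parameter: per-group sizes, index
#' distributions (log-normal fitted to median/IQR), covariate
#' frequencies, age summaries, the disc/well layout, the negative
#' control rate, the total-EV-concentration distribution and the
#' concentration normalization scale.
#'
#' @param n_healthy,n_hcc Group sizes.
#' @param groups Per-group parameter lists; see the default structure
#'   returned by this function. Supplied entries override defaults
#'   group-wise.
#' @param control_mean Mean count in a PBS negative-control well.
#' @param n_control Negative-control wells per disc.
#' @param wells_per_disc Wells per disc (samples share a disc's
#'   controls).
#' @param conc_meanlog,conc_sdlog Log-normal parameters of the total EV
#'   concentration (particles/mL).
#' @param scale Concentration normalization scale (particles/mL) used by
#'   [ev_index()].
#' @param noise `"poisson"` (default) or `"none"`; `"none"` replaces
#'   every stochastic count by its mean and collapses the index
#'   distribution onto its median (useful for exactness tests).
#' @param seed Integer seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_healthy = 50L, n_hcc = 136L, groups = list(),
                        control_mean = 20, n_control = 2L,
                        wells_per_disc = 16L,
                        conc_meanlog = log(1e10), conc_sdlog = 0.5,
                        scale = 1e9, noise = c("poisson", "none"),
                        seed = 1L) {
  noise <- match.arg(noise)
  g <- group_defaults()
  for (nm in names(groups)) {
    if (!nm %in% names(g)) stopf("unknown group '%s'", nm)
    g[[nm]][names(groups[[nm]])] <- groups[[nm]]
  }
  g$healthy$n <- as.integer(n_healthy)
  g$hcc$n <- as.integer(n_hcc)
  for (nm in names(g)) {
    if (g[[nm]]$n <= 0) stopf("group sizes must be positive")
    probs <- unlist(g[[nm]][grep("^p_", names(g[[nm]]))])
    if (any(probs < 0 | probs > 1)) stopf("covariate frequencies must be in [0,1]")
  }
  if (control_mean < 0) stopf("`control_mean` must be >= 0")
  if (!is_count(n_control) || n_control < 1) stopf("need >= 1 control well")
  if (wells_per_disc <= n_control) stopf("disc must have sample wells")
  if (scale <= 0) stopf("`scale` must be > 0")
  structure(list(groups = g, control_mean = control_mean,
                 n_control = as.integer(n_control),
                 wells_per_disc = as.integer(wells_per_disc),
                 conc_meanlog = conc_meanlog, conc_sdlog = conc_sdlog,
                 scale = scale, noise = noise, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a subject-level cohort table
#'
#' Per subject: a true CD98+ EV index is drawn from the group's
#' log-normal (fitted to its median/IQR), a total EV concentration is
#' drawn log-normal, and the latent sample-well rate is
#' `index * concentration / scale + control_mean`. The observed sample
#' well count is Poisson around that rate; each disc carries
#' `n_control` PBS control wells, Poisson around `control_mean`, shared
#' by the subjects on that disc. Ages are normal around the group
#' median (sd = IQR/1.349); sex, smoking, alcohol and cirrhosis are
#' Bernoulli at the group frequencies, independent of the index. HCC
#' subjects additionally get log-normal AFP and tumor size and a
#' stage I/II label; these fields are `NA` for healthy subjects.
#'
#' @param spec A [cohort_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return data.frame of class `ev_cohort`, one row per subject, with
#'   columns `subject_id`, `group`, `age`, `sex`, `smoking`, `alcohol`,
#'   `cirrhosis`, `afp`, `tumor_size`, `stage`, `disc_id`,
#'   `sample_well_count`, `control_1..control_k`,
#'   `total_ev_concentration`, `true_index`.
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  exact <- spec$noise == "none"
  with_seed(seed, {
    rows <- lapply(names(spec$groups), function(gname) {
      g <- spec$groups[[gname]]
      n <- g$n
      if (exact) {
        true_index <- rep(g$index_median, n)
      } else {
        p <- lognormal_from_median_iqr(g$index_median, g$index_iqr)
        true_index <- stats::rlnorm(n, p[["mu"]], p[["sigma"]])
      }
      conc <- if (exact) rep(exp(spec$conc_meanlog), n) else
        stats::rlnorm(n, spec$conc_meanlog, spec$conc_sdlog)
      latent <- true_index * conc / spec$scale + spec$control_mean
      count <- if (exact) latent else stats::rpois(n, latent)
      age_sd <- g$age_iqr / (2 * stats::qnorm(0.75))
      df <- data.frame(
        group = gname,
        age = if (exact) rep(g$age_median, n) else
          stats::rnorm(n, g$age_median, age_sd),
        sex = ifelse(stats::runif(n) < g$p_male, "M", "F"),
        smoking = stats::runif(n) < g$p_smoking,
        alcohol = stats::runif(n) < g$p_alcohol,
        cirrhosis = stats::runif(n) < g$p_cirrhosis,
        afp = NA_real_, tumor_size = NA_real_, stage = NA_character_,
        sample_well_count = count,
        total_ev_concentration = conc,
        true_index = true_index
      )
      if (gname == "hcc") {
        df$afp <- stats::rlnorm(n, g$afp_meanlog, g$afp_sdlog)
        df$tumor_size <- stats::rlnorm(n, g$tumor_size_meanlog,
                                       g$tumor_size_sdlog)
        df$stage <- ifelse(stats::runif(n) < g$p_stage1, "I", "II")
      }
      df
    })
    df <- do.call(rbind, rows)
    n_all <- nrow(df)
    df$subject_id <- sprintf("S%03d", seq_len(n_all))
    samples_per_disc <- spec$wells_per_disc - spec$n_control
    df$disc_id <- (seq_len(n_all) - 1L) %/% samples_per_disc + 1L
    n_disc <- max(df$disc_id)
    ctrl <- matrix(
      if (exact) rep(spec$control_mean, n_disc * spec$n_control) else
        stats::rpois(n_disc * spec$n_control, spec$control_mean),
      nrow = n_disc)
    for (j in seq_len(spec$n_control)) {
      df[[sprintf("control_%d", j)]] <- ctrl[df$disc_id, j]
    }
    rownames(df) <- NULL
    cols <- c("subject_id", "group", "age", "sex", "smoking", "alcohol",
              "cirrhosis", "afp", "tumor_size", "stage", "disc_id",
              "sample_well_count",
              sprintf("control_%d", seq_len(spec$n_control)),
              "total_ev_concentration", "true_index")
    df <- df[, cols]
    attr(df, "scale") <- spec$scale
    class(df) <- c("ev_cohort", "data.frame")
    df
  })
}

#' Derive the CD98+ EV index for every subject
#'
#' Applies [normalize_score()] (sample well count minus the mean of the
#' disc's negative-control wells, floored at 0) and [ev_index()]
#' (division by `concentration / scale`) row-wise.
#'
#' @param cohort An `ev_cohort` (or any data.frame with the cohort
#'   schema).
#' @param scale Concentration scale; defaults to the attribute recorded
#'   by [simulate_cohort()], else 1e9.
#' @return The cohort with a `cd98_index` column appended.
#' @export
derive_index <- function(cohort, scale = NULL) {
  scale <- scale %||% attr(cohort, "scale") %||% 1e9
  ctrl_cols <- grep("^control_[0-9]+$", names(cohort), value = TRUE)
  if (length(ctrl_cols) == 0L) {
    stopf("cohort has no control_* columns; cannot normalize disc %s",
          paste(unique(cohort$disc_id), collapse = ","))
  }
  ctrl <- as.matrix(cohort[, ctrl_cols, drop = FALSE])
  score <- normalize_score(cohort$sample_well_count, ctrl)
  cohort$cd98_index <- ev_index(score, cohort$total_ev_concentration, scale)
  cohort
}

#' Validate the cohort table schema
#'
#' Checks column presence and types, non-negative counts, positive
#' concentrations, and that HCC-only fields (`afp`, `tumor_size`,
#' `stage`) are `NA` for healthy subjects.
#'
#' @param cohort data.frame to validate.
#' @return Invisibly `TRUE`; otherwise an error naming the violation.
#' @export
validate_cohort <- function(cohort) {
  need <- c("subject_id", "group", "age", "sex", "smoking", "alcohol",
            "cirrhosis", "afp", "tumor_size", "stage", "disc_id",
            "sample_well_count", "control_1", "total_ev_concentration")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) stopf("cohort lacks columns: %s",
                             paste(missing, collapse = ", "))
  if (!all(cohort$group %in% c("healthy", "hcc"))) {
    stopf("`group` must be 'healthy' or 'hcc'")
  }
  if (any(cohort$sample_well_count < 0)) stopf("well counts must be >= 0")
  ctrl_cols <- grep("^control_[0-9]+$", names(cohort), value = TRUE)
  if (any(as.matrix(cohort[, ctrl_cols]) < 0)) stopf("control counts must be >= 0")
  if (any(cohort$total_ev_concentration <= 0)) {
    stopf("total EV concentration must be > 0")
  }
  healthy <- cohort$group == "healthy"
  if (any(!is.na(cohort$afp[healthy])) ||
      any(!is.na(cohort$tumor_size[healthy])) ||
      any(!is.na(cohort$stage[healthy]))) {
    stopf("hcc-only fields must be absent (NA) for healthy subjects")
  }
  invisible(TRUE)
}

#' Write / read a cohort CSV
#'
#' Fixed-header CSV round trip for the cohort table.
#'
#' @param cohort An `ev_cohort`.
#' @param path CSV path.
#' @param scale Concentration scale stored for [derive_index()].
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   an `ev_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, scale = 1e9) {
  df <- utils::read.csv(path, colClasses = c(stage = "character"))
  validate_cohort(df)
  attr(df, "scale") <- scale
  class(df) <- c("ev_cohort", "data.frame")
  df
}
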