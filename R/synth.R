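#' Configure the synthetic cohort generator
#'
#' The generator emulates the development sample's marginal structure:
#' correlated subscale scores with the published baseline means and SDs,
#' a latent utility built from a true mapping plus Gaussian noise, a
#' ceiling mechanism reproducing the observed mass at utility 1, and a
#' self-assessed performance status (0-4) cut from the latent utility at
#' quantiles matching the published status mix.
#'
#' The ceiling mechanism (`ceiling_rule = "latent-censor"`) collapses the
#' top `target_ceiling_fraction` of the latent distribution to exactly 1:
#' real EQ-5D-5L value sets have a discrete gap between full health (1) and
#' the best impaired state, so the observed distribution has a point mass
#' at 1 sitting above a continuum - which a Gaussian latent censored at the
#' model-implied threshold reproduces, while also keeping the mean utility
#' near the published 0.777.  With `target_ceiling_fraction = NULL` the
#' threshold is 1, i.e. classic Tobit censoring (the data-generating process
#' the Tobit estimator assumes).  `ceiling_rule = "clip"` plainly clips the
#' latent at 1.
#'
#' @param n Cohort size (default 238, the development sample).
#' @param seed Integer seed; all randomness in the generator flows from it.
#' @param subscale_means,subscale_sds Length-5 vectors (PWB, SWB, EWB, FWB,
#'   BCS); defaults are the published baseline values.
#' @param subscale_correlation Exchangeable correlation between subscale
#'   latents (default 0.4; the development study reports no correlation
#'   matrix, so this is a configurable package choice).
#' @param true_mapping The mapping that generates the latent utility
#'   (default: the published OLS Model 4 coefficients).
#' @param noise_sd Gaussian noise SD on the latent utility (default 0.08).
#' @param ceiling_rule `"latent-censor"` or `"clip"` (see above).
#' @param target_ceiling_fraction Fraction of the cohort at utility 1
#'   (default 0.248, the published baseline ceiling mass); `NULL` means
#'   censor exactly at 1.
#' @param status_probs Target frequencies of performance status 0, 1, 2 and
#'   3-or-4 (defaults 0.408, 0.483, 0.071, 0.038, the published mix).
#' @param status_cutpoints Optional 3 cutpoints on the latent utility scale
#'   (overrides the quantile calibration from `status_probs`).
#' @return A `synth_config` object.
#' @examples
#' cfg <- synth_config(n = 238, seed = 1)
#' cohort <- generate_cohort(cfg)
#' mean(cohort$utility == 1)  # near 0.248
#' @export
synth_config <- function(n = 238L, seed = 1L,
                         subscale_means = c(PWB = 21.1, SWB = 22.2, EWB = 18.0,
                                            FWB = 20.0, BCS = 21.7),
                         subscale_sds = c(PWB = 6.0, SWB = 6.1, EWB = 4.7,
                                          FWB = 6.7, BCS = 6.1),
                         subscale_correlation = 0.4,
                         true_mapping = published_mapping("ols", 4),
                         noise_sd = 0.08,
                         ceiling_rule = c("latent-censor", "clip"),
                         target_ceiling_fraction = 0.248,
                         status_probs = c(0.408, 0.483, 0.071, 0.038),
                         status_cutpoints = NULL) {
  ceiling_rule <- match.arg(ceiling_rule)
  stopifnot(length(subscale_means) == 5L, length(subscale_sds) == 5L,
            subscale_correlation >= 0, subscale_correlation < 1,
            noise_sd >= 0, inherits(true_mapping, "factb_mapping"))
  names(subscale_means) <- names(subscale_sds) <- names(.SUBSCALES)
  if (!is.null(target_ceiling_fraction)) {
    stopifnot(target_ceiling_fraction >= 0, target_ceiling_fraction < 1)
    if (ceiling_rule == "clip") {
      warning("target_ceiling_fraction is ignored under ceiling_rule = 'clip'")
    }
  }
  status_probs <- status_probs / sum(status_probs)
  cfg <- structure(list(
    n = as.integer(n), seed = as.integer(seed),
    subscale_means = subscale_means, subscale_sds = subscale_sds,
    subscale_correlation = subscale_correlation,
    true_mapping = true_mapping, noise_sd = noise_sd,
    ceiling_rule = ceiling_rule,
    target_ceiling_fraction = target_ceiling_fraction,
    status_probs = status_probs, status_cutpoints = status_cutpoints
  ), class = "synth_config")
  mom <- latent_moments(cfg)
  if (mom$sd <= 0 && !is.null(target_ceiling_fraction) &&
      target_ceiling_fraction > 0 && mom$mean < 1) {
    warning("infeasible ceiling target: latent utility is degenerate below 1")
  }
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  mom <- latent_moments(x)
  cat(sprintf("synthetic cohort config: n = %d, seed = %d\n", x$n, x$seed))
  cat(sprintf("  latent utility ~ N(%.4f, %.4f^2), ceiling rule %s",
              mom$mean, mom$sd, x$ceiling_rule))
  if (!is.null(x$target_ceiling_fraction)) {
    cat(sprintf(" (target %.1f%% at 1)", 100 * x$target_ceiling_fraction))
  }
  cat("\n")
  invisible(x)
}

# Model-implied mean/SD of the latent utility (ignoring rounding/clamping of
# the subscale scores, which perturbs these only marginally).
latent_moments <- function(cfg) {
  cf <- coef(cfg$true_mapping)
  covs <- cfg$true_mapping$covariates
  a <- cf[covs] * cfg$subscale_sds[covs]
  rho <- cfg$subscale_correlation
  v_index <- sum(a^2) + rho * (sum(a)^2 - sum(a^2))
  list(mean = cf[["(Intercept)"]] + sum(cf[covs] * cfg$subscale_means[covs]),
       sd = sqrt(v_index + cfg$noise_sd^2))
}

# Calibrated on the realized latent distribution (rounding and clamping of
# the subscale scores make it slightly non-normal, so analytic normal
# quantiles would drift off target); falls back to normal theory when no
# latent sample is supplied.
ceiling_threshold <- function(cfg, latent = NULL) {
  if (cfg$ceiling_rule != "latent-censor") return(Inf)
  if (is.null(cfg$target_ceiling_fraction)) return(1)
  if (cfg$target_ceiling_fraction <= 0) return(Inf)
  if (!is.null(latent)) {
    return(quantile(latent, 1 - cfg$target_ceiling_fraction, names = FALSE))
  }
  mom <- latent_moments(cfg)
  mom$mean + qnorm(1 - cfg$target_ceiling_fraction) * mom$sd
}

status_cutpoints_of <- function(cfg, latent = NULL) {
  if (!is.null(cfg$status_cutpoints)) return(sort(cfg$status_cutpoints))
  # cumulative from the worst group upward: P(3or4), P(>=2), P(>=1)
  cum <- cumsum(rev(cfg$status_probs))[1:3]
  if (!is.null(latent)) return(quantile(latent, cum, names = FALSE))
  mom <- latent_moments(cfg)
  mom$mean + qnorm(cum) * mom$sd
}

#' Generate a synthetic cohort
#'
#' Draws exchangeably-correlated continuous subscale latents, rounds
#' (half-up) and clamps them to each subscale's integer range, builds the
#' latent utility from the configured true mapping plus Gaussian noise,
#' applies the ceiling rule, and assigns performance status by cutting the
#' latent utility.  Fully reproducible: the same config (including seed)
#' yields the identical cohort.
#'
#' @param cfg A [synth_config()].
#' @return A data frame of class `factb_cohort`: columns `id`, `PWB`,
#'   `SWB`, `EWB`, `FWB`, `BCS`, `utility`, `status`, and `latent` (the
#'   generator's latent utility, kept for follow-up simulation; fitters
#'   ignore it).
#' @export
generate_cohort <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  rho <- cfg$subscale_correlation
  R <- matrix(rho, 5, 5); diag(R) <- 1
  z <- matrix(rnorm(n * 5), n, 5) %*% chol(R)
  scores <- vapply(1:5, function(j) {
    raw <- cfg$subscale_means[j] + cfg$subscale_sds[j] * z[, j]
    pmin(pmax(floor(raw + 0.5), 0), .SUBSCALE_MAX[j])
  }, numeric(n))
  colnames(scores) <- names(.SUBSCALES)
  scores <- as.data.frame(scores)

  cf <- coef(cfg$true_mapping)
  covs <- cfg$true_mapping$covariates
  latent <- cf[["(Intercept)"]] +
    drop(as.matrix(scores[covs]) %*% cf[covs]) +
    rnorm(n, 0, cfg$noise_sd)

  thr <- ceiling_threshold(cfg, latent)
  utility <- if (cfg$ceiling_rule == "clip") {
    pmin(latent, 1)
  } else {
    ifelse(latent >= thr, 1, pmin(latent, 1))
  }

  cuts <- status_cutpoints_of(cfg, latent)
  status <- ifelse(latent >= cuts[3], 0L,
            ifelse(latent >= cuts[2], 1L,
            ifelse(latent >= cuts[1], 2L, 3L)))
  # split the merged worst group between status 3 and 4
  worst <- status == 3L
  status[worst] <- status[worst] + (runif(sum(worst)) < 0.5)

  out <- cbind(data.frame(id = seq_len(n)), scores,
               data.frame(utility = utility, status = as.integer(status),
                          latent = latent))
  class(out) <- c("factb_cohort", "data.frame")
  attr(out, "config") <- cfg
  attr(out, "threshold") <- thr
  attr(out, "cutpoints") <- cuts
  out
}

#' Simulate a follow-up wave from a baseline cohort
#'
#' Each subject is retained with probability `1 - attrition`; retained
#' subjects' latent utilities drift by Gaussian noise of SD `drift_sd` and
#' are re-censored under the baseline ceiling rule, subscale scores drift
#' by a proportional integer perturbation (SD `20 * drift_sd` points), and
#' performance status is re-derived from the drifted latent.  With
#' `attrition = 0` and `drift_sd = 0` the follow-up equals the baseline.
#'
#' @param cohort A baseline cohort from [generate_cohort()].
#' @param cfg The config used to generate it (defaults to the one stored on
#'   the cohort).
#' @param attrition Probability a subject is lost to follow-up
#'   (default 0.07: 238 subjects retain about 221).
#' @param drift_sd SD of the latent-utility drift (default 0.05).
#' @param seed Seed for the follow-up randomness (default `cfg$seed + 1`).
#' @return A `factb_cohort` data frame; `id` values are a subset of the
#'   baseline ids.
#' @export
generate_followup <- function(cohort, cfg = attr(cohort, "config"),
                              attrition = 0.07, drift_sd = 0.05,
                              seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synth_config"), attrition >= 0, attrition < 1,
            drift_sd >= 0)
  set.seed(seed)
  n <- nrow(cohort)
  keep <- runif(n) >= attrition
  fu <- cohort[keep, , drop = FALSE]
  m <- nrow(fu)

  score_drift_sd <- 20 * drift_sd
  for (j in names(.SUBSCALES)) {
    drifted <- fu[[j]] + floor(rnorm(m, 0, score_drift_sd) + 0.5)
    fu[[j]] <- pmin(pmax(drifted, 0), .SUBSCALE_MAX[[j]])
  }
  fu$latent <- fu$latent + rnorm(m, 0, drift_sd)

  # reuse the baseline calibration: the ceiling threshold and status
  # cutpoints are population constants, so drift moves subjects across them
  thr <- attr(cohort, "threshold") %||% ceiling_threshold(cfg)
  fu$utility <- if (cfg$ceiling_rule == "clip") {
    pmin(fu$latent, 1)
  } else {
    ifelse(fu$latent >= thr, 1, pmin(fu$latent, 1))
  }
  cuts <- attr(cohort, "cutpoints") %||% status_cutpoints_of(cfg)
  status <- ifelse(fu$latent >= cuts[3], 0L,
            ifelse(fu$latent >= cuts[2], 1L,
            ifelse(fu$latent >= cuts[1], 2L, 3L)))
  # subjects already in the worst group keep their baseline 3-or-4 label;
  # new entrants are split at random
  stay_worst <- status == 3L & fu$status >= 3L
  new_worst <- status == 3L & fu$status < 3L
  status[stay_worst] <- fu$status[stay_worst]
  status[new_worst] <- 3L + (runif(sum(new_worst)) < 0.5)
  fu$status <- as.integer(status)
  rownames(fu) <- NULL
  class(fu) <- c("factb_cohort", "data.frame")
  attr(fu, "config") <- cfg
  fu
}

#' Write / read cohort CSV files
#'
#' The cohort CSV schema is the one the fitters read: columns `id`,
#' `PWB`..`BCS`, `utility`, `status` (the generator's `latent` column is
#' not written).
#'
#' @param cohort A cohort data frame.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- intersect(c("id", names(.SUBSCALES), "utility", "status"),
                    names(cohort))
  write.csv(cohort[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(names(.SUBSCALES), "utility"), names(dat))
  if (length(missing_cols)) {
    stop("cohort CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  class(dat) <- c("factb_cohort", "data.frame")
  dat
}
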