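#' Validate mappings against observed utilities by performance status
#'
#' Emulates the follow-up validation: within each self-assessed performance
#' status group (0, 1, 2, and 3-4 merged, as in the development study) the
#' observed and predicted mean utilities are compared with a signed-rank
#' test, each mapping's predictions are tested for decreasing trend across
#' status with Cuzick's test (group scores 0, 1, 2, 3; the merged group
#' scores 3), and every |observed - predicted| group-mean discrepancy is
#' flagged against the minimally important difference (MID) of the EQ-5D
#' for cancer patients: 0.08 (UK value set) and 0.06 (US value set).
#'
#' @param cohort Data frame with subscale columns, `utility` and a
#'   `status` column (0..4).
#' @param mappings A single `factb_mapping` or a named list of them.
#' @param mid Named MID thresholds.
#' @return An object of class `factb_validation`: list with `means` (group
#'   x mapping table of observed/predicted means and discrepancies),
#'   `signed_rank` (p-values), `trend` (Cuzick p per mapping),
#'   `max_discrepancy`, and `mid` flags.
#' @examples
#' cohort <- generate_cohort(synth_config(n = 400, seed = 11))
#' v <- validate_by_status(cohort, published_mapping("ols", 4))
#' v$max_discrepancy
#' @export
validate_by_status <- function(cohort, mappings,
                               mid = c(UK = 0.08, US = 0.06)) {
  if (inherits(mappings, "factb_mapping")) {
    mappings <- setNames(list(mappings),
                         paste(mappings$method,
                               if (!is.na(mappings$model)) mappings$model else "custom",
                               sep = "_"))
  }
  if (is.null(names(mappings)) || any(!nzchar(names(mappings)))) {
    names(mappings) <- paste0("mapping_", seq_along(mappings))
  }
  if (!"status" %in% names(cohort)) stop("cohort has no status column")
  status <- cohort$status
  if (any(!status %in% 0:4)) stop("status values must be 0..4")
  merged <- ifelse(status >= 3, 3L, as.integer(status))
  group_labels <- c(`0` = "0", `1` = "1", `2` = "2", `3` = "3 or 4")
  groups <- sort(unique(merged))
  skipped <- setdiff(0:3, groups)
  if (length(skipped)) {
    message("empty status group(s) skipped: ",
            paste(group_labels[as.character(skipped)], collapse = ", "))
  }

  pred <- lapply(mappings, predict, newdata = cohort)
  means <- data.frame(group = group_labels[as.character(groups)],
                      n = as.integer(table(merged)[as.character(groups)]),
                      observed = tapply(cohort$utility, merged, mean)[as.character(groups)],
                      stringsAsFactors = FALSE)
  sr <- matrix(NA_real_, nrow = length(groups), ncol = length(mappings),
               dimnames = list(means$group, names(mappings)))
  for (j in seq_along(mappings)) {
    pj <- pred[[j]]
    means[[names(mappings)[j]]] <-
      tapply(pj, merged, mean)[as.character(groups)]
    for (i in seq_along(groups)) {
      sel <- merged == groups[i]
      sr[i, j] <- signed_rank_test(cohort$utility[sel], pj[sel])$p.value
    }
  }
  trend <- vapply(c(list(observed = cohort$utility), pred), function(v) {
    cuzick_trend(v, merged, scores = as.numeric(groups))$p.value
  }, numeric(1))

  disc <- abs(as.matrix(means[names(mappings)]) - means$observed)
  dimnames(disc) <- list(means$group, names(mappings))
  structure(list(
    means = means, signed_rank = sr, trend = trend,
    discrepancy = disc, max_discrepancy = max(disc),
    mid = mid,
    within_mid = vapply(mid, function(th) all(disc < th), logical(1))
  ), class = "factb_validation")
}

#' @export
print.factb_validation <- function(x, digits = 4, ...) {
  cat("validation by self-assessed performance status\n")
  print(cbind(x$means[c("group", "n")],
              round(x$means[setdiff(names(x$means), c("group", "n"))], digits)),
        row.names = FALSE)
  cat("\nsigned-rank p-values (observed vs predicted within group):\n")
  print(round(x$signed_rank, digits))
  cat("\nCuzick trend p-values (decreasing with status):\n")
  print(signif(x$trend, 3))
  cat(sprintf("\nmax |observed - predicted| group mean: %.4f\n", x$max_discrepancy))
  for (nm in names(x$mid)) {
    cat(sprintf("  within %s MID (%.2f): %s\n", nm, x$mid[[nm]],
                ifelse(x$within_mid[[nm]], "yes", "no")))
  }
  invisible(x)
}

#' Group-mean discrepancies from a published-style status-means table
#'
#' Computes |observed - predicted| for every mapping row of a table in the
#' [published_status_means()] layout (an `observed` row plus one row per
#' method x model) and the table-wide maximum.
#'
#' @param status_means Data frame in the [published_status_means()] layout.
#' @return List with `discrepancy` (data frame) and `max` (scalar).
#' @export
status_mean_discrepancies <- function(status_means = published_status_means()) {
  ps_cols <- grep("^ps", names(status_means), value = TRUE)
  obs <- status_means[status_means$method == "observed", ps_cols]
  if (nrow(obs) != 1L) stop("table must contain exactly one 'observed' row")
  pred <- status_means[status_means$method != "observed", ]
  disc <- abs(sweep(as.matrix(pred[ps_cols]), 2L, as.numeric(obs)))
  out <- cbind(pred[c("method", "model")], disc)
  rownames(out) <- NULL
  list(discrepancy = out, max = max(disc))
}
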