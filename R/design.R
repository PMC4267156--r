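#' Model specifications for the mapping regressions
#'
#' Five preset specifications were examined in the development study:
#' Model 1 uses all five subscales; Model 2 the four FACT-G subscales
#' (PWB, SWB, EWB, FWB); Model 3 the three TOI subscales (PWB, FWB, BCS);
#' Models 4 and 5 drop SWB from Models 1 and 2 respectively (its coefficient
#' was small, insignificant and sometimes negative), giving
#' Model 4 = PWB, EWB, FWB, BCS and Model 5 = PWB, EWB, FWB.
#'
#' @param model Preset id 1..5, or `NULL` when `covariates` is given.
#' @param covariates Explicit ordered subset of
#'   `c("PWB","SWB","EWB","FWB","BCS")` (overrides `model`).
#' @param extra Character vector of additional numeric columns to enter the
#'   design linearly (e.g. a language indicator).
#' @return A `model_spec` object: list with `model`, `covariates`, `extra`.
#' @examples
#' model_spec(4)
#' model_spec(covariates = c("PWB", "FWB"), extra = "language")
#' @export
model_spec <- function(model = NULL, covariates = NULL, extra = character()) {
  presets <- list(
    `1` = c("PWB", "SWB", "EWB", "FWB", "BCS"),
    `2` = c("PWB", "SWB", "EWB", "FWB"),
    `3` = c("PWB", "FWB", "BCS"),
    `4` = c("PWB", "EWB", "FWB", "BCS"),
    `5` = c("PWB", "EWB", "FWB")
  )
  if (is.null(covariates)) {
    if (is.null(model)) stop("give either a preset model id (1..5) or covariates")
    key <- as.character(model)
    if (!key %in% names(presets)) stop("unknown model preset: ", model)
    covariates <- presets[[key]]
  } else {
    bad <- setdiff(covariates, names(.SUBSCALES))
    if (length(bad)) stop("unknown subscale covariate(s): ", paste(bad, collapse = ", "))
    if (anyDuplicated(covariates)) stop("duplicated covariates")
    model <- NULL
  }
  structure(list(model = if (is.null(model)) NA_integer_ else as.integer(model),
                 covariates = covariates, extra = as.character(extra)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("mapping model spec",
      if (!is.na(x$model)) sprintf("(Model %d)", x$model) else "(custom)",
      "\n  covariates:", paste(c(x$covariates, x$extra), collapse = " + "), "\n")
  invisible(x)
}

as_model_spec <- function(spec) {
  if (inherits(spec, "model_spec")) return(spec)
  if (is.numeric(spec) && length(spec) == 1L) return(model_spec(spec))
  if (is.character(spec)) return(model_spec(covariates = spec))
  stop("cannot interpret model specification")
}

#' Build the regression design from a cohort
#'
#' Assembles the design matrix (leading intercept column, then the spec's
#' covariates in order) and the utility outcome.  Rows with any undefined
#' required covariate or undefined utility are dropped, mirroring the
#' development study's exclusion of subjects whose missing values survived
#' half-rule imputation; the number dropped is reported on the result.
#'
#' @param cohort Data frame with subscale columns, a `utility` column, and
#'   any extra covariate columns named by the spec.
#' @param spec A [model_spec()] (or a preset id / covariate vector).
#' @return List with `x` (n x (p+1) matrix), `y` (length-n vector),
#'   `dropped` (row count removed) and `rows` (row indices kept).
#' @export
build_design <- function(cohort, spec = model_spec(4)) {
  spec <- as_model_spec(spec)
  vars <- c(spec$covariates, spec$extra)
  missing_cols <- setdiff(c(vars, "utility"), names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  block <- cohort[, c(vars, "utility"), drop = FALSE]
  keep <- complete.cases(block)
  if (!any(keep)) stop("empty design: no cohort row has all required covariates defined")
  x <- cbind(`(Intercept)` = 1, as.matrix(block[keep, vars, drop = FALSE]))
  storage.mode(x) <- "double"
  list(x = x, y = as.numeric(block$utility[keep]),
       dropped = sum(!keep), rows = which(keep), spec = spec)
}
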