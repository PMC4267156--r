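#' Recode a raw FACT-B item response
#'
#' Items are rated on a 5-point Likert scale coded 0-4.  Negatively worded
#' items are reversed (`4 - raw`) so that a higher score always indicates
#' better quality of life.  Reversal is an involution: applying it twice
#' returns the raw response.
#'
#' @param raw Integer vector of raw responses in 0..4 (`NA` allowed and
#'   passed through).
#' @param negatively_worded Logical scalar or vector: reverse these items.
#' @return Recoded responses on the same 0-4 scale.
#' @examples
#' recode_item(0:4, TRUE)   # 4 3 2 1 0
#' recode_item(0:4, FALSE)  # unchanged
#' @export
recode_item <- function(raw, negatively_worded = FALSE) {
  ok <- is.na(raw) | (raw %in% 0:4)
  if (!all(ok)) {
    stop("invalid item response(s): ", paste(unique(raw[!ok]), collapse = ", "),
         " (must be 0..4 or NA)")
  }
  ifelse(rep_len(negatively_worded, length(raw)), 4 - raw, raw)
}

#' Score one subscale with half-rule imputation
#'
#' A subscale score is defined only when strictly more than half of its items
#' were answered; missing items are then imputed with the mean of the
#' answered ones.  Equivalently the score is `sum(answered) * n_items /
#' n_answered`, which may be non-integer; it is kept at full precision.
#' When the half-rule fails the score is undefined (`NA`), which is a legal
#' result, not an error.
#'
#' @param items Numeric vector of recoded responses (0-4, `NA` = missing).
#' @param n_items Expected number of items; defaults to `length(items)`.
#' @return The prorated subscale score, or `NA` if the half-rule fails.
#' @examples
#' score_subscale(c(2, 2, 2, 2, NA, NA, NA))  # 14: strictly more than half answered
#' score_subscale(c(2, 2, 2, NA, NA, NA, NA)) # NA: 3 of 7 is not enough
#' @export
score_subscale <- function(items, n_items = length(items)) {
  if (length(items) != n_items) {
    stop("expected ", n_items, " items, got ", length(items))
  }
  answered <- sum(!is.na(items))
  if (answered <= n_items / 2) return(NA_real_)
  sum(items, na.rm = TRUE) * n_items / answered
}

#' Compute FACT-B composite scores
#'
#' FACT-G is the sum of PWB, SWB, EWB and FWB (range 0-108); the Trial
#' Outcome Index (TOI) is PWB + FWB + BCS (range 0-96); the FACT-B total is
#' the sum of all five subscales (range 0-148).  A composite is undefined
#' (`NA`) whenever any of its components is undefined.
#'
#' @param profile A named list, vector or data frame with elements/columns
#'   `PWB`, `SWB`, `EWB`, `FWB`, `BCS` (each may be `NA`).
#' @return A data frame with columns `FACTG`, `TOI`, `FACTB` (one row per
#'   input row; a single row for vector input).
#' @examples
#' compute_composites(c(PWB = 21.1, SWB = 22.2, EWB = 18.0, FWB = 20.0, BCS = 21.7))
#' @export
compute_composites <- function(profile) {
  prof <- if (is.data.frame(profile)) profile else as.data.frame(as.list(profile))
  missing_cols <- setdiff(names(.SUBSCALES), names(prof))
  if (length(missing_cols)) {
    stop("profile is missing subscale(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- lapply(.COMPOSITES, function(parts) {
    rowSums(as.data.frame(prof[parts]))  # rowSums propagates NA without na.rm
  })
  as.data.frame(out)
}

#' Score item-level FACT-B responses
#'
#' Applies polarity recoding and the half-rule to a table of item responses,
#' returning subscale scores and composites for each subject.
#'
#' @param responses Data frame with one row per subject and one column per
#'   manifest item id (blank/`NA` = missing).  Extra columns (e.g. an id)
#'   are carried through unchanged.
#' @param manifest An item manifest, see [fact_b_manifest()].
#' @return A data frame: carried-through non-item columns, then `PWB`,
#'   `SWB`, `EWB`, `FWB`, `BCS`, `FACTG`, `TOI`, `FACTB`.
#' @export
score_factb <- function(responses, manifest = fact_b_manifest()) {
  validate_manifest(manifest)
  missing_items <- setdiff(manifest$item_id, names(responses))
  if (length(missing_items)) {
    stop("response table is missing item column(s): ",
         paste(head(missing_items, 5L), collapse = ", "),
         if (length(missing_items) > 5L) ", ...")
  }
  extra <- responses[, setdiff(names(responses), manifest$item_id), drop = FALSE]
  scores <- lapply(names(.SUBSCALES), function(s) {
    ids <- manifest$item_id[manifest$subscale == s]
    neg <- manifest$negatively_worded[manifest$subscale == s]
    item_mat <- as.matrix(responses[, ids, drop = FALSE])
    recoded <- vapply(seq_along(ids), function(j) {
      recode_item(item_mat[, j], neg[j])
    }, numeric(nrow(item_mat)))
    recoded <- matrix(recoded, nrow = nrow(item_mat))
    apply(recoded, 1L, score_subscale, n_items = .SUBSCALES[[s]])
  })
  names(scores) <- names(.SUBSCALES)
  scores <- as.data.frame(scores)
  cbind(extra, scores, compute_composites(scores))
}

#' Read item-level or subscale-level FACT-B CSV files
#'
#' `read_items_csv()` reads a comma-delimited table with one row per subject
#' and one column per manifest item (blank cells are missing).
#' `read_subscales_csv()` reads a pre-scored table with columns `PWB`,
#' `SWB`, `EWB`, `FWB`, `BCS` (plus any extras), bypassing item scoring.
#'
#' @param path Path to the CSV file.
#' @return A data frame.
#' @export
read_items_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_items_csv
#' @export
read_subscales_csv <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(names(.SUBSCALES), names(dat))
  if (length(missing_cols)) {
    stop("subscale CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dat
}
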