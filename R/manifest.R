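#' Item manifest for the FACT-B
#'
#' The FACT-B (version 4) has 37 items in five subscales: physical well-being
#' (PWB, 7 items), social/family well-being (SWB, 7), emotional well-being
#' (EWB, 6), functional well-being (FWB, 7) and the breast-cancer subscale
#' (BCS, 10).  A manifest records, for every item, its identifier, its
#' subscale, and whether it is negatively worded (so that the raw 0-4
#' response must be reversed before scoring).
#'
#' The package ships a default manifest with placeholder identifiers
#' (`PWB1`..`PWB7`, ..., `BCS10`).  Which items are negatively worded is a
#' property of the licensed questionnaire and is not encoded in the
#' placeholder default (all items are marked positively worded); for real
#' use, supply a manifest CSV with the actual item identifiers and polarity.
#'
#' @param path Optional path to a manifest CSV with columns `item_id`,
#'   `subscale` and `negatively_worded` (logical or 0/1).  When `NULL`, the
#'   placeholder default manifest is returned.
#' @return A data frame with columns `item_id` (character), `subscale`
#'   (factor with levels PWB, SWB, EWB, FWB, BCS) and `negatively_worded`
#'   (logical), one row per item, 37 rows in total.
#' @examples
#' m <- fact_b_manifest()
#' table(m$subscale)
#' @export
fact_b_manifest <- function(path = NULL) {
  if (is.null(path)) {
    man <- data.frame(
      item_id = unlist(lapply(names(.SUBSCALES), function(s)
        paste0(s, seq_len(.SUBSCALES[[s]])))),
      subscale = rep(names(.SUBSCALES), .SUBSCALES),
      negatively_worded = FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    man <- read.csv(path, stringsAsFactors = FALSE)
    required <- c("item_id", "subscale", "negatively_worded")
    missing_cols <- setdiff(required, names(man))
    if (length(missing_cols)) {
      stop("manifest is missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    man$item_id <- as.character(man$item_id)
    man$negatively_worded <- as.logical(man$negatively_worded)
  }
  validate_manifest(man)
  man$subscale <- factor(man$subscale, levels = names(.SUBSCALES))
  man
}

validate_manifest <- function(man) {
  if (anyDuplicated(man$item_id)) stop("manifest item_ids must be unique")
  if (any(is.na(man$negatively_worded))) {
    stop("manifest negatively_worded must be TRUE/FALSE (or 0/1)")
  }
  bad <- setdiff(unique(as.character(man$subscale)), names(.SUBSCALES))
  if (length(bad)) stop("unknown subscale(s) in manifest: ", paste(bad, collapse = ", "))
  counts <- table(factor(as.character(man$subscale), levels = names(.SUBSCALES)))
  if (!identical(as.integer(counts), as.integer(.SUBSCALES))) {
    stop("manifest must have exactly 7/7/6/7/10 items for PWB/SWB/EWB/FWB/BCS ",
         "(got ", paste(counts, collapse = "/"), ")")
  }
  invisible(man)
}
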