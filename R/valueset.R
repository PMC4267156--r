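#' EQ-5D-5L value sets
#'
#' A value set assigns a utility to each of the 5^5 = 3125 EQ-5D-5L health
#' states (five dimensions - mobility MO, self-care SC, usual activities UA,
#' pain/discomfort PD, anxiety/depression AD - each at levels 1..5).  Full
#' health `11111` maps to exactly 1; the floor `u_min` is value-set specific
#' (-0.111 for the Japanese crosswalk set, -0.594 for the UK one).
#'
#' The actual crosswalk tables are licensed external artifacts and are not
#' bundled.  [read_value_set()] loads a user-supplied CSV; [stub_value_set()]
#' generates a clearly-labelled *synthetic* stand-in with a configurable
#' floor, monotone in every dimension, for tests and examples only.
#'
#' @name value_sets
NULL

new_value_set <- function(table, name, smallest_increment = NULL) {
  table <- table[order(state_index(table)), , drop = FALSE]
  rownames(table) <- NULL
  u <- table$utility
  if (nrow(table) != 3125L) stop("value set must have 3125 rows, got ", nrow(table))
  if (abs(u[1L] - 1) > 1e-12) stop("full health state 11111 must map to exactly 1")
  if (any(u > 1 + 1e-12)) stop("value-set utilities must not exceed 1")
  if (is.null(smallest_increment)) {
    su <- sort(unique(u))
    smallest_increment <- min(diff(su))
  }
  structure(
    list(name = name, table = table, u_min = min(u), u_max = 1,
         smallest_increment = smallest_increment),
    class = "eq5d_value_set"
  )
}

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat("EQ-5D-5L value set:", x$name, "\n")
  cat(sprintf("  3125 states, utilities in [%.4g, 1], smallest increment %.4g\n",
              x$u_min, x$smallest_increment))
  invisible(x)
}

state_index <- function(states) {
  dims <- c("MO", "SC", "UA", "PD", "AD")
  missing_cols <- setdiff(dims, names(states))
  if (length(missing_cols)) {
    stop("EQ-5D-5L state table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lv <- as.matrix(states[, dims, drop = FALSE])
  if (any(is.na(lv)) || any(lv < 1 | lv > 5) || any(lv != round(lv))) {
    stop("EQ-5D-5L levels must be integers in 1..5")
  }
  as.integer((lv[, 1] - 1) * 625 + (lv[, 2] - 1) * 125 +
             (lv[, 3] - 1) * 25 + (lv[, 4] - 1) * 5 + lv[, 5])
}

all_states <- function() {
  g <- expand.grid(AD = 1:5, PD = 1:5, UA = 1:5, SC = 1:5, MO = 1:5)
  g[, c("MO", "SC", "UA", "PD", "AD")]
}

#' Generate a synthetic stub value set
#'
#' Builds an additive-decrement value set: utility = 1 - sum of per-dimension
#' decrements, with dimension weights in realistic proportions and level
#' severities rising from 0 (level 1) to 1 (level 5), rescaled so the worst
#' state `55555` sits exactly at `floor`.  This is a synthetic stand-in for
#' the licensed crosswalk tables: it reproduces their range and monotone
#' structure, not their actual values.
#'
#' @param floor Utility of the worst state (default -0.111, the Japanese
#'   crosswalk range; use -0.594 for the UK range).
#' @param name Label stored on the value set.
#' @return An `eq5d_value_set` object.
#' @examples
#' vs <- stub_value_set()
#' utility_of(data.frame(MO = 1, SC = 1, UA = 1, PD = 1, AD = 1), vs)  # exactly 1
#' @export
stub_value_set <- function(floor = -0.111, name = sprintf("synthetic-stub(%g)", floor)) {
  if (floor >= 1) stop("floor must be below 1")
  weights <- c(MO = 0.23, SC = 0.19, UA = 0.16, PD = 0.24, AD = 0.18) * (1 - floor)
  severity <- c(0, 0.12, 0.32, 0.62, 1)  # level 1..5
  states <- all_states()
  dec <- vapply(names(weights), function(d) weights[[d]] * severity[states[[d]]],
                numeric(nrow(states)))
  states$utility <- 1 - rowSums(dec)
  new_value_set(states, name = name)
}

#' Read a value-set CSV
#'
#' Two schemas are accepted: a full table with columns `MO,SC,UA,PD,AD,utility`
#' (3125 rows), or an additive-decrement schema with columns
#' `dimension,level,decrement` (25 rows; level-1 decrements must be 0), which
#' is expanded to the full table on load.
#'
#' @param path Path to the CSV file.
#' @param name Label stored on the value set (defaults to the file name).
#' @return An `eq5d_value_set` object.
#' @export
read_value_set <- function(path, name = basename(path)) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  if (all(c("MO", "SC", "UA", "PD", "AD", "utility") %in% names(dat))) {
    return(new_value_set(dat[, c("MO", "SC", "UA", "PD", "AD", "utility")], name))
  }
  if (all(c("dimension", "level", "decrement") %in% names(dat))) {
    dims <- c("MO", "SC", "UA", "PD", "AD")
    if (!setequal(unique(dat$dimension), dims)) {
      stop("decrement schema must cover dimensions ", paste(dims, collapse = ", "))
    }
    dec_of <- function(d, lv) {
      rows <- dat[dat$dimension == d, ]
      rows <- rows[match(lv, rows$level), ]
      if (any(is.na(rows$decrement))) stop("decrement table misses levels for ", d)
      rows$decrement
    }
    lvl1 <- dat$decrement[dat$level == 1]
    if (any(abs(lvl1) > 1e-12)) stop("level-1 decrements must be 0")
    states <- all_states()
    dec <- vapply(dims, function(d) dec_of(d, states[[d]]), numeric(nrow(states)))
    states$utility <- 1 - rowSums(dec)
    return(new_value_set(states, name))
  }
  stop("unrecognized value-set schema: need MO,SC,UA,PD,AD,utility or ",
       "dimension,level,decrement columns")
}

#' Compute utility indices for EQ-5D-5L states
#'
#' Pure table lookup: the same state always yields the same utility; full
#' health `11111` yields exactly 1.
#'
#' @param states Data frame with columns `MO`, `SC`, `UA`, `PD`, `AD`
#'   (integer levels 1..5), one row per respondent.
#' @param value_set An `eq5d_value_set` object.
#' @return Numeric vector of utilities.
#' @export
utility_of <- function(states, value_set) {
  stopifnot(inherits(value_set, "eq5d_value_set"))
  idx <- state_index(states)
  value_set$table$utility[idx]
}

#' Read EQ-5D-5L responses from CSV
#'
#' @param path CSV with columns `MO,SC,UA,PD,AD` (levels 1-5); extra columns
#'   are carried through.
#' @return A data frame.
#' @export
read_eq5d_csv <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  state_index(dat)  # validates
  dat
}
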