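#' Linear transform of a raw Likert scale response to the 0-100 score scale
#'
#' EPIC multi-item scale scores are reported on a 0-100 scale obtained by a
#' linear (affine) transform of the raw response range, with higher scores
#' representing better health-related quality of life. This helper performs
#' that transform for a single item or an already-aggregated raw scale score.
#'
#' @param raw Numeric vector of raw responses.
#' @param min_raw Lower end of the declared raw range (maps to 0).
#' @param max_raw Upper end of the declared raw range (maps to 100).
#' @return Numeric vector of scores in \[0, 100\].
#' @examples
#' likert_to_0_100(2, 0, 4) # 50
#' @export
likert_to_0_100 <- function(raw, min_raw, max_raw) {
  if (!is.numeric(raw) || !is.numeric(min_raw) || !is.numeric(max_raw)) {
    stop("'raw', 'min_raw' and 'max_raw' must be numeric", call. = FALSE)
  }
  if (min_raw >= max_raw) {
    stop("'min_raw' must be strictly less than 'max_raw'", call. = FALSE)
  }
  bad <- which(!is.na(raw) & (raw < min_raw | raw > max_raw))
  if (length(bad)) {
    stop(sprintf(
      "raw response %s outside declared range [%s, %s]",
      format(raw[bad[1L]]), format(min_raw), format(max_raw)
    ), call. = FALSE)
  }
  100 * (raw - min_raw) / (max_raw - min_raw)
}

eq5d_dimensions <- c(
  "mobility", "self_care", "usual_activities",
  "pain_discomfort", "anxiety_depression"
)

#' Construct EQ-5D-3L descriptive states
#'
#' The EQ-5D-3L descriptive system records five dimensions (mobility,
#' self-care, usual activities, pain/discomfort, anxiety/depression), each at
#' one of three severity levels, giving 3^5 = 243 distinct health states.
#'
#' @param mobility,self_care,usual_activities,pain_discomfort,anxiety_depression
#'   Integer vectors of severity levels, each in \{1, 2, 3\}.
#' @return A data frame of class `eq5d_state` with one row per state and the
#'   five dimension columns, plus a `state` column holding the conventional
#'   five-digit code (e.g. "21111").
#' @examples
#' eq5d_state(1, 1, 1, 1, 1)   # full health
#' nrow(eq5d_all_states())     # 243
#' @export
eq5d_state <- function(mobility, self_care, usual_activities,
                       pain_discomfort, anxiety_depression) {
  df <- data.frame(
    mobility = as.integer(mobility),
    self_care = as.integer(self_care),
    usual_activities = as.integer(usual_activities),
    pain_discomfort = as.integer(pain_discomfort),
    anxiety_depression = as.integer(anxiety_depression)
  )
  for (d in eq5d_dimensions) {
    v <- df[[d]]
    if (anyNA(v)) {
      stop(sprintf("dimension '%s' has a missing level; states with a missing dimension cannot be scored", d),
           call. = FALSE)
    }
    if (any(v < 1L | v > 3L)) {
      stop(sprintf("dimension '%s' has a level outside {1, 2, 3}", d), call. = FALSE)
    }
  }
  df$state <- do.call(paste0, df[eq5d_dimensions])
  class(df) <- c("eq5d_state", "data.frame")
  df
}

#' @rdname eq5d_state
#' @export
eq5d_all_states <- function() {
  g <- expand.grid(
    anxiety_depression = 1:3, pain_discomfort = 1:3,
    usual_activities = 1:3, self_care = 1:3, mobility = 1:3
  )
  eq5d_state(g$mobility, g$self_care, g$usual_activities,
             g$pain_discomfort, g$anxiety_depression)
}

# Derived regressors that published 3L valuation models use beyond the ten
# per-dimension level decrements. All are functions of the level vector only.
value_set_extra_terms <- c("any", "n3", "c2", "c3", "d1", "i2", "i2sq", "i3", "i3sq")

extra_term_value <- function(name, levels_mat) {
  c2 <- rowSums(levels_mat == 2L)
  c3 <- rowSums(levels_mat == 3L)
  moved <- c2 + c3
  switch(name,
    any  = as.numeric(moved > 0),           # indicator: any deviation from full health
    n3   = as.numeric(c3 > 0),              # indicator: any dimension at level 3
    c2   = c2,                              # count of dimensions at level 2
    c3   = c3,                              # count of dimensions at level 3
    d1   = pmax(moved - 1, 0),              # deviations beyond the first
    i2   = pmax(c2 - 1, 0),                 # level-2 dimensions beyond the first
    i2sq = pmax(c2 - 1, 0)^2,
    i3   = pmax(c3 - 1, 0),                 # level-3 dimensions beyond the first
    i3sq = pmax(c3 - 1, 0)^2,
    stop(sprintf("unknown extra term '%s' (supported: %s)", name,
                 paste(value_set_extra_terms, collapse = ", ")), call. = FALSE)
  )
}

#' Construct an EQ-5D-3L value set (tariff)
#'
#' A value set converts an EQ-5D-3L descriptive state into a utility by the
#' additive rule `1 + sum(level decrements) + sum(extra-term contributions)`.
#' Level-1 responses contribute nothing by convention, so the full-health
#' state (1,1,1,1,1) always scores exactly 1. Decrements are stored as signed
#' deltas (negative for disutility). Extra terms are named derived regressors
#' of the level vector (see Details) with a signed coefficient each, covering
#' the interaction structures used by published 3L valuation models (e.g. the
#' UK "N3" term or the US "D1"/"I2 squared"/"I3" terms).
#'
#' @details Supported extra-term names: `any` (indicator of any deviation from
#'   full health), `n3` (any dimension at level 3), `c2`/`c3` (counts of
#'   dimensions at level 2/3), `d1` (deviations beyond the first), `i2`/`i3`
#'   (level-2/level-3 dimensions beyond the first) and their squares
#'   `i2sq`/`i3sq`.
#'
#' @param name Character label for the value set.
#' @param decrements Named list with one entry per dimension
#'   (`mobility`, ..., `anxiety_depression`), each a numeric vector with
#'   elements `"2"` and `"3"` giving the level-2 and level-3 utility deltas.
#' @param extra_terms Named numeric vector of extra-term coefficients
#'   (possibly empty).
#' @return An object of class `eq5d_value_set`.
#' @seealso [read_value_set()] to load one from a JSON config,
#'   [score_eq5d()] to apply it.
#' @export
eq5d_value_set <- function(name, decrements, extra_terms = numeric(0)) {
  if (!is.character(name) || length(name) != 1L) {
    stop("'name' must be a single character string", call. = FALSE)
  }
  missing_dims <- setdiff(eq5d_dimensions, names(decrements))
  if (length(missing_dims)) {
    stop(sprintf("value set '%s' is missing decrements for: %s",
                 name, paste(missing_dims, collapse = ", ")), call. = FALSE)
  }
  dec <- matrix(0, nrow = 5L, ncol = 3L,
                dimnames = list(eq5d_dimensions, c("1", "2", "3")))
  for (d in eq5d_dimensions) {
    entry <- unlist(decrements[[d]])
    for (lev in c("2", "3")) {
      if (!lev %in% names(entry) || is.na(entry[[lev]])) {
        stop(sprintf("value set '%s': dimension '%s' lacks a level-%s decrement",
                     name, d, lev), call. = FALSE)
      }
      dec[d, lev] <- as.numeric(entry[[lev]])
    }
  }
  extra <- unlist(extra_terms)
  if (length(extra)) {
    unknown <- setdiff(names(extra), value_set_extra_terms)
    if (length(unknown)) {
      stop(sprintf("value set '%s': unknown extra terms: %s",
                   name, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(
    list(name = name, decrements = dec, extra_terms = extra),
    class = "eq5d_value_set"
  )
}

#' @exportS3Method base::print
print.eq5d_value_set <- function(x, ...) {
  cat("EQ-5D-3L value set:", x$name, "\n")
  cat("Level decrements (utility deltas):\n")
  print(round(x$decrements[, c("2", "3"), drop = FALSE], 4))
  if (length(x$extra_terms)) {
    cat("Extra terms:\n")
    print(round(x$extra_terms, 4))
  }
  invisible(x)
}

#' Load a value set from a JSON configuration file
#'
#' The file must hold an object with fields `name`, `decrements` (five
#' dimension blocks, each with `"2"` and `"3"` entries) and optionally
#' `extra_terms`. The schema is validated on load; a malformed file raises a
#' configuration error naming the missing piece.
#'
#' @param path Path to the JSON file.
#' @return An `eq5d_value_set`.
#' @examples
#' vs <- read_value_set(system.file("extdata", "value_set_us3l.json",
#'                                  package = "epicmapr"))
#' score_eq5d(eq5d_state(1, 1, 1, 1, 1), vs) # exactly 1
#' @export
read_value_set <- function(path) {
  if (!file.exists(path)) stop(sprintf("value-set file not found: %s", path), call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (field in c("name", "decrements")) {
    if (is.null(cfg[[field]])) {
      stop(sprintf("value-set file %s lacks required field '%s'", path, field),
           call. = FALSE)
    }
  }
  eq5d_value_set(cfg$name, cfg$decrements,
                 extra_terms = unlist(cfg$extra_terms))
}

#' The packaged US EQ-5D-3L value set
#'
#' Convenience loader for the US societal 3L tariff shipped with the package
#' (transcribed at the published rounded precision from the US valuation
#' study; see the packaged JSON file for the numbers).
#'
#' @return An `eq5d_value_set`.
#' @export
us_value_set <- function() {
  read_value_set(system.file("extdata", "value_set_us3l.json",
                             package = "epicmapr", mustWork = TRUE))
}

#' Score EQ-5D-3L states to utilities
#'
#' Applies the additive tariff rule
#' `utility = 1 + sum(level decrements) + sum(extra-term contributions)`.
#' Scoring is deterministic and the full-health state scores exactly 1 under
#' every well-formed value set. Utilities below 0 are permitted (states worse
#' than dead); the only hard bound a tariff imposes is at 1.
#'
#' @param state An `eq5d_state` data frame (one or more rows), or anything
#'   coercible via [eq5d_state()] column names.
#' @param value_set An `eq5d_value_set`.
#' @return Numeric vector of utilities, one per state.
#' @export
score_eq5d <- function(state, value_set) {
  if (!inherits(value_set, "eq5d_value_set")) {
    stop("'value_set' must be an eq5d_value_set", call. = FALSE)
  }
  if (!inherits(state, "eq5d_state")) {
    if (is.data.frame(state) && all(eq5d_dimensions %in% names(state))) {
      state <- eq5d_state(state$mobility, state$self_care, state$usual_activities,
                          state$pain_discomfort, state$anxiety_depression)
    } else {
      stop("'state' must be an eq5d_state or a data frame with the five dimension columns",
           call. = FALSE)
    }
  }
  lev <- as.matrix(state[eq5d_dimensions])
  u <- rep(1, nrow(lev))
  for (i in seq_along(eq5d_dimensions)) {
    d <- eq5d_dimensions[i]
    u <- u + unname(value_set$decrements[d, lev[, i]])
  }
  for (term in names(value_set$extra_terms)) {
    u <- u + value_set$extra_terms[[term]] * extra_term_value(term, lev)
  }
  u
}

# ---- record validation -----------------------------------------------------

epic_domain_cols <- c("epic_urinary", "epic_bowel", "epic_sexual", "epic_hormonal")
epic_subdomain_cols <- c(
  "epic_uf", "epic_ub", "epic_uirr", "epic_uinc",
  "epic_bf", "epic_bb", "epic_sf", "epic_sb", "epic_hf", "epic_hb"
)
covariate_cols <- c("age", "race_other", "zubrod", "psa_ge4")

#' Validate patient records against field invariants
#'
#' Checks every present field of one or more patient records: EPIC scores must
#' lie in \[0, 100\], age must be positive, and the indicator covariates
#' (`race_other`, `zubrod`, `psa_ge4`) must be exactly 0 or 1. Violations are
#' returned, not thrown, so a whole table can be screened in one pass.
#'
#' @param records Data frame of patient records using the standard column
#'   names (`epic_urinary`, ..., `epic_hb`, `age`, `race_other`, `zubrod`,
#'   `psa_ge4`, optionally `eq5d`). Missing columns and `NA` entries are not
#'   violations; they affect complete-case status instead
#'   (see [complete_cases()]).
#' @return Data frame with columns `row`, `field`, `value`, `problem`; zero
#'   rows when every present field is valid.
#' @export
validate_record <- function(records) {
  records <- as.data.frame(records)
  out <- list()
  add <- function(rows, field, values, problem) {
    if (length(rows)) {
      out[[length(out) + 1L]] <<- data.frame(
        row = rows, field = field, value = values, problem = problem
      )
    }
  }
  for (col in intersect(c(epic_domain_cols, epic_subdomain_cols), names(records))) {
    v <- records[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    add(bad, col, v[bad], "score outside [0, 100]")
  }
  if ("age" %in% names(records)) {
    v <- records$age
    bad <- which(!is.na(v) & v <= 0)
    add(bad, "age", v[bad], "age must be positive")
  }
  for (col in intersect(c("race_other", "zubrod", "psa_ge4"), names(records))) {
    v <- records[[col]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    add(bad, col, v[bad], "indicator must be exactly 0 or 1")
  }
  if ("eq5d" %in% names(records)) {
    v <- records$eq5d
    bad <- which(!is.na(v) & v > 1)
    add(bad, "eq5d", v[bad], "utility cannot exceed 1")
  }
  if (!length(out)) {
    return(data.frame(row = integer(0), field = character(0),
                      value = numeric(0), problem = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$row), , drop = FALSE]
}

#' Complete-case status per model specification group
#'
#' Model groups differ in which fields they require: odd groups (1, 3, 5) use
#' the four EPIC domain scores, even groups (2, 4, 6) the ten sub-domain
#' scores; groups 3-6 additionally require age and race, and groups 5-6
#' require Zubrod performance status and the PSA category. A record is a
#' complete case for a group when every required field is present and
#' non-missing (and, when `require_utility`, the observed `eq5d` utility too —
#' the inclusion rule for estimation runs).
#'
#' @param records Data frame of patient records (standard column names).
#' @param group Integer 1-6.
#' @param require_utility Require a non-missing `eq5d` column as well?
#' @return Logical vector, one element per record.
#' @export
complete_cases <- function(records, group, require_utility = FALSE) {
  stopifnot(group %in% 1:6)
  records <- as.data.frame(records)
  needed <- if (group %% 2L == 1L) epic_domain_cols else epic_subdomain_cols
  if (group >= 3L) needed <- c(needed, "age", "race_other")
  if (group >= 5L) needed <- c(needed, "zubrod", "psa_ge4")
  if (require_utility) needed <- c(needed, "eq5d")
  ok <- rep(TRUE, nrow(records))
  for (col in needed) {
    ok <- ok & if (col %in% names(records)) !is.na(records[[col]]) else FALSE
  }
  ok
}
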