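# Classification of ICD-10 causes into preventable / treatable avoidable
# mortality and into 14 reporting cause groups.

#' The 14 reporting cause groups
#'
#' Avoidable deaths are reported in fourteen cause groups. The labels are
#' configurable; the default set covers the major chapters of an
#' OECD/Eurostat-style avoidability list.
#'
#' @param labels character vector of exactly 14 group names. Must include
#'   cardiovascular, cerebrovascular, cancer, injuries and alcohol_drug.
#' @return character vector of class `cause_groups`.
#' @export
cause_groups <- function(labels = c(
  "infectious", "cancer", "diabetes_endocrine", "cardiovascular",
  "cerebrovascular", "other_circulatory", "respiratory", "digestive",
  "genitourinary", "maternal_perinatal", "congenital", "injuries",
  "alcohol_drug", "other_avoidable")) {
  labels <- as.character(labels)
  if (length(labels) != 14L || anyDuplicated(labels))
    stop("exactly 14 distinct cause-group labels are required")
  need <- c("cardiovascular", "cerebrovascular", "cancer", "injuries",
            "alcohol_drug")
  miss <- setdiff(need, labels)
  if (length(miss))
    stop("cause groups must include: ", paste(miss, collapse = ", "))
  structure(labels, class = "cause_groups")
}

.icd_ok <- function(code) grepl("^[A-Z][0-9]{2}[0-9]?$", code)

# numeric rank of a 3-character code for range comparisons
.icd_rank <- function(code3) {
  (utf8ToInt(substr(code3, 1, 1)) - utf8ToInt("A")) * 100 +
    as.integer(substr(code3, 2, 3))
}

#' Avoidability map
#'
#' A table of ICD-10 code patterns with age ranges, fractional allocation to
#' the preventable and treatable categories and a reporting cause group.
#' Patterns are single 3-character codes (`"K35"`), 3-character ranges
#' (`"C33-C34"`) or exact 4-character codes (`"I219"`, which shadow any
#' 3-character entry covering their prefix). Ages above `age_cutoff` are
#' never avoidable.
#'
#' @param entries data.frame with columns `icd10_pattern`, `age_min`,
#'   `age_max`, `frac_preventable`, `frac_treatable`, `cause_group`.
#' @param groups a [cause_groups()] set that every entry must map into.
#' @param age_cutoff oldest avoidable age in years (default 74).
#' @return An object of class `avoidability_map`.
#' @export
avoidability_map <- function(entries, groups = cause_groups(), age_cutoff = 74) {
  need <- c("icd10_pattern", "age_min", "age_max", "frac_preventable",
            "frac_treatable", "cause_group")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("avoidability map is missing column(s): ", paste(miss, collapse = ", "))
  entries <- entries[need]
  entries$icd10_pattern <- toupper(gsub("\\.", "", entries$icd10_pattern))
  fp <- entries$frac_preventable; ft <- entries$frac_treatable
  if (any(fp < 0 | fp > 1 | ft < 0 | ft > 1 | fp + ft > 1 + 1e-12))
    stop("category fractions must lie in [0,1] and sum to at most 1")
  if (any(entries$age_max > age_cutoff))
    stop("entry age ranges must not exceed the age cutoff of ", age_cutoff)
  if (any(!entries$cause_group %in% groups))
    stop("unknown cause group(s): ",
         paste(setdiff(entries$cause_group, groups), collapse = ", "))
  parsed <- lapply(entries$icd10_pattern, .parse_pattern)
  # overlap check: no two entries may claim the same (3-char code, age),
  # except a 4-char refinement shadowing its 3-char parent
  cover <- do.call(rbind, lapply(seq_along(parsed), function(i) {
    p <- parsed[[i]]
    if (p$nchar4) return(NULL)
    data.frame(code = p$lo:p$hi, amin = entries$age_min[i],
               amax = entries$age_max[i])
  }))
  if (!is.null(cover) && nrow(cover) > 1) {
    for (cd in unique(cover$code[duplicated(cover$code)])) {
      cc <- cover[cover$code == cd, ]
      cc <- cc[order(cc$amin), ]
      if (any(cc$amin[-1] <= cc$amax[-nrow(cc)]))
        stop("overlapping avoidability entries at code rank ", cd)
    }
  }
  four <- vapply(parsed, `[[`, TRUE, "nchar4")
  if (anyDuplicated(entries$icd10_pattern[four]))
    stop("duplicate 4-character entries")
  structure(list(entries = entries, parsed = parsed, groups = groups,
                 age_cutoff = age_cutoff),
            class = "avoidability_map")
}

.parse_pattern <- function(pat) {
  if (grepl("^[A-Z][0-9]{3}$", pat)) {
    return(list(nchar4 = TRUE, code = pat))
  }
  if (grepl("^[A-Z][0-9]{2}$", pat)) {
    r <- .icd_rank(pat)
    return(list(nchar4 = FALSE, lo = r, hi = r))
  }
  if (grepl("^[A-Z][0-9]{2}-[A-Z][0-9]{2}$", pat)) {
    lo <- .icd_rank(substr(pat, 1, 3)); hi <- .icd_rank(substr(pat, 5, 7))
    if (lo > hi) stop("descending ICD-10 range: ", pat)
    return(list(nchar4 = FALSE, lo = lo, hi = hi))
  }
  stop("malformed ICD-10 pattern: ", pat)
}

#' @export
print.avoidability_map <- function(x, ...) {
  e <- x$entries
  cat(sprintf(paste0("Avoidability map: %d entries (%d preventable-only, ",
                     "%d treatable-only, %d shared), age cutoff %d\n"),
              nrow(e), sum(e$frac_preventable == 1), sum(e$frac_treatable == 1),
              sum(e$frac_preventable > 0 & e$frac_treatable > 0), x$age_cutoff))
  invisible(x)
}

#' Read an avoidability map from CSV
#'
#' @param path CSV with the [avoidability_map()] entry columns.
#' @param groups,age_cutoff passed to [avoidability_map()].
#' @return An [avoidability_map()].
#' @export
read_avoidability_map <- function(path, groups = cause_groups(),
                                  age_cutoff = 74) {
  avoidability_map(utils::read.csv(path, stringsAsFactors = FALSE),
                   groups = groups, age_cutoff = age_cutoff)
}

#' Packaged default avoidability map
#'
#' A best-effort, editable approximation of the OECD/Eurostat avoidability
#' list (code ranges, age windows, category fractions and reporting group
#' per entry), shipped as CSV under `inst/extdata/`. It is a configuration
#' default, not a reproduction of the authoritative document; analyses that
#' must match a specific list revision should load their own CSV via
#' [read_avoidability_map()]. Causes listed as both preventable and
#' treatable carry a 50/50 split unless the CSV says otherwise.
#'
#' @return An [avoidability_map()].
#' @export
default_avoidability_map <- function() {
  read_avoidability_map(system.file("extdata", "avoidable_causes.csv",
                                    package = "avoidmort", mustWork = TRUE))
}

#' Toy avoidability map
#'
#' A small fully in-code map over eight representative ICD-10 codes, used by
#' the synthetic-data generator and the test-suite so that no external
#' document is needed.
#'
#' @return An [avoidability_map()].
#' @export
toy_avoidability_map <- function() {
  avoidability_map(data.frame(
    icd10_pattern = c("I21", "I64", "C34", "C50", "V89", "K35", "F10", "A41"),
    age_min = 0L, age_max = 74L,
    frac_preventable = c(0.5, 0.5, 1, 0, 1, 0, 1, 0),
    frac_treatable   = c(0.5, 0.5, 0, 1, 0, 1, 0, 1),
    cause_group = c("cardiovascular", "cerebrovascular", "cancer", "cancer",
                    "injuries", "digestive", "alcohol_drug", "infectious"),
    stringsAsFactors = FALSE))
}

#' Classify one cause of death at one age group
#'
#' Looks a (normalised) ICD-10 code and an age group up in an avoidability
#' map. Codes not on the list, and any age group lying entirely above the
#' age cutoff, are unavoidable: `(0, 0, NA)`. A 4-character code first tries
#' an exact 4-character entry; otherwise its 3-character prefix is matched
#' against single codes and ranges. Age groups straddling the cutoff are an
#' error (none exist on the standard grid).
#'
#' @param code ICD-10 code, 3 or 4 characters (dots tolerated).
#' @param age_group an age-group label (e.g. `"50-54"`) or numeric start age.
#' @param map an [avoidability_map()].
#' @param grid the [age_grid()] the label lives on.
#' @return list with `frac_preventable`, `frac_treatable`, `cause_group`
#'   (NA when unlisted/unavoidable).
#' @examples
#' classify_cause("C34", "50-54", toy_avoidability_map()) # preventable cancer
#' @export
classify_cause <- function(code, age_group, map, grid = who_age_grid()) {
  stopifnot(inherits(map, "avoidability_map"))
  code <- toupper(gsub("\\.", "", code))
  if (!.icd_ok(code)) stop("malformed ICD-10 code: ", code)
  i <- .age_index(age_group, grid)
  .classify1(code, grid$start[i], grid$width[i], map)
}

.classify1 <- function(code, start, width, map) {
  none <- list(frac_preventable = 0, frac_treatable = 0,
               cause_group = NA_character_)
  cutoff <- map$age_cutoff
  if (start > cutoff) return(none)
  end <- if (is.finite(width)) start + width - 1 else Inf
  if (end > cutoff)
    stop("age group ", start, "-", end, " straddles the avoidability cutoff of ",
         cutoff)
  hit <- NA_integer_
  if (nchar(code) == 4L) {
    for (j in seq_along(map$parsed)) {
      p <- map$parsed[[j]]
      if (p$nchar4 && p$code == code) { hit <- j; break }
    }
  }
  if (is.na(hit)) {
    r <- .icd_rank(substr(code, 1, 3))
    for (j in seq_along(map$parsed)) {
      p <- map$parsed[[j]]
      if (!p$nchar4 && r >= p$lo && r <= p$hi) { hit <- j; break }
    }
  }
  if (is.na(hit)) return(none)
  e <- map$entries[hit, ]
  if (start < e$age_min || end > e$age_max) return(none)
  list(frac_preventable = e$frac_preventable, frac_treatable = e$frac_treatable,
       cause_group = e$cause_group)
}

#' Split a rate surface into avoidability categories
#'
#' Reallocates the ICD-10-coded cause axis of a rate surface onto the fixed
#' axis {preventable, treatable} x 14 cause groups plus a `non_avoidable`
#' remainder. Every age group's total rate is conserved exactly; all mass at
#' ages above the cutoff goes to the remainder.
#'
#' @param surface a [rate_surface()] whose columns are ICD-10 codes (the
#'   reserved `"OTHER"` column is always unavoidable).
#' @param map an [avoidability_map()].
#' @return A [rate_surface()] with 29 category columns and attribute
#'   `split = TRUE`; attribute `axis` is a data.frame describing each
#'   column's category and cause group.
#' @export
split_avoidable <- function(surface, map) {
  stopifnot(inherits(surface, "rate_surface"), inherits(map, "avoidability_map"))
  if (isTRUE(attr(surface, "split")))
    stop("surface is already avoidability-split")
  grid <- surface$age
  grp <- as.character(map$groups)
  cols <- c(paste0("preventable.", grp), paste0("treatable.", grp),
            "non_avoidable")
  axis <- data.frame(
    column = cols,
    category = c(rep("preventable", 14), rep("treatable", 14), "none"),
    cause_group = c(grp, grp, NA_character_),
    stringsAsFactors = FALSE)
  out <- matrix(0, nrow(grid), length(cols),
                dimnames = list(grid$label, cols))
  for (code in colnames(surface$m)) {
    v <- surface$m[, code]
    if (code == OTHER_CAUSE || !.icd_ok(code)) {
      out[, "non_avoidable"] <- out[, "non_avoidable"] + v
      next
    }
    for (i in seq_len(nrow(grid))) {
      if (v[i] == 0) next
      cl <- .classify1(code, grid$start[i], grid$width[i], map)
      fp <- cl$frac_preventable; ft <- cl$frac_treatable
      if (fp > 0)
        out[i, paste0("preventable.", cl$cause_group)] <-
          out[i, paste0("preventable.", cl$cause_group)] + fp * v[i]
      if (ft > 0)
        out[i, paste0("treatable.", cl$cause_group)] <-
          out[i, paste0("treatable.", cl$cause_group)] + ft * v[i]
      out[i, "non_avoidable"] <- out[i, "non_avoidable"] + (1 - fp - ft) * v[i]
    }
  }
  res <- rate_surface(out, age = grid, country = surface$country,
                      year = surface$year, sex = surface$sex)
  attr(res, "split") <- TRUE
  attr(res, "axis") <- axis
  attr(res, "age_cutoff") <- map$age_cutoff
  res
}

# columns of a split surface belonging to the requested categories
.category_columns <- function(surface, categories) {
  if (!isTRUE(attr(surface, "split")))
    stop("surface must be avoidability-split first (see split_avoidable)")
  categories <- match.arg(categories, c("preventable", "treatable"),
                          several.ok = TRUE)
  axis <- attr(surface, "axis")
  axis$column[axis$category %in% categories]
}
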