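# Mortality count panels: WHO-MDB-dialect reader, country grouping metadata
# and conversion of counts to rate surfaces.

ALL_CAUSE <- "ALL"       # marker for all-cause rows (these carry population)
OTHER_CAUSE <- "OTHER"   # reserved label for unclassified residual deaths

.SEX_CODES <- c("1" = "male", "2" = "female",
                "male" = "male", "female" = "female",
                "m" = "male", "f" = "female")

.normalize_sex <- function(x) {
  s <- .SEX_CODES[tolower(as.character(x))]
  if (anyNA(s))
    stop("unrecognised sex code(s): ",
         paste(unique(x[is.na(s)]), collapse = ", "))
  unname(s)
}

#' Country group metadata
#'
#' Defines the two analysis blocs (new and established member states), the
#' countries excluded altogether, and countries with partial year coverage.
#'
#' @param nms,ems character vectors of country identifiers for the two blocs.
#' @param excluded countries dropped from all analyses.
#' @param partial_coverage named list/vector: country -> first valid year.
#' @return An object of class `country_groups`.
#' @seealso [eu_country_groups()] for the packaged EU grouping.
#' @export
country_groups <- function(nms, ems, excluded = character(0),
                           partial_coverage = list()) {
  nms <- as.character(nms); ems <- as.character(ems)
  if (length(intersect(nms, ems)))
    stop("a country cannot be in both blocs: ",
         paste(intersect(nms, ems), collapse = ", "))
  if (length(intersect(excluded, c(nms, ems))))
    stop("excluded countries must not appear in a bloc")
  structure(list(nms = nms, ems = ems, excluded = as.character(excluded),
                 partial_coverage = partial_coverage),
            class = "country_groups")
}

#' EU member-state grouping
#'
#' The packaged default grouping of EU member states: countries acceding in
#' 2004 or later form the new-member-state (NMS) bloc, the remainder
#' (including the United Kingdom) the established (EMS) bloc. Greece is
#' excluded because of its late ICD-10 adoption; Ireland enters from 2007.
#'
#' @return A [country_groups()] object.
#' @export
eu_country_groups <- function() {
  country_groups(
    nms = c("Bulgaria", "Croatia", "Cyprus", "Czech Republic", "Estonia",
            "Hungary", "Latvia", "Lithuania", "Malta", "Poland", "Romania",
            "Slovakia", "Slovenia"),
    ems = c("Austria", "Belgium", "Denmark", "Finland", "France", "Germany",
            "Ireland", "Italy", "Luxembourg", "Netherlands", "Portugal",
            "Spain", "Sweden", "United Kingdom"),
    excluded = "Greece",
    partial_coverage = list(Ireland = 2007L)
  )
}

#' @export
print.country_groups <- function(x, ...) {
  cat("Country groups: ", length(x$nms), " NMS, ", length(x$ems), " EMS, ",
      length(x$excluded), " excluded\n", sep = "")
  invisible(x)
}

#' Mortality count panel
#'
#' A validated long-format panel of death and population counts by country,
#' year, sex, age group and ICD-10 cause. All-cause rows use the cause
#' marker `"ALL"` and carry the population counts. Within each stratum and
#' age group, cause-specific deaths must not exceed the all-cause total
#' (the residual is treated as unclassified).
#'
#' @param records data.frame with columns `country`, `year`, `sex`,
#'   `age_start`, `cause`, `deaths` and (on all-cause rows) `population`.
#' @param age the [age_grid()] the `age_start` values live on.
#' @param validate run the consistency checks (default TRUE).
#' @return An object of class `mortality_panel`.
#' @export
mortality_panel <- function(records, age = who_age_grid(), validate = TRUE) {
  need <- c("country", "year", "sex", "age_start", "cause", "deaths")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  if (!"population" %in% names(records)) records$population <- NA_real_
  records <- records[c(need, "population")]
  records$country <- as.character(records$country)
  records$cause <- toupper(as.character(records$cause))
  if (nrow(records)) records$sex <- .normalize_sex(records$sex)
  if (validate && nrow(records)) {
    if (anyNA(records$deaths) || any(records$deaths < 0))
      stop("validation error: negative or missing death counts")
    .age_index(unique(records$age_start), age)
    pop <- records$population[records$cause == ALL_CAUSE]
    if (any(!is.na(pop) & pop < 0))
      stop("validation error: negative population counts")
    # cause closure: cause-specific deaths must sum to <= all-cause deaths
    key <- interaction(records$country, records$year, records$sex,
                       records$age_start, drop = TRUE)
    is_all <- records$cause == ALL_CAUSE
    csum <- tapply(records$deaths[!is_all], key[!is_all], sum)
    atot <- tapply(records$deaths[is_all], key[is_all], sum)
    csum <- csum[!is.na(csum)]; atot <- atot[!is.na(atot)]
    shared <- intersect(names(csum), names(atot))
    bad <- csum[shared] > atot[shared] * (1 + 1e-9) + 1e-9
    if (any(bad))
      stop("validation error: cause-specific deaths exceed all-cause deaths in ",
           sum(bad), " stratum/age cell(s)")
  }
  structure(list(records = records, age = age), class = "mortality_panel")
}

#' @export
print.mortality_panel <- function(x, ...) {
  r <- x$records
  cat(sprintf("Mortality panel: %d records, %d countries, years %s, %d causes\n",
              nrow(r), length(unique(r$country)),
              if (nrow(r)) paste0(min(r$year), "-", max(r$year)) else "-",
              length(setdiff(unique(r$cause), ALL_CAUSE))))
  invisible(x)
}

#' Number of records in a panel
#' @param panel a [mortality_panel()].
#' @return integer count.
#' @export
panel_size <- function(panel) nrow(panel$records)

#' Strata present in a panel
#' @param panel a [mortality_panel()].
#' @return data.frame with columns country, year, sex (unique, sorted).
#' @export
panel_strata <- function(panel) {
  r <- unique(panel$records[c("country", "year", "sex")])
  r <- r[order(r$country, r$year, r$sex), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Country-group metadata attached to a panel
#' @param panel a [mortality_panel()].
#' @return a [country_groups()] object or NULL.
#' @export
panel_groups <- function(panel) attr(panel, "groups")

#' Drop excluded countries and out-of-coverage years
#'
#' Removes records for excluded countries and for country-years before a
#' country's first valid year. Idempotent. The number of dropped records is
#' reported via `message()`.
#'
#' @param panel a [mortality_panel()].
#' @param groups a [country_groups()].
#' @return the filtered panel.
#' @export
filter_panel <- function(panel, groups) {
  stopifnot(inherits(panel, "mortality_panel"), inherits(groups, "country_groups"))
  r <- panel$records
  drop <- r$country %in% groups$excluded
  for (cc in names(groups$partial_coverage)) {
    drop <- drop | (r$country == cc & r$year < groups$partial_coverage[[cc]])
  }
  message("filter_panel: dropped ", sum(drop), " record(s)")
  out <- mortality_panel(r[!drop, , drop = FALSE], age = panel$age,
                         validate = FALSE)
  attr(out, "groups") <- attr(panel, "groups")
  out
}

#' WHO-MDB dialect description
#'
#' Describes how a delimited WHO Mortality Database style file maps onto the
#' canonical panel: layout (`"long"` = one row per age group, `"wide"` = one
#' column per age bin), column-name mapping and, for wide files, the age-bin
#' column labels in grid order.
#'
#' @param layout `"long"` or `"wide"`.
#' @param columns named character vector mapping canonical names (`country`,
#'   `year`, `sex`, `cause`, and for long files `age_start`, `deaths`,
#'   `population`) to file column names.
#' @param age_cols for wide files: character vector of age-bin column names,
#'   one per grid group, in grid order.
#' @param sep field separator (default ",").
#' @return A `who_dialect` list.
#' @export
who_dialect <- function(layout = c("long", "wide"), columns = NULL,
                        age_cols = NULL, sep = ",") {
  layout <- match.arg(layout)
  defaults <- c(country = "country", year = "year", sex = "sex",
                cause = "cause", age_start = "age_start",
                deaths = "deaths", population = "population")
  if (!is.null(columns)) defaults[names(columns)] <- columns
  if (layout == "wide" && is.null(age_cols))
    age_cols <- c("d0", "d1_4", paste0("d", seq(5, 80, 5), "_", seq(9, 84, 5)),
                  "d85p")
  structure(list(layout = layout, columns = defaults, age_cols = age_cols,
                 sep = sep), class = "who_dialect")
}

#' Read a dialect description from YAML
#'
#' @param path YAML file with keys `layout`, `columns`, `age_cols`, `sep`.
#' @return A [who_dialect()].
#' @export
dialect_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  who_dialect(layout = y$layout %||% "long",
              columns = unlist(y$columns),
              age_cols = unlist(y$age_cols),
              sep = y$sep %||% ",")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_delim <- function(path, sep) {
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("format error in '", path, "': missing column(s): ",
         paste(miss, collapse = ", "))
}

#' Read a WHO-MDB style count file into a panel
#'
#' Reads delimited death counts (and, for wide layouts, a companion
#' population file) and returns a validated [mortality_panel()]. When
#' `groups` is supplied, records for excluded countries and out-of-coverage
#' years are dropped with a logged count.
#'
#' @param path deaths file.
#' @param dialect a [who_dialect()] (default: canonical long layout).
#' @param pop_path population file, required for wide layouts (columns as
#'   the deaths file minus `cause`).
#' @param age target [age_grid()].
#' @param groups optional [country_groups()] used to filter on read.
#' @return A [mortality_panel()].
#' @export
read_who_mdb <- function(path, dialect = who_dialect("long"), pop_path = NULL,
                         age = who_age_grid(), groups = NULL) {
  stopifnot(inherits(dialect, "who_dialect"))
  cmap <- dialect$columns
  df <- .read_delim(path, dialect$sep)
  if (dialect$layout == "long") {
    need <- cmap[c("country", "year", "sex", "age_start", "cause", "deaths")]
    .require_columns(df, need, path)
    rec <- data.frame(country = df[[cmap["country"]]],
                      year = df[[cmap["year"]]],
                      sex = df[[cmap["sex"]]],
                      age_start = df[[cmap["age_start"]]],
                      cause = df[[cmap["cause"]]],
                      deaths = df[[cmap["deaths"]]],
                      stringsAsFactors = FALSE)
    rec$population <- if (cmap["population"] %in% names(df))
      df[[cmap["population"]]] else NA_real_
  } else {
    need <- cmap[c("country", "year", "sex", "cause")]
    .require_columns(df, need, path)
    .require_columns(df, dialect$age_cols, path)
    if (length(dialect$age_cols) != nrow(age))
      stop("format error: ", length(dialect$age_cols),
           " age-bin columns cannot be mapped onto a ", nrow(age),
           "-group age grid")
    rec <- .melt_wide(df, cmap, dialect$age_cols, age, value = "deaths")
    rec$population <- NA_real_
    if (!is.null(pop_path)) {
      pf <- .read_delim(pop_path, dialect$sep)
      .require_columns(pf, cmap[c("country", "year", "sex")], pop_path)
      .require_columns(pf, dialect$age_cols, pop_path)
      pop <- .melt_wide(pf, cmap, dialect$age_cols, age, value = "population",
                        with_cause = FALSE)
      key <- function(d) paste(d$country, d$year, d$sex, d$age_start, sep = "\r")
      idx <- match(key(rec), key(pop))
      rec$population <- ifelse(rec$cause == ALL_CAUSE, pop$population[idx],
                               NA_real_)
    }
  }
  if (nrow(rec) && (anyNA(rec$deaths) || any(rec$deaths < 0)))
    stop("validation error: negative or missing death counts in '", path, "'")
  panel <- mortality_panel(rec, age = age)
  if (!is.null(groups)) panel <- filter_panel(panel, groups)
  panel
}

.melt_wide <- function(df, cmap, age_cols, age, value, with_cause = TRUE) {
  k <- length(age_cols)
  n <- nrow(df)
  rec <- data.frame(
    country = rep(df[[cmap["country"]]], each = k),
    year = rep(df[[cmap["year"]]], each = k),
    sex = rep(df[[cmap["sex"]]], each = k),
    age_start = rep(age$start, times = n),
    stringsAsFactors = FALSE)
  rec$cause <- if (with_cause) rep(df[[cmap["cause"]]], each = k) else ALL_CAUSE
  vals <- as.matrix(df[age_cols])
  rec[[value]] <- as.vector(t(vals))
  rec
}

#' Write a panel as canonical long CSV
#'
#' Columns: country, year, sex, age_start, cause, deaths, population.
#' Re-reading the file with the default dialect yields an identical panel.
#'
#' @param panel a [mortality_panel()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "mortality_panel"))
  utils::write.csv(panel$records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Age-by-cause rate surface
#'
#' The working currency of the pipeline: a matrix of death rates (deaths per
#' person-year) for one (country, year, sex) stratum, rows = age groups,
#' columns = causes (ICD-10 codes, or avoidability categories after
#' [split_avoidable()]). The all-cause rate of an age group is the row sum;
#' a residual column keeps the cause axis closed.
#'
#' @param m_cause numeric matrix (age groups x causes) with column names.
#' @param age an [age_grid()] with `nrow(m_cause)` groups.
#' @param country,year,sex stratum identifiers.
#' @return An object of class `rate_surface`.
#' @export
rate_surface <- function(m_cause, age = who_age_grid(), country = NA_character_,
                         year = NA_integer_, sex = "female") {
  stopifnot(is.matrix(m_cause), !is.null(colnames(m_cause)),
            inherits(age, "age_grid"), nrow(m_cause) == nrow(age))
  if (anyNA(m_cause) || any(m_cause < 0))
    stop("rates must be non-negative and finite")
  structure(list(m = m_cause, age = age,
                 country = as.character(country), year = year,
                 sex = .normalize_sex(sex)),
            class = "rate_surface")
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf("Rate surface %s/%s/%s: %d age groups x %d causes%s\n",
              x$country, x$year, x$sex, nrow(x$m), ncol(x$m),
              if (isTRUE(attr(x, "split"))) " (avoidability-split)" else ""))
  invisible(x)
}

#' All-cause rates of a surface
#' @param surface a [rate_surface()].
#' @return numeric vector, one rate per age group.
#' @export
rate_all <- function(surface) {
  stopifnot(inherits(surface, "rate_surface"))
  rowSums(surface$m)
}

#' Cause-specific rate matrix of a surface
#' @param surface a [rate_surface()].
#' @return numeric matrix (age x cause).
#' @export
rate_matrix <- function(surface) {
  stopifnot(inherits(surface, "rate_surface"))
  surface$m
}

#' Build a rate surface from a panel stratum
#'
#' Divides death counts by population person-years for one
#' (country, year, sex) stratum. Deaths not assigned to any listed cause
#' (the all-cause total minus the sum over causes) are placed in the
#' reserved `"OTHER"` column so that cause-specific rates sum exactly to the
#' all-cause rate in every age group.
#'
#' @param panel a [mortality_panel()].
#' @param country,year,sex the stratum.
#' @return A [rate_surface()].
#' @export
build_rates <- function(panel, country, year, sex) {
  stopifnot(inherits(panel, "mortality_panel"))
  sex <- .normalize_sex(sex)
  r <- panel$records
  r <- r[r$country == country & r$year == year & r$sex == sex, , drop = FALSE]
  if (!nrow(r))
    stop("stratum not found in panel: ", country, "/", year, "/", sex)
  age <- panel$age
  k <- nrow(age)
  all_rows <- r[r$cause == ALL_CAUSE, , drop = FALSE]
  i <- .age_index(all_rows$age_start, age)
  pop <- rep(NA_real_, k); pop[i] <- all_rows$population
  all_d <- rep(0, k); all_d[i] <- all_rows$deaths
  bad <- is.na(pop) | pop <= 0
  if (any(bad))
    stop("zero or missing population in age group(s): ",
         paste(age$label[bad], collapse = ", "))
  causes <- sort(setdiff(unique(r$cause), ALL_CAUSE))
  m <- matrix(0, k, length(causes) + 1L,
              dimnames = list(age$label, c(causes, OTHER_CAUSE)))
  for (cz in causes) {
    rows <- r[r$cause == cz, , drop = FALSE]
    j <- .age_index(rows$age_start, age)
    m[j, cz] <- rows$deaths / pop[j]
  }
  resid <- all_d / pop - rowSums(m)
  if (any(resid < -1e-9 * pmax(all_d / pop, 1e-12)))
    stop("cause-specific deaths exceed the all-cause total for stratum ",
         country, "/", year, "/", sex)
  m[, OTHER_CAUSE] <- pmax(resid, 0)
  rate_surface(m, age = age, country = country, year = year, sex = sex)
}
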