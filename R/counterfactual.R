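# Counterfactual scenarios: deletion of avoidable mortality and
# substitution of one bloc's avoidable rates by the other bloc's average.

#' Scenario specification
#'
#' The three scenario kinds are `status_quo` (rates pass through
#' unchanged), `delete` (the selected avoidability categories are removed
#' from every country) and `substitute` (the selected categories in NMS
#' countries are set to the EMS average). With both categories selected,
#' delete/substitute act on all avoidable mortality.
#'
#' @param kind `"status_quo"`, `"delete"` or `"substitute"`.
#' @param categories subset of `c("preventable", "treatable")`; both =
#'   avoidable. Ignored for `status_quo`.
#' @return An object of class `scenario_spec` with a canonical `name`.
#' @seealso [table2_scenarios()] for the seven standard scenarios.
#' @export
scenario_spec <- function(kind = c("status_quo", "delete", "substitute"),
                          categories = c("preventable", "treatable")) {
  kind <- match.arg(kind)
  categories <- if (kind == "status_quo") character(0) else
    match.arg(categories, several.ok = TRUE)
  name <- if (kind == "status_quo") "status_quo" else
    paste0(kind, "_", if (length(categories) == 2L) "avoidable" else categories)
  structure(list(kind = kind, categories = categories, name = name),
            class = "scenario_spec")
}

#' The seven standard scenarios
#'
#' Status quo, substitution of avoidable / preventable-only /
#' treatable-only rates, and deletion of avoidable / preventable-only /
#' treatable-only mortality — one per row of the standard results table.
#'
#' @return Named list of [scenario_spec()] objects in presentation order.
#' @export
table2_scenarios <- function() {
  specs <- list(
    scenario_spec("status_quo"),
    scenario_spec("substitute", c("preventable", "treatable")),
    scenario_spec("substitute", "preventable"),
    scenario_spec("substitute", "treatable"),
    scenario_spec("delete", c("preventable", "treatable")),
    scenario_spec("delete", "preventable"),
    scenario_spec("delete", "treatable"))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Delete avoidability categories from a split surface
#'
#' Sets the rates of the selected categories to zero; the all-cause rate of
#' each age group drops by the deleted mass (rate subtraction under cause
#' independence). Only ages below the avoidability cutoff carry avoidable
#' mass, so older ages are untouched.
#'
#' @param surface an avoidability-split [rate_surface()]
#'   (see [split_avoidable()]).
#' @param categories subset of `c("preventable", "treatable")`.
#' @return The cause-deleted [rate_surface()].
#' @export
delete_causes <- function(surface, categories = c("preventable", "treatable")) {
  cols <- .category_columns(surface, categories)
  out <- surface
  out$m[, cols] <- 0
  out
}

#' Average reference rates across countries
#'
#' Unweighted arithmetic mean of the age- and category-specific rates over a
#' set of aligned surfaces (each country one vote); with
#' `weights = "population"`, a weighted mean using the supplied per-country
#' weights instead.
#'
#' @param surfaces non-empty list of aligned [rate_surface()] objects
#'   (same grid and cause axis, one year/sex).
#' @param weights `"equal"` (default) or `"population"`.
#' @param population numeric vector of country weights, required for
#'   population weighting.
#' @return A [rate_surface()] holding the mean rates.
#' @export
reference_rates <- function(surfaces, weights = c("equal", "population"),
                            population = NULL) {
  weights <- match.arg(weights)
  if (!length(surfaces)) stop("no surfaces to average")
  stopifnot(all(vapply(surfaces, inherits, TRUE, "rate_surface")))
  m1 <- surfaces[[1]]$m
  for (s in surfaces[-1]) {
    if (!identical(dim(s$m), dim(m1)) ||
        !identical(colnames(s$m), colnames(m1)))
      stop("surfaces are not aligned on the same age x cause grid")
  }
  w <- if (weights == "equal") rep(1, length(surfaces)) else {
    if (is.null(population) || length(population) != length(surfaces))
      stop("population weights required, one per surface")
    population
  }
  w <- w / sum(w)
  m <- Reduce(`+`, Map(function(s, wi) wi * s$m, surfaces, w))
  out <- surfaces[[1]]
  out$m <- m
  out$country <- "reference"
  out
}

#' Substitute reference rates into a surface
#'
#' Sets the selected avoidability categories of `surface` equal to the
#' corresponding rates of `reference` (two-sided matching by default; with
#' `one_sided = TRUE` a cell is only ever lowered, never raised). All other
#' cells, including everything above the avoidability cutoff, are unchanged.
#'
#' @param surface,reference aligned avoidability-split [rate_surface()]s.
#' @param categories subset of `c("preventable", "treatable")`; an empty
#'   selection is the identity.
#' @param one_sided restrict to one-sided reduction (default FALSE).
#' @return The substituted [rate_surface()].
#' @export
substitute_rates <- function(surface, reference,
                             categories = c("preventable", "treatable"),
                             one_sided = FALSE) {
  if (!length(categories)) return(surface)
  cols <- .category_columns(surface, categories)
  if (!identical(dim(surface$m), dim(reference$m)) ||
      !identical(colnames(surface$m), colnames(reference$m)))
    stop("surface and reference are not aligned")
  out <- surface
  repl <- reference$m[, cols, drop = FALSE]
  if (one_sided) repl <- pmin(repl, surface$m[, cols, drop = FALSE])
  if (any(repl < 0)) stop("reference rates produce negative substituted rates")
  out$m[, cols] <- repl
  out
}

# apply one scenario to one stratum's split surface
.apply_scenario <- function(surface, spec, groups, reference = NULL) {
  switch(spec$kind,
    status_quo = surface,
    delete = delete_causes(surface, spec$categories),
    substitute = {
      if (surface$country %in% groups$nms) {
        if (is.null(reference))
          stop("no reference rates available for ", surface$year, "/",
               surface$sex)
        substitute_rates(surface, reference, spec$categories)
      } else surface
    })
}

# build split surfaces for every stratum of a filtered panel; returns a
# list keyed country/year/sex plus a strata data.frame
.split_panel <- function(panel, groups, map) {
  panel <- suppressMessages(filter_panel(panel, groups))
  strata <- panel_strata(panel)
  strata <- strata[strata$country %in% c(groups$nms, groups$ems), , drop = FALSE]
  surfaces <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    s <- build_rates(panel, strata$country[i], strata$year[i], strata$sex[i])
    surfaces[[i]] <- split_avoidable(s, map)
  }
  names(surfaces) <- paste(strata$country, strata$year, strata$sex, sep = "/")
  list(strata = strata, surfaces = surfaces)
}

# EMS mean split surface per (year, sex)
.reference_table <- function(sp, groups, weights = "equal") {
  refs <- list()
  ems <- sp$strata$country %in% groups$ems
  for (key in unique(paste(sp$strata$year, sp$strata$sex, sep = "/"))) {
    ys <- strsplit(key, "/", fixed = TRUE)[[1]]
    sel <- ems & sp$strata$year == as.integer(ys[1]) & sp$strata$sex == ys[2]
    if (any(sel)) refs[[key]] <- reference_rates(sp$surfaces[sel],
                                                 weights = weights)
  }
  refs
}

#' Run counterfactual scenarios over a panel
#'
#' For every (country, year, sex) stratum covered by `groups`, builds the
#' avoidability-split rate surface, applies each scenario and computes the
#' life expectancy at birth and lifespan disparity of the resulting
#' schedule. Deletion scenarios act on all countries; substitution acts on
#' NMS countries only, with the reference computed per year and sex as the
#' average over the EMS countries present.
#'
#' @param panel a [mortality_panel()].
#' @param specs a [scenario_spec()] or list of them
#'   (default [table2_scenarios()]).
#' @param groups a [country_groups()]; defaults to the grouping attached to
#'   the panel by [simulate_panel()].
#' @param map an [avoidability_map()].
#' @param weights reference averaging, `"equal"` or `"population"`.
#' @return data.frame with columns country, year, sex, scenario, e0,
#'   edagger.
#' @export
run_scenarios <- function(panel, specs = table2_scenarios(),
                          groups = panel_groups(panel),
                          map = default_avoidability_map(),
                          weights = "equal") {
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "scenario_spec")))
  if (is.null(groups)) stop("no country groups supplied or attached to panel")
  sp <- .split_panel(panel, groups, map)
  needs_ref <- any(vapply(specs, function(s) s$kind == "substitute", TRUE))
  refs <- if (needs_ref) .reference_table(sp, groups, weights) else list()
  n <- nrow(sp$strata)
  out <- vector("list", length(specs))
  for (j in seq_along(specs)) {
    spec <- specs[[j]]
    e0 <- ed <- numeric(n)
    for (i in seq_len(n)) {
      surf <- sp$surfaces[[i]]
      key <- paste(sp$strata$year[i], sp$strata$sex[i], sep = "/")
      if (spec$kind == "substitute" && surf$country %in% groups$nms &&
          is.null(refs[[key]]))
        stop("substitute scenario: no EMS strata available for ", key)
      cf <- .apply_scenario(surf, spec, groups, refs[[key]])
      mall <- rate_all(cf)
      e0[i] <- measure_from_rates(mall, "e0", age = cf$age, sex = cf$sex)
      ed[i] <- measure_from_rates(mall, "edagger", age = cf$age, sex = cf$sex)
    }
    out[[j]] <- data.frame(sp$strata, scenario = spec$name, e0 = e0,
                           edagger = ed, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run a single counterfactual scenario
#'
#' Convenience wrapper around [run_scenarios()] for one [scenario_spec()].
#'
#' @inheritParams run_scenarios
#' @param spec a single [scenario_spec()].
#' @return data.frame with one row per stratum: country, year, sex,
#'   scenario, e0, edagger.
#' @export
run_scenario <- function(panel, spec, groups = panel_groups(panel),
                         map = default_avoidability_map(),
                         weights = "equal") {
  run_scenarios(panel, list(spec), groups = groups, map = map,
                weights = weights)
}
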