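# Synthetic WHO-MDB-style mortality panels with known ground truth:
# two country blocs, Gompertz-Makeham hazards, age-varying cause mixes and
# a configurable avoidable-mortality excess in one bloc.

# toy ICD-10 codes used by the generator, with their reporting groups;
# R99 (ill-defined) is deliberately absent from the toy avoidability map
.TOY_CODES <- data.frame(
  code = c("I21", "I64", "C34", "C50", "V89", "K35", "F10", "A41", "R99"),
  group = c("cardiovascular", "cerebrovascular", "cancer", "cancer",
            "injuries", "digestive", "alcohol_drug", "infectious", "other"),
  stringsAsFactors = FALSE)

# age profiles of the cause mix: cardiovascular/cerebrovascular shares rise
# with age, injuries fall, cancers and alcohol peak in mid-life; weights are
# normalised to shares at every age
.toy_cause_mix <- function(mid) {
  w <- cbind(
    I21 = 0.04 + 0.40 * (mid / 90)^2,
    I64 = 0.01 + 0.15 * (mid / 90)^2,
    C34 = 0.25 * exp(-((mid - 62) / 18)^2),
    C50 = 0.15 * exp(-((mid - 60) / 20)^2),
    V89 = 0.22 * exp(-mid / 35) + 0.01,
    K35 = rep(0.01, length(mid)),
    F10 = 0.10 * exp(-((mid - 50) / 20)^2),
    A41 = rep(0.02, length(mid)),
    R99 = rep(0.30, length(mid)))
  w / rowSums(w)
}

#' Simulation configuration
#'
#' Describes a two-bloc synthetic mortality panel. Bloc A plays the role of
#' the established member states, bloc B the new member states. Each sex
#' has a Gompertz-Makeham total hazard `mu(x) = a*exp(b*x) + c`, split
#' across a toy set of ICD-10 causes by an age-dependent mix; hazards are
#' treated as constant within each abridged interval (midpoint evaluation).
#' In bloc B the avoidable fraction of each selected cause is multiplied by
#' `avoidable_excess`, so that the two blocs differ only in avoidable cells
#' and the non-avoidable remainder is identical.
#'
#' @param countries_per_bloc countries in each bloc (default 3).
#' @param years calendar years of the panel (default 2005:2019).
#' @param sexes subset of `c("male", "female")`.
#' @param gompertz named list `male`/`female` of `c(a=, b=, c=)` hazard
#'   parameters. Defaults give baseline e0 of about 78 (men) and 83 (women).
#' @param avoidable_excess multiplier (>= 0) on the avoidable part of the
#'   selected causes in bloc B (default 1.5).
#' @param excess_groups cause groups receiving the excess (default: all).
#' @param excess_ages age window `c(min, max)` (group start ages, years)
#'   within which the excess applies (default `c(0, 74)`).
#' @param population person-years per age group per country.
#' @param sampling `"poisson"` draws death counts as Poisson around the
#'   expected value; `"expected"` uses the deterministic expectation.
#' @param seed integer RNG seed used by Poisson sampling.
#' @param age the [age_grid()].
#' @param cause_mix optional share matrix (age group x toy cause) overriding
#'   the built-in mix; rows must sum to 1.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(countries_per_bloc = 3L, years = 2005:2019,
                       sexes = c("male", "female"),
                       gompertz = list(
                         male = c(a = 2.2e-5, b = 0.097, c = 7.5e-4),
                         female = c(a = 1.2e-5, b = 0.100, c = 6.0e-4)),
                       avoidable_excess = 1.5, excess_groups = NULL,
                       excess_ages = c(0, 74),
                       population = c(1e5, 4e5, rep(5e5, 16), 3e5),
                       sampling = c("poisson", "expected"), seed = 1L,
                       age = who_age_grid(), cause_mix = NULL) {
  sampling <- match.arg(sampling)
  sexes <- match.arg(sexes, several.ok = TRUE)
  stopifnot(countries_per_bloc >= 1, length(years) >= 1,
            avoidable_excess >= 0, length(population) == nrow(age),
            all(population > 0))
  for (s in sexes) {
    g <- gompertz[[s]]
    if (is.null(g) || !all(c("a", "b", "c") %in% names(g)) || any(g < 0))
      stop("gompertz parameters (a, b, c >= 0) required for sex: ", s)
  }
  mid <- age_midpoints(age)
  mix <- if (is.null(cause_mix)) .toy_cause_mix(mid) else as.matrix(cause_mix)
  if (nrow(mix) != nrow(age) || is.null(colnames(mix)))
    stop("cause_mix must have one named row of shares per age group")
  if (any(mix < 0) || any(abs(rowSums(mix) - 1) > 1e-9))
    stop("validation error: cause-mix shares must be non-negative and sum to 1 at every age")
  structure(list(countries_per_bloc = as.integer(countries_per_bloc),
                 years = as.integer(years), sexes = sexes,
                 gompertz = gompertz, avoidable_excess = avoidable_excess,
                 excess_groups = excess_groups, excess_ages = excess_ages,
                 population = population, sampling = sampling,
                 seed = as.integer(seed), age = age, cause_mix = mix),
            class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Keys mirror the [sim_config()] arguments (scalars and plain lists;
#' `cause_mix` is not settable from YAML). A two-element `years` entry is
#' read as an inclusive from-to range.
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
sim_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("countries_per_bloc", "avoidable_excess", "seed", "sampling"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$years)) {
    yrs <- unlist(y$years)
    # a two-element vector is read as an inclusive from-to range
    args$years <- if (length(yrs) == 2) seq(yrs[1], yrs[2]) else yrs
  }
  if (!is.null(y$sexes)) args$sexes <- unlist(y$sexes)
  if (!is.null(y$excess_groups)) args$excess_groups <- unlist(y$excess_groups)
  if (!is.null(y$excess_ages)) args$excess_ages <- unlist(y$excess_ages)
  if (!is.null(y$population)) args$population <- unlist(y$population)
  if (!is.null(y$gompertz))
    args$gompertz <- lapply(y$gompertz, function(g) unlist(g))
  do.call(sim_config, args)
}

# per-cell multiplier taking bloc A rates to bloc B rates: the avoidable
# fraction of the selected causes within the age window is scaled by k
.excess_factors <- function(cfg, map = toy_avoidability_map()) {
  age <- cfg$age
  codes <- colnames(cfg$cause_mix)
  fac <- matrix(1, nrow(age), length(codes), dimnames = list(age$label, codes))
  if (cfg$avoidable_excess == 1) return(fac)
  groups <- .TOY_CODES$group[match(codes, .TOY_CODES$code)]
  in_window <- age$start >= cfg$excess_ages[1] & age$start <= cfg$excess_ages[2]
  for (j in seq_along(codes)) {
    if (!.icd_ok(codes[j])) next
    if (!is.null(cfg$excess_groups) && !(groups[j] %in% cfg$excess_groups)) next
    for (i in seq_len(nrow(age))) {
      if (!in_window[i] || age$start[i] > map$age_cutoff) next
      cl <- .classify1(codes[j], age$start[i], age$width[i], map)
      fa <- cl$frac_preventable + cl$frac_treatable
      fac[i, j] <- 1 + (cfg$avoidable_excess - 1) * fa
    }
  }
  fac
}

#' Noise-free ground-truth rate surfaces
#'
#' The expected age x cause rates implied by a configuration, one surface
#' per (bloc, sex); all countries of a bloc and all years share the same
#' truth. Useful for parameter-recovery assertions.
#'
#' @param cfg a [sim_config()].
#' @return Named list (`"A/male"`, `"B/male"`, ...) of [rate_surface()]s.
#' @export
ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mid <- age_midpoints(cfg$age)
  fac <- .excess_factors(cfg)
  out <- list()
  for (s in cfg$sexes) {
    g <- cfg$gompertz[[s]]
    mu <- g["a"] * exp(g["b"] * mid) + g["c"]
    base <- cfg$cause_mix * mu
    out[[paste0("A/", s)]] <- rate_surface(base, age = cfg$age, country = "A",
                                           year = NA_integer_, sex = s)
    out[[paste0("B/", s)]] <- rate_surface(base * fac, age = cfg$age,
                                           country = "B", year = NA_integer_,
                                           sex = s)
  }
  out
}

#' Simulate a two-bloc mortality panel
#'
#' Draws death counts for every (country, year, sex, age group, cause) cell
#' of the configured panel: `population x rate` exactly in expected mode,
#' or a Poisson draw around it. All-cause rows (cause `"ALL"`) carry the
#' population and the sum of the cause-specific deaths. The returned panel
#' has the bloc grouping attached (`panel_groups()`): bloc B countries play
#' the NMS role, bloc A the EMS role. Identical seeds give identical
#' panels.
#'
#' @param cfg a [sim_config()].
#' @return A [mortality_panel()] with a [country_groups()] attribute.
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  truth <- ground_truth(cfg)
  age <- cfg$age
  k <- nrow(age)
  codes <- colnames(cfg$cause_mix)
  nc <- length(codes)
  countries <- list(A = paste0("EMS", seq_len(cfg$countries_per_bloc)),
                    B = paste0("NMS", seq_len(cfg$countries_per_bloc)))
  chunks <- list()
  for (bloc in c("A", "B")) for (s in cfg$sexes) {
    m <- truth[[paste0(bloc, "/", s)]]$m # k x nc expected rates
    lam <- as.vector(m * cfg$population) # expected deaths, age-major
    for (ctry in countries[[bloc]]) for (yr in cfg$years) {
      deaths <- if (cfg$sampling == "expected") lam else
        stats::rpois(length(lam), lam)
      dmat <- matrix(deaths, k, nc)
      chunks[[length(chunks) + 1L]] <- data.frame(
        country = ctry, year = yr, sex = s,
        age_start = rep(age$start, nc + 1L),
        cause = rep(c(codes, ALL_CAUSE), each = k),
        deaths = c(deaths, rowSums(dmat)),
        population = c(rep(NA_real_, k * nc), cfg$population),
        stringsAsFactors = FALSE)
    }
  }
  panel <- mortality_panel(do.call(rbind, chunks), age = age, validate = FALSE)
  attr(panel, "groups") <- country_groups(nms = countries$B,
                                          ems = countries$A)
  panel
}

#' Write ground truth rates as long CSV
#'
#' Columns: bloc, sex, age_start, cause, rate.
#'
#' @param cfg a [sim_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cfg, path) {
  truth <- ground_truth(cfg)
  rows <- lapply(names(truth), function(nm) {
    bs <- strsplit(nm, "/", fixed = TRUE)[[1]]
    s <- truth[[nm]]
    data.frame(bloc = bs[1], sex = bs[2],
               age_start = rep(s$age$start, ncol(s$m)),
               cause = rep(colnames(s$m), each = nrow(s$m)),
               rate = as.vector(s$m), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
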