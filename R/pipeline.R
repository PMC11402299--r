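# Group aggregation, the seven-scenario summary table and the end-to-end pipeline.

.SCENARIO_LABELS <- c(
  status_quo = "Status quo",
  substitute_avoidable = "Average mortality rates for all avoidable causes applied to NMS",
  substitute_preventable = "Average mortality rates for only preventable causes applied to NMS",
  substitute_treatable = "Average mortality rates for only treatable causes applied to NMS",
  delete_avoidable = "All avoidable deaths removed",
  delete_preventable = "Only preventable deaths removed",
  delete_treatable = "Only treatable deaths removed")

#' Aggregate per-stratum results into bloc summaries
#'
#' Averages the per-stratum e0 and e-dagger of [run_scenarios()] into bloc
#' means, one row per (sex, scenario). Means are unweighted over the
#' (country, year) cells present for each bloc, so a country with partial
#' year coverage contributes only its observed years. The difference
#' columns are NMS mean minus EMS mean.
#'
#' @param results data.frame from [run_scenarios()].
#' @param groups a [country_groups()].
#' @return data.frame with columns sex, scenario, e0_nms, e0_ems, e0_diff,
#'   edagger_nms, edagger_ems, edagger_diff.
#' @export
aggregate_groups <- function(results, groups) {
  stopifnot(inherits(groups, "country_groups"),
            all(c("country", "sex", "scenario", "e0", "edagger") %in%
                  names(results)))
  in_nms <- results$country %in% groups$nms
  in_ems <- results$country %in% groups$ems
  if (!any(in_nms) || !any(in_ems))
    stop("empty bloc: results must cover both NMS and EMS countries")
  cells <- unique(results[c("sex", "scenario")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- results$sex == cells$sex[i] & results$scenario == cells$scenario[i]
    nms <- results[sel & in_nms, ]; ems <- results[sel & in_ems, ]
    if (!nrow(nms) || !nrow(ems))
      stop("empty bloc for ", cells$sex[i], "/", cells$scenario[i])
    data.frame(sex = cells$sex[i], scenario = cells$scenario[i],
               e0_nms = mean(nms$e0), e0_ems = mean(ems$e0),
               e0_diff = mean(nms$e0) - mean(ems$e0),
               edagger_nms = mean(nms$edagger), edagger_ems = mean(ems$edagger),
               edagger_diff = mean(nms$edagger) - mean(ems$edagger),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(match(out$sex, c("male", "female")),
               match(out$scenario, names(.SCENARIO_LABELS)))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Render bloc summaries as the standard seven-scenario Markdown table
#'
#' Seven scenario rows per sex in fixed presentation order, six numeric
#' columns (NMS, EMS and their difference for e0 and for lifespan
#' disparity), rounded to 2 decimals at render time only.
#'
#' @param summaries data.frame from [aggregate_groups()].
#' @param path optional output file.
#' @param scenarios scenario names expected (default: all seven).
#' @return character vector of Markdown lines, invisibly if `path` given.
#' @export
render_table2 <- function(summaries, path = NULL,
                          scenarios = names(.SCENARIO_LABELS)) {
  miss <- setdiff(scenarios, unique(summaries$scenario))
  if (length(miss))
    stop("missing scenario(s) in summaries: ", paste(miss, collapse = ", "))
  fmt <- function(x) sprintf("%.2f", x)
  lines <- c(
    "| Sex | Scenario | e0 NMS | e0 EMS | e0 Difference | e-dagger NMS | e-dagger EMS | e-dagger Difference |",
    "|---|---|---|---|---|---|---|---|")
  for (s in intersect(c("male", "female"), unique(summaries$sex))) {
    for (sc in scenarios) {
      r <- summaries[summaries$sex == s & summaries$scenario == sc, ]
      lines <- c(lines, paste("|", tools::toTitleCase(s), "|",
                              .SCENARIO_LABELS[[sc]], "|",
                              fmt(r$e0_nms), "|", fmt(r$e0_ems), "|",
                              fmt(r$e0_diff), "|", fmt(r$edagger_nms), "|",
                              fmt(r$edagger_ems), "|", fmt(r$edagger_diff),
                              "|"))
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Run the full analysis pipeline
#'
#' Orchestrates panel (simulated or read from file) -> scenario runs ->
#' bloc aggregation -> per-bloc decompositions, writing all artifacts under
#' `out_dir`: `scenarios.csv` (per-stratum e0/e-dagger), `group_summary.csv`
#' and `table2.md` (bloc summaries), `decomposition.csv` (age x category
#' contributions of every non-status-quo scenario to the pooled bloc mean
#' surfaces, for e0 and e-dagger) and `log.txt` (versions, seed, config
#' echo and the avoidability-map checksum).
#'
#' @param panel a [mortality_panel()], or NULL to simulate from `cfg`.
#' @param cfg a [sim_config()] used when `panel` is NULL.
#' @param out_dir output directory (created if needed).
#' @param specs scenario list (default [table2_scenarios()]).
#' @param groups a [country_groups()]; defaults to the panel's attribute.
#' @param map an [avoidability_map()]; the simulated panel uses the toy map.
#' @param n_steps decomposition steps.
#' @param weights reference averaging, `"equal"` or `"population"`.
#' @return Invisibly, a list with `results`, `summary` and the decomposition
#'   data.frame.
#' @export
run_pipeline <- function(panel = NULL, cfg = sim_config(), out_dir,
                         specs = table2_scenarios(), groups = NULL,
                         map = NULL, n_steps = 20, weights = "equal") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  simulated <- is.null(panel)
  if (simulated) panel <- simulate_panel(cfg)
  if (is.null(groups)) groups <- panel_groups(panel)
  if (is.null(groups)) stop("no country groups supplied or attached to panel")
  if (is.null(map))
    map <- if (simulated) toy_avoidability_map() else default_avoidability_map()
  if (inherits(specs, "scenario_spec")) specs <- list(specs)

  results <- run_scenarios(panel, specs, groups = groups, map = map,
                           weights = weights)
  utils::write.csv(results, file.path(out_dir, "scenarios.csv"),
                   row.names = FALSE)
  summary <- aggregate_groups(results, groups)
  utils::write.csv(summary, file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE)
  have <- vapply(specs, `[[`, "", "name")
  render_table2(summary, file.path(out_dir, "table2.md"), scenarios = have)

  decomp <- .pooled_decompositions(panel, specs, groups, map, n_steps, weights)
  utils::write.csv(decomp, file.path(out_dir, "decomposition.csv"),
                   row.names = FALSE)
  .write_log(file.path(out_dir, "log.txt"), cfg, simulated, map, n_steps,
             weights, nrow(results))
  invisible(list(results = results, summary = summary, decomposition = decomp))
}

# decompose pooled (bloc-mean) status-quo vs counterfactual surfaces for
# each non-status-quo scenario, sex, bloc and measure
.pooled_decompositions <- function(panel, specs, groups, map, n_steps,
                                   weights) {
  sp <- .split_panel(panel, groups, map)
  refs <- .reference_table(sp, groups, weights)
  blocs <- list(NMS = groups$nms, EMS = groups$ems)
  rows <- list()
  for (s in unique(sp$strata$sex)) {
    for (bl in names(blocs)) {
      sel <- which(sp$strata$sex == s & sp$strata$country %in% blocs[[bl]])
      if (!length(sel)) next
      pooled_from <- reference_rates(sp$surfaces[sel])
      pooled_from$country <- bl
      for (spec in specs) {
        if (spec$kind == "status_quo") next
        cfs <- lapply(sel, function(i) {
          key <- paste(sp$strata$year[i], s, sep = "/")
          .apply_scenario(sp$surfaces[[i]], spec, groups, refs[[key]])
        })
        pooled_to <- reference_rates(cfs)
        pooled_to$country <- bl
        for (ms in c("e0", "edagger")) {
          d <- decompose_surfaces(pooled_from, pooled_to, measure = ms,
                                  n_steps = n_steps)
          df <- as.data.frame(d)
          df$sex <- s; df$bloc <- bl; df$scenario <- spec$name
          df$total <- d$total
          rows[[length(rows) + 1L]] <- df
        }
      }
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

.write_log <- function(path, cfg, simulated, map, n_steps, weights, n_rows) {
  map_csv <- tempfile(fileext = ".csv")
  utils::write.csv(map$entries, map_csv, row.names = FALSE)
  checksum <- unname(tools::md5sum(map_csv))
  unlink(map_csv)
  lines <- c(
    paste0("avoidmort ", as.character(utils::packageVersion("avoidmort"))),
    R.version.string,
    paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    paste0("input: ", if (simulated) "simulated" else "file"),
    if (simulated) c(
      paste0("seed: ", cfg$seed),
      paste0("sampling: ", cfg$sampling),
      paste0("countries_per_bloc: ", cfg$countries_per_bloc),
      paste0("years: ", min(cfg$years), "-", max(cfg$years)),
      paste0("avoidable_excess: ", cfg$avoidable_excess)),
    paste0("n_steps: ", n_steps),
    paste0("reference_weights: ", weights),
    paste0("avoidability_map_md5: ", checksum),
    paste0("result_rows: ", n_rows))
  writeLines(lines, path)
  invisible(path)
}
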