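test_that("lung cancer is preventable, appendicitis treatable", {
  map <- default_avoidability_map()
  lung <- classify_cause("C34", "50-54", map)
  expect_equal(lung$frac_preventable, 1)
  expect_equal(lung$frac_treatable, 0)
  expect_equal(lung$cause_group, "cancer")
  app <- classify_cause("K35", "40-44", map)
  expect_equal(app$frac_treatable, 1)
  expect_equal(app$frac_preventable, 0)
})

test_that("no cause is avoidable above the age cutoff", {
  map <- default_avoidability_map()
  for (code in c("C34", "K35", "I21", "V89")) {
    cl <- classify_cause(code, "80-84", map)
    expect_equal(cl$frac_preventable, 0)
    expect_equal(cl$frac_treatable, 0)
    expect_true(is.na(cl$cause_group))
    expect_true(is.na(classify_cause(code, "85+", map)$cause_group))
  }
})

test_that("unlisted and malformed codes behave as specified", {
  map <- toy_avoidability_map()
  cl <- classify_cause("R99", "50-54", map)
  expect_equal(cl$frac_preventable + cl$frac_treatable, 0)
  expect_error(classify_cause("NOPE", "50-54", map), "malformed")
  expect_error(classify_cause("1234", "50-54", map), "malformed")
})

test_that("age groups straddling the cutoff are an error", {
  map <- toy_avoidability_map()
  g <- age_grid(c(0, 70), c(70, Inf))
  expect_error(classify_cause("I21", 70, map, grid = g), "straddle")
})

test_that("a 4-character entry shadows its 3-character parent", {
  map <- avoidability_map(data.frame(
    icd10_pattern = c("I20-I25", "I219"),
    age_min = 0, age_max = 74,
    frac_preventable = c(1, 0), frac_treatable = c(0, 1),
    cause_group = "cardiovascular"))
  expect_equal(classify_cause("I219", "50-54", map)$frac_treatable, 1)
  expect_equal(classify_cause("I211", "50-54", map)$frac_preventable, 1)
  expect_equal(classify_cause("I21", "50-54", map)$frac_preventable, 1)
})

test_that("map validation rejects bad tables", {
  base <- data.frame(icd10_pattern = "C34", age_min = 0, age_max = 74,
                     frac_preventable = 0.7, frac_treatable = 0.6,
                     cause_group = "cancer")
  expect_error(avoidability_map(base), "sum to at most 1")
  base$frac_treatable <- 0.3; base$age_max <- 80
  expect_error(avoidability_map(base), "age cutoff")
  two <- data.frame(icd10_pattern = c("C30-C39", "C34"),
                    age_min = 0, age_max = 74,
                    frac_preventable = 1, frac_treatable = 0,
                    cause_group = "cancer")
  expect_error(avoidability_map(two), "overlapping")
  bad_group <- data.frame(icd10_pattern = "C34", age_min = 0, age_max = 74,
                          frac_preventable = 1, frac_treatable = 0,
                          cause_group = "nope")
  expect_error(avoidability_map(bad_group), "unknown cause group")
})

test_that("the packaged default map loads and matches the list shape", {
  map <- default_avoidability_map()
  expect_s3_class(map, "avoidability_map")
  expect_equal(map$age_cutoff, 74)
  e <- map$entries
  expect_true(all(e$frac_preventable + e$frac_treatable <= 1 + 1e-12))
  shared <- e$frac_preventable > 0 & e$frac_treatable > 0
  expect_true(all(e$frac_preventable[shared] == 0.5)) # default 50/50 split
  expect_true(all(e$cause_group %in% cause_groups()))
})

test_that("split_avoidable conserves total rates and respects the cutoff", {
  map <- toy_avoidability_map()
  mid <- age_midpoints(who_age_grid())
  m <- cbind(I21 = 1e-4 + 1e-3 * (mid / 90)^2,
             C34 = 5e-4 * exp(-((mid - 60) / 20)^2),
             R99 = rep(2e-4, 19))
  s <- surface_from(m)
  ss <- split_avoidable(s, map)
  expect_equal(unname(rowSums(ss$m)), unname(rate_all(s)), tolerance = 1e-12)
  # I21 splits 50/50 between preventable and treatable
  i <- which(who_age_grid()$start == 50)
  expect_equal(unname(ss$m[i, "preventable.cardiovascular"]),
               unname(m[i, "I21"] / 2))
  expect_equal(unname(ss$m[i, "treatable.cardiovascular"]),
               unname(m[i, "I21"] / 2))
  # above the cutoff everything is remainder
  old <- who_age_grid()$start >= 75
  avoid_cols <- setdiff(colnames(ss$m), "non_avoidable")
  expect_true(all(ss$m[old, avoid_cols] == 0))
  expect_equal(unname(ss$m[old, "non_avoidable"]), unname(rate_all(s)[old]))
})

test_that("a surface of unlisted codes is entirely non-avoidable", {
  s <- surface_from(cbind(R99 = rep(1e-3, 19), OTHER = rep(1e-4, 19)))
  ss <- split_avoidable(s, toy_avoidability_map())
  expect_equal(unname(ss$m[, "non_avoidable"]), unname(rate_all(s)))
  expect_equal(sum(ss$m[, colnames(ss$m) != "non_avoidable"]), 0)
})

test_that("adding a map entry never decreases the avoidable rate", {
  mid <- age_midpoints(who_age_grid())
  m <- cbind(I21 = rep(1e-3, 19), K35 = rep(2e-4, 19), R99 = rep(5e-4, 19))
  s <- surface_from(m)
  entries <- toy_avoidability_map()$entries
  for (k in 2:nrow(entries)) {
    small <- avoidability_map(entries[seq_len(k - 1), ])
    big <- avoidability_map(entries[seq_len(k), ])
    avoid <- function(map) {
      ss <- split_avoidable(s, map)
      sum(ss$m[, colnames(ss$m) != "non_avoidable"])
    }
    expect_gte(avoid(big), avoid(small))
  }
})
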