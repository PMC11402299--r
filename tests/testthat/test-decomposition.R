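# a random plausible mortality surface and a bloc-style partner whose
# cell rates differ by independent factors in [0.7, 1.4] (a few years of e0)
rand_surface_pair <- function(seed, n_causes = 3) {
  set.seed(seed)
  mid <- age_midpoints(who_age_grid())
  a <- stats::runif(1, 5e-6, 4e-5); b <- stats::runif(1, 0.07, 0.105)
  cc <- stats::runif(1, 1e-4, 3e-3)
  mu <- a * exp(b * mid) + cc
  shares <- matrix(stats::runif(19 * n_causes, 0.05, 1), 19)
  shares <- shares / rowSums(shares)
  m <- shares * mu
  colnames(m) <- paste0("G", seq_len(n_causes))
  m2 <- m * matrix(stats::runif(length(m), 0.7, 1.4), nrow(m))
  list(from = surface_from(m), to = surface_from(m2))
}

test_that("identical endpoints decompose to an all-zero matrix", {
  p <- rand_surface_pair(1)
  d <- decompose_surfaces(p$from, p$from, "e0")
  expect_true(all(d$contributions == 0))
  expect_equal(d$total, 0)
})

test_that("a single differing cell receives the whole total", {
  p <- rand_surface_pair(2)
  to <- p$from
  to$m[10, 2] <- to$m[10, 2] * 2
  d <- decompose_surfaces(p$from, to, "e0", n_steps = 20)
  expect_equal(sum(d$contributions != 0), 1)
  delta <- measure_from_rates(rowSums(to$m), "e0", sex = "male") -
    measure_from_rates(rowSums(p$from$m), "e0", sex = "male")
  expect_lt(abs(sum(d$contributions) - delta), 1e-6)
  expect_equal(unname(d$contributions[10, 2]), sum(d$contributions))
})

test_that("contributions sum to the direct difference within 1e-4 years", {
  # bloc contrasts from the synthetic generator under randomised hazards
  # at the generator's default avoidable excess
  set.seed(31)
  map <- toy_avoidability_map()
  for (seed in 1:10) {
    cfg <- sim_config(
      sexes = "male",
      gompertz = list(male = c(
        a = stats::runif(1, 5e-6, 4e-5), b = stats::runif(1, 0.07, 0.105),
        c = stats::runif(1, 1e-4, 3e-3))))
    truth <- ground_truth(cfg)
    from <- split_avoidable(truth[["B/male"]], map)
    to <- split_avoidable(truth[["A/male"]], map)
    for (ms in c("e0", "edagger")) {
      d <- decompose_surfaces(from, to, ms, n_steps = 20)
      expect_lt(abs(sum(d$contributions) - d$total), 1e-4)
    }
  }
})

test_that("integration error shrinks as steps double", {
  p <- rand_surface_pair(7)
  err <- vapply(c(2, 4, 8, 16), function(N) {
    d <- decompose_surfaces(p$from, p$to, "e0", n_steps = N)
    abs(sum(d$contributions) - d$total)
  }, 0)
  expect_true(all(diff(err) <= 0))
})

test_that("swapping endpoints negates every contribution", {
  p <- rand_surface_pair(11)
  d1 <- decompose_surfaces(p$from, p$to, "e0")
  d2 <- decompose_surfaces(p$to, p$from, "e0")
  expect_lt(max(abs(d1$contributions + d2$contributions)), 1e-8)
})

test_that("contributions are additive over a coarser cause binning", {
  # decompose on the fine axis, then on an axis with causes merged; totals
  # per merged bin must agree
  p <- rand_surface_pair(13)
  d_fine <- decompose_surfaces(p$from, p$to, "e0", n_steps = 20)
  merge2 <- function(s) {
    m <- cbind(G12 = s$m[, 1] + s$m[, 2], G3 = s$m[, 3])
    surface_from(m, sex = s$sex)
  }
  d_coarse <- decompose_surfaces(merge2(p$from), merge2(p$to), "e0",
                                 n_steps = 20)
  expect_lt(max(abs((d_fine$contributions[, 1] + d_fine$contributions[, 2]) -
                      d_coarse$contributions[, 1])), 1e-4)
  expect_lt(abs(sum(d_fine$contributions) - sum(d_coarse$contributions)),
            1e-4)
})

test_that("decompose validates its inputs", {
  p <- rand_surface_pair(3)
  expect_error(decompose_surfaces(p$from, p$to, "e0", n_steps = 0), ">= 1")
  small <- p$to; small$m <- small$m[, 1:2]
  expect_error(decompose_surfaces(p$from, small), "not aligned")
  other_sex <- p$to; other_sex$sex <- "female"
  expect_error(decompose_surfaces(p$from, other_sex), "different sexes")
})

test_that("log-path decomposition also conserves the total", {
  p <- rand_surface_pair(17)
  d <- decompose_surfaces(p$from, p$to, "e0", n_steps = 20, path = "log")
  expect_lt(abs(sum(d$contributions) - d$total), 1e-4)
})

test_that("a delete-nothing scenario decomposes to the zero matrix", {
  p <- simulate_panel(small_cfg())
  d <- decompose_scenario_gain(p, scenario_spec("status_quo"),
                               "NMS1", 2005, "male",
                               map = toy_avoidability_map())
  expect_true(all(d$contributions == 0))
})

test_that("scenario-gain totals agree with run_scenarios differences", {
  p <- simulate_panel(small_cfg(avoidable_excess = 1.6))
  res <- run_scenarios(p, list(scenario_spec("status_quo"),
                               scenario_spec("substitute")),
                       map = toy_avoidability_map())
  d <- decompose_scenario_gain(p, scenario_spec("substitute"),
                               "NMS1", 2005, "male",
                               map = toy_avoidability_map())
  sel <- res$country == "NMS1" & res$year == 2005 & res$sex == "male"
  gain <- res$e0[sel & res$scenario == "substitute_avoidable"] -
    res$e0[sel & res$scenario == "status_quo"]
  expect_equal(d$total, gain, tolerance = 1e-12)
  expect_lt(abs(sum(d$contributions) - gain), 1e-4)
  expect_gt(gain, 0)
})

test_that("localised avoidable excess is attributed to the right cells", {
  cfg <- small_cfg(avoidable_excess = 2,
                   excess_groups = c("cardiovascular", "injuries"),
                   excess_ages = c(45, 84))
  truth <- ground_truth(cfg)
  map <- toy_avoidability_map()
  from <- split_avoidable(truth[["B/male"]], map) # worse bloc
  to <- split_avoidable(truth[["A/male"]], map)
  d <- decompose_surfaces(from, to, "e0", n_steps = 20)
  axis <- attr(from, "axis")
  target_cols <- axis$column[axis$cause_group %in%
                               c("cardiovascular", "injuries") &
                               !is.na(axis$cause_group)]
  target_rows <- who_age_grid()$start >= 45 & who_age_grid()$start < 75
  share <- sum(d$contributions[target_rows, target_cols]) /
    sum(d$contributions)
  expect_gte(share, 0.99)
})
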