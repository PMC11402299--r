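# Shared fixtures, all built in code.

# 3-group toy schedule with independently hand-computed (exact-fraction)
# life-table oracle values, frozen before the implementation was written.
toy_grid <- function() age_grid(c(0, 5, 10), c(5, 5, Inf))
toy_mx <- c(0.02, 0.05, 0.1)
toy_ax <- c(2.5, 2.5, NA)
toy_oracle <- list(
  qx = c(0.09523809523809523, 0.2222222222222222, 1.0),
  lx = c(100000, 90476.19047619047, 70370.37037037036),
  dx = c(9523.809523809523, 20105.820105820105, 70370.37037037036),
  Lx = c(476190.4761904762, 402116.4021164021, 703703.7037037037),
  Tx = c(1582010.582010582, 1105820.1058201059, 703703.7037037037),
  ex = c(15.82010582010582, 12.222222222222221, 10.0),
  e0 = 15.82010582010582,
  edagger = 10.6063660031914)

# tiny hand-written panel: one stratum, two causes (60/40 split of 100
# deaths in one age group) plus all-cause rows everywhere
tiny_panel <- function() {
  grid <- who_age_grid()
  all_rows <- data.frame(country = "X", year = 2010, sex = "male",
                         age_start = grid$start, cause = "ALL",
                         deaths = 10, population = 1000)
  i <- which(grid$start == 50)
  all_rows$deaths[i] <- 100
  cause_rows <- data.frame(country = "X", year = 2010, sex = "male",
                           age_start = 50, cause = c("C34", "K35"),
                           deaths = c(60, 40), population = NA_real_)
  mortality_panel(rbind(all_rows, cause_rows))
}

# small expected-mode simulation shared by several tests
small_cfg <- function(...) {
  sim_config(countries_per_bloc = 1, years = 2005:2006,
             sampling = "expected", ...)
}

# surface with given cause columns on the WHO grid
surface_from <- function(m_cause, sex = "male", country = "X", year = 2010) {
  rate_surface(m_cause, age = who_age_grid(), country = country,
               year = year, sex = sex)
}
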