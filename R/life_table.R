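# Abridged period life tables, e0 and the e-dagger lifespan disparity.

# Andreev-Kingkade style rule for average years lived in the first year of
# life by infants who die, driven by the infant death rate m0.
.ak_a0 <- function(m0, sex) {
  if (sex == "male") {
    if (m0 < 0.02300) 0.14929 - 1.99545 * m0
    else if (m0 < 0.08307) 0.02832 + 3.26021 * m0
    else 0.29915
  } else {
    if (m0 < 0.01724) 0.14903 - 2.05527 * m0
    else if (m0 < 0.06891) 0.04667 + 3.88089 * m0
    else 0.31411
  }
}

# default ax: AK rule for a 0-1 first group, half the interval elsewhere
.default_ax <- function(mx, start, width, sex) {
  k <- length(mx)
  ax <- width / 2
  if (start[1] == 0 && width[1] == 1) ax[1] <- .ak_a0(mx[1], sex)
  ax[k] <- NA_real_ # open interval handled via L = l/m
  ax
}

# Core column engine on bare vectors; radix 1. Returns list of columns.
# Kept free of data.frame overhead because the decomposition calls it tens
# of thousands of times.
.lt_cols <- function(mx, width, ax, need_e = TRUE) {
  k <- length(mx)
  cl <- seq_len(k - 1L)
  q <- numeric(k)
  q[cl] <- pmin(1, width[cl] * mx[cl] / (1 + (width[cl] - ax[cl]) * mx[cl]))
  q[k] <- 1
  l <- cumprod(c(1, 1 - q[cl]))
  d <- l * q
  L <- numeric(k)
  L[cl] <- width[cl] * l[cl] - d[cl] * (width[cl] - ax[cl])
  L[k] <- if (l[k] > 0) l[k] / mx[k] else 0
  out <- list(q = q, l = l, d = d, L = L)
  if (need_e) {
    Tx <- rev(cumsum(rev(L)))
    out$T <- Tx
    out$e <- ifelse(l > 0, Tx / l, 0)
  }
  out
}

.edagger_from_cols <- function(cols, width, ax) {
  k <- length(cols$q)
  cl <- seq_len(k - 1L)
  e <- cols$e
  ebar <- numeric(k)
  ebar[cl] <- e[cl + 1L] + (1 - ax[cl] / width[cl]) * (e[cl] - e[cl + 1L])
  ebar[k] <- e[k]
  sum(cols$d * ebar) / cols$l[1]
}

.check_rates <- function(mx, k) {
  if (!is.numeric(mx) || length(mx) != k)
    stop("`mx` must be a numeric vector with one rate per age group")
  if (anyNA(mx) || any(mx < 0)) stop("death rates must be non-negative and finite")
  if (mx[k] <= 0) stop("open-interval death rate must be strictly positive")
}

#' Abridged period life table
#'
#' Builds an abridged life table from age-specific all-cause death rates.
#' Closed intervals use the conversion `qx = n*mx / (1 + (n - ax)*mx)`; the
#' open interval is closed with `Lx = lx / mx`. The default `ax` convention
#' is an Andreev-Kingkade style rule for age 0 (when the grid starts with a
#' 0-1 group) and half the interval width elsewhere.
#'
#' @param mx numeric vector of death rates (deaths per person-year), one per
#'   group of `age`.
#' @param age an [age_grid()]; defaults to the 19-group WHO grid.
#' @param sex `"female"` or `"male"`; only used by the infant `ax` rule.
#' @param ax optional explicit average years lived in the interval by those
#'   dying in it (closed intervals; the open-interval entry is ignored).
#' @param radix starting cohort size `l0` (default 100000; cancels in all
#'   summary measures).
#' @return A `life_table`: a data.frame with columns
#'   `x, n, mx, ax, qx, lx, dx, Lx, Tx, ex`.
#' @examples
#' lt <- make_life_table(rep(0.01, 19))
#' life_expectancy(lt) # 100 for a constant hazard
#' @export
make_life_table <- function(mx, age = who_age_grid(), sex = c("female", "male"),
                            ax = NULL, radix = 1e5) {
  stopifnot(inherits(age, "age_grid"))
  sex <- match.arg(sex)
  k <- nrow(age)
  .check_rates(mx, k)
  if (is.null(ax)) {
    ax <- .default_ax(mx, age$start, age$width, sex)
  } else {
    stopifnot(is.numeric(ax), length(ax) == k)
    if (any(ax[-k] < 0 | ax[-k] > age$width[-k]))
      stop("ax must lie within the interval width")
  }
  cols <- .lt_cols(mx, age$width, ax)
  ax_out <- ax
  ax_out[k] <- 1 / mx[k] # mean remaining lifetime in the open group
  out <- data.frame(x = age$start, n = age$width, mx = mx, ax = ax_out,
                    qx = cols$q, lx = radix * cols$l, dx = radix * cols$d,
                    Lx = radix * cols$L, Tx = radix * cols$T, ex = cols$e)
  structure(out, class = c("life_table", "data.frame"),
            sex = sex, radix = radix, ax_closed = ax)
}

#' @export
print.life_table <- function(x, digits = 4, ...) {
  cat(sprintf("Abridged life table (%s, radix %g): e0 = %.3f, e-dagger = %.3f\n",
              attr(x, "sex"), attr(x, "radix"),
              life_expectancy(x), e_dagger(x)))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' Life expectancy at birth
#'
#' `e0 = T0 / l0`, the mean age at death of the synthetic cohort.
#'
#' @param lt a [make_life_table()] result.
#' @return years (scalar).
#' @export
life_expectancy <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  lt$Tx[1] / lt$lx[1]
}

#' Lifespan disparity (e-dagger)
#'
#' The average remaining life expectancy at the ages when deaths occur:
#' `e-dagger = (1/l0) * sum(dx * ebar_x)`, where within a closed interval the
#' remaining expectancy at the mean age at death is interpolated as
#' `ebar_x = e_{x+n} + (1 - ax/n) * (e_x - e_{x+n})` and the open interval
#' uses `ebar = e_x`. Lower values indicate more compressed lifespans.
#'
#' @inheritParams life_expectancy
#' @return years (scalar).
#' @export
e_dagger <- function(lt) {
  stopifnot(inherits(lt, "life_table"))
  k <- nrow(lt)
  ax <- attr(lt, "ax_closed")
  cols <- list(q = lt$qx, l = lt$lx, d = lt$dx, e = lt$ex)
  .edagger_from_cols(cols, lt$n, ax)
}

#' Summary measure from a rate schedule
#'
#' Pure functional wrapper composing [make_life_table()] with the requested
#' summary; this is the function the decomposition differentiates.
#'
#' @inheritParams make_life_table
#' @param which `"e0"` or `"edagger"`.
#' @return years (scalar).
#' @export
measure_from_rates <- function(mx, which = c("e0", "edagger"),
                               age = who_age_grid(), sex = c("female", "male"),
                               ax = NULL) {
  which <- match.arg(which)
  sex <- match.arg(sex)
  k <- nrow(age)
  .check_rates(mx, k)
  if (is.null(ax)) ax <- .default_ax(mx, age$start, age$width, sex)
  cols <- .lt_cols(mx, age$width, ax)
  if (which == "e0") cols$T[1] else .edagger_from_cols(cols, age$width, ax)
}
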