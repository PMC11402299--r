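#' Abridged age grid
#'
#' The grouped-age scale on which all rates, life tables and decompositions
#' in this package live. A grid is an ordered set of contiguous,
#' non-overlapping age groups; the last group is open-ended.
#'
#' @param start integer vector of age-group lower bounds (years).
#' @param width interval widths in years; `Inf` marks the open-ended last
#'   group (and only the last group may be open).
#' @return An object of class `age_grid`: a data.frame with columns
#'   `label`, `start`, `width`.
#' @seealso [who_age_grid()] for the standard 19-group grid.
#' @export
age_grid <- function(start, width) {
  stopifnot(is.numeric(start), is.numeric(width), length(start) == length(width),
            length(start) >= 2L)
  if (is.unsorted(start, strictly = TRUE))
    stop("age-group starts must be strictly increasing")
  k <- length(start)
  open <- !is.finite(width)
  if (any(open[-k]) || !open[k])
    stop("exactly the last age group must be open-ended (width = Inf)")
  if (any(width[-k] <= 0)) stop("age-group widths must be positive")
  gap <- start[-1L] - (start[-k] + width[-k])
  if (any(abs(gap) > 1e-9)) stop("age groups must be contiguous and non-overlapping")
  label <- c(ifelse(width[-k] == 1, as.character(start[-k]),
                    paste0(start[-k], "-", start[-k] + width[-k] - 1)),
             paste0(start[k], "+"))
  structure(data.frame(label = label, start = start, width = width,
                       stringsAsFactors = FALSE),
            class = c("age_grid", "data.frame"))
}

#' Standard WHO-style abridged age grid
#'
#' The 19-group grid 0, 1-4, 5-9, ..., 80-84, 85+ used by the WHO Mortality
#' Database tabulations.
#'
#' @return An [age_grid()] with 19 groups.
#' @export
who_age_grid <- function() {
  g <- age_grid(c(0L, 1L, seq(5L, 85L, 5L)), c(1, 4, rep(5, 16), Inf))
  stopifnot(nrow(g) == 19L)
  g
}

#' Age-group midpoints
#'
#' Midpoint of each closed interval; the open interval is represented by its
#' start plus `open_offset` years.
#'
#' @param grid an [age_grid()].
#' @param open_offset years added to the open group's start (default 5).
#' @return numeric vector, one midpoint per group.
#' @export
age_midpoints <- function(grid, open_offset = 5) {
  stopifnot(inherits(grid, "age_grid"))
  k <- nrow(grid)
  mid <- grid$start + grid$width / 2
  mid[k] <- grid$start[k] + open_offset
  mid
}

# resolve a label or numeric start to a row index of the grid
.age_index <- function(age_group, grid) {
  if (is.character(age_group)) {
    i <- match(age_group, grid$label)
  } else {
    i <- match(age_group, grid$start)
  }
  if (anyNA(i))
    stop("age group(s) not on the age grid: ",
         paste(age_group[is.na(i)], collapse = ", "))
  i
}
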