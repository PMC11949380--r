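#' State space of the illness-death model
#'
#' The model distinguishes three states: `FREE` (alive without a prior
#' cardiovascular diagnosis), `CVD` (alive with cardiovascular disease) and
#' `DEAD`. Disease entry is irreversible, so the allowed one-step transitions
#' are FREE -> FREE/CVD/DEAD and CVD -> CVD/DEAD; DEAD is the single absorbing
#' state with only a self-loop. All-cause death is used, so there is exactly
#' one absorbing state.
#'
#' @return An object of class `state_space`: a list with the ordered state
#'   labels, the transient and absorbing subsets, and the allowed-transition
#'   indicator matrix.
#' @examples
#' ss <- state_space()
#' ss$allowed["CVD", ]   # CVD can only stay or die
#' @export
state_space <- function() {
  states <- c("FREE", "CVD", "DEAD")
  allowed <- matrix(FALSE, 3, 3, dimnames = list(from = states, to = states))
  allowed["FREE", c("FREE", "CVD", "DEAD")] <- TRUE
  allowed["CVD", c("CVD", "DEAD")] <- TRUE
  allowed["DEAD", "DEAD"] <- TRUE
  structure(
    list(
      states = states,
      transient = c("FREE", "CVD"),
      absorbing = "DEAD",
      allowed = allowed
    ),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat("Illness-death state space:", paste(x$states, collapse = " -> "), "\n")
  cat("Absorbing:", x$absorbing, "(all-cause death; single absorbing state)\n")
  invisible(x)
}

#' Quarterly age grid
#'
#' Discrete age grid in months. The default spans ages 40 to 100 years
#' (480 to 1200 months) in 3-month steps: 241 grid points and 240 intervals
#' of 0.25 years each. Transitions occur between consecutive grid points;
#' state is assigned at grid points.
#'
#' @param start_month first grid point (months).
#' @param end_month last grid point (months); the horizon of the model.
#' @param step_months interval length in months; must divide
#'   `end_month - start_month`.
#' @return An object of class `age_grid`: list with `start`, `end`, `step`,
#'   the vector of grid `points`, and `n_intervals`.
#' @examples
#' g <- age_grid()
#' g$n_intervals            # 240
#' range(g$points) / 12     # ages 40 and 100 in years
#' @export
age_grid <- function(start_month = 480L, end_month = 1200L, step_months = 3L) {
  start_month <- as.integer(start_month)
  end_month <- as.integer(end_month)
  step_months <- as.integer(step_months)
  if (step_months <= 0L) stop("step_months must be positive")
  if (end_month <= start_month) stop("end_month must exceed start_month")
  if ((end_month - start_month) %% step_months != 0L) {
    stop("(end_month - start_month) must be divisible by step_months")
  }
  points <- seq.int(start_month, end_month, by = step_months)
  structure(
    list(
      start = start_month, end = end_month, step = step_months,
      points = points, n_intervals = length(points) - 1L
    ),
    class = "age_grid"
  )
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf(
    "Age grid: %d-%d months (%.0f-%.0f years), step %d months, %d intervals\n",
    x$start, x$end, x$start / 12, x$end / 12, x$step, x$n_intervals
  ))
  invisible(x)
}

#' Convert months of age to years
#' @param months age in months.
#' @return age in years (`months / 12`).
#' @export
months_to_years <- function(months) months / 12

#' Categorical levels of the study design
#'
#' `period_labels()`: the five five-year calendar periods of the study
#' window, 1996-2020 (first is the reference). `gender_levels()` and
#' `education_levels()`: the stratum labels used throughout.
#'
#' @return Character vector of labels.
#' @export
period_labels <- function() {
  c("1996-2000", "2001-2005", "2006-2010", "2011-2015", "2016-2020")
}

#' @rdname period_labels
#' @export
gender_levels <- function() c("women", "men")

#' @rdname period_labels
#' @export
education_levels <- function() c("basic", "secondary", "tertiary")

# grid-point index of an on-grid age (1-based); errors if off-grid
grid_index <- function(grid, age_month) {
  idx <- match(age_month, grid$points)
  if (is.na(idx)) {
    stop(sprintf("age %s months is not on the grid (%d-%d by %d)",
                 format(age_month), grid$start, grid$end, grid$step))
  }
  idx
}
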