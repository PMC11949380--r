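#' Forward state-occupancy recursion
#'
#' Propagates a start state through the Markov transition matrices of a
#' `transition_probs` object: the occupancy row vector at each grid point is
#' the previous one multiplied by the interval's transition matrix. Exact
#' given the probabilities.
#'
#' @param probs a `transition_probs`.
#' @param start_state a transient state label (`FREE` or `CVD`).
#' @param start_age starting age in months; must be a grid point strictly
#'   below the horizon.
#' @return An `occupancy_curve`: matrix with one row per grid point from
#'   `start_age` to the horizon and one column per state; row sums are 1 and
#'   DEAD occupancy is non-decreasing.
#' @examples
#' tp <- predict(scenario_model("baseline"), period = "1996-2000")
#' oc <- occupancy_forward(tp)
#' tail(oc, 1)   # distribution at age 100
#' @export
occupancy_forward <- function(probs, start_state = "FREE", start_age = 480) {
  stopifnot(inherits(probs, "transition_probs"))
  states <- state_space()$states
  start_state <- match.arg(start_state, state_space()$transient)
  grid <- probs$grid
  if (start_age >= grid$end) stop("start_age must be below the horizon ", grid$end)
  i0 <- grid_index(grid, start_age)
  npt <- length(grid$points) - i0 + 1L
  occ <- matrix(0, npt, 3L, dimnames = list(NULL, states))
  occ[1L, start_state] <- 1
  v <- occ[1L, ]
  for (k in seq_len(npt - 1L)) {
    v <- v %*% probs$p[i0 + k - 1L, , ]
    occ[k + 1L, ] <- v
  }
  structure(occ, ages = grid$points[i0:length(grid$points)],
            class = c("occupancy_curve", "matrix"))
}

#' First-passage distribution of disease onset
#'
#' Distribution of the interval in which the first FREE -> CVD transition
#' occurs for a cohort starting FREE at `start_age`: the probability of
#' having stayed FREE through every earlier interval times the interval's
#' incidence probability. Onset age is assigned to the destination grid
#' point of the transition interval (the assessment at which the event is
#' first observed). The total mass of the distribution is the lifetime
#' risk.
#'
#' @inheritParams occupancy_forward
#' @return A data frame with `interval`, `onset_age_month` (destination grid
#'   point) and `prob`; total mass in attribute `mass`.
#' @export
first_passage <- function(probs, start_age = 480) {
  stopifnot(inherits(probs, "transition_probs"))
  grid <- probs$grid
  if (start_age >= grid$end) stop("start_age must be below the horizon ", grid$end)
  i0 <- grid_index(grid, start_age)
  idx <- i0:grid$n_intervals
  p_stay <- probs$p[idx, "FREE", "FREE"]
  p_inc <- probs$p[idx, "FREE", "CVD"]
  surv <- c(1, cumprod(p_stay))[seq_along(idx)]  # P(FREE at interval start)
  f <- surv * p_inc
  out <- data.frame(
    interval = idx,
    onset_age_month = grid$points[idx + 1L],
    prob = f
  )
  attr(out, "mass") <- sum(f)
  out
}

#' Lifetime risk of disease
#'
#' Probability that a person FREE at `start_age` ever enters the CVD state
#' before death or the model horizon: the total mass of the first-passage
#' distribution.
#'
#' @inheritParams occupancy_forward
#' @return A proportion in [0, 1].
#' @export
lifetime_risk <- function(probs, start_age = 480) {
  attr(first_passage(probs, start_age), "mass")
}

#' Mean age at disease onset
#'
#' Expectation of the onset age under the first-passage distribution,
#' conditional on onset occurring before death or the horizon. Onset age is
#' the destination grid point of the transition interval. If the lifetime
#' risk is zero the mean is undefined: `NA` is returned with a warning.
#'
#' @inheritParams occupancy_forward
#' @return Mean onset age in years, or `NA` if onset is impossible.
#' @export
mean_onset_age <- function(probs, start_age = 480) {
  fp <- first_passage(probs, start_age)
  mass <- attr(fp, "mass")
  if (mass <= 0) {
    warning("lifetime risk is zero; mean onset age is undefined")
    return(NA_real_)
  }
  sum(fp$prob * fp$onset_age_month) / mass / 12
}

#' State expectancies from age 40
#'
#' Expected years spent in each transient state by a synthetic cohort
#' starting FREE at `start_age`, under a single period's transition
#' probabilities. Occupancy is counted at interval starts: each occupied
#' interval start contributes one quarter (0.25 years). The horizon is
#' truncated at the grid end (age 100); survivors there contribute nothing
#' further, so a deathless chain gives exactly 60 years from age 40.
#'
#' @inheritParams occupancy_forward
#' @return Named vector with `e_free`, `e_cvd`, `tle` (= e_free + e_cvd)
#'   and `pct_free` (100 * e_free / tle, unrounded).
#' @export
state_expectancies <- function(probs, start_age = 480, start_state = "FREE") {
  occ <- occupancy_forward(probs, start_state = start_state,
                           start_age = start_age)
  step_years <- probs$grid$step / 12
  starts <- seq_len(nrow(occ) - 1L)
  e_free <- step_years * sum(occ[starts, "FREE"])
  e_cvd <- step_years * sum(occ[starts, "CVD"])
  tle <- e_free + e_cvd
  c(e_free = e_free, e_cvd = e_cvd, tle = tle,
    pct_free = if (tle > 0) 100 * e_free / tle else NA_real_)
}

#' Conditional total life expectancy
#'
#' Expected remaining years alive for a person occupying `start_state`
#' (default CVD) at `start_age` (default 780 months = 65 years), with the
#' same interval-start occupancy counting and horizon truncation as
#' [state_expectancies()].
#'
#' @inheritParams occupancy_forward
#' @return Remaining life expectancy in years.
#' @export
conditional_tle <- function(probs, start_age = 780, start_state = "CVD") {
  e <- state_expectancies(probs, start_age = start_age,
                          start_state = start_state)
  unname(e["tle"])
}

#' All multistate metrics from one transition-probability context
#'
#' Computes the full metric set — lifetime risk, mean onset age, CVD-free
#' and CVD expectancy, total life expectancy, percent of life CVD-free
#' (all from FREE at `start_age`), and conditional TLE in the CVD state at
#' `cond_age` — by the matrix method.
#'
#' @inheritParams occupancy_forward
#' @param cond_age age (months) for the conditional-TLE metric.
#' @return A one-row `data.frame` (a metrics row) with the context labels
#'   and the seven metrics.
#' @export
multistate_metrics <- function(probs, start_age = 480, cond_age = 780) {
  e <- state_expectancies(probs, start_age = start_age)
  lr <- lifetime_risk(probs, start_age = start_age)
  onset <- if (lr > 0) mean_onset_age(probs, start_age = start_age) else {
    warning("lifetime risk is zero; mean onset age is undefined")
    NA_real_
  }
  metrics_row(
    period = probs$period, subgroup = probs$subgroup,
    lifetime_risk = lr, onset_age_mean = onset,
    e_free = unname(e["e_free"]), e_cvd = unname(e["e_cvd"]),
    tle = unname(e["tle"]), pct_free = unname(e["pct_free"]),
    tle65_cvd = conditional_tle(probs, start_age = cond_age)
  )
}

metrics_row <- function(period, subgroup, lifetime_risk, onset_age_mean,
                        e_free, e_cvd, tle, pct_free, tle65_cvd) {
  data.frame(
    period = period, subgroup = subgroup, lifetime_risk = lifetime_risk,
    onset_age_mean = onset_age_mean, e_free = e_free, e_cvd = e_cvd,
    tle = tle, pct_free = pct_free, tle65_cvd = tle65_cvd
  )
}

#' Microsimulation oracle for the matrix metrics
#'
#' Simulates `n` individual trajectories directly from a
#' `transition_probs` object and computes every metric empirically: a
#' cohort starting FREE at `start_age` (lifetime risk, onset age,
#' expectancies) and a second cohort starting in CVD at `cond_age`
#' (conditional TLE). Serves as an independent check on the matrix
#' functionals; agreement is expected within Monte-Carlo error.
#'
#' @inheritParams multistate_metrics
#' @param n number of simulated trajectories (>= 1).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return A metrics row as in [multistate_metrics()], with an `se`
#'   attribute holding Monte-Carlo standard errors for the six primary
#'   metrics.
#' @export
microsim_metrics <- function(probs, n, seed, start_age = 480, cond_age = 780) {
  stopifnot(inherits(probs, "transition_probs"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  set.seed(as.integer(seed))
  grid <- probs$grid
  step_years <- grid$step / 12

  sim_cohort <- function(i0, start_state) {
    state <- rep.int(match(start_state, state_space()$states), n)
    free_q <- integer(n)
    cvd_q <- integer(n)
    onset_t <- rep.int(NA_integer_, n)
    for (t in i0:grid$n_intervals) {
      alive <- which(state < 3L)
      if (length(alive) == 0L) break
      st <- state[alive]
      free_here <- alive[st == 1L]
      cvd_here <- alive[st == 2L]
      free_q[free_here] <- free_q[free_here] + 1L
      cvd_q[cvd_here] <- cvd_q[cvd_here] + 1L
      u <- stats::runif(length(alive))
      snext <- st
      if (length(free_here) > 0L) {
        uf <- u[st == 1L]
        pfc <- probs$p[t, "FREE", "CVD"]
        pfd <- probs$p[t, "FREE", "DEAD"]
        sf <- ifelse(uf < pfc, 2L, ifelse(uf < pfc + pfd, 3L, 1L))
        snext[st == 1L] <- sf
        new_onset <- free_here[sf == 2L]
        onset_t[new_onset] <- t
      }
      if (length(cvd_here) > 0L) {
        pcd <- probs$p[t, "CVD", "DEAD"]
        snext[st == 2L] <- ifelse(u[st == 2L] < pcd, 3L, 2L)
      }
      state[alive] <- snext
    }
    list(free_q = free_q, cvd_q = cvd_q, onset_t = onset_t)
  }

  i0 <- grid_index(grid, start_age)
  a <- sim_cohort(i0, "FREE")
  onset_years <- grid$points[a$onset_t + 1L] / 12
  had <- !is.na(a$onset_t)
  lr <- mean(had)
  onset_mean <- if (any(had)) mean(onset_years[had]) else NA_real_
  ef_i <- step_years * a$free_q
  ec_i <- step_years * a$cvd_q
  tle_i <- ef_i + ec_i

  ic <- grid_index(grid, cond_age)
  b <- sim_cohort(ic, "CVD")
  t65_i <- step_years * (b$free_q + b$cvd_q)

  row <- metrics_row(
    period = probs$period, subgroup = probs$subgroup,
    lifetime_risk = lr, onset_age_mean = onset_mean,
    e_free = mean(ef_i), e_cvd = mean(ec_i), tle = mean(tle_i),
    pct_free = if (mean(tle_i) > 0) 100 * mean(ef_i) / mean(tle_i) else NA_real_,
    tle65_cvd = mean(t65_i)
  )
  attr(row, "se") <- c(
    lifetime_risk = sqrt(lr * (1 - lr) / n),
    onset_age_mean = if (sum(had) > 1L) {
      stats::sd(onset_years[had]) / sqrt(sum(had))
    } else NA_real_,
    e_free = stats::sd(ef_i) / sqrt(n),
    e_cvd = stats::sd(ec_i) / sqrt(n),
    tle = stats::sd(tle_i) / sqrt(n),
    tle65_cvd = stats::sd(t65_i) / sqrt(n)
  )
  attr(row, "n") <- n
  row
}
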