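#' Transition-model objects
#'
#' A `transition_model` holds, for each transient origin state, the
#' multinomial-logit coefficients of the one-step (quarterly) transition
#' probabilities:
#' \deqn{\log(p_{ij} / p_{i,stay}) = a_{ij} + b_{1,ij} x + b_{2,ij} x^2 +
#'   \delta_{ij}^T Period}
#' where \eqn{x} is age in months, centered and scaled
#' (`(age - age_center) / age_scale`), `Period` is dummy-coded with the first
#' period as reference, and the reference destination is the "stay" state of
#' each origin (FREE -> FREE, CVD -> CVD). Predicted probabilities are
#' invariant to both the age scaling and the reference choice. For origin CVD
#' only one destination (DEAD) competes with staying, so the model reduces to
#' a binary logit.
#'
#' Objects come from [fit_transition_model()] (estimated from data) or
#' [scenario_model()] (known true parameters for simulation). True models may
#' additionally carry additive stratum shifts of the linear predictors by
#' gender and education, used by the synthetic generator.
#'
#' @param coef list with elements `FREE` (matrix, rows `CVD` and `DEAD`) and
#'   `CVD` (matrix, row `DEAD`); columns `(Intercept)`, `age`, `age2` and one
#'   dummy per non-reference period.
#' @param periods character vector of period labels; first is the reference.
#' @param age_center,age_scale centering and scaling constants for age in
#'   months.
#' @param grid an [age_grid()].
#' @param shifts optional list of per-transition stratum shifts (see
#'   [scenario_model()]); `NULL` for fitted models.
#' @param fit optional list of fit results (standard errors, vcov, logLik,
#'   counts, convergence), attached by [fit_transition_model()].
#' @return An object of class `transition_model`.
#' @keywords internal
new_transition_model <- function(coef, periods, age_center = 840,
                                 age_scale = 120, grid = age_grid(),
                                 shifts = NULL, fit = NULL) {
  stopifnot(is.list(coef), all(c("FREE", "CVD") %in% names(coef)))
  ncol_expect <- 3L + max(0L, length(periods) - 1L)
  for (org in c("FREE", "CVD")) {
    m <- coef[[org]]
    if (!is.matrix(m) || !all(is.finite(m))) {
      stop("coefficients for origin ", org, " must be a finite matrix")
    }
  }
  if (nrow(coef$FREE) != 2L || !identical(rownames(coef$FREE), c("CVD", "DEAD"))) {
    stop("coef$FREE must have rows CVD and DEAD")
  }
  if (nrow(coef$CVD) != 1L || !identical(rownames(coef$CVD), "DEAD")) {
    stop("coef$CVD must have the single row DEAD")
  }
  structure(
    list(
      coef = coef, periods = periods,
      age_center = age_center, age_scale = age_scale,
      grid = grid, reference = "stay", shifts = shifts, fit = fit
    ),
    class = "transition_model"
  )
}

model_coef_names <- function(periods) {
  c("(Intercept)", "age", "age2",
    if (length(periods) > 1L) periods[-1L] else character(0))
}

#' Known true transition models for synthetic scenarios
#'
#' Returns a fully parameterized quarterly transition model used by the
#' synthetic register generator. Coefficients are fixed constants chosen from
#' Gompertz-style hazard reasoning (see the package vignette): per-step
#' incidence and mortality rise with age, mortality from CVD exceeds
#' mortality from FREE at every age, and period effects lower mortality (and
#' mildly lower incidence) in later periods.
#'
#' Scenarios:
#' \describe{
#'   \item{`baseline`}{realistic age-increasing hazards; gender and education
#'     carried as labels but with no effect (exchangeable strata).}
#'   \item{`no_cvd`}{incidence intercept at -40, so disease onset effectively
#'     never occurs.}
#'   \item{`constant_hazard`}{age and period coefficients zero; per-step
#'     probabilities constant over age.}
#'   \item{`strong_gradient`}{baseline hazards plus a protective education
#'     gradient and higher male incidence and mortality (additive shifts of
#'     the linear predictors).}
#' }
#'
#' @param scenario_name one of `scenario_names()`.
#' @param grid an [age_grid()].
#' @return A `transition_model` with known parameters.
#' @examples
#' m <- scenario_model("baseline")
#' p <- predict(m, period = "1996-2000")
#' p$p[1, "FREE", ]   # one-step probabilities at age 40
#' @export
scenario_model <- function(scenario_name = scenario_names(), grid = age_grid()) {
  scenario_name <- match.arg(scenario_name)
  periods <- period_labels()
  cn <- model_coef_names(periods)
  mk <- function(int, b1, b2, delta) {
    stats::setNames(c(int, b1, b2, delta), cn)
  }
  # per-quarter scale; age x = (months - 840)/120, x in [-3, 3]
  base_free <- rbind(
    CVD  = mk(-4.96, 0.52, -0.04, c(-0.05, -0.10, -0.15, -0.20)),
    DEAD = mk(-5.99, 0.95,  0.08, c(-0.10, -0.20, -0.30, -0.40))
  )
  base_cvd <- rbind(
    DEAD = mk(-4.83, 0.92, 0.04, c(-0.10, -0.20, -0.30, -0.40))
  )
  shifts <- NULL
  if (scenario_name == "no_cvd") {
    base_free["CVD", "(Intercept)"] <- -40
  } else if (scenario_name == "constant_hazard") {
    base_free <- rbind(
      CVD  = mk(-4.20, 0, 0, c(0, 0, 0, 0)),
      DEAD = mk(-4.60, 0, 0, c(0, 0, 0, 0))
    )
    base_cvd <- rbind(DEAD = mk(-3.60, 0, 0, c(0, 0, 0, 0)))
  } else if (scenario_name == "strong_gradient") {
    shifts <- list(
      "FREE:CVD" = list(
        gender = c(women = 0, men = 0.30),
        education = c(basic = 0, secondary = -0.25, tertiary = -0.50)
      ),
      "FREE:DEAD" = list(
        gender = c(women = 0, men = 0.45),
        education = c(basic = 0, secondary = -0.25, tertiary = -0.50)
      ),
      "CVD:DEAD" = list(
        gender = c(women = 0, men = 0.45),
        education = c(basic = 0, secondary = -0.25, tertiary = -0.50)
      )
    )
  }
  m <- new_transition_model(
    coef = list(FREE = base_free, CVD = base_cvd),
    periods = periods, grid = grid, shifts = shifts
  )
  m$scenario <- scenario_name
  m
}

#' @rdname scenario_model
#' @export
scenario_names <- function() {
  c("baseline", "no_cvd", "constant_hazard", "strong_gradient")
}

# linear predictors for one origin at ages x (scaled), one period index,
# optional stratum shifts; returns matrix [length(x) x destinations]
model_eta <- function(model, origin, x, period, gender = NULL, education = NULL) {
  cf <- model$coef[[origin]]
  X <- cbind(1, x, x^2)
  if (length(model$periods) > 1L) {
    dum <- matrix(0, length(x), length(model$periods) - 1L)
    pidx <- match(period, model$periods)
    if (is.na(pidx)) stop("unknown period label: ", period)
    if (pidx > 1L) dum[, pidx - 1L] <- 1
    X <- cbind(X, dum)
  }
  eta <- X %*% t(cf)
  if (!is.null(model$shifts)) {
    for (d in rownames(cf)) {
      key <- paste0(origin, ":", d)
      sh <- model$shifts[[key]]
      if (is.null(sh)) next
      add <- 0
      if (!is.null(gender)) add <- add + unname(sh$gender[gender])
      if (!is.null(education)) add <- add + unname(sh$education[education])
      eta[, d] <- eta[, d] + add
    }
  }
  eta
}

# softmax over destinations incl. the reference "stay" state (eta = 0)
eta_to_probs <- function(eta) {
  denom <- 1 + rowSums(exp(eta))
  p <- exp(eta) / denom
  cbind(stay = 1 / denom, p)
}

#' Per-step transition probabilities on the age grid
#'
#' Evaluates a `transition_model` at every age interval of the grid for a
#' single period (and, for true models with stratum shifts, a single gender
#' and education context), returning the full row-stochastic transition
#' array. The selected period's dummy is set to 1 and all others to 0; the
#' reference period corresponds to all dummies 0. Probabilities are obtained
#' by inverse logit (softmax) over the allowed destinations of each origin.
#' Age is evaluated at the starting grid point of each interval.
#'
#' @param model a `transition_model`.
#' @param period a period label among `model$periods`.
#' @param gender,education optional stratum labels, used only when the model
#'   carries stratum shifts (scenario models); ignored with a warning never
#'   raised otherwise.
#' @param grid an [age_grid()]; defaults to the model's grid.
#' @param subgroup optional subgroup label stored in the result; derived from
#'   gender/education when missing.
#' @return A `transition_probs` object (see [transition_probs()]).
#' @export
predict_transition_probs <- function(model, period, gender = NULL,
                                     education = NULL, grid = NULL,
                                     subgroup = NULL) {
  stopifnot(inherits(model, "transition_model"))
  if (is.null(grid)) grid <- model$grid
  if (!period %in% model$periods) stop("unknown period label: ", period)
  ages <- grid$points[-length(grid$points)]  # interval starts
  x <- (ages - model$age_center) / model$age_scale
  states <- state_space()$states
  p <- array(0, dim = c(grid$n_intervals, 3, 3),
             dimnames = list(NULL, from = states, to = states))
  # origin FREE: destinations CVD, DEAD vs stay FREE
  pf <- eta_to_probs(model_eta(model, "FREE", x, period, gender, education))
  p[, "FREE", "FREE"] <- pf[, "stay"]
  p[, "FREE", "CVD"] <- pf[, "CVD"]
  p[, "FREE", "DEAD"] <- pf[, "DEAD"]
  # origin CVD: destination DEAD vs stay CVD
  pc <- eta_to_probs(model_eta(model, "CVD", x, period, gender, education))
  p[, "CVD", "CVD"] <- pc[, "stay"]
  p[, "CVD", "DEAD"] <- pc[, "DEAD"]
  p[, "DEAD", "DEAD"] <- 1
  if (is.null(subgroup)) {
    subgroup <- paste(c("total", gender, education), collapse = ":")
    if (!is.null(gender) || !is.null(education)) {
      subgroup <- paste(c(gender, education), collapse = ":")
    }
  }
  transition_probs(p, grid = grid, period = period, subgroup = subgroup)
}

#' @rdname predict_transition_probs
#' @param object a `transition_model`.
#' @param ... passed on to [predict_transition_probs()].
#' @export
predict.transition_model <- function(object, ...) {
  predict_transition_probs(object, ...)
}

#' Transition-probability array
#'
#' Container for the per-step transition probabilities of one period and
#' subgroup context: an array indexed by (age interval, origin state,
#' destination state). The constructor validates the invariants: every origin
#' row sums to 1 within 1e-12, forbidden transitions (CVD -> FREE, DEAD ->
#' transient) are exactly zero, the DEAD row is the identity row, and all
#' entries lie in [0, 1].
#'
#' @param p numeric array `[n_intervals, 3, 3]` with state dimnames
#'   `FREE, CVD, DEAD`.
#' @param grid the [age_grid()] the intervals refer to.
#' @param period,subgroup context metadata labels.
#' @return An object of class `transition_probs`.
#' @export
transition_probs <- function(p, grid = age_grid(), period = NA_character_,
                             subgroup = "total") {
  states <- state_space()$states
  if (!is.array(p) || !identical(dim(p), c(grid$n_intervals, 3L, 3L))) {
    stop("p must be an [n_intervals x 3 x 3] array matching the grid")
  }
  dimnames(p) <- list(NULL, from = states, to = states)
  if (any(p < -1e-15) || any(p > 1 + 1e-15)) {
    stop("transition probabilities must lie in [0, 1]")
  }
  if (any(p[, "CVD", "FREE"] != 0)) stop("forbidden transition CVD -> FREE must be exactly 0")
  if (any(p[, "DEAD", "FREE"] != 0) || any(p[, "DEAD", "CVD"] != 0) ||
      any(p[, "DEAD", "DEAD"] != 1)) {
    stop("DEAD row must be the identity row")
  }
  rs <- apply(p, c(1, 2), sum)
  if (max(abs(rs - 1)) > 1e-12) {
    stop("origin rows must sum to 1 within 1e-12 (max deviation ",
         format(max(abs(rs - 1))), ")")
  }
  structure(
    list(p = p, grid = grid, period = period, subgroup = subgroup),
    class = "transition_probs"
  )
}

#' @export
print.transition_probs <- function(x, ...) {
  cat(sprintf(
    "Per-step transition probabilities: %d intervals, period %s, subgroup %s\n",
    x$grid$n_intervals, x$period, x$subgroup
  ))
  a40 <- x$p[1, "FREE", ]
  cat("  at age 40, from FREE:",
      paste(sprintf("%s %.5f", names(a40), a40), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.transition_probs <- function(x, log = "y", ...) {
  ages <- x$grid$points[-length(x$grid$points)] / 12
  ys <- cbind(
    `FREE -> CVD` = x$p[, "FREE", "CVD"],
    `FREE -> DEAD` = x$p[, "FREE", "DEAD"],
    `CVD -> DEAD` = x$p[, "CVD", "DEAD"]
  )
  graphics::matplot(ages, pmax(ys, 1e-12), type = "l", lty = 1, lwd = 2,
                    col = c("#1b7837", "#2166ac", "#b2182b"), log = log,
                    xlab = "Age (years)", ylab = "Per-quarter probability",
                    main = sprintf("Transition probabilities (%s, %s)",
                                   x$period, x$subgroup), ...)
  graphics::legend("topleft", colnames(ys), lty = 1, lwd = 2, bty = "n",
                   col = c("#1b7837", "#2166ac", "#b2182b"))
  invisible(x)
}

#' Export transition probabilities as a long table
#'
#' @param probs a `transition_probs` object or list of them.
#' @return A data frame with columns `age_month`, `origin`, `destination`,
#'   `probability`, `period`, `subgroup` (allowed transitions only).
#' @export
transition_probs_table <- function(probs) {
  if (inherits(probs, "transition_probs")) probs <- list(probs)
  out <- lapply(probs, function(tp) {
    ages <- tp$grid$points[-length(tp$grid$points)]
    pairs <- list(c("FREE", "FREE"), c("FREE", "CVD"), c("FREE", "DEAD"),
                  c("CVD", "CVD"), c("CVD", "DEAD"))
    do.call(rbind, lapply(pairs, function(pr) {
      data.frame(
        age_month = ages, origin = pr[1], destination = pr[2],
        probability = tp$p[, pr[1], pr[2]],
        period = tp$period, subgroup = tp$subgroup
      )
    }))
  })
  do.call(rbind, out)
}
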