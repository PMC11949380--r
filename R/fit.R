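#' Aggregate a person-period panel into transition counts
#'
#' Collapses person-period rows into counts per (age, period, gender,
#' education, origin, destination) cell. The multinomial likelihood of the
#' grouped counts is identical (up to a constant) to the row-level
#' likelihood, so fitting on counts gives the same estimates and standard
#' errors at a fraction of the cost.
#'
#' @param panel a person-period data frame.
#' @param grid the [age_grid()].
#' @return A `transition_counts` data frame.
#' @export
aggregate_transitions <- function(panel, grid = age_grid()) {
  if (nrow(panel) == 0L) return(empty_counts(grid))
  tb <- table(
    age_month = factor(panel$age_month, levels = grid$points[-length(grid$points)]),
    period = panel$period, gender = panel$gender, education = panel$education,
    state_now = panel$state_now, state_next = panel$state_next
  )
  df <- as.data.frame(tb, responseName = "n", stringsAsFactors = TRUE)
  df <- df[df$n > 0L, , drop = FALSE]
  df$age_month <- as.integer(as.character(df$age_month))
  df$state_now <- factor(as.character(df$state_now), levels = c("FREE", "CVD"))
  df$state_next <- factor(as.character(df$state_next), levels = state_space()$states)
  df <- df[order(df$age_month, df$period, df$gender, df$education,
                 df$state_now, df$state_next), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("transition_counts", "data.frame"), grid = grid)
}

as_transition_counts <- function(data, grid) {
  if (inherits(data, "transition_counts")) return(data)
  aggregate_transitions(data, grid)
}

# grouped multinomial log-likelihood; Y [cells x dest incl. ref first],
# eta [cells x nonref dests]
grouped_loglik <- function(Y, eta) {
  logdenom <- log1p(rowSums(exp(eta)))
  ll <- -rowSums(Y) * logdenom
  ll <- ll + rowSums(Y[, -1L, drop = FALSE] * eta)
  sum(ll)
}

# Newton-Raphson for the grouped multinomial logit; B [m x p] start values.
# Returns list(B, vcov, loglik, iter, converged).
newton_multinom <- function(X, Y, B) {
  m <- ncol(Y) - 1L
  p <- ncol(X)
  N <- rowSums(Y)
  ll_at <- function(B) grouped_loglik(Y, X %*% t(B))
  ll <- ll_at(B)
  converged <- FALSE
  iter <- 0L
  H <- NULL
  for (iter in seq_len(50L)) {
    eta <- X %*% t(B)
    E <- exp(eta)
    P <- E / (1 + rowSums(E))
    G <- crossprod(X, Y[, -1L, drop = FALSE] - N * P)  # [p x m]
    H <- matrix(0, m * p, m * p)
    for (j in seq_len(m)) {
      for (k in seq_len(j)) {
        w <- if (j == k) N * P[, j] * (1 - P[, j]) else -N * P[, j] * P[, k]
        blk <- crossprod(X, X * w)
        rj <- (j - 1L) * p + seq_len(p)
        rk <- (k - 1L) * p + seq_len(p)
        H[rj, rk] <- -blk
        if (j != k) H[rk, rj] <- -blk
      }
    }
    step <- tryCatch(solve(-H, as.vector(G)), error = function(e) NULL)
    if (is.null(step)) break
    sc <- 1
    repeat {
      Bn <- B + matrix(sc * step, m, p, byrow = TRUE)
      lln <- ll_at(Bn)
      if (is.finite(lln) && lln >= ll - 1e-10) break
      sc <- sc / 2
      if (sc < 1e-8) break
    }
    moved <- max(abs(Bn - B))
    B <- Bn
    ll <- lln
    if (max(abs(G)) < 1e-8 && moved < 1e-10) {
      converged <- TRUE
      break
    }
  }
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, m * p, m * p))
  list(B = B, vcov = vc, loglik = ll, iter = iter, converged = converged)
}

# design matrix for one origin's cells
fit_design <- function(age_month, period, covariates, age_center, age_scale,
                       periods_used) {
  x <- (age_month - age_center) / age_scale
  X <- matrix(1, length(x), 1, dimnames = list(NULL, "(Intercept)"))
  if ("age" %in% covariates) X <- cbind(X, age = x)
  if ("age2" %in% covariates) X <- cbind(X, age2 = x^2)
  if ("period" %in% covariates && length(periods_used) > 1L) {
    for (pl in periods_used[-1L]) {
      X <- cbind(X, as.numeric(period == pl))
      colnames(X)[ncol(X)] <- pl
    }
  }
  X
}

fit_one_origin <- function(counts, origin, covariates, age_center, age_scale,
                           periods_used) {
  sub <- counts[as.character(counts$state_now) == origin, , drop = FALSE]
  if (nrow(sub) == 0L || sum(sub$n) == 0L) {
    stop("no observations with origin state ", origin)
  }
  dests <- if (origin == "FREE") c("FREE", "CVD", "DEAD") else c("CVD", "DEAD")
  tot <- tapply(sub$n, factor(as.character(sub$state_next), levels = dests), sum)
  tot[is.na(tot)] <- 0
  zero <- names(tot)[tot == 0]
  if (length(zero) > 0L) {
    stop(sprintf(
      "perfect separation fitting origin %s: destination %s never observed (intercept diverges)",
      origin, paste(zero, collapse = ", ")
    ))
  }
  # collapse to covariate cells
  cell <- interaction(sub$age_month, sub$period, drop = TRUE)
  keys <- !duplicated(cell)
  age_c <- sub$age_month[keys]
  per_c <- sub$period[keys]
  Y <- matrix(0, sum(keys), length(dests), dimnames = list(NULL, dests))
  ci <- match(cell, cell[keys])
  di <- match(as.character(sub$state_next), dests)
  for (r in seq_len(nrow(sub))) Y[ci[r], di[r]] <- Y[ci[r], di[r]] + sub$n[r]
  X <- fit_design(age_c, per_c, covariates, age_center, age_scale, periods_used)
  m <- length(dests) - 1L
  p <- ncol(X)
  # warm start from nnet, fall back to zero start
  B0 <- matrix(0, m, p)
  st <- tryCatch({
    fit0 <- nnet::multinom(Y ~ X - 1, trace = FALSE, maxit = 200)
    cf <- stats::coef(fit0)
    if (is.null(dim(cf))) cf <- matrix(cf, 1L, p)
    cf
  }, error = function(e) NULL)
  if (!is.null(st) && all(is.finite(st)) && identical(dim(st), c(m, p))) B0 <- st
  nf <- newton_multinom(X, Y, B0)
  if (max(abs(nf$B)) > 30) {
    worst <- which(abs(nf$B) == max(abs(nf$B)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "perfect separation fitting origin %s: coefficient for %s (destination %s) diverges",
      origin, colnames(X)[worst[2]], dests[-1L][worst[1]]
    ))
  }
  B <- nf$B
  dimnames(B) <- list(dests[-1L], colnames(X))
  se <- matrix(sqrt(pmax(diag(nf$vcov), 0)), m, p, byrow = TRUE,
               dimnames = dimnames(B))
  list(coef = B, se = se, vcov = nf$vcov, loglik = nf$loglik,
       n_obs = sum(Y), n_cells = nrow(Y), iter = nf$iter,
       converged = nf$converged, coef_names = colnames(X))
}

# expand fitted per-origin coefficients to the full model column layout
expand_coef <- function(B, periods) {
  cn <- model_coef_names(periods)
  out <- matrix(0, nrow(B), length(cn), dimnames = list(rownames(B), cn))
  out[, colnames(B)] <- B
  out
}

#' Fit the multinomial-logit transition model
#'
#' Maximum-likelihood fit of the per-step transition probabilities as
#' multinomial logistic regressions of the next state on age, age squared
#' and calendar period, run separately for each transient origin state
#' (FREE: three-destination multinomial; CVD: binary stay-or-die logit,
#' the degenerate case of the same model). The reference destination is the
#' origin's "stay" state and the reference period the first period present
#' in the data; predicted probabilities are invariant to both choices and
#' to the age centering/scaling constants.
#'
#' The fit aggregates the data to covariate-cell counts, takes a
#' [nnet::multinom()] warm start, and polishes with Newton-Raphson on the
#' grouped likelihood to near machine precision; standard errors come from
#' the analytic Hessian at the optimum. Perfect separation (a destination
#' never observed, or a diverging coefficient) is reported as an error
#' rather than silently penalized.
#'
#' @param data a person-period panel or a `transition_counts` aggregate.
#' @param covariates subset of `c("age", "age2", "period")`; the intercept
#'   is always included. The default is the full specification.
#' @param stratum optional named list, e.g. `list(gender = "women")`, that
#'   restricts the fit to one stratum. Stratifying variables are never
#'   entered as covariates.
#' @param age_center,age_scale age scaling constants (months); stored with
#'   the model so predictions are exact.
#' @param grid the [age_grid()].
#' @return A fitted `transition_model`; see [new_transition_model()]. The
#'   `fit` element carries per-origin standard errors, covariance matrices,
#'   log-likelihoods and convergence diagnostics.
#' @examples
#' cfg <- scenario_config(n_persons = 2000, seed = 7)
#' cnt <- simulate_individuals(scenario_model("baseline"), cfg, format = "counts")
#' fit <- fit_transition_model(cnt)
#' summary(fit)
#' @export
fit_transition_model <- function(data, covariates = c("age", "age2", "period"),
                                 stratum = NULL, age_center = 840,
                                 age_scale = 120, grid = age_grid()) {
  if (length(covariates) > 0L) {
    covariates <- match.arg(covariates, several.ok = TRUE)
  }
  counts <- as_transition_counts(data, grid)
  if (!is.null(stratum)) {
    for (v in names(stratum)) {
      counts <- counts[as.character(counts[[v]]) %in% stratum[[v]], , drop = FALSE]
    }
  }
  if (nrow(counts) == 0L || sum(counts$n) == 0L) {
    stop("no observations to fit", if (!is.null(stratum)) {
      paste0(" in stratum ", paste(unlist(stratum), collapse = ":"))
    } else "")
  }
  present <- tapply(counts$n, counts$period, sum)
  periods_used <- period_labels()[!is.na(present) & present > 0]
  fits <- list(
    FREE = fit_one_origin(counts, "FREE", covariates, age_center, age_scale,
                          periods_used),
    CVD = fit_one_origin(counts, "CVD", covariates, age_center, age_scale,
                         periods_used)
  )
  coef <- list(FREE = expand_coef(fits$FREE$coef, periods_used),
               CVD = expand_coef(fits$CVD$coef, periods_used))
  m <- new_transition_model(
    coef = coef, periods = periods_used, age_center = age_center,
    age_scale = age_scale, grid = grid,
    fit = list(
      FREE = fits$FREE[c("se", "vcov", "loglik", "n_obs", "n_cells",
                         "iter", "converged", "coef_names")],
      CVD = fits$CVD[c("se", "vcov", "loglik", "n_obs", "n_cells",
                       "iter", "converged", "coef_names")],
      covariates = covariates, stratum = stratum
    )
  )
  m
}

#' Fit transition models for the study subpopulations
#'
#' Fits the transition model separately for each subpopulation of a
#' stratification scheme: `"total"` (one model on all data), `"by_gender"`
#' (two models), or `"by_gender_education"` (six models, gender crossed
#' with education). Stratum models never include the stratifying
#' variable(s) as covariates — the gender models do not control for
#' education and vice versa, so each stratum's probabilities describe that
#' subpopulation as it exists.
#'
#' @param data a person-period panel or `transition_counts`.
#' @param scheme stratification scheme.
#' @param ... passed to [fit_transition_model()].
#' @return A named list of `transition_model`s of class
#'   `transition_model_set`; names are `total`, `women`/`men`, or
#'   `women_basic` ... `men_tertiary`.
#' @export
fit_stratified <- function(data, scheme = c("total", "by_gender",
                                            "by_gender_education"), ...) {
  scheme <- match.arg(scheme)
  counts <- as_transition_counts(data, age_grid())
  strata <- switch(scheme,
    total = list(total = NULL),
    by_gender = {
      s <- lapply(gender_levels(), function(g) list(gender = g))
      names(s) <- gender_levels()
      s
    },
    by_gender_education = {
      s <- list()
      for (g in gender_levels()) {
        for (e in education_levels()) {
          s[[paste(g, e, sep = "_")]] <- list(gender = g, education = e)
        }
      }
      s
    }
  )
  models <- vector("list", length(strata))
  names(models) <- names(strata)
  for (nm in names(strata)) {
    models[[nm]] <- tryCatch(
      fit_transition_model(counts, stratum = strata[[nm]], ...),
      error = function(e) {
        stop(sprintf("stratum %s: %s", nm, conditionMessage(e)), call. = FALSE)
      }
    )
    models[[nm]]$stratum_label <- nm
  }
  structure(models, class = "transition_model_set", scheme = scheme)
}

#' @export
print.transition_model_set <- function(x, ...) {
  cat(sprintf("Stratified transition models (scheme %s): %s\n",
              attr(x, "scheme"), paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Grouped log-likelihood of a transition model on data
#'
#' Evaluates the multinomial log-likelihood of any `transition_model`
#' (fitted or true) on a person-period panel or count aggregate. Useful for
#' likelihood comparisons, e.g. checking that a fitted model's likelihood
#' is at least that of the generating parameters on the same data.
#'
#' @param model a `transition_model`.
#' @param data a person-period panel or `transition_counts`.
#' @return The log-likelihood (sum of `n * log p(state_next)` over rows).
#' @export
transition_loglik <- function(model, data) {
  counts <- as_transition_counts(data, model$grid)
  if (nrow(counts) == 0L) stop("no observations")
  states <- state_space()$states
  ll <- 0
  for (origin in c("FREE", "CVD")) {
    sub <- counts[as.character(counts$state_now) == origin, , drop = FALSE]
    if (nrow(sub) == 0L) next
    for (per in unique(as.character(sub$period))) {
      sp <- sub[as.character(sub$period) == per, , drop = FALSE]
      key <- paste(sp$gender, sp$education)
      for (k in unique(key)) {
        sk <- sp[key == k, , drop = FALSE]
        g <- as.character(sk$gender[1]); e <- as.character(sk$education[1])
        x <- (sk$age_month - model$age_center) / model$age_scale
        pm <- eta_to_probs(model_eta(model, origin, x, per,
                                     gender = if (is.null(model$shifts)) NULL else g,
                                     education = if (is.null(model$shifts)) NULL else e))
        dest <- as.character(sk$state_next)
        pcol <- ifelse(dest == origin, "stay", dest)
        ll <- ll + sum(sk$n * log(pm[cbind(seq_len(nrow(sk)), match(pcol, colnames(pm)))]))
      }
    }
  }
  ll
}

#' @export
coef.transition_model <- function(object, origin = NULL, ...) {
  if (is.null(origin)) return(object$coef)
  object$coef[[match.arg(origin, c("FREE", "CVD"))]]
}

#' @export
vcov.transition_model <- function(object, origin = c("FREE", "CVD"), ...) {
  if (is.null(object$fit)) stop("model has no fit information (true model?)")
  object$fit[[match.arg(origin)]]$vcov
}

#' @export
logLik.transition_model <- function(object, ...) {
  if (is.null(object$fit)) stop("model has no fit information (true model?)")
  ll <- object$fit$FREE$loglik + object$fit$CVD$loglik
  npar <- length(object$fit$FREE$coef_names) * 2L +
    length(object$fit$CVD$coef_names)
  structure(ll, df = npar, nobs = object$fit$FREE$n_obs + object$fit$CVD$n_obs,
            class = "logLik")
}

#' @export
print.transition_model <- function(x, ...) {
  kind <- if (is.null(x$fit)) {
    sprintf("true model (scenario %s)", x$scenario %||% "custom")
  } else {
    sprintf("fitted on %s person-quarters",
            format(x$fit$FREE$n_obs + x$fit$CVD$n_obs, big.mark = ","))
  }
  cat("Quarterly multinomial-logit transition model,", kind, "\n")
  cat("Periods:", paste(x$periods, collapse = ", "),
      sprintf("(reference %s)\n", x$periods[1]))
  cat(sprintf("Age scaling: (months - %g) / %g\n", x$age_center, x$age_scale))
  for (org in c("FREE", "CVD")) {
    cat("\nOrigin", org, "(reference destination: stay):\n")
    print(round(x$coef[[org]], 4))
  }
  invisible(x)
}

#' @export
summary.transition_model <- function(object, ...) {
  out <- list(model = object, tables = list())
  for (org in c("FREE", "CVD")) {
    cf <- object$coef[[org]]
    if (!is.null(object$fit)) {
      used <- object$fit[[org]]$coef_names
      se <- object$fit[[org]]$se
      tb <- data.frame(
        destination = rep(rownames(cf), each = length(used)),
        term = rep(used, nrow(cf)),
        estimate = as.vector(t(cf[, used, drop = FALSE])),
        std_error = as.vector(t(se))
      )
      tb$z <- tb$estimate / tb$std_error
      out$tables[[org]] <- tb
    } else {
      out$tables[[org]] <- data.frame(
        destination = rep(rownames(cf), each = ncol(cf)),
        term = rep(colnames(cf), nrow(cf)),
        estimate = as.vector(t(cf))
      )
    }
  }
  class(out) <- "summary.transition_model"
  out
}

#' @export
print.summary.transition_model <- function(x, ...) {
  print(x$model)
  for (org in names(x$tables)) {
    cat("\nCoefficients, origin", org, ":\n")
    print(x$tables[[org]], row.names = FALSE, digits = 4)
    if (!is.null(x$model$fit)) {
      fi <- x$model$fit[[org]]
      cat(sprintf("logLik %.2f on %s rows (%d cells), Newton iterations %d, converged %s\n",
                  fi$loglik, format(fi$n_obs, big.mark = ","), fi$n_cells,
                  fi$iter, fi$converged))
    }
  }
  invisible(x)
}

#' @export
simulate.transition_model <- function(object, nsim = 1, seed = NULL, ...) {
  cfg <- scenario_config(n_persons = nsim, seed = seed, ...)
  simulate_individuals(object, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a transition model to a structured text file
#'
#' Writes/reads the coefficients, period labels, age-scaling constants and
#' reference conventions as YAML, so models can be archived and re-used
#' without refitting.
#'
#' @param model a `transition_model`.
#' @param path file path.
#' @return `read_transition_model` returns the `transition_model`.
#' @export
write_transition_model <- function(model, path) {
  obj <- list(
    periods = model$periods,
    age_center = model$age_center, age_scale = model$age_scale,
    reference = model$reference,
    grid = list(start = model$grid$start, end = model$grid$end,
                step = model$grid$step),
    coef = lapply(model$coef, function(m) {
      lapply(seq_len(nrow(m)), function(i) {
        list(destination = rownames(m)[i],
             values = as.list(stats::setNames(m[i, ], colnames(m))))
      })
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_transition_model
#' @export
read_transition_model <- function(path) {
  obj <- yaml::read_yaml(path)
  cn <- model_coef_names(obj$periods)
  coef <- lapply(obj$coef, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) unlist(r$values)[cn]))
    rownames(m) <- vapply(rows, function(r) r$destination, character(1))
    colnames(m) <- cn
    m
  })
  new_transition_model(
    coef = coef, periods = obj$periods,
    age_center = obj$age_center, age_scale = obj$age_scale,
    grid = age_grid(obj$grid$start, obj$grid$end, obj$grid$step)
  )
}
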