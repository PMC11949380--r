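#' Configuration of a synthetic register scenario
#'
#' Describes the population whose quarterly trajectories the generator
#' simulates: cohort size, seed, entry distribution over calendar time,
#' gender and education, and the observation-window rule. Calendar time is
#' indexed in quarters with 0 = first quarter of 1996; the observation
#' window spans quarters 0-99 (1996-2020), split into five 5-year periods
#' of 20 quarters each.
#'
#' Every person enters the model FREE at exactly 480 months (age 40) — or in
#' CVD with probability `start_cvd_prob` — at a calendar quarter drawn
#' uniformly from `entry_quarters`, and evolves until death or age 100.
#' With `observe = "window"` (the register-entry rule) only person-quarters
#' falling inside the calendar window are emitted, so people who turned 40
#' before 1996 are left-truncated and contribute only their in-window old
#' ages, as in an administrative register. `observe = "all"` keeps every
#' person-quarter (periods outside the window are clamped to the nearest
#' period regime).
#'
#' @param n_persons number of simulated persons (0 allowed: empty output).
#' @param seed integer RNG seed; mandatory for simulation.
#' @param gender_probs named probabilities for `women`/`men`; sum to 1.
#' @param education_probs either a named length-3 probability vector
#'   (`basic`, `secondary`, `tertiary`), or a 5 x 3 matrix of per-period
#'   probabilities (rows = periods) applied according to each person's entry
#'   period — this is how an upward education drift across periods is
#'   specified. Each row must sum to 1.
#' @param entry_quarters integer vector of calendar quarters (0 = 1996Q1)
#'   from which each person's age-40 quarter is drawn uniformly. The default
#'   `-239:99` lets entry cohorts range from people aged ~100 at the window
#'   start to people turning 40 in its last quarter, giving register-like
#'   age-period coverage.
#' @param start_cvd_prob probability of entering in the CVD state at age 40.
#' @param observe `"window"` (default) or `"all"`, see above.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_persons, seed = NULL,
                            gender_probs = c(women = 0.5, men = 0.5),
                            education_probs = c(basic = 0.35, secondary = 0.35,
                                                tertiary = 0.30),
                            entry_quarters = -239:99,
                            start_cvd_prob = 0,
                            observe = c("window", "all")) {
  observe <- match.arg(observe)
  n_persons <- as.integer(n_persons)
  if (is.na(n_persons) || n_persons < 0L) stop("n_persons must be >= 0")
  if (abs(sum(gender_probs) - 1) > 1e-12 || any(gender_probs < 0)) {
    stop("gender_probs must be non-negative and sum to 1")
  }
  if (is.matrix(education_probs)) {
    if (!identical(dim(education_probs), c(5L, 3L))) {
      stop("education_probs matrix must be 5 periods x 3 levels")
    }
    if (any(abs(rowSums(education_probs) - 1) > 1e-12) || any(education_probs < 0)) {
      stop("each education_probs row must be a probability vector summing to 1")
    }
  } else {
    if (length(education_probs) != 3L ||
        abs(sum(education_probs) - 1) > 1e-12 || any(education_probs < 0)) {
      stop("education_probs must be 3 non-negative proportions summing to 1")
    }
    education_probs <- matrix(rep(education_probs, each = 5), 5, 3)
  }
  colnames(education_probs) <- education_levels()
  if (length(entry_quarters) < 1L) stop("entry_quarters must be non-empty")
  if (start_cvd_prob < 0 || start_cvd_prob > 1) {
    stop("start_cvd_prob must be in [0, 1]")
  }
  structure(
    list(
      n_persons = n_persons, seed = seed,
      gender_probs = gender_probs, education_probs = education_probs,
      entry_quarters = as.integer(entry_quarters),
      start_cvd_prob = start_cvd_prob, observe = observe
    ),
    class = "scenario_config"
  )
}

# period index (1..5) of a calendar quarter, clamped outside the window
quarter_to_period_idx <- function(q) {
  pmin(pmax(q %/% 20L + 1L, 1L), 5L)
}

empty_panel <- function() {
  data.frame(
    person_id = integer(0),
    age_month = integer(0),
    period = factor(character(0), levels = period_labels()),
    gender = factor(character(0), levels = gender_levels()),
    education = factor(character(0), levels = education_levels()),
    state_now = factor(character(0), levels = c("FREE", "CVD")),
    state_next = factor(character(0), levels = state_space()$states),
    calendar_quarter = integer(0)
  )
}

# per-step probability lookup arrays [n_intervals, 5 periods, 2 genders, 3 edu]
step_prob_arrays <- function(model, grid) {
  ni <- grid$n_intervals
  ages <- grid$points[-length(grid$points)]
  x <- (ages - model$age_center) / model$age_scale
  p_fc <- p_fd <- p_cd <- array(0, dim = c(ni, 5L, 2L, 3L))
  gl <- gender_levels(); el <- education_levels()
  for (pi in seq_len(5L)) {
    for (gi in 1:2) {
      for (ei in 1:3) {
        pf <- eta_to_probs(model_eta(model, "FREE", x, period_labels()[pi],
                                     gender = gl[gi], education = el[ei]))
        pc <- eta_to_probs(model_eta(model, "CVD", x, period_labels()[pi],
                                     gender = gl[gi], education = el[ei]))
        p_fc[, pi, gi, ei] <- pf[, "CVD"]
        p_fd[, pi, gi, ei] <- pf[, "DEAD"]
        p_cd[, pi, gi, ei] <- pc[, "DEAD"]
      }
    }
  }
  list(fc = p_fc, fd = p_fd, cd = p_cd)
}

#' Simulate register-like quarterly trajectories
#'
#' Generates person-period records from a known `transition_model` under a
#' [scenario_config()]. Each person starts at 480 months and is advanced one
#' quarter at a time by sampling the next state from the model's one-step
#' probabilities for the person's current age, calendar period, gender and
#' education; simulation stops at death or age 100. Output rows are the
#' person-quarters selected by the observation rule of the config.
#'
#' Randomness is consumed in a fixed, documented order — entry
#' characteristics first (gender, entry quarter, education, initial state),
#' then one uniform draw per alive person per age step, age-major with
#' persons in index order — so the output is byte-identical across runs with
#' the same seed and config, for either output format.
#'
#' @param model a `transition_model` (typically [scenario_model()]).
#' @param config a [scenario_config()]; its `seed` must be set.
#' @param format `"panel"` returns the person-period table (one row per
#'   person-quarter); `"counts"` returns the aggregated transition counts
#'   (identical information for estimation, far smaller for large cohorts).
#' @return A `data.frame`: the person-period panel with columns `person_id`,
#'   `age_month`, `period`, `gender`, `education`, `state_now`, `state_next`,
#'   `calendar_quarter`; or a `transition_counts` aggregate with a final
#'   `n` column instead of person identifiers.
#' @examples
#' cfg <- scenario_config(n_persons = 100, seed = 1)
#' pp <- simulate_individuals(scenario_model("baseline"), cfg)
#' head(pp)
#' @export
simulate_individuals <- function(model, config, format = c("panel", "counts")) {
  format <- match.arg(format)
  stopifnot(inherits(model, "transition_model"), inherits(config, "scenario_config"))
  grid <- model$grid
  if (grid$n_intervals < 1L) stop("model grid has no intervals")
  n <- config$n_persons
  if (n == 0L) {
    if (format == "panel") return(empty_panel())
    return(empty_counts())
  }
  if (is.null(config$seed)) stop("config$seed must be set for simulation")
  set.seed(as.integer(config$seed))
  ni <- grid$n_intervals

  # entry characteristics (fixed draw order)
  gender <- 1L + as.integer(stats::runif(n) > config$gender_probs["women"])
  eq <- config$entry_quarters
  q0 <- eq[1L + as.integer(floor(stats::runif(n) * length(eq)))]
  ep <- quarter_to_period_idx(q0)
  cum1 <- config$education_probs[, 1L]
  cum2 <- cum1 + config$education_probs[, 2L]
  ue <- stats::runif(n)
  education <- 1L + as.integer(ue > cum1[ep]) + as.integer(ue > cum2[ep])
  state <- rep(1L, n)
  if (config$start_cvd_prob > 0) {
    state[stats::runif(n) < config$start_cvd_prob] <- 2L
  }

  pr <- step_prob_arrays(model, grid)
  in_window <- config$observe == "window"

  counts <- integer(ni * 5L * 2L * 3L * 5L)  # (t, period, gender, edu, ttype)
  rows <- if (format == "panel") vector("list", ni) else NULL

  for (t in seq_len(ni)) {
    alive <- which(state < 3L)
    if (length(alive) == 0L) break
    qcur <- q0[alive] + (t - 1L)
    per <- quarter_to_period_idx(qcur)
    g <- gender[alive]; e <- education[alive]
    snow <- state[alive]
    u <- stats::runif(length(alive))
    snext <- snow
    isf <- snow == 1L
    if (any(isf)) {
      ii <- cbind(t, per[isf], g[isf], e[isf])
      pfc <- pr$fc[ii]; pfd <- pr$fd[ii]
      sf <- ifelse(u[isf] < pfc, 2L, ifelse(u[isf] < pfc + pfd, 3L, 1L))
      snext[isf] <- sf
    }
    isc <- snow == 2L
    if (any(isc)) {
      pcd <- pr$cd[cbind(t, per[isc], g[isc], e[isc])]
      snext[isc] <- ifelse(u[isc] < pcd, 3L, 2L)
    }
    obs <- if (in_window) (qcur >= 0L & qcur <= 99L) else rep(TRUE, length(alive))
    if (any(obs)) {
      if (format == "counts") {
        ttype <- ifelse(snow[obs] == 1L, snext[obs],
                        ifelse(snext[obs] == 2L, 4L, 5L))
        idx <- ((((t - 1L) * 5L + (per[obs] - 1L)) * 2L +
                   (g[obs] - 1L)) * 3L + (e[obs] - 1L)) * 5L + ttype
        counts <- counts + tabulate(idx, nbins = length(counts))
      } else {
        rows[[t]] <- list(
          pid = alive[obs], per = per[obs], g = g[obs], e = e[obs],
          snow = snow[obs], snext = snext[obs], q = qcur[obs]
        )
      }
    }
    state[alive] <- snext
  }

  if (format == "counts") return(counts_from_vector(counts, grid))

  keep <- !vapply(rows, is.null, logical(1))
  tidx <- which(keep)
  nper <- vapply(rows[keep], function(r) length(r$pid), integer(1))
  tt <- rep(tidx, nper)
  cat1 <- function(f) unlist(lapply(rows[keep], `[[`, f), use.names = FALSE)
  states <- state_space()$states
  out <- data.frame(
    person_id = cat1("pid"),
    age_month = grid$points[tt],
    period = factor(period_labels()[cat1("per")], levels = period_labels()),
    gender = factor(gender_levels()[cat1("g")], levels = gender_levels()),
    education = factor(education_levels()[cat1("e")], levels = education_levels()),
    state_now = factor(states[cat1("snow")], levels = c("FREE", "CVD")),
    state_next = factor(states[cat1("snext")], levels = states),
    calendar_quarter = cat1("q")
  )
  out <- out[order(out$person_id, out$age_month), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_counts <- function(grid = age_grid()) {
  out <- data.frame(
    age_month = integer(0),
    period = factor(character(0), levels = period_labels()),
    gender = factor(character(0), levels = gender_levels()),
    education = factor(character(0), levels = education_levels()),
    state_now = factor(character(0), levels = c("FREE", "CVD")),
    state_next = factor(character(0), levels = state_space()$states),
    n = integer(0)
  )
  structure(out, class = c("transition_counts", "data.frame"), grid = grid)
}

# unpack the flat count vector into the long transition_counts frame
counts_from_vector <- function(counts, grid) {
  nz <- which(counts > 0L)
  if (length(nz) == 0L) return(empty_counts(grid))
  ttype <- (nz - 1L) %% 5L + 1L
  rest <- (nz - 1L) %/% 5L
  e <- rest %% 3L + 1L; rest <- rest %/% 3L
  g <- rest %% 2L + 1L; rest <- rest %/% 2L
  per <- rest %% 5L + 1L
  t <- rest %/% 5L + 1L
  states <- state_space()$states
  snow <- ifelse(ttype <= 3L, 1L, 2L)
  snext <- c(1L, 2L, 3L, 2L, 3L)[ttype]
  out <- data.frame(
    age_month = grid$points[t],
    period = factor(period_labels()[per], levels = period_labels()),
    gender = factor(gender_levels()[g], levels = gender_levels()),
    education = factor(education_levels()[e], levels = education_levels()),
    state_now = factor(states[snow], levels = c("FREE", "CVD")),
    state_next = factor(states[snext], levels = states),
    n = counts[nz]
  )
  out <- out[order(out$age_month, out$period, out$gender, out$education,
                   out$state_now, out$state_next), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("transition_counts", "data.frame"), grid = grid)
}

#' Relabel calendar periods of a person-period panel
#'
#' Applies a period-regime rule to a panel. The rule may be a single period
#' label (constant rule), the string `"calendar5"` (map calendar quarters
#' 0-99 to the five 5-year periods; quarters outside the window are
#' unmapped and raise an error), or a function taking the panel and
#' returning one period label per row.
#'
#' @param panel a person-period data frame.
#' @param rule the regime rule as above.
#' @return The panel with its `period` column replaced.
#' @export
assign_periods <- function(panel, rule = "calendar5") {
  if (nrow(panel) == 0L) return(panel)
  if (is.function(rule)) {
    lab <- rule(panel)
  } else if (identical(rule, "calendar5")) {
    if (is.null(panel$calendar_quarter)) {
      stop("rule 'calendar5' needs a calendar_quarter column")
    }
    q <- panel$calendar_quarter
    if (any(q < 0L | q > 99L)) {
      stop("unmapped calendar time: quarters outside 0-99 have no period label")
    }
    lab <- period_labels()[q %/% 20L + 1L]
  } else if (is.character(rule) && length(rule) == 1L &&
             rule %in% period_labels()) {
    lab <- rep(rule, nrow(panel))
  } else {
    stop("rule must be a period label, 'calendar5', or a function")
  }
  if (length(lab) != nrow(panel) || any(is.na(lab)) ||
      !all(lab %in% period_labels())) {
    stop("unmapped calendar time: rule produced labels outside the period set")
  }
  panel$period <- factor(lab, levels = period_labels())
  panel
}

#' Validate a person-period panel
#'
#' Checks the structural invariants of the quarterly person-period table:
#' required columns; ages on the grid and strictly below its end; no rows
#' with current state DEAD; every `state_next` reachable from its
#' `state_now`; and within each person a contiguous, consistent trajectory
#' (consecutive quarters chain `state_next` into the next row's
#' `state_now`, and an absorbed or once-diseased person never reappears
#' FREE).
#'
#' @param panel a person-period data frame.
#' @param grid the [age_grid()] the ages must lie on.
#' @return `TRUE` invisibly; errors describe the first violation found.
#' @export
validate_panel <- function(panel, grid = age_grid()) {
  need <- c("person_id", "age_month", "period", "gender", "education",
            "state_now", "state_next")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0L) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(panel) == 0L) return(invisible(TRUE))
  if (!all(panel$age_month %in% grid$points)) stop("age_month values off the grid")
  if (any(panel$age_month >= grid$end)) stop("age_month must be < the grid end")
  snow <- as.character(panel$state_now)
  snext <- as.character(panel$state_next)
  if (any(snow == "DEAD")) stop("rows with state_now = DEAD are not allowed")
  allowed <- state_space()$allowed
  ok <- allowed[cbind(snow, snext)]
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("forbidden transition %s -> %s at row %d",
                 snow[bad], snext[bad], bad))
  }
  o <- order(panel$person_id, panel$age_month)
  pid <- panel$person_id[o]; age <- panel$age_month[o]
  sn <- snow[o]; sx <- snext[o]
  same <- pid[-1] == pid[-length(pid)]
  consec <- same & (age[-1] - age[-length(age)] == grid$step)
  if (any(consec)) {
    i <- which(consec)
    if (!all(sx[i] == sn[i + 1])) {
      stop("inconsistent trajectory: state_next does not match the following state_now")
    }
  }
  # irreversibility across window gaps too
  if (any(same)) {
    i <- which(same)
    if (any(sn[i] == "CVD" & sn[i + 1] == "FREE")) {
      stop("inconsistent trajectory: person returns from CVD to FREE")
    }
  }
  invisible(TRUE)
}

#' Read and write person-period panels as CSV
#'
#' Headered UTF-8 CSV with one row per person-quarter and the documented
#' columns `person_id`, `age_month`, `period`, `gender`, `education`,
#' `state_now`, `state_next`, `calendar_quarter`.
#'
#' @param panel a person-period data frame.
#' @param path file path.
#' @return `read_panel_csv` returns the panel with factor columns restored.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$period <- factor(out$period, levels = period_labels())
  out$gender <- factor(out$gender, levels = gender_levels())
  out$education <- factor(out$education, levels = education_levels())
  out$state_now <- factor(out$state_now, levels = c("FREE", "CVD"))
  out$state_next <- factor(out$state_next, levels = state_space()$states)
  out
}
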