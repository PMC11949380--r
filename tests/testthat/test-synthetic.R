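test_that("scenario models satisfy their construction constraints", {
  expect_error(scenario_model("nonsense"), "arg")
  for (sc in scenario_names()) {
    m <- scenario_model(sc)
    for (per in period_labels()) {
      tp <- predict(m, period = per)
      # CVD mortality exceeds FREE mortality at every age
      expect_true(all(tp$p[, "CVD", "DEAD"] > tp$p[, "FREE", "DEAD"]))
    }
  }
  # incidence and mortality increase with age except under constant hazards
  tp <- predict(scenario_model("baseline"), period = "1996-2000")
  expect_true(all(diff(tp$p[, "FREE", "CVD"]) > 0))
  expect_true(all(diff(tp$p[, "FREE", "DEAD"]) > 0))
  expect_true(all(diff(tp$p[, "CVD", "DEAD"]) > 0))
  i40 <- 1L
  i80 <- match(960, age_grid()$points)
  expect_gt(tp$p[i80, "FREE", "CVD"], tp$p[i40, "FREE", "CVD"])
  tpc <- predict(scenario_model("constant_hazard"), period = "1996-2000")
  expect_equal(diff(range(tpc$p[, "FREE", "DEAD"])), 0)
  # degenerate no-incidence scenario
  tpn <- predict(scenario_model("no_cvd"), period = "1996-2000")
  expect_true(all(tpn$p[, "FREE", "CVD"] < 1e-12))
  # later periods have lower mortality
  p1 <- predict(scenario_model("baseline"), period = "1996-2000")
  p5 <- predict(scenario_model("baseline"), period = "2016-2020")
  expect_true(all(p5$p[, "FREE", "DEAD"] < p1$p[, "FREE", "DEAD"]))
  expect_true(all(p5$p[, "CVD", "DEAD"] < p1$p[, "CVD", "DEAD"]))
})

test_that("simulated panels are valid, reproducible and scenario-consistent", {
  cfg <- scenario_config(n_persons = 300, seed = 5)
  pp <- simulate_individuals(scenario_model("baseline"), cfg)
  expect_true(validate_panel(pp))
  expect_gt(nrow(pp), 0)
  # byte-identical under the same seed and config
  pp2 <- simulate_individuals(scenario_model("baseline"), cfg)
  expect_identical(pp, pp2)
  # panel and counts formats agree
  cnt <- simulate_individuals(scenario_model("baseline"), cfg, format = "counts")
  expect_identical(as.data.frame(aggregate_transitions(pp)), as.data.frame(cnt))
  # empty cohort: empty table with the full schema
  p0 <- simulate_individuals(scenario_model("baseline"),
                             scenario_config(0, seed = 1))
  expect_equal(nrow(p0), 0L)
  expect_true(all(c("person_id", "age_month", "period", "gender", "education",
                    "state_now", "state_next") %in% names(p0)))
  # no CVD rows under the no-incidence scenario
  pn <- simulate_individuals(scenario_model("no_cvd"),
                             scenario_config(500, seed = 8))
  expect_false(any(pn$state_now == "CVD"))
  expect_false(any(pn$state_next == "CVD"))
})

test_that("empirical transition fractions match the generating probabilities", {
  m <- scenario_model("baseline")
  cnt <- simulate_individuals(m, scenario_config(200000, seed = 101),
                              format = "counts")
  # FREE -> CVD at 600 months, within each period, against the model value
  sub <- cnt[cnt$age_month == 600 & cnt$state_now == "FREE", ]
  for (per in period_labels()) {
    sp <- sub[sub$period == per, ]
    n_at_risk <- sum(sp$n)
    k <- sum(sp$n[sp$state_next == "CVD"])
    p_true <- predict(m, period = per)$p[match(600, age_grid()$points), "FREE", "CVD"]
    se <- sqrt(p_true * (1 - p_true) / n_at_risk)
    expect_lt(abs(k / n_at_risk - p_true), 3 * se)
  }
})

test_that("constant-hazard pooled death fraction equals the constant", {
  m <- scenario_model("constant_hazard")
  cnt <- simulate_individuals(m, scenario_config(50000, seed = 21),
                              format = "counts")
  sub <- cnt[cnt$state_now == "FREE", ]
  n_at_risk <- sum(sub$n)
  k <- sum(sub$n[sub$state_next == "DEAD"])
  p_true <- predict(m, period = "1996-2000")$p[1, "FREE", "DEAD"]
  se <- sqrt(p_true * (1 - p_true) / n_at_risk)
  expect_lt(abs(k / n_at_risk - p_true), 3 * se)
})

test_that("period assignment rules relabel panels correctly", {
  pp <- tiny_panel(n = 2000, seed = 13)
  # constant rule
  p1 <- assign_periods(pp, "1996-2000")
  expect_true(all(p1$period == "1996-2000"))
  # calendar rule reproduces the generator labels inside the window
  pc <- assign_periods(pp, "calendar5")
  expect_identical(pc$period, pp$period)
  # even person-level split: each label holds ~20% of persons
  rule <- function(panel) period_labels()[1 + panel$person_id %% 5]
  pe <- assign_periods(pp, rule)
  per_person <- tapply(as.integer(pe$period), pe$person_id, unique)
  n <- length(per_person)
  frac <- tabulate(unlist(per_person), 5) / n
  se <- sqrt(0.2 * 0.8 / n)
  expect_true(all(abs(frac - 0.2) < 3 * se))
  # empty table passes through; unmapped times raise
  expect_equal(nrow(assign_periods(pp[0, ], "calendar5")), 0L)
  bad <- pp
  bad$calendar_quarter[1] <- 120L
  expect_error(assign_periods(bad, "calendar5"), "unmapped")
  expect_error(assign_periods(pp, function(p) rep("2030-2035", nrow(p))),
               "unmapped")
})

test_that("panel validator catches broken trajectories", {
  pp <- tiny_panel(n = 100, seed = 3)
  bad <- pp
  bad$state_next[bad$state_now == "CVD"][1] <- "FREE"
  expect_error(validate_panel(bad), "forbidden")
  bad2 <- pp
  i <- which(bad2$state_now == "FREE" & bad2$state_next == "FREE")[1]
  bad2$state_next[i] <- "DEAD"  # next row still has the person alive
  expect_error(validate_panel(bad2), "inconsistent|forbidden")
  bad3 <- pp
  bad3$age_month[1] <- 1200L
  expect_error(validate_panel(bad3), "grid|end")
})

test_that("panel CSV round-trips", {
  pp <- tiny_panel(n = 50, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_panel_csv(pp, f)
  back <- read_panel_csv(f)
  expect_equal(back$person_id, pp$person_id)
  expect_equal(as.character(back$state_next), as.character(pp$state_next))
  expect_equal(levels(back$period), period_labels())
  unlink(f)
})

test_that("education drift configs shift the entry distribution by period", {
  drift <- rbind(c(0.50, 0.30, 0.20), c(0.45, 0.32, 0.23), c(0.38, 0.34, 0.28),
                 c(0.31, 0.35, 0.34), c(0.25, 0.35, 0.40))
  cfg <- scenario_config(n_persons = 40000, seed = 6, education_probs = drift,
                         entry_quarters = 0:99)
  pp <- simulate_individuals(scenario_model("baseline"), cfg,
                             format = "counts")
  # entry rows only (age 480): share of tertiary should rise across periods
  ent <- pp[pp$age_month == 480, ]
  sh <- tapply(ent$n, list(ent$period, ent$education), sum)
  tert <- sh[, "tertiary"] / rowSums(sh)
  expect_gt(tert["2016-2020"], tert["1996-2000"] + 0.1)
})
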