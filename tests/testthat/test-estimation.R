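test_that("softmax prediction reproduces hand-computed probabilities", {
  # eta(CVD) = -4, eta(DEAD) = -5 against the stay reference
  cn <- model_coef_names("1996-2000")
  coef <- list(
    FREE = rbind(CVD = c(-4, 0, 0), DEAD = c(-5, 0, 0)),
    CVD = rbind(DEAD = c(-30, 0, 0))
  )
  for (o in names(coef)) colnames(coef[[o]]) <- cn
  m <- new_transition_model(coef, periods = "1996-2000")
  tp <- predict(m, period = "1996-2000")
  expect_equal(tp$p[1, "FREE", "CVD"], 0.017868, tolerance = 1e-6 / 0.017868)
  expect_equal(tp$p[1, "FREE", "DEAD"], 0.006573, tolerance = 1e-6 / 0.006573)
  expect_equal(tp$p[1, "FREE", "FREE"], 0.975559, tolerance = 1e-6)
  # intercept -30 limit: probability numerically zero everywhere
  expect_true(all(tp$p[, "CVD", "DEAD"] < 1e-12))
  expect_error(predict(m, period = "2001-2005"), "unknown period")
})

test_that("predicted rows are row-stochastic for arbitrary coefficients", {
  set.seed(42)
  for (r in 1:20) {
    cn <- model_coef_names(period_labels())
    coef <- list(
      FREE = matrix(rnorm(2 * length(cn), sd = 2), 2,
                    dimnames = list(c("CVD", "DEAD"), cn)),
      CVD = matrix(rnorm(length(cn), sd = 2), 1,
                   dimnames = list("DEAD", cn))
    )
    m <- new_transition_model(coef, periods = period_labels())
    tp <- predict(m, period = sample(period_labels(), 1))
    rs <- apply(tp$p, c(1, 2), sum)
    expect_lt(max(abs(rs - 1)), 1e-12)
    expect_true(all(tp$p[, "CVD", "FREE"] == 0))
  }
})

test_that("intercept-only fit on a single cell is saturated", {
  # single age, single period: MLE probabilities = empirical fractions
  pp <- data.frame(
    person_id = 1:200, age_month = 480L,
    period = factor("1996-2000", levels = period_labels()),
    gender = factor("women", levels = gender_levels()),
    education = factor("basic", levels = education_levels()),
    state_now = factor("FREE", levels = c("FREE", "CVD")),
    state_next = factor(rep(c("FREE", "CVD", "DEAD"), c(150, 30, 20)),
                        levels = state_space()$states)
  )
  ppc <- data.frame(
    person_id = 201:300, age_month = 480L,
    period = factor("1996-2000", levels = period_labels()),
    gender = factor("women", levels = gender_levels()),
    education = factor("basic", levels = education_levels()),
    state_now = factor("CVD", levels = c("FREE", "CVD")),
    state_next = factor(rep(c("CVD", "DEAD"), c(90, 10)),
                        levels = state_space()$states)
  )
  fit <- fit_transition_model(rbind(pp, ppc), covariates = character(0))
  tp <- predict(fit, period = "1996-2000")
  expect_equal(tp$p[1, "FREE", "FREE"], 0.75, tolerance = 1e-8)
  expect_equal(tp$p[1, "FREE", "CVD"], 0.15, tolerance = 1e-8)
  expect_equal(tp$p[1, "FREE", "DEAD"], 0.10, tolerance = 1e-8)
  expect_equal(tp$p[1, "CVD", "DEAD"], 0.10, tolerance = 1e-8)
  # the forbidden CVD -> FREE edge is not in the model at all
  expect_identical(unique(tp$p[, "CVD", "FREE"]), 0)
})

test_that("parameter recovery and likelihood dominance on simulated data", {
  true <- scenario_model("baseline")
  cnt <- simulate_individuals(true, scenario_config(60000, seed = 33),
                              format = "counts")
  fit <- fit_transition_model(cnt)
  for (org in c("FREE", "CVD")) {
    used <- fit$fit[[org]]$coef_names
    est <- fit$coef[[org]][, used, drop = FALSE]
    se <- fit$fit[[org]]$se
    tru <- true$coef[[org]][, used, drop = FALSE]
    expect_true(all(abs(est - tru) / se < 4),
                label = paste("recovery within 4 SE, origin", org))
  }
  # MLE dominates the generating parameters in likelihood
  expect_gte(transition_loglik(fit, cnt), transition_loglik(true, cnt))
})

test_that("predictions are invariant to the age-scaling constants", {
  cnt <- simulate_individuals(scenario_model("baseline"),
                              scenario_config(20000, seed = 14),
                              format = "counts")
  f1 <- fit_transition_model(cnt, age_center = 840, age_scale = 120)
  f2 <- fit_transition_model(cnt, age_center = 600, age_scale = 60)
  for (per in period_labels()) {
    t1 <- predict(f1, period = per)
    t2 <- predict(f2, period = per)
    expect_lt(max(abs(t1$p - t2$p)), 1e-10)
  }
})

test_that("degenerate inputs and separation raise informative errors", {
  no_rows <- tiny_panel(0, seed = 1)
  expect_error(fit_transition_model(no_rows), "no observations")
  # no deaths ever observed from CVD -> separation error naming destination
  pp <- tiny_panel(n = 800, seed = 19)
  pp2 <- pp[!(pp$state_now == "CVD" & pp$state_next == "DEAD"), ]
  expect_error(fit_transition_model(pp2), "separation.*DEAD")
})

test_that("stratified fitting yields the scheme's model map", {
  cnt <- simulate_individuals(scenario_model("baseline"),
                              scenario_config(30000, seed = 55),
                              format = "counts")
  ms <- fit_stratified(cnt, "total")
  expect_named(ms, "total")
  mg <- fit_stratified(cnt, "by_gender")
  expect_named(mg, c("women", "men"))
  mge <- fit_stratified(cnt, "by_gender_education")
  expect_length(mge, 6L)
  expect_named(mge, c("women_basic", "women_secondary", "women_tertiary",
                      "men_basic", "men_secondary", "men_tertiary"))
  # exchangeable strata (baseline has no gender effect): estimates agree
  d <- coef(mg$women)$FREE - coef(mg$men)$FREE
  pooled_se <- sqrt(mg$women$fit$FREE$se^2 + mg$men$fit$FREE$se^2)
  used <- mg$women$fit$FREE$coef_names
  expect_true(all(abs(d[, used]) / pooled_se < 4))
  # empty stratum errors name the stratum
  w <- cnt[cnt$gender == "women", ]
  expect_error(fit_stratified(w, "by_gender"), "stratum men")
  expect_error(fit_stratified(cnt[0, ], "total"), "stratum total")
})

test_that("model serialization round-trips exactly", {
  m <- scenario_model("baseline")
  f <- tempfile(fileext = ".yaml")
  write_transition_model(m, f)
  back <- read_transition_model(f)
  expect_equal(back$coef, m$coef)
  expect_equal(back$periods, m$periods)
  tp1 <- predict(m, period = "2006-2010")
  tp2 <- predict(back, period = "2006-2010")
  expect_equal(tp1$p, tp2$p, tolerance = 1e-14)
  unlink(f)
})
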