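test_that("pooled education weights are person-period proportions", {
  pp <- tiny_panel(n = 1500, seed = 23)
  w <- pooled_education_weights(pp)
  tab <- table(pp$education) / nrow(pp)
  expect_equal(unclass(w)[names(tab)], c(tab), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(unclass(w)), 1, tolerance = 1e-12)
  # 2:1:1 row counts -> 0.50 / 0.25 / 0.25
  fake <- pp[rep(1, 4), ]
  fake$education <- factor(c("basic", "basic", "secondary", "tertiary"),
                           levels = education_levels())
  w2 <- pooled_education_weights(fake)
  expect_equal(as.numeric(unclass(w2)), c(0.50, 0.25, 0.25))
  # single-education population -> degenerate weights
  onlyb <- pp
  onlyb$education <- factor("basic", levels = education_levels())
  w3 <- pooled_education_weights(onlyb)
  expect_equal(as.numeric(unclass(w3)), c(1, 0, 0))
  expect_error(pooled_education_weights(pp[0, ]), "no observations")
  expect_error(education_weights(0.6, 0.6, -0.2), "non-negative")
  expect_error(education_weights(0.5, 0.3, 0.1), "sum to 1")
})

test_that("standardized probabilities are the entrywise mixture", {
  m <- scenario_model("strong_gradient")
  by_edu <- lapply(setNames(education_levels(), education_levels()),
                   function(e) predict(m, period = "1996-2000",
                                       gender = "women", education = e))
  # identical inputs: mixture of equals is the input
  same <- list(basic = by_edu$basic, secondary = by_edu$basic,
               tertiary = by_edu$basic)
  w <- education_weights(0.2, 0.3, 0.5)
  out_same <- standardize_transition_probs(same, w)
  expect_equal(out_same$p, by_edu$basic$p, tolerance = 1e-14)
  # degenerate weights select one input
  w100 <- education_weights(1, 0, 0)
  out_b <- standardize_transition_probs(by_edu, w100)
  expect_equal(out_b$p, by_edu$basic$p, tolerance = 1e-14)
  # hand mixture: 0.5*0.02 + 0.3*0.04 + 0.2*0.06 = 0.034
  mk <- function(pfc) const_chain(p_fc = pfc, p_fd = 0.01, p_cd = 0.05)
  mix <- standardize_transition_probs(
    list(basic = mk(0.02), secondary = mk(0.04), tertiary = mk(0.06)),
    education_weights(0.5, 0.3, 0.2)
  )
  expect_equal(unique(round(mix$p[, "FREE", "CVD"], 15)), 0.034,
               tolerance = 1e-12)
  # mixture probabilities stay within the convex hull of the inputs
  lo <- pmin(by_edu$basic$p, by_edu$secondary$p, by_edu$tertiary$p)
  hi <- pmax(by_edu$basic$p, by_edu$secondary$p, by_edu$tertiary$p)
  out <- standardize_transition_probs(by_edu, education_weights(0.4, 0.35, 0.25))
  expect_true(all(out$p >= lo - 1e-12 & out$p <= hi + 1e-12))
  # mismatched contexts refuse to mix
  wrongper <- list(basic = by_edu$basic, secondary = by_edu$secondary,
                   tertiary = predict(m, period = "2016-2020",
                                      gender = "women", education = "tertiary"))
  expect_error(standardize_transition_probs(wrongper, w), "different periods")
})

test_that("education adjustment attenuates gains under upward drift", {
  # protective education effects + upward drift: the education-adjusted
  # increase in CVD-free expectancy between first and last period must not
  # exceed the unadjusted increase
  m <- scenario_model("strong_gradient")
  drift <- rbind(c(0.50, 0.30, 0.20), c(0.44, 0.32, 0.24), c(0.38, 0.34, 0.28),
                 c(0.31, 0.35, 0.34), c(0.25, 0.35, 0.40))
  cnt <- simulate_individuals(
    m, scenario_config(150000, seed = 61, education_probs = drift),
    format = "counts"
  )
  w <- pooled_education_weights(cnt)
  per <- c("1996-2000", "2016-2020")
  for (g in gender_levels()) {
    # unadjusted: fit without education, as the population exists
    unadj <- fit_transition_model(cnt, stratum = list(gender = g))
    e_un <- vapply(per, function(p) {
      unname(state_expectancies(predict(unadj, period = p))["e_free"])
    }, numeric(1))
    # adjusted: education-specific fits mixed with fixed pooled weights
    by_edu <- lapply(setNames(education_levels(), education_levels()),
                     function(e) {
      fit_transition_model(cnt, stratum = list(gender = g, education = e))
    })
    e_ad <- vapply(per, function(p) {
      probs <- lapply(by_edu, predict, period = p)
      unname(state_expectancies(standardize_transition_probs(probs, w))["e_free"])
    }, numeric(1))
    expect_lte(diff(e_ad), diff(e_un))
  }
})
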