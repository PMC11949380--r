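test_that("occupancy recursion matches closed forms and degenerate chains", {
  # identity chain: everyone stays FREE
  occ <- occupancy_forward(const_chain())
  expect_true(all(occ[, "FREE"] == 1))
  # immediate absorption from CVD
  occ2 <- occupancy_forward(const_chain(p_cd = 1), start_state = "CVD")
  expect_equal(unname(occ2[1, "CVD"]), 1)
  expect_true(all(occ2[-1, "DEAD"] == 1))
  # geometric survival: FREE occupancy after 10 steps = 0.97^10
  occ3 <- occupancy_forward(const_chain(p_fc = 0.02, p_fd = 0.01))
  expect_equal(unname(occ3[11, "FREE"]), 0.97^10, tolerance = 1e-12)
  # invariants: rows sum to 1, DEAD non-decreasing
  expect_lt(max(abs(rowSums(occ3) - 1)), 1e-12)
  expect_true(all(diff(occ3[, "DEAD"]) >= 0))
  expect_error(occupancy_forward(const_chain(), start_age = 1200), "horizon")
})

test_that("lifetime risk matches truncated-geometric arithmetic", {
  expect_equal(lifetime_risk(const_chain()), 0)
  expect_equal(lifetime_risk(const_chain(p_fc = 1)), 1)
  ch <- const_chain(p_fc = 0.02, p_fd = 0.01)
  expect_equal(lifetime_risk(ch), 0.02 * (1 - 0.97^240) / 0.03,
               tolerance = 1e-10)
  # accounting identity: onset + death-free + surviving-free = 1
  occ <- occupancy_forward(ch)
  p_surv_free <- unname(occ[241, "FREE"])
  p_stay <- ch$p[, "FREE", "FREE"]
  surv <- c(1, cumprod(p_stay))[1:240]
  p_die_free <- sum(surv * ch$p[, "FREE", "DEAD"])
  expect_equal(lifetime_risk(ch) + p_die_free + p_surv_free, 1,
               tolerance = 1e-12)
})

test_that("mean onset age follows the destination-point convention", {
  # onset possible only in the first interval -> 40.25 years
  pfc <- c(0.5, rep(0, 239))
  ch1 <- vector_chain(pfc, rep(0, 240), rep(0, 240))
  expect_equal(mean_onset_age(ch1), 40.25)
  # no onset possible -> NA with warning
  expect_warning(v <- mean_onset_age(const_chain()), "undefined")
  expect_true(is.na(v))
  # constant chain against independent brute-force first-passage summation
  ch <- const_chain(p_fc = 0.02, p_fd = 0.01)
  f <- numeric(240); s <- 1
  for (t in 1:240) { f[t] <- s * 0.02; s <- s * 0.97 }
  oracle <- sum(f * (480 + 3 * (1:240))) / sum(f) / 12
  expect_equal(mean_onset_age(ch), oracle, tolerance = 1e-12)
  expect_equal(oracle, 48.2931858826, tolerance = 1e-10)
})

test_that("expectancies expose the truncation and counting conventions", {
  # deathless chain: exactly 60 years of life between 40 and 100
  e0 <- state_expectancies(const_chain(p_fc = 0.02))
  expect_equal(unname(e0["tle"]), 60)
  expect_equal(unname(e0["e_free"] + e0["e_cvd"]), unname(e0["tle"]))
  # constant mortality, no incidence: truncated geometric
  e1 <- state_expectancies(const_chain(p_fd = 0.01))
  expect_equal(unname(e1["tle"]), 0.25 * (1 - 0.99^240) / 0.01,
               tolerance = 1e-10)
  expect_equal(unname(e1["e_cvd"]), 0)
  # additivity holds for arbitrary age-varying chains
  set.seed(7)
  ch <- vector_chain(runif(240, 0, 0.05), runif(240, 0, 0.05),
                     runif(240, 0, 0.1))
  e <- state_expectancies(ch)
  expect_lt(abs(e["e_free"] + e["e_cvd"] - e["tle"]), 1e-9)
  expect_equal(unname(e["pct_free"]), unname(100 * e["e_free"] / e["tle"]))
})

test_that("conditional TLE at 65 follows the same conventions", {
  expect_equal(conditional_tle(const_chain()), 35)        # deathless: 140 quarters
  expect_equal(conditional_tle(const_chain(p_cd = 1)), 0.25)  # immediate death
  expect_equal(conditional_tle(const_chain(p_cd = 0.05)),
               0.25 * (1 - 0.95^140) / 0.05, tolerance = 1e-10)
})

test_that("raising incidence raises lifetime risk; raising mortality lowers TLE", {
  set.seed(99)
  for (r in 1:5) {
    pfc <- runif(240, 0, 0.03); pfd <- runif(240, 0, 0.03)
    pcd <- runif(240, 0, 0.06)
    ch <- vector_chain(pfc, pfd, pcd)
    up_inc <- vector_chain(pmin(pfc + 0.01, 1 - pfd), pfd, pcd)
    expect_gte(lifetime_risk(up_inc), lifetime_risk(ch))
    up_dead <- vector_chain(pfc, pmin(pfd + 0.01, 1 - pfc), pmin(pcd + 0.01, 1))
    expect_lte(state_expectancies(up_dead)["tle"], state_expectancies(ch)["tle"])
  }
})

test_that("microsimulation oracle agrees with the matrix functionals", {
  tp <- predict(scenario_model("baseline"), period = "2006-2010")
  mat <- multistate_metrics(tp)
  mic <- microsim_metrics(tp, n = 30000, seed = 77)
  se <- attr(mic, "se")
  for (k in names(se)) {
    expect_lt(abs(mic[[k]] - mat[[k]]), 4 * se[[k]])
  }
  # determinism and degenerate cases
  mic2 <- microsim_metrics(tp, n = 30000, seed = 77)
  expect_identical(mic, mic2)
  expect_error(microsim_metrics(tp, n = 0, seed = 1), ">= 1")
  none <- suppressWarnings(
    microsim_metrics(predict(scenario_model("no_cvd"), period = "1996-2000"),
                     n = 2000, seed = 5)
  )
  expect_equal(none$lifetime_risk, 0)
})
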