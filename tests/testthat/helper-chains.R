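# constant-probability transition chains used across tests
const_chain <- function(p_fc = 0, p_fd = 0, p_cd = 0, grid = age_grid(),
                        period = "1996-2000", subgroup = "total") {
  ni <- grid$n_intervals
  p <- array(0, c(ni, 3L, 3L))
  p[, 1, 2] <- p_fc
  p[, 1, 3] <- p_fd
  p[, 1, 1] <- 1 - p_fc - p_fd
  p[, 2, 3] <- p_cd
  p[, 2, 2] <- 1 - p_cd
  p[, 3, 3] <- 1
  transition_probs(p, grid = grid, period = period, subgroup = subgroup)
}

# age-varying chain from explicit per-interval vectors
vector_chain <- function(p_fc, p_fd, p_cd, grid = age_grid(),
                         period = "1996-2000", subgroup = "total") {
  ni <- grid$n_intervals
  p <- array(0, c(ni, 3L, 3L))
  p[, 1, 2] <- p_fc
  p[, 1, 3] <- p_fd
  p[, 1, 1] <- 1 - p_fc - p_fd
  p[, 2, 3] <- p_cd
  p[, 2, 2] <- 1 - p_cd
  p[, 3, 3] <- 1
  transition_probs(p, grid = grid, period = period, subgroup = subgroup)
}

# small deterministic panel for reporting-free unit tests
tiny_panel <- function(n = 400, seed = 11, scenario = "baseline") {
  simulate_individuals(scenario_model(scenario),
                       scenario_config(n_persons = n, seed = seed))
}
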