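# Independent oracles used across the test files. These re-derive the
# survival quantities from first principles (sums over risk sets, explicit
# product limits) so they share no code with the package's implementation
# path.

# Exact Cox partial log-likelihood for a single covariate, with the Efron or
# Breslow handling of tied event times.
oracle_partial_loglik <- function(beta, time, event, x,
                                  ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sumD <- sum(exp(eta[D]))
    sumR <- sum(exp(eta[R]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sumR - if (ties == "efron") (l / d) * sumD else 0)
    }
  }
  ll
}

# Brute-force grid maximizer of the exact partial likelihood (coarse scan
# then fine refinement; final resolution 1e-5).
oracle_grid_mle <- function(time, event, x, ties = "efron") {
  grid <- seq(-4, 4, by = 0.01)
  ll <- vapply(grid, oracle_partial_loglik, numeric(1),
               time = time, event = event, x = x, ties = ties)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_partial_loglik, numeric(1),
                time = time, event = event, x = x, ties = ties)
  fine[which.max(llf)]
}

# Hand product-limit estimator evaluated at time t.
oracle_km_at <- function(time, event, t) {
  s <- 1
  for (u in sort(unique(time[event == 1 & time <= t]))) {
    n <- sum(time >= u)
    d <- sum(time == u & event == 1)
    s <- s * (1 - d / n)
  }
  s
}

# Hand two-group log-rank statistic (observed minus expected over distinct
# event times, hypergeometric variance).
oracle_logrank <- function(time, event, group) {
  g1 <- group == sort(unique(group))[1L]
  o1 <- e1 <- v <- 0
  for (u in sort(unique(time[event == 1]))) {
    at <- time >= u
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v
}

# Small deterministic cohort builder used by the data-model and index tests:
# a two-SNP panel with hand-set genotypes and outcomes.
tiny_panel <- function() {
  panel_spec(list(
    snp_spec("rs1", "GENEA", "A", "G", "dominant", "variant"),
    snp_spec("rs2", "GENEB", "T", "C", "additive", "variant")
  ), covariate_set = c("age_group", "sex"))
}

tiny_subjects <- function() {
  data.frame(
    subject_id = paste0("P", 1:5),
    age_group = c("<=64", ">64", "<=64", ">64", "<=64"),
    sex = c("male", "female", "male", "male", "female"),
    smoking = c("ever", "never", "ever", "ever", "never"),
    pack_years = c(30, NA, 45, 20, NA),
    histology = c("SCC", "AC", "AC", "LCC", "SCC"),
    stage = c("I", "II-IIIA", "I", "I", "II-IIIA"),
    adjuvant_chemo = c("no", "yes", "no", "no", "yes"),
    os_time = c(12, 30, 45.5, 60, 24),
    os_event = c(1, 0, 1, 0, 1),
    dfs_time = c(8, 30, 45.5, 55, 24),
    dfs_event = c(1, 0, 1, 1, 1),
    rs1 = c("AA", "GA", "AG", "GG", NA),
    rs2 = c("TT", "TC", "CC", "CT", "TT"),
    stringsAsFactors = FALSE)
}

# Simulation helper for two-group exponential survival with administrative
# censoring at a fixed cutoff; used by recovery and calibration tests.
sim_two_group <- function(n, hr, p_high, rate, cutoff, seed) {
  set.seed(seed)
  z <- as.numeric(runif(n) < p_high)
  t_event <- rexp(n) / (rate * exp(log(hr) * z))
  list(time = pmin(t_event, cutoff),
       event = as.numeric(t_event <= cutoff),
       z = z)
}

# Baseline exponential rate giving a target marginal event fraction under
# administrative censoring at `cutoff` for a binary covariate model.
solve_rate <- function(target, hr, p_high, cutoff) {
  stats::uniroot(function(r) {
    p_high * (1 - exp(-r * hr * cutoff)) +
      (1 - p_high) * (1 - exp(-r * cutoff)) - target
  }, c(1e-6, 1))$root
}
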