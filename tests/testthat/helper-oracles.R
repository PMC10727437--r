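# Independent oracles kept deliberately simple: direct formula evaluation
# and brute-force summation, no shared code with the implementation paths
# they check.

# piecewise Gaussian evaluated longhand, scalar only
room_oracle <- function(temp, p_max, t_opt, a, b) {
  if (temp <= t_opt) p_max * exp(-a * (temp - t_opt)^2)
  else p_max * exp(-b * (temp - t_opt)^2)
}

# Monte-Carlo marginalization of the study effect: returns the marginal
# negative log-likelihood and its MC standard error
mc_marginal_nll <- function(table, params, sigma_resid, sigma_study,
                            n_draws = 1e6, seed = 42) {
  set.seed(seed)
  total <- 0
  total_var <- 0
  for (sid in unique(table$study_id)) {
    sub <- table[table$study_id == sid, ]
    u <- rnorm(n_draws, 0, sigma_study)
    ll <- vapply(seq_len(nrow(sub)), function(i) {
      mu <- params$p_max * exp(u) *
        room_oracle_shape(sub$temperature[i], params)
    dnorm(sub$rgr[i], mu, sigma_resid, log = TRUE)
    }, numeric(n_draws))
    ll <- rowSums(ll)
    m <- max(ll)
    lik <- exp(ll - m)
    log_marg <- m + log(mean(lik))
    se_log <- sd(lik) / (mean(lik) * sqrt(n_draws))
    total <- total - log_marg
    total_var <- total_var + se_log^2
  }
  list(nll = total, se = sqrt(total_var))
}

room_oracle_shape <- function(temp, params) {
  room_oracle(temp, params$p_max, params$t_opt, params$a, params$b) /
    params$p_max
}

# tiny two-study fixture used by the quadrature tests
quadrature_fixture <- function() {
  tibble::tibble(
    study_id = rep(c("s1", "s2"), each = 3),
    species = "A_pinnata",
    temperature = c(15, 25, 35, 10, 24.5, 40),
    rgr = c(0.12, 0.26, 0.20, 0.05, 0.22, 0.10),
    rgr_source = "reported"
  )
}
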