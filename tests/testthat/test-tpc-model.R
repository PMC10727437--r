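published_pinnata <- room_params(0.25, 24.5, 0.0155, 0.00344)

test_that("Room curve matches hand evaluation at and around the optimum", {
  expect_equal(room_performance(24.5, published_pinnata), 0.25)
  expect_equal(room_performance(34.5, published_pinnata),
               0.25 * exp(-0.00344 * 100))
  expect_equal(room_performance(14.5, published_pinnata),
               0.25 * exp(-0.0155 * 100))
  temps <- seq(-10, 60, by = 0.7)
  expect_equal(room_performance(temps, published_pinnata),
               vapply(temps, room_oracle, numeric(1),
                      0.25, 24.5, 0.0155, 0.00344))
})

test_that("Room curve is positive, continuous at the optimum, unimodal, and scale-equivariant", {
  set.seed(11)
  for (i in 1:20) {
    p <- room_params(p_max = runif(1, 0.01, 2), t_opt = runif(1, 5, 45),
                     a = runif(1, 1e-4, 0.5), b = runif(1, 1e-4, 0.5))
    # strictly positive wherever the exponent is representable (the true
    # value only underflows to 0 beyond ~exp(-745))
    expect_true(all(room_performance(seq(p$t_opt - 30, p$t_opt + 30, by = 1),
                                     p) > 0))
    eps <- 10^-(4:9)
    gap <- abs(room_performance(p$t_opt - eps, p) -
                 room_performance(p$t_opt + eps, p))
    expect_true(all(diff(gap) <= 0))
    expect_lt(gap[length(gap)], 1e-12)
    rise <- room_performance(seq(p$t_opt - 30, p$t_opt, length.out = 40), p)
    fall <- room_performance(seq(p$t_opt, p$t_opt + 30, length.out = 40), p)
    expect_true(all(diff(rise) > 0))
    expect_true(all(diff(fall) < 0))
    p3 <- room_params(3 * p$p_max, p$t_opt, p$a, p$b)
    expect_equal(room_performance(c(0, 20, 40), p3),
                 3 * room_performance(c(0, 20, 40), p))
  }
})

test_that("equal shape coefficients give an exactly symmetric Gaussian", {
  p <- room_params(0.3, 22, 0.01, 0.01)
  d <- seq(0.5, 25, by = 0.5)
  expect_equal(room_performance(p$t_opt - d, p),
               room_performance(p$t_opt + d, p))
})

test_that("joint NLL reproduces Gaussian density arithmetic", {
  one <- tibble::tibble(study_id = "s1", species = "A_pinnata",
                        temperature = 24.5, rgr = 0.25,
                        rgr_source = "reported")
  # record exactly on the curve + zero offset, unit SDs: two standard-normal
  # log densities at zero
  expect_equal(
    negative_log_likelihood(one, published_pinnata, 1, 1, c(s1 = 0)),
    log(2 * pi))

  # additivity: a second record changes the NLL by exactly its own term
  two <- dplyr::bind_rows(one, tibble::tibble(
    study_id = "s1", species = "A_pinnata", temperature = 30,
    rgr = 0.2, rgr_source = "reported"))
  term <- -dnorm(0.2, room_performance(30, published_pinnata), 1, log = TRUE)
  expect_equal(
    negative_log_likelihood(two, published_pinnata, 1, 1, c(s1 = 0)) -
      negative_log_likelihood(one, published_pinnata, 1, 1, c(s1 = 0)),
    term)

  # doubling the residual SD with zero residuals adds ln 2 per record
  tbl <- tibble::tibble(study_id = "s1", species = "A_pinnata",
                        temperature = c(10, 20, 30),
                        rgr = room_performance(c(10, 20, 30), published_pinnata),
                        rgr_source = "reported")
  expect_equal(
    negative_log_likelihood(tbl, published_pinnata, 2, 1, c(s1 = 0)) -
      negative_log_likelihood(tbl, published_pinnata, 1, 1, c(s1 = 0)),
    3 * log(2))

  expect_error(
    negative_log_likelihood(one, published_pinnata, 0, 1, c(s1 = 0)),
    "sigma_resid")
  expect_error(
    negative_log_likelihood(one, published_pinnata, 1, 1, c(other = 0)),
    "offset")
})

test_that("sigma_study = 0 degenerates the marginal NLL to the fixed-effects NLL", {
  tbl <- quadrature_fixture()
  u0 <- c(s1 = 0, s2 = 0)
  expect_identical(
    integrated_nll(tbl, published_pinnata, 0.05, 0),
    negative_log_likelihood(tbl, published_pinnata, 0.05, 0, u0))
})

test_that("Gauss-Hermite marginalization agrees with a Monte-Carlo oracle", {
  tbl <- quadrature_fixture()
  q <- integrated_nll(tbl, published_pinnata, 0.05, 0.3, n_nodes = 21)
  mc <- mc_marginal_nll(tbl, published_pinnata, 0.05, 0.3, n_draws = 1e6)
  expect_lt(abs(q - mc$nll), 3 * mc$se)
})

test_that("quadrature is refined: 21 vs 61 nodes differ below 1e-6", {
  tbl <- quadrature_fixture()
  q21 <- integrated_nll(tbl, published_pinnata, 0.05, 0.3, n_nodes = 21)
  q61 <- integrated_nll(tbl, published_pinnata, 0.05, 0.3, n_nodes = 61)
  expect_lt(abs(q21 - q61), 1e-6)
})

test_that("marginal NLL stays finite where a naive likelihood underflows", {
  tbl <- quadrature_fixture()
  far <- room_params(1.9, 45, 0.9, 0.9)  # grotesque parameters
  val <- integrated_nll(tbl, far, 0.001, 2)
  expect_true(is.finite(val))
})

test_that("near-noiseless simulation recovers all four parameters within 1%", {
  spec <- simulation_spec(published_pinnata, sigma_resid = 1e-3,
                          sigma_study = 0, n_studies = 6,
                          temperatures = seq(5, 45, by = 4), seed = 5)
  tbl <- simulate_records(spec)
  fit <- fit_tpc(tbl, fit_config(n_starts = 4, seed = 3))
  expect_true(fit$converged)
  expect_equal(fit$params$p_max, 0.25, tolerance = 0.01)
  expect_equal(fit$params$t_opt, 24.5, tolerance = 0.01 * 24.5)
  expect_equal(fit$params$a, 0.0155, tolerance = 0.01)
  expect_equal(fit$params$b, 0.00344, tolerance = 0.01)
  expect_equal(fit$n_obs, nrow(tbl))
})

test_that("the fitted optimum beats random perturbations of itself", {
  spec <- simulation_spec(published_pinnata, sigma_resid = 0.03,
                          sigma_study = 0.2, n_studies = 8,
                          temperatures = seq(5, 45, by = 5), seed = 21)
  tbl <- simulate_records(spec)
  fit <- fit_tpc(tbl, fit_config(n_starts = 4, seed = 2))
  nll_hat <- -fit$loglik
  set.seed(17)
  for (i in 1:10) {
    pert <- room_params(fit$params$p_max * exp(rnorm(1, 0, 0.1)),
                        fit$params$t_opt + rnorm(1, 0, 1),
                        fit$params$a * exp(rnorm(1, 0, 0.2)),
                        fit$params$b * exp(rnorm(1, 0, 0.2)))
    nll_pert <- integrated_nll(tbl, pert, fit$variance$sigma_resid,
                               fit$variance$sigma_study)
    expect_gte(nll_pert, nll_hat - 1e-8)
  }
})

test_that("fit_tpc enforces its preconditions and is seed-reproducible", {
  tbl <- quadrature_fixture()
  expect_error(fit_tpc(tbl[0, ]), "empty")
  one_t <- tbl; one_t$temperature <- 25
  expect_error(fit_tpc(one_t), "two distinct temperature")
  mixed <- tbl; mixed$species[1] <- "A_nilotica"
  expect_error(fit_tpc(mixed), "single species")

  spec <- simulation_spec(published_pinnata, n_studies = 5,
                          temperatures = seq(5, 45, by = 8), seed = 9)
  tbl <- simulate_records(spec)
  f1 <- fit_tpc(tbl, fit_config(n_starts = 3, seed = 4))
  f2 <- fit_tpc(tbl, fit_config(n_starts = 3, seed = 4))
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$loglik, f2$loglik)
})

test_that("fit JSON round-trips the handoff fields", {
  spec <- simulation_spec(published_pinnata, n_studies = 4,
                          temperatures = seq(10, 40, by = 10), seed = 2)
  fit <- fit_tpc(simulate_records(spec), fit_config(n_starts = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- read_fit_json(path)
  expect_equal(unlist(back$params), unlist(fit$params))
  expect_equal(back$variance$sigma_resid, fit$variance$sigma_resid)
  expect_equal(back$loglik, fit$loglik)
  expect_true(back$converged)
})
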