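test_that("links expand coefficients exactly", {
  d <- tjs_design(5, tau = 3)
  spec <- tjs_model_spec()
  layout <- transjs:::build_layout(spec, d, "translocation")
  # constant phi/p, beta over occasions 3..5 (2 free coefficients)
  expect_equal(layout$k, 1 + 1 + 1 + 2)
  theta <- numeric(layout$k)
  theta[1] <- log(500)
  pars <- expand_parameters(theta, spec, d, "translocation")[[1]]
  expect_equal(pars$N, 500)
  expect_equal(attr(pars, "phi_monthly"), rep(0.5, 4))
  expect_equal(pars$p, c(1, rep(0.5, 4)))        # release pinned to 1
  expect_equal(pars$beta, c(0, 0, 1 / 3, 1 / 3, 1 / 3))
  expect_equal(sum(pars$beta), 1, tolerance = 1e-12)
  expect_error(expand_parameters(numeric(3), spec, d, "translocation"),
               "length")
})

test_that("uneven intervals raise monthly survival to the interval length", {
  d <- tjs_design(3, occasion_times = c(0, 6, 18), tau = 2)
  theta <- c(log(100), stats::qlogis(0.95), 0, 0)
  pars <- expand_parameters(theta, tjs_model_spec(), d,
                            "translocation")[[1]]
  expect_equal(pars$phi, c(0.95^6, 0.95^12), tolerance = 1e-12)
})

test_that("abundance recursion matches hand arithmetic", {
  d <- tjs_design(2, occasion_times = c(0, 6), tau = 2)
  pars <- tjs_params(N = 100, phi = 0.9, p = c(1, 0.5), beta = c(0, 1))
  # n0 = 30, interval survival 0.9, N * beta_2 = 100
  expect_equal(transjs:::abundance_recursion(pars, d, 30,
                                             "translocation")[2],
               30 * 0.9 + 100)
  d5 <- tjs_design(5, tau = 2)
  geo <- tjs_params(N = 0, phi = rep(0.5, 4), p = c(1, rep(0.5, 4)),
                    beta = c(0, 1, 0, 0, 0))
  geo$beta <- c(0, 1, 0, 0, 0)
  nt <- transjs:::abundance_recursion(
    tjs_params(N = 0, phi = rep(0.5, 4), p = c(1, rep(0.5, 4)),
               beta = c(0, 1, 0, 0, 0)), d5, 16, "translocation")
  # no recruitment mass (N = 0): geometric decline of the release cohort
  expect_equal(nt, 16 * 0.5 ^ (0:4))
  # no deaths: everyone released plus the whole superpopulation by T
  nt2 <- transjs:::abundance_recursion(
    tjs_params(N = 40, phi = rep(1, 4), p = c(1, rep(0.5, 4)),
               beta = c(0, 0.25, 0.25, 0.25, 0.25)), d5, 16,
    "translocation")
  expect_equal(nt2[5], 16 + 40)
})

test_that("fitting a seeded scenario replicate recovers the truth region", {
  sim <- simulate_scenario(tjs_scenario(5), seed = 1234)
  fit <- fit_mle(sim$histories, sim$design, model = "translocation",
                 options = list(nstarts = 2, seed = 1))
  expect_true(fit$converged)
  expect_equal(fit$abundance[1], sim$design$n0)   # N_1 = n0 exactly
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logLik)
  phi_hat <- mean(attr(fit$params[[1]], "phi_monthly"))
  phi_true <- mean(sim$truth$phi_monthly)
  expect_lt(abs(phi_hat^12 - phi_true^12) / phi_true^12, 0.15)
  p_hat <- fit$params[[1]]$p[2]
  expect_lt(abs(p_hat - mean(sim$truth$p[-1])), 0.1)
})

test_that("an all-translocated dataset drives N to its boundary and is flagged", {
  set.seed(2)
  det <- cbind(1L, matrix(rbinom(20 * 4, 1, 0.6), 20))
  h <- tjs_histories(det, "translocated")
  d <- tjs_design(5, tau = 4)
  fit <- fit_mle(h, d, model = "translocation",
                 options = list(nstarts = 2))
  expect_lt(fit$params[[1]]$N, 0.5)
  expect_true(any(grepl("N at lower support", fit$boundary)))
})

test_that("maximized likelihood is invariant to covariate scaling", {
  spec5 <- tjs_scenario(5)
  sim <- simulate_scenario(spec5, seed = 99)
  d <- sim$design
  d$covariates <- data.frame(effort = c(2, 3, 2, 4, 3, 2, 4, 3, 2, 3))
  sp1 <- tjs_model_spec(p = ~effort)
  fit1 <- fit_mle(sim$histories, d, sp1, "translocation",
                  options = list(nstarts = 1))
  d10 <- d
  d10$covariates$effort <- d$covariates$effort * 10
  fit10 <- fit_mle(sim$histories, d10, sp1, "translocation",
                   options = list(nstarts = 1))
  expect_equal(fit1$logLik, fit10$logLik, tolerance = 1e-5)
  expect_false(isTRUE(all.equal(fit1$theta, fit10$theta)))
})

test_that("multi-start optimisation is stable on a well-behaved fixture", {
  sim <- simulate_scenario(tjs_scenario(2), seed = 31)
  fit <- fit_mle(sim$histories, sim$design, model = "translocation",
                 options = list(nstarts = 5, seed = 4))
  expect_true(fit$converged)
  expect_lt(max(fit$start_objectives) - min(fit$start_objectives), 1e-6)
})

test_that("fully time-dependent standard fits hit survival boundaries on sparse data while the constrained model does not", {
  sim <- simulate_scenario(tjs_scenario(1), seed = 17)   # low detection
  full_time <- tjs_model_spec(phi = ~time, p = ~time)
  fstd <- fit_mle(sim$histories, sim$design, full_time, "standard",
                  options = list(nstarts = 2))
  ftr <- fit_mle(sim$histories, sim$design, tjs_model_spec(),
                 "translocation", options = list(nstarts = 2))
  expect_true(any(grepl("phi at upper boundary", fstd$boundary)))
  expect_length(ftr$boundary, 0)
})

test_that("bootstrap intervals are reproducible, bracket the estimate, and collapse without variability", {
  sim <- simulate_scenario(tjs_scenario(5), seed = 1234)
  b1 <- bootstrap_ci(sim$histories, sim$design, model = "translocation",
                     B = 15, seed = 8, options = list(nstarts = 1))
  b2 <- bootstrap_ci(sim$histories, sim$design, model = "translocation",
                     B = 15, seed = 8, options = list(nstarts = 1))
  expect_identical(b1$abundance, b2$abundance)
  mid <- sim$design$T %/% 2
  expect_gte(b1$fit$abundance[mid], b1$abundance[mid, "lower"])
  expect_lte(b1$fit$abundance[mid], b1$abundance[mid, "upper"])

  # duplicating one history removes resampling variability entirely
  one <- tjs_histories(matrix(rep(c(1L, 1L, 0L, 1L, 0L), each = 1),
                              nrow = 1), "translocated")
  dup <- one[rep(1, 25), ]
  dup$id <- sprintf("d%02d", 1:25)
  d <- tjs_design(5, tau = 4)
  bz <- bootstrap_ci(dup, d, model = "translocation", B = 5, seed = 1,
                     options = list(nstarts = 1))
  expect_equal(unname(bz$abundance[, "upper"] - bz$abundance[, "lower"]),
               rep(0, 5), tolerance = 1e-6)
})

test_that("AIC selection ranks, ties and flags correctly", {
  sim <- simulate_scenario(tjs_scenario(5), seed = 7)
  specs <- list(tjs_model_spec(name = "constant"),
                tjs_model_spec(name = "constant-dup"))
  tab <- aic_select(specs, sim$histories, sim$design, "translocation",
                    options = list(nstarts = 1))
  expect_equal(tab$AIC[1], tab$AIC[2], tolerance = 1e-6)
  expect_equal(tab$dAIC[1], 0)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik)
  expect_error(aic_select(list(), sim$histories, sim$design), "at least")
})

test_that("AIC prefers the generating model on data without a covariate effect", {
  # nested specs, data simulated from the smaller (constant-p) model
  wins <- 0L
  for (r in 1:20) {
    sim <- simulate_scenario(tjs_scenario(5), seed = 5000 + r)
    d <- sim$design
    set.seed(600 + r)
    d$covariates <- data.frame(noise = rnorm(10))
    tab <- aic_select(list(tjs_model_spec(name = "constant"),
                           tjs_model_spec(p = ~noise, name = "noise")),
                      sim$histories, d, "translocation",
                      options = list(nstarts = 1))
    if (tab$name[1] == "constant") wins <- wins + 1L
  }
  expect_gt(wins, 10L)
})

test_that("model-spec configs parse into the spec they describe", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("phi: ~1", "p: ~effort + moon", "N: ~group",
               "beta: ~time"), path)
  sp <- read_model_spec(path)
  expect_equal(sp$p, c("effort", "moon"))
  expect_equal(sp$N, "group")
  expect_equal(sp$phi, character(0))
})
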