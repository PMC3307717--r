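# small shared fixture: a quick dataset for sampler tests
local_fixture <- local({
  set.seed(314)
  loc <- random_locus(8)
  params <- fmr1_regime_params(8)
  sim <- simulate_patterns(loc, params, 60, seed = 314)
  list(loc = loc, params = params, patterns = sim$patterns)
})

test_that("posterior summary quantiles follow the type-7 convention", {
  draws <- matrix(rep(1:100, 3), ncol = 3,
                  dimnames = list(NULL, c("r1", "d1", "mu1")))
  fake <- structure(list(
    draws = draws / 100, loglik = rep(0, 100), chain = rep(1L, 100),
    free_names = colnames(draws),
    fixed = list(theta = c(r1 = 0, d1 = 1, r3p = 0, d3p = 1, r3d = 0,
                           d3d = 1, mu1 = 1, delta1 = 0, mu3 = 1,
                           delta3 = 1, e_fail = 0, e_inap = 0),
                 densities = rep(0.5, 8), fix_site_densities = TRUE),
    variant = "in_vivo_default", errors_off = TRUE),
    class = "methylhmm_samples")
  tb <- summarize_posterior(fake)
  rownames(tb) <- tb$parameter
  expect_equal(tb["r1", "median"], 50.5 / 100)
  expect_equal(tb["r1", "q10"], 10.9 / 100)
  expect_equal(tb["r1", "q90"], 90.1 / 100)
  # constant column: all three summaries coincide
  fake$draws[, "mu1"] <- 0.7
  tb2 <- summarize_posterior(fake)
  rownames(tb2) <- tb2$parameter
  expect_equal(unlist(tb2["mu1", c("median", "q10", "q90")]),
               c(median = 0.7, q10 = 0.7, q90 = 0.7))
  short <- fake
  short$draws <- short$draws[1:10, ]
  expect_error(summarize_posterior(short), "100")
})

test_that("derived quantities use the closed forms and the extended scale", {
  draws <- cbind(r1 = c(0.12, 0.5), d1 = c(0.002, 1),
                 mu1 = c(0.99, 0.8), delta1 = c(0.02, 0))
  fake <- structure(list(
    draws = draws, loglik = c(0, 0), chain = c(1L, 1L),
    free_names = colnames(draws),
    fixed = list(theta = c(r1 = 0, d1 = 1, r3p = 0.3, d3p = 0.7, r3d = 0.2,
                           d3d = 0.8, mu1 = 1, delta1 = 0, mu3 = 1,
                           delta3 = 1, e_fail = 0, e_inap = 0),
                 densities = rep(0.5, 4), fix_site_densities = TRUE),
    variant = "in_vivo_default", errors_off = TRUE),
    class = "methylhmm_samples")
  der <- derived_quantities(fake)
  expect_equal(unname(der[1, "assoc_len_dnmt1"]), 500)
  expect_equal(unname(der[1, "nonassoc_len_dnmt1"]), 1 / 0.12,
               tolerance = 1e-12)
  expect_equal(unname(der[1, "assoc_freq_dnmt1"]),
               0.12 / (0.12 + 0.002 * 0.88))
  expect_equal(unname(der[1, "hemi_ratio_dnmt1"]), 49.5)
  expect_equal(unname(der[2, "assoc_len_dnmt1"]), 1)  # d = 1: one bp tracts
  expect_equal(unname(der[2, "hemi_ratio_dnmt1"]), Inf)  # delta1 = 0 draw
  # fixed DNMT3 entries propagate from the fixed theta
  expect_equal(unname(der[1, "assoc_freq_dnmt3_parent"]),
               0.3 / (0.3 + 0.7 * 0.7))
})

test_that("extended-scale quantiles censor infinite ratio draws sensibly", {
  q <- dnmtHMM:::.quantile_ext(c(1, 2, 3, Inf), c(0.25, 0.5, 0.9))
  expect_equal(q[1], 1.75)
  expect_equal(q[2], 2.5)
  expect_equal(q[3], Inf)
  # all-finite agrees with stats::quantile type 7
  x <- c(5, 1, 9, 3, 7)
  expect_equal(dnmtHMM:::.quantile_ext(x, c(0.1, 0.5, 0.8)),
               unname(stats::quantile(x, c(0.1, 0.5, 0.8), type = 7)))
})

test_that("prior-only sampling reproduces the prior quantiles", {
  fx <- local_fixture
  s <- run_mcmc(fx$patterns, fx$loc, fix_site_densities = TRUE,
                priors = prior_spec(d1 = prior_beta(2, 5)),
                control = mcmc_control(n_iter = 4000, burnin = 500, thin = 2,
                                       n_chains = 1),
                seed = 42, prior_only = TRUE)
  # uniform(0,1) parameter
  expect_lt(abs(median(s$draws[, "r1"]) - 0.5), 0.06)
  expect_lt(abs(unname(quantile(s$draws[, "r1"], 0.1)) - 0.1), 0.05)
  expect_lt(suppressWarnings(  # rejected proposals duplicate draws (ties)
    ks.test(s$draws[, "mu1"], "punif"))$statistic, 0.08)
  # beta-prior parameter
  expect_lt(abs(median(s$draws[, "d1"]) - qbeta(0.5, 2, 5)), 0.05)
})

test_that("sampler is reproducible given a seed and draws respect supports", {
  fx <- local_fixture
  ctl <- mcmc_control(n_iter = 300, burnin = 100, thin = 2, n_chains = 2)
  s1 <- run_mcmc(fx$patterns, fx$loc, fix_site_densities = TRUE,
                 control = ctl, seed = 7)
  s2 <- run_mcmc(fx$patterns, fx$loc, fix_site_densities = TRUE,
                 control = ctl, seed = 7)
  expect_identical(s1$draws, s2$draws)
  expect_true(all(s1$draws >= 0 & s1$draws <= 1))
  s3 <- run_mcmc(fx$patterns, fx$loc, fix_site_densities = TRUE,
                 control = ctl, seed = 8)
  expect_false(identical(s1$draws, s3$draws))
})

test_that("variant constraints shape the free parameter set", {
  fx <- local_fixture
  ctl <- mcmc_control(n_iter = 200, burnin = 50, thin = 1, n_chains = 1)
  s_vitro <- run_mcmc(fx$patterns, fx$loc, variant = "in_vitro_dnmt1",
                      fix_site_densities = TRUE, control = ctl, seed = 1)
  expect_false(any(grepl("3p|3d", colnames(s_vitro$draws))))
  expect_true(all(c("r1", "d1", "mu1", "delta1") %in% colnames(s_vitro$draws)))
  s_hemi <- run_mcmc(fx$patterns, fx$loc, variant = "dnmt3_hemi",
                     fix_site_densities = TRUE, control = ctl, seed = 1)
  expect_true(all(c("mu3", "delta3") %in% colnames(s_hemi$draws)))
  expect_false(any(c("mu1", "delta1") %in% colnames(s_hemi$draws)))
  s_err <- run_mcmc(fx$patterns, fx$loc, errors_off = TRUE,
                    fix_site_densities = TRUE, control = ctl, seed = 1)
  expect_false("e_inap" %in% colnames(s_err$draws))
  # fixed-value priors remove parameters from sampling
  s_fix <- run_mcmc(fx$patterns, fx$loc, fix_site_densities = TRUE,
                    priors = prior_spec(e_inap = prior_fixed(0.02)),
                    control = ctl, seed = 1)
  expect_false("e_inap" %in% colnames(s_fix$draws))
  expect_equal(s_fix$fixed$theta[["e_inap"]], 0.02)
})

test_that("convergence diagnostics separate identical and disjoint chains", {
  set.seed(60)
  # two chains of independent draws from the same distribution: pass
  draws <- cbind(a = rnorm(400, 0.5, 0.05), b = runif(400))
  ok <- structure(list(draws = draws, chain = rep(1:2, each = 200),
                       control = list(n_chains = 2)),
                  class = "methylhmm_samples")
  dg <- convergence_diagnostics(ok)
  expect_true(all(dg$rhat < 1.05))
  expect_true(all(dg$ess > 100))
  expect_false(any(dg$flag))
  # chains stuck at different values: designed failure
  bad <- ok
  bad$draws[, "a"] <- rep(c(0.2, 0.8), each = 200) + rnorm(400, 0, 0.001)
  dgb <- convergence_diagnostics(bad)
  expect_gt(dgb$rhat[dgb$parameter == "a"], 2)
  expect_true(dgb$flag[dgb$parameter == "a"])
  # single chain warns and reports ESS only
  single <- ok
  single$chain <- rep(1L, 400)
  expect_warning(dgs <- convergence_diagnostics(single), "single chain")
  expect_true(all(is.na(dgs$rhat)))
})

test_that("diagnostics broadly agree with coda on a well-behaved chain", {
  skip_if_not_installed("coda")
  set.seed(61)
  x <- as.vector(stats::arima.sim(list(ar = 0.5), 600)) / 10 + 0.5
  obj <- structure(list(draws = cbind(p = x), chain = rep(1L, 600),
                        control = list(n_chains = 1)),
                   class = "methylhmm_samples")
  dg <- suppressWarnings(convergence_diagnostics(obj))
  ess_coda <- unname(coda::effectiveSize(coda::mcmc(x)))
  expect_lt(abs(dg$ess - ess_coda) / ess_coda, 0.35)
})

test_that("posterior samples round-trip through the TSV writer", {
  fx <- local_fixture
  s <- run_mcmc(fx$patterns, fx$loc, fix_site_densities = TRUE,
                control = mcmc_control(n_iter = 150, burnin = 50, thin = 1,
                                       n_chains = 1), seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_samples(s, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# seed: 3", lines)))
  tab <- read.delim(f, comment.char = "#", check.names = FALSE)
  expect_equal(nrow(tab), nrow(s$draws))
  expect_equal(tab$r1, unname(s$draws[, "r1"]))
})
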