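test_that("sigma derives from the 95% CI width with a floor", {
  expect_equal(sigma_from_ci(0, 3.92), 1)
  expect_equal(sigma_from_ci(5, 5), 0.1)
  expect_equal(sigma_from_ci(0, 19.6), 5)
  expect_error(sigma_from_ci(3, 1))
})

test_that("K = 1 fits equal the precision-weighted mean closed form", {
  expect_equal(mqtl_mixture(c(10, 14), c(1, 1), K = 1)$mean, 12)
  expect_equal(mqtl_mixture(c(0, 10), c(1, 3), K = 1)$mean, 1)
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(20, 50, 10)
    s <- runif(20, 0.2, 5)
    fit <- mqtl_mixture(x, s, K = 1)
    expect_equal(fit$mean, sum(x / s^2) / sum(1 / s^2), tolerance = 1e-8)
  }
})

test_that("the EM log-likelihood never decreases across iterations", {
  set.seed(33)
  for (rep in 1:6) {
    x <- c(rnorm(15, 20, 2), rnorm(15, 60, 2))
    s <- runif(30, 0.3, 4)
    fit <- mqtl_mixture(x, s, K = sample(2:4, 1), restarts = 3, seed = rep)
    expect_true(all(diff(fit$logLik_path) >= -1e-8))
  }
})

test_that("EM reaches the brute-force grid optimum on small instances", {
  x <- c(5, 5.1, 4.9, 80, 79.8, 80.2)
  fit <- mqtl_mixture(x, 0.5, K = 2, seed = 1)
  expect_equal(fit$mean, c(5, 80), tolerance = 0.01)
  oracle <- grid_oracle_lnL(x, 0.5, seq(4.5, 5.5, 0.01), seq(79.5, 80.5, 0.01))
  expect_gte(fit$logLik, oracle - 1e-3)
  expect_equal(fit$logLik, oracle, tolerance = 1e-4)

  x2 <- c(1, 1.3, 0.8, 6, 6.2)
  s2 <- c(0.4, 0.6, 0.5, 0.4, 0.7)
  fit2 <- mqtl_mixture(x2, s2, K = 2, seed = 2)
  oracle2 <- grid_oracle_lnL(x2, s2, seq(0.3, 1.8, 0.01), seq(5.5, 6.7, 0.01))
  expect_gte(fit2$logLik, oracle2 - 1e-3)
})

test_that("posteriors are proper and membership counts are conserved", {
  set.seed(5)
  x <- c(rnorm(12, 10, 1), rnorm(8, 40, 1))
  fit <- mqtl_mixture(x, 1, K = 2, seed = 5)
  expect_equal(rowSums(fit$posterior), rep(1, 20), tolerance = 1e-10)
  expect_equal(sum(abs(fit$pi)), 1, tolerance = 1e-10)
  cls <- predict(fit, type = "class")
  expect_equal(sum(tabulate(cls, 2)), 20)
  # predict on new data agrees with training posteriors
  p <- predict(fit, newdata = list(x = x, sigma = rep(1, 20)))
  expect_equal(p, fit$posterior, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("information criteria follow their formulas", {
  fake <- structure(list(logLik = -100, p = 1, n = 50, K = 1,
                         mean = 0, pi = 1,
                         x = rep(0, 50), sigma = rep(1, 50),
                         posterior = matrix(1, 50, 1)),
                    class = "mqtl_mixture")
  ic <- information_criteria(fake, n = 50)
  expect_equal(unname(ic["AIC"]), 202)
  expect_equal(unname(ic["AIC3"]), 203)
  expect_equal(unname(ic["BIC"]), 200 + log(50))
  # K = 1: classification likelihood equals the mixture likelihood
  x <- rnorm(30)
  f1 <- mqtl_mixture(x, 1, K = 1)
  ic1 <- information_criteria(f1)
  expect_equal(unname(ic1["AWE"]),
               -2 * f1$logLik + 2 * (1.5 + log(30)), tolerance = 1e-8)
  # AICc collapses to the +Inf sentinel at n = p + 1
  f2 <- mqtl_mixture(c(0, 10), c(1, 1), K = 1)
  expect_equal(unname(information_criteria(f2, n = 2)["AICc"]), Inf)
})

test_that("the 3-of-5 vote rule picks K as specified", {
  # four criteria minimal at K = 2, AWE at K = 3 -> K = 2
  tab <- data.frame(K = 1:3,
                    AIC = c(10, 1, 5), AIC3 = c(10, 1, 5),
                    AICc = c(10, 1, 5), BIC = c(10, 1, 5),
                    AWE = c(10, 5, 1))
  expect_equal(vote_K(tab)$K, 2)
  # no K reaches 3 votes: smallest among the most-voted wins
  tab2 <- data.frame(K = 2:4,
                     AIC = c(1, 5, 9), AICc = c(1, 5, 9),
                     AIC3 = c(5, 1, 9), BIC = c(5, 1, 9),
                     AWE = c(5, 9, 1))
  expect_equal(vote_K(tab2)$K, 2)
})

test_that("model selection recovers two well-separated clusters", {
  # separation 20 sigma, n = 40
  hits <- vapply(1:25, function(s) {
    set.seed(1000 + s)
    x <- c(rnorm(20, 30, 1), rnorm(20, 50, 1))
    select_mqtl_model(x, 1, seed = s)$K
  }, 0)
  expect_gte(mean(hits == 2), 0.95)
})

test_that("parameters are recovered within 3 standard errors at 8-sigma separation", {
  ok_K <- logical(40)
  ok_mu <- logical(40)
  for (s in 1:40) {
    set.seed(2000 + s)
    mu_true <- c(20, 28)  # separation 8 x sigma = 8
    x <- c(rnorm(20, mu_true[1], 1), rnorm(20, mu_true[2], 1))
    sel <- select_mqtl_model(x, 1, seed = s)
    ok_K[s] <- sel$K == 2
    if (ok_K[s]) {
      mu_hat <- sort(sel$fit$mean)
      ok_mu[s] <- all(abs(mu_hat - mu_true) < 3 * 1 / sqrt(20))
    }
  }
  expect_gte(mean(ok_K), 0.90)
  expect_gte(mean(ok_mu[ok_K]), 0.90)
})

test_that("MQTL assembly computes CIs, PVE, membership and stress shares", {
  obs <- make_projected(c(10, 10.5, 9.5), r2 = c(10, 20, 30))
  fit <- mqtl_mixture(obs$consensus_peak_cm,
                      sigma_from_ci(obs$consensus_ci_lo_cm,
                                    obs$consensus_ci_hi_cm), K = 1)
  mq <- build_mqtl(fit, obs, "CaLG01")
  expect_equal(mq$pve_pct, 20)
  expect_equal(mq$mqtl_id, "CaMQAST1.1")
  expect_equal(mq$n_qtl, 3)

  # CI half-width 1.96 / sqrt(precision): one observation, sigma chosen so
  # the posterior-weighted precision is 3.8416 cM^-2
  obs1 <- make_projected(50)
  fit1 <- mqtl_mixture(50, 1 / sqrt(3.8416), K = 1)
  mq1 <- build_mqtl(fit1, obs1, "CaLG04")
  expect_equal(mq1$ci_hi_cm - mq1$position_cm, 1, tolerance = 1e-6)

  # a QTL whose CI spans all component CIs is shared by all of them
  obs6 <- make_projected(c(10, 20, 30, 40, 50, 60, 35),
                         ci_lo = c(9.9, 19.9, 29.9, 39.9, 49.9, 59.9, 0),
                         ci_hi = c(10.1, 20.1, 30.1, 40.1, 50.1, 60.1, 70))
  sg <- sigma_from_ci(obs6$consensus_ci_lo_cm, obs6$consensus_ci_hi_cm)
  fit6 <- mqtl_mixture(obs6$consensus_peak_cm, sg, K = 6, seed = 3)
  mq6 <- build_mqtl(fit6, obs6, "CaLG05")
  mem <- attr(mq6, "membership")
  wide <- mem[mem$qtl_id == "q7", ]
  expect_equal(nrow(wide), 6)  # member (primary or shared) of all 6
  # conservation: primary memberships partition the observations
  expect_equal(sum(mq6$n_qtl), 7)
  expect_true(all(mq6$n_shared >= mq6$n_qtl))
})

test_that("stress contributions are percentages of member counts", {
  expect_equal(stress_contributions(c("DROUGHT", "DROUGHT", "SALINITY",
                                      "DROUGHT")),
               c(DROUGHT = 75, SALINITY = 25))
  expect_equal(stress_contributions(rep("DROUGHT", 7)), c(DROUGHT = 100))
  expect_equal(unname(stress_contributions(c("DROUGHT", "HEAT", "SALINITY",
                                             "COLD"))),
               rep(25, 4))
})

test_that("component means agree with mclust in the homoscedastic limit", {
  skip_if_not_installed("mclust")
  # equal known sigmas: our estimator and a free-variance Gaussian mixture
  # should locate well-separated components in the same places
  set.seed(71)
  x <- c(rnorm(40, 25, 1), rnorm(60, 70, 1))
  fit <- mqtl_mixture(x, 1, K = 2, seed = 7)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves it by name
  mc <- mclust::Mclust(x, G = 2, modelNames = "E", verbose = FALSE)
  expect_equal(sort(fit$mean), sort(unname(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(sort(fit$pi), sort(unname(mc$parameters$pro)),
               tolerance = 0.05)
})

test_that("mixture simulate and plot methods run and respect dimensions", {
  fit <- mqtl_mixture(c(rnorm(10, 5, 0.5), rnorm(10, 30, 0.5)), 0.5, K = 2,
                      seed = 8)
  sim <- simulate(fit, seed = 1)
  expect_equal(nrow(sim), 20)
  expect_true(all(sim$component %in% 1:2))
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
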