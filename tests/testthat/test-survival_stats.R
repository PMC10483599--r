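test_that("Kaplan-Meier matches the closed form without censoring", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0))
  expect_equal(km$median, 2)
  # no censoring: KM equals the empirical survival function
  set.seed(2)
  t <- rexp(40)
  km2 <- km_estimate(t, rep(1, 40))
  emp <- sapply(km2$time, function(u) mean(t > u))
  expect_equal(km2$surv, emp, tolerance = 1e-12)
})

test_that("all-censored data keeps survival at 1 with undefined median", {
  km <- km_estimate(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(km$surv == 1))
  expect_true(is.na(km$median))
  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier reproduces a hand-computed product-limit table", {
  # 6 patients: times 2, 4+, 6, 8+, 10, 12; hand product-limit:
  # t=2: 5/6; t=6: 5/6*3/4 = 0.625; t=10: 0.625*1/2 = 0.3125; t=12: 0
  km <- km_estimate(c(2, 4, 6, 8, 10, 12), c(1, 0, 1, 0, 1, 1))
  ev <- km$n_event > 0
  expect_equal(km$time[ev], c(2, 6, 10, 12))
  expect_equal(km$surv[ev], c(5/6, 0.625, 0.3125, 0), tolerance = 1e-12)
  expect_equal(km$median, 10)  # earliest time with S <= 0.5
  expect_true(all(diff(km$n_risk) <= 0))
})

test_that("log-rank test separates separated groups and honours df contract", {
  # duplicated data in two groups: no difference
  t <- c(1, 3, 5, 7); e <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)
  # complete separation: all early deaths vs all late deaths, 10 + 10
  lr <- logrank_test(c(1:10, 101:110), rep(1, 20), rep(c("early", "late"), each = 10))
  expect_lt(lr$p, 0.01)
  expect_equal(lr$df, 1)
  # three groups -> 2 df
  lr3 <- logrank_test(c(1:6), rep(1, 6), rep(c("a", "b", "c"), 2))
  expect_equal(lr3$df, 2)
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "2 non-empty|at least 2")
})

test_that("Cox fits match brute-force partial-likelihood maximization", {
  # tie-free 6-patient fixture, one binary covariate
  t <- c(2, 5, 7, 11, 13, 17)
  e <- c(1, 1, 0, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0)
  d <- data.frame(sample_id = as.character(1:6), os_months = t, event = e, x = x)
  fit <- cox_fit(d, "x")
  beta_oracle <- brute_force_cox_beta(t, e, x)
  expect_equal(fit$terms$beta, beta_oracle, tolerance = 1e-4)
  # Efron equals Breslow on tie-free data
  fit_b <- cox_fit(d, "x", ties = "breslow")
  expect_equal(fit$terms$beta, fit_b$terms$beta, tolerance = 1e-10)
  expect_equal(fit$aic, fit_b$aic, tolerance = 1e-10)
  # CI structure and AIC definition
  expect_lt(fit$terms$ci_lo, fit$terms$hr)
  expect_gt(fit$terms$ci_hi, fit$terms$hr)
  expect_equal(fit$aic, 2 * 1 - 2 * fit$loglik)
})

test_that("Cox point estimates obey the standard invariances", {
  set.seed(7)
  n <- 80
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(0.8 * x))
  cens <- rexp(n, 0.03)
  d <- data.frame(sample_id = as.character(1:n),
                  os_months = pmin(t, cens),
                  event = as.integer(t <= cens), x = x)
  fit <- cox_fit(d, "x")
  # time-unit rescaling leaves the hazard ratio unchanged
  d2 <- d; d2$os_months <- d2$os_months * 30.44
  expect_equal(cox_fit(d2, "x")$terms$hr, fit$terms$hr, tolerance = 1e-8)
  # flipping the 0/1 covariate inverts the hazard ratio
  d3 <- d; d3$x <- 1 - d3$x
  expect_equal(cox_fit(d3, "x")$terms$hr, 1 / fit$terms$hr, tolerance = 1e-6)
  # duplicating every patient keeps the point estimate, shrinks the SE
  # (duplication introduces ties, so the exact invariance holds for Breslow)
  fit_b <- cox_fit(d, "x", ties = "breslow")
  d4 <- rbind(d, d)
  fit4 <- cox_fit(d4, "x", ties = "breslow")
  expect_equal(fit4$terms$beta, fit_b$terms$beta, tolerance = 1e-6)
  expect_lt(fit4$terms$se, fit_b$terms$se)
  # degenerate covariate
  d5 <- d; d5$x <- 1
  expect_error(cox_fit(d5, "x"), "constant")
  # no events
  d6 <- d; d6$event <- 0
  expect_error(cox_fit(d6, "x"), "no events")
})

test_that("univariate screen retains truly prognostic covariates", {
  set.seed(31)
  n <- 131
  strong <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  t <- rexp(n, 0.05 * exp(log(3) * strong))
  cens <- rexp(n, 0.02)
  d <- data.frame(sample_id = as.character(1:n),
                  os_months = pmin(t, cens), event = as.integer(t <= cens),
                  strong = strong, noise = noise)
  sc <- univariate_screen(d, c("strong", "noise"))
  expect_true("strong" %in% sc$retained)
  expect_equal(nrow(sc$table), 2)
  empty <- univariate_screen(d, character(0))
  expect_length(empty$retained, 0)
})

test_that("backward selection drops noise, keeps signal, and is a fixed point", {
  set.seed(34)
  n <- 400
  strong <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  t <- rexp(n, 0.05 * exp(1.1 * strong))
  cens <- rexp(n, 0.02)
  d <- data.frame(sample_id = as.character(1:n),
                  os_months = pmin(t, cens), event = as.integer(t <= cens),
                  strong = strong, noise = noise)
  sel <- backward_selection(d, c("strong", "noise"))
  expect_equal(sel$terms$term, "strong")
  expect_equal(sel$dropped, "noise")
  # all-significant starting set: identical to the full fit
  full <- cox_fit(d, "strong")
  again <- backward_selection(d, "strong")
  expect_equal(again$terms$beta, full$terms$beta)
  # determinism
  expect_equal(backward_selection(d, c("strong", "noise"))$terms,
               sel$terms)
  # everything removable -> explicit empty model, not an error
  d$pure1 <- rnorm(n); d$pure2 <- rnorm(n)
  empty <- backward_selection(d, c("pure1", "pure2"), p_drop = 1e-12)
  expect_equal(nrow(empty$terms), 0)
})

test_that("combined strata behave additively under proportional hazards", {
  set.seed(35)
  n <- 1200
  ctc_high <- rbinom(n, 1, 0.5) == 1
  aneuploid <- rbinom(n, 1, 0.5) == 1
  lhr_a <- log(3.24); lhr_c <- log(2.92)
  t <- rexp(n, 0.02 * exp(lhr_a * aneuploid + lhr_c * ctc_high))
  cens <- rexp(n, 0.015)
  d <- data.frame(sample_id = as.character(1:n),
                  os_months = pmin(t, cens), event = as.integer(t <= cens),
                  ctc_count = ifelse(ctc_high, 8, 1), who_status = 0,
                  ctc_high = ctc_high, aneuploid = aneuploid)
  cs <- combined_strata_fit(d)
  expect_equal(cs$fit$terms$term,
               c("ctc_low.aneuploid", "ctc_high.euploid", "ctc_high.aneuploid"))
  hr <- setNames(cs$fit$terms$hr, cs$fit$terms$term)
  # double-positive HR ~ product of the marginal HRs (generative identity)
  expect_equal(unname(hr["ctc_high.aneuploid"]),
               unname(hr["ctc_low.aneuploid"] * hr["ctc_high.euploid"]),
               tolerance = 0.35)
  expect_gt(unname(hr["ctc_high.aneuploid"]), max(hr[1:2]))
  expect_lt(cs$logrank$p, 1e-10)
  expect_length(cs$km, 4)
  # empty reference group
  d_bad <- d[d$ctc_high | d$aneuploid, ]
  expect_error(combined_strata_fit(d_bad), "reference")
})

test_that("required events follows the Schoenfeld formula", {
  expect_equal(required_events(hr = 2), 66L)
  # direct evaluation for another configuration
  hr <- 3.24; p <- 0.6
  expect_equal(required_events(hr, p_group = p),
               as.integer(ceiling((qnorm(0.975) + qnorm(0.8))^2 /
                                    (p * (1 - p) * log(hr)^2))))
  # lower power strictly shrinks the requirement
  expect_lt(required_events(hr = 2, power = 0.5), required_events(hr = 2))
  # balanced groups minimize the requirement
  d_bal <- required_events(hr = 2, p_group = 0.5)
  for (p in c(0.1, 0.3, 0.7, 0.9))
    expect_gte(required_events(hr = 2, p_group = p), d_bal)
  expect_error(required_events(1), "!= 1")
  expect_error(required_events(2, p_group = 1), "p_group")
})

test_that("clinical preparation recomputes dichotomies and joins scores", {
  clin <- data.frame(sample_id = c("a", "b", "c"),
                     os_months = c(5, 10, 15), event = c(1, 0, 1),
                     ctc_count = c(0, 5, 12), who_status = c(0, 1, 2))
  out <- prepare_clinical(clin)
  expect_equal(out$ctc_high, c(FALSE, TRUE, TRUE))
  expect_equal(out$who_high, c(FALSE, TRUE, TRUE))
  scores <- data.frame(sample_id = c("c", "a", "b"),
                       score = c(30, 10, 20), gw_z = c(9, -1, 2),
                       status = c("aneuploid", "euploid", "euploid"))
  out2 <- prepare_clinical(clin, scores)
  expect_equal(out2$aneuploid, c(FALSE, FALSE, TRUE))
  expect_equal(out2$gw_z, c(-1, 2, 9))
  expect_error(prepare_clinical(clin[, -2]), "os_months")
  expect_error(prepare_clinical(clin, scores[1:2, ]), "no score")
})
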