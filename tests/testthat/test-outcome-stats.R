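test_that("fisher enrichment matches hypergeometric enumeration", {
  # balanced table: OR = 1, p = 1
  f <- rep(c(1, 0), each = 20)
  g <- rep(c(1, 0, 1, 0), each = 10)
  bal <- fisher_enrichment(f, g)
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(bal$p, 1)
  # complete separation [[5,0],[0,5]]: p = 2 / C(10,5)
  f2 <- rep(c(1, 0), each = 5)
  sep <- fisher_enrichment(f2, f2)
  expect_identical(sep$odds_ratio, Inf)
  expect_equal(sep$p, 2 / choose(10, 5), tolerance = 1e-12)
  # swapping group labels inverts the odds ratio, keeps p
  inv <- fisher_enrichment(f2, 1 - f2)
  expect_equal(inv$odds_ratio, 0)
  expect_equal(inv$p, sep$p)
  # constant vector: NA with reason
  con <- fisher_enrichment(rep(1, 10), f2)
  expect_true(is.na(con$p))
  expect_identical(con$reason, "constant vector")
})

test_that("km estimator matches product-limit hand computations", {
  # events at t = 1..5, no censoring
  r <- data.frame(time = 1:5, event = 1L)
  km <- km_estimate(r)
  expect_equal(km$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(km$median, 3)
  # no events: S = 1 everywhere, median NA
  r0 <- data.frame(time = c(2, 4, 6), event = 0L)
  km0 <- km_estimate(r0)
  expect_true(all(km0$surv == 1))
  expect_true(is.na(km0$median))
  # one event at t = 2 among 4, others censored at 10: S(2) = 0.75
  r1 <- data.frame(time = c(2, 10, 10, 10), event = c(1L, 0L, 0L, 0L))
  km1 <- km_estimate(r1)
  expect_equal(km1$surv[km1$time == 2], 0.75)
  # censoring-free KM equals the empirical survival function
  set.seed(30)
  t <- round(rexp(40, 0.1), 3)
  kme <- km_estimate(data.frame(time = t, event = 1L))
  emp <- vapply(kme$time, function(x) mean(t > x), 0)
  expect_equal(kme$surv, emp, tolerance = 1e-12)
})

test_that("logrank agrees with the cox score test and handles extremes", {
  # identical groups: chi2 ~ 0, p ~ 1
  base <- data.frame(time = c(1, 2, 3, 4), event = 1L)
  same <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  # ties present; use distinct times for the equivalence check below
  set.seed(31)
  df <- data.frame(time = sort(runif(30, 1, 100)), event = 1L,
                   group = rep(c("a", "b"), 15))
  lr <- logrank_test(df)
  sc <- survival::coxph(survival::Surv(time, event) ~ group, data = df,
                        ties = "efron")
  expect_equal(lr$chi2, unname(sc$score), tolerance = 1e-6)
  # permuting rows leaves the statistic unchanged
  lr2 <- logrank_test(df[sample(nrow(df)), ])
  expect_equal(lr2$chi2, lr$chi2)
  expect_error(logrank_test(df[df$group == "a", ]),
               class = "cllstrat_validation_error")
  # extreme-pair mode picks best and worst median survival groups
  g3 <- rbind(
    data.frame(time = rexp(40, 1 / 10) + 0.1, event = 1L, group = "bad"),
    data.frame(time = rexp(40, 1 / 40) + 0.1, event = 1L, group = "mid"),
    data.frame(time = rexp(40, 1 / 90) + 0.1, event = 1L, group = "good"))
  ep <- logrank_test(g3, mode = "extreme_pair")
  expect_setequal(ep$groups_compared, c("bad", "good"))
  expect_identical(ep$df, 1L)
})

test_that("cox betas match a hand-maximized partial likelihood", {
  # two patients, events at t1 < t2, covariate x = (1, 0):
  # partial likelihood = e^b / (e^b + 1); monotone -> flagged
  two <- data.frame(time = c(1, 2), event = 1L)
  flagged <- cox_univariate(c(1, 0), two)
  expect_true(flagged$flagged)
  # four-patient toy with a finite optimum: solve score equation by hand
  df <- data.frame(time = c(1, 2, 3, 4), event = 1L)
  x <- c(1, 0, 1, 0)
  # score(b) = 2 - [e^b*2/(2e^b+2) + e^b/(e^b+2) + e^b/(e^b+1)] (no ties)
  score <- function(b) {
    2 - (2 * exp(b) / (2 * exp(b) + 2) + exp(b) / (exp(b) + 2) +
           exp(b) / (exp(b) + 1))
  }
  b_hand <- uniroot(score, c(-5, 5), tol = 1e-12)$root
  fit <- cox_univariate(x, df)
  expect_equal(fit$beta, b_hand, tolerance = 1e-6)
  # zero events in one arm: monotone likelihood flagged
  mono <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                     event = c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_true(cox_univariate(c(1, 1, 1, 0, 0, 0), mono)$flagged)
  expect_true(cox_univariate(rep(1, 6), mono)$flagged)
})

test_that("cox type-I error is near nominal under a planted null", {
  set.seed(32)
  n_sims <- 500L
  n <- 120L
  rejected <- 0L
  for (i in seq_len(n_sims)) {
    x <- rbinom(n, 1L, 0.4)
    t_ev <- rexp(n, 1 / 40)
    cens <- runif(n, 0, 120)
    rec <- data.frame(time = pmin(t_ev, cens),
                      event = as.integer(t_ev <= cens))
    p <- cox_univariate(x, rec)$p
    if (!is.na(p) && p < 0.05) rejected <- rejected + 1L
  }
  rate <- rejected / n_sims
  # nominal 0.05 within 3 binomial standard errors
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("subgroup hazard structure is recovered from synthetic cohorts", {
  co <- generate_cohort(cll_cohort_spec(seed = 33))
  pfs <- co$survival[co$survival$endpoint == "PFS", ]
  pfs$group <- co$true_labels[pfs$patient]
  u <- pfs[grepl("^u-", pfs$group), ]
  # planted scales 24 < 40 < 60 months: medians must be ordered
  meds <- vapply(c("u-GS1", "u-GS2", "u-GS3"), function(g)
    km_estimate(u[u$group == g, ])$median, 0)
  expect_true(meds["u-GS1"] < meds["u-GS2"])
  expect_true(meds["u-GS2"] < meds["u-GS3"])
  lr <- logrank_test(u, mode = "extreme_pair")
  expect_setequal(lr$groups_compared, c("u-GS1", "u-GS3"))
  expect_lt(lr$p, 0.01)
  # screening: the TP53-block feature is associated with PFS in u-stratum
  X <- co$feature_matrix$values[u$patient, , drop = FALSE]
  scr <- cox_screen(X[, c("CD_TP53", "CD_MYD88"), drop = FALSE],
                    u[, c("patient", "time", "event")])
  expect_lt(scr$fdr[scr$feature == "CD_TP53"], 0.05)
})
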