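test_that("staining categorization follows the six published bins", {
  expect_identical(categorizeStaining(c(5, 30, 80)), c(1L, 3L, 5L))
  expect_identical(categorizeStaining(50, anyNuclear = FALSE), 0L)
  ## boundaries: <10 -> 1, [10,25] -> 2, (25,50] -> 3, (50,75] -> 4, >75 -> 5
  expect_identical(categorizeStaining(c(9.9, 10, 25, 25.1, 50, 50.1, 75,
                                        75.1, 100)),
                   c(1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L))
  expect_error(categorizeStaining(120), "0, 100")
})

test_that("dichotomization splits at the low-staining cutoff", {
  expect_identical(as.character(dichotomize(c(0, 2, 3, 5))),
                   c("low", "low", "high", "high"))
  expect_error(dichotomize(7), "0..5")
})

test_that("cohort summary reproduces shares computed from category counts", {
  counts <- c(5, 24, 22, 19, 15, 2)
  cohort <- data.frame(ar_category = rep(0:5, counts))
  s <- cohortSummary(cohort)
  expect_equal(s$staining$n, counts)
  ## low = categories 0-2 = 51/87
  expect_equal(s$arGroups$percent[s$arGroups$group == "low"], 58.6)
  expect_equal(s$arGroups$percent[s$arGroups$group == "high"], 41.4)
  ## single-patient cohort: every share 100
  s1 <- cohortSummary(data.frame(ar_category = 4, gender = "male"))
  expect_equal(s1$arGroups$n[s1$arGroups$group == "high"], 1)
  expect_equal(s1$features$percent, 100)
  expect_equal(s1$features$ar_high_pct, 100)
  expect_error(cohortSummary(data.frame()), "empty")
})

test_that("chi-square matches the direct Pearson formula", {
  ## observed equal to expected: statistic 0, p 1
  t0 <- rbind(c(10, 20), c(20, 40))
  r0 <- chiSquare(t0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  ## chemotherapy-response style 2x2
  t1 <- rbind(c(6, 3), c(10, 27))
  r1 <- chiSquare(t1)
  ## direct formula oracle
  E <- outer(rowSums(t1), colSums(t1)) / sum(t1)
  expect_equal(r1$statistic, sum((t1 - E)^2 / E), tolerance = 1e-12)
  expect_equal(r1$statistic, 5.01, tolerance = 0.01)
  expect_equal(r1$df, 1)
  ## doubling the table doubles the statistic
  expect_equal(chiSquare(2 * t1)$statistic, 2 * r1$statistic,
               tolerance = 1e-12)
  ## Yates correction shrinks the 2x2 statistic
  expect_lt(chiSquare(t1, yates = TRUE)$statistic, r1$statistic)
  expect_error(chiSquare(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Spearman correlation uses mid-ranks and monotone invariance", {
  expect_equal(spearmanRho(1:5, 1:5), 1)
  expect_equal(spearmanRho(1:5, 5:1), -1)
  ## mid-rank hand computation: ranks (1, 2.5, 2.5, 4) vs (1, 2, 3.5, 3.5)
  expect_equal(spearmanRho(c(1, 2, 2, 3), c(1, 2, 3, 3)), 3.75 / 4.5)
  set.seed(41)
  x <- sample(0:5, 50, replace = TRUE)
  y <- sample(0:5, 50, replace = TRUE)
  expect_equal(spearmanRho(x, y), spearmanRho(exp(x), y^3 + 1))
  expect_equal(spearmanRho(x, y), cor(x, y, method = "spearman"))
  expect_error(spearmanRho(rep(1, 5), 1:5), "variance")
  expect_error(spearmanRho(1:4, 1:5), "lengths")
})

test_that("Kaplan-Meier estimator matches closed forms", {
  ## no censoring: S(t) = 1 - ECDF
  times <- c(3, 1, 4, 2, 5)
  km <- kaplanMeier(times, rep(1, 5))
  expect_equal(km$surv, 1 - ecdf(times)(sort(times)))
  ## all censored: S stays at 1
  kmC <- kaplanMeier(times, rep(0, 5))
  expect_true(all(kmC$surv == 1))
  ## censoring mid-series: product-limit hand computation
  km2 <- kaplanMeier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  ## monotone non-increasing, bounded by [0, 1]
  expect_true(all(diff(km$surv) <= 0))
  expect_true(all(km$surv >= 0 & km$surv <= 1))
  expect_error(kaplanMeier(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test behaves at the null and under strong effects", {
  times <- rexp(40, 0.1)
  ## two identical groups: statistic exactly 0
  r <- logRank(rep(c("a", "b"), each = 40), rep(times, 2),
               rep(1, 80))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$df, 1)
  ## strong effect, moderate n: overwhelmingly significant
  set.seed(42)
  rejections <- vapply(1:20, function(s) {
    t1 <- rexp(500, 0.01); t2 <- rexp(500, 0.03)
    logRank(rep(c("lo", "hi"), each = 500), c(t1, t2),
            rep(1, 1000))$p < 0.001
  }, logical(1))
  expect_gte(mean(rejections), 0.99)
  ## permutation null: p-values uniform
  set.seed(43)
  tt <- rexp(40, 0.05); ev <- rbinom(40, 1, 0.8)
  ps <- vapply(1:500, function(i) {
    logRank(sample(rep(c("a", "b"), 20)), tt, ev)$p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(logRank(rep("a", 5), rexp(5), rep(1, 5)), "2 nonempty")
})

test_that("Cox fit recovers known hazards and matches a likelihood oracle", {
  set.seed(44)
  ## null covariate: coefficient near zero at large n
  x <- rnorm(2000)
  t0 <- rexp(2000, 0.05)
  f0 <- coxFit(data.frame(x = x), t0, rep(1, 2000))
  expect_lt(abs(f0$coef[1]), 0.1)
  ## HR = 2 recovery across seeds
  errs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    g <- rbinom(1000, 1, 0.5)
    tt <- rexp(1000, 0.02 * 2^g)
    coxFit(data.frame(g = g), tt, rep(1, 1000))$coef[1] - log(2)
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.15)
  ## 4-subject toy data: matches a 1-D Breslow partial-likelihood oracle
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 0); xx <- c(1, 0, 1, 0)
  fit <- coxFit(data.frame(x = xx), tt, ev)
  breslowLogLik <- function(beta) {
    ll <- 0
    for (i in which(ev == 1)) {
      risk <- which(tt >= tt[i])
      ll <- ll + beta * xx[i] - log(sum(exp(beta * xx[risk])))
    }
    ll
  }
  opt <- optimize(breslowLogLik, c(-5, 5), maximum = TRUE,
                  tol = 1e-10)
  expect_equal(unname(fit$coef[1]), opt$maximum, tolerance = 1e-4)
  ## HR/CI consistency
  expect_equal(unname(fit$hr), exp(unname(fit$coef)))
  expect_true(fit$ci_lower <= fit$hr & fit$hr <= fit$ci_upper)
  expect_error(coxFit(data.frame(x = rep(1, 5)), rexp(5), rep(1, 5)),
               "constant")
})

test_that("stepwise selection keeps strong covariates and drops noise", {
  ## with k null candidates screened at pEnter = 0.05, a false entry occurs
  ## with probability about 1 - 0.95^k per run, so the expected behaviour is
  ## "strong always in, on average well under one noise covariate alongside"
  set.seed(45)
  res <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 1000
    strong <- rbinom(n, 1, 0.5)
    noise <- matrix(rnorm(n * 5), n)
    colnames(noise) <- paste0("noise", 1:5)
    tt <- rexp(n, 0.02 * 3^strong)
    sel <- stepwiseCox(data.frame(strong = strong, noise), tt,
                       rep(1, n))$selected
    c(hasStrong = "strong" %in% sel, extras = length(sel) - 1)
  }, numeric(2))
  expect_equal(mean(res["hasStrong", ]), 1)
  expect_lt(mean(res["extras", ]), 1)
  ## all-noise candidates: the empty model at roughly the 0.95^k rate
  set.seed(46)
  nsel <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    n <- 300
    noise <- matrix(rnorm(n * 4), n)
    colnames(noise) <- paste0("n", 1:4)
    length(stepwiseCox(as.data.frame(noise), rexp(n, 0.05),
                       rep(1, n))$selected)
  }, numeric(1))
  expect_gte(mean(nsel == 0), 0.6)
  expect_lt(mean(nsel), 0.5)
  ## single strongly predictive candidate is selected
  set.seed(47)
  g <- rbinom(500, 1, 0.5)
  tt <- rexp(500, 0.02 * 3^g)
  res <- stepwiseCox(data.frame(g = g), tt, rep(1, 500))
  expect_identical(res$selected, "g")
  expect_error(stepwiseCox(data.frame(), rexp(5), rep(1, 5)),
               "no candidates")
})
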