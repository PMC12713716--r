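## O(n^2) pairwise-counting oracle for the Mann-Whitney AUC
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("AUC matches hand cases and the pairwise-counting oracle", {
  expect_equal(auc_score(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(auc_score(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  s8 <- c(0.1, 0.4, 0.35, 0.8, 0.8, 0.2, 0.9, 0.5)
  l8 <- c(0, 0, 1, 1, 0, 1, 1, 1)
  expect_equal(auc_score(s8, l8), auc_brute(s8, l8))
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    s <- round(runif(n), 2)          # rounded scores force ties
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc_score(s, l), auc_brute(s, l))
  }
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(8)
  s <- runif(30); l <- c(0, 1, rbinom(28, 1, 0.5))
  a <- auc_score(s, l)
  expect_equal(auc_score(qlogis(s), l), a)
  expect_equal(auc_score(s^3 + 2 * s, l), a)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- runif(50); l <- c(0, 1, rbinom(48, 1, 0.5))
  expect_equal(auc_score(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))))
})

test_that("threshold rules match exhaustive-scan oracles", {
  ## perfectly separated scores
  s <- c(rep(0.9, 10), rep(0.1, 10)); l <- rep(c(1, 0), each = 10)
  tm <- threshold_metrics(s, l, "fixed_0.5")
  expect_equal(tm$sensitivity, 1); expect_equal(tm$specificity, 1)
  set.seed(12)
  for (i in 1:10) {
    s <- runif(40); l <- c(rep(1, 20), rep(0, 20))
    ## sens = spec rule: no observed threshold does better
    tm <- threshold_metrics(s, l, "sens_eq_spec")
    gaps <- vapply(sort(unique(s)), function(t) {
      pred <- s >= t
      abs(mean(pred[l == 1]) - mean(!pred[l == 0]))
    }, numeric(1))
    got <- abs(tm$sensitivity - tm$specificity)
    expect_lte(got, min(gaps) + 1e-12)
    ## sens >= 0.95 rule keeps at least 19 of 20 positives
    tm95 <- threshold_metrics(s, l, "sens_0.95")
    expect_gte(sum(s[l == 1] >= tm95$threshold), 19)
    ## and is the largest such threshold
    larger <- sort(unique(s))[sort(unique(s)) > tm95$threshold]
    for (t in larger)
      expect_lt(mean(s[l == 1] >= t), 0.95)
  }
})

test_that("null data gives coefficients near zero", {
  set.seed(3)
  d <- data.frame(label = rep(c(0, 1), 100), x = rnorm(200))
  f <- fit_sdm(d, c(x = "linear"), use_mixed = "never")
  expect_lt(abs(f$coef_std["x"]), 2.5 / sqrt(200) * 3)  # ~3 SE of 0
  expect_equal(f$engine, "glm")
})

test_that("single-covariate logistic fit matches a likelihood grid search", {
  d <- simulate_logistic(300, -0.4, 1.2, seed = 21)
  f <- fit_sdm(d, c(x = "linear"), use_mixed = "never")
  ## brute-force likelihood surface, progressively refined
  ll <- function(b0, b1) sum(d$label * plogis(b0 + b1 * d$x, log.p = TRUE) +
                               (1 - d$label) *
                                 plogis(-(b0 + b1 * d$x), log.p = TRUE))
  ctr <- c(0, 0); width <- 4
  for (it in 1:6) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
    b1s <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    best <- grid[which.max(mapply(ll, grid$b0, grid$b1)), ]
    ctr <- c(best$b0, best$b1); width <- width / 5
  }
  ## compare on the data scale (grid search works on raw x)
  expect_equal(unname(f$coef_data["(Intercept)"]), ctr[1], tolerance = 1e-3)
  expect_equal(unname(f$coef_data["x"]), ctr[2], tolerance = 1e-3)
})

test_that("known logistic coefficients are recovered within 2 SE", {
  hits <- 0
  for (seed in 1:50) {
    d <- simulate_logistic(2000, 0.3, 0.8, seed = 100 + seed)
    f <- fit_sdm(d, c(x = "linear"), use_mixed = "never")
    g <- glm(label ~ x, data = d, family = binomial())
    ## the standardized fit back-transforms to the raw-scale estimate
    expect_equal(unname(f$coef_data["x"]), unname(coef(g)["x"]),
                 tolerance = 1e-6)
    se <- summary(g)$coefficients["x", "Std. Error"]
    hits <- hits + (abs(f$coef_data["x"] - 0.8) < 2 * se)
  }
  expect_gte(hits, 45)   # >= 90% of seeds
})

test_that("mixed fits recover a year random intercept and report Laplace AIC", {
  set.seed(77)
  n <- 1500
  yr <- sample(2010:2014, n, TRUE)
  u <- setNames(rnorm(5, 0, 1.2), 2010:2014)
  x <- rnorm(n)
  d <- data.frame(label = rbinom(n, 1, plogis(0.2 + x + u[as.character(yr)])),
                  x = x, year = yr)
  f <- fit_sdm(d, c(x = "linear"), use_mixed = "always")
  expect_equal(f$engine, "glmer")
  expect_gt(f$ranef_var, 0.1)
  ## AIC = 2k - 2 logLik with k counting the variance parameter
  k <- length(f$coef_std) + 1
  expect_equal(f$aic, 2 * k - 2 * f$loglik)
  ## and the engine agrees with an independent mixed-model implementation
  skip_if_not_installed("glmmTMB")
  g <- glmmTMB::glmmTMB(label ~ x + (1 | year),
                        data = transform(d, x = scale(x)[, 1]),
                        family = binomial())
  expect_equal(f$aic, AIC(g), tolerance = 1e-3)
})

test_that("boundary variance falls back to plain logistic with a flag", {
  d <- simulate_logistic(400, 0, 1, seed = 5)
  d$year <- rep(2015:2016, each = 200)   # year carries no signal
  f <- fit_sdm(d, c(x = "linear"), use_mixed = "auto")
  expect_true(f$fallback)
  expect_equal(f$engine, "glm")
  ## single year level can never fit a mixed model
  d1 <- d; d1$year <- 2015
  f1 <- fit_sdm(d1, c(x = "linear"), use_mixed = "auto")
  expect_true(f1$fallback)
})

test_that("data-scale coefficients reproduce standardized predictions", {
  d <- small_july_dataset()
  f <- fit_sdm(d, full_quadratic_terms(c("MINTEMP", "NDVI")))
  a <- f$coef_data
  eta_manual <- a["(Intercept)"] +
    a["MINTEMP"] * d$MINTEMP + a["MINTEMP^2"] * d$MINTEMP^2 +
    a["NDVI"] * d$NDVI + a["NDVI^2"] * d$NDVI^2
  expect_equal(unname(predict(f, d, "link")), unname(eta_manual),
               tolerance = 1e-8)
})

test_that("stepwise respects marginality and never increases AIC", {
  d <- small_july_dataset()
  full <- full_quadratic_terms(model_vars)
  f_full <- fit_sdm(d, full)
  sel <- stepwise_aic(d, full)
  expect_lte(sel$aic, f_full$aic)
  ## no quadratic without its linear term, by construction of term sets
  expect_true(all(sel$terms %in% c("linear", "quadratic")))
  path <- attr(sel, "path")
  expect_equal(path$action[1], "<full>")
  expect_true(all(diff(path$aic) < 0))
})

test_that("selection keeps the signal and drops the noise covariate", {
  ## AIC retains a useless single term when its LRT statistic exceeds 2,
  ## which happens with the chi-square(1) tail probability 0.157, so a
  ## pure-noise covariate survives (either term) in roughly a quarter of
  ## replicates by design of the criterion itself; the consistency claims
  ## that hold are majority removal of noise and near-certain retention of
  ## the true signal
  dropped <- 0; signal_kept <- 0
  n_rep <- 40
  for (seed in seq_len(n_rep)) {
    set.seed(300 + seed)
    n <- 400
    x <- rnorm(n); noise <- rnorm(n)
    d <- data.frame(label = rbinom(n, 1, plogis(1.2 * x - 0.8 * x^2)),
                    x = x, noise = noise)
    sel <- stepwise_aic(d, full_quadratic_terms(c("x", "noise")),
                        use_mixed = "never")
    dropped <- dropped + !("noise" %in% names(sel$terms))
    signal_kept <- signal_kept +
      identical(unname(sel$terms["x"]), "quadratic")
  }
  expect_gte(dropped / n_rep, 0.55)
  expect_gte(signal_kept / n_rep, 0.95)
})

test_that("stepwise equals exhaustive hierarchical-subset enumeration", {
  for (seed in c(1, 2, 3)) {
    set.seed(400 + seed)
    n <- 300
    x1 <- rnorm(n); x2 <- rnorm(n)
    d <- data.frame(label = rbinom(n, 1, plogis(0.5 + x1 - 0.7 * x1^2)),
                    x1 = x1, x2 = x2)
    sel <- stepwise_aic(d, full_quadratic_terms(c("x1", "x2")),
                        use_mixed = "never")
    ## enumerate all 9 hierarchical term subsets
    lv <- c("none", "linear", "quadratic")
    best_aic <- Inf; best_terms <- NULL
    for (t1 in lv) for (t2 in lv) {
      tt <- c(x1 = t1, x2 = t2)
      tt <- tt[tt != "none"]
      f <- fit_sdm(d, tt, use_mixed = "never")
      if (f$aic < best_aic) { best_aic <- f$aic; best_terms <- f$terms }
    }
    expect_equal(sel$aic, best_aic, tolerance = 1e-8)
    expect_identical(sel$terms, best_terms)
  }
})

test_that("constant covariates are dropped before fitting", {
  d <- small_july_dataset()
  d$flat <- 5
  f <- fit_sdm(d, full_quadratic_terms(c("MINTEMP", "flat")))
  expect_false("flat" %in% names(f$terms))
  expect_equal(f$dropped_constant, "flat")
})

test_that("cross-validation partitions rows into stratified folds", {
  d <- small_july_dataset()
  f <- stepwise_aic(d, full_quadratic_terms(model_vars))
  cvr <- cross_validate(d, f$terms, k = 5, seed = 4)
  folds <- attr(cvr, "folds")
  expect_equal(length(folds), nrow(d))
  expect_true(all(folds %in% 1:5))           # every row in exactly one fold
  for (i in 1:5)
    expect_setequal(unique(d$label[folds == i]), c(0, 1))
  expect_equal(nrow(cvr), 5 * 3)             # 5 folds x 3 threshold rules
  ## AUC is threshold-free: identical across rules within a fold
  expect_true(all(tapply(cvr$auc, cvr$fold, function(v)
    length(unique(v))) == 1))
  expect_true(all(cvr$auc >= 0 & cvr$auc <= 1))
  expect_true(all(cvr$sens >= 0 & cvr$sens <= 1))
})

test_that("cross-validation errors when a class has fewer members than folds", {
  d <- small_july_dataset()[1:8, ]
  expect_error(cross_validate(d, c(MINTEMP = "linear"), k = 5, seed = 1),
               "each class")
})

test_that("strongly separable data yields mean CV AUC > 0.9", {
  set.seed(55)
  n <- 200
  x <- c(rnorm(n / 2, -2), rnorm(n / 2, 2))
  d <- data.frame(label = rep(c(0, 1), each = n / 2), x = x)
  cvr <- cross_validate(d, c(x = "linear"), k = 5, seed = 2)
  expect_gt(attr(cvr, "summary")$auc[1], 0.9)
})
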