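test_that("AUROC handles perfect ordering, ties, and chance", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c("bad", "bad", "good", "good")), 1)
  expect_equal(roc_auc(c(0.8, 0.4, 0.4, 0.2),
                       c("bad", "bad", "good", "good")), 0.875)
  expect_error(roc_auc(1:3, rep("bad", 3)), "both classes")
  set.seed(20)
  s <- runif(2000); y <- sample(c("bad", "good"), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(s, y) - 0.5), 0.03)
})

test_that("AUROC equals the brute-force pair-counting oracle", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    s <- sample(round(runif(n), 2))  # rounded scores force ties
    y <- sample(c(rep("bad", 2), rep("good", 2),
                  sample(c("bad", "good"), n - 4, replace = TRUE)))
    expect_equal(roc_auc(s, y), auc_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("classification metrics do the confusion arithmetic", {
  all_good <- classification_metrics(rep("good", 4), rep("good", 4))
  expect_equal(unname(all_good["accuracy"]), 100)
  # TP=2 FN=0 TN=5 FP=2 with positive = good
  pred <- c(rep("good", 4), rep("bad", 5))
  truth <- c(rep("good", 2), rep("bad", 7))
  m <- classification_metrics(pred, truth, positive = "good")
  expect_equal(unname(m["sensitivity"]), 100)
  expect_equal(unname(m["specificity"]), 100 * 5 / 7, tolerance = 1e-10)
  expect_equal(unname(m["accuracy"]), 100 * 7 / 9, tolerance = 1e-10)
  # degenerate single-class predictions keep F1 defined
  z <- classification_metrics(rep("bad", 5), c("good", rep("bad", 4)))
  expect_equal(unname(z["f1"]), 0)
  expect_error(classification_metrics(character(0), character(0)), "empty")
})

test_that("Kaplan-Meier estimates match hand computation and an oracle", {
  flat <- km_curve(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(flat$surv == 1))
  two <- km_curve(c(1, 2), c(1, 1))
  expect_equal(two$surv, c(0.5, 0))
  set.seed(22)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    t <- round(runif(n, 1, 50)); e <- rbinom(n, 1, 0.6)
    km <- km_curve(t, e)
    orc <- km_oracle(t, e)
    expect_equal(km$surv[match(orc$time, km$time)], orc$surv, tolerance = 1e-12)
    expect_equal(sum(km$n_event), sum(e))
  }
})

test_that("log-rank: identical groups, order invariance, oracle, and power", {
  t <- c(3, 6, 9, 12); e <- c(1, 0, 1, 1)
  same <- logrank_test(t, e, t, e)
  expect_equal(same$chisq, 0, tolerance = 1e-10)
  expect_equal(same$p, 1, tolerance = 1e-10)
  set.seed(23)
  t1 <- rexp(10, 0.1); e1 <- rbinom(10, 1, 0.8)
  t2 <- rexp(10, 0.3); e2 <- rbinom(10, 1, 0.8)
  ord <- sample(10)
  a <- logrank_test(t1, e1, t2, e2)
  b <- logrank_test(t1[ord], e1[ord], t2, e2)
  expect_equal(a$chisq, b$chisq)
  expect_equal(a$chisq, logrank_oracle(t1, e1, t2, e2), tolerance = 1e-8)
  hits <- 0
  for (s in 1:100) {
    x1 <- rexp(200, 0.03); x2 <- rexp(200, 0.09)
    if (logrank_test(x1, rep(1, 200), x2, rep(1, 200))$p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 95)
  expect_error(logrank_test(numeric(0), numeric(0), t, e), "non-empty")
})

test_that("Cox HR: brute-force likelihood, null behaviour, and recovery", {
  set.seed(24)
  t <- c(2, 4, 5, 7, 8, 11, 13, 16, 21, 25)
  e <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1)
  g <- rep(c(0, 1), 5)
  fit <- cox_hr_binary(t, e, g)
  beta_grid <- optimize(function(b) -cox_pl_oracle(b, t, e, g), c(-5, 5),
                        tol = 1e-9)$minimum
  expect_equal(fit$beta, beta_grid, tolerance = 1e-4)
  expect_true(fit$ci[1] <= fit$hr && fit$hr <= fit$ci[2])
  # null: group-independent hazards, CI covers 1 most of the time
  cover <- 0
  for (s in 1:50) {
    tt <- rexp(400, 0.05); gg <- rep(c(0, 1), 200)
    f <- cox_hr_binary(tt, rep(1, 400), gg)
    if (f$ci[1] <= 1 && 1 <= f$ci[2]) cover <- cover + 1
  }
  expect_gte(cover, 43)
  # recovery of a rate ratio of 3 at n = 1000
  t0 <- rexp(500, 0.02); t1 <- rexp(500, 0.06)
  f3 <- cox_hr_binary(c(t0, t1), rep(1, 1000),
                      factor(rep(c("lo", "hi"), each = 500),
                             levels = c("lo", "hi")))
  expect_lt(abs(f3$hr - 3) / 3, 0.2)
  expect_error(cox_hr_binary(c(1, 2), c(0, 0), c(0, 1)), "no events")
})

test_that("Cox direction agrees with the log-rank worse group", {
  set.seed(25)
  for (i in 1:10) {
    n <- 120
    g <- rep(c("low", "high"), each = n / 2)
    rate <- ifelse(g == "high", 0.08, 0.02)
    t <- rexp(n, rate); e <- rep(1, n)
    f <- cox_hr_binary(t, e, factor(g, levels = c("low", "high")))
    expect_gt(f$hr, 1)
  }
})

test_that("TNM stratification puts only stage IV in the high-risk group", {
  expect_equal(tnm_stratify(c("II", "IIIA", "IIIB", "IV")),
               c("low", "low", "low", "high"))
  expect_error(tnm_stratify("III"), "unknown stage")
})

test_that("cohort summary rounds percentages half-up like a clinical table", {
  clin <- data.frame(
    age = rep(66, 78),
    sex = c(rep("male", 43), rep("female", 35)),
    stage = c(rep("II", 17), rep("IIIA", 29), rep("IIIB", 5), rep("IV", 27)),
    T_stage = c(rep("T2", 18), rep("T3", 39), rep("T4", 21)),
    N_stage = c(rep("N0", 57), rep("N1", 13), rep("N2", 8)),
    M_stage = c(rep("M0", 51), rep("M1", 27)),
    survival_months = rep(19, 78))
  s <- cohort_summary(clin)
  expect_equal(s$sex$percent, c(55, 45))
  expect_equal(s$stage$percent, c(22, 37, 6, 35))
  expect_equal(s$T_stage$percent, c(23, 50, 27))
  expect_equal(s$N_stage$percent, c(73, 17, 10))
  expect_equal(s$M_stage$percent, c(65, 35))
  expect_error(cohort_summary(clin[0, ]), "empty")
})

test_that("importance thresholds follow the 2x mean / 2x median rules", {
  set.seed(26)
  n <- 80
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- ifelse(X[, 1] + 0.3 * rnorm(n) > 0, "bad", "good")
  lr <- fit_submodel("logistic_model", X, y, n_configs = 5, seed = 27)
  imp <- feature_importance(lr)
  expect_equal(imp$rule, "2x mean")
  expect_equal(imp$threshold, 2 * mean(imp$ranked$importance))
  expect_true("f1" %in% imp$retained)
  expect_setequal(imp$retained,
                  imp$ranked$feature[imp$ranked$importance >= imp$threshold &
                                       imp$ranked$importance > 0])
  sv <- fit_submodel("svm", X, y, n_configs = 5, seed = 28,
                     fixed = list(kernel = "linear"))
  impsv <- feature_importance(sv)
  expect_equal(impsv$rule, "2x median")
  expect_equal(impsv$threshold, 2 * median(impsv$ranked$importance))
  expect_true("f1" %in% impsv$retained)
  rbf <- fit_submodel("svm", X, y, n_configs = 3, seed = 29,
                      fixed = list(kernel = "radial", gamma = 0.1))
  expect_error(feature_importance(rbf), "linear")
  rf <- fit_submodel("random_forest", X, y, n_configs = 3, seed = 30)
  imprf <- feature_importance(rf)
  expect_equal(imprf$ranked$feature[1], "f1")
  dt <- fit_submodel("decision_tree", X, y, n_configs = 3, seed = 31)
  impdt <- feature_importance(dt)
  expect_true(all(impdt$ranked$importance >= 0))
})
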