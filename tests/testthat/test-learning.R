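sep_data <- function(n = 60, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  y <- ifelse(X[, 1] > 0, "bad", "good")
  X[, 1] <- X[, 1] + sign(X[, 1])  # widen the margin
  list(X = X, y = y)
}

test_that("sampled hyperparameters respect the search distributions", {
  set.seed(10)
  for (fam in algorithm_families()) {
    for (i in 1:30) {
      cfg <- immunocontext:::.sample_config(fam)
      switch(fam,
        decision_tree = {
          expect_true(cfg$maxdepth %in% 1:20 && cfg$minbucket %in% 1:20)
          expect_true(cfg$split %in% c("gini", "information"))
        },
        random_forest = {
          expect_true(cfg$num_trees %in% 50:500 && cfg$max_depth %in% 1:20)
          expect_true(cfg$feature_fraction >= 0.1 && cfg$feature_fraction <= 1)
        },
        svm = {
          expect_true(cfg$kernel %in% c("linear", "radial"))
          expect_true(cfg$cost >= 1e-3 && cfg$cost <= 1e3)
        },
        logistic_model = {
          expect_true(cfg$penalty %in% c("L1", "L2"))
          expect_true(cfg$lambda >= 1e-3 && cfg$lambda <= 1e3)
        },
        knn = {
          expect_true(cfg$k %in% 1:25)
          expect_true(cfg$weighting %in% c("uniform", "distance"))
        })
    }
  }
})

test_that("random search evaluates n_configs and returns a pinned winner when collapsed", {
  d <- sep_data()
  pin <- list(k = 7, weighting = "uniform")
  rs <- random_search("knn", d$X, d$y, n_configs = 8, folds = 3, seed = 2,
                      fixed = pin)
  expect_equal(rs$n_evaluated, 8)
  expect_equal(rs$config[names(pin)], pin)
  rs2 <- random_search("knn", d$X, d$y, n_configs = 8, folds = 3, seed = 2,
                       fixed = pin)
  expect_identical(rs$config, rs2$config)
  expect_identical(rs$cv_scores, rs2$cv_scores)
})

test_that("perfectly separable data reach CV AUROC 1", {
  d <- sep_data(n = 60)
  rs <- random_search("svm", d$X, d$y, n_configs = 5, folds = 5, seed = 4,
                      fixed = list(kernel = "linear", cost = 1))
  expect_equal(rs$cv_mean, 1)
  expect_error(random_search("svm", d$X, rep("bad", 60), n_configs = 2, seed = 1),
               "both")
})

test_that("nested selection finds the family that can read an oracle feature", {
  set.seed(12)
  n <- 60
  X <- cbind(oracle = rep(c(1, 0), n / 2), noise = rnorm(n))
  y <- ifelse(X[, "oracle"] == 1, "bad", "good")
  ns <- nested_select(X, y, families = c("decision_tree", "knn"),
                      n_configs = 5, seed = 5)
  expect_equal(mean(as.numeric(ns$scores[ns$family, ])), 1)
  expect_match(ns$summary$formatted[1], "^[0-9.]+±[0-9.]+$")
})

test_that("pure-noise labels give chance-level outer AUROC", {
  set.seed(14)
  n <- 200
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- sample(rep(c("bad", "good"), n / 2))
  ns <- nested_select(X, y, n_configs = 8, seed = 6)
  win <- mean(as.numeric(ns$scores[ns$family, ]))
  expect_gt(win, 0.35)
  expect_lt(win, 0.65)
})

test_that("final submodels separate separable data and are reproducible", {
  d <- sep_data(n = 50)
  sm <- fit_submodel("decision_tree", d$X, d$y, n_configs = 6, seed = 7)
  expect_equal(sm$train_auroc, 1)
  pr <- predict_submodel(sm, d$X)
  expect_equal(pr$prediction, d$y)
  sm2 <- fit_submodel("decision_tree", d$X, d$y, n_configs = 6, seed = 7)
  expect_identical(predict_submodel(sm2, d$X)$score, pr$score)
  smrf <- fit_submodel("random_forest", d$X, d$y, n_configs = 4, seed = 8)
  expect_identical(predict_submodel(smrf, d$X)$score,
                   predict_submodel(fit_submodel("random_forest", d$X, d$y,
                                                 n_configs = 4, seed = 8),
                                    d$X)$score)
})

test_that("the Youden threshold maximises sensitivity + specificity - 1", {
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.1)
  y <- c("bad", "bad", "good", "bad", "good", "good")
  thr <- youden_threshold(scores, y)
  # brute force over candidate thresholds
  Js <- sapply(unique(scores), function(t) {
    pred <- scores >= t
    sum(pred & y == "bad") / 3 + sum(!pred & y == "good") / 3 - 1
  })
  pred <- scores >= thr
  J <- sum(pred & y == "bad") / 3 + sum(!pred & y == "good") / 3 - 1
  expect_equal(J, max(Js))
})

test_that("ensemble vote rule: high risk iff two or more bad votes", {
  combos <- expand.grid(v1 = c("bad", "good"), v2 = c("bad", "good"),
                        v3 = c("bad", "good"), v4 = c("bad", "good"),
                        stringsAsFactors = FALSE)
  features <- data.frame(x = 1)  # stubs ignore content
  for (i in seq_len(nrow(combos))) {
    ens <- list(submodels = lapply(as.character(combos[i, ]), stub_vote),
                vote_threshold = 2)
    pr <- ensemble_predict(ens, features)
    n_bad <- sum(combos[i, ] == "bad")
    expect_equal(pr$votes, n_bad)
    expect_equal(pr$risk, ifelse(n_bad >= 2, "high", "low"))
  }
})

test_that("flipping a vote from good to bad never lowers the risk", {
  features <- data.frame(x = 1)
  for (i in 0:3) {
    base <- c(rep("bad", i), rep("good", 4 - i))
    flip <- base; flip[match("good", flip)] <- "bad"
    r0 <- ensemble_predict(list(submodels = lapply(base, stub_vote),
                                vote_threshold = 2), features)$risk
    r1 <- ensemble_predict(list(submodels = lapply(flip, stub_vote),
                                vote_threshold = 2), features)$risk
    expect_false(r0 == "high" && r1 == "low")
  }
})

test_that("tuning and training never touch held-out test rows", {
  set.seed(15)
  n <- 40
  sc <- feature_schema()
  fm <- as.data.frame(matrix(rnorm(n * 201), n, 201,
                             dimnames = list(NULL, sc$all)),
                      check.names = FALSE)
  fm <- cbind(patient_id = sprintf("P%02d", 1:n), fm)
  y <- rep(c("bad", "good"), n / 2)
  sp <- stratified_split(y, 0.25, seed = 9)
  audit_start()
  ens <- build_ensemble(fm[sp$train, ], y[sp$train], n_configs = 2, seed = 10)
  rs <- random_search("knn", as.matrix(fm[sp$train, sc$clinical]), y[sp$train],
                      n_configs = 2, folds = 2, seed = 11,
                      ids = fm$patient_id[sp$train])
  touched <- audit_stop()
  test_ids <- fm$patient_id[sp$test]
  expect_length(intersect(touched, test_ids), 0)
  expect_gt(length(touched), 0)
  # prediction on the test set still works after the audit
  expect_equal(nrow(ensemble_predict(ens, fm[sp$test, ])), length(sp$test))
})

test_that("normalisation statistics come from training folds only", {
  set.seed(16)
  X <- matrix(rnorm(30 * 3), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("bad", "good"), 15)
  m <- immunocontext:::.fit_model("knn", list(k = 3, weighting = "uniform"),
                                  X[1:20, ], y[1:20])
  expect_equal(m$norm$center, colMeans(X[1:20, ]))
  expect_equal(m$norm$scale, apply(X[1:20, ], 2, sd))
})
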