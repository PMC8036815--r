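#' @useDynLib immunocontext, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- leakage audit -------------------------------------------------------

.audit_env <- new.env(parent = emptyenv())
.audit_env$active <- FALSE
.audit_env$ids <- character(0)

#' Row-access audit for leakage checks
#'
#' While enabled, every training-side routine ([random_search()],
#' [nested_select()], [fit_submodel()], [build_ensemble()]) records the
#' patient ids of the rows it touches.  Comparing the log against the
#' held-out test ids verifies that model selection and tuning never see
#' test rows.
#'
#' @return `audit_start()` clears the log and enables recording;
#'   `audit_stop()` disables recording and returns the character vector
#'   of accessed ids.
#' @export
audit_start <- function() {
  .audit_env$active <- TRUE
  .audit_env$ids <- character(0)
  invisible(NULL)
}

#' @rdname audit_start
#' @export
audit_stop <- function() {
  .audit_env$active <- FALSE
  unique(.audit_env$ids)
}

.audit_touch <- function(ids) {
  if (isTRUE(.audit_env$active) && length(ids))
    .audit_env$ids <- c(.audit_env$ids, as.character(ids))
  invisible(NULL)
}

# ---- algorithm space -----------------------------------------------------

#' The five classifier families
#'
#' Decision tree, random forest, support vector machine, regularised
#' logistic model (the pipeline's "LR" family) and k-nearest
#' neighbours.  Feature normalisation (z-scoring with training-fold
#' statistics) is applied to all families except the two tree-based
#' ones, which are scale-invariant.
#'
#' @return character vector of family names.
#' @export
algorithm_families <- function() {
  c("decision_tree", "random_forest", "svm", "logistic_model", "knn")
}

.needs_norm <- function(family) family %in% c("svm", "logistic_model", "knn")

# draw one hyperparameter configuration from the family's search
# distributions (consumes the current RNG stream)
.sample_config <- function(family) {
  switch(family,
    decision_tree = list(maxdepth = sample.int(20, 1),
                         minbucket = sample.int(20, 1),
                         split = sample(c("gini", "information"), 1)),
    random_forest = list(num_trees = sample(50:500, 1),
                         max_depth = sample.int(20, 1),
                         feature_fraction = stats::runif(1, 0.1, 1)),
    svm = {
      kernel <- sample(c("linear", "radial"), 1)
      list(kernel = kernel,
           cost = 10^stats::runif(1, -3, 3),
           gamma = if (kernel == "radial") 10^stats::runif(1, -4, 1) else NA_real_)
    },
    logistic_model = list(penalty = sample(c("L1", "L2"), 1),
                          lambda = 10^stats::runif(1, -3, 3)),
    knn = list(k = sample.int(25, 1),
               weighting = sample(c("uniform", "distance"), 1)),
    stop("unknown family: ", family))
}

.norm_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.norm_apply <- function(X, norm) {
  if (is.null(norm)) return(X)
  sweep(sweep(X, 2, norm$center), 2, norm$scale, "/")
}

# ---- single-model fit / predict ------------------------------------------

.fit_model <- function(family, config, X, y, seed = 1L) {
  stopifnot(is.matrix(X))
  y <- factor(as.character(y), levels = c("good", "bad"))
  if (any(is.na(y)) || nlevels(droplevels(y)) != 2)
    stop("labels must take both values 'good' and 'bad'")
  norm <- if (.needs_norm(family)) .norm_fit(X) else NULL
  Xn <- .norm_apply(X, norm)
  fit <- switch(family,
    decision_tree = {
      df <- data.frame(.y = y, Xn, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = config$split),
                   control = rpart::rpart.control(maxdepth = config$maxdepth,
                                                  minbucket = config$minbucket,
                                                  cp = 0, xval = 0))
    },
    random_forest = ranger::ranger(
      x = as.data.frame(Xn), y = y, num.trees = config$num_trees,
      max.depth = config$max_depth,
      mtry = max(1L, floor(config$feature_fraction * ncol(Xn))),
      probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1),
    svm = {
      args <- list(x = Xn, y = y, kernel = config$kernel, cost = config$cost,
                   scale = FALSE, probability = FALSE)
      if (config$kernel == "radial") args$gamma <- config$gamma
      do.call(e1071::svm, args)
    },
    logistic_model = glmnet::glmnet(
      Xn, y, family = "binomial",
      alpha = if (config$penalty == "L1") 1 else 0,
      lambda = config$lambda, standardize = FALSE),
    knn = list(X = Xn, y_bad = y == "bad", k = config$k,
               weighting = config$weighting),
    stop("unknown family: ", family))
  structure(list(family = family, config = config, fit = fit, norm = norm,
                 features = colnames(X)),
            class = "ic_model")
}

# score oriented so that larger = more likely bad prognosis
.predict_score <- function(model, X) {
  stopifnot(inherits(model, "ic_model"))
  if (!is.null(model$features)) X <- X[, model$features, drop = FALSE]
  Xn <- .norm_apply(X, model$norm)
  switch(model$family,
    decision_tree = {
      p <- predict(model$fit, newdata = data.frame(Xn, check.names = FALSE),
                   type = "prob")
      as.numeric(p[, "bad"])
    },
    random_forest = {
      p <- predict(model$fit, data = as.data.frame(Xn), num.threads = 1)$predictions
      as.numeric(p[, "bad"])
    },
    svm = {
      pr <- predict(model$fit, Xn, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      first <- strsplit(colnames(dv)[1], "/")[[1]][1]
      if (identical(first, "bad")) as.numeric(dv[, 1]) else -as.numeric(dv[, 1])
    },
    logistic_model = as.numeric(predict(model$fit, newx = Xn, type = "response")),
    knn = {
      tr <- model$fit$X
      k <- min(model$fit$k, nrow(tr))
      d2 <- outer(rowSums(Xn^2), rowSums(tr^2), "+") - 2 * Xn %*% t(tr)
      d2[d2 < 0] <- 0
      apply(d2, 1, function(row) {
        nb <- order(row)[seq_len(k)]
        w <- if (model$fit$weighting == "distance") 1 / (sqrt(row[nb]) + 1e-8)
             else rep(1, k)
        sum(w * model$fit$y_bad[nb]) / sum(w)
      })
    })
}

# stratified fold assignment; every fold holds members of each class
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(as.character(y))) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.check_two_classes <- function(y) {
  if (length(unique(as.character(y))) < 2)
    stop("training data must contain both prognosis classes")
}

# ---- random search --------------------------------------------------------

#' Random hyperparameter search with stratified k-fold CV
#'
#' Samples `n_configs` configurations from the family's hyperparameter
#' distributions and scores each by mean AUROC over stratified
#' cross-validation folds.  Normalisation statistics are computed on the
#' training part of each fold only.  Ties on mean AUROC are broken by
#' lower across-fold variance, then by sampling order.
#'
#' @param family one of [algorithm_families()].
#' @param X numeric feature matrix.
#' @param y labels, values "good"/"bad".
#' @param n_configs number of sampled configurations (default 200).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed (governs sampling and fold assignment).
#' @param ids optional patient ids per row, recorded by the leakage
#'   audit.
#' @param fixed named list of hyperparameters pinned to given values
#'   (e.g. `list(kernel = "linear")`), overriding the sampled ones.
#' @return list with `config` (winner), `cv_mean`, `cv_scores`
#'   (winner's per-fold AUROC), `n_evaluated`, and `all` (data frame of
#'   every configuration's mean and variance).
#' @export
random_search <- function(family, X, y, n_configs = 200, folds = 5, seed = 1L,
                          ids = NULL, fixed = NULL) {
  .check_two_classes(y)
  .audit_touch(if (is.null(ids)) rownames(X) else ids)
  set.seed(seed)
  configs <- lapply(seq_len(n_configs), function(i) {
    cfg <- .sample_config(family)
    if (!is.null(fixed)) cfg <- utils::modifyList(cfg, fixed)
    cfg
  })
  fold <- .stratified_folds(y, folds)
  score_mat <- matrix(NA_real_, n_configs, folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (c in seq_len(n_configs)) {
      m <- .fit_model(family, configs[[c]], X[tr, , drop = FALSE], y[tr],
                      seed = seed + c)
      s <- .predict_score(m, X[!tr, , drop = FALSE])
      score_mat[c, f] <- roc_auc(s, y[!tr], positive = "bad")
    }
  }
  means <- rowMeans(score_mat)
  vars <- apply(score_mat, 1, stats::var)
  best <- order(-means, vars, seq_len(n_configs))[1]
  list(config = configs[[best]], cv_mean = means[best],
       cv_scores = score_mat[best, ], n_evaluated = n_configs,
       all = data.frame(config = seq_len(n_configs), mean = means, var = vars))
}

# ---- nested selection -----------------------------------------------------

#' Nested cross-validation algorithm selection
#'
#' Outer stratified CV (default 2 folds) compares classifier families;
#' within each outer training part, every family is tuned by
#' [random_search()] (inner CV, default 5 folds) and the tuned model is
#' scored on the outer evaluation fold.  The family with the highest
#' mean outer AUROC wins; ties go to the family with the least variance
#' across outer folds.
#'
#' @inheritParams random_search
#' @param families families to compare (default all five).
#' @param outer_folds,inner_folds fold counts for the two CV levels.
#' @return list with `family` (winner), `scores` (family x fold AUROC
#'   data frame), and `summary` (per family: mean, half-range formatted
#'   as `"mean +/- halfrange"`).
#' @export
nested_select <- function(X, y, families = algorithm_families(),
                          outer_folds = 2, inner_folds = 5,
                          n_configs = 200, seed = 1L, ids = NULL) {
  .check_two_classes(y)
  .audit_touch(if (is.null(ids)) rownames(X) else ids)
  set.seed(seed)
  fold <- .stratified_folds(y, outer_folds)
  scores <- matrix(NA_real_, length(families), outer_folds,
                   dimnames = list(families, NULL))
  for (f in seq_len(outer_folds)) {
    tr <- fold != f
    for (fam in families) {
      rs <- random_search(fam, X[tr, , drop = FALSE], y[tr],
                          n_configs = n_configs, folds = inner_folds,
                          seed = .subseed(seed, f * 100 + match(fam, families)),
                          ids = character(0))
      m <- .fit_model(fam, rs$config, X[tr, , drop = FALSE], y[tr],
                      seed = .subseed(seed, f))
      s <- .predict_score(m, X[!tr, , drop = FALSE])
      scores[fam, f] <- roc_auc(s, y[!tr], positive = "bad")
    }
  }
  means <- rowMeans(scores)
  vars <- apply(scores, 1, stats::var)
  win <- families[order(-means, vars, seq_along(families))[1]]
  halfrange <- apply(scores, 1, function(v) diff(range(v)) / 2)
  summary <- data.frame(family = families, mean_auroc = means,
                        halfrange = halfrange,
                        formatted = sprintf("%.1f±%.1f", 100 * means,
                                            100 * halfrange))
  list(family = win, scores = as.data.frame(scores), summary = summary)
}

.subseed <- function(seed, i) as.integer((as.numeric(seed) * 1103 + i * 7919) %% 2147483647L)

# ---- final submodel fit ---------------------------------------------------

#' Tune and fit a final submodel with an operating threshold
#'
#' Runs [random_search()] on the whole training set, refits the winning
#' configuration on all training rows, and selects the decision
#' threshold maximising Youden's J (sensitivity + specificity - 1) on
#' the training ROC; predictions are bad-prognosis when the score is at
#' or above the threshold.
#'
#' @inheritParams random_search
#' @param feature_set optional feature-set name stored for bookkeeping.
#' @return object of class `ic_submodel`: the fitted `ic_model` plus
#'   `threshold`, `config`, `feature_set`, `train_auroc`.
#' @export
fit_submodel <- function(family, X, y, n_configs = 200, folds = 5, seed = 1L,
                         feature_set = NULL, ids = NULL, fixed = NULL) {
  .audit_touch(if (is.null(ids)) rownames(X) else ids)
  rs <- random_search(family, X, y, n_configs = n_configs, folds = folds,
                      seed = seed, ids = character(0), fixed = fixed)
  model <- .fit_model(family, rs$config, X, y, seed = seed)
  s <- .predict_score(model, X)
  thr <- youden_threshold(s, y)
  structure(list(model = model, family = family, config = rs$config,
                 threshold = thr, feature_set = feature_set,
                 train_auroc = roc_auc(s, y, positive = "bad"),
                 cv_mean = rs$cv_mean),
            class = "ic_submodel")
}

#' Youden-optimal threshold on training scores
#'
#' Among the observed score values, picks the threshold (predict bad iff
#' score >= threshold) maximising J = sensitivity + specificity - 1 on
#' the bad class; ties go to the higher threshold (fewer positives).
#'
#' @param scores numeric scores, larger = more likely bad.
#' @param y labels "good"/"bad".
#' @return numeric threshold.
#' @export
youden_threshold <- function(scores, y) {
  .check_two_classes(y)
  cand <- sort(unique(scores), decreasing = TRUE)
  bad <- y == "bad"
  J <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & bad) / sum(bad)
    spec <- sum(!pred & !bad) / sum(!bad)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(J)]
}

#' Predict with a fitted submodel
#'
#' @param submodel an `ic_submodel`.
#' @param X feature matrix (must contain the submodel's columns).
#' @return list with numeric `score` and character `prediction`
#'   ("bad"/"good").
#' @export
predict_submodel <- function(submodel, X) {
  stopifnot(inherits(submodel, "ic_submodel"))
  s <- .predict_score(submodel$model, X)
  list(score = s, prediction = ifelse(s >= submodel$threshold, "bad", "good"))
}

# ---- ensemble -------------------------------------------------------------

#' The reference four-submodel ensemble composition
#'
#' A linear-kernel SVM on image features, a decision tree on image and
#' clinical features, a logistic model on image and spatial features,
#' and a random forest on all features.
#'
#' @return list of four `(family, feature_set, fixed)` entries; the SVM
#'   entry fixes the kernel to linear.
#' @export
default_ensemble_spec <- function() {
  list(
    list(family = "svm", feature_set = "image", fixed = list(kernel = "linear")),
    list(family = "decision_tree", feature_set = "image and clinical", fixed = NULL),
    list(family = "logistic_model", feature_set = "image and spatial", fixed = NULL),
    list(family = "random_forest", feature_set = "image, spatial, and clinical",
         fixed = NULL))
}

#' Train the majority-vote ensemble
#'
#' Fits the four submodels of [default_ensemble_spec()] (each tuned by
#' [fit_submodel()] on its feature subset) and assembles them into a
#' voting ensemble: a patient is high risk when at least `vote_threshold`
#' submodels predict a bad prognosis.
#'
#' @param features data frame with `patient_id` plus the 201 schema
#'   columns (training rows only).
#' @param labels "good"/"bad" per row.
#' @param n_configs configurations per submodel search.
#' @param seed integer seed.
#' @param vote_threshold votes needed for high risk (default 2).
#' @param spec ensemble composition (default [default_ensemble_spec()]).
#' @return object of class `ic_ensemble`.
#' @export
build_ensemble <- function(features, labels, n_configs = 200, seed = 1L,
                           vote_threshold = 2, spec = default_ensemble_spec()) {
  stopifnot(vote_threshold %in% 1:4)
  ids <- if ("patient_id" %in% names(features)) features$patient_id else rownames(features)
  .audit_touch(ids)
  submodels <- lapply(seq_along(spec), function(k) {
    sp <- spec[[k]]
    Xk <- .feature_matrix(feature_subset(features, sp$feature_set))
    fit_submodel(sp$family, Xk, labels, n_configs = n_configs,
                 seed = .subseed(seed, k), feature_set = sp$feature_set,
                 ids = character(0), fixed = sp$fixed)
  })
  structure(list(submodels = submodels, vote_threshold = vote_threshold,
                 seed = seed),
            class = "ic_ensemble")
}

#' Ensemble risk prediction by submodel vote
#'
#' Each submodel casts a bad-prognosis vote when its thresholded score
#' says so; the vote count (0-4) is the ensemble's ordinal score and a
#' patient is high risk iff the count reaches the vote threshold.
#'
#' @param ensemble an `ic_ensemble` (or a list with `submodels` of
#'   objects answering [predict_submodel()], for stubbing).
#' @param features data frame with the 201 schema columns.
#' @return data frame with `votes` (integer 0-4) and `risk`
#'   ("high"/"low").
#' @export
ensemble_predict <- function(ensemble, features) {
  vm <- vapply(ensemble$submodels, function(sm) {
    if (is.function(sm)) return(as.numeric(sm(features) == "bad"))
    Xk <- .feature_matrix(feature_subset(features, sm$feature_set))
    as.numeric(predict_submodel(sm, Xk)$prediction == "bad")
  }, numeric(nrow(features)))
  if (is.null(dim(vm))) vm <- matrix(vm, nrow = nrow(features))
  votes <- rowSums(vm)
  data.frame(votes = as.integer(votes),
             risk = ifelse(votes >= ensemble$vote_threshold, "high", "low"))
}

.feature_matrix <- function(features) {
  drop <- intersect(c("patient_id"), names(features))
  m <- as.matrix(features[, setdiff(names(features), drop), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- if ("patient_id" %in% names(features)) features$patient_id else NULL
  m
}
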