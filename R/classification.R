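# Leave-one-subject-out feature-selection classification framework.
#
# For each held-out subject, features are ranked on the training subjects
# only (no leakage); for every feature count j in the grid a classifier is
# trained on the top-j features and the held-out subject classified. The
# accuracy curve over feature counts is averaged across folds, the optimal
# feature count K is its argmax (smallest K on ties), and the final feature
# set is the K features most frequent among the folds' top-K selections
# (occurrence-rate ranking). Note the published procedure picks K from the
# same curve the held-out subjects produced — a mild optimistic selection
# bias inherent to the framework; see the methods vignette.

.FS_METHODS <- c("Corr", "Fisher", "Relief", "LARS")
.CLASSIFIERS <- c("LR", "Boost", "Tree", "RF")

# ---- feature scoring -------------------------------------------------------

.score_corr <- function(X, y01) {
  suppressWarnings(abs(as.numeric(stats::cor(X, y01))))
}

.score_fisher <- function(X, y) {
  lv <- levels(y)
  n_c <- table(y)
  mu <- colMeans(X)
  num <- den <- numeric(ncol(X))
  for (g in lv) {
    Xg <- X[y == g, , drop = FALSE]
    mg <- colMeans(Xg)
    vg <- colMeans(sweep(Xg, 2L, mg)^2)        # population variance
    num <- num + n_c[[g]] * (mg - mu)^2
    den <- den + n_c[[g]] * vg
  }
  ifelse(den > 0, num / den, Inf * (num > 0))
}

.score_relief <- function(X, y, k = 10L) {
  n <- nrow(X)
  p <- ncol(X)
  rng <- apply(X, 2L, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xs <- sweep(X, 2L, rng, "/")
  W <- numeric(p)
  cls <- as.integer(y)
  for (i in seq_len(n)) {
    diffs <- abs(sweep(Xs, 2L, Xs[i, ]))       # n x p absolute differences
    dist <- rowSums(diffs)
    dist[i] <- Inf
    hits <- which(cls == cls[i]); hits <- hits[hits != i]
    miss <- which(cls != cls[i])
    kh <- min(k, length(hits)); km <- min(k, length(miss))
    if (kh < 1L || km < 1L) next
    nh <- hits[order(dist[hits], hits)][seq_len(kh)]
    nm <- miss[order(dist[miss], miss)][seq_len(km)]
    W <- W + colMeans(diffs[nm, , drop = FALSE]) -
      colMeans(diffs[nh, , drop = FALSE])
  }
  W / n
}

.score_lars_entry <- function(X, y01) {
  p <- ncol(X)
  corr <- .score_corr(X, y01)
  corr[is.na(corr)] <- 0
  if (p < 2L) return(list(entry = rep(1L, p), corr = corr))
  fit <- glmnet::glmnet(X, y01, family = "gaussian", alpha = 1,
                        nlambda = 200L, lambda.min.ratio = 1e-4,
                        standardize = TRUE)
  B <- as.matrix(fit$beta)
  entry <- apply(B != 0, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
  entry[is.na(entry)] <- ncol(B) + 1L          # never entered: after the path
  list(entry = entry, corr = corr)
}

#' Rank features on training data
#'
#' Deterministic ranking, best feature first. `Corr`: descending absolute
#' Pearson correlation with the class label. `Fisher`: descending Fisher
#' score `sum_c n_c (mu_c - mu)^2 / sum_c n_c sigma_c^2` with population
#' variances. `Relief`: ReliefF weights (k = 10 nearest hits/misses,
#' range-scaled Manhattan distances, every training subject used as an
#' instance, no sampling — hence deterministic). `LARS`: order of entry into
#' the least-angle/lasso regularization path (features that never enter are
#' appended in descending `|corr|`). Zero-variance features rank last.
#'
#' @param train_features Subjects x features numeric matrix.
#' @param train_labels Two-class factor (or coercible).
#' @param method One of `"Corr"`, `"Fisher"`, `"Relief"`, `"LARS"`.
#' @return Integer permutation of the feature indices, best first.
#' @export
fs_rank <- function(train_features, train_labels,
                    method = c("Corr", "Fisher", "Relief", "LARS")) {
  method <- match.arg(method)
  X <- as.matrix(train_features)
  y <- factor(train_labels)
  stopifnot(nlevels(y) == 2L, min(table(y)) >= 2L)
  y01 <- as.numeric(y) - 1
  zero_var <- apply(X, 2L, function(v) stats::sd(v) == 0)
  ord <- switch(method,
    Corr = {
      s <- .score_corr(X, y01); s[is.na(s)] <- 0
      order(-s, seq_along(s))
    },
    Fisher = {
      s <- .score_fisher(X, y); s[is.na(s)] <- 0
      order(-s, seq_along(s))
    },
    Relief = {
      s <- .score_relief(X, y); s[is.na(s)] <- 0
      order(-s, seq_along(s))
    },
    LARS = {
      le <- .score_lars_entry(X, y01)
      order(le$entry, -le$corr, seq_along(le$entry))
    })
  if (any(zero_var))
    ord <- c(ord[!zero_var[ord]], ord[zero_var[ord]])
  as.integer(ord)
}

# ---- classifiers -----------------------------------------------------------

.clf_frame <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df
}

.clf_fit <- function(classifier, X, y, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  oldseed <- .snapshot_rng()
  on.exit(.restore_rng(oldseed))
  set.seed(seed)
  switch(classifier,
    LR = {
      Xp <- if (ncol(X) < 2L) cbind(X, 0) else X   # glmnet needs >= 2 columns
      # glmnet warns about small LOOCV training classes; that is expected here
      fit <- suppressWarnings(
        glmnet::glmnet(Xp, y, family = "binomial", alpha = 0,
                       lambda = 1 / nrow(Xp), standardize = TRUE))
      list(kind = "LR", fit = fit, p = ncol(X), levels = levels(y))
    },
    Boost = .adaboost_fit(X, y, n_stumps = 50L),
    Tree = {
      df <- .clf_frame(X); df$.y <- y
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            cp = 0, minsplit = 2L, xval = 0L,
                            maxsurrogate = 0L, maxcompete = 0L))
      list(kind = "Tree", fit = fit, levels = levels(y))
    },
    RF = {
      fit <- randomForest::randomForest(.clf_frame(X), y, ntree = 100L)
      list(kind = "RF", fit = fit, levels = levels(y))
    },
    stop("unknown classifier: ", classifier))
}

.clf_predict <- function(model, X) {
  X <- as.matrix(X)
  out <- switch(model$kind,
    LR = {
      Xp <- if (model$p < 2L) cbind(X, 0) else X
      as.character(stats::predict(model$fit, newx = Xp, type = "class"))
    },
    Boost = .adaboost_predict(model, X),
    Tree = as.character(stats::predict(model$fit, newdata = .clf_frame(X),
                                       type = "class")),
    RF = as.character(stats::predict(model$fit, newdata = .clf_frame(X))))
  factor(out, levels = model$levels)
}

# Discrete AdaBoost.M1 over decision stumps (depth-1 rpart trees).
.adaboost_fit <- function(X, y, n_stumps = 50L) {
  n <- nrow(X)
  df <- .clf_frame(X)
  df$.y <- y
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_stumps)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = 1L, minsplit = 2L, minbucket = 1L,
                          cp = -1, xval = 0L, maxsurrogate = 0L,
                          maxcompete = 0L))
    pred <- stats::predict(fit, newdata = df, type = "class")
    err <- sum(w[pred != y])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break                     # perfect stump: stop early
    w <- w * exp(alpha * (pred != y)) / sum(w * exp(alpha * (pred != y)))
  }
  if (length(stumps) == 0L) { stumps <- list(fit); alphas <- 1 }
  list(kind = "Boost", stumps = stumps, alphas = alphas, levels = levels(y))
}

.adaboost_predict <- function(model, X) {
  df <- .clf_frame(X)
  score <- numeric(nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- stats::predict(model$stumps[[m]], newdata = df, type = "class")
    score <- score + model$alphas[m] * ifelse(pred == model$levels[2L], 1, -1)
  }
  ifelse(score > 0, model$levels[2L], model$levels[1L])
}

# ---- LOOCV framework -------------------------------------------------------

#' Default feature-count grid
#'
#' Dense 1..min(50, F), then log-spaced up to F. `exhaustive = TRUE` gives
#' the literal 1..F loop of the published framework.
#'
#' @param n_features Total feature count F.
#' @param exhaustive Use every feature count.
#' @return Increasing integer vector of feature counts.
#' @export
default_feature_grid <- function(n_features, exhaustive = FALSE) {
  if (exhaustive) return(seq_len(n_features))
  dense <- seq_len(min(50L, n_features))
  if (n_features <= 50L) return(dense)
  sparse <- unique(round(exp(seq(log(50), log(n_features), length.out = 20L))))
  sort(unique(c(dense, sparse)))
}

#' Leave-one-subject-out cross-validation with in-fold feature selection
#'
#' The published classification framework: per held-out subject, rank
#' features on the training subjects only, evaluate every feature count in
#' the grid, average the accuracy curve over folds, take the argmax K
#' (smallest K on ties), and rank features by occurrence among the folds'
#' top-K selections (ties broken by better mean training rank, then index).
#'
#' @param features Subjects x features matrix.
#' @param labels Two-class labels (factor or coercible); the second factor
#'   level is treated as positive (patient) for sensitivity/specificity.
#' @param fs_method Feature-selection method, see [fs_rank()].
#' @param classifier One of `"LR"`, `"Boost"`, `"Tree"`, `"RF"`.
#' @param feature_grid Increasing feature counts to evaluate (default
#'   [default_feature_grid()]).
#' @param seed Seed; per-fold classifier seeds derive from it, so reruns are
#'   identical.
#' @return A `cv_result`: list with `acc_matrix` (subjects x grid), `ACC_CV`,
#'   `feature_grid`, `K`, `acc` (ACC_CV at K), `sem` (SE of the per-fold 0/1
#'   accuracies at K, `sqrt(p(1-p)/N)`), `optimal_features`, `occurrence`,
#'   `confusion` (2x2, rows = truth), `sensitivity`, `specificity`,
#'   `fold_rankings`, `fs_method`, `classifier`.
#' @export
run_loocv <- function(features, labels, fs_method = "Corr",
                      classifier = "LR", feature_grid = NULL, seed = 1L) {
  X <- as.matrix(features)
  y <- factor(labels)
  N <- nrow(X)
  F_ <- ncol(X)
  stopifnot(N >= 4L, nlevels(y) == 2L, min(table(y)) >= 2L)
  if (is.null(feature_grid)) feature_grid <- default_feature_grid(F_)
  feature_grid <- sort(unique(as.integer(feature_grid)))
  stopifnot(all(feature_grid >= 1L), all(feature_grid <= F_))
  G <- length(feature_grid)
  acc <- matrix(NA_real_, N, G)
  pred <- matrix(NA_character_, N, G)
  keep_r <- max(feature_grid)
  fold_rankings <- matrix(NA_integer_, N, keep_r)
  rank_position <- matrix(NA_integer_, N, F_)   # fold x feature -> rank
  for (i in seq_len(N)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    rk <- fs_rank(Xtr, ytr, fs_method)
    fold_rankings[i, ] <- rk[seq_len(keep_r)]
    rank_position[i, rk] <- seq_len(F_)
    for (gi in seq_len(G)) {
      j <- feature_grid[gi]
      sel <- rk[seq_len(j)]
      model <- .clf_fit(classifier, Xtr[, sel, drop = FALSE], ytr,
                        seed = .derive_seed(seed, i * 1000L + gi))
      ph <- .clf_predict(model, X[i, sel, drop = FALSE])
      pred[i, gi] <- as.character(ph)
      acc[i, gi] <- as.numeric(ph == y[i])
    }
  }
  ACC_CV <- colMeans(acc)
  kg <- which.max(ACC_CV)                       # first max = smallest K
  K <- feature_grid[kg]
  # occurrence-rate ranking of the folds' top-K selections
  topk <- fold_rankings[, seq_len(K), drop = FALSE]
  occ <- tabulate(topk, nbins = F_)
  mean_rank <- colMeans(rank_position)
  ord <- order(-occ, mean_rank, seq_len(F_))
  optimal_features <- ord[seq_len(K)]
  a_K <- acc[, kg]
  sem <- sqrt(mean((a_K - mean(a_K))^2) / N)
  confusion <- table(truth = y, predicted = factor(pred[, kg],
                                                   levels = levels(y)))
  pos <- levels(y)[2L]
  neg <- levels(y)[1L]
  sens <- confusion[pos, pos] / sum(confusion[pos, ])
  spec <- confusion[neg, neg] / sum(confusion[neg, ])
  structure(list(acc_matrix = acc, ACC_CV = ACC_CV,
                 feature_grid = feature_grid, K = K, acc = ACC_CV[kg],
                 sem = sem, optimal_features = optimal_features,
                 occurrence = occ, confusion = confusion,
                 sensitivity = sens, specificity = spec,
                 fold_rankings = fold_rankings, fs_method = fs_method,
                 classifier = classifier, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s + %s: ACC = %.4f +/- %.4f at K = %d features\n",
              x$fs_method, x$classifier, x$acc, x$sem, x$K))
  invisible(x)
}

#' Run the full feature-selection x classifier grid
#'
#' @inheritParams run_loocv
#' @param fs_methods,classifiers Method sets (defaults: the four of each).
#' @return Named list of `cv_result`, names `"<fs>_<clf>"`.
#' @export
grid_classification <- function(features, labels,
                                fs_methods = .FS_METHODS,
                                classifiers = .CLASSIFIERS,
                                feature_grid = NULL, seed = 1L) {
  out <- list()
  for (fs in fs_methods)
    for (clf in classifiers)
      out[[paste(fs, clf, sep = "_")]] <-
        run_loocv(features, labels, fs, clf, feature_grid, seed)
  out
}

#' Summarize a classification grid
#'
#' Accuracy +/- SEM per (feature selection, classifier) combination with the
#' best cell flagged; ties go to the first combination in the given order.
#'
#' @param results List of `cv_result` (e.g. from [grid_classification()]).
#' @return Data frame: fs, classifier, acc, sem, K, sensitivity,
#'   specificity, best.
#' @export
summarize_grid <- function(results) {
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(fs = r$fs_method, classifier = r$classifier, acc = r$acc,
               sem = r$sem, K = r$K, sensitivity = r$sensitivity,
               specificity = r$specificity)))
  rownames(tab) <- names(results)
  tab$best <- FALSE
  tab$best[which.max(tab$acc)] <- TRUE
  tab
}
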