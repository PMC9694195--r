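# Each registry entry is fit(x, y, seed) -> object and score(object, x) ->
# continuous positive-class score.  Fits receive a plain numeric matrix and
# a 0/1 integer vector.  Training-constant columns are dropped before
# fitting (several of the underlying learners degenerate on them); if no
# column survives, the model scores 0.5 everywhere.

dr_drop_constant <- function(x) {
  keep <- which(apply(x, 2, function(c) diff(range(c))) > 0)
  list(x = x[, keep, drop = FALSE], keep = keep)
}

dr_with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# ---- multilayer perceptron -------------------------------------------------
# Two ReLU hidden layers (default 400, 100), sigmoid output, log-loss with
# L2 penalty, full-batch Adam.  Written natively: the installed stack has no
# multi-hidden-layer perceptron.
dr_mlp_fit <- function(x, y, seed, hidden = c(400, 100), l2 = 0.01,
                       lr = 1e-3, max_iter = 200, tol = 1e-4, patience = 10) {
  dr_with_seed(seed, {
    sizes <- c(ncol(x), hidden, 1L)
    L <- length(sizes) - 1L
    W <- lapply(seq_len(L), function(l)
      matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                          sd = sqrt(2 / (sizes[l] + sizes[l + 1]))),
             sizes[l], sizes[l + 1]))
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(v) v * 0); vb <- mb
    n <- nrow(x); beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    best <- Inf; stall <- 0L
    for (it in seq_len(max_iter)) {
      a <- list(x); z <- list()
      for (l in seq_len(L)) {
        z[[l]] <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1]] <- if (l < L) pmax(z[[l]], 0) else 1 / (1 + exp(-z[[l]]))
      }
      p <- as.vector(a[[L + 1]])
      loss <- -mean(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12)) +
        l2 / (2 * n) * sum(vapply(W, function(w) sum(w^2), numeric(1)))
      if (loss < best - tol) { best <- loss; stall <- 0L } else stall <- stall + 1L
      if (stall >= patience) break
      delta <- matrix((p - y) / n, ncol = 1)
      for (l in rev(seq_len(L))) {
        gW <- crossprod(a[[l]], delta) + l2 / n * W[[l]]
        gb <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (z[[l - 1]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        corr1 <- 1 - beta1^it; corr2 <- 1 - beta2^it
        W[[l]] <- W[[l]] - lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
      }
    }
    list(W = W, b = b)
  })
}

dr_mlp_score <- function(fit, x) {
  a <- x
  L <- length(fit$W)
  for (l in seq_len(L)) {
    a <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    if (l < L) a <- pmax(a, 0)
  }
  as.vector(1 / (1 + exp(-a)))
}

# ---- AdaBoost of stumps ----------------------------------------------------
# Discrete AdaBoost (SAMME) with depth-1 rpart stumps, 50 rounds.
dr_ada_fit <- function(x, y, seed, n_rounds = 50) {
  dr_with_seed(seed, {
    n <- nrow(x)
    w <- rep(1 / n, n)
    yy <- ifelse(y == 1, 1, -1)
    df <- as.data.frame(x)
    stumps <- list(); alphas <- numeric(0)
    for (m in seq_len(n_rounds)) {
      fit <- rpart::rpart(factor(yy) ~ ., data = df, weights = w / mean(w),
                          method = "class",
                          control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                         minsplit = 2, xval = 0))
      pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
      err <- sum(w[pred != yy])
      if (err <= 0) { stumps[[m]] <- fit; alphas[m] <- 10; break }
      if (err >= 0.5) break
      alpha <- 0.5 * log((1 - err) / err)
      stumps[[m]] <- fit; alphas[m] <- alpha
      w <- w * exp(-alpha * yy * pred)
      w <- w / sum(w)
    }
    list(stumps = stumps, alphas = alphas, cols = colnames(df))
  })
}

dr_ada_score <- function(fit, x) {
  df <- as.data.frame(x)
  if (!length(fit$stumps)) return(rep(0.5, nrow(df)))
  s <- numeric(nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(predict(fit$stumps[[m]], df, type = "class") == "1", 1, -1)
    s <- s + fit$alphas[m] * pred
  }
  s
}

# ---- k-nearest neighbours --------------------------------------------------
dr_knn_score <- function(train_x, train_y, test_x, k = 5) {
  k <- min(k, nrow(train_x))
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * test_x %*% t(train_x)
  apply(d2, 1, function(row) mean(train_y[order(row)[seq_len(k)]]))
}

#' The ten-classifier registry
#'
#' Returns the fixed registry of ten models used for feature-group
#' comparison: Gaussian naive Bayes (NB), logistic regression with
#' internally cross-validated L2 regularization (LR), a single decision
#' tree (DT), gradient-boosted trees (GBDT; 100 rounds, depth 3, learning
#' rate 0.1), a multilayer perceptron with hidden layers (400, 100) and L2
#' penalty 0.01 (nn), k-nearest neighbours with k = 5 (KNN), AdaBoost of
#' stumps (Ada), linear discriminant analysis (DA), a random forest of 200
#' trees (RF), and an RBF-kernel support vector classifier with class
#' probabilities (SVM).  Every model emits a continuous score for the
#' positive class.
#'
#' @return Named list of entries with `fit(x, y, seed)` and
#'   `score(model, x)` functions.
#' @export
model_registry <- function() {
  list(
    NB = list(
      fit = function(x, y, seed) {
        cc <- dr_drop_constant(x)
        list(keep = cc$keep,
             fit = if (length(cc$keep))
               e1071::naiveBayes(as.data.frame(cc$x), factor(y)) else NULL)
      },
      score = function(m, x) {
        if (is.null(m$fit)) return(rep(0.5, nrow(x)))
        predict(m$fit, as.data.frame(x[, m$keep, drop = FALSE]),
                type = "raw", threshold = 1e-3)[, "1"]
      }),
    LR = list(
      fit = function(x, y, seed) {
        cc <- dr_drop_constant(x)
        if (length(cc$keep) < 2) {
          df <- data.frame(y = y, x1 = if (length(cc$keep)) cc$x[, 1] else 0)
          return(list(keep = cc$keep, glm = stats::glm(y ~ ., data = df,
                                                       family = stats::binomial())))
        }
        k <- max(3, min(5, min(table(y))))
        foldid <- make_stratified_folds(y, k, seed)
        list(keep = cc$keep,
             fit = glmnet::cv.glmnet(cc$x, y, family = "binomial",
                                     foldid = foldid, nlambda = 50))
      },
      score = function(m, x) {
        if (!is.null(m$glm)) {
          df <- data.frame(x1 = if (length(m$keep)) x[, m$keep[1]] else
            rep(0, nrow(x)))
          return(as.vector(predict(m$glm, df, type = "response")))
        }
        as.vector(predict(m$fit, x[, m$keep, drop = FALSE],
                          s = "lambda.min", type = "response"))
      }),
    DT = list(
      fit = function(x, y, seed) {
        dr_with_seed(seed,
          rpart::rpart(factor(y) ~ ., data = as.data.frame(x), method = "class",
                       control = rpart::rpart.control(xval = 0)))
      },
      score = function(m, x) predict(m, as.data.frame(x), type = "prob")[, "1"]),
    GBDT = list(
      fit = function(x, y, seed) {
        cc <- dr_drop_constant(x)
        dtrain <- xgboost::xgb.DMatrix(cc$x, label = y, nthread = 1)
        fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                                eta = 0.1, max_depth = 3,
                                                nthread = 1, seed = seed),
                                  data = dtrain, nrounds = 100, verbose = 0)
        list(keep = cc$keep, fit = fit)
      },
      score = function(m, x)
        predict(m$fit, xgboost::xgb.DMatrix(x[, m$keep, drop = FALSE], nthread = 1))),
    nn = list(
      fit = function(x, y, seed) {
        cc <- dr_drop_constant(x)
        list(keep = cc$keep,
             fit = if (length(cc$keep)) dr_mlp_fit(cc$x, y, seed) else NULL)
      },
      score = function(m, x) {
        if (is.null(m$fit)) return(rep(0.5, nrow(x)))
        dr_mlp_score(m$fit, x[, m$keep, drop = FALSE])
      }),
    KNN = list(
      fit = function(x, y, seed) list(x = x, y = y),
      score = function(m, x) dr_knn_score(m$x, m$y, x)),
    Ada = list(
      fit = function(x, y, seed) dr_ada_fit(x, y, seed),
      score = function(m, x) dr_ada_score(m, x)),
    DA = list(
      fit = function(x, y, seed) {
        cc <- dr_drop_constant(x)
        list(keep = cc$keep,
             fit = if (length(cc$keep)) MASS::lda(cc$x, grouping = factor(y)) else NULL)
      },
      score = function(m, x) {
        if (is.null(m$fit)) return(rep(0.5, nrow(x)))
        predict(m$fit, x[, m$keep, drop = FALSE])$posterior[, "1"]
      }),
    RF = list(
      fit = function(x, y, seed) {
        dr_with_seed(seed,
          randomForest::randomForest(x, factor(y), ntree = 200))
      },
      score = function(m, x) predict(m, x, type = "prob")[, "1"]),
    SVM = list(
      fit = function(x, y, seed) {
        cc <- dr_drop_constant(x)
        fit <- if (length(cc$keep))
          dr_with_seed(seed,
            e1071::svm(cc$x, factor(y), kernel = "radial", probability = TRUE)) else NULL
        list(keep = cc$keep, fit = fit)
      },
      score = function(m, x) {
        if (is.null(m$fit)) return(rep(0.5, nrow(x)))
        xs <- x[, m$keep, drop = FALSE]
        p <- tryCatch({
          pr <- predict(m$fit, xs, probability = TRUE)
          attr(pr, "probabilities")[, "1"]
        }, error = function(e) NULL)
        if (!is.null(p)) return(p)
        # fall back to oriented decision values
        pr <- predict(m$fit, xs, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        lab <- strsplit(colnames(dv)[1], "/")[[1]]
        if (lab[1] == "1") as.vector(dv) else -as.vector(dv)
      })
  )
}
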