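#' Train a binary classifier producing a continuous positive-class score
#'
#' Four classifier families are supported. Random Forest (the default model
#' of the pipeline) and Decision Tree are the package's own CART
#' implementation (Gini impurity, bootstrap bagging, per-node feature
#' subsampling); KNN scores by the positive fraction among the k nearest
#' training rows (FNN); Naive Bayes is Gaussian per feature and class.
#'
#' @param kind One of `"RandomForest"`, `"DecisionTree"`, `"KNN"`,
#'   `"NaiveBayes"` (aliases `"rf"`, `"tree"`, `"knn"`, `"nb"`).
#' @param x Numeric feature matrix (rows = samples).
#' @param y 0/1 labels, both classes present.
#' @param hyper Named list of hyperparameters. Random Forest: `ntree` (100),
#'   `mtry` (`floor(sqrt(p))`), `min_node` (1), `max_depth` (0 = unlimited).
#'   Decision Tree: `min_node` (1), `max_depth` (0). KNN: `k` (5).
#' @param seed RNG seed (tree methods are seed-deterministic).
#' @return Object of class `hinmda_classifier`.
#' @export
train_classifier <- function(kind, x, y, hyper = list(), seed = 1) {
  kind <- switch(tolower(kind),
                 randomforest = , rf = "RandomForest",
                 decisiontree = , tree = "DecisionTree",
                 knn = "KNN",
                 naivebayes = , nb = "NaiveBayes",
                 stop("unknown classifier kind: ", kind, call. = FALSE))
  x <- as.matrix(x); y <- as.integer(y)
  if (nrow(x) == 0) stop("empty training set", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  p <- ncol(x)
  fit <- switch(kind,
    RandomForest = {
      h <- utils::modifyList(list(ntree = 100, mtry = max(1, floor(sqrt(p))),
                                  min_node = 1, max_depth = 0), hyper)
      set.seed(seed)
      list(trees = cpp_forest_train(x, y, h$ntree, h$mtry, h$min_node,
                                    h$max_depth, TRUE), hyper = h)
    },
    DecisionTree = {
      h <- utils::modifyList(list(min_node = 1, max_depth = 0), hyper)
      set.seed(seed)
      list(trees = cpp_forest_train(x, y, 1L, p, h$min_node, h$max_depth,
                                    FALSE), hyper = h)
    },
    KNN = {
      h <- utils::modifyList(list(k = 5), hyper)
      list(x = x, y = y, hyper = h)
    },
    NaiveBayes = {
      mu <- s2 <- matrix(0, 2, p)
      for (cl in 0:1) {
        xc <- x[y == cl, , drop = FALSE]
        mu[cl + 1, ] <- colMeans(xc)
        s2[cl + 1, ] <- apply(xc, 2, stats::var)
      }
      s2[!is.finite(s2)] <- 0
      s2 <- s2 + 1e-9  # variance floor for constant features
      list(mu = mu, s2 = s2, prior = c(mean(y == 0), mean(y == 1)))
    })
  structure(list(kind = kind, fit = fit, p = p), class = "hinmda_classifier")
}

#' Positive-class scores of a fitted classifier
#' @param model A `hinmda_classifier`.
#' @param x Feature matrix with the training dimensionality.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "hinmda_classifier"))
  x <- as.matrix(x)
  if (ncol(x) != model$p) {
    stop("feature dimension ", ncol(x), " != training dimension ", model$p,
         call. = FALSE)
  }
  switch(model$kind,
    RandomForest = ,
    DecisionTree = cpp_forest_predict(model$fit$trees, x),
    KNN = {
      nn <- FNN::get.knnx(model$fit$x, x, k = model$fit$hyper$k)
      rowMeans(matrix(model$fit$y[nn$nn.index], nrow = nrow(x)))
    },
    NaiveBayes = {
      ll <- vapply(1:2, function(ci) {
        mu <- model$fit$mu[ci, ]; s2 <- model$fit$s2[ci, ]
        rowSums(sweep(sweep(x, 2, mu)^2, 2, -2 * s2, "/")) -
          0.5 * sum(log(2 * pi * s2)) + log(model$fit$prior[ci])
      }, numeric(nrow(x)))
      1 / (1 + exp(ll[, 1] - ll[, 2]))
    })
}
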