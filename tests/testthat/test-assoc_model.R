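# hand-built node_features: two latent groups so classifiers have signal
fake_features <- function(n_m = 6, n_d = 4, p = 3, seed = 1) {
  set.seed(seed)
  mk <- function(n, prefix) {
    M <- matrix(runif(n * p), n, p,
                dimnames = list(paste0(prefix, seq_len(n)), NULL))
    M
  }
  structure(list(mirna_attr = mk(n_m, "m"), mirna_behav = mk(n_m, "m"),
                 disease_attr = mk(n_d, "d"), disease_behav = mk(n_d, "d")),
            class = "node_features")
}

test_that("pair features concatenate fused node vectors per mode", {
  f <- fake_features()
  x <- pair_features(f, "m1", "d2", mode = "both")
  expect_equal(ncol(x), 4 * 3)
  expect_equal(unname(x[1, 1:3]), unname(f$mirna_attr["m1", ]))
  expect_equal(unname(x[1, 7:9]), unname(f$disease_attr["d2", ]))
  expect_equal(ncol(pair_features(f, "m1", "d1", mode = "attribute")), 6)
  expect_error(pair_features(f, "nope", "d1"), "unknown miRNA")
})

test_that("negative sampling is matched, disjoint, and reproducible", {
  f <- fake_features(3, 3)
  pos <- data.frame(miRNA = c("m1", "m1", "m2", "m3"),
                    disease = c("d1", "d2", "d1", "d3"))
  ds <- build_pair_dataset(pos, f, seed = 5)
  expect_equal(sum(ds$samples$label == 1), 4)
  expect_equal(sum(ds$samples$label == 0), 4)
  key <- paste(ds$samples$miRNA, ds$samples$disease)
  expect_equal(anyDuplicated(key), 0)
  negk <- key[ds$samples$label == 0]
  posk <- paste(pos$miRNA, pos$disease)
  expect_length(intersect(negk, posk), 0)
  ds2 <- build_pair_dataset(pos, f, seed = 5)
  expect_identical(ds$samples, ds2$samples)
})

test_that("insufficient negatives is an error", {
  f <- fake_features(2, 2)
  pos <- data.frame(miRNA = c("m1", "m1", "m2"),
                    disease = c("d1", "d2", "d1"))
  expect_error(build_pair_dataset(pos, f), "insufficient negatives")
})

test_that("k-fold split partitions with near-equal sizes", {
  f5 <- kfold_split(100, 5, seed = 1)
  expect_equal(unname(table(f5)), rep(20L, 5), ignore_attr = TRUE)
  f5b <- kfold_split(101, 5, seed = 1)
  expect_equal(sort(as.vector(table(f5b)), decreasing = TRUE),
               c(21L, 20L, 20L, 20L, 20L))
  expect_length(f5, 100)
  expect_setequal(unique(f5), 1:5)
  expect_error(kfold_split(10, k = 1), "k must be")
  expect_error(kfold_split(3, k = 5), "fewer samples")
})

test_that("classifiers fit, score deterministically, and separate a toy set", {
  set.seed(20)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  X <- cbind(y * 2 + rnorm(n, sd = 0.1), rnorm(n))  # linearly separable
  for (kind in c("rf", "tree", "knn", "nb")) {
    m <- train_classifier(kind, X, y, seed = 3)
    s <- predict_scores(m, X)
    expect_equal(suppressWarnings(auc_score(s, y)), 1,
                 tolerance = 1e-12, label = kind)
    m2 <- train_classifier(kind, X, y, seed = 3)
    expect_identical(s, predict_scores(m2, X))
  }
  expect_error(train_classifier("rf", X, rep(1, n)), "one class")
  expect_error(train_classifier("svm", X, y), "unknown classifier")
  expect_error(predict_scores(train_classifier("rf", X, y), X[, 1, drop = FALSE]),
               "dimension")
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(21)
  n <- 200
  X <- matrix(rnorm(n * 8), n, 8)
  y <- sample(rep(c(0, 1), each = n / 2))
  folds <- kfold_split(n, 5, seed = 2)
  aucs <- vapply(1:5, function(f) {
    m <- train_classifier("rf", X[folds != f, ], y[folds != f], seed = f)
    suppressWarnings(auc_score(predict_scores(m, X[folds == f, ]),
                               y[folds == f]))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("cross_validate aggregates fold metrics exactly", {
  f <- fake_features(8, 6, p = 4, seed = 3)
  mirnas <- rownames(f$mirna_attr); diseases <- rownames(f$disease_attr)
  set.seed(22)
  pos <- unique(data.frame(miRNA = sample(mirnas, 20, replace = TRUE),
                           disease = sample(diseases, 20, replace = TRUE)))
  ds <- build_pair_dataset(pos, f, seed = 1)
  r <- suppressWarnings(cross_validate(ds, kind = "knn", k = 3, seed = 1))
  expect_equal(nrow(r$per_fold), 3)
  for (mn in r$summary$metric) {
    expect_equal(r$summary$mean[r$summary$metric == mn],
                 mean(r$per_fold[[mn]]), tolerance = 1e-12)
  }
  # folds partition and train/test never overlap by construction
  expect_length(r$folds, nrow(ds$samples))
  expect_setequal(unique(r$folds), 1:3)
})

test_that("rank_candidates excludes training positives and sorts deterministically", {
  f <- fake_features(5, 2)
  pos <- data.frame(miRNA = c("m1", "m2"), disease = c("d1", "d1"))
  all_pos <- data.frame(miRNA = paste0("m", 1:5),
                        disease = rep("d2", 5))
  ds <- build_pair_dataset(rbind(pos, all_pos[1:3, ]), f, seed = 2)
  m <- train_classifier("knn", ds$X, ds$samples$label, hyper = list(k = 3))
  r <- rank_candidates("d1", m, f, pos)
  expect_false(any(c("m1", "m2") %in% r$miRNA))
  expect_equal(nrow(r), 3)
  expect_true(all(diff(r$score) <= 0))
  # ties broken by miRNA id
  tied <- r$miRNA[duplicated(r$score) | duplicated(r$score, fromLast = TRUE)]
  if (length(tied) > 1) expect_equal(tied, sort(tied))
  # exclusion rule empties the list when every miRNA is known
  full <- data.frame(miRNA = paste0("m", 1:5), disease = "d1")
  expect_equal(nrow(rank_candidates("d1", m, f, full)), 0)
  expect_error(rank_candidates("zzz", m, f, pos), "unknown disease")
})
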