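#' Fuse attribute and behavior information into per-node feature vectors
#'
#' miRNA attribute vectors are 3-mer frequencies and disease attribute
#' vectors are rows of the semantic similarity matrix; both are compressed
#' to a common dimension by one stacked autoencoder per node class (their
#' input dimensions differ), then paired with the node's GraRep behavior
#' vector. Nodes lacking an attribute source (no sequence / no DAG) get a
#' zero attribute code under the default `missing = "zero"` policy, or are
#' dropped under `missing = "drop"`.
#'
#' @param net A `hetnet`.
#' @param kmer Matrix from [kmer_table()] (rows = miRNA ids).
#' @param simmat Matrix from [semantic_similarity_matrix()] (rows = disease
#'   ids).
#' @param embedding Matrix from [grarep_embed()] over the network node order.
#' @param code_dim Attribute code dimension after the autoencoder
#'   (default 64, so the fused node vector is 128-dimensional).
#' @param sae_epochs,sae_lr Autoencoder training parameters.
#' @param seed RNG seed for both autoencoders.
#' @param sae_bypass Skip the autoencoder and use raw attribute vectors
#'   (dimensions then differ between classes).
#' @param missing `"zero"` or `"drop"` for nodes without attribute data.
#' @return Object of class `node_features`: list with matrices
#'   `mirna_attr`, `mirna_behav`, `disease_attr`, `disease_behav`
#'   (rownames = node ids) and the fitted `sae_mirna`, `sae_disease`.
#' @export
build_node_features <- function(net, kmer, simmat, embedding, code_dim = 64,
                                sae_epochs = 100, sae_lr = 2e-3, seed = 42,
                                sae_bypass = FALSE,
                                missing = c("zero", "drop")) {
  missing <- match.arg(missing)
  mirnas <- nodes_of_type(net, "miRNA")
  diseases <- nodes_of_type(net, "disease")

  take <- function(ids, attr_mat, label) {
    have <- ids %in% rownames(attr_mat)
    if (any(!have)) {
      warning(sum(!have), " ", label, "(s) without attribute data (",
              missing, " policy)", call. = FALSE)
      if (missing == "drop") ids <- ids[have]
    }
    M <- matrix(0, length(ids), ncol(attr_mat),
                dimnames = list(ids, colnames(attr_mat)))
    hit <- intersect(ids, rownames(attr_mat))
    M[hit, ] <- attr_mat[hit, , drop = FALSE]
    M
  }
  m_attr_raw <- take(mirnas, kmer, "miRNA")
  d_attr_raw <- take(diseases, simmat, "disease")
  mirnas <- rownames(m_attr_raw); diseases <- rownames(d_attr_raw)

  if (sae_bypass) {
    m_attr <- m_attr_raw; d_attr <- d_attr_raw
    sae_m <- sae_d <- NULL
  } else {
    sae_m <- sae_train(m_attr_raw, hidden_sizes = code_dim,
                       epochs = sae_epochs, lr = sae_lr, seed = seed)
    sae_d <- sae_train(d_attr_raw, hidden_sizes = code_dim,
                       epochs = sae_epochs, lr = sae_lr, seed = seed + 1)
    m_attr <- sae_encode(sae_m, m_attr_raw)
    d_attr <- sae_encode(sae_d, d_attr_raw)
  }

  key <- function(ids, ntype) paste(ntype, ids, sep = ":")
  m_behav <- embedding[key(mirnas, "miRNA"), , drop = FALSE]
  d_behav <- embedding[key(diseases, "disease"), , drop = FALSE]
  rownames(m_behav) <- mirnas; rownames(d_behav) <- diseases

  structure(list(mirna_attr = m_attr, mirna_behav = m_behav,
                 disease_attr = d_attr, disease_behav = d_behav,
                 sae_mirna = sae_m, sae_disease = sae_d),
            class = "node_features")
}

.fused <- function(features, what, mode) {
  attr_m <- features[[paste0(what, "_attr")]]
  behav_m <- features[[paste0(what, "_behav")]]
  switch(mode,
         attribute = attr_m,
         behavior = behav_m,
         both = cbind(attr_m, behav_m),
         stop("mode must be one of attribute/behavior/both", call. = FALSE))
}

#' Feature vector(s) of (miRNA, disease) pairs
#'
#' The pair vector concatenates the fused miRNA node vector and the fused
#' disease node vector; `mode` selects attribute-only, behavior-only, or
#' both (the feature-combination ablation axis).
#'
#' @param features A `node_features` object.
#' @param mirna,disease Character vectors of equal length (recycled if one
#'   is scalar).
#' @param mode `"both"` (default), `"attribute"`, or `"behavior"`.
#' @return Numeric matrix, one row per pair.
#' @export
pair_features <- function(features, mirna, disease, mode = "both") {
  fm <- .fused(features, "mirna", mode)
  fd <- .fused(features, "disease", mode)
  n <- max(length(mirna), length(disease))
  mirna <- rep_len(mirna, n); disease <- rep_len(disease, n)
  miss_m <- setdiff(mirna, rownames(fm))
  miss_d <- setdiff(disease, rownames(fd))
  if (length(miss_m)) stop("unknown miRNA id(s): ",
                           paste(utils::head(miss_m, 3), collapse = ", "),
                           call. = FALSE)
  if (length(miss_d)) stop("unknown disease id(s): ",
                           paste(utils::head(miss_d, 3), collapse = ", "),
                           call. = FALSE)
  cbind(fm[mirna, , drop = FALSE], fd[disease, , drop = FALSE])
}

#' Build a labelled pair dataset with matched negative sampling
#'
#' Negatives are drawn uniformly without replacement from all
#' miRNA x disease pairs over featured nodes, minus the positives, matched
#' 1:1 in count with the positives.
#'
#' @param positives data.frame with columns `miRNA`, `disease` (known
#'   associations).
#' @param features A `node_features` object.
#' @param mode Feature mode for [pair_features()].
#' @param seed RNG seed for negative sampling.
#' @return Object of class `pair_dataset`: list with `samples` (data.frame
#'   `miRNA`, `disease`, `label`) and feature matrix `X`.
#' @export
build_pair_dataset <- function(positives, features, mode = "both",
                               seed = 42) {
  mirnas <- rownames(features$mirna_attr)
  diseases <- rownames(features$disease_attr)
  pos <- unique(positives[, c("miRNA", "disease")])
  keep <- pos$miRNA %in% mirnas & pos$disease %in% diseases
  if (any(!keep)) {
    warning(sum(!keep), " positive pair(s) dropped: nodes without features",
            call. = FALSE)
    pos <- pos[keep, , drop = FALSE]
  }
  npos <- nrow(pos)
  if (npos == 0) stop("no usable positive pairs", call. = FALSE)
  n_universe <- length(mirnas) * length(diseases)
  if (npos > n_universe - npos) {
    stop("insufficient negatives: ", npos, " positives but only ",
         n_universe - npos, " non-positive pairs", call. = FALSE)
  }
  pos_key <- paste(pos$miRNA, pos$disease, sep = "\t")
  # enumerate the complement lazily by linear index over the m x d grid
  all_idx <- seq_len(n_universe)
  grid_key <- function(idx) {
    mi <- ((idx - 1) %% length(mirnas)) + 1
    di <- ((idx - 1) %/% length(mirnas)) + 1
    paste(mirnas[mi], diseases[di], sep = "\t")
  }
  pos_idx <- match(pos_key, grid_key(all_idx))  # small scale: direct match
  neg_pool <- setdiff(all_idx, pos_idx)
  set.seed(seed)
  neg_idx <- sample(neg_pool, npos)
  neg <- data.frame(
    miRNA = mirnas[((neg_idx - 1) %% length(mirnas)) + 1],
    disease = diseases[((neg_idx - 1) %/% length(mirnas)) + 1],
    stringsAsFactors = FALSE)
  samples <- rbind(
    data.frame(miRNA = pos$miRNA, disease = pos$disease, label = 1L),
    data.frame(miRNA = neg$miRNA, disease = neg$disease, label = 0L))
  rownames(samples) <- NULL
  X <- pair_features(features, samples$miRNA, samples$disease, mode)
  structure(list(samples = samples, X = X, mode = mode, seed = seed),
            class = "pair_dataset")
}

#' Random k-fold partition
#'
#' @param n Number of samples (or a `pair_dataset`).
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return Integer vector of fold labels in `1..k`; fold sizes differ by at
#'   most 1.
#' @export
kfold_split <- function(n, k = 5, seed = 42) {
  if (inherits(n, "pair_dataset")) n <- nrow(n$samples)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("fewer samples than folds", call. = FALSE)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' k-fold cross-validation of a pair dataset
#'
#' Splits the labelled pairs into `k` random folds; each fold in turn is the
#' test set and the rest the training set (never overlapping), the
#' classifier is refitted, and the full metric panel is computed per fold
#' and summarized as mean +/- standard deviation.
#'
#' @param dataset A `pair_dataset`.
#' @param kind Classifier kind for [train_classifier()].
#' @param k Number of folds.
#' @param seed RNG seed (fold split and classifier fits).
#' @param threshold Decision threshold for confusion-matrix metrics.
#' @param hyper Classifier hyperparameters.
#' @return Object of class `cv_report`: list with `per_fold` (data.frame),
#'   `summary` (mean and sd per metric), `folds`, and pooled `roc`/`pr`
#'   curve points.
#' @export
cross_validate <- function(dataset, kind = "RandomForest", k = 5, seed = 42,
                           threshold = 0.5, hyper = list()) {
  stopifnot(inherits(dataset, "pair_dataset"))
  folds <- kfold_split(nrow(dataset$samples), k = k, seed = seed)
  metric_names <- c("Acc", "Prec", "Sen", "Spec", "MCC", "AUC", "AUPR")
  per_fold <- data.frame(fold = seq_len(k))
  for (mn in metric_names) per_fold[[mn]] <- NA_real_
  all_scores <- numeric(0); all_labels <- integer(0)
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    model <- train_classifier(kind, dataset$X[tr, , drop = FALSE],
                              dataset$samples$label[tr],
                              hyper = hyper, seed = seed + f)
    sc <- predict_scores(model, dataset$X[te, , drop = FALSE])
    ev <- evaluate_scores(sc, dataset$samples$label[te], threshold)
    for (mn in metric_names) per_fold[[mn]][f] <- ev[[mn]]
    all_scores <- c(all_scores, sc)
    all_labels <- c(all_labels, dataset$samples$label[te])
  }
  summ <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(mn) mean(per_fold[[mn]]), 0),
    sd = vapply(metric_names, function(mn) stats::sd(per_fold[[mn]]), 0))
  rownames(summ) <- NULL
  structure(list(per_fold = per_fold, summary = summ, folds = folds,
                 kind = kind, k = k, seed = seed,
                 roc = roc_points(all_scores, all_labels),
                 pr = pr_points(all_scores, all_labels)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(x$k, "-fold cross-validation, classifier: ", x$kind, "\n", sep = "")
  s <- x$summary
  cat(paste0(s$metric, " = ", sprintf("%.4f", s$mean), " +/- ",
             sprintf("%.4f", s$sd), collapse = "\n"), "\n")
  invisible(x)
}

#' Rank candidate miRNAs for one disease
#'
#' Scores every featured miRNA paired with the disease, excluding pairs
#' present in the training positives, and returns a descending-score list
#' (ties broken by miRNA id so output is deterministic).
#'
#' @param disease Disease id.
#' @param model Fitted `hinmda_classifier` (trained on all
#'   positives+negatives).
#' @param features A `node_features` object.
#' @param training_positives data.frame with `miRNA`, `disease` columns.
#' @param mode Feature mode used at training time.
#' @param top Optional cap on list length (the case-study protocol uses 50).
#' @return data.frame with `miRNA`, `score`, sorted.
#' @export
rank_candidates <- function(disease, model, features, training_positives,
                            mode = "both", top = NULL) {
  diseases <- rownames(features$disease_attr)
  if (!disease %in% diseases) {
    stop("unknown disease id: ", disease, call. = FALSE)
  }
  mirnas <- rownames(features$mirna_attr)
  known <- training_positives$miRNA[training_positives$disease == disease]
  cand <- sort(setdiff(mirnas, known), method = "radix")
  if (length(cand) == 0) {
    return(data.frame(miRNA = character(0), score = numeric(0)))
  }
  X <- pair_features(features, cand, disease, mode)
  sc <- predict_scores(model, X)
  ord <- order(-sc, cand, method = "radix")
  out <- data.frame(miRNA = cand[ord], score = sc[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(top)) out <- utils::head(out, top)
  rownames(out) <- NULL
  out
}
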