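# Independent brute-force oracles. These deliberately use naive loops /
# closed forms, never the package's own code paths.

# dictionary-count k-mer oracle
oracle_kmer <- function(seq, k = 3) {
  s <- chartr("T", "U", toupper(seq))
  words <- rna_kmers(k)   # shared constant ordering only
  counts <- setNames(rep(0, length(words)), words)
  n <- nchar(s) - k + 1
  for (i in seq_len(n)) {
    w <- substr(s, i, i + k - 1)
    counts[w] <- counts[w] + 1
  }
  counts / n
}

# semantic contribution oracle: max over downward paths of delta^len
# equals delta^(shortest child-edge distance from node down to the disease)
oracle_semantic <- function(parents, disease, delta) {
  # parents: data.frame(child, parent) restricted to the DAG
  nodes <- unique(c(parents$child, parents$parent, disease))
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[disease] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(parents))) {
      ch <- parents$child[r]; pa <- parents$parent[r]
      if (dist[ch] + 1 < dist[pa]) { dist[pa] <- dist[ch] + 1; changed <- TRUE }
    }
    if (!changed) break
  }
  contrib <- delta^dist
  list(DV = sum(contrib), contributions = contrib)
}

# confusion-matrix oracle with explicit loops
oracle_confusion <- function(scores, labels, thr = 0.5) {
  TP <- TN <- FP <- FN <- 0
  for (i in seq_along(scores)) {
    pred <- if (scores[i] >= thr) 1 else 0
    if (pred == 1 && labels[i] == 1) TP <- TP + 1
    if (pred == 0 && labels[i] == 0) TN <- TN + 1
    if (pred == 1 && labels[i] == 0) FP <- FP + 1
    if (pred == 0 && labels[i] == 1) FN <- FN + 1
  }
  n <- length(scores)
  list(Acc = (TP + TN) / n,
       Prec = if (TP + FP > 0) TP / (TP + FP) else NaN,
       Sen = if (TP + FN > 0) TP / (TP + FN) else NaN,
       Spec = if (TN + FP > 0) TN / (TN + FP) else NaN,
       MCC = {
         den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
         if (den == 0) NaN else (TP * TN - FP * FN) / den
       })
}

# pair-counting AUC oracle (probability a positive outranks a negative)
oracle_auc <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (a in ps) for (b in ns) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# step-wise AUPR oracle over distinct thresholds, explicit counting
oracle_aupr <- function(scores, labels) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0; prev_rec <- 0
  for (t in thr) {
    TP <- sum(scores >= t & labels == 1)
    FP <- sum(scores >= t & labels == 0)
    prec <- TP / (TP + FP); rec <- TP / P
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

random_rna <- function(n_min = 18, n_max = 30) {
  L <- sample(n_min:n_max, 1)
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}
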