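#' Configuration for a synthetic planted-signal study
#'
#' The generator partitions nodes of all five types into `blocks` latent
#' communities. Every association class draws within-block pairs with
#' probability `p_in` and cross-block pairs with `p_out`, planting a block
#' structure that network embeddings can recover. True miRNA-disease
#' associations are the pairs drawn this way for that class; a fraction
#' `observed_frac` becomes the observed positives (and the network's
#' miRNA-disease edges), the rest is held out as recoverable truth. miRNA
#' sequences are random RNA with a block-preferred 3-mer enriched
#' `kmer_bias` times, and disease DAGs share block-level ancestors, giving
#' the attribute features an independent, weaker signal.
#'
#' @param blocks Number of latent blocks.
#' @param n_mirna,n_disease,n_protein,n_lncrna,n_drug Node counts per type.
#' @param p_in,p_out Within-/cross-block edge probabilities
#'   (`0 <= p_out < p_in <= 1`).
#' @param observed_frac Fraction of true miRNA-disease associations released
#'   as observed positives.
#' @param seq_len Length-2 integer range of miRNA sequence lengths.
#' @param dag_depth Length-2 integer range of disease DAG depths (ancestors
#'   between disease and root).
#' @param kmer_bias Number of preferred-3-mer insertions per sequence.
#' @param seed Master RNG seed; every output stream derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(blocks = 5, n_mirna = 100, n_disease = 80,
                             n_protein = 120, n_lncrna = 50, n_drug = 40,
                             p_in = 0.15, p_out = 0.01, observed_frac = 0.7,
                             seq_len = c(18, 30), dag_depth = c(2, 5),
                             kmer_bias = 1, seed = 42) {
  cfg <- list(blocks = blocks, n_mirna = n_mirna, n_disease = n_disease,
              n_protein = n_protein, n_lncrna = n_lncrna, n_drug = n_drug,
              p_in = p_in, p_out = p_out, observed_frac = observed_frac,
              seq_len = seq_len, dag_depth = dag_depth,
              kmer_bias = kmer_bias, seed = seed)
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("require 0 <= p_out < p_in <= 1", call. = FALSE)
  }
  if (any(c(blocks, n_mirna, n_disease, n_protein, n_lncrna, n_drug) < 1)) {
    stop("all counts must be >= 1", call. = FALSE)
  }
  if (observed_frac <= 0 || observed_frac > 1) {
    stop("observed_frac must be in (0, 1]", call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

.block_of <- function(n, blocks) rep_len(seq_len(blocks), n)

.draw_pairs <- function(ids_a, blk_a, ids_b, blk_b, p_in, p_out,
                        same_type = FALSE) {
  # Bernoulli draw over the full bipartite (or upper-triangular) grid
  na <- length(ids_a); nb <- length(ids_b)
  P <- matrix(p_out, na, nb)
  P[outer(blk_a, blk_b, "==")] <- p_in
  U <- matrix(stats::runif(na * nb), na, nb)
  hit <- which(U < P, arr.ind = TRUE)
  if (same_type) hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  data.frame(source = ids_a[hit[, 1]], target = ids_b[hit[, 2]],
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study on disk
#'
#' Writes, under `out_dir`: one TSV edge list per association class
#' (`<class>.tsv`), the miRNA FASTA (`mirna.fasta`), the disease hierarchy
#' (`disease_hierarchy.tsv`, child-parent TSV), the observed positives
#' (`positives.tsv`), the truth table over all unobserved miRNA-disease
#' pairs (`truth.tsv`: miRNA, disease, label), and the latent block
#' assignment (`blocks.tsv`). Identical seeds give byte-identical files.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with `paths` (named file paths, incl.
#'   `edge_lists` keyed by class), `blocks` (data.frame), and the in-memory
#'   `positives` and `truth` tables.
#' @export
generate_study <- function(config = synthetic_config(), out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  B <- config$blocks
  ids <- list(
    miRNA   = sprintf("mir%03d", seq_len(config$n_mirna)),
    lncRNA  = sprintf("lnc%03d", seq_len(config$n_lncrna)),
    protein = sprintf("pro%03d", seq_len(config$n_protein)),
    disease = sprintf("dis%03d", seq_len(config$n_disease)),
    drug    = sprintf("drg%03d", seq_len(config$n_drug)))
  blk <- lapply(ids, function(v) .block_of(length(v), B))

  blocks_df <- do.call(rbind, lapply(names(ids), function(tp) {
    data.frame(id = ids[[tp]], ntype = tp, block = blk[[tp]],
               stringsAsFactors = FALSE)
  }))

  classes <- association_classes()
  edge_paths <- character(0)
  md_true <- NULL

  # independent stream per output: derive a sub-seed for each
  stream <- 0L
  next_seed <- function() {
    stream <<- stream + 1L
    set.seed((config$seed * 131L + stream) %% .Machine$integer.max)
  }

  for (cls in names(classes)) {
    tp <- classes[[cls]]
    next_seed()
    # true miRNA-disease associations are within-block by construction:
    # cross-block pairs of this class are never drawn, so they are all true
    # negatives in the truth table
    pairs <- .draw_pairs(ids[[tp[1]]], blk[[tp[1]]],
                         ids[[tp[2]]], blk[[tp[2]]],
                         config$p_in,
                         if (cls == "miRNA-disease") 0 else config$p_out,
                         same_type = tp[1] == tp[2])
    if (cls == "miRNA-disease") {
      md_true <- pairs
      next  # written below after the observed/held-out split
    }
    path <- file.path(out_dir, paste0(cls, ".tsv"))
    utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    edge_paths[cls] <- path
  }

  # observed/held-out split of the true miRNA-disease associations
  next_seed()
  n_true <- nrow(md_true)
  n_obs <- floor(config$observed_frac * n_true)
  obs_idx <- sort(sample.int(n_true, n_obs))
  observed <- md_true[obs_idx, , drop = FALSE]
  heldout <- md_true[-obs_idx, , drop = FALSE]

  md_path <- file.path(out_dir, "miRNA-disease.tsv")
  utils::write.table(observed, md_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  edge_paths["miRNA-disease"] <- md_path

  positives <- data.frame(miRNA = observed$source, disease = observed$target,
                          stringsAsFactors = FALSE)
  pos_path <- file.path(out_dir, "positives.tsv")
  utils::write.table(positives, pos_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # truth over every unobserved miRNA x disease pair
  grid <- expand.grid(miRNA = ids$miRNA, disease = ids$disease,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keym <- function(df, a = "miRNA", b = "disease") paste(df[[a]], df[[b]])
  grid <- grid[!(keym(grid) %in% keym(positives)), , drop = FALSE]
  grid$label <- as.integer(keym(grid) %in%
                             paste(heldout$source, heldout$target))
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(grid, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  # miRNA sequences with block-preferred 3-mer enrichment
  next_seed()
  kmers <- rna_kmers(3)
  pref <- kmers[round(seq(1, length(kmers), length.out = B))]
  alph <- c("A", "C", "G", "U")
  fasta_path <- file.path(out_dir, "mirna.fasta")
  con <- file(fasta_path, "w")
  pick <- function(rng) { s <- seq(rng[1], rng[2]); s[sample.int(length(s), 1)] }
  for (i in seq_along(ids$miRNA)) {
    L <- pick(config$seq_len)
    s <- sample(alph, L, replace = TRUE)
    pk <- strsplit(pref[blk$miRNA[i]], "")[[1]]
    for (b in seq_len(config$kmer_bias)) {
      pos <- sample.int(L - 2, 1)
      s[pos:(pos + 2)] <- pk
    }
    writeLines(c(paste0(">", ids$miRNA[i]), paste(s, collapse = "")), con)
  }
  close(con)

  # disease hierarchy: shared block-ancestor chains under one root
  next_seed()
  anc_per_block <- 3
  rows <- data.frame(child = character(0), parent = character(0))
  for (b in seq_len(B)) {
    anc <- sprintf("B%dA%d", b, seq_len(anc_per_block))
    rows <- rbind(rows, data.frame(child = anc,
                                   parent = c("ROOT", anc[-anc_per_block])))
  }
  for (i in seq_along(ids$disease)) {
    b <- blk$disease[i]
    depth <- pick(config$dag_depth)
    n_shared <- min(anc_per_block, max(1, depth - 1))
    chain <- sprintf("B%dA%d", b, n_shared)   # deepest shared ancestor used
    n_priv <- max(0, depth - 1 - n_shared)
    parent <- chain
    if (n_priv > 0) {
      priv <- sprintf("%s_anc%d", ids$disease[i], seq_len(n_priv))
      rows <- rbind(rows, data.frame(child = priv,
                                     parent = c(parent, priv[-n_priv])))
      parent <- priv[n_priv]
    }
    rows <- rbind(rows, data.frame(child = ids$disease[i], parent = parent))
  }
  dag_path <- file.path(out_dir, "disease_hierarchy.tsv")
  utils::write.table(rows, dag_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  blocks_path <- file.path(out_dir, "blocks.tsv")
  utils::write.table(blocks_df, blocks_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  invisible(list(
    paths = list(edge_lists = as.list(edge_paths), fasta = fasta_path,
                 hierarchy = dag_path, positives = pos_path,
                 truth = truth_path, blocks = blocks_path),
    blocks = blocks_df, positives = positives,
    truth = grid, config = config))
}

#' Precision-at-N of ranked predictions against a truth table
#'
#' @param ranked data.frame with `miRNA`, `disease` in descending score
#'   order (observed positives already excluded).
#' @param truth data.frame with `miRNA`, `disease`, `label` (1 = held-out
#'   true association).
#' @param n_values Integer vector of list depths N.
#' @return data.frame of `N`, `precision` (fraction of the top N that are
#'   held-out true associations).
#' @export
truth_recovery_report <- function(ranked, truth, n_values = c(10, 20, 50)) {
  key <- paste(ranked$miRNA, ranked$disease)
  tkey <- paste(truth$miRNA, truth$disease)
  hit <- match(key, tkey)
  if (all(is.na(hit))) {
    stop("prediction and truth id spaces do not overlap", call. = FALSE)
  }
  lab <- ifelse(is.na(hit), 0L, truth$label[hit])
  data.frame(N = n_values,
             precision = vapply(n_values, function(N) {
               mean(lab[seq_len(min(N, length(lab)))])
             }, 0))
}
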