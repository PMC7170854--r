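# Programmatic fixtures: small edge-list files, toy hierarchies, random
# symmetric adjacencies. Everything is built in code at test time.

write_edges <- function(rows, path) {
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), ""), path)
  path
}

# six-node toy: 2 miRNAs, 2 diseases, 1 protein, 1 lncRNA, 5 edges
# m1-p1, m2-p1, p1-d1, m1-l1, l1-d2
toy_net_paths <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  list(
    "miRNA-protein" = write_edges(list(c("m1", "p1"), c("m2", "p1")),
                                  file.path(dir, "mp.tsv")),
    "protein-disease" = write_edges(list(c("p1", "d1")),
                                    file.path(dir, "pd.tsv")),
    "miRNA-lncRNA" = write_edges(list(c("m1", "l1")),
                                 file.path(dir, "ml.tsv")),
    "lncRNA-disease" = write_edges(list(c("l1", "d2")),
                                   file.path(dir, "ld.tsv")))
}

# random connected-ish symmetric adjacency with zero diagonal
random_adjacency <- function(n, p = 0.2) {
  S <- matrix(0, n, n)
  up <- upper.tri(S)
  S[up] <- as.numeric(runif(sum(up)) < p)
  S <- S + t(S)
  # ensure no isolated nodes so transition rows are stochastic
  for (i in which(rowSums(S) == 0)) {
    j <- if (i == 1) 2 else i - 1
    S[i, j] <- S[j, i] <- 1
  }
  S
}

# hierarchy rows as a data.frame(child, parent)
hier_df <- function(...) {
  rows <- list(...)
  data.frame(child = vapply(rows, `[[`, "", 1),
             parent = vapply(rows, `[[`, "", 2),
             stringsAsFactors = FALSE)
}

# small planted-signal study for fast end-to-end tests
small_sim_config <- function(seed = 11) {
  synthetic_config(blocks = 2, n_mirna = 24, n_disease = 16, n_protein = 20,
                   n_lncrna = 10, n_drug = 8, p_in = 0.3, p_out = 0.02,
                   seed = seed)
}
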