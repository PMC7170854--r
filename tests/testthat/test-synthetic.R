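test_that("identical seeds give byte-identical studies", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 9)
  generate_study(cfg, d1)
  generate_study(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  # and a different seed changes the study
  generate_study(small_sim_config(seed = 10), d2)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "positives.tsv"))),
                         unname(tools::md5sum(file.path(d2, "positives.tsv")))))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(p_in = 0.1, p_out = 0.2), "p_out < p_in")
  expect_error(synthetic_config(n_mirna = 0), "counts")
  expect_error(synthetic_config(observed_frac = 0), "observed_frac")
})

test_that("generated network loads and satisfies all hetnet invariants", {
  d <- withr::local_tempdir()
  sim <- generate_study(small_sim_config(), d)
  net <- load_edge_lists(sim$paths$edge_lists, verbose = FALSE)
  expect_equal(anyDuplicated(net$edges[, c("i", "j", "class")]), 0)
  expect_true(all(net$edges$i < net$edges$j))          # no self-loops
  S <- as.matrix(adjacency_matrix(net))
  expect_equal(S, t(S))
  expect_equal(sum(S) %% 2, 0)
  expect_true(all(net$nodes$ntype %in% node_types()))
})

test_that("observed positives are floor(frac * planted) and within-block", {
  d <- withr::local_tempdir()
  cfg <- small_sim_config()
  sim <- generate_study(cfg, d)
  planted <- nrow(sim$positives) + sum(sim$truth$label)
  expect_equal(nrow(sim$positives), floor(cfg$observed_frac * planted))
  blk <- setNames(sim$blocks$block, sim$blocks$id)
  # every true association (observed or held out) joins same-block nodes
  expect_true(all(blk[sim$positives$miRNA] == blk[sim$positives$disease]))
  held <- sim$truth[sim$truth$label == 1, ]
  expect_true(all(blk[held$miRNA] == blk[held$disease]))
  # every cross-block pair in the truth table is a true negative
  cross <- sim$truth[blk[sim$truth$miRNA] != blk[sim$truth$disease], ]
  expect_true(all(cross$label == 0))
  # truth + positives tile the full miRNA x disease grid
  expect_equal(nrow(sim$truth) + nrow(sim$positives),
               cfg$n_mirna * cfg$n_disease)
})

test_that("truth_recovery_report computes precision-at-N", {
  truth <- data.frame(miRNA = rep(paste0("m", 1:4), each = 2),
                      disease = rep(c("d1", "d2"), 4),
                      label = c(1, 1, 1, 0, 0, 0, 0, 0))
  # perfect ranking: held-out positives first
  perfect <- truth[order(-truth$label), c("miRNA", "disease")]
  rep1 <- truth_recovery_report(perfect, truth, n_values = c(1, 3, 8))
  expect_equal(rep1$precision, c(1, 1, 3 / 8))
  expect_error(truth_recovery_report(
    data.frame(miRNA = "zz", disease = "qq"), truth), "do not overlap")
})

test_that("random rankings recover at prevalence rate on average", {
  d <- withr::local_tempdir()
  sim <- generate_study(small_sim_config(seed = 4), d)
  truth <- sim$truth
  prev <- mean(truth$label)
  set.seed(30)
  precs <- replicate(20, {
    idx <- sample(nrow(truth))
    truth_recovery_report(truth[idx, c("miRNA", "disease")], truth,
                          n_values = 50)$precision
  })
  # binomial noise around prevalence
  expect_lt(abs(mean(precs) - prev), 3 * sqrt(prev * (1 - prev) / (50 * 20)) + 0.02)
})

test_that("sequences carry the block-preferred 3-mer enrichment", {
  d <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 12)
  sim <- generate_study(cfg, d)
  km <- kmer_table(sim$paths$fasta)
  blk <- setNames(sim$blocks$block, sim$blocks$id)
  pref <- rna_kmers(3)[round(seq(1, 64, length.out = cfg$blocks))]
  # mean frequency of a block's preferred word is higher inside the block
  for (b in seq_len(cfg$blocks)) {
    inb <- km[blk[rownames(km)] == b, pref[b]]
    outb <- km[blk[rownames(km)] != b, pref[b]]
    expect_gt(mean(inb), mean(outb))
  }
})

test_that("disease DAGs share more ancestry within blocks", {
  d <- withr::local_tempdir()
  cfg <- small_sim_config(seed = 13)
  sim <- generate_study(cfg, d)
  hier <- read_disease_hierarchy(sim$paths$hierarchy)
  dis <- sim$blocks$id[sim$blocks$ntype == "disease"]
  M <- semantic_similarity_matrix(hier, dis)
  blk <- setNames(sim$blocks$block, sim$blocks$id)
  same <- outer(blk[dis], blk[dis], "==") & upper.tri(M)
  diff <- (!outer(blk[dis], blk[dis], "==")) & upper.tri(M)
  expect_gt(mean(M[same]), mean(M[diff]))
})
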