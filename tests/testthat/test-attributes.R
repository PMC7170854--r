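test_that("k-mer frequencies match hand-derived cases", {
  v <- kmer_frequency("UUU")
  expect_equal(unname(v["UUU"]), 1)
  expect_equal(sum(v), 1)

  v <- kmer_frequency("UGCAUGC")  # 5 windows
  expect_equal(unname(v["UGC"]), 0.4)
  expect_equal(unname(v[c("GCA", "CAU", "AUG")]), rep(0.2, 3))
  expect_equal(sum(v != 0), 4)

  # DNA alphabet is normalized T -> U
  expect_equal(kmer_frequency("TGCATGC"), kmer_frequency("UGCAUGC"))
})

test_that("k-mer errors and invalid-character policies", {
  expect_error(kmer_frequency("AU"), "shorter than k")
  expect_error(kmer_frequency("AUGNNN"), "invalid character")
  # skip mode drops windows touching invalid bases
  v <- kmer_frequency("AUGNAUG", invalid = "skip")
  expect_equal(unname(v["AUG"]), 1)
})

test_that("k-mer vectors match the dictionary-count oracle on random RNA", {
  set.seed(101)
  for (i in 1:200) {
    s <- random_rna()
    v <- kmer_frequency(s)
    expect_equal(v, oracle_kmer(s), tolerance = 1e-12)
    expect_equal(sum(v), 1, tolerance = 1e-12)
  }
})

test_that("kmer_table reads FASTA and preserves ids", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "x.fasta")
  writeLines(c(">mir1 extra comment", "UUUUUU", ">mir2", "ACGTACG"), fa)
  m <- kmer_table(fa)
  expect_equal(rownames(m), c("mir1", "mir2"))
  expect_equal(unname(m["mir1", "UUU"]), 1)
  expect_equal(rowSums(m), c(mir1 = 1, mir2 = 1))
})

test_that("semantic value closed forms", {
  # single disease
  h <- hier_df(c("other", "ROOT"))  # irrelevant link
  dag <- disease_dag(hier_df(c("x", "y")), "D")  # D absent from hierarchy
  expect_equal(semantic_value(dag)$DV, 1)

  # chain g -> p -> D (g grandparent): child links D->p->g
  h <- hier_df(c("D", "p"), c("p", "g"))
  sv <- semantic_value(disease_dag(h, "D"), delta = 0.5)
  expect_equal(sv$DV, 1.75, tolerance = 1e-12)
  expect_equal(sort(unname(sv$contributions), decreasing = TRUE),
               c(1, 0.5, 0.25), tolerance = 1e-12)

  # diamond: D has parents p1, p2, both children of g
  h <- hier_df(c("D", "p1"), c("D", "p2"), c("p1", "g"), c("p2", "g"))
  sv <- semantic_value(disease_dag(h, "D"), delta = 0.5)
  expect_equal(unname(sv$contributions["g"]), 0.25, tolerance = 1e-12)
  expect_equal(sv$DV, 2.25, tolerance = 1e-12)
})

test_that("semantic value equals brute-force shortest-path oracle on random DAGs", {
  set.seed(7)
  for (rep in 1:25) {
    # random layered DAG of <= 20 nodes above a sink disease
    n <- sample(3:20, 1)
    labels <- c("D", paste0("a", seq_len(n - 1)))
    rows <- list()
    for (i in 2:n) {
      # each ancestor gets 1-2 children among the lower-numbered nodes
      for (ch in sample(seq_len(i - 1), sample(seq_len(min(2, i - 1)), 1))) {
        rows <- c(rows, list(c(labels[ch], labels[i])))
      }
    }
    h <- do.call(hier_df, rows)
    delta <- runif(1, 0.2, 0.8)
    sv <- semantic_value(disease_dag(h, "D"), delta = delta)
    or <- oracle_semantic(h, "D", delta)
    expect_equal(sv$DV, or$DV, tolerance = 1e-10)
    expect_equal(sv$contributions[names(or$contributions)],
                 or$contributions, tolerance = 1e-10)
  }
})

test_that("semantic similarity closed forms", {
  h <- hier_df(c("s1", "r"), c("s2", "r"))
  d1 <- disease_dag(h, "s1"); d2 <- disease_dag(h, "s2")
  expect_equal(semantic_similarity(d1, d1), 1, tolerance = 1e-12)
  expect_equal(semantic_similarity(d1, d2), 1 / 3, tolerance = 1e-12)
  # disjoint DAGs
  h2 <- hier_df(c("u1", "q"), c("u2", "q"))
  expect_equal(semantic_similarity(d1, disease_dag(h2, "u1")), 0)
})

test_that("similarity matrix is symmetric with unit diagonal and sibling 1/3", {
  h <- hier_df(c("s1", "r"), c("s2", "r"), c("z", "q"))
  M <- semantic_similarity_matrix(h, c("s1", "s2", "z"))
  expect_equal(diag(M), c(s1 = 1, s2 = 1, z = 1))
  expect_equal(M, t(M))
  expect_equal(M["s1", "s2"], 1 / 3, tolerance = 1e-12)
  expect_equal(M["s1", "z"], 0)
  expect_true(all(M >= 0 & M <= 1))
  # single disease
  expect_equal(semantic_similarity_matrix(h, "z"), matrix(1, 1, 1,
               dimnames = list("z", "z")))
})

test_that("adding a shared ancestor increases similarity", {
  h0 <- hier_df(c("s1", "r"), c("s2", "r"))
  h1 <- rbind(h0, hier_df(c("r", "g")))  # deepen the shared chain
  s0 <- semantic_similarity(disease_dag(h0, "s1"), disease_dag(h0, "s2"))
  s1 <- semantic_similarity(disease_dag(h1, "s1"), disease_dag(h1, "s2"))
  expect_gt(s1, s0)
})

test_that("missing diseases are zero-filled with a warning or dropped", {
  h <- hier_df(c("s1", "r"), c("s2", "r"))
  expect_warning(M <- semantic_similarity_matrix(h, c("s1", "nope")),
                 "missing from hierarchy")
  expect_equal(unname(M["nope", ]), c(0, 0))
  suppressWarnings(
    M2 <- semantic_similarity_matrix(h, c("s1", "nope"), missing = "drop"))
  expect_equal(rownames(M2), "s1")
})
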