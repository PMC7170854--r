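test_that("duplicate and reversed edges collapse to one", {
  dir <- withr::local_tempdir()
  p <- write_edges(list(c("m1", "p1"), c("m1", "p1"), c("p1", "m1")),
                   file.path(dir, "mp.tsv"))
  # reversed orientation: the file column order determines ntype, so feed the
  # reversed pair through a file of the same class with swapped ids
  net <- load_edge_lists(list("miRNA-protein" = p), verbose = FALSE)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
})

test_that("reversed orientation across files is de-duplicated", {
  dir <- withr::local_tempdir()
  # same class twice is impossible (named list), so reversed rows live in
  # one file; endpoint typing still follows columns, ids disambiguate
  p <- write_edges(list(c("m1", "p1")), file.path(dir, "a.tsv"))
  q <- write_edges(list(c("m1", "p1"), c("m2", "p1")), file.path(dir, "b.tsv"))
  n1 <- load_edge_lists(list("miRNA-protein" = p), verbose = FALSE)
  n2 <- load_edge_lists(list("miRNA-protein" = q), verbose = FALSE)
  expect_equal(nrow(n2$edges), 2)
  expect_true(all(n1$nodes$id %in% n2$nodes$id))
})

test_that("nine single-edge files union to nine edges, one per class", {
  dir <- withr::local_tempdir()
  cls <- association_classes()
  paths <- lapply(names(cls), function(cn) {
    tp <- cls[[cn]]
    a <- paste0(substr(tp[1], 1, 2), "1_", cn)
    b <- paste0(substr(tp[2], 1, 2), "2_", cn)
    write_edges(list(c(a, b)), file.path(dir, paste0(gsub("-", "_", cn), ".tsv")))
  })
  names(paths) <- names(cls)
  net <- load_edge_lists(paths, verbose = FALSE)
  expect_equal(nrow(net$edges), 9)
  expect_equal(unname(table(net$edges$class)[names(cls)]),
               rep(1L, 9), ignore_attr = TRUE)
})

test_that("six-node toy matches hand counts and node order is sorted", {
  net <- load_edge_lists(toy_net_paths(), verbose = FALSE)
  expect_equal(nrow(net$nodes), 6)
  expect_equal(as.vector(table(net$nodes$ntype)[c("miRNA", "disease",
                                                  "protein", "lncRNA")]),
               c(2, 2, 1, 1))
  expect_equal(nrow(net$edges), 5)
  # deterministic (ntype, id) order
  expect_equal(net$nodes$id, net$nodes$id[order(net$nodes$ntype, net$nodes$id,
                                                method = "radix")])
})

test_that("loading is idempotent", {
  paths <- toy_net_paths()
  n1 <- load_edge_lists(paths, verbose = FALSE)
  n2 <- load_edge_lists(paths, verbose = FALSE)
  expect_identical(n1, n2)
})

test_that("loader errors are specific", {
  dir <- withr::local_tempdir()
  p <- write_edges(list(c("m1", "p1")), file.path(dir, "x.tsv"))
  expect_error(load_edge_lists(list("miRNA-unicorn" = p)),
               "unknown association class")
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("a\tb", "oneFieldOnly"), bad)
  expect_error(load_edge_lists(list("miRNA-protein" = bad), verbose = FALSE),
               "bad.tsv at line 2")
  # id used as two different types
  q <- write_edges(list(c("x1", "p1")), file.path(dir, "ml.tsv"))
  r <- write_edges(list(c("x1", "d1")), file.path(dir, "pd.tsv"))
  expect_error(load_edge_lists(list("miRNA-protein" = q,
                                    "protein-disease" = r), verbose = FALSE),
               "identifier collision")
})

test_that("adjacency matrix matches the 3-node path and is symmetric", {
  dir <- withr::local_tempdir()
  paths <- list(
    "miRNA-protein" = write_edges(list(c("m1", "p1")), file.path(dir, "a.tsv")),
    "protein-disease" = write_edges(list(c("p1", "d1")), file.path(dir, "b.tsv")))
  net <- load_edge_lists(paths, verbose = FALSE)
  S <- as.matrix(adjacency_matrix(net))
  # sorted order: disease:d1, miRNA:m1, protein:p1 -> path d1-p1-m1
  expect_equal(unname(S), rbind(c(0, 0, 1), c(0, 0, 1), c(1, 1, 0)))
  expect_equal(S, t(S))
  expect_equal(diag(S), setNames(rep(0, 3), rownames(S)))
})

test_that("adjacency row sums equal degrees; total equals twice edge count", {
  net <- load_edge_lists(toy_net_paths(), verbose = FALSE)
  S <- as.matrix(adjacency_matrix(net))
  deg <- setNames(rep(0L, nrow(net$nodes)), seq_len(nrow(net$nodes)))
  for (r in seq_len(nrow(net$edges))) {
    deg[net$edges$i[r]] <- deg[net$edges$i[r]] + 1L
    deg[net$edges$j[r]] <- deg[net$edges$j[r]] + 1L
  }
  expect_equal(unname(rowSums(S)), as.numeric(deg))
  expect_equal(sum(S), 2 * nrow(net$edges))
})

test_that("network archive round-trips losslessly", {
  net <- load_edge_lists(toy_net_paths(), verbose = FALSE)
  dir <- withr::local_tempdir()
  write_network(net, dir)
  back <- read_network(dir)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$index, net$index)
})
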