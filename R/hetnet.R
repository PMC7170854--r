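#' @useDynLib hinmda, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods as
NULL

#' The nine association classes of the heterogeneous network
#'
#' Each association class joins two of the five node types
#' (miRNA, lncRNA, protein, disease, drug). The class name determines the
#' node types of an edge's endpoints: the first id column of an edge-list
#' file carries the first type, the second column the second type.
#'
#' @return Named list mapping class name to a length-2 character vector of
#'   endpoint node types.
#' @export
association_classes <- function() {
  list(
    "miRNA-lncRNA"    = c("miRNA",   "lncRNA"),
    "miRNA-protein"   = c("miRNA",   "protein"),
    "lncRNA-disease"  = c("lncRNA",  "disease"),
    "drug-disease"    = c("drug",    "disease"),
    "lncRNA-protein"  = c("lncRNA",  "protein"),
    "drug-protein"    = c("drug",    "protein"),
    "protein-protein" = c("protein", "protein"),
    "protein-disease" = c("protein", "disease"),
    "miRNA-disease"   = c("miRNA",   "disease")
  )
}

#' The five node types
#' @return Character vector of the node type names.
#' @export
node_types <- function() c("miRNA", "lncRNA", "protein", "disease", "drug")

.norm_id <- function(x, case_fold = FALSE, trim = TRUE) {
  if (trim) x <- trimws(x)
  if (case_fold) x <- tolower(x)
  x
}

#' Load typed edge-list files into a heterogeneous network
#'
#' Reads one TSV file per association class (columns
#' `source_id <TAB> target_id`, optional extra columns ignored), unifies
#' identifiers by exact string match (after optional trimming/case-folding),
#' removes duplicate edges (including reversed duplicates) and self-loops,
#' and indexes nodes in a deterministic `(ntype, id)` lexicographic order.
#'
#' @param paths_by_class Named list/character vector mapping association-class
#'   names (see [association_classes()]) to file paths.
#' @param header Logical; do the files carry a header line to skip?
#' @param case_fold Lower-case identifiers before matching?
#' @param trim Trim surrounding whitespace from identifiers?
#' @param verbose Log per-class and per-type summary counts?
#'
#' @return An object of class `hetnet`: a list with `nodes` (data.frame of
#'   `id`, `ntype`, in node order), `edges` (data.frame of node-order indices
#'   `i < j` and the association `class`), and `index` (named integer vector
#'   keyed by `"ntype:id"`).
#' @export
load_edge_lists <- function(paths_by_class, header = FALSE, case_fold = FALSE,
                            trim = TRUE, verbose = TRUE) {
  classes <- association_classes()
  paths_by_class <- as.list(paths_by_class)
  unknown <- setdiff(names(paths_by_class), names(classes))
  if (length(unknown) > 0 || is.null(names(paths_by_class))) {
    stop("unknown association class(es): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  reg <- new.env(parent = emptyenv())  # id -> ntype registry
  e_src <- character(0); e_dst <- character(0); e_cls <- character(0)

  for (cls in names(paths_by_class)) {
    path <- paths_by_class[[cls]]
    if (!file.exists(path)) stop("edge-list file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    if (header && length(lines) > 0) lines <- lines[-1]
    keep <- nzchar(trimws(lines))
    lineno <- seq_along(lines)[keep] + as.integer(header)
    lines <- lines[keep]
    if (length(lines) == 0) next
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2)) {
      bad <- which(nf < 2)[1]
      stop(sprintf("malformed row in %s at line %d: expected >= 2 tab-separated fields",
                   path, lineno[bad]), call. = FALSE)
    }
    src <- .norm_id(vapply(fields, `[[`, "", 1L), case_fold, trim)
    dst <- .norm_id(vapply(fields, `[[`, "", 2L), case_fold, trim)
    if (any(!nzchar(src) | !nzchar(dst))) {
      bad <- which(!nzchar(src) | !nzchar(dst))[1]
      stop(sprintf("malformed row in %s at line %d: empty identifier",
                   path, lineno[bad]), call. = FALSE)
    }
    tpair <- classes[[cls]]
    look <- function(id) if (exists(id, envir = reg)) get(id, envir = reg) else NA_character_
    for (r in seq_along(src)) {
      a <- src[r]; b <- dst[r]
      ta <- look(a); tb <- look(b)
      if (tpair[1] != tpair[2]) {
        # a row may be written in either orientation; resolve against the
        # registry, defaulting fresh ids to the column order
        swapped <- (!is.na(ta) && ta == tpair[2]) || (!is.na(tb) && tb == tpair[1])
        if (swapped) { tmp <- a; a <- b; b <- tmp; tmp <- ta; ta <- tb; tb <- tmp }
      }
      for (side in 1:2) {
        id <- if (side == 1) a else b
        want <- tpair[side]
        have <- if (side == 1) ta else tb
        if (is.na(have)) {
          assign(id, want, envir = reg)
        } else if (have != want) {
          stop(sprintf(
            "identifier collision: id '%s' used as both '%s' and '%s' (class %s, file %s, line %d)",
            id, have, want, cls, path, lineno[r]), call. = FALSE)
        }
      }
      src[r] <- a; dst[r] <- b
    }
    e_src <- c(e_src, src); e_dst <- c(e_dst, dst)
    e_cls <- c(e_cls, rep(cls, length(src)))
  }

  ids <- ls(reg)
  types <- unname(vapply(ids, function(i) get(i, envir = reg), ""))
  if (length(ids) == 0) stop("no edges loaded: all files empty", call. = FALSE)

  # deterministic node order: (ntype, id) lexicographic, C collation
  ord <- order(types, ids, method = "radix")
  nodes <- data.frame(id = ids[ord], ntype = types[ord],
                      stringsAsFactors = FALSE)
  key <- paste(nodes$ntype, nodes$id, sep = ":")
  index <- stats::setNames(seq_len(nrow(nodes)), key)

  i <- index[paste(types[match(e_src, ids)], e_src, sep = ":")]
  j <- index[paste(types[match(e_dst, ids)], e_dst, sep = ":")]
  loops <- i == j
  if (any(loops) && verbose) {
    message("dropping ", sum(loops), " self-loop(s)")
  }
  i2 <- pmin(i, j)[!loops]; j2 <- pmax(i, j)[!loops]; cls2 <- e_cls[!loops]
  dup <- duplicated(paste(i2, j2, cls2))
  edges <- data.frame(i = unname(i2[!dup]), j = unname(j2[!dup]),
                      class = cls2[!dup], stringsAsFactors = FALSE)
  edges <- edges[order(edges$i, edges$j, edges$class), , drop = FALSE]
  rownames(edges) <- NULL

  net <- structure(list(nodes = nodes, edges = edges, index = index),
                   class = "hetnet")
  if (verbose) {
    tc <- table(edges$class); tn <- table(nodes$ntype)
    message("hetnet: ", nrow(nodes), " nodes, ", nrow(edges), " edges")
    message("  per class: ", paste(names(tc), tc, sep = "=", collapse = ", "))
    message("  per type:  ", paste(names(tn), tn, sep = "=", collapse = ", "))
  }
  net
}

#' @export
print.hetnet <- function(x, ...) {
  cat("Heterogeneous network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  print(table(x$nodes$ntype))
  invisible(x)
}

#' Node ids of one type, in network node order
#' @param net A `hetnet`.
#' @param ntype One of [node_types()].
#' @return Character vector of ids.
#' @export
nodes_of_type <- function(net, ntype) {
  stopifnot(inherits(net, "hetnet"), ntype %in% node_types())
  net$nodes$id[net$nodes$ntype == ntype]
}

#' Binary adjacency matrix of the network
#'
#' Symmetric 0/1 sparse matrix over the network node order, zero diagonal;
#' an entry is 1 iff any association class joins the two nodes.
#'
#' @param net A `hetnet`.
#' @return A sparse symmetric `Matrix::dgCMatrix` with `"ntype:id"` dimnames.
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "hetnet"))
  n <- nrow(net$nodes)
  if (n == 0) stop("empty network", call. = FALSE)
  key <- paste(net$nodes$ntype, net$nodes$id, sep = ":")
  # distinct node pairs (an i-j pair may carry several classes)
  pair <- unique(net$edges[, c("i", "j")])
  S <- Matrix::sparseMatrix(
    i = c(pair$i, pair$j), j = c(pair$j, pair$i), x = 1,
    dims = c(n, n), dimnames = list(key, key))
  S@x[] <- 1  # collapse any accidental multiplicity
  methods::as(S, "dMatrix")
}

#' Write a network as a two-file TSV archive
#'
#' `<dir>/nodes.tsv` (id, ntype, in node order) and `<dir>/edges.tsv`
#' (source_key, target_key, class). Round-trips losslessly via
#' [read_network()].
#'
#' @param net A `hetnet`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(net$nodes, file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  key <- paste(net$nodes$ntype, net$nodes$id, sep = ":")
  ed <- data.frame(source = key[net$edges$i], target = key[net$edges$j],
                   class = net$edges$class)
  utils::write.table(ed, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a network archive written by [write_network()]
#' @param dir Archive directory.
#' @return A `hetnet`.
#' @export
read_network <- function(dir) {
  nodes <- utils::read.delim(file.path(dir, "nodes.tsv"),
                             stringsAsFactors = FALSE)
  ed <- utils::read.delim(file.path(dir, "edges.tsv"),
                          stringsAsFactors = FALSE)
  key <- paste(nodes$ntype, nodes$id, sep = ":")
  index <- stats::setNames(seq_len(nrow(nodes)), key)
  edges <- data.frame(i = unname(index[ed$source]),
                      j = unname(index[ed$target]),
                      class = ed$class, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, index = index),
            class = "hetnet")
}
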