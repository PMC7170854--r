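#' All k-mers over the RNA alphabet in lexicographic order
#' @param k Word length.
#' @return Character vector of length `4^k`.
#' @export
rna_kmers <- function(k = 3) {
  stopifnot(k >= 1)
  alph <- c("A", "C", "G", "U")
  words <- alph
  if (k > 1) for (i in 2:k) {
    words <- as.vector(outer(words, alph, paste0))
  }
  sort(words, method = "radix")
}

#' k-mer frequency vector of an RNA sequence
#'
#' Slides a window of length `k` over the sequence (after `T -> U`
#' normalization and upper-casing) and reports, for each of the `4^k`
#' possible words, the fraction of windows equal to it. Components sum to 1
#' for any valid sequence.
#'
#' @param sequence RNA (or DNA) string.
#' @param k Word length (default 3, giving a 64-dimensional vector).
#' @param invalid `"reject"` (default) errors on characters outside
#'   `A,C,G,U,T`; `"skip"` drops windows containing them.
#' @return Named numeric vector over [rna_kmers()] order.
#' @export
kmer_frequency <- function(sequence, k = 3, invalid = c("reject", "skip")) {
  invalid <- match.arg(invalid)
  s <- chartr("Tt", "Uu", toupper(as.character(sequence)))
  s <- toupper(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) < k) {
    stop("sequence shorter than k = ", k, call. = FALSE)
  }
  ok <- chars %in% c("A", "C", "G", "U")
  if (invalid == "reject" && !all(ok)) {
    stop("invalid character(s) in sequence: ",
         paste(unique(chars[!ok]), collapse = ","), call. = FALSE)
  }
  n_win <- length(chars) - k + 1
  words <- vapply(seq_len(n_win),
                  function(i) paste(chars[i:(i + k - 1)], collapse = ""),
                  "")
  if (invalid == "skip") {
    valid_pos <- ok
    words <- words[vapply(seq_len(n_win),
                          function(i) all(valid_pos[i:(i + k - 1)]), TRUE)]
    if (length(words) == 0) stop("no valid window of length ", k, call. = FALSE)
  }
  lv <- rna_kmers(k)
  counts <- table(factor(words, levels = lv))
  v <- as.numeric(counts) / length(words)
  names(v) <- lv
  v
}

#' k-mer frequency table for a FASTA file of miRNA sequences
#'
#' @param fasta Path to a FASTA file (RNA or DNA alphabet).
#' @param k Word length.
#' @param id_transform Optional function applied to FASTA record names to
#'   recover network node ids (e.g. prefix stripping).
#' @param invalid Passed to [kmer_frequency()].
#' @return Numeric matrix, one row per sequence (rownames = ids), `4^k` columns.
#' @export
kmer_table <- function(fasta, k = 3, id_transform = NULL,
                       invalid = "reject") {
  seqs <- Biostrings::readBStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (!is.null(id_transform)) ids <- id_transform(ids)
  m <- t(vapply(as.character(seqs),
                function(s) kmer_frequency(s, k = k, invalid = invalid),
                numeric(4^k)))
  rownames(m) <- ids
  m
}

# ---- disease DAG semantic similarity -------------------------------------

#' Load a MeSH-style disease hierarchy from a child-parent TSV
#'
#' @param path TSV with columns `child_id <TAB> parent_id` (no header by
#'   default).
#' @param header Skip a header line?
#' @return data.frame with columns `child`, `parent`.
#' @export
read_disease_hierarchy <- function(path, header = FALSE) {
  h <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                         col.names = c("child", "parent"))
  h$child <- trimws(h$child); h$parent <- trimws(h$parent)
  unique(h[nzchar(h$child) & nzchar(h$parent), , drop = FALSE])
}

#' Extract one disease's DAG (ancestor closure) from a hierarchy
#'
#' The DAG of disease `A` contains `A` and all of its ancestors, with the
#' parent links restricted to those nodes; `A` is the unique sink.
#'
#' @param hierarchy data.frame from [read_disease_hierarchy()].
#' @param disease Disease id.
#' @return Object of class `disease_dag`: list with `disease`, `nodes`, and
#'   `parents` (data.frame `child`, `parent` within the closure).
#' @export
disease_dag <- function(hierarchy, disease) {
  nodes <- disease
  frontier <- disease
  while (length(frontier) > 0) {
    par <- unique(hierarchy$parent[hierarchy$child %in% frontier])
    frontier <- setdiff(par, nodes)
    nodes <- c(nodes, frontier)
    if (length(nodes) > nrow(hierarchy) + 1) {
      stop("cycle detected in hierarchy near disease ", disease, call. = FALSE)
    }
  }
  links <- hierarchy[hierarchy$child %in% nodes & hierarchy$parent %in% nodes, ,
                     drop = FALSE]
  structure(list(disease = disease, nodes = nodes, parents = links),
            class = "disease_dag")
}

#' Semantic value of a disease from its DAG
#'
#' The disease itself contributes 1; every ancestor `d` contributes
#' `max(delta * contribution(d'))` over its children `d'` inside the DAG,
#' i.e. the contribution decays by the factor `delta` per generation along
#' the best (max) path down to the disease. The semantic value `DV` is the
#' sum of all contributions.
#'
#' @param dag A `disease_dag`.
#' @param delta Semantic contribution factor in (0, 1), default 0.5.
#' @return List with `DV` (numeric) and `contributions` (named vector over
#'   DAG nodes).
#' @export
semantic_value <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta < 1)
  nodes <- dag$nodes
  contrib <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  contrib[dag$disease] <- 1
  # children map within the DAG: parent -> children
  kids <- split(dag$parents$child, dag$parents$parent)
  # propagate upward from the disease; iterate until fixpoint (DAG is small)
  repeat {
    changed <- FALSE
    for (d in nodes) {
      if (d == dag$disease) next
      ch <- kids[[d]]
      if (is.null(ch)) {
        # node with no children inside the closure cannot reach the disease;
        # a valid DAG never produces this
        stop("DAG node '", d, "' has no path to disease '", dag$disease, "'",
             call. = FALSE)
      }
      vals <- contrib[ch]
      if (all(is.na(vals))) next
      new <- delta * max(vals, na.rm = TRUE)
      if (is.na(contrib[d]) || new > contrib[d] + 1e-15) {
        contrib[d] <- new; changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (anyNA(contrib)) {
    stop("cycle or disconnected node detected in DAG of '", dag$disease, "'",
         call. = FALSE)
  }
  list(DV = sum(contrib), contributions = contrib)
}

#' Semantic similarity between two diseases
#'
#' Shared-ancestor overlap: the contributions of the common DAG nodes under
#' each disease are summed and normalized by the two semantic values, giving
#' a score in `[0, 1]` with `SS(d, d) = 1`.
#'
#' @param dag_i,dag_j `disease_dag` objects.
#' @param delta Semantic contribution factor.
#' @return Numeric scalar.
#' @export
semantic_similarity <- function(dag_i, dag_j, delta = 0.5) {
  si <- semantic_value(dag_i, delta)
  sj <- semantic_value(dag_j, delta)
  common <- intersect(names(si$contributions), names(sj$contributions))
  if (length(common) == 0) return(0)
  sum(si$contributions[common] + sj$contributions[common]) / (si$DV + sj$DV)
}

#' Pairwise semantic similarity matrix over an ordered disease list
#'
#' A disease's row is its attribute vector: its semantic similarity to every
#' disease in the order (dimension = number of diseases). Diseases missing
#' from the hierarchy get an all-zero row/column (with unit diagonal kept
#' off) and a warning, unless `missing = "drop"`.
#'
#' @param hierarchy data.frame from [read_disease_hierarchy()].
#' @param order Character vector of disease ids fixing the matrix order.
#' @param delta Semantic contribution factor.
#' @param missing `"zero"` (default) or `"drop"` for diseases absent from
#'   the hierarchy.
#' @return Symmetric numeric matrix with unit diagonal for covered diseases.
#' @export
semantic_similarity_matrix <- function(hierarchy, order, delta = 0.5,
                                       missing = c("zero", "drop")) {
  missing <- match.arg(missing)
  known <- unique(c(hierarchy$child, hierarchy$parent))
  covered <- order %in% known
  if (any(!covered)) {
    warning(sum(!covered), " disease(s) missing from hierarchy: ",
            paste(utils::head(order[!covered], 5), collapse = ", "),
            if (sum(!covered) > 5) ", ..." else "", call. = FALSE)
    if (missing == "drop") order <- order[covered]
  }
  dags <- lapply(order, function(d) {
    if (d %in% known) disease_dag(hierarchy, d) else NULL
  })
  sems <- lapply(dags, function(g) {
    if (is.null(g)) NULL else semantic_value(g, delta)
  })
  n <- length(order)
  M <- matrix(0, n, n, dimnames = list(order, order))
  for (a in seq_len(n)) {
    if (is.null(sems[[a]])) next
    M[a, a] <- 1
    if (a == n) next
    for (b in seq((a + 1), n)) {
      if (is.null(sems[[b]])) next
      common <- intersect(names(sems[[a]]$contributions),
                          names(sems[[b]]$contributions))
      if (length(common) == 0) next
      ss <- sum(sems[[a]]$contributions[common] +
                  sems[[b]]$contributions[common]) /
        (sems[[a]]$DV + sems[[b]]$DV)
      M[a, b] <- ss; M[b, a] <- ss
    }
  }
  M
}
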