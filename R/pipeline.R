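#' Write / read a numeric matrix as TSV with row keys
#' @param m Matrix with rownames.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @keywords internal
write_matrix_tsv <- function(m, path) {
  df <- data.frame(key = rownames(m), as.data.frame(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @keywords internal
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.default_config <- function() {
  list(
    out_dir = "hinmda_run",
    seed = 42,
    simulate = NULL,            # synthetic_config() arguments, or NULL
    edge_lists = NULL,          # named list class -> path (if not simulated)
    fasta = NULL, hierarchy = NULL, positives = NULL,
    delta = 0.5,
    grarep = list(K = 4, d = 16),
    sae = list(code_dim = 64, epochs = 100, lr = 2e-3),
    classifier = list(kind = "RandomForest", hyper = list()),
    mode = "both", k_folds = 5, threshold = 0.5)
}

#' Load a pipeline configuration from YAML
#'
#' Unset keys fall back to the pipeline defaults (Delta = 0.5, K = 4,
#' d = 16, 64-dim attribute codes, Random Forest, mode "both", 5 folds).
#'
#' @param path YAML file.
#' @return Named config list.
#' @export
read_run_config <- function(path) {
  utils::modifyList(.default_config(), yaml::read_yaml(path))
}

.stage_hash <- function(cfg_slice, in_files) {
  in_files <- in_files[file.exists(in_files)]
  digest_in <- tools::md5sum(in_files)
  paste(tools::md5sum(
    {
      f <- tempfile()
      writeLines(c(utils::capture.output(utils::str(cfg_slice)), digest_in), f)
      f
    }), collapse = "")
}

.stage_fresh <- function(out_dir, stage, hash, outputs) {
  hf <- file.path(out_dir, paste0(".", stage, ".hash"))
  if (!file.exists(hf) || !all(file.exists(outputs))) return(FALSE)
  rec <- readLines(hf, warn = FALSE)
  # line 1: input/config hash; rest: md5 of each output at completion time
  identical(rec, c(hash, unname(tools::md5sum(sort(outputs)))))
}

.stage_done <- function(out_dir, stage, hash, outputs) {
  writeLines(c(hash, unname(tools::md5sum(sort(outputs)))),
             file.path(out_dir, paste0(".", stage, ".hash")))
}

#' Run the full prediction pipeline
#'
#' Stages, in dependency order: `simulate` (optional synthetic inputs),
#' `build-net` (load/deduplicate edge lists), `embed` (GraRep behavior
#' vectors), `featurize` (k-mer + DAG similarity attributes, autoencoder
#' codes), `cv` (negative sampling, fold split, classifier,
#' cross-validated metric report). A stage whose config and input files
#' are unchanged (MD5 content hash) and whose outputs exist is skipped, so
#' reruns are idempotent; the resolved config is serialized next to every
#' report for provenance.
#'
#' @param config Config list (see [read_run_config()]); missing keys take
#'   defaults.
#' @param verbose Log stage progress?
#' @return List with `report` (`cv_report`), `paths` of all artifacts, and
#'   the in-memory `net`, `features`, `dataset`.
#' @export
run_pipeline <- function(config = list(), verbose = TRUE) {
  cfg <- utils::modifyList(.default_config(), config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[hinmda] ", ...)

  # -- simulate ------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_cfg <- do.call(synthetic_config,
                       utils::modifyList(list(seed = cfg$seed),
                                         cfg$simulate))
    sim_dir <- file.path(out, "sim")
    h <- .stage_hash(sim_cfg, character(0))
    probe <- file.path(sim_dir, "positives.tsv")
    if (!.stage_fresh(out, "simulate", h, probe)) {
      say("simulate: generating synthetic study")
      generate_study(sim_cfg, sim_dir)
      .stage_done(out, "simulate", h, probe)
    } else say("simulate: up to date, skipped")
    cls <- names(association_classes())
    cfg$edge_lists <- stats::setNames(
      as.list(file.path(sim_dir, paste0(cls, ".tsv"))), cls)
    cfg$fasta <- file.path(sim_dir, "mirna.fasta")
    cfg$hierarchy <- file.path(sim_dir, "disease_hierarchy.tsv")
    cfg$positives <- file.path(sim_dir, "positives.tsv")
  }
  for (need in c("edge_lists", "fasta", "hierarchy", "positives")) {
    if (is.null(cfg[[need]])) stop("config lacks '", need, "'", call. = FALSE)
  }
  miss <- !file.exists(unlist(cfg$edge_lists))
  if (any(miss)) stop("missing edge list(s): ",
                      paste(unlist(cfg$edge_lists)[miss], collapse = ", "),
                      call. = FALSE)
  for (f in c(cfg$fasta, cfg$hierarchy, cfg$positives)) {
    if (!file.exists(f)) stop("missing input: ", f, call. = FALSE)
  }

  # -- build-net -----------------------------------------------------------
  net_dir <- file.path(out, "net")
  h <- .stage_hash(cfg["edge_lists"], unlist(cfg$edge_lists))
  net_files <- file.path(net_dir, c("nodes.tsv", "edges.tsv"))
  if (!.stage_fresh(out, "build-net", h, net_files)) {
    say("build-net: loading edge lists")
    net <- load_edge_lists(cfg$edge_lists, verbose = verbose)
    write_network(net, net_dir)
    .stage_done(out, "build-net", h, net_files)
  } else {
    say("build-net: up to date, skipped")
    net <- read_network(net_dir)
  }

  # -- embed ---------------------------------------------------------------
  emb_path <- file.path(out, "embedding.tsv")
  h <- .stage_hash(cfg$grarep, file.path(net_dir, c("nodes.tsv", "edges.tsv")))
  if (!.stage_fresh(out, "embed", h, emb_path)) {
    say("embed: GraRep K=", cfg$grarep$K, " d=", cfg$grarep$d)
    W <- grarep_embed(adjacency_matrix(net), K = cfg$grarep$K,
                      d = cfg$grarep$d)
    write_matrix_tsv(W, emb_path)
    .stage_done(out, "embed", h, emb_path)
  } else {
    say("embed: up to date, skipped")
    W <- read_matrix_tsv(emb_path)
  }

  # -- featurize -----------------------------------------------------------
  feat_dir <- file.path(out, "features")
  dir.create(feat_dir, showWarnings = FALSE)
  feat_files <- file.path(feat_dir, c("mirna_attr.tsv", "mirna_behav.tsv",
                                      "disease_attr.tsv",
                                      "disease_behav.tsv"))
  h <- .stage_hash(list(cfg$delta, cfg$sae, cfg$seed),
                   c(cfg$fasta, cfg$hierarchy, emb_path))
  if (!.stage_fresh(out, "featurize", h, feat_files)) {
    say("featurize: k-mer + semantic similarity + autoencoder")
    kmer <- kmer_table(cfg$fasta)
    dis <- nodes_of_type(net, "disease")
    hier <- read_disease_hierarchy(cfg$hierarchy)
    simmat <- semantic_similarity_matrix(hier, dis, delta = cfg$delta)
    features <- build_node_features(net, kmer, simmat, W,
                                    code_dim = cfg$sae$code_dim,
                                    sae_epochs = cfg$sae$epochs,
                                    sae_lr = cfg$sae$lr, seed = cfg$seed)
    for (nm in c("mirna_attr", "mirna_behav", "disease_attr",
                 "disease_behav")) {
      write_matrix_tsv(features[[nm]],
                       file.path(feat_dir, paste0(nm, ".tsv")))
    }
    .stage_done(out, "featurize", h, feat_files)
  } else {
    say("featurize: up to date, skipped")
    features <- structure(
      stats::setNames(lapply(feat_files, read_matrix_tsv),
                      c("mirna_attr", "mirna_behav", "disease_attr",
                        "disease_behav")),
      class = "node_features")
  }

  # -- cv ------------------------------------------------------------------
  say("cv: ", cfg$k_folds, "-fold, classifier ", cfg$classifier$kind,
      ", mode ", cfg$mode)
  pos <- utils::read.delim(cfg$positives, header = FALSE,
                           col.names = c("miRNA", "disease"),
                           stringsAsFactors = FALSE)
  dataset <- build_pair_dataset(pos, features, mode = cfg$mode,
                                seed = cfg$seed)
  report <- cross_validate(dataset, kind = cfg$classifier$kind,
                           k = cfg$k_folds, seed = cfg$seed,
                           threshold = cfg$threshold,
                           hyper = cfg$classifier$hyper)
  report_path <- file.path(out, "report.json")
  jsonlite::write_json(
    list(config = cfg[c("seed", "delta", "grarep", "sae", "mode",
                        "k_folds", "threshold")],
         classifier = cfg$classifier$kind,
         per_fold = report$per_fold,
         summary = report$summary),
    report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$roc, file.path(out, "roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$pr, file.path(out, "pr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  say("done: mean AUC = ",
      sprintf("%.4f", report$summary$mean[report$summary$metric == "AUC"]))

  list(report = report,
       paths = list(net = net_dir, embedding = emb_path,
                    features = feat_dir, report = report_path),
       net = net, features = features, dataset = dataset, config = cfg)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all`, `cv` (alias of `run-all`), and
#' `predict`. Shared flags: `--config <yaml>`, `--out <dir>`,
#' `--seed <int>`; `predict` adds `--disease <id>` and `--top <n>`.
#' Install target: `inst/scripts/hinmda` wraps this function for Rscript.
#'
#' @param args Character vector of CLI arguments.
#' @return Exit status 0, invisibly.
#' @export
hinmda_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: hinmda <simulate|run-all|cv|predict> [--config f.yaml]",
        "[--out dir] [--seed n] [--disease id] [--top n]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(config = NULL, out = NULL, seed = NULL, disease = NULL,
              top = "50")
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      stop("bad argument: ", args[i], call. = FALSE)
    }
    opt[[key]] <- args[i + 1]; i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_run_config(opt$config) else
    utils::modifyList(.default_config(), list(simulate = list()))
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)

  if (cmd == "simulate") {
    sim_cfg <- do.call(synthetic_config,
                       utils::modifyList(list(seed = cfg$seed),
                                         if (is.null(cfg$simulate)) list()
                                         else cfg$simulate))
    generate_study(sim_cfg, cfg$out_dir)
    message("synthetic study written to ", cfg$out_dir)
  } else if (cmd %in% c("run-all", "cv")) {
    run_pipeline(cfg)
  } else if (cmd == "predict") {
    if (is.null(opt$disease)) stop("predict requires --disease", call. = FALSE)
    res <- run_pipeline(cfg)
    model <- train_classifier(cfg$classifier$kind, res$dataset$X,
                              res$dataset$samples$label,
                              hyper = cfg$classifier$hyper, seed = cfg$seed)
    pos <- res$dataset$samples[res$dataset$samples$label == 1,
                               c("miRNA", "disease")]
    ranked <- rank_candidates(opt$disease, model, res$features, pos,
                              mode = cfg$mode, top = as.integer(opt$top))
    out_file <- file.path(cfg$out_dir, paste0("ranked_", opt$disease, ".tsv"))
    utils::write.table(ranked, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    message("ranked candidates written to ", out_file)
  } else {
    stop("unknown subcommand: ", cmd, call. = FALSE)
  }
  invisible(0L)
}
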