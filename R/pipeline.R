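# Run configuration and the pipeline steps tying the modules together:
# extract -> rank -> top-k -> grid search -> jackknife -> ROC. Every step
# writes its outputs plus the resolved configuration next to them, so a run
# can be reproduced from its output directory alone.

#' Build a run configuration
#'
#' A plain named list of resolved paths and parameters, serializable to a
#' key-value text file. Unknown keys are rejected so typos fail loudly.
#'
#' @param manifest Path to the dataset manifest TSV.
#' @param fasta Path to the sequence FASTA.
#' @param pssm_dir Directory of `<protein_id>.pssm` files.
#' @param annotations Path to the GO annotation table (GAF or TSV).
#' @param out_dir Output directory.
#' @param lpc_orders Integer vector of LPC orders.
#' @param preset `"default"` (1080-dim descriptor block) or `"compact"`
#'   (aac + dpc, 420 dims, for small/fast runs).
#' @param top_k Features kept after ranking (e.g. 322 for large
#'   low-similarity-style runs, 70 for small high-similarity-style runs);
#'   `NA` keeps everything.
#' @param rfe_cost Linear-SVM C used by SVM-RFE.
#' @param cost,gamma RBF parameters used when `grid_search = FALSE`.
#' @param grid_search Tune (C, gamma) by grid search before the jackknife.
#' @param protocol Jackknife selection protocol
#'   (`"rank_once"` or `"nested"`).
#' @param seed Integer seed for any randomized step (grid-search folds).
#' @return Named list of class `run_config`.
#' @export
run_config <- function(manifest, fasta, pssm_dir, annotations, out_dir,
                       lpc_orders = 3:10, preset = "default", top_k = NA,
                       rfe_cost = 1, cost = 8, gamma = 1 / 16,
                       grid_search = FALSE, protocol = "rank_once",
                       seed = 1) {
  structure(list(manifest = manifest, fasta = fasta, pssm_dir = pssm_dir,
                 annotations = annotations, out_dir = out_dir,
                 lpc_orders = as.integer(lpc_orders), preset = preset,
                 top_k = if (is.na(top_k)) NA_integer_ else as.integer(top_k),
                 rfe_cost = rfe_cost, cost = cost, gamma = gamma,
                 grid_search = isTRUE(grid_search), protocol = protocol,
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_preset <- function(name) {
  switch(name,
    default = descriptor_preset(),
    compact = descriptor_preset(groups = c("aac", "dpc")),
    stop("unknown descriptor preset: ", name, call. = FALSE))
}

#' Serialize / parse a run configuration
#'
#' Key-value text format, one `key<TAB>value` line per entry; vectors are
#' comma-joined.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  vals <- vapply(config, function(v) paste(as.character(v), collapse = ","),
                 character(1))
  writeLines(paste(names(config), vals, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x) paste(x[-1], collapse = "\t")),
                          vapply(kv, `[[`, character(1), 1))
  num <- function(x) as.numeric(x)
  run_config(
    manifest = vals$manifest, fasta = vals$fasta, pssm_dir = vals$pssm_dir,
    annotations = vals$annotations, out_dir = vals$out_dir,
    lpc_orders = as.integer(strsplit(vals$lpc_orders, ",")[[1]]),
    preset = vals$preset,
    top_k = if (vals$top_k %in% c("NA", "")) NA else as.integer(vals$top_k),
    rfe_cost = num(vals$rfe_cost), cost = num(vals$cost),
    gamma = num(vals$gamma),
    grid_search = vals$grid_search == "TRUE",
    protocol = vals$protocol, seed = as.integer(vals$seed)
  )
}

ensure_out_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(config$out_dir, "run_config.tsv"))
  config$out_dir
}

#' Pipeline step: feature extraction
#'
#' Reads all inputs named by the configuration, extracts the integrated
#' feature matrix and writes `features.tsv`, `vocabulary.txt` and
#' `dropped.txt` into the output directory.
#'
#' @param config A [run_config()].
#' @return The feature tibble, invisibly.
#' @export
run_extract <- function(config) {
  out <- ensure_out_dir(config)
  manifest <- read_manifest(config$manifest)
  sequences <- read_fasta_sequences(config$fasta)
  annotations <- read_go_annotations(config$annotations)
  feats <- extract_features(manifest, sequences, config$pssm_dir, annotations,
                            lpc_orders = lpc_config(config$lpc_orders),
                            preset = resolve_preset(config$preset))
  write_feature_tsv(feats, file.path(out, "features.tsv"))
  write_go_vocabulary(attr(feats, "vocabulary"), file.path(out, "vocabulary.txt"))
  writeLines(attr(feats, "drop_report"), file.path(out, "dropped.txt"))
  invisible(feats)
}

#' Pipeline step: SVM-RFE ranking
#'
#' Ranks `features.tsv` and writes `ranking.tsv` plus a per-block composition
#' summary of the top-k set (`block_composition.tsv`).
#'
#' @param config A [run_config()].
#' @return The `svm_rfe_ranking`, invisibly.
#' @export
run_rank <- function(config) {
  out <- ensure_out_dir(config)
  feats <- read_feature_tsv(file.path(out, "features.tsv"))
  ranking <- svm_rfe(feats, cost = config$rfe_cost)
  write_ranking_tsv(ranking, file.path(out, "ranking.tsv"))
  k <- if (is.na(config$top_k)) length(ranking$rank_list) else config$top_k
  comp <- table(factor(feature_block(utils::head(ranking$rank_list, k)),
                       levels = c("pssm_lpc", "profeat", "go", "other")))
  utils::write.table(as.data.frame(comp), file.path(out, "block_composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("block", "n_top_features"))
  invisible(ranking)
}

read_ranking_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(rank_list = df$feature,
                 elimination_order = rev(df$feature),
                 criterion_trace = rev(df$criterion),
                 features = df$feature, cost = NA_real_, step = 1L),
            class = "svm_rfe_ranking")
}

#' Pipeline step: jackknife evaluation (with optional grid search)
#'
#' Truncates to the configured top-k feature set, optionally tunes (C, gamma)
#' by cross-validated grid search, runs the jackknife and writes
#' `report.json`, `predictions.tsv` and the macro-averaged `roc.tsv`.
#'
#' @param config A [run_config()].
#' @return The `jackknife_report`, invisibly.
#' @export
run_jackknife <- function(config) {
  out <- ensure_out_dir(config)
  feats <- read_feature_tsv(file.path(out, "features.tsv"))
  ranking_path <- file.path(out, "ranking.tsv")
  ranking <- if (file.exists(ranking_path)) read_ranking_tsv(ranking_path) else NULL
  if (!is.na(config$top_k) && !is.null(ranking)) {
    feats <- top_k(feats, ranking, min(config$top_k, length(ranking$rank_list)))
  }
  params <- if (config$grid_search) {
    gs <- grid_search(feats, protocol = "cv", seed = config$seed)
    utils::write.table(gs$table, file.path(out, "grid_search.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gs$best
  } else {
    svm_params(config$cost, config$gamma)
  }
  report <- jackknife(feats, params, protocol = config$protocol,
                      k = NULL, rfe_cost = config$rfe_cost)
  write_report(report, file.path(out, "report.json"),
               file.path(out, "predictions.tsv"))
  roc <- report_roc(report)
  write_roc_tsv(roc$macro, file.path(out, "roc.tsv"))
  invisible(report)
}

#' Run the whole pipeline
#'
#' extract -> rank -> top-k -> (grid search) -> jackknife -> ROC, writing all
#' step outputs into `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return The `jackknife_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  run_extract(config)
  run_rank(config)
  run_jackknife(config)
}

#' Train a final model and predict new proteins
#'
#' Trains on the configured dataset (after optional top-k truncation) and
#' scores a second dataset extracted with the same settings and the frozen
#' training vocabulary.
#'
#' @param config A [run_config()] for the training dataset.
#' @param new_manifest,new_fasta,new_pssm_dir,new_annotations Inputs for the
#'   proteins to score.
#' @return Tibble with `protein_id` and `predicted` class; also written as
#'   `predictions_new.tsv`.
#' @export
run_predict <- function(config, new_manifest, new_fasta, new_pssm_dir,
                        new_annotations) {
  out <- ensure_out_dir(config)
  feats <- read_feature_tsv(file.path(out, "features.tsv"))
  vocab <- read_go_vocabulary(file.path(out, "vocabulary.txt"))
  ranking_path <- file.path(out, "ranking.tsv")
  keep_features <- setdiff(names(feats), id_columns())
  if (!is.na(config$top_k) && file.exists(ranking_path)) {
    ranking <- read_ranking_tsv(ranking_path)
    feats <- top_k(feats, ranking, min(config$top_k, length(ranking$rank_list)))
    keep_features <- setdiff(names(feats), id_columns())
  }
  model <- svm_train(feats, svm_params(config$cost, config$gamma))
  new_feats <- extract_features(read_manifest(new_manifest),
                                read_fasta_sequences(new_fasta),
                                new_pssm_dir,
                                read_go_annotations(new_annotations),
                                lpc_orders = lpc_config(config$lpc_orders),
                                preset = resolve_preset(config$preset),
                                vocabulary = vocab)
  new_feats <- new_feats[, c(id_columns(), keep_features)]
  pred <- predict(model, new_feats)
  res <- tibble::tibble(protein_id = new_feats$protein_id,
                        predicted = as.character(pred))
  utils::write.table(res, file.path(out, "predictions_new.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  res
}
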