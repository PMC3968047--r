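# Integration of the three feature blocks (pssm_lpc | profeat | go) into one
# samples-by-features tibble keyed by protein_id and class.

#' Tag feature names with their block
#'
#' @param feature_names Character vector of feature column names.
#' @return Character vector with values `"pssm_lpc"`, `"profeat"`, `"go"` or
#'   `"other"`.
#' @export
feature_block <- function(feature_names) {
  dplyr::case_when(
    startsWith(feature_names, "pssm_") ~ "pssm_lpc",
    startsWith(feature_names, "profeat_") ~ "profeat",
    startsWith(feature_names, "go_") ~ "go",
    TRUE ~ "other"
  )
}

#' Names of the non-feature columns in a feature tibble
#' @return `c("protein_id", "class")`
#' @export
id_columns <- function() c("protein_id", "class")

# split a feature tibble into the numeric matrix + labels
feature_matrix_parts <- function(data) {
  stopifnot(all(id_columns() %in% names(data)))
  feats <- setdiff(names(data), id_columns())
  x <- as.matrix(data[, feats, drop = FALSE])
  if (!is.numeric(x)) stop("feature columns must be numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("feature matrix contains non-finite values",
                               call. = FALSE)
  if (anyDuplicated(feats)) stop("feature names must be unique", call. = FALSE)
  rownames(x) <- data$protein_id
  list(x = x, y = as_class_factor(data$class), features = feats)
}

#' Read a dataset manifest
#'
#' A manifest is a two-column TSV (`protein_id`, `class`) assigning each
#' protein one of the four structural classes.
#'
#' @param path Manifest TSV path (header row required).
#' @return Tibble with `protein_id` and `class` (canonical factor).
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_id", "class") %in% names(df))) {
    stop("manifest must have columns protein_id and class", call. = FALSE)
  }
  tibble::tibble(protein_id = as.character(df$protein_id),
                 class = as_class_factor(df$class))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences (names = record
#'   ids up to the first whitespace).
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Extract the integrated feature matrix for a dataset
#'
#' Runs the full feature extraction for every protein in the manifest:
#' sigmoid-normalized PSSM -> LPC block, physicochemical descriptor block,
#' and binary GO block over a dataset-scoped vocabulary. Proteins without GO
#' annotations are dropped (reported via the `drop_report` attribute), as the
#' annotation block is undefined for them. Column order is pssm_lpc, profeat,
#' go.
#'
#' @param manifest Tibble with `protein_id`, `class` (see [read_manifest()]).
#' @param sequences Named character vector of sequences
#'   (see [read_fasta_sequences()]).
#' @param pssm_dir Directory holding `<protein_id>.pssm` files, or a named
#'   list of `pssm` objects.
#' @param annotations A `go_annotations` tibble.
#' @param lpc_orders LPC orders (default `3:10`).
#' @param preset Descriptor preset (default [descriptor_preset()], 1080 dims).
#' @param vocabulary Optional frozen `go_vocabulary`; by default built from
#'   the kept proteins of this dataset.
#' @return Tibble (`protein_id`, `class`, then feature columns) with
#'   attributes `drop_report` (dropped protein ids) and `vocabulary`.
#' @export
extract_features <- function(manifest, sequences, pssm_dir, annotations,
                             lpc_orders = lpc_config(),
                             preset = descriptor_preset(),
                             vocabulary = NULL) {
  ids <- manifest$protein_id
  miss_seq <- setdiff(ids, names(sequences))
  if (length(miss_seq) > 0) {
    stop("missing sequence(s) for: ", paste(utils::head(miss_seq, 5), collapse = ", "),
         call. = FALSE)
  }
  flt <- filter_unannotated(ids, annotations)
  kept <- flt$kept
  if (length(kept) == 0) stop("no annotated proteins left after filtering",
                              call. = FALSE)
  if (is.null(vocabulary)) vocabulary <- build_go_vocabulary(annotations, kept)

  get_pssm <- if (is.list(pssm_dir)) {
    function(id) {
      if (is.null(pssm_dir[[id]])) stop("missing PSSM for: ", id, call. = FALSE)
      pssm_dir[[id]]
    }
  } else {
    function(id) {
      f <- file.path(pssm_dir, paste0(id, ".pssm"))
      if (!file.exists(f)) stop("missing PSSM file for: ", id, call. = FALSE)
      read_pssm(f)
    }
  }

  lpc_rows <- lapply(kept, function(id) {
    encode_pssm_lpc(sigmoid_normalize(get_pssm(id)), lpc_orders)
  })
  prof_rows <- lapply(kept, function(id) {
    profeat_block(sequences[[id]], preset)
  })
  go_m <- encode_go(kept, annotations, vocabulary)

  out <- dplyr::bind_cols(
    tibble::tibble(protein_id = kept,
                   class = as_class_factor(manifest$class[match(kept, ids)])),
    tibble::as_tibble(do.call(rbind, lpc_rows)),
    tibble::as_tibble(do.call(rbind, prof_rows)),
    tibble::as_tibble(go_m)
  )
  attr(out, "drop_report") <- flt$dropped
  attr(out, "vocabulary") <- vocabulary
  out
}

#' Total integrated feature dimension
#'
#' @param lpc_orders LPC orders.
#' @param preset Descriptor preset.
#' @param vocab_size GO vocabulary size.
#' @return Integer: LPC block + descriptor block + GO block dimensions.
#' @export
#' @examples
#' integrated_dim(vocab_size = 3245)  # 1040 + 1080 + 3245 = 5365
integrated_dim <- function(lpc_orders = lpc_config(),
                           preset = descriptor_preset(),
                           vocab_size) {
  lpc_block_dim(lpc_orders) + preset_dim(preset) + as.integer(vocab_size)
}

#' Write / read a feature tibble as TSV
#'
#' @param data Feature tibble.
#' @param path TSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_feature_tsv <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  if ("class" %in% names(out)) out$class <- as_class_factor(out$class)
  out
}
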