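# Gene Ontology annotation features: parse GAF 2.x or two-column TSV tables,
# drop unannotated proteins, build a dataset-scoped term vocabulary and encode
# each protein as a binary membership vector over it.

go_id_regex <- "^GO:[0-9]{7}$"

#' Read protein -> GO-term annotations
#'
#' Accepts GAF 2.x (17 columns, `!` comment lines; column 2 = protein id,
#' column 4 = qualifier, column 5 = GO id) or a two-column TSV
#' (protein_id, GO id). Syntactically invalid GO identifiers are skipped with
#' a warning and counted in the parse report. Duplicate (protein, term) rows
#' collapse to one.
#'
#' @param path Annotation file path.
#' @param format `"auto"` (sniff GAF by `!gaf-version` header or column
#'   count), `"gaf"` or `"tsv"`.
#' @param drop_not For GAF input, drop rows whose qualifier contains `NOT`
#'   (off by default; the qualifier is otherwise ignored).
#' @return A tibble of class `go_annotations` with columns `protein_id`,
#'   `go_id` (one row per distinct pair), and a `report` attribute listing
#'   `n_records`, `n_skipped_invalid` and `n_dropped_not`.
#' @export
read_go_annotations <- function(path, format = c("auto", "gaf", "tsv"),
                                drop_not = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  comments <- grepl("^!", lines)
  body <- lines[!comments & nzchar(trimws(lines))]
  if (format == "auto") {
    is_gaf <- any(grepl("^!gaf-version", lines)) ||
      (length(body) > 0 && length(strsplit(body[[1]], "\t", fixed = TRUE)[[1]]) >= 15)
    format <- if (is_gaf) "gaf" else "tsv"
  }
  n_not <- 0L
  if (length(body) == 0) {
    pairs <- tibble::tibble(protein_id = character(), go_id = character())
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (format == "gaf") {
      ok_len <- lengths(fields) >= 5
      if (!all(ok_len)) {
        stop("malformed GAF row (fewer than 5 columns) at data line ",
             which(!ok_len)[[1]], call. = FALSE)
      }
      prot <- vapply(fields, `[[`, character(1), 2)
      qual <- vapply(fields, `[[`, character(1), 4)
      term <- vapply(fields, `[[`, character(1), 5)
      if (drop_not) {
        keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
        n_not <- sum(!keep)
        prot <- prot[keep]; term <- term[keep]
      }
    } else {
      ok_len <- lengths(fields) >= 2
      if (!all(ok_len)) {
        stop("malformed TSV row (fewer than 2 columns) at data line ",
             which(!ok_len)[[1]], call. = FALSE)
      }
      prot <- vapply(fields, `[[`, character(1), 1)
      term <- vapply(fields, `[[`, character(1), 2)
    }
    valid <- grepl(go_id_regex, term)
    if (any(!valid)) {
      warning(sum(!valid), " record(s) with invalid GO identifiers skipped",
              call. = FALSE)
    }
    pairs <- tibble::tibble(protein_id = prot[valid], go_id = term[valid])
  }
  out <- dplyr::distinct(pairs)
  attr(out, "report") <- list(
    format = format,
    n_records = length(body),
    n_skipped_invalid = if (length(body)) sum(!grepl(go_id_regex,
      vapply(strsplit(body, "\t", fixed = TRUE), function(f) {
        f[[min(length(f), if (format == "gaf") 5 else 2)]]
      }, character(1)))) else 0L,
    n_dropped_not = n_not
  )
  class(out) <- c("go_annotations", class(out))
  out
}

# protein -> character vector of terms, as a named list
go_term_sets <- function(annotations, ids = NULL) {
  sets <- split(annotations$go_id, annotations$protein_id)
  if (!is.null(ids)) {
    sets <- sets[intersect(ids, names(sets))]
  }
  sets
}

#' Split dataset ids into GO-annotated and unannotated
#'
#' Proteins without any known GO term carry no annotation signal and are
#' discarded from downstream feature matrices.
#'
#' @param ids Character vector of dataset protein ids.
#' @param annotations A `go_annotations` tibble (or any tibble with
#'   `protein_id`, `go_id`).
#' @return List with `kept` and `dropped` character vectors (both in input
#'   order) and `n_dropped`.
#' @export
filter_unannotated <- function(ids, annotations) {
  annotated <- unique(annotations$protein_id[nzchar(annotations$go_id)])
  keep <- ids %in% annotated
  list(kept = ids[keep], dropped = ids[!keep], n_dropped = sum(!keep))
}

#' Build a dataset-scoped GO vocabulary
#'
#' The vocabulary is the union of GO terms over the given proteins, ordered
#' lexicographically by identifier so the binary encoding basis is
#' deterministic across runs and input row orders.
#'
#' @param annotations A `go_annotations` tibble.
#' @param ids Optional protein ids to scope the union to (default: all
#'   annotated proteins in `annotations`).
#' @return Character vector of class `go_vocabulary` (sorted, no duplicates).
#' @export
build_go_vocabulary <- function(annotations, ids = NULL) {
  ann <- annotations
  if (!is.null(ids)) ann <- ann[ann$protein_id %in% ids, , drop = FALSE]
  terms <- sort(unique(ann$go_id))
  if (length(terms) == 0) {
    stop("no GO terms found: cannot build an empty vocabulary", call. = FALSE)
  }
  structure(terms, class = "go_vocabulary")
}

#' Write / read a vocabulary as one term per line
#'
#' @param vocab A `go_vocabulary`.
#' @param path File path.
#' @return `path` (write) or a `go_vocabulary` (read).
#' @export
write_go_vocabulary <- function(vocab, path) {
  writeLines(as.character(vocab), path)
  invisible(path)
}

#' @rdname write_go_vocabulary
#' @export
read_go_vocabulary <- function(path) {
  structure(readLines(path, warn = FALSE), class = "go_vocabulary")
}

#' Binary GO encoding of proteins
#'
#' Component i of a protein's vector is 1 iff vocabulary term i belongs to the
#' protein's annotation set. Terms outside the vocabulary are ignored (with a
#' message), matching a vocabulary frozen on the training dataset.
#'
#' @param ids Protein ids to encode; each must have at least one annotation.
#' @param annotations A `go_annotations` tibble.
#' @param vocab A `go_vocabulary` from [build_go_vocabulary()].
#' @return Numeric 0/1 matrix, rows = `ids`, columns named
#'   `go_<identifier>` (":" replaced by "_").
#' @export
encode_go <- function(ids, annotations, vocab) {
  sets <- go_term_sets(annotations)
  missing_ids <- setdiff(ids, names(sets))
  if (length(missing_ids) > 0) {
    stop("unannotated protein(s) must be filtered before encoding: ",
         paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
  }
  vterms <- as.character(vocab)
  unseen <- setdiff(unique(unlist(sets[ids], use.names = FALSE)), vterms)
  if (length(unseen) > 0) {
    message(length(unseen), " GO term(s) outside the vocabulary ignored")
  }
  m <- matrix(0, nrow = length(ids), ncol = length(vterms),
              dimnames = list(ids, paste0("go_", sub(":", "_", vterms))))
  for (i in seq_along(ids)) {
    m[i, vterms %in% sets[[ids[[i]]]]] <- 1
  }
  m
}
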