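# PSI-BLAST ASCII PSSM input, sigmoid normalization.

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the ASCII profile dialect written by PSI-BLAST (the `-Q` output):
#' three header lines, one row per residue position starting with the position
#' index and the query residue, followed by 20 integer log-odds columns (a
#' second block of 20 percentage columns, if present, is ignored), and footer
#' lines after the body.
#'
#' @param path Path to a PSSM file.
#' @return An object of class `pssm`: a list with `protein_id` (file stem),
#'   `scores` (L x 20 integer matrix, columns in [aa_alphabet()] order),
#'   `residues` (length-L character vector of query residues) and `L`.
#' @export
#' @examples
#' p <- tempfile(fileext = ".pssm")
#' write_pssm(new_pssm(matrix(0L, 3, 20), residues = c("A", "R", "N")), p)
#' m <- read_pssm(p)
#' m$L
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop("PSSM file too short: ", path, call. = FALSE)
  body <- lines[-(1:3)]
  row_re <- "^\\s*[0-9]+\\s+[A-Za-z]"
  scores <- list()
  residues <- character()
  for (i in seq_along(body)) {
    ln <- body[[i]]
    if (!nzchar(trimws(ln))) break  # blank line ends the body
    if (!grepl(row_re, ln)) break   # footer (lambda/K lines etc.)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 22) {
      stop("malformed PSSM row at line ", i + 3, " of ", path,
           ": expected position, residue and >= 20 score columns", call. = FALSE)
    }
    vals <- suppressWarnings(as.integer(tok[3:22]))
    if (anyNA(vals)) {
      stop("malformed PSSM row at line ", i + 3, " of ", path,
           ": non-integer score column", call. = FALSE)
    }
    residues[[length(residues) + 1L]] <- toupper(tok[[2]])
    scores[[length(scores) + 1L]] <- vals
  }
  if (length(scores) == 0) {
    stop("no PSSM body rows found in ", path, call. = FALSE)
  }
  m <- do.call(rbind, scores)
  new_pssm(m, residues = residues,
           protein_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a PSSM object
#'
#' @param scores L x 20 integer matrix of log-odds scores, columns in
#'   [aa_alphabet()] order.
#' @param residues Optional length-L character vector of query residues.
#' @param protein_id Protein identifier.
#' @return An object of class `pssm`.
#' @export
new_pssm <- function(scores, residues = NULL, protein_id = "protein") {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20) stop("PSSM must have exactly 20 columns", call. = FALSE)
  if (nrow(scores) < 1) stop("PSSM must have at least one row", call. = FALSE)
  storage.mode(scores) <- "integer"
  colnames(scores) <- aa_alphabet()
  if (is.null(residues)) residues <- rep("X", nrow(scores))
  if (length(residues) != nrow(scores)) {
    stop("`residues` length must equal nrow(scores)", call. = FALSE)
  }
  structure(list(protein_id = protein_id, scores = scores,
                 residues = as.character(residues), L = nrow(scores)),
            class = "pssm")
}

#' Write a PSSM object in the PSI-BLAST ASCII dialect
#'
#' Emits a file that [read_pssm()] parses back bit-identically (three header
#' lines, position/residue/20-score rows, a footer). Used by the synthetic
#' data generator.
#'
#' @param pssm A `pssm` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "pssm"))
  hdr <- c("",
           "Last position-specific scoring matrix computed, weighted, and scaled",
           paste0("           ", paste(sprintf("%3s", aa_alphabet()), collapse = " ")))
  rows <- vapply(seq_len(pssm$L), function(i) {
    paste0(sprintf("%5d %s  ", i, pssm$residues[[i]]),
           paste(sprintf("%3d", pssm$scores[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(hdr, rows, "", "                      K         Lambda"), path)
  invisible(path)
}

#' @export
print.pssm <- function(x, ...) {
  cat("<pssm> ", x$protein_id, ": ", x$L, " positions x 20 residues\n", sep = "")
  invisible(x)
}

#' Sigmoid normalization of a PSSM
#'
#' Maps every integer log-odds score x to 1 / (1 + exp(-x)), so all entries
#' lie strictly in (0, 1) while preserving shape and monotone order.
#'
#' @param pssm A `pssm` object (or a bare numeric matrix).
#' @return For a `pssm`, an object of class `normalized_pssm` (list with
#'   `protein_id`, `values`, `L`); for a matrix, the normalized matrix.
#' @export
#' @examples
#' sigmoid_normalize(new_pssm(matrix(0L, 2, 20)))$values[1, 1]  # 0.5
sigmoid_normalize <- function(pssm) {
  if (is.matrix(pssm)) return(1 / (1 + exp(-pssm)))
  stopifnot(inherits(pssm, "pssm"))
  v <- 1 / (1 + exp(-pssm$scores))
  structure(list(protein_id = pssm$protein_id, values = v, L = pssm$L),
            class = "normalized_pssm")
}
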