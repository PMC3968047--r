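write_tsv_ann <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  writeLines(rows, path)
  path
}

test_that("duplicate TSV annotation rows collapse to one", {
  ann <- read_go_annotations(write_tsv_ann(c("P1\tGO:0000001", "P1\tGO:0000001")))
  expect_equal(nrow(ann), 1)
  expect_equal(ann$protein_id, "P1")
})

test_that("GAF comment lines are ignored and columns 2/5 are used", {
  gaf_row <- function(prot, term, qual = "") {
    paste(c("UniProtKB", prot, "SYMB", qual, term, "REF", "IEA", "", "F",
            "name", "syn", "protein", "taxon:9606", "20260101", "DB", "", ""),
          collapse = "\t")
  }
  path <- write_tsv_ann(c("!gaf-version: 2.1", "! comment",
                          gaf_row("P1", "GO:0000007"),
                          gaf_row("P2", "GO:0000002", "NOT")))
  ann <- read_go_annotations(path)
  expect_setequal(ann$protein_id, c("P1", "P2"))
  ann2 <- read_go_annotations(path, drop_not = TRUE)
  expect_equal(ann2$protein_id, "P1")
  expect_equal(attr(ann2, "report")$n_dropped_not, 1L)
})

test_that("empty annotation file gives an empty map with a zero-record report", {
  ann <- read_go_annotations(write_tsv_ann(character()))
  expect_equal(nrow(ann), 0)
  expect_equal(attr(ann, "report")$n_records, 0L)
})

test_that("invalid GO identifiers are skipped with a warning and counted", {
  path <- write_tsv_ann(c("P1\tGO:0000001", "P2\tGO:1", "P3\tnotago"))
  expect_warning(ann <- read_go_annotations(path), "invalid GO")
  expect_equal(ann$protein_id, "P1")
  expect_equal(attr(ann, "report")$n_skipped_invalid, 2L)
})

test_that("filter_unannotated splits ids by annotation status", {
  ann <- read_go_annotations(write_tsv_ann(
    c("P1\tGO:0000001", "P2\tGO:0000002", "P4\tGO:0000001")))
  flt <- filter_unannotated(c("P1", "P2", "P3", "P4", "P5"), ann)
  expect_equal(flt$kept, c("P1", "P2", "P4"))
  expect_equal(flt$dropped, c("P3", "P5"))
  expect_equal(flt$n_dropped, 2L)
  all_ann <- filter_unannotated(c("P1", "P2"), ann)
  expect_length(all_ann$dropped, 0)
})

test_that("vocabulary is the sorted union, idempotent and row-order independent", {
  rows <- c("PA\tGO:0000002", "PB\tGO:0000001", "PB\tGO:0000002")
  v1 <- build_go_vocabulary(read_go_annotations(write_tsv_ann(rows)))
  v2 <- build_go_vocabulary(read_go_annotations(write_tsv_ann(rev(rows))))
  expect_identical(as.character(v1), c("GO:0000001", "GO:0000002"))
  expect_identical(v1, v2)
  expect_identical(build_go_vocabulary(read_go_annotations(write_tsv_ann(rows)),
                                       ids = c("PA", "PB")), v1)
  single <- build_go_vocabulary(
    read_go_annotations(write_tsv_ann(c("PX\tGO:0000009", "PX\tGO:0000004"))))
  expect_length(single, 2)
  expect_error(build_go_vocabulary(
    read_go_annotations(write_tsv_ann(character()))), "empty")
})

test_that("binary encoding places ones at vocabulary positions", {
  ann <- read_go_annotations(write_tsv_ann(
    c("P1\tGO:0000001", "P2\tGO:0000001", "P2\tGO:0000002", "P2\tGO:0000003")))
  vocab <- build_go_vocabulary(ann)
  m <- encode_go(c("P1", "P2"), ann, vocab)
  expect_equal(unname(m["P1", ]), c(1, 0, 0))
  expect_equal(unname(m["P2", ]), c(1, 1, 1))
  expect_identical(colnames(m),
                   paste0("go_GO_000000", 1:3))
  expect_error(encode_go("P9", ann, vocab), "unannotated")
})

test_that("terms outside a frozen vocabulary are ignored", {
  ann <- read_go_annotations(write_tsv_ann(
    c("P1\tGO:0000001", "P1\tGO:0000005")))
  vocab <- structure("GO:0000001", class = "go_vocabulary")
  expect_message(m <- encode_go("P1", ann, vocab), "outside the vocabulary")
  expect_equal(unname(m["P1", ]), 1)
})

test_that("vocabulary round-trips through its one-term-per-line file", {
  v <- structure(c("GO:0000001", "GO:0000042"), class = "go_vocabulary")
  path <- tempfile()
  write_go_vocabulary(v, path)
  expect_identical(read_go_vocabulary(path), v)
})

test_that("generator ground truth matches filtering and vocabulary size", {
  spec <- synthetic_spec(n_per_class = c(5, 5, 5, 5), n_go_terms = 30,
                         unannotated_fraction = 0.1, seed = 31)
  d <- generate_synthetic_dataset(spec)
  flt <- filter_unannotated(d$manifest$protein_id, d$annotations)
  expect_setequal(flt$dropped, d$ground_truth$unannotated)
  expect_equal(flt$n_dropped, floor(0.1 * 20))
  vocab <- build_go_vocabulary(d$annotations, flt$kept)
  expect_length(vocab, d$ground_truth$n_distinct_terms)
  # per-protein encoded sum equals the planted annotation count
  m <- encode_go(flt$kept, d$annotations, vocab)
  for (id in flt$kept) {
    expect_equal(unname(rowSums(m)[[id]]),
                 unname(d$ground_truth$annotation_counts[[id]]))
  }
})
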