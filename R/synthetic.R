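# Seeded synthetic datasets emulating the full input stack: random amino-acid
# sequences, PSI-BLAST-style PSSM files whose per-column positional
# autocorrelation depends on the structural class (what the LPC block
# measures), and GO annotations with class-enriched marker terms (what the
# binary block measures). Ground truth is recorded so recovery is testable.

#' Specification of a synthetic dataset
#'
#' Class signal is planted in two places: designated PSSM columns follow an
#' AR(1) process with a class-specific autocorrelation coefficient, and each
#' class has a marker GO term carried by an `go_enrichment` fraction of its
#' proteins. The remaining PSSM columns are white noise and the remaining GO
#' terms are class-independent background.
#'
#' @param n_per_class Integer(4): proteins per class (default 25 each).
#' @param seq_length Integer(2): min/max sequence length (default 120..200).
#' @param ar_coef Numeric(4): per-class AR(1) coefficient of the designated
#'   PSSM columns, |coef| < 1 (default 0.8, -0.8, 0.4, 0.0).
#' @param n_signal_columns How many of the 20 PSSM columns carry the AR
#'   signal (default 6).
#' @param score_sd Innovation standard deviation of the PSSM score process
#'   (default 3).
#' @param n_go_terms Size of the GO term pool, including the 4 class markers
#'   (default 40).
#' @param go_enrichment Probability that a protein carries its class marker
#'   term (default 0.9).
#' @param background_terms Mean number of background terms per protein
#'   (default 2).
#' @param unannotated_fraction Fraction of proteins left without any GO
#'   annotation (default 0).
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(25, 25, 25, 25),
                           seq_length = c(120, 200),
                           ar_coef = c(0.8, -0.8, 0.4, 0.0),
                           n_signal_columns = 6,
                           score_sd = 3,
                           n_go_terms = 40,
                           go_enrichment = 0.9,
                           background_terms = 2,
                           unannotated_fraction = 0,
                           seed = 1) {
  stopifnot(length(n_per_class) == 4, all(n_per_class >= 1),
            length(seq_length) == 2, seq_length[1] >= 12,
            seq_length[1] <= seq_length[2],
            length(ar_coef) == 4, all(abs(ar_coef) < 1),
            n_signal_columns >= 1, n_signal_columns <= 20,
            n_go_terms >= 5,
            go_enrichment >= 0, go_enrichment <= 1,
            unannotated_fraction >= 0, unannotated_fraction < 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 seq_length = as.integer(seq_length),
                 ar_coef = ar_coef,
                 n_signal_columns = as.integer(n_signal_columns),
                 score_sd = score_sd,
                 n_go_terms = as.integer(n_go_terms),
                 go_enrichment = go_enrichment,
                 background_terms = background_terms,
                 unannotated_fraction = unannotated_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

go_term_id <- function(i) sprintf("GO:%07d", i)

#' Simulate one class-conditioned PSSM
#'
#' The first `n_signal_columns` score columns follow a rounded AR(1) process
#' x_t = coef * x_(t-1) + e_t (e ~ N(0, score_sd)); the rest are rounded
#' white noise. Scores are clamped to \[-15, 15\], the usual log-odds range.
#'
#' @param residues Character vector of query residues (defines L).
#' @param ar_coef AR(1) coefficient, |coef| < 1.
#' @param n_signal_columns Columns carrying the AR signal.
#' @param score_sd Innovation standard deviation.
#' @param protein_id Identifier for the resulting object.
#' @return A `pssm` object (valid input for [write_pssm()] / [read_pssm()]).
#' @export
make_pssm <- function(residues, ar_coef, n_signal_columns = 6, score_sd = 3,
                      protein_id = "synthetic") {
  stopifnot(abs(ar_coef) < 1)
  L <- length(residues)
  scores <- matrix(0L, L, 20)
  for (j in seq_len(20)) {
    e <- stats::rnorm(L, sd = score_sd)
    x <- if (j <= n_signal_columns) {
      # stationary start, then the AR(1) recursion
      x0 <- numeric(L)
      x0[1] <- stats::rnorm(1, sd = score_sd / sqrt(1 - ar_coef^2))
      for (t in seq_len(L - 1)) x0[t + 1] <- ar_coef * x0[t] + e[t + 1]
      x0
    } else {
      e
    }
    scores[, j] <- pmax(pmin(round(x), 15L), -15L)
  }
  new_pssm(scores, residues = residues, protein_id = protein_id)
}

#' Generate a synthetic dataset
#'
#' Draws sequences, PSSMs, GO annotations and a class manifest from a
#' [synthetic_spec()]. With `dir` given, writes `sequences.fasta`,
#' `pssm/<id>.pssm`, `annotations.tsv` (two-column, headerless),
#' `manifest.tsv` and `ground_truth.json`; the same seed always produces
#' byte-identical files. The in-memory objects are returned either way.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (created if missing).
#' @return List with `manifest` (tibble), `sequences` (named character),
#'   `pssms` (named list of `pssm`), `annotations` (`go_annotations` tibble),
#'   and `ground_truth` (class labels, marker terms, planted feature names,
#'   per-protein annotation counts, unannotated ids, distinct term count).
#' @export
generate_synthetic_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    classes <- structural_classes()
    labels <- rep(classes, times = spec$n_per_class)
    n <- length(labels)
    ids <- sprintf("SYN%04d", seq_len(n))
    aa <- aa_alphabet()

    lens <- sample(seq(spec$seq_length[1], spec$seq_length[2]), n, replace = TRUE)
    sequences <- vapply(lens, function(L) {
      paste(sample(aa, L, replace = TRUE), collapse = "")
    }, character(1))
    names(sequences) <- ids

    pssms <- lapply(seq_len(n), function(i) {
      make_pssm(strsplit(sequences[[i]], "")[[1]],
                ar_coef = spec$ar_coef[[match(labels[[i]], classes)]],
                n_signal_columns = spec$n_signal_columns,
                score_sd = spec$score_sd,
                protein_id = ids[[i]])
    })
    names(pssms) <- ids

    # GO: terms 1..4 are the class markers, the rest background
    marker <- go_term_id(1:4)
    names(marker) <- classes
    background <- if (spec$n_go_terms > 4) go_term_id(5:spec$n_go_terms) else character()
    n_unann <- floor(spec$unannotated_fraction * n)
    unannotated <- if (n_unann > 0) sample(ids, n_unann) else character()
    ann_rows <- purrr::map_dfr(seq_len(n), function(i) {
      if (ids[[i]] %in% unannotated) return(NULL)
      terms <- character()
      if (stats::runif(1) < spec$go_enrichment) {
        terms <- marker[[labels[[i]]]]
      }
      n_bg <- min(stats::rpois(1, spec$background_terms), length(background))
      if (n_bg > 0) terms <- c(terms, sample(background, n_bg))
      if (length(terms) == 0) terms <- sample(background, 1)
      tibble::tibble(protein_id = ids[[i]], go_id = sort(unique(terms)))
    })
    class(ann_rows) <- c("go_annotations", class(ann_rows))

    manifest <- tibble::tibble(protein_id = ids, class = as_class_factor(labels))
    ground_truth <- list(
      classes = stats::setNames(labels, ids),
      marker_terms = as.list(marker),
      planted_features = unname(paste0("go_", sub(":", "_", marker))),
      signal_residues = aa[seq_len(spec$n_signal_columns)],
      annotation_counts = as.list(table(ann_rows$protein_id)),
      unannotated = unannotated,
      n_distinct_terms = length(unique(ann_rows$go_id)),
      seed = spec$seed
    )

    if (!is.null(dir)) {
      dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
      ss <- Biostrings::AAStringSet(sequences)
      Biostrings::writeXStringSet(ss, file.path(dir, "sequences.fasta"))
      for (id in ids) write_pssm(pssms[[id]], file.path(dir, "pssm", paste0(id, ".pssm")))
      utils::write.table(as.data.frame(ann_rows)[, c("protein_id", "go_id")],
                         file.path(dir, "annotations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
      utils::write.table(as.data.frame(manifest), file.path(dir, "manifest.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
    }

    list(manifest = manifest, sequences = sequences, pssms = pssms,
         annotations = ann_rows, ground_truth = ground_truth)
  })
}

#' Names of the features a synthetic dataset plants as informative
#'
#' The class signal is carried by (a) the four GO marker features and (b) the
#' lag-1 LPC predictor coefficient of every designated AR(1) PSSM column —
#' the coefficient that estimates the planted positional autocorrelation —
#' at every extracted order.
#'
#' @param ground_truth The `ground_truth` element returned by
#'   [generate_synthetic_dataset()].
#' @param lpc_orders The LPC orders used at feature extraction.
#' @return Character vector of feature names.
#' @export
planted_feature_names <- function(ground_truth, lpc_orders = lpc_config()) {
  lpc_feats <- as.vector(outer(
    unlist(ground_truth$signal_residues), as.integer(lpc_orders),
    function(r, p) paste0("pssm_", r, "_p", p, "_a1")))
  c(unlist(ground_truth$planted_features), lpc_feats)
}

#' Simulate a jointly-informative feature pair
#'
#' Builds a two-class dataset where the class signal lives in the difference
#' of two features: `joint_1 = z + u` and `joint_2 = u`, with z = +/- delta by
#' class and u a shared noise component much larger than delta. Each feature
#' is therefore nearly uninformative on its own (tiny univariate F-score),
#' but the pair jointly separates the classes and a linear SVM recovers the
#' weight pattern (1, -1). Remaining features are independent N(0, 1) noise.
#'
#' @param n Total samples (split evenly over two classes).
#' @param n_noise Number of pure-noise features.
#' @param delta Class half-separation of the latent signal z.
#' @param shared_sd Standard deviation of the shared noise u.
#' @param seed Integer seed.
#' @return Feature tibble (`protein_id`, `class`, `joint_1`, `joint_2`,
#'   `noise_*`).
#' @export
simulate_joint_signal <- function(n = 80, n_noise = 18, delta = 1.5,
                                  shared_sd = 3, seed = 1) {
  stopifnot(n %% 2 == 0)
  withr::with_seed(seed, {
    cls <- rep(structural_classes()[1:2], each = n / 2)
    z <- ifelse(cls == structural_classes()[1], delta, -delta)
    u <- stats::rnorm(n, sd = shared_sd)
    noise <- matrix(stats::rnorm(n * n_noise), n, n_noise,
                    dimnames = list(NULL, paste0("noise_", seq_len(n_noise))))
    dplyr::bind_cols(
      tibble::tibble(protein_id = sprintf("S%03d", seq_len(n)),
                     class = as_class_factor(cls),
                     joint_1 = z + u, joint_2 = u),
      tibble::as_tibble(noise)
    )
  })
}
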