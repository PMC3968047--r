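# Amino-acid alphabet, numeric property scales, CTD partitions and derived
# physicochemical distance matrices. All descriptor groups draw on these
# tables; they ship as code so the feature definitions are fully reproducible.

#' The 20-letter amino-acid alphabet
#'
#' One-letter codes in the fixed order used for all residue-indexed feature
#' blocks (PSSM columns, AAC, QSO residue terms).
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Numeric amino-acid property scales
#'
#' Seven classical per-residue scales used by the autocorrelation descriptors
#' and to derive the package's physicochemical distance matrices:
#' Kyte-Doolittle hydropathy, Hopp-Woods hydrophilicity, normalized van der
#' Waals volume, Grantham polarity, polarizability, isoelectric point and
#' residue mass. Scales are standardized (zero mean, unit population variance
#' over the 20 residues) before use in autocorrelation descriptors.
#'
#' @return A tibble with column `residue` plus one column per scale.
#' @export
aa_property_scales <- function() {
  aa <- aa_alphabet()
  tibble::tibble(
    residue = aa,
    hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    hydrophilicity = c(-0.5, 3.0, 0.2, 3.0, -1.0, 0.2, 3.0, 0.0, -0.5, -1.8,
                       -1.8, 3.0, -1.3, -2.5, 0.0, 0.3, -0.4, -3.4, -2.3, -1.5),
    vdw_volume = c(1.00, 6.13, 2.95, 2.78, 2.43, 3.95, 3.78, 0.00, 4.66, 4.00,
                   4.00, 4.77, 4.43, 5.89, 2.72, 1.60, 2.60, 8.08, 6.47, 3.00),
    polarity = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
                 4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    polarizability = c(0.046, 0.291, 0.134, 0.105, 0.128, 0.180, 0.151, 0.000,
                       0.230, 0.186, 0.186, 0.219, 0.221, 0.290, 0.131, 0.062,
                       0.108, 0.409, 0.298, 0.140),
    isoelectric_point = c(6.00, 10.76, 5.41, 2.77, 5.07, 5.65, 3.22, 5.97,
                          7.59, 6.02, 5.98, 9.74, 5.74, 5.48, 6.30, 5.68,
                          5.60, 5.89, 5.66, 5.96),
    residue_mass = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12,
                     57.05, 137.14, 113.16, 113.16, 128.17, 131.19, 147.18,
                     97.12, 87.08, 101.10, 186.21, 163.18, 99.13)
  )
}

# property scales as a named-matrix (rows = scales, cols = residues)
aa_scale_matrix <- function() {
  tab <- aa_property_scales()
  m <- t(as.matrix(tab[, -1]))
  colnames(m) <- tab$residue
  m
}

# standardize one scale to zero mean / unit population variance over 20 residues
standardize_scale <- function(p) {
  mu <- mean(p)
  sigma <- sqrt(mean((p - mu)^2))
  (p - mu) / sigma
}

#' Three-group physicochemical partitions for CTD descriptors
#'
#' The seven classical attribute partitions (hydrophobicity, normalized van
#' der Waals volume, polarity, polarizability, charge, secondary-structure
#' propensity, solvent accessibility), each splitting the 20 residues into
#' three groups.
#'
#' @return Named list; each element is a list of three character vectors
#'   (`g1`, `g2`, `g3`) that together cover the alphabet.
#' @export
ctd_partitions <- function() {
  split3 <- function(g1, g2, g3) {
    list(g1 = strsplit(g1, "")[[1]],
         g2 = strsplit(g2, "")[[1]],
         g3 = strsplit(g3, "")[[1]])
  }
  list(
    hydrophobicity   = split3("RKEDQN",   "GASTPHY",          "CLVIMFW"),
    vdw_volume       = split3("GASTPDC",  "NVEQIL",           "MHKFRYW"),
    polarity         = split3("LIFWCMVY", "PATGS",            "HQRKNED"),
    polarizability   = split3("GASDT",    "CPNVEQIL",         "KMHFRYW"),
    charge           = split3("KR",       "ANCQGHILMFPSTWYV", "DE"),
    secondary_struct = split3("EALMQKRH", "VIYCWFT",          "GNPSD"),
    solvent_access   = split3("ALFCGIVW", "RKQEND",           "MPSTHY")
  )
}

#' Physicochemical inter-residue distance matrices
#'
#' Two 20x20 symmetric distance matrices with zero diagonal, derived from the
#' packaged property scales and used by the sequence-order descriptors (SOCN,
#' QSO). `"physicochemical"` is the Euclidean distance in the full
#' standardized 7-scale space; `"polarity_volume"` uses only the polarity,
#' van der Waals volume and polarizability scales. Both are scaled to a
#' maximum entry of 1. These are package-computed matrices (documented,
#' deterministic), not reproductions of any published distance table.
#'
#' @return Named list of two 20x20 numeric matrices with residue dimnames.
#' @export
aa_distance_matrices <- function() {
  m <- aa_scale_matrix()
  zs <- t(apply(m, 1, standardize_scale))
  dist_from <- function(rows) {
    d <- as.matrix(stats::dist(t(zs[rows, , drop = FALSE])))
    d / max(d)
  }
  list(
    physicochemical = dist_from(rownames(zs)),
    polarity_volume = dist_from(c("polarity", "vdw_volume", "polarizability"))
  )
}

# validate / repair a sequence string -> character vector of residues.
# nonstandard: "error" (default) or "replace" with a documented map
# (B->D, Z->E, J->L, U->C, O->K, X->A).
check_sequence <- function(seq, nonstandard = c("error", "replace")) {
  nonstandard <- match.arg(nonstandard)
  if (length(seq) != 1 || !is.character(seq)) {
    stop("`seq` must be a single character string", call. = FALSE)
  }
  res <- strsplit(toupper(seq), "")[[1]]
  bad <- !(res %in% aa_alphabet())
  if (any(bad)) {
    if (nonstandard == "error") {
      stop("non-standard residue(s) in sequence: ",
           paste(unique(res[bad]), collapse = ", "),
           " (set nonstandard = \"replace\" to substitute)", call. = FALSE)
    }
    map <- c(B = "D", Z = "E", J = "L", U = "C", O = "K", X = "A")
    unknown <- setdiff(unique(res[bad]), names(map))
    if (length(unknown) > 0) {
      stop("cannot substitute residue(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    res[bad] <- map[res[bad]]
  }
  res
}
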