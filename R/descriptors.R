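# PROFEAT-style structural and physicochemical sequence descriptors:
# amino-acid / dipeptide composition, autocorrelation families
# (normalized Moreau-Broto, Moran, Geary), composition/transition/distribution
# (CTD), sequence-order-coupling numbers (SOCN) and quasi-sequence-order (QSO).

#' Amino-acid composition
#'
#' @param seq Character string over the 20-letter alphabet.
#' @param nonstandard How to treat non-standard residues; see [check_sequence()]
#'   conventions ("error" or "replace").
#' @return Named numeric vector of 20 relative frequencies (sums to 1).
#' @export
#' @examples
#' aac("AAAA")[["aac_A"]]
aac <- function(seq, nonstandard = "error") {
  res <- check_sequence(seq, nonstandard)
  f <- table(factor(res, levels = aa_alphabet())) / length(res)
  v <- as.numeric(f)
  names(v) <- paste0("aac_", aa_alphabet())
  v
}

#' Dipeptide composition
#'
#' Relative frequencies of the 400 ordered residue pairs; denominator L - 1.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 400 (sums to 1).
#' @export
dpc <- function(seq, nonstandard = "error") {
  res <- check_sequence(seq, nonstandard)
  L <- length(res)
  if (L < 2) stop("dipeptide composition needs length >= 2", call. = FALSE)
  aa <- aa_alphabet()
  pairs <- paste0(res[-L], res[-1])
  lv <- as.vector(t(outer(aa, aa, paste0)))  # AA, AR, AN, ... residue-major
  f <- table(factor(pairs, levels = lv)) / (L - 1)
  v <- as.numeric(f)
  names(v) <- paste0("dpc_", lv)
  v
}

#' Composition/transition/distribution (CTD) descriptors
#'
#' For each three-group physicochemical partition: 3 composition values
#' (group fractions), 3 transition values (adjacent cross-group pair counts
#' over L - 1, for unordered pairs 1-2, 1-3, 2-3), and 15 distribution values
#' (per group, the sequence positions of its first, 25%, 50%, 75% and last
#' residue, as a percentage of L; 0 for an absent group). The k-th quantile
#' occurrence for fraction f is `max(1, ceiling(f * n))` among the group's n
#' occurrences.
#'
#' @inheritParams aac
#' @param partitions Named list of 3-group partitions; default
#'   [ctd_partitions()].
#' @return Named numeric vector of length `21 * length(partitions)`.
#' @export
ctd <- function(seq, partitions = ctd_partitions(), nonstandard = "error") {
  res <- check_sequence(seq, nonstandard)
  L <- length(res)
  if (L < 2) stop("CTD needs length >= 2", call. = FALSE)
  out <- lapply(names(partitions), function(pn) {
    part <- partitions[[pn]]
    if (length(part) != 3 ||
        !setequal(unlist(part), aa_alphabet())) {
      stop("partition '", pn, "' must split the 20 residues into 3 groups",
           call. = FALSE)
    }
    grp <- integer(L)
    for (g in 1:3) grp[res %in% part[[g]]] <- g
    comp <- tabulate(grp, 3) / L
    names(comp) <- paste0("ctd_", pn, "_c", 1:3)
    # transitions between unordered group pairs among adjacent residues
    a <- grp[-L]; b <- grp[-1]
    tr <- c(sum((a == 1 & b == 2) | (a == 2 & b == 1)),
            sum((a == 1 & b == 3) | (a == 3 & b == 1)),
            sum((a == 2 & b == 3) | (a == 3 & b == 2))) / (L - 1)
    names(tr) <- paste0("ctd_", pn, "_t", c("12", "13", "23"))
    dist_v <- unlist(lapply(1:3, function(g) {
      pos <- which(grp == g)
      n <- length(pos)
      if (n == 0) {
        q <- rep(0, 5)
      } else {
        ranks <- pmax(1, ceiling(c(0, 0.25, 0.5, 0.75, 1) * n))
        q <- 100 * pos[ranks] / L
      }
      names(q) <- paste0("ctd_", pn, "_d", g, "_", c("first", "p25", "p50", "p75", "last"))
      q
    }))
    c(comp, tr, dist_v)
  })
  unlist(out)
}

#' Sequence autocorrelation descriptors
#'
#' Autocorrelation of a numeric residue property along the sequence, for lags
#' d = 1..maxlag. The property scale is standardized to zero mean and unit
#' population variance over the 20 residues before encoding. Conventions:
#' * normalized Moreau-Broto: `AC(d) = sum_i p_i p_(i+d) / (L - d)`
#' * Moran: centered lag-covariance over sequence variance
#'   `I(d) = [sum_i (p_i - pbar)(p_(i+d) - pbar) / (L - d)] / [sum_i (p_i - pbar)^2 / L]`
#' * Geary: `C(d) = [sum_i (p_i - p_(i+d))^2 / (2(L - d))] / [sum_i (p_i - pbar)^2 / (L - 1)]`
#'
#' Moran and Geary return 0 for a zero-variance encoded sequence (e.g. a
#' homopolymer).
#'
#' @inheritParams aac
#' @param type One of `"moreau_broto"`, `"moran"`, `"geary"`.
#' @param property Either the name of a packaged scale (see
#'   [aa_property_scales()]) or a named numeric vector over the 20 residues.
#' @param maxlag Largest lag; requires `L > maxlag`.
#' @return Named numeric vector of length `maxlag`.
#' @export
autocorrelation <- function(seq, type = c("moreau_broto", "moran", "geary"),
                            property = "hydropathy", maxlag = 21,
                            nonstandard = "error") {
  type <- match.arg(type)
  res <- check_sequence(seq, nonstandard)
  L <- length(res)
  if (L <= maxlag) {
    stop("sequence length ", L, " must exceed maxlag ", maxlag, call. = FALSE)
  }
  if (is.character(property)) {
    tab <- aa_property_scales()
    if (!property %in% names(tab)[-1]) {
      stop("unknown property scale: ", property, call. = FALSE)
    }
    pv <- stats::setNames(tab[[property]], tab$residue)
    pname <- property
  } else {
    pv <- property[aa_alphabet()]
    if (anyNA(pv)) stop("`property` must name all 20 residues", call. = FALSE)
    pname <- "custom"
  }
  p <- standardize_scale(as.numeric(pv[aa_alphabet()]))[match(res, aa_alphabet())]
  pbar <- mean(p)
  v <- vapply(seq_len(maxlag), function(d) {
    head_ <- p[seq_len(L - d)]
    tail_ <- p[seq_len(L - d) + d]
    switch(type,
      moreau_broto = sum(head_ * tail_) / (L - d),
      moran = {
        denom <- sum((p - pbar)^2) / L
        if (denom <= 0) 0 else (sum((head_ - pbar) * (tail_ - pbar)) / (L - d)) / denom
      },
      geary = {
        denom <- sum((p - pbar)^2) / (L - 1)
        if (denom <= 0) 0 else (sum((head_ - tail_)^2) / (2 * (L - d))) / denom
      })
  }, numeric(1))
  names(v) <- paste0("ac_", abbreviate_type(type), "_", pname, "_d", seq_len(maxlag))
  v
}

abbreviate_type <- function(type) {
  c(moreau_broto = "mb", moran = "moran", geary = "geary")[[type]]
}

#' Sequence-order-coupling numbers
#'
#' `tau_d = sum_i dist(s_i, s_(i+d))^2` for d = 1..maxlag, per distance matrix.
#'
#' @inheritParams aac
#' @param maxlag Largest coupling lag; requires `L > maxlag`.
#' @param matrices Named list of 20x20 distance matrices; default
#'   [aa_distance_matrices()].
#' @return Named numeric vector of length `maxlag * length(matrices)`.
#' @export
socn <- function(seq, maxlag = 8, matrices = aa_distance_matrices(),
                 nonstandard = "error") {
  res <- check_sequence(seq, nonstandard)
  L <- length(res)
  if (L <= maxlag) {
    stop("sequence length ", L, " must exceed maxlag ", maxlag, call. = FALSE)
  }
  unlist(lapply(names(matrices), function(mn) {
    dm <- matrices[[mn]]
    tau <- vapply(seq_len(maxlag), function(d) {
      i <- seq_len(L - d)
      sum(dm[cbind(res[i], res[i + d])]^2)
    }, numeric(1))
    stats::setNames(tau, paste0("socn_", mn, "_d", seq_len(maxlag)))
  }))
}

#' Quasi-sequence-order descriptors
#'
#' Per distance matrix: 20 residue terms `f_r / (sum f + w * sum tau)` followed
#' by `maxlag` order terms `w * tau_d / (sum f + w * sum tau)`, where `f_r` are
#' residue counts and `tau_d` the coupling numbers of [socn()]. Each matrix's
#' 20 + maxlag values sum to 1.
#'
#' @inheritParams socn
#' @param w Weight of the sequence-order terms (default 0.1).
#' @return Named numeric vector of length `(20 + maxlag) * length(matrices)`.
#' @export
qso <- function(seq, maxlag = 8, w = 0.1, matrices = aa_distance_matrices(),
                nonstandard = "error") {
  res <- check_sequence(seq, nonstandard)
  L <- length(res)
  if (L <= maxlag) {
    stop("sequence length ", L, " must exceed maxlag ", maxlag, call. = FALSE)
  }
  f <- as.numeric(table(factor(res, levels = aa_alphabet())))
  unlist(lapply(names(matrices), function(mn) {
    dm <- matrices[[mn]]
    tau <- vapply(seq_len(maxlag), function(d) {
      i <- seq_len(L - d)
      sum(dm[cbind(res[i], res[i + d])]^2)
    }, numeric(1))
    denom <- sum(f) + w * sum(tau)
    stats::setNames(c(f / denom, w * tau / denom),
                    c(paste0("qso_", mn, "_f_", aa_alphabet()),
                      paste0("qso_", mn, "_t", seq_len(maxlag))))
  }))
}

#' Descriptor preset
#'
#' Declares which descriptor groups are enabled and with what parameters; the
#' total dimension is computable in closed form via [preset_dim()]. The
#' shipped default totals 1080 dimensions: aac (20) + dpc (400) +
#' autocorrelation over 3 types x 7 scales x maxlag 21 (441) + CTD over 7
#' partitions (147) + SOCN over 2 matrices x maxlag 8 (16) + QSO over 2
#' matrices x maxlag 8 (56).
#'
#' @param groups Character vector of enabled groups, a subset of
#'   `c("aac", "dpc", "autocorrelation", "ctd", "socn", "qso")`.
#' @param ac_types Autocorrelation types to include.
#' @param ac_properties Property scale names for autocorrelation.
#' @param ac_maxlag Autocorrelation maximum lag.
#' @param ctd_properties Partition names for CTD (subset of
#'   `names(ctd_partitions())`).
#' @param so_maxlag Maximum lag for SOCN and QSO.
#' @param qso_w QSO sequence-order weight.
#' @param matrices Distance matrices for SOCN/QSO.
#' @param nonstandard Non-standard residue policy passed to every group.
#' @return An object of class `descriptor_preset`.
#' @export
descriptor_preset <- function(groups = c("aac", "dpc", "autocorrelation",
                                         "ctd", "socn", "qso"),
                              ac_types = c("moreau_broto", "moran", "geary"),
                              ac_properties = setdiff(names(aa_property_scales()), "residue"),
                              ac_maxlag = 21,
                              ctd_properties = names(ctd_partitions()),
                              so_maxlag = 8,
                              qso_w = 0.1,
                              matrices = aa_distance_matrices(),
                              nonstandard = "error") {
  allowed <- c("aac", "dpc", "autocorrelation", "ctd", "socn", "qso")
  bad <- setdiff(groups, allowed)
  if (length(bad) > 0) stop("unknown descriptor group(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  structure(list(groups = groups,
                 ac_types = match.arg(ac_types,
                                      c("moreau_broto", "moran", "geary"),
                                      several.ok = TRUE),
                 ac_properties = ac_properties,
                 ac_maxlag = as.integer(ac_maxlag),
                 ctd_properties = ctd_properties,
                 so_maxlag = as.integer(so_maxlag),
                 qso_w = qso_w,
                 matrices = matrices,
                 nonstandard = nonstandard),
            class = "descriptor_preset")
}

#' Closed-form dimension of a descriptor preset
#'
#' @param preset A [descriptor_preset()].
#' @return Integer total dimension.
#' @export
#' @examples
#' preset_dim(descriptor_preset())  # 1080
preset_dim <- function(preset = descriptor_preset()) {
  stopifnot(inherits(preset, "descriptor_preset"))
  nmat <- length(preset$matrices)
  d <- 0L
  if ("aac" %in% preset$groups) d <- d + 20L
  if ("dpc" %in% preset$groups) d <- d + 400L
  if ("autocorrelation" %in% preset$groups) {
    d <- d + length(preset$ac_types) * length(preset$ac_properties) * preset$ac_maxlag
  }
  if ("ctd" %in% preset$groups) d <- d + 21L * length(preset$ctd_properties)
  if ("socn" %in% preset$groups) d <- d + nmat * preset$so_maxlag
  if ("qso" %in% preset$groups) d <- d + nmat * (20L + preset$so_maxlag)
  as.integer(d)
}

#' Minimum sequence length admissible for a preset
#'
#' @param preset A [descriptor_preset()].
#' @return Integer; sequences must be strictly longer than every enabled lag
#'   and at least 2 residues.
#' @export
preset_min_length <- function(preset = descriptor_preset()) {
  lags <- 1L
  if ("autocorrelation" %in% preset$groups) lags <- max(lags, preset$ac_maxlag)
  if (any(c("socn", "qso") %in% preset$groups)) lags <- max(lags, preset$so_maxlag)
  lags + 1L
}

#' Full physicochemical descriptor block for one sequence
#'
#' Concatenates the enabled descriptor groups in the fixed order aac, dpc,
#' autocorrelation, ctd, socn, qso. All feature names carry the `profeat_`
#' block prefix. The default preset emits 1080 dimensions.
#'
#' @inheritParams aac
#' @param preset A [descriptor_preset()].
#' @return Named numeric vector of length `preset_dim(preset)`.
#' @export
profeat_block <- function(seq, preset = descriptor_preset()) {
  stopifnot(inherits(preset, "descriptor_preset"))
  ns <- preset$nonstandard
  parts <- list()
  with_group <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("descriptor group '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  if ("aac" %in% preset$groups) {
    parts$aac <- with_group("aac", aac(seq, ns))
  }
  if ("dpc" %in% preset$groups) {
    parts$dpc <- with_group("dpc", dpc(seq, ns))
  }
  if ("autocorrelation" %in% preset$groups) {
    parts$ac <- with_group("autocorrelation", unlist(lapply(preset$ac_types, function(ty) {
      unlist(lapply(preset$ac_properties, function(pr) {
        autocorrelation(seq, ty, pr, preset$ac_maxlag, ns)
      }))
    })))
  }
  if ("ctd" %in% preset$groups) {
    parts$ctd <- with_group("ctd",
      ctd(seq, ctd_partitions()[preset$ctd_properties], ns))
  }
  if ("socn" %in% preset$groups) {
    parts$socn <- with_group("socn",
      socn(seq, preset$so_maxlag, preset$matrices, ns))
  }
  if ("qso" %in% preset$groups) {
    parts$qso <- with_group("qso",
      qso(seq, preset$so_maxlag, preset$qso_w, preset$matrices, ns))
  }
  v <- unlist(parts, use.names = TRUE)
  # unlist() prefixes list names; replace with the block tag
  names(v) <- paste0("profeat_", sub("^[a-z]+\\.", "", names(v)))
  v
}
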