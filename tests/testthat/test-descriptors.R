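test_that("aac and dpc recover direct counts", {
  a <- aac("AAAA")
  expect_equal(unname(a[["aac_A"]]), 1)
  expect_equal(sum(a), 1)
  d <- dpc("ARAR")
  expect_equal(unname(d[["dpc_AR"]]), 2 / 3)
  expect_equal(unname(d[["dpc_RA"]]), 1 / 3)
  expect_equal(sum(d), 1)
})

test_that("simplex-valued groups sum to 1 on random sequences", {
  withr::with_seed(21, {
    for (i in 1:5) {
      s <- random_sequence(sample(30:80, 1))
      expect_equal(sum(aac(s)), 1, tolerance = 1e-12)
      expect_equal(sum(dpc(s)), 1, tolerance = 1e-12)
      q <- qso(s, maxlag = 8)
      for (mn in names(aa_distance_matrices())) {
        expect_equal(sum(q[grep(paste0("qso_", mn, "_"), names(q), fixed = TRUE)]),
                     1, tolerance = 1e-12)
      }
    }
  })
})

test_that("non-standard residues error by default and substitute on request", {
  expect_error(aac("AXRB"), "non-standard")
  expect_equal(unname(aac("AXA", nonstandard = "replace")[["aac_A"]]), 1)
})

test_that("CTD of a single-group homopolymer is degenerate as expected", {
  # poly-R: hydrophobicity group 1 (polar)
  v <- ctd(strrep("R", 10), ctd_partitions()["hydrophobicity"])
  expect_equal(unname(v[["ctd_hydrophobicity_c1"]]), 1)
  expect_equal(unname(v[["ctd_hydrophobicity_c2"]]), 0)
  expect_true(all(v[grep("_t", names(v))] == 0))
  expect_equal(unname(v[["ctd_hydrophobicity_d1_first"]]), 100 * 1 / 10)
  expect_equal(unname(v[["ctd_hydrophobicity_d1_last"]]), 100)
  expect_true(all(v[grep("_d2_|_d3_", names(v))] == 0))
})

test_that("alternating two-group sequence has transition 1-2 = (L-1)/(L-1)", {
  # R (group 1) and G (group 2) under hydrophobicity; every adjacent pair crosses
  s <- paste(rep(c("R", "G"), 5), collapse = "")
  v <- ctd(s, ctd_partitions()["hydrophobicity"])
  expect_equal(unname(v[["ctd_hydrophobicity_t12"]]), 9 / 9)
  expect_equal(unname(v[["ctd_hydrophobicity_t13"]]), 0)
})

test_that("CTD matches an independent index-walk oracle on a random 60-mer", {
  s <- random_sequence(60, seed = 22)
  res <- strsplit(s, "")[[1]]
  parts <- ctd_partitions()
  v <- ctd(s, parts)
  for (pn in names(parts)) {
    grp <- integer(60)
    for (g in 1:3) grp[res %in% parts[[pn]][[g]]] <- g
    # composition by explicit walk
    for (g in 1:3) {
      expect_equal(unname(v[[paste0("ctd_", pn, "_c", g)]]),
                   sum(grp == g) / 60)
    }
    # transitions by explicit walk
    tr <- c("12" = 0, "13" = 0, "23" = 0)
    for (i in 1:59) {
      pair <- sort(c(grp[i], grp[i + 1]))
      if (pair[1] != pair[2]) {
        key <- paste0(pair[1], pair[2])
        tr[key] <- tr[key] + 1
      }
    }
    for (key in names(tr)) {
      expect_equal(unname(v[[paste0("ctd_", pn, "_t", key)]]),
                   unname(tr[[key]]) / 59)
    }
    # distribution by explicit position lookup
    for (g in 1:3) {
      pos <- which(grp == g)
      n <- length(pos)
      expected <- if (n == 0) rep(0, 5) else {
        100 * pos[pmax(1, ceiling(c(0, .25, .5, .75, 1) * n))] / 60
      }
      got <- v[paste0("ctd_", pn, "_d", g, "_",
                      c("first", "p25", "p50", "p75", "last"))]
      expect_equal(unname(got), expected)
    }
  }
})

test_that("Moran autocorrelation is 0 for a homopolymer", {
  expect_true(all(autocorrelation(strrep("A", 30), "moran", maxlag = 5) == 0))
  expect_true(all(autocorrelation(strrep("A", 30), "geary", maxlag = 5) == 0))
})

test_that("Moreau-Broto of a homopolymer is the squared standardized value", {
  tab <- aa_property_scales()
  z <- standardize_scale(tab$hydropathy)[match("W", tab$residue)]
  v <- autocorrelation(strrep("W", 25), "moreau_broto", "hydropathy", maxlag = 4)
  expect_equal(unname(v), rep(z^2, 4))
})

test_that("lag-1 Moran matches the brute-force double sum", {
  s <- random_sequence(10, seed = 23)
  res <- strsplit(s, "")[[1]]
  tab <- aa_property_scales()
  p <- standardize_scale(tab$polarity)[match(res, tab$residue)]
  L <- 10; d <- 1
  pbar <- mean(p)
  brute <- (sum((p[1:(L - d)] - pbar) * (p[(1 + d):L] - pbar)) / (L - d)) /
    (sum((p - pbar)^2) / L)
  v <- autocorrelation(s, "moran", "polarity", maxlag = 2)
  expect_equal(unname(v[[1]]), brute)
})

test_that("SOCN is zero for a homopolymer and QSO reduces to AAC", {
  s <- strrep("K", 20)
  expect_true(all(socn(s, maxlag = 5) == 0))
  q <- qso(s, maxlag = 5)
  mats <- names(aa_distance_matrices())
  for (mn in mats) {
    expect_equal(unname(q[[paste0("qso_", mn, "_f_K")]]), 1)
    expect_true(all(q[paste0("qso_", mn, "_t", 1:5)] == 0))
  }
})

test_that("two-residue SOCN equals the squared pair distance", {
  mats <- aa_distance_matrices()
  v <- socn("AR", maxlag = 1, matrices = mats)
  for (mn in names(mats)) {
    expect_equal(unname(v[[paste0("socn_", mn, "_d1")]]),
                 mats[[mn]]["A", "R"]^2)
  }
})

test_that("sequences not longer than maxlag are rejected", {
  expect_error(autocorrelation(random_sequence(10, 1), maxlag = 10), "exceed")
  expect_error(socn(random_sequence(5, 1), maxlag = 6), "exceed")
  expect_error(qso(random_sequence(5, 1), maxlag = 5), "exceed")
})

test_that("default preset emits 1080 dimensions; aac+dpc emits 420", {
  s <- random_sequence(60, seed = 24)
  expect_identical(preset_dim(descriptor_preset()), 1080L)
  v <- profeat_block(s)
  expect_length(v, 1080)
  expect_true(all(startsWith(names(v), "profeat_")))
  expect_false(anyDuplicated(names(v)) > 0)
  small <- descriptor_preset(groups = c("aac", "dpc"))
  expect_identical(preset_dim(small), 420L)
  expect_length(profeat_block(s, small), 420)
})

test_that("preset dimension formula matches emitted length for varied presets", {
  s <- random_sequence(70, seed = 25)
  presets <- list(
    descriptor_preset(groups = c("aac", "ctd")),
    descriptor_preset(groups = c("autocorrelation"), ac_types = "moran",
                      ac_properties = c("hydropathy", "polarity"), ac_maxlag = 9),
    descriptor_preset(groups = c("socn", "qso"), so_maxlag = 12),
    descriptor_preset(groups = c("dpc", "qso"), so_maxlag = 3)
  )
  for (p in presets) {
    expect_length(profeat_block(s, p), preset_dim(p))
  }
})

test_that("descriptor block is deterministic and aac permutation-invariant", {
  s <- random_sequence(50, seed = 26)
  expect_identical(profeat_block(s), profeat_block(s))
  perm <- withr::with_seed(27, {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  })
  expect_equal(aac(perm), aac(s))
  expect_gt(max(abs(dpc(perm) - dpc(s))), 0)
  expect_gt(max(abs(socn(perm, 5) - socn(s, 5))), 0)
})
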