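test_that("domain block follows the 0-if-present scoring and catalog order", {
  cat6 <- tiny_catalog()
  ann <- list(p_with = cat6[5], p_two = cat6[c(1, 3)])

  # empty annotation set: every domain absent, all ones under as_printed
  expect_equal(unname(domain_features("unknown", ann, cat6)), rep(1, 6))

  v <- domain_features("p_with", ann, cat6)
  expect_equal(unname(v[5]), 0)
  expect_equal(unname(v[-5]), rep(1, 5))
  expect_equal(names(v), cat6)

  # polarity complement: as_printed + presence = all ones
  for (id in c("p_with", "p_two", "unknown")) {
    expect_equal(unname(domain_features(id, ann, cat6, "as_printed") +
                          domain_features(id, ann, cat6, "presence")),
                 rep(1, 6))
  }
})

test_that("physicochemical means average index values and skip X", {
  aa <- tiny_aaindex()
  expect_equal(unname(physchem_features("AAAA", aa)["p_const"]), 2.5)
  expect_equal(unname(physchem_features("AC", aa)["p_ac"]), 2.0)
  # X is skipped and the effective length reduced
  expect_equal(unname(physchem_features("AXC", aa)["p_ac"]), 2.0)
  expect_error(physchem_features("XXX", aa), "unknown residues")
  expect_error(physchem_features("AB!", aa), "invalid residue")
  # bounded by each property's residue range
  withr::with_seed(11, {
    for (i in 1:20) {
      s <- paste(sample(RES20, 30, replace = TRUE), collapse = "")
      v <- physchem_features(s, default_aaindex_table())
      tab <- default_aaindex_table()
      expect_true(all(v >= apply(tab, 1, min) - 1e-12))
      expect_true(all(v <= apply(tab, 1, max) + 1e-12))
    }
  })
})

test_that("PSSM standardization is the logistic squashing into (0,1)", {
  z <- pssm(matrix(0L, 4, 20))
  expect_equal(standardize_pssm(z), matrix(0.5, 4, 20,
                                           dimnames = list(NULL, RES20)))
  m <- pssm(matrix(c(-10L, 0L, 3L, 10L), 4, 20))
  s <- standardize_pssm(m)
  expect_true(all(s > 0 & s < 1))
  # monotone in the raw score
  expect_true(all(diff(s[, 1]) > 0))
  short <- pssm(matrix(0L, 3, 20))
  expect_error(standardize_pssm(short), "length >= 4")
})

test_that("GM(2,1) matches an independent least-squares oracle", {
  # constant series: the difference target is zero, minimum-norm solution is 0
  expect_equal(unname(fit_gm21(c(2, 2, 2, 2))), c(0, 0, 0))
  expect_error(fit_gm21(c(1, -1, 2, 3)), "positive")
  expect_error(fit_gm21(c(1, 2, 3)), "at least 4")

  expect_equal(unname(fit_gm21(1:5)), oracle_gm21(1:5), tolerance = 1e-10)

  withr::with_seed(7, {
    for (i in 1:200) {
      L <- sample(4:40, 1)
      x0 <- runif(L, 0.01, 1)
      expect_equal(unname(fit_gm21(x0)), oracle_gm21(x0), tolerance = 1e-8)
      # scaling the series keeps implementation and oracle in agreement
      lam <- runif(1, 0.1, 10)
      expect_equal(unname(fit_gm21(lam * x0)), oracle_gm21(lam * x0),
                   tolerance = 1e-8)
    }
  })
})

test_that("the PSSM descriptor concatenates 20 means and 60 grey coefficients", {
  z <- pssm(matrix(0L, 4, 20))
  v <- pssm_features(z)
  expect_length(v, 80L)
  expect_equal(unname(v[1:20]), rep(0.5, 20))
  expect_equal(unname(v[21:80]), rep(0, 60))

  withr::with_seed(3, {
    m <- pssm(matrix(sample(-10:10, 200, replace = TRUE), 10, 20))
  })
  v1 <- pssm_features(m)
  expect_length(v1, 80L)
  expect_true(all(v1[1:20] > 0 & v1[1:20] < 1))
  # permuting rows keeps the means but changes the grey-model block
  mp <- pssm(unclass(m)[c(5, 3, 8, 1, 10, 2, 7, 4, 9, 6), ])
  v2 <- pssm_features(mp)
  expect_equal(v2[1:20], v1[1:20])
  expect_false(isTRUE(all.equal(v2[21:80], v1[21:80])))
})

test_that("full feature vectors have the fixed 167-name layout and block structure", {
  cat63 <- default_domain_catalog()
  aa <- default_aaindex_table()
  withr::with_seed(9, {
    seq1 <- paste(sample(RES20, 30, replace = TRUE), collapse = "")
    scores <- matrix(sample(-10:10, 30 * 20, replace = TRUE), 30, 20)
  })
  prot <- list(id = "p1", sequence = seq1)
  ann <- list(p1 = cat63[c(2, 10)], p1b = cat63[3])
  ps <- pssm(scores, protein_id = "p1")

  v <- extract_features(prot, ann, ps, cat63, aa)
  expect_length(v, 167L)
  expect_equal(names(v), feature_names(cat63, aa))
  expect_true(all(is.finite(v)))
  expect_true(all(v[1:63] %in% c(0, 1)))

  # determinism
  expect_identical(extract_features(prot, ann, ps, cat63, aa), v)

  # changing only the annotation changes only the domain block
  prot2 <- list(id = "p1b", sequence = seq1)
  v2 <- extract_features(prot2, ann, ps, cat63, aa)
  expect_false(identical(v2[1:63], v[1:63]))
  expect_equal(unname(v2[64:167]), unname(v[64:167]))

  # sequence/PSSM length mismatch is refused
  expect_error(extract_features(list(id = "p1", sequence = "ACDE"), ann, ps,
                                cat63, aa), "length")
})

test_that("extract_feature_matrix reads per-protein PSSM files from a directory", {
  dir <- tempfile()
  dir.create(file.path(dir))
  withr::with_seed(21, {
    prot <- data.frame(id = c("a1", "a2"),
                       sequence = replicate(2, paste(sample(RES20, 12, replace = TRUE),
                                                     collapse = "")),
                       stringsAsFactors = FALSE)
    for (i in 1:2) {
      sc <- matrix(sample(-9:9, 12 * 20, replace = TRUE), 12, 20)
      writeLines(format_pssm(pssm(sc, protein_id = prot$id[i],
                                  residues = strsplit(prot$sequence[i], "")[[1]])),
                 file.path(dir, paste0(prot$id[i], ".pssm")))
    }
  })
  x <- extract_feature_matrix(prot, list(a1 = tiny_catalog()[1]), dir,
                              catalog = default_domain_catalog(),
                              table = default_aaindex_table())
  expect_equal(dim(x), c(2L, 167L))
  expect_equal(rownames(x), prot$id)
})
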