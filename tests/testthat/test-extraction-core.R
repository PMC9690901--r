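# Rule-based extraction: patterns derived from the value domains, the
# three-class contract, ICD range filtering, and certainty banding.

test_that("a standard formula line is extracted concretely, feature by feature", {
  text <- "Maessig differenziertes Adenokarzinom. ypT3 ypN1a (2/25) L1 V0 R0 M0."
  res <- extract_tnm(text)
  expected <- c(T = "3", N = "1a", M = "0", L = "1", V = "0", R = "0",
                X1 = "25", X2 = "2")
  for (f in names(expected)) {
    expect_identical(res[[f]]$result_class, "concrete", info = f)
    expect_identical(res[[f]]$value, unname(expected[f]), info = f)
  }
})

test_that("prefixes, case and subdivision letters are all accepted", {
  res <- extract_tnm("cT4a cN2b M1a")
  expect_identical(res$T$value, "4a")
  expect_identical(res$N$value, "2b")
  expect_identical(res$M$value, "1a")
  expect_identical(extract_tnm("rT2")$T$value, "2")
  expect_identical(extract_tnm("pTis")$T$value, "is")
  # tokens embedded in words do not match
  expect_identical(extract_tnm("Tumor Lymphknoten Verlauf Rand")$T$result_class,
                   "empty")
})

test_that("two distinct values yield ambiguous; repeated identical values stay concrete", {
  amb <- extract_tnm("Es findet sich pT2, im Nachtrag jedoch pT3.")
  expect_identical(amb$T$result_class, "ambiguous")
  expect_true(is.na(amb$T$value))
  expect_length(amb$T$spans, 2L)
  rep2 <- extract_tnm("pT3 bestaetigt, nochmals pT3.")
  expect_identical(rep2$T$result_class, "concrete")
  expect_identical(rep2$T$value, "3")
  expect_length(rep2$T$spans, 2L)
})

test_that("a matched X for M, L, V, R is class empty with the X span recorded", {
  for (tok in c("MX", "LX", "VX", "RX")) {
    f <- substr(tok, 1, 1)
    res <- extract_tnm(paste0("Befund: ", tok, "."))[[f]]
    expect_identical(res$result_class, "empty", info = tok)
    expect_true(is.na(res$value), info = tok)
    expect_length(res$spans, 1L)
  }
  # for T and N, X is an ordinary concrete value
  resT <- extract_tnm("pTX pNX")
  expect_identical(resT$T$result_class, "concrete")
  expect_identical(resT$T$value, "X")
  expect_identical(resT$N$value, "X")
})

test_that("empty text yields all-empty results with zero spans", {
  res <- extract_tnm("")
  for (f in names(res)) {
    expect_identical(res[[f]]$result_class, "empty", info = f)
    expect_length(res[[f]]$spans, 0L)
  }
})

test_that("spans are faithful: slicing the text reproduces a pattern match", {
  text <- "Adenokarzinom des Rektums. ypT3 ypN1a (2/25) L1 V0 R0 M0. C20."
  res <- extract_tnm(text)
  specs <- feature_specs()
  for (f in names(specs)) {
    for (span in res[[f]]$spans) {
      piece <- substr(text, span[1], span[2])
      expect_true(grepl(specs[[f]]$pattern, piece, perl = TRUE),
                  info = paste(f, piece))
    }
  }
})

test_that("the lymph-node fraction maps to X2 (affected) over X1 (removed)", {
  res <- extract_tnm("pN1 (3/17)")
  expect_identical(res$X2$value, "3")
  expect_identical(res$X1$value, "17")
  # fallback phrasing without parentheses
  res2 <- extract_tnm("Es wurden 3/17 Lymphknoten befallen.")
  expect_identical(res2$X2$value, "3")
  expect_identical(res2$X1$value, "17")
  # two distinct fractions are a conflict
  res3 <- extract_tnm("pN1 (3/17) spaeter (4/20)")
  expect_identical(res3$X1$result_class, "ambiguous")
  expect_identical(res3$X2$result_class, "ambiguous")
})

test_that("ICD extraction filters to the digestive range before the class decision", {
  one <- extract_icd_localization("Lokalisation: C18.7.")
  expect_identical(one$result_class, "concrete")
  expect_identical(one$value, "C18.7")
  expect_identical(one$term, "Colon sigmoideum")
  # out-of-range codes are discarded, not ambiguous
  lung <- extract_icd_localization("Metastase einer Neoplasie C34.1.")
  expect_identical(lung$result_class, "empty")
  mixed <- extract_icd_localization("Primarius C18.2, Zweitbefund C34.1.")
  expect_identical(mixed$result_class, "concrete")
  expect_identical(mixed$value, "C18.2")
  two <- extract_icd_localization("C18.2 sowie C20.")
  expect_identical(two$result_class, "ambiguous")
  # range boundaries
  expect_identical(extract_icd_localization("C17.0")$result_class, "concrete")
  expect_identical(extract_icd_localization("C22.1")$result_class, "concrete")
  expect_identical(extract_icd_localization("C22.2")$result_class, "empty")
  expect_identical(extract_icd_localization("C16.9")$result_class, "empty")
})

test_that("an in-range code missing from the lookup is concrete but flagged unmapped", {
  lookup <- data.frame(code = "C18.7", term = "Colon sigmoideum",
                       stringsAsFactors = FALSE)
  res <- extract_icd_localization("Befund: C19.", lookup = lookup)
  expect_identical(res$result_class, "concrete")
  expect_identical(res$value, "C19")
  expect_true(res$term_unmapped)
})

test_that("certainty bands switch exactly at the documented thresholds", {
  expect_identical(certainty_band(0.95), "green")
  expect_identical(certainty_band(0.9499999), "yellow")
  expect_identical(certainty_band(0.90), "yellow")
  expect_identical(certainty_band(0.8999999), "red")
  expect_identical(certainty_band(1), "green")
  expect_identical(certainty_band(0), "red")
  expect_error(certainty_band(1.2), "probability")
  expect_error(certainty_band(-0.1), "probability")
})

test_that("the class partition holds on arbitrary input (fuzzing)", {
  chars <- c(letters, LETTERS, 0:9, " ", ".", "(", ")", "/", "\n")
  withr::with_seed(42, {
    for (i in 1:60) {
      text <- paste(sample(chars, sample(5:120, 1), replace = TRUE),
                    collapse = "")
      res <- c(extract_tnm(text), list(ICD = extract_icd_localization(text)))
      for (r in res) {
        expect_true(r$result_class %in% c("concrete", "ambiguous", "empty"))
        if (r$result_class == "concrete") {
          expect_false(is.na(r$value))
          expect_gt(length(r$spans), 0L)
        } else {
          expect_true(is.na(r$value))
        }
        if (r$result_class == "ambiguous") expect_gte(length(r$spans), 2L)
      }
    }
  })
})

test_that("adding a conflicting mention never turns a concrete result back concrete", {
  base <- "Befund: pT2 pN0 (0/12) M0 L0 V0 R0. C18.2."
  dom <- tnm_domains()
  for (f in c("T", "N", "M", "L", "V", "R")) {
    before <- extract_tnm(base)[[f]]
    expect_identical(before$result_class, "concrete")
    alt <- setdiff(dom[[f]], c(before$value, "X"))[1]
    prefix <- if (f %in% c("T", "N", "M")) "p" else ""
    text <- paste0(base, " Nachtrag: ", prefix, f, alt, ".")
    expect_identical(extract_tnm(text)[[f]]$result_class, "ambiguous", info = f)
  }
})
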