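toy_catalog <- function(windows = c("LLTPQQD", "LPSPAAE")) {
  degron_catalog(data.frame(substrate_name = sprintf("W%02d", seq_along(windows)),
                            window_seq = windows),
                 window_length = nchar(windows[1L]))
}

test_that("the frequency matrix tallies columns exactly", {
  pfm <- build_pfm(toy_catalog())
  expect_equal(unname(pfm["L", 1]), 2L)
  expect_equal(unname(pfm["L", 2]), 1L)
  expect_equal(unname(pfm["P", 2]), 1L)
  expect_equal(unname(pfm["P", 4]), 2L)
  expect_true(all(colSums(unclass(pfm)) == attr(pfm, "n_sequences")))

  single <- build_pfm(toy_catalog("LLTPQQD"))
  expect_true(all(colSums(unclass(single) > 0) == 1L))
  expect_true(all(apply(unclass(single), 2, max) == 1L))

  rep5 <- build_pfm(suppressWarnings(toy_catalog(rep("LLTPQQD", 5))))
  expect_true(all(apply(unclass(rep5), 2, max) == 5L))

  expect_error(
    build_pfm(structure(list(instances = data.frame(substrate_name = character(0),
                                                    window_seq = character(0)),
                             window_length = 7L, zero_column = 3L),
                        class = "degron_catalog")),
    class = "degscan_validation_error")
})

test_that("information content follows the Shannon formula", {
  pfm1 <- build_pfm(toy_catalog("LLTPQQD"))
  expect_equal(column_information(pfm1), rep(log2(20), 7), tolerance = 1e-12)

  # columns with two equiprobable residues lose exactly one bit
  pfm2 <- build_pfm(toy_catalog())
  ic <- column_information(pfm2)
  expect_equal(ic[2], log2(20) - 1, tolerance = 1e-12)
  expect_equal(ic[1], log2(20), tolerance = 1e-12)

  # a column uniform over all 20 residues carries 0 bits
  wins <- paste0("LL", c(rep("T", 10), rep("S", 10)), "P",
                 AA20, "Q", "D")
  pfm20 <- build_pfm(toy_catalog(wins))
  expect_equal(column_information(pfm20)[5], 0, tolerance = 1e-12)

  # small-sample correction subtracts 19 / (2 ln2 n), floored at zero
  corrected <- column_information(pfm2, small_sample_correction = TRUE)
  expect_equal(corrected, pmax(0, ic - 19 / (2 * log(2) * 2)), tolerance = 1e-12)
  expect_true(all(column_information(pfm20, small_sample_correction = TRUE) >= 0))
})

test_that("information content is bounded by [0, log2(20)] without correction", {
  set.seed(11)
  for (i in 1:20) {
    wins <- vapply(1:8, function(j) {
      paste0(paste(sample(AA20, 2, replace = TRUE), collapse = ""),
             sample(c("S", "T"), 1), "P",
             paste(sample(AA20, 3, replace = TRUE), collapse = ""))
    }, character(1))
    ic <- column_information(build_pfm(toy_catalog(wins)))
    expect_true(all(ic >= -1e-12 & ic <= log2(20) + 1e-12))
  }
})

test_that("consensus derivation applies the inclusion threshold per column", {
  pfm <- build_pfm(toy_catalog())
  m5 <- derive_consensus(pfm, include_threshold = 0.5, max_class = 4)
  expect_equal(m5$columns,
               list("L", c("L", "P"), c("S", "T"), "P",
                    c("A", "Q"), c("A", "Q"), c("D", "E")))
  expect_equal(m5$zero_column, 3L)
  expect_equal(m5$plus4_column, 7L)

  m6 <- derive_consensus(pfm, include_threshold = 0.6, max_class = 4)
  expect_equal(serialize_pattern(m6), "L..P...")
})

test_that("consensus derivation is deterministic and order-independent", {
  wins <- c("LLTPQQD", "LPSPAAE", "PLTPRRE", "LLSPWWT")
  a <- derive_consensus(build_pfm(toy_catalog(wins)))
  b <- derive_consensus(build_pfm(toy_catalog(rev(wins))))
  expect_equal(serialize_pattern(a), serialize_pattern(b))
  expect_equal(serialize_pattern(a),
               serialize_pattern(derive_consensus(build_pfm(toy_catalog(wins)))))
})

test_that("a vanishing threshold with max_class 20 recovers the observed residue sets", {
  set.seed(42)
  wins <- vapply(1:12, function(j) {
    paste0(paste(sample(AA20, 2, replace = TRUE), collapse = ""),
           sample(c("S", "T"), 1), "P",
           paste(sample(AA20, 3, replace = TRUE), collapse = ""))
  }, character(1))
  cat <- toy_catalog(wins)
  m <- derive_consensus(build_pfm(cat), include_threshold = 1e-9, max_class = 20)
  chars <- do.call(rbind, strsplit(wins, ""))
  for (j in 1:7) {
    observed <- sort(unique(chars[, j]))
    got <- if (is.null(m$columns[[j]])) sort(AA20) else m$columns[[j]]
    expect_equal(got, observed)
  }
})

test_that("a non-CPD-like catalog triggers the zero-column warning, not an error", {
  # zero column residues are S/T by catalog invariant, but deriving with a
  # low threshold can pull other residues into the class only if present;
  # force the warning by deriving with zero_column pointing at a mixed column
  pfm <- build_pfm(toy_catalog(c("LLTPQQD", "LPSPAAE")))
  expect_warning(derive_consensus(pfm, include_threshold = 0.4, zero_column = 1L),
                 "S/T")
})

test_that("the validated CPD pattern parses to the documented column classes", {
  m <- validated_cpd()
  expect_equal(length(m), 7L)
  sizes <- vapply(m$columns, function(cl) if (is.null(cl)) 20L else length(cl),
                  integer(1))
  expect_equal(sizes, c(2L, 2L, 2L, 1L, 20L, 20L, 4L))
  expect_equal(m$columns[[3]], c("S", "T"))
  expect_equal(m$columns[[7]], c("D", "E", "S", "T"))
  expect_equal(m$zero_column, 3L)
  expect_equal(m$plus4_column, 7L)
})

test_that("pattern parsing handles singletons and rejects malformed input", {
  p <- parse_pattern("P")
  expect_equal(p$columns, list("P"))

  expect_error(parse_pattern("[TS]P..["), "position")
  expect_error(parse_pattern("[TS]P..["), class = "degscan_validation_error")
  expect_error(parse_pattern("[]P"), "empty")
  expect_error(parse_pattern("[T1]P"), "illegal")
  expect_error(parse_pattern("a"), "illegal")
  expect_error(parse_pattern(""), "empty")
})

test_that("serialization is canonical and round-trips under set equality", {
  m <- validated_cpd()
  expect_equal(serialize_pattern(m), "[LP][LP][ST]P..[DEST]")
  expect_equal(serialize_pattern(cpd_motif(list("P"))), "P")
  expect_equal(serialize_pattern(cpd_motif(list(NULL, NULL, NULL))), "...")

  # parse -> serialize -> parse is a fixed point on column sets
  set.seed(7)
  for (i in 1:25) {
    m1 <- random_motif()
    s1 <- serialize_pattern(m1)
    m2 <- parse_pattern(s1)
    expect_equal(m2$columns, m1$columns)
    expect_equal(serialize_pattern(m2), s1)
  }
})

test_that("frequency-ordered serialization requires an attached pfm", {
  m <- validated_cpd()
  expect_error(serialize_pattern(m, ordering = "frequency"),
               class = "degscan_validation_error")

  pfm <- build_pfm(toy_catalog(c("LLTPQQD", "LPSPAAE", "PLTPQQE", "LLTPQQE")))
  mf <- derive_consensus(pfm, include_threshold = 0.25, max_class = 4)
  # column 1: L appears 3/4, P 1/4 -> frequency order L before P either way;
  # column 7: E 3/4, D 1/4 -> frequency order ED, alphabetical DE
  expect_match(serialize_pattern(mf, ordering = "frequency"), "\\[ED\\]$")
  expect_match(serialize_pattern(mf, ordering = "alphabetical"), "\\[DE\\]$")
})

test_that("motif documents round-trip through YAML", {
  m <- validated_cpd()
  p <- tempfile(fileext = ".yaml")
  write_motif(m, p, provenance = "test")
  m2 <- read_motif(p)
  expect_equal(m2$columns, m$columns)
  expect_equal(m2$zero_column, m$zero_column)
})
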