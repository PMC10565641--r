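# Shared helpers: the validated CPD pattern, an independent naive scanning
# oracle, and random motif / sequence generators for property tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

cpd_pattern <- "[LP][LP][TS]P..[TSDE]"

validated_cpd <- function() parse_pattern(cpd_pattern)

# Naive window-enumeration oracle: per-column set membership, no regex.
naive_scan <- function(motif, seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(motif$columns)
  n <- length(ch)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    cl <- motif$columns[[j]]
    seg <- ch[j:(j + n - L)]
    if (!is.null(cl)) ok <- ok & seg %in% cl
  }
  which(ok)
}

# Random degenerate motif: each column wildcard with prob p_wild, else a
# random residue class of size 1..4.
random_motif <- function(L = sample(3:8, 1L), p_wild = 0.35) {
  cols <- lapply(seq_len(L), function(j) {
    if (runif(1) < p_wild) NULL else sample(AA20, sample(1:4, 1L))
  })
  if (all(vapply(cols, is.null, logical(1)))) cols[[1L]] <- sample(AA20, 2L)
  cpd_motif(cols)
}

# Random protein-like sequence, optionally salted with ambiguity codes.
random_seq <- function(n, with_ambiguity = FALSE) {
  alpha <- if (with_ambiguity) c(AA20, "X", "B", "Z") else AA20
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

random_seq_fixed <- function(n, seed) {
  set.seed(seed)
  random_seq(n)
}

# Write a degron TSV from a character vector of windows.
write_degron_fixture <- function(windows, path = tempfile(fileext = ".tsv"),
                                 names = sprintf("TOY%02d", seq_along(windows))) {
  writeLines(c("substrate_name\twindow_seq",
               paste(names, windows, sep = "\t")), path)
  path
}

extdata <- function(...) system.file("extdata", ..., package = "degscan")
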