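#' Position-frequency matrix from a degron catalog
#'
#' Tallies residues column-wise over all windows in the catalog. Duplicated
#' windows legitimately up-weight their residues.
#'
#' @param catalog a [degron_catalog()]; must be non-empty.
#' @return An object of class `pfm`: a 20 x L integer matrix of counts
#'   (rows = amino acids, alphabetical) with attributes `n_sequences`,
#'   `zero_column`.
#' @examples
#' cat2 <- degron_catalog(
#'   data.frame(substrate_name = c("A", "B"),
#'              window_seq = c("LLTPQQD", "LPSPAAE")),
#'   window_length = 7)
#' build_pfm(cat2)
#' @export
build_pfm <- function(catalog) {
  stopifnot(inherits(catalog, "degron_catalog"))
  n <- nrow(catalog$instances)
  if (n == 0L) stop_validation("cannot build a frequency matrix from an empty catalog")
  L <- catalog$window_length
  m <- matrix(0L, nrow = length(AA_ALPHABET), ncol = L,
              dimnames = list(AA_ALPHABET, seq_len(L)))
  chars <- do.call(rbind, strsplit(catalog$instances$window_seq, "", fixed = TRUE))
  for (j in seq_len(L)) {
    tab <- table(factor(chars[, j], levels = AA_ALPHABET))
    m[, j] <- as.integer(tab)
  }
  structure(m, class = c("pfm", "matrix"),
            n_sequences = n, zero_column = catalog$zero_column)
}

#' Per-column information content of a frequency matrix
#'
#' Shannon information content in bits: `IC_j = log2(20) - H_j` where `H_j`
#' is the entropy of column j's empirical residue distribution. With
#' `small_sample_correction`, the Miller-Madow style bias term
#' `(|A| - 1) / (2 ln 2 n)` with `|A| = 20` is subtracted and the result
#' floored at 0 bits.
#'
#' @param pfm a [build_pfm()] result.
#' @param small_sample_correction logical.
#' @return Numeric vector of length L, bits per column.
#' @export
column_information <- function(pfm, small_sample_correction = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  n <- attr(pfm, "n_sequences")
  ic <- apply(unname(unclass(pfm)), 2L, function(cnt) {
    f <- cnt / sum(cnt)
    f <- f[f > 0]
    log2(length(AA_ALPHABET)) + sum(f * log2(f))
  })
  if (small_sample_correction) {
    ic <- pmax(0, ic - (length(AA_ALPHABET) - 1) / (2 * log(2) * n))
  }
  ic
}

#' Consensus motifs
#'
#' A consensus motif is an ordered list of columns, each either an explicit
#' residue class (a set of amino acids) or a wildcard (no constraint). The
#' phospho-acceptor column ('0') and the '+4' column (zero + 4), the two
#' positions FBXW7 reads out, are annotated. The printed CPD consensus
#' `"[LP][LP][TS]P..[TSDE]"` parses to a 7-column motif with zero column 3
#' and '+4' column 7.
#'
#' @param columns list of length L; each element a character vector of
#'   residues, or `NULL` for wildcard.
#' @param zero_column 1-based index of the '0' column, or `NA`.
#' @param pfm optional attached [build_pfm()] matrix (enables
#'   frequency-ordered serialization).
#' @return An object of class `cpd_motif`.
#' @export
cpd_motif <- function(columns, zero_column = NA_integer_, pfm = NULL) {
  stopifnot(is.list(columns), length(columns) >= 1L)
  columns <- lapply(columns, function(cl) {
    if (is.null(cl)) return(NULL)
    cl <- unique(toupper(cl))
    bad <- setdiff(cl, AA_ALPHABET)
    if (length(bad)) stop_validation("illegal residue(s) in motif class: %s",
                                     paste(bad, collapse = ", "))
    if (length(cl) == 0L) stop_validation("empty residue class in motif")
    sort(cl)
  })
  L <- length(columns)
  zero_column <- as.integer(zero_column)
  plus4 <- if (!is.na(zero_column) && zero_column + 4L <= L) zero_column + 4L else NA_integer_
  structure(
    list(columns = columns, length = L,
         zero_column = zero_column, plus4_column = plus4, pfm = pfm),
    class = "cpd_motif")
}

#' @export
length.cpd_motif <- function(x) x$length

#' Derive a degenerate consensus motif from a frequency matrix
#'
#' Per column, the class is the set of residues whose relative frequency is
#' at least `include_threshold`; if that set is empty or larger than
#' `max_class` the column becomes a wildcard. The result is deterministic and
#' independent of instance order.
#'
#' @inheritParams column_information
#' @param include_threshold inclusion frequency in (0, 1]; default 0.2.
#' @param max_class largest residue class emitted before falling back to a
#'   wildcard; default 4.
#' @param zero_column 1-based phospho-acceptor column; defaults to the
#'   catalog's, carried on the pfm.
#' @return A [cpd_motif()] with the pfm attached.
#' @export
derive_consensus <- function(pfm, include_threshold = 0.2, max_class = 4L,
                             zero_column = attr(pfm, "zero_column")) {
  stopifnot(inherits(pfm, "pfm"))
  if (include_threshold <= 0 || include_threshold > 1) {
    stop_validation("include_threshold must lie in (0, 1]")
  }
  n <- attr(pfm, "n_sequences")
  cols <- lapply(seq_len(ncol(pfm)), function(j) {
    f <- unclass(pfm)[, j] / n
    cls <- names(f)[f >= include_threshold]
    if (length(cls) == 0L || length(cls) > max_class) NULL else cls
  })
  m <- cpd_motif(cols, zero_column = zero_column, pfm = pfm)
  zc <- m$zero_column
  if (!is.na(zc) && !is.null(m$columns[[zc]]) &&
      !all(m$columns[[zc]] %in% c("S", "T"))) {
    warning(sprintf("derived '0'-column class {%s} is not restricted to S/T; catalog may not be CPD-like",
                    paste(m$columns[[zc]], collapse = ",")))
  }
  m
}

#' Parse a bracket-notation motif
#'
#' Accepts single uppercase residue letters, `.` for wildcard and `[...]`
#' for residue classes, e.g. the validated CPD `"[LP][LP][TS]P..[TSDE]"`.
#' When `zero_column` is not given it defaults to the first column whose
#' class is a subset of \{S, T\} and is immediately followed by an
#' invariant-P column (the phospho-acceptor + obligatory proline of CPD
#' convention); `NA` if no such column exists.
#'
#' @param text the pattern string.
#' @param zero_column optional explicit '0' column.
#' @return A [cpd_motif()].
#' @examples
#' parse_pattern("[LP][LP][TS]P..[TSDE]")
#' @export
parse_pattern <- function(text, zero_column = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- str_chars(text)
  cols <- list()
  i <- 1L
  while (i <= length(ch)) {
    c0 <- ch[i]
    if (c0 == ".") {
      cols[[length(cols) + 1L]] <- NULL_marker()
      i <- i + 1L
    } else if (c0 == "[") {
      j <- i + 1L
      cls <- character()
      repeat {
        if (j > length(ch)) {
          stop_validation("unterminated residue class starting at position %d in %s",
                          i, sQuote(text))
        }
        if (ch[j] == "]") break
        if (!ch[j] %in% AA_ALPHABET) {
          stop_validation("illegal character '%s' at position %d in %s",
                          ch[j], j, sQuote(text))
        }
        cls <- c(cls, ch[j])
        j <- j + 1L
      }
      if (length(cls) == 0L) {
        stop_validation("empty residue class at position %d in %s", i, sQuote(text))
      }
      cols[[length(cols) + 1L]] <- cls
      i <- j + 1L
    } else if (c0 %in% AA_ALPHABET) {
      cols[[length(cols) + 1L]] <- c0
      i <- i + 1L
    } else {
      stop_validation("illegal character '%s' at position %d in %s", c0, i, sQuote(text))
    }
  }
  if (length(cols) == 0L) stop_validation("empty motif pattern")
  cols <- lapply(cols, function(x) if (identical(x, ".WILD.")) NULL else x)
  if (is.null(zero_column)) {
    zero_column <- NA_integer_
    for (k in seq_along(cols)) {
      cl <- cols[[k]]
      nxt <- if (k < length(cols)) cols[[k + 1L]] else NULL
      if (!is.null(cl) && all(cl %in% c("S", "T")) &&
          !is.null(nxt) && identical(nxt, "P")) {
        zero_column <- k
        break
      }
    }
  }
  cpd_motif(cols, zero_column = zero_column)
}

# Internal marker so that list construction can hold "wildcard" before the
# final NULL conversion (appending NULL to a list drops the element).
NULL_marker <- function() ".WILD."

#' Serialize a motif to bracket notation
#'
#' Single-residue classes are emitted bare, wildcards as `.`, larger classes
#' in brackets. `ordering = "alphabetical"` is the canonical form;
#' `"frequency"` orders residues by their column frequency in the attached
#' pfm (ties alphabetical) and errors without one. Motif equality is set
#' equality per column, so `"[LP][LP][TS]P..[TSDE]"` canonicalizes to
#' `"[LP][LP][ST]P..[DEST]"`.
#'
#' @param motif a [cpd_motif()].
#' @param ordering `"alphabetical"` or `"frequency"`.
#' @return The pattern string.
#' @export
serialize_pattern <- function(motif, ordering = c("alphabetical", "frequency")) {
  stopifnot(inherits(motif, "cpd_motif"))
  ordering <- match.arg(ordering)
  if (ordering == "frequency" && is.null(motif$pfm)) {
    stop_validation("frequency ordering requires a motif with an attached pfm")
  }
  parts <- vapply(seq_along(motif$columns), function(j) {
    cl <- motif$columns[[j]]
    if (is.null(cl)) return(".")
    if (ordering == "frequency") {
      f <- unclass(motif$pfm)[cl, j]
      cl <- cl[order(-f, cl)]
    } else {
      cl <- sort(cl)
    }
    if (length(cl) == 1L) cl else paste0("[", paste(cl, collapse = ""), "]")
  }, character(1))
  paste(parts, collapse = "")
}

#' @export
print.cpd_motif <- function(x, ...) {
  cat(sprintf("cpd_motif: %s  (L = %d", serialize_pattern(x), x$length))
  if (!is.na(x$zero_column)) {
    cat(sprintf(", '0' column = %d, '+4' column = %s",
                x$zero_column,
                if (is.na(x$plus4_column)) "NA" else x$plus4_column))
  }
  cat(")\n")
  invisible(x)
}

#' @export
format.cpd_motif <- function(x, ...) serialize_pattern(x)

#' Write / read a motif document
#'
#' Persists a motif as a small YAML document with keys `pattern`,
#' `zero_column`, `plus4_column` and `provenance`; the bracket notation is
#' the interchange string.
#'
#' @param motif a [cpd_motif()].
#' @param path file path.
#' @param provenance free-text provenance note.
#' @return `write_motif` the path, invisibly; `read_motif` a [cpd_motif()].
#' @export
write_motif <- function(motif, path, provenance = "degscan") {
  doc <- list(pattern = serialize_pattern(motif),
              zero_column = if (is.na(motif$zero_column)) NULL else motif$zero_column,
              plus4_column = if (is.na(motif$plus4_column)) NULL else motif$plus4_column,
              provenance = provenance)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_motif
#' @export
read_motif <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$pattern)) stop_validation("motif document %s lacks a 'pattern' key", path)
  parse_pattern(doc$pattern, zero_column = doc$zero_column)
}
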