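#' Degron catalogs
#'
#' A degron catalog holds experimentally validated phosphodegron windows:
#' fixed-length peptides aligned on the phospho-acceptor ('0') residue. The
#' catalog is the training material for the position-frequency matrix and the
#' consensus motif. For the FBXW7 Cdc4-phosphodegron (CPD) the window length
#' is 7 and the phospho-acceptor sits in column 3, so that column 3 + 4 is the
#' '+4' position of CPD convention.
#'
#' @param instances data.frame with columns `substrate_name`, `window_seq`
#'   and optionally `zero_protein_pos` (1-based position of the '0' residue in
#'   the source protein) and `source_ref`.
#' @param window_length integer window length L shared by all instances.
#' @param zero_column 1-based column index of the phospho-acceptor within the
#'   window.
#' @return An object of class `degron_catalog`: a list with elements
#'   `instances` (data.frame), `window_length` and `zero_column`.
#' @examples
#' degron_catalog(
#'   data.frame(substrate_name = c("TOY1", "TOY2"),
#'              window_seq = c("LLTPQQD", "LPSPAAE")),
#'   window_length = 7, zero_column = 3)
#' @export
degron_catalog <- function(instances, window_length, zero_column = 3L) {
  window_length <- as.integer(window_length)
  zero_column <- as.integer(zero_column)
  if (!is.data.frame(instances) || !all(c("substrate_name", "window_seq") %in%
                                        names(instances))) {
    stop_validation("instances must be a data.frame with columns substrate_name and window_seq")
  }
  if (zero_column < 1L || zero_column > window_length) {
    stop_validation("zero_column (%d) must lie in 1..window_length (%d)",
                    zero_column, window_length)
  }
  if (!"zero_protein_pos" %in% names(instances)) instances$zero_protein_pos <- NA_integer_
  if (!"source_ref" %in% names(instances)) instances$source_ref <- NA_character_
  instances$window_seq <- toupper(as.character(instances$window_seq))

  for (i in seq_len(nrow(instances))) {
    nm <- instances$substrate_name[i]
    w <- instances$window_seq[i]
    if (nchar(w) != window_length) {
      stop_validation("instance '%s': window '%s' has length %d, expected %d",
                      nm, w, nchar(w), window_length)
    }
    ch <- str_chars(w)
    bad <- setdiff(ch, AA_ALPHABET)
    if (length(bad)) {
      stop_validation("instance '%s': illegal residue(s) %s in window '%s'",
                      nm, paste(sQuote(bad), collapse = ", "), w)
    }
    if (!ch[zero_column] %in% c("S", "T")) {
      stop_validation(
        "instance '%s': column-%d residue '%s' is not a phospho-acceptor (S/T)",
        nm, zero_column, ch[zero_column])
    }
  }
  dup <- duplicated(instances$window_seq)
  if (any(dup)) {
    warning(sprintf("catalog contains %d duplicated window(s) (%s); duplicates up-weight the frequency matrix",
                    sum(dup),
                    paste(unique(instances$window_seq[dup]), collapse = ", ")))
  }
  structure(
    list(instances = instances,
         window_length = window_length,
         zero_column = zero_column),
    class = "degron_catalog")
}

#' Read a degron table from TSV
#'
#' The file is tab-delimited UTF-8 with a header line; lines starting with
#' `#` are ignored. Required columns: `substrate_name`, `window_seq`;
#' optional: `zero_protein_pos`, `source_ref`. Row order is preserved.
#'
#' @param path path to the TSV file.
#' @inheritParams degron_catalog
#' @return A [degron_catalog()].
#' @export
read_degron_table <- function(path, window_length = 7L, zero_column = 3L) {
  if (!file.exists(path)) stop_validation("degron table not found: %s", path)
  raw <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  if (!any(keep)) stop_validation("degron table %s has no data", path)
  lines <- raw[keep]
  line_no <- which(keep)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("substrate_name", "window_seq")
  if (!all(need %in% header)) {
    stop_validation("degron table %s: header must contain %s",
                    path, paste(need, collapse = ", "))
  }
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < length(header)) f <- c(f, rep("", length(header) - length(f)))
    if (length(f) > length(header)) {
      stop_validation("degron table %s line %d: %d fields, header has %d",
                      path, line_no[i], length(f), length(header))
    }
    setNames(as.list(f), header)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if ("zero_protein_pos" %in% names(df)) {
    suppressWarnings(df$zero_protein_pos <- as.integer(df$zero_protein_pos))
  }
  degron_catalog(df, window_length = window_length, zero_column = zero_column)
}

#' Write a degron catalog to TSV
#'
#' Inverse of [read_degron_table()]: the written file round-trips up to
#' whitespace normalization.
#'
#' @param catalog a [degron_catalog()].
#' @param path output path.
#' @export
write_degron_table <- function(catalog, path) {
  stopifnot(inherits(catalog, "degron_catalog"))
  df <- catalog$instances[, c("substrate_name", "window_seq",
                              "zero_protein_pos", "source_ref")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.degron_catalog <- function(x, ...) {
  cat(sprintf("degron_catalog: %d validated window(s), L = %d, '0' column = %d\n",
              nrow(x$instances), x$window_length, x$zero_column))
  print(utils::head(x$instances, 10L), row.names = FALSE)
  if (nrow(x$instances) > 10L) cat(sprintf("... and %d more\n", nrow(x$instances) - 10L))
  invisible(x)
}

#' @export
length.degron_catalog <- function(x) nrow(x$instances)
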