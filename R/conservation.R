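#' Ortholog families
#'
#' An ortholog family is a multiple sequence alignment (equal-length rows,
#' `-` gaps) of one gene's orthologs, with one member designated as the
#' reference — the protein that was scanned (e.g. the human sequence).
#'
#' @param members named character vector of aligned sequences (names are
#'   member ids / species tags).
#' @param reference_id name of the reference member.
#' @param gene_symbol gene label for reporting.
#' @return An object of class `ortholog_family`.
#' @export
ortholog_family <- function(members, reference_id, gene_symbol = reference_id) {
  members <- toupper(members)
  if (is.null(names(members)) || any(!nzchar(names(members)))) {
    stop_validation("ortholog family members must be named")
  }
  if (length(unique(nchar(members))) != 1L) {
    stop_validation("aligned sequences must all have the same length")
  }
  if (!reference_id %in% names(members)) {
    stop_validation("reference_id '%s' not among family members", reference_id)
  }
  structure(list(gene_symbol = gene_symbol, reference_id = reference_id,
                 members = members),
            class = "ortholog_family")
}

#' Read an aligned-FASTA ortholog family
#'
#' One family per file; the reference row is selected by id.
#'
#' @param path aligned FASTA path.
#' @param reference_id id of the reference row (default: first record).
#' @param gene_symbol gene label (default: reference id).
#' @return An [ortholog_family()].
#' @export
read_alignment <- function(path, reference_id = NULL, gene_symbol = NULL) {
  if (!file.exists(path)) stop_validation("alignment not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  members <- setNames(toupper(as.character(ss)), sub("\\s.*$", "", names(ss)))
  if (is.null(reference_id)) reference_id <- names(members)[1L]
  ortholog_family(members, reference_id,
                  gene_symbol = if (is.null(gene_symbol)) reference_id else gene_symbol)
}

#' Map an ungapped reference window to alignment columns
#'
#' Returns the alignment columns holding the reference residues
#' `ref_start .. ref_start + L - 1` (1-based, ungapped coordinates),
#' skipping reference gaps.
#'
#' @param family an [ortholog_family()].
#' @param ref_start 1-based ungapped start in the reference protein.
#' @param L window length.
#' @return Integer vector of L alignment column indices.
#' @export
map_window_to_alignment <- function(family, ref_start, L) {
  stopifnot(inherits(family, "ortholog_family"))
  ref <- str_chars(family$members[[family$reference_id]])
  resid_cols <- which(ref != "-")
  if (ref_start < 1L || ref_start + L - 1L > length(resid_cols)) {
    stop_validation(
      "window %d..%d exceeds the reference's ungapped length (%d residues)",
      ref_start, ref_start + L - 1L, length(resid_cols))
  }
  resid_cols[ref_start:(ref_start + L - 1L)]
}

#' Score conservation of a motif window across orthologs
#'
#' Two transparent scores over a user-supplied alignment:
#' `motif_retention`, the fraction of non-reference members whose aligned
#' window still satisfies every non-wildcard motif class; and
#' `column_identity`, the per-column fraction of non-reference members whose
#' residue equals the reference residue. Gaps never count as matching — at
#' class columns, at wildcard columns, and for identity — because an absent
#' residue cannot evidence conservation.
#'
#' @param motif a [cpd_motif()].
#' @param family an [ortholog_family()] with at least 2 members.
#' @param ref_start 1-based ungapped start of the window in the reference.
#' @param L window length (defaults to the motif length).
#' @return An object of class `conservation_result`: list with
#'   `gene_symbol`, `ref_window_start`, `motif_retention`,
#'   `column_identity` (length-L numeric), `n_members`.
#' @export
score_conservation <- function(motif, family, ref_start, L = motif$length) {
  stopifnot(inherits(motif, "cpd_motif"), inherits(family, "ortholog_family"))
  if (length(family$members) < 2L) {
    stop_validation("family '%s' has < 2 members; nothing to compare", family$gene_symbol)
  }
  if (L != motif$length) {
    stop_validation("window length %d differs from motif length %d", L, motif$length)
  }
  cols <- map_window_to_alignment(family, ref_start, L)
  others <- family$members[names(family$members) != family$reference_id]
  ref_window <- str_chars(family$members[[family$reference_id]])[cols]

  window_chars <- t(vapply(others, function(s) str_chars(s)[cols], character(L)))
  retains <- apply(window_chars, 1L, function(w) {
    if (any(w == "-")) return(FALSE)
    for (j in seq_len(L)) {
      cl <- motif$columns[[j]]
      if (!is.null(cl) && !w[j] %in% cl) return(FALSE)
    }
    TRUE
  })
  identity <- vapply(seq_len(L), function(j) {
    mean(window_chars[, j] == ref_window[j] & window_chars[, j] != "-")
  }, numeric(1))

  structure(
    list(gene_symbol = family$gene_symbol,
         ref_window_start = as.integer(ref_start),
         motif_retention = mean(retains),
         column_identity = identity,
         n_members = length(family$members)),
    class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf("conservation_result: %s window @%d  retention = %.3f  mean identity = %.3f  (n = %d)\n",
              x$gene_symbol, x$ref_window_start, x$motif_retention,
              mean(x$column_identity), x$n_members))
  invisible(x)
}

#' Write conservation results to TSV
#'
#' @param results a list of `conservation_result` objects (or a single one).
#' @param path output path.
#' @param report_threshold retention at or above which a window is flagged
#'   `highly_conserved` (a reporting convention, default 0.8).
#' @export
write_conservation_tsv <- function(results, path, report_threshold = 0.8) {
  if (inherits(results, "conservation_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(gene_symbol = r$gene_symbol,
               ref_window_start = r$ref_window_start,
               motif_retention = r$motif_retention,
               mean_column_identity = mean(r$column_identity),
               column_identity = paste(sprintf("%.4f", r$column_identity), collapse = ","),
               n_members = r$n_members,
               highly_conserved = r$motif_retention >= report_threshold,
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(gene_symbol = character(0), ref_window_start = integer(0),
                     motif_retention = numeric(0), mean_column_identity = numeric(0),
                     column_identity = character(0), n_members = integer(0),
                     highly_conserved = logical(0))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
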