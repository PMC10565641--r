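#' Read a protein FASTA
#'
#' Reads a canonical-proteome FASTA via Biostrings and applies the package's
#' sanitization contract: sequences are uppercased, a single trailing `*`
#' (stop) is stripped, an internal `*` or an empty sequence is an error
#' naming the record, and duplicate protein ids are an error. Two header
#' dialects are supported: `"uniprot"` parses `db|ACC|NAME` accessions and a
#' `GN=` gene symbol; `"plain"` uses the first whitespace-delimited token as
#' both protein id and gene symbol.
#'
#' @param path FASTA file path.
#' @param header_dialect `"uniprot"` or `"plain"`.
#' @return data.frame with columns `protein_id`, `gene_symbol`, `sequence`.
#' @export
read_fasta <- function(path, header_dialect = c("uniprot", "plain")) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) stop_validation("FASTA not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- toupper(as.character(ss))
  recs <- lapply(seq_along(seqs), function(i) {
    h <- headers[i]
    s <- gsub("[[:space:]]", "", seqs[i])
    s <- sub("\\*$", "", s)
    first <- sub("\\s.*$", "", h)
    if (grepl("*", s, fixed = TRUE)) {
      stop_validation("record '%s': internal stop codon '*' in sequence", first)
    }
    if (!nzchar(s)) stop_validation("record '%s': empty sequence", first)
    bad <- setdiff(unique(str_chars(s)), c(AA_ALPHABET, AA_AMBIGUITY))
    if (length(bad)) {
      stop_validation("record '%s': illegal character(s) %s",
                      first, paste(sQuote(bad), collapse = ", "))
    }
    if (header_dialect == "uniprot") {
      pid <- if (grepl("^[a-z]+\\|[^|]+\\|", h)) sub("^[a-z]+\\|([^|]+)\\|.*$", "\\1", h) else first
      gene <- if (grepl("GN=", h, fixed = TRUE)) sub("^.*GN=([^ ]+).*$", "\\1", h) else ""
    } else {
      pid <- first
      gene <- first
    }
    list(protein_id = pid, gene_symbol = gene, sequence = s)
  })
  ids <- vapply(recs, `[[`, character(1), "protein_id")
  if (anyDuplicated(ids)) {
    stop_validation("duplicate protein_id(s): %s",
                    paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  data.frame(protein_id = ids,
             gene_symbol = vapply(recs, `[[`, character(1), "gene_symbol"),
             sequence = vapply(recs, `[[`, character(1), "sequence"),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path output path.
#' @param uniprot_style emit `sp|id|id_SYN GN=gene` headers (so the file
#'   round-trips through the uniprot dialect); otherwise plain ids.
#' @export
write_fasta <- function(records, path, uniprot_style = FALSE) {
  headers <- if (uniprot_style) {
    sprintf("sp|%s|%s_SYN GN=%s", records$protein_id, records$protein_id,
            ifelse(nzchar(records$gene_symbol), records$gene_symbol, records$protein_id))
  } else {
    records$protein_id
  }
  ss <- Biostrings::AAStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

# Build the (perl) regular expression for a motif: classes become character
# classes, wildcards become '.', which deliberately also matches ambiguity
# codes (X,B,Z,U,O) — a wildcard imposes no constraint, an explicit class
# never admits an ambiguity code.
motif_regex <- function(motif) {
  parts <- vapply(motif$columns, function(cl) {
    if (is.null(cl)) "." else if (length(cl) == 1L) cl
    else paste0("[", paste(cl, collapse = ""), "]")
  }, character(1))
  paste(parts, collapse = "")
}

#' Scan one protein for motif matches
#'
#' Reports every window (1-based start) whose substring satisfies all column
#' classes; overlapping matches are all reported, sorted by start. The '0'
#' and '+4' protein coordinates are `start + zero_column - 1` and that + 4.
#'
#' @param motif a [cpd_motif()].
#' @param record a single-row data.frame (or list) with `protein_id`,
#'   `gene_symbol`, `sequence`.
#' @return data.frame with columns `protein_id`, `gene_symbol`, `start_pos`,
#'   `match_seq`, `zero_pos`, `plus4_pos` (zero rows if no match).
#' @examples
#' m <- parse_pattern("[LP][LP][TS]P..[TSDE]")
#' scan_protein(m, list(protein_id = "P1", gene_symbol = "TOY1",
#'                      sequence = "MLLTPQQD"))
#' @export
scan_protein <- function(motif, record) {
  stopifnot(inherits(motif, "cpd_motif"))
  seq <- record$sequence
  starts <- scan_starts(motif, seq)
  n <- length(starts)
  L <- motif$length
  zc <- motif$zero_column
  data.frame(
    protein_id = rep(record$protein_id, n),
    gene_symbol = rep(record$gene_symbol, n),
    start_pos = starts,
    match_seq = if (n) substring(seq, starts, starts + L - 1L) else character(0),
    zero_pos = if (is.na(zc)) rep(NA_integer_, n) else starts + zc - 1L,
    plus4_pos = if (is.na(zc)) rep(NA_integer_, n) else starts + zc + 3L,
    stringsAsFactors = FALSE)
}

# All 1-based match starts of motif in a sequence string, including
# overlapping matches (zero-width lookahead).
scan_starts <- function(motif, seq) {
  if (nchar(seq) < motif$length) return(integer(0))
  pat <- paste0("(?=", motif_regex(motif), ")")
  m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  starts <- as.integer(m)
  starts[starts <= nchar(seq) - motif$length + 1L]
}

#' Scan a proteome and aggregate per gene
#'
#' Concatenates per-protein scans (input order, then start position) and
#' aggregates match counts per gene symbol. Records without a gene symbol
#' are aggregated under their protein id, with a warning.
#'
#' @param motif a [cpd_motif()].
#' @param records data.frame of protein records ([read_fasta()]).
#' @return An object of class `candidate_table`: list with `matches`
#'   (data.frame), `per_gene` (named integer vector) and `candidate_genes`
#'   (character vector of genes with >= 1 match).
#' @export
scan_proteome <- function(motif, records) {
  if (!NROW(records)) stop_validation("scan_proteome: no protein records supplied")
  missing_gene <- !nzchar(records$gene_symbol)
  if (any(missing_gene)) {
    warning(sprintf("%d record(s) lack a gene symbol; using protein_id as aggregation key",
                    sum(missing_gene)))
    records$gene_symbol[missing_gene] <- records$protein_id[missing_gene]
  }
  pieces <- lapply(seq_len(nrow(records)), function(i) scan_protein(motif, records[i, ]))
  matches <- do.call(rbind, pieces)
  if (is.null(matches)) {
    matches <- scan_protein(motif, list(protein_id = character(0),
                                        gene_symbol = character(0),
                                        sequence = character(0)))[0, ]
  }
  per_gene <- if (nrow(matches)) {
    tab <- table(matches$gene_symbol)
    setNames(as.integer(tab), names(tab))
  } else {
    setNames(integer(0), character(0))
  }
  structure(
    list(matches = matches, per_gene = per_gene,
         candidate_genes = unique(matches$gene_symbol)),
    class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("candidate_table: %d match(es) in %d candidate gene(s)\n",
              nrow(x$matches), length(x$candidate_genes)))
  print(utils::head(x$matches, 10L), row.names = FALSE)
  if (nrow(x$matches) > 10L) cat(sprintf("... and %d more\n", nrow(x$matches) - 10L))
  invisible(x)
}

#' Write / read a candidates table
#'
#' One row per match, TSV columns `gene_symbol`, `protein_id`,
#' `n_matches_in_gene`, `start_pos`, `zero_pos`, `plus4_pos`, `match_seq`.
#' `read_candidates_tsv` reconstructs the `candidate_table`.
#'
#' @param table a `candidate_table` from [scan_proteome()].
#' @param path file path.
#' @export
write_candidates_tsv <- function(table, path) {
  stopifnot(inherits(table, "candidate_table"))
  m <- table$matches
  out <- data.frame(
    gene_symbol = m$gene_symbol,
    protein_id = m$protein_id,
    n_matches_in_gene = if (nrow(m)) unname(table$per_gene[m$gene_symbol]) else integer(0),
    start_pos = m$start_pos,
    zero_pos = m$zero_pos,
    plus4_pos = m$plus4_pos,
    match_seq = m$match_seq,
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates_tsv
#' @export
read_candidates_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  matches <- df[, c("protein_id", "gene_symbol", "start_pos", "match_seq",
                    "zero_pos", "plus4_pos")]
  per_gene <- if (nrow(matches)) {
    tab <- table(matches$gene_symbol)
    setNames(as.integer(tab), names(tab))
  } else setNames(integer(0), character(0))
  structure(list(matches = matches, per_gene = per_gene,
                 candidate_genes = unique(matches$gene_symbol)),
            class = "candidate_table")
}
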