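#' Read a phosphosite table
#'
#' Minimal TSV contract emulating a PhosphoSitePlus extract: columns
#' `protein_id`, `position` (1-based) and `residue` (single letter).
#' Comment lines (`#`) are ignored.
#'
#' @param path TSV path.
#' @return data.frame with the three columns, validated.
#' @export
read_phosphosites <- function(path) {
  if (!file.exists(path)) stop_validation("phosphosite table not found: %s", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue")
  if (!all(need %in% names(df))) {
    stop_validation("phosphosite table %s must have columns %s",
                    path, paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df$residue <- toupper(df$residue)
  if (any(is.na(df$position)) || any(df$position < 1L)) {
    stop_validation("phosphosite positions must be integers >= 1")
  }
  if (any(!df$residue %in% AA_ALPHABET)) {
    stop_validation("phosphosite residues must be standard amino-acid letters")
  }
  df[, need]
}

#' Annotate matches with known phosphosites at '0' and '+4'
#'
#' For each match, `phospho_zero` (`phospho_plus4`) is TRUE iff a site row
#' exists with the match's protein id, position equal to the match's '0'
#' ('+4') protein coordinate, and a recorded residue that agrees with the
#' actual sequence residue at that position. Sites whose recorded residue
#' disagrees with the sequence are reported and treated as absent (guards
#' against coordinate-version drift); sites on unknown proteins are reported
#' and ignored. Match coordinates and counts are never altered.
#'
#' @param table a `candidate_table` from [scan_proteome()].
#' @param sites a phosphosite data.frame ([read_phosphosites()]).
#' @param records protein records ([read_fasta()]) used to verify residues.
#' @return The match data.frame with logical columns `phospho_zero` and
#'   `phospho_plus4` appended.
#' @export
annotate_phospho <- function(table, sites, records) {
  stopifnot(inherits(table, "candidate_table"))
  m <- table$matches
  seqs <- setNames(records$sequence, records$protein_id)

  unknown <- !sites$protein_id %in% names(seqs)
  if (any(unknown)) {
    log_msg("annotate", "%d phosphosite(s) on unknown protein id(s) ignored: %s",
            sum(unknown), paste(unique(sites$protein_id[unknown]), collapse = ", "))
    sites <- sites[!unknown, , drop = FALSE]
  }
  if (nrow(sites)) {
    actual <- substring(seqs[sites$protein_id], sites$position, sites$position)
    mismatch <- actual != sites$residue
    if (any(mismatch)) {
      log_msg("annotate", "%d phosphosite(s) with residue disagreeing with the sequence treated as absent",
              sum(mismatch))
      sites <- sites[!mismatch, , drop = FALSE]
    }
  }
  key <- function(pid, pos) paste(pid, pos, sep = "\r")
  site_keys <- key(sites$protein_id, sites$position)
  m$phospho_zero <- key(m$protein_id, m$zero_pos) %in% site_keys
  m$phospho_plus4 <- key(m$protein_id, m$plus4_pos) %in% site_keys
  m
}

#' Read / write GMT gene-set files
#'
#' GMT: one set per line — set name, description, then member genes,
#' tab-delimited.
#'
#' @param path GMT file path.
#' @return `read_gmt`: named list of character vectors (attribute
#'   `description` holds the per-set description strings).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_validation("GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3L
  if (any(bad)) {
    stop_validation("GMT %s line %d: need name, description and >= 1 member",
                    path, which(bad)[1L])
  }
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    stop_validation("GMT %s: duplicated set name(s): %s", path,
                    paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  attr(sets, "description") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "description")
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Venn overlap between a candidate list and one gene set
#'
#' Exact set-intersection counts after defensive deduplication; symbols are
#' compared case-insensitively (both sides uppercased).
#'
#' @param candidate_genes character vector of candidate gene symbols.
#' @param gene_set character vector of gene-set members.
#' @return list with integer elements `both`, `candidates_only`, `set_only`.
#' @examples
#' venn_overlap(c("A", "B", "C"), c("B", "C", "D"))
#' @export
venn_overlap <- function(candidate_genes, gene_set) {
  cand <- unique(toupper(candidate_genes))
  gs <- unique(toupper(gene_set))
  both <- length(intersect(cand, gs))
  list(both = both,
       candidates_only = length(cand) - both,
       set_only = length(gs) - both)
}
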