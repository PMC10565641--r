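#' Uniform amino-acid background distribution
#'
#' @return Named numeric vector over the 20 standard residues summing to 1.
#' @export
uniform_background <- function() {
  setNames(rep(1 / length(AA_ALPHABET), length(AA_ALPHABET)), AA_ALPHABET)
}

check_background <- function(background) {
  if (is.null(names(background)) ||
      !setequal(names(background), AA_ALPHABET) ||
      any(background < 0) || abs(sum(background) - 1) > 1e-8) {
    stop_validation("background must be a named distribution over the 20 residues summing to 1")
  }
  background[AA_ALPHABET]
}

#' Analytic per-window match probability of a motif
#'
#' Under an i.i.d. background, the probability that a random window
#' satisfies the motif is the product over columns of the background mass of
#' each column's class (a wildcard contributes 1). For the validated CPD
#' `"[LP][LP][TS]P..[TSDE]"` on a uniform background this is
#' `(2/20)^3 * (1/20) * (4/20) = 1e-5`.
#'
#' @param motif a [cpd_motif()].
#' @param background named residue distribution (default uniform).
#' @return The per-window match probability.
#' @export
expected_match_rate <- function(motif, background = uniform_background()) {
  stopifnot(inherits(motif, "cpd_motif"))
  background <- check_background(background)
  prod(vapply(motif$columns, function(cl) {
    if (is.null(cl)) 1 else sum(background[cl])
  }, numeric(1)))
}

# One sequence satisfying the motif, drawn uniformly: an independent uniform
# draw per column from its class (wildcard -> full alphabet).
sample_motif_instance <- function(motif) {
  paste(vapply(motif$columns, function(cl) {
    if (is.null(cl)) sample(AA_ALPHABET, 1L) else if (length(cl) == 1L) cl
    else sample(cl, 1L)
  }, character(1)), collapse = "")
}

#' Generate a synthetic proteome with implanted degrons
#'
#' Proteins are i.i.d. draws from `background`; `n_implants` motif-matching
#' windows (drawn uniformly from the motif's satisfying sequences) are
#' written at random non-overlapping positions, at least one motif length
#' apart, and recorded in the implant truth table. With
#' `clean_background = TRUE`, accidental matches outside implant positions
#' are re-drawn (up to `max_retries` rounds per protein) and any survivors
#' are masked by forcing one class column outside all implants to a
#' non-class residue, so scanning recovers exactly the implants. Fully
#' reproducible from `seed`.
#'
#' @param n_proteins number of proteins.
#' @param protein_length a single length or a `c(min, max)` range.
#' @param background named residue distribution.
#' @param motif a [cpd_motif()]; required when `n_implants > 0` or
#'   `clean_background = TRUE`.
#' @param n_implants total number of implanted windows across the proteome.
#' @param clean_background scrub accidental (non-implant) matches.
#' @param seed integer seed.
#' @param max_retries redraw rounds per protein before masking (default 100).
#' @return list with `records` (protein data.frame, see [read_fasta()]) and
#'   `truth` (data.frame `protein_id`, `start_pos`, `implant_seq`).
#' @export
gen_proteome <- function(n_proteins, protein_length, background = uniform_background(),
                         motif = NULL, n_implants = 0L, clean_background = FALSE,
                         seed = 1L, max_retries = 100L) {
  background <- check_background(background)
  if ((n_implants > 0L || clean_background) && !inherits(motif, "cpd_motif")) {
    stop_validation("a motif is required for implanting or background cleaning")
  }
  with_seed(seed, {
    lens <- if (length(protein_length) == 2L) {
      sample(protein_length[1L]:protein_length[2L], n_proteins, replace = TRUE)
    } else {
      rep(as.integer(protein_length), n_proteins)
    }
    L <- if (!is.null(motif)) motif$length else 0L
    if (n_implants > 0L && any(lens < L)) {
      stop_validation("implant geometry impossible: protein shorter than the motif")
    }
    # assign implants to proteins
    implant_of <- if (n_implants > 0L) sort(sample.int(n_proteins, n_implants, replace = TRUE)) else integer(0)

    truth <- list()
    records <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      len <- lens[i]
      chars <- sample(AA_ALPHABET, len, replace = TRUE, prob = background)
      k_i <- sum(implant_of == i)
      starts <- integer(0)
      if (k_i > 0L) {
        # non-overlapping starts with >= L separation (so any non-implant
        # window overlaps at most one implant and is maskable outside it)
        for (r in seq_len(k_i)) {
          placed <- FALSE
          for (try in seq_len(1000L)) {
            s <- sample.int(len - L + 1L, 1L)
            if (all(abs(s - starts) >= 2L * L)) { starts <- c(starts, s); placed <- TRUE; break }
          }
          if (!placed) {
            stop_validation("implant geometry impossible: could not place %d implants in a %d-residue protein",
                            k_i, len)
          }
        }
        starts <- sort(starts)
        for (s in starts) {
          inst <- sample_motif_instance(motif)
          chars[s:(s + L - 1L)] <- str_chars(inst)
          truth[[length(truth) + 1L]] <- data.frame(
            protein_id = sprintf("SYN%04d", i), start_pos = s,
            implant_seq = inst, stringsAsFactors = FALSE)
        }
      }
      if (clean_background) {
        chars <- scrub_background(chars, motif, starts, background, max_retries)
      }
      records[[i]] <- data.frame(
        protein_id = sprintf("SYN%04d", i),
        gene_symbol = sprintf("GENE%04d", i),
        sequence = paste(chars, collapse = ""),
        stringsAsFactors = FALSE)
    }
    list(records = do.call(rbind, records),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(protein_id = character(0), start_pos = integer(0),
                      implant_seq = character(0)))
  })
}

# Remove accidental motif matches from a character vector, preserving the
# implanted windows. Redraw non-implant positions of accidental windows up
# to max_retries rounds, then mask deterministically by substituting a
# non-class residue at a class column outside all implants.
scrub_background <- function(chars, motif, implant_starts, background, max_retries) {
  L <- motif$length
  in_implant <- rep(FALSE, length(chars))
  for (s in implant_starts) in_implant[s:(s + L - 1L)] <- TRUE

  accidental <- function(ch) {
    st <- scan_starts(motif, paste(ch, collapse = ""))
    setdiff(st, implant_starts)
  }
  for (round in seq_len(max_retries)) {
    acc <- accidental(chars)
    if (!length(acc)) return(chars)
    for (s in acc) {
      idx <- s:(s + L - 1L)
      redraw <- idx[!in_implant[idx]]
      chars[redraw] <- sample(AA_ALPHABET, length(redraw), replace = TRUE, prob = background)
    }
  }
  # deterministic masking of whatever survived the retry budget
  repeat {
    acc <- accidental(chars)
    if (!length(acc)) break
    s <- acc[1L]
    masked <- FALSE
    # prefer the '0' column, then any class column, outside all implants
    zc <- motif$zero_column
    cand_cols <- c(if (!is.na(zc)) zc, seq_len(L))
    for (j in cand_cols) {
      cl <- motif$columns[[j]]
      pos <- s + j - 1L
      if (!is.null(cl) && !in_implant[pos]) {
        chars[pos] <- setdiff(AA_ALPHABET, cl)[1L]
        masked <- TRUE
        break
      }
    }
    if (!masked) {
      stop("cannot scrub accidental match at position ", s,
           ": no class column outside implanted windows")
    }
    log_msg("simulate", "masked accidental match at position %d after retry budget", s)
  }
  chars
}

#' Generate a gapless ortholog family from a reference
#'
#' Each ortholog mutates each site independently with probability
#' `sub_prob` to a uniformly chosen different residue; `preserve_window`
#' (`c(start, L)`) exempts the degron window from mutation. The output is an
#' identity (gapless) alignment.
#'
#' @param reference a protein record (list/row with `protein_id`,
#'   `gene_symbol`, `sequence`) or a plain sequence string.
#' @param n_orthologs number of non-reference members.
#' @param sub_prob per-site substitution probability in `[0, 1]`.
#' @param preserve_window optional `c(start, L)`, 1-based.
#' @param seed integer seed.
#' @return An [ortholog_family()] with members `ref` plus `orth01`, ...
#' @export
gen_ortholog_family <- function(reference, n_orthologs, sub_prob,
                                preserve_window = NULL, seed = 1L) {
  if (is.character(reference)) {
    reference <- list(protein_id = "ref", gene_symbol = "ref", sequence = reference)
  }
  if (sub_prob < 0 || sub_prob > 1) stop_validation("sub_prob must lie in [0, 1]")
  ref_chars <- str_chars(reference$sequence)
  n <- length(ref_chars)
  protect <- rep(FALSE, n)
  if (!is.null(preserve_window)) {
    idx <- preserve_window[1L]:(preserve_window[1L] + preserve_window[2L] - 1L)
    if (any(idx < 1L | idx > n)) stop_validation("preserve_window outside the reference")
    protect[idx] <- TRUE
  }
  with_seed(seed, {
    members <- c(setNames(list(ref_chars), reference$protein_id),
                 lapply(seq_len(n_orthologs), function(o) {
                   ch <- ref_chars
                   hit <- runif(n) < sub_prob & !protect
                   for (p in which(hit)) {
                     ch[p] <- sample(setdiff(AA_ALPHABET, ch[p]), 1L)
                   }
                   ch
                 }))
    names(members)[-1L] <- sprintf("orth%02d", seq_len(n_orthologs))
    ortholog_family(vapply(members, paste, character(1), collapse = ""),
                    reference_id = reference$protein_id,
                    gene_symbol = reference$gene_symbol)
  })
}

#' Generate a gene-set collection with one spiked (truly enriched) set
#'
#' Null sets are sampled uniformly without replacement from the universe;
#' the spiked set draws `spiked_overlap` members from the candidate list and
#' the remainder from the non-candidates, giving a set whose candidate
#' overlap is controlled (e.g. 5x the expected `size * n / N`). The truth
#' records which set was spiked.
#'
#' @param universe character vector of gene symbols.
#' @param n_sets total number of sets (including the spiked one).
#' @param set_size_range `c(min, max)` for null-set sizes.
#' @param spiked_size size of the spiked set.
#' @param spiked_overlap number of spiked-set members drawn from
#'   `candidates`.
#' @param candidates candidate gene list the spike is built against.
#' @param seed integer seed.
#' @return list with `sets` (named list, GMT-ready) and `truth` (list with
#'   `spiked_set` name and `spiked_overlap`).
#' @export
gen_genesets <- function(universe, n_sets, set_size_range, spiked_size,
                         spiked_overlap, candidates, seed = 1L) {
  universe <- unique(toupper(universe))
  candidates <- intersect(unique(toupper(candidates)), universe)
  if (spiked_overlap > length(candidates)) {
    stop_validation("spiked_overlap exceeds the candidate list")
  }
  if (spiked_size > length(universe) || max(set_size_range) > length(universe)) {
    stop_validation("set sizes must not exceed the universe")
  }
  if (spiked_size - spiked_overlap > length(universe) - length(candidates)) {
    stop_validation("not enough non-candidates to fill the spiked set")
  }
  with_seed(seed, {
    sizes <- sample(set_size_range[1L]:set_size_range[2L], n_sets - 1L, replace = TRUE)
    sets <- lapply(sizes, function(sz) sample(universe, sz))
    spiked <- c(sample(candidates, spiked_overlap),
                sample(setdiff(universe, candidates), spiked_size - spiked_overlap))
    spiked_index <- sample.int(n_sets, 1L)
    all_sets <- append(sets, list(spiked), after = spiked_index - 1L)
    names(all_sets) <- sprintf("SET%03d", seq_len(n_sets))
    list(sets = all_sets,
         truth = list(spiked_set = names(all_sets)[spiked_index],
                      spiked_overlap = spiked_overlap))
  })
}

#' Generate a synthetic phosphosite table for a candidate table
#'
#' Emits a site row at the '0' position of a random subset of matches (and
#' optionally at '+4'), plus decoy sites at random non-match positions —
#' enough structure to exercise phosphosite annotation.
#'
#' @param table a `candidate_table`.
#' @param records protein records the table was scanned from.
#' @param frac_zero fraction of matches receiving a '0' site.
#' @param frac_plus4 fraction receiving a '+4' site.
#' @param n_decoys random decoy sites elsewhere.
#' @param seed integer seed.
#' @return Phosphosite data.frame (`protein_id`, `position`, `residue`).
#' @export
gen_phosphosites <- function(table, records, frac_zero = 0.5, frac_plus4 = 0.3,
                             n_decoys = 20L, seed = 1L) {
  stopifnot(inherits(table, "candidate_table"))
  m <- table$matches
  seqs <- setNames(records$sequence, records$protein_id)
  with_seed(seed, {
    pick <- function(pos_col, frac) {
      if (!nrow(m)) return(NULL)
      sel <- which(runif(nrow(m)) < frac)
      if (!length(sel)) return(NULL)
      pos <- m[[pos_col]][sel]
      data.frame(protein_id = m$protein_id[sel], position = pos,
                 residue = substring(seqs[m$protein_id[sel]], pos, pos),
                 stringsAsFactors = FALSE)
    }
    decoys <- if (n_decoys > 0L) {
      pid <- sample(records$protein_id, n_decoys, replace = TRUE)
      pos <- vapply(pid, function(p) sample.int(nchar(seqs[[p]]), 1L), integer(1))
      data.frame(protein_id = pid, position = pos,
                 residue = substring(seqs[pid], pos, pos),
                 stringsAsFactors = FALSE)
    } else NULL
    out <- rbind(pick("zero_pos", frac_zero), pick("plus4_pos", frac_plus4), decoys)
    out <- out[!duplicated(paste(out$protein_id, out$position)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
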