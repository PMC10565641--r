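#' Pipeline configuration
#'
#' A flat key-value configuration for [run_pipeline()]. Exactly one motif
#' source must be given: `motif_pattern` (bracket notation) or `degron_tsv`
#' (a validated-degron table from which the consensus is derived with
#' `include_threshold` / `max_class`). Optional stages are enabled by their
#' inputs being present.
#'
#' Recognised keys: `motif_pattern`, `degron_tsv`, `window_length`,
#' `zero_column`, `include_threshold`, `max_class`, `proteome_fasta`,
#' `fasta_dialect`, `phosphosites_tsv`, `ortholog_dir`, `ortholog_ref_start`
#' (named list or NULL), `gmt`, `universe` (path to a one-symbol-per-line
#' file, or NULL for all scanned genes), `venn_set`, `conservation_threshold`,
#' `fdr_cut`, `out_dir`, `seed`.
#'
#' @param ... configuration keys.
#' @param config_file optional YAML file; explicit keys in `...` override it.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., config_file = NULL) {
  defaults <- list(
    motif_pattern = NULL, degron_tsv = NULL,
    window_length = 7L, zero_column = 3L,
    include_threshold = 0.2, max_class = 4L,
    proteome_fasta = NULL, fasta_dialect = "uniprot",
    phosphosites_tsv = NULL, ortholog_dir = NULL, ortholog_ref_start = NULL,
    gmt = NULL, universe = NULL, venn_set = NULL,
    conservation_threshold = 0.8, fdr_cut = 0.05,
    out_dir = "degscan_out", seed = 1L)
  cfg <- defaults
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop_validation("config file not found: %s", config_file)
    cfg <- modifyList(cfg, yaml::read_yaml(config_file))
  }
  override <- list(...)
  if (length(override)) cfg <- modifyList(cfg, override)

  has_pat <- !is.null(cfg$motif_pattern)
  has_tsv <- !is.null(cfg$degron_tsv)
  if (has_pat == has_tsv) {
    stop_validation("exactly one motif source must be given: motif_pattern or degron_tsv")
  }
  if (is.null(cfg$proteome_fasta)) stop_validation("proteome_fasta is required")
  for (key in c("degron_tsv", "proteome_fasta", "phosphosites_tsv", "gmt",
                "universe", "ortholog_dir")) {
    for (p in cfg[[key]]) {
      if (!is.null(p) && !file.exists(p)) stop_validation("%s: path does not exist: %s", key, p)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end degron discovery pipeline
#'
#' Stages: build or parse the consensus motif, scan the proteome, annotate
#' phosphosites (optional), score ortholog conservation (optional), test
#' gene-set overrepresentation and the Venn overlap with a designated set
#' (optional). Writes `motif.yaml`, `candidates.tsv`, `annotated.tsv`,
#' `conservation.tsv`, `enrichment.tsv`, `venn.json` and a `manifest.json`
#' recording package version, seed, parameters and input checksums; the run
#' is deterministic given identical inputs.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @return Invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- pipeline_config(config_file = config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    tool = "degscan", version = as.character(utils::packageVersion("degscan")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "out_dir")],
    inputs = list(), outputs = character(0), complete = FALSE)
  paths <- c(config$degron_tsv, config$proteome_fasta, config$phosphosites_tsv,
             config$gmt, config$universe)
  manifest$inputs <- as.list(tools::md5sum(paths))
  write_manifest <- function() {
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  write_manifest()
  run_stage <- function(stage, expr) {
    log_msg(stage, "starting")
    tryCatch(expr, error = function(e) {
      write_manifest()
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  motif <- run_stage("motif", {
    if (!is.null(config$motif_pattern)) {
      parse_pattern(config$motif_pattern)
    } else {
      catalog <- read_degron_table(config$degron_tsv,
                                   window_length = config$window_length,
                                   zero_column = config$zero_column)
      derive_consensus(build_pfm(catalog),
                       include_threshold = config$include_threshold,
                       max_class = config$max_class)
    }
  })
  write_motif(motif, out("motif.yaml"))
  log_msg("motif", "consensus: %s", serialize_pattern(motif))

  records <- run_stage("read", read_fasta(config$proteome_fasta, config$fasta_dialect))
  table <- run_stage("scan", scan_proteome(motif, records))
  write_candidates_tsv(table, out("candidates.tsv"))
  log_msg("scan", "%d match(es) in %d candidate gene(s) over %d protein(s)",
          nrow(table$matches), length(table$candidate_genes), nrow(records))

  annotated <- NULL
  if (!is.null(config$phosphosites_tsv)) {
    annotated <- run_stage("annotate", {
      sites <- read_phosphosites(config$phosphosites_tsv)
      annotate_phospho(table, sites, records)
    })
    write.table(annotated, out("annotated.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  conservation <- NULL
  if (!is.null(config$ortholog_dir)) {
    conservation <- run_stage("conserve", {
      files <- sort(list.files(config$ortholog_dir, pattern = "\\.(fa|fasta|aln)$",
                               full.names = TRUE))
      lapply(files, function(f) {
        fam <- read_alignment(f)
        ref_ungapped <- gsub("-", "", fam$members[[fam$reference_id]], fixed = TRUE)
        st <- config$ortholog_ref_start[[fam$reference_id]]
        if (is.null(st)) {
          # default: first motif match in the ungapped reference
          hits <- scan_starts(motif, ref_ungapped)
          if (!length(hits)) return(NULL)
          st <- hits[1L]
        }
        score_conservation(motif, fam, st)
      })
    })
    conservation <- Filter(Negate(is.null), conservation)
    write_conservation_tsv(conservation, out("conservation.tsv"),
                           report_threshold = config$conservation_threshold)
  }

  enrichment <- NULL
  venn <- NULL
  if (!is.null(config$gmt)) {
    stage <- run_stage("enrich", {
      sets <- do.call(c, lapply(config$gmt, read_gmt))
      universe <- if (is.null(config$universe)) {
        unique(records$gene_symbol)
      } else {
        readLines(config$universe)
      }
      res <- ora(table$candidate_genes, sets, universe)
      v <- if (!is.null(config$venn_set) && config$venn_set %in% names(sets)) {
        venn_overlap(table$candidate_genes, sets[[config$venn_set]])
      }
      list(res = res, venn = v)
    })
    enrichment <- stage$res
    venn <- stage$venn
    if (!is.null(venn)) {
      jsonlite::write_json(venn, out("venn.json"), auto_unbox = TRUE)
    }
    write.table(enrichment, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    sig <- sum(enrichment$q_value <= config$fdr_cut)
    log_msg("enrich", "%d set(s) at q <= %g", sig, config$fdr_cut)
  }

  manifest$outputs <- list.files(config$out_dir)
  manifest$complete <- TRUE
  write_manifest()
  log_msg("pipeline", "done; outputs in %s", config$out_dir)
  invisible(list(motif = motif, records = records, candidates = table,
                 annotated = annotated, conservation = conservation,
                 enrichment = enrichment, venn = venn,
                 out_dir = config$out_dir))
}
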