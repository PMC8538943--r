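# End-to-end pipeline orchestration and a thin command-line dispatcher.
# Every intermediate artifact is written to disk so each stage can be
# audited independently; all randomness flows from a single seed.

log_msg <- function(con, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full simulated barcoding pipeline
#'
#' simulate -> align -> distances -> barcode gap -> bootstrap tree ->
#' identification -> phenology, writing every intermediate artifact into
#' `out_dir` (FASTA, CSV and Newick).  With `aligner = "pre-aligned"` an
#' externally aligned FASTA can be supplied instead of the built-in
#' progressive aligner.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; all stage seeds derive from it.
#' @param complex a [complex_config()] (its seed is overridden by `seed`).
#' @param season a [season_config()] (ditto, `seed + 1`).
#' @param config an [assignment_config()].
#' @param aligner `"builtin"` or `"pre-aligned"`.
#' @param alignment_path aligned FASTA used when `aligner = "pre-aligned"`.
#' @return (invisibly) a list with the key in-memory results: `complex`,
#'   `season`, `alignment`, `gap`, `report`, `phenology`, `composition`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         complex = complex_config(),
                         season = season_config(),
                         config = assignment_config(),
                         aligner = c("builtin", "pre-aligned"),
                         alignment_path = NULL) {
  aligner <- match.arg(aligner)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logf))
  log_msg(logf, "larvalID %s | seed %d | %s", packageVersion("larvalID"),
          seed, format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  complex$seed <- as.integer(seed)
  season$seed <- as.integer(seed + 1L)
  log_msg(logf, "config: %d species, %d bp, inter K2P %.3f, threshold %.2f%%, support >%g%%, %d bootstrap replicates",
          complex$n_species, complex$seq_length, complex$interspecific_k2p,
          config$similarity_threshold, config$clade_support_threshold,
          config$bootstrap_replicates)

  cx <- simulate_reference_complex(complex)
  sn <- simulate_larval_season(cx, season)
  write_barcode_fasta(cx$references, file.path(out_dir, "references.fasta"))
  write_barcode_fasta(sn$queries, file.path(out_dir, "larvae.fasta"))
  write.csv(cx$truth, file.path(out_dir, "reference_truth.csv"),
            row.names = FALSE)
  write.csv(sn$records, file.path(out_dir, "larval_records.csv"),
            row.names = FALSE)
  log_msg(logf, "simulated %d references, %d larvae",
          length(cx$references), length(sn$queries))

  combined <- c(cx$references, sn$queries)
  aln <- if (aligner == "pre-aligned") {
    if (is.null(alignment_path)) stop("alignment_path required", call. = FALSE)
    read_alignment(alignment_path)
  } else {
    progressive_msa(combined)
  }
  write_alignment(aln, file.path(out_dir, "alignment.fasta"))
  log_msg(logf, "alignment: %d rows x %d columns", length(aln),
          attr(aln, "n_columns"))

  dm_k2p <- distance_matrix(aln, "k2p")
  dm_sim <- distance_matrix(aln, "similarity_percent")
  write_distance_csv(dm_k2p, file.path(out_dir, "distances_k2p.csv"))
  write_distance_csv(dm_sim, file.path(out_dir, "similarity_percent.csv"))

  labels <- species_labels(cx$references)
  gap <- barcode_gap_analysis(dm_k2p, labels)
  write_gap_report(gap, file.path(out_dir, "barcode_gap.csv"))
  log_msg(logf, "barcode gap present for %d of %d species",
          sum(gap$per_species$gap_present, na.rm = TRUE),
          nrow(gap$per_species))

  report <- assign_batch(aln, labels, config, seed = seed + 2L)
  write.csv(as.data.frame(report), file.path(out_dir, "assignments.csv"),
            row.names = FALSE)
  write_newick(attr(report, "tree"), file.path(out_dir, "tree.nwk"))
  log_msg(logf, "assigned %d queries: %d species calls, %d unassigned, %d conflicts",
          nrow(report), sum(!report$final_call %in% c("unassigned", "conflict")),
          sum(report$final_call == "unassigned"),
          sum(report$final_call == "conflict"))

  records <- sn$records
  records$species <- report$final_call[match(records$id, report$query_id)]
  records$species[is.na(records$species) |
                    records$species == "conflict"] <- "unassigned"
  phen <- build_phenology(records)
  write_phenology_csv(phen, file.path(out_dir, "phenology.csv"))
  comp <- composition_summary(records, "grass_type")
  write.csv(comp, file.path(out_dir, "composition.csv"), row.names = FALSE)
  log_msg(logf, "phenology: %d identified larvae, %d unassigned",
          nrow(phen$table), phen$n_unassigned)

  invisible(list(complex = cx, season = sn, alignment = aln, gap = gap,
                 report = report, phenology = phen, composition = comp))
}

# minimal --flag value parser; returns a named list
parse_flags <- function(argv) {
  out <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'", call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- argv[i + 1L]; i <- i + 2L
    }
  }
  out
}

cli_usage <- function() {
  paste(
    "usage: larvalid <subcommand> [--flag value ...]",
    "",
    "subcommands:",
    "  pipeline  --out DIR [--seed N] [--bootstrap N] [--threshold PCT] [--support PCT]",
    "  simulate  --out DIR [--seed N] [--queries N]",
    "  consensus --forward FQ --reverse FQ --out FASTA [--fwd-primer SEQ --rev-primer SEQ]",
    "  align     --in FASTA --out FASTA",
    "  distances --in ALN --out CSV [--metric k2p|p|similarity_percent]",
    "  gap       --in ALN --labels CSV --out CSV [--metric k2p]",
    "  tree      --in ALN --out NWK [--metric k2p] [--bootstrap N] [--seed N] [--outgroup ID]",
    "  identify  --ref FASTA --query FASTA --labels CSV --out CSV",
    "            [--threshold 91.25] [--support 70] [--bootstrap 1000] [--seed N]",
    "  phenology --records CSV --out CSV",
    sep = "\n")
}

#' Command-line entry point
#'
#' Dispatches the pipeline stages as subcommands.  Designed to be called
#' from a thin `Rscript` wrapper (see `inst/scripts/larvalid`); returns an
#' exit code instead of quitting so it is testable in-process.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return integer exit code: 0 success, 1 stage failure, 2 usage error.
#' @export
cli_main <- function(argv = character(0)) {
  if (!length(argv) || argv[1L] %in% c("-h", "--help", "help")) {
    message(cli_usage())
    return(2L)
  }
  sub <- argv[1L]
  known <- c("pipeline", "simulate", "consensus", "align", "distances",
             "gap", "tree", "identify", "phenology")
  if (!sub %in% known) {
    message("unknown subcommand '", sub, "'\n", cli_usage())
    return(2L)
  }
  flags <- tryCatch(parse_flags(argv[-1L]), error = function(e) e)
  if (inherits(flags, "error")) {
    message(conditionMessage(flags), "\n", cli_usage())
    return(2L)
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  res <- tryCatch({
    switch(sub,
      pipeline = {
        if (is.null(flags$out)) stop("pipeline: --out DIR is required")
        run_pipeline(flags$out, seed = as.integer(num(flags$seed, 1)),
                     config = assignment_config(
                       similarity_threshold = num(flags$threshold, 91.25),
                       clade_support_threshold = num(flags$support, 70),
                       bootstrap_replicates = num(flags$bootstrap, 1000)))
      },
      simulate = {
        if (is.null(flags$out)) stop("simulate: --out DIR is required")
        dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
        cc <- complex_config(seed = as.integer(num(flags$seed, 1)),
                             n_queries_per_species =
                               as.integer(num(flags$queries, 0)))
        cx <- simulate_reference_complex(cc)
        write_barcode_fasta(cx$references,
                            file.path(flags$out, "references.fasta"))
        if (!is.null(cx$queries))
          write_barcode_fasta(cx$queries, file.path(flags$out, "larvae.fasta"))
        write.csv(cx$truth, file.path(flags$out, "truth.csv"),
                  row.names = FALSE)
      },
      consensus = {
        fwd <- read_trace_fastq(check_file(flags$forward), "forward")
        rev_ <- read_trace_fastq(check_file(flags$reverse), "reverse")
        primers <- if (!is.null(flags$`fwd-primer`))
          primer_pair(flags$`fwd-primer`, flags$`rev-primer`) else NULL
        ids <- intersect(names(fwd), names(rev_))
        if (!length(ids)) stop("no read ids shared by the two files")
        cons <- lapply(ids, function(i)
          build_consensus(fwd[[i]], rev_[[i]], primers, id = i))
        out <- barcode_set(setNames(vapply(cons, `[[`, character(1),
                                           "sequence"), ids))
        write_barcode_fasta(out, flags$out)
      },
      align = {
        bs <- read_barcode_fasta(check_file(flags$`in`))
        write_alignment(progressive_msa(bs), flags$out)
      },
      distances = {
        aln <- read_alignment(check_file(flags$`in`))
        m <- if (is.null(flags$metric)) "k2p" else flags$metric
        write_distance_csv(distance_matrix(aln, m), flags$out)
      },
      gap = {
        aln <- read_alignment(check_file(flags$`in`))
        meta <- read_metadata_csv(check_file(flags$labels))
        labels <- setNames(as.character(meta$species), meta$id)
        m <- if (is.null(flags$metric)) "k2p" else flags$metric
        gap <- barcode_gap_analysis(distance_matrix(aln, m), labels)
        write_gap_report(gap, flags$out)
      },
      tree = {
        aln <- read_alignment(check_file(flags$`in`))
        m <- if (is.null(flags$metric)) "k2p" else flags$metric
        tr <- bootstrap_tree(aln, m,
                             n_replicates = as.integer(num(flags$bootstrap,
                                                           100)),
                             seed = as.integer(num(flags$seed, 1)))
        if (!is.null(flags$outgroup))
          tr <- ape::root(tr, flags$outgroup, resolve.root = TRUE)
        write_newick(tr, flags$out)
      },
      identify = {
        refs <- read_barcode_fasta(check_file(flags$ref),
                                   metadata = flags$labels)
        qry <- read_barcode_fasta(check_file(flags$query))
        combined <- c(refs, qry)
        aln <- progressive_msa(combined)
        cfg <- assignment_config(
          similarity_threshold = num(flags$threshold, 91.25),
          clade_support_threshold = num(flags$support, 70),
          bootstrap_replicates = num(flags$bootstrap, 1000))
        rep <- assign_batch(aln, species_labels(refs), cfg,
                            seed = as.integer(num(flags$seed, 1)),
                            query_ids = names(qry$seq))
        write.csv(as.data.frame(rep), flags$out, row.names = FALSE)
      },
      phenology = {
        rec <- read.csv(check_file(flags$records), stringsAsFactors = FALSE)
        phen <- build_phenology(rec)
        write_phenology_csv(phen, flags$out)
        comp <- composition_summary(rec, "grass_type")
        write.csv(comp, paste0(flags$out, ".composition.csv"),
                  row.names = FALSE)
      })
    0L
  }, error = function(e) {
    message("error in stage '", sub, "': ", conditionMessage(e))
    1L
  })
  res
}

check_file <- function(path) {
  if (is.null(path)) stop("required input file flag missing", call. = FALSE)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  path
}
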