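# Sequence records, FASTA/FASTQ ingest and consensus-contig assembly.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")
IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", D = "H", H = "D", V = "B", N = "N", "-" = "-")
LIFE_STAGES <- c("adult", "larva", "unknown")
LOCI <- c("COI", "ITS2", "18S", "other")

#' Normalise a nucleotide string
#'
#' Uppercases, maps RNA-style `U` to `T`, and verifies that only IUPAC codes
#' (optionally `-`) remain.
#'
#' @param seq character vector of sequences.
#' @param allow_gap allow the gap character `-` (alignment context)?
#' @param what label used in error messages.
#' @return normalised character vector.
#' @keywords internal
normalize_seq <- function(seq, allow_gap = FALSE, what = "sequence") {
  seq <- chartr("u", "T", toupper(seq))
  seq <- chartr("U", "T", seq)
  ok_chars <- c(IUPAC_CHARS, if (allow_gap) "-")
  bad <- !vapply(strsplit(seq, ""), function(ch) all(ch %in% ok_chars),
                 logical(1))
  if (any(bad)) {
    ch <- strsplit(seq[which(bad)[1L]], "")[[1L]]
    pos <- which(!ch %in% ok_chars)[1L]
    stop(sprintf("invalid character '%s' at position %d in %s",
                 ch[pos], pos, what), call. = FALSE)
  }
  seq
}

#' Construct a set of barcode sequence records
#'
#' A `barcode_set` couples unaligned sequences with specimen metadata
#' (species label, life stage, location, collection date, head-capsule
#' width, locus).  It is the common currency of the ingest and
#' identification stages.
#'
#' @param seq named character vector of IUPAC nucleotide sequences; names are
#'   specimen ids and must be unique and non-empty.
#' @param meta optional data frame keyed by `id` with any of the columns
#'   `species`, `stage`, `location`, `date`, `head_capsule_mm`, `locus`.
#'   Records without metadata receive empty/unknown defaults.
#' @return an object of class `barcode_set`: a list with elements `seq`
#'   (named character) and `meta` (data frame, one row per sequence).
#' @examples
#' bs <- barcode_set(c(q1 = "ACGT", q2 = "acgt"))
#' bs$seq
#' @export
barcode_set <- function(seq, meta = NULL) {
  ids <- names(seq)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must have a non-empty id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ids: ", paste(dup, collapse = ", "), call. = FALSE)
  if (any(!nzchar(seq))) {
    stop("empty sequence for id(s): ",
         paste(ids[!nzchar(seq)], collapse = ", "), call. = FALSE)
  }
  seq <- vapply(seq_along(seq), function(i)
    normalize_seq(seq[[i]], what = paste0("sequence '", ids[i], "'")),
    character(1))
  names(seq) <- ids
  full <- data.frame(id = ids, species = "", stage = "unknown",
                     location = "", date = as.Date(NA),
                     head_capsule_mm = NA_real_, locus = "other",
                     stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (!"id" %in% names(meta))
      stop("metadata must contain an 'id' column", call. = FALSE)
    extra <- setdiff(meta$id, ids)
    if (length(extra))
      warning("metadata ids absent from sequences: ",
              paste(extra, collapse = ", "), call. = FALSE)
    idx <- match(full$id, meta$id)
    for (col in intersect(names(meta),
                          c("species", "stage", "location", "locus"))) {
      v <- as.character(meta[[col]][idx])
      full[[col]][!is.na(idx) & !is.na(v)] <- v[!is.na(idx) & !is.na(v)]
    }
    if ("date" %in% names(meta))
      full$date[!is.na(idx)] <- as.Date(as.character(meta$date[idx[!is.na(idx)]]))
    if ("head_capsule_mm" %in% names(meta))
      full$head_capsule_mm[!is.na(idx)] <-
        as.numeric(meta$head_capsule_mm[idx[!is.na(idx)]])
  }
  full$stage[!full$stage %in% LIFE_STAGES] <- "unknown"
  full$locus[!full$locus %in% LOCI] <- "other"
  structure(list(seq = seq, meta = full), class = "barcode_set")
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("barcode_set: %d sequences (%d labelled)\n",
              length(x$seq), sum(nzchar(x$meta$species))))
  rng <- range(nchar(x$seq))
  cat(sprintf("  lengths %d-%d bp; stages: %s\n", rng[1], rng[2],
              paste(sprintf("%s=%d", names(table(x$meta$stage)),
                            table(x$meta$stage)), collapse = ", ")))
  invisible(x)
}

#' @export
length.barcode_set <- function(x) length(x$seq)

#' @export
`[.barcode_set` <- function(x, i) {
  ids <- names(x$seq)[i]
  barcode_set(x$seq[i], x$meta[match(ids, x$meta$id), , drop = FALSE])
}

#' Combine barcode sets
#' @param ... `barcode_set` objects.
#' @return a single `barcode_set`; ids must remain unique.
#' @export
c.barcode_set <- function(...) {
  sets <- list(...)
  barcode_set(do.call(c, lapply(sets, `[[`, "seq")),
              do.call(rbind, lapply(sets, `[[`, "meta")))
}

#' Species labels of a barcode set
#'
#' @param x a `barcode_set`.
#' @return named character vector id -> species; unlabelled records are `""`.
#' @export
species_labels <- function(x) {
  stopifnot(inherits(x, "barcode_set"))
  setNames(x$meta$species, x$meta$id)
}

# Structural pre-scan so malformed FASTA errors can name the offending line;
# actual parsing is delegated to Biostrings.
check_fasta_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty))
    stop("FASTA parse error in '", path, "': file is empty", call. = FALSE)
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop(sprintf("FASTA parse error in '%s': line %d does not start with '>'",
                 path, nonempty[1]), call. = FALSE)
  is_hdr <- startsWith(trimws(lines[nonempty]), ">")
  hdr_pos <- nonempty[is_hdr]
  runlen <- diff(c(which(is_hdr), length(nonempty) + 1L)) - 1L
  if (any(runlen == 0L))
    stop(sprintf("FASTA parse error in '%s': empty sequence after header at line %d",
                 path, hdr_pos[which(runlen == 0L)[1L]]), call. = FALSE)
  invisible(TRUE)
}

#' Read barcode sequences from FASTA, optionally joining metadata
#'
#' Sequences are uppercased on ingest and `U` is mapped to `T`.  The record
#' id is the first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @param metadata optional path to a CSV keyed by `id` with columns among
#'   `id,species,stage,location,date,head_capsule_mm,locus` (dates ISO-8601).
#' @return a [barcode_set()].
#' @export
read_barcode_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_fasta_structure(path)
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "[ \t]"), `[[`, character(1), 1L)
  seqs <- setNames(as.character(x), ids)
  meta <- if (!is.null(metadata)) read_metadata_csv(metadata) else NULL
  barcode_set(seqs, meta)
}

#' Read a specimen metadata table
#'
#' Comma-separated with a header row; dates ISO-8601.
#'
#' @param path CSV file with an `id` column.
#' @return data frame.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(meta))
    stop("metadata file '", path, "' lacks an 'id' column", call. = FALSE)
  meta
}

#' Write a barcode set to FASTA
#'
#' Sequences are wrapped at 80 columns.  Gap characters are rejected:
#' unaligned sequence files must not contain `-` (use [write_alignment()]
#' for alignments).
#'
#' @param x a `barcode_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(x, path) {
  stopifnot(inherits(x, "barcode_set"))
  if (!length(x$seq)) stop("no records to write", call. = FALSE)
  if (any(grepl("-", x$seq, fixed = TRUE)))
    stop("sequences contain '-': gaps are only valid inside alignments",
         call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::BStringSet(x$seq), path, width = 80L)
  invisible(path)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Ambiguity codes map to their complements (R<->Y, S<->S, W<->W, K<->M,
#' B<->V, D<->H, N<->N); `-` is preserved so aligned rows can be flipped.
#'
#' @param seq a single IUPAC string.
#' @return the reverse complement, same length.
#' @examples
#' reverse_complement("AAN")  # "NTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- normalize_seq(seq, allow_gap = TRUE)
  ch <- rev(strsplit(seq, "")[[1L]])
  paste(IUPAC_COMPLEMENT[ch], collapse = "")
}

#' Construct a directional Sanger-style read
#'
#' @param bases IUPAC string.
#' @param qualities optional integer vector of per-base quality scores
#'   (0-60), same length as `bases`.
#' @param direction `"forward"` or `"reverse"`.
#' @return an object of class `trace_read`.
#' @export
trace_read <- function(bases, qualities = NULL,
                       direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  bases <- normalize_seq(bases, what = "read")
  if (!is.null(qualities)) {
    qualities <- as.integer(qualities)
    if (length(qualities) != nchar(bases))
      stop("qualities and bases differ in length", call. = FALSE)
    if (any(qualities < 0L | qualities > 93L))
      stop("quality scores must be in [0, 93]", call. = FALSE)
  }
  structure(list(direction = direction, bases = bases, qualities = qualities),
            class = "trace_read")
}

#' @export
print.trace_read <- function(x, ...) {
  cat(sprintf("trace_read (%s): %d bp%s\n", x$direction, nchar(x$bases),
              if (is.null(x$qualities)) ", no qualities"
              else sprintf(", mean quality %.1f", mean(x$qualities))))
  invisible(x)
}

#' Read paired Sanger-style reads from FASTQ
#'
#' Qualities are decoded with the Sanger/offset-33 convention.
#'
#' @param path FASTQ file.
#' @param direction direction assigned to every read in the file.
#' @return list of `trace_read` objects, named by read id.
#' @export
read_trace_fastq <- function(path, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # Biostrings warns about dropping its own metadata columns here; benign
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- as(Biostrings::quality(x), "IntegerList")
  ids <- vapply(strsplit(names(x), "[ \t]"), `[[`, character(1), 1L)
  out <- lapply(seq_along(x), function(i)
    trace_read(as.character(x[[i]]), as.integer(quals[[i]]), direction))
  setNames(out, ids)
}

#' Write trace reads to FASTQ (Sanger offset-33)
#' @param reads named list of `trace_read` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(reads)) {
    r <- reads[[id]]
    q <- r$qualities
    if (is.null(q)) q <- rep(40L, nchar(r$bases))
    writeLines(c(paste0("@", id), r$bases, "+",
                 intToUtf8(q + 33L, multiple = FALSE)), con)
  }
  invisible(path)
}

#' A primer pair, both written 5'->3' on their own strands
#' @param forward_primer,reverse_primer ACGT strings.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward_primer, reverse_primer) {
  fp <- normalize_seq(forward_primer, what = "forward primer")
  rp <- normalize_seq(reverse_primer, what = "reverse primer")
  if (!nzchar(fp) || !nzchar(rp)) stop("primers must be non-empty", call. = FALSE)
  structure(list(forward_primer = fp, reverse_primer = rp),
            class = "primer_pair")
}

#' Quality-trim the ends of a read
#'
#' Bases are removed from each end until a sliding window of length
#' `window` has mean quality at or above `quality_threshold`; within that
#' first acceptable window, any remaining end bases individually below the
#' threshold are also dropped (so a stretch of bad calls just inside an
#' acceptable window does not survive).  The interior is never touched.
#' Reads without qualities are returned unchanged.
#'
#' @param read a `trace_read`.
#' @param quality_threshold minimum mean window quality (default 20).
#' @param window sliding window length (default 10); clipped to the read
#'   length for very short reads.
#' @return the trimmed `trace_read`.
#' @export
trim_read <- function(read, quality_threshold = 20, window = 10) {
  stopifnot(inherits(read, "trace_read"))
  q <- read$qualities
  if (is.null(q)) return(read)
  n <- length(q)
  w <- min(window, n)
  wmeans <- as.numeric(stats::filter(q, rep(1 / w, w), sides = 1))
  # wmeans[i] = mean(q[(i-w+1)..i]); window starting at s ends at s+w-1
  starts_ok <- which(wmeans[seq(w, n)] >= quality_threshold)
  if (!length(starts_ok))
    stop("read empty after quality trimming (all windows below threshold)",
         call. = FALSE)
  s <- starts_ok[1L]
  e <- starts_ok[length(starts_ok)] + w - 1L
  # a mean-acceptable window may still begin/end with poor calls
  while (s <= e && q[s] < quality_threshold) s <- s + 1L
  while (e >= s && q[e] < quality_threshold) e <- e - 1L
  if (s > e)
    stop("read empty after quality trimming (all windows below threshold)",
         call. = FALSE)
  trace_read(substr(read$bases, s, e), q[s:e], read$direction)
}

# Locate `primer` within the first `search_bp` bases of `seq` allowing up to
# `max_mismatch` mismatches (IUPAC-aware).  Returns the end position of the
# best (leftmost, fewest-mismatch) match, or 0L.
match_primer_start <- function(seq, primer, max_mismatch = 1L,
                               search_bp = 60L) {
  sm <- iupac_masks_cpp(seq)
  pm <- iupac_masks_cpp(primer)
  lp <- length(pm)
  if (lp > length(sm)) return(0L)
  last_start <- min(search_bp, length(sm) - lp + 1L)
  best <- c(pos = 0L, mm = max_mismatch + 1L)
  for (s in seq_len(last_start)) {
    mm <- sum(bitwAnd(sm[s:(s + lp - 1L)], pm) == 0L)
    if (mm < best["mm"]) best <- c(pos = s, mm = mm)
  }
  if (best[["mm"]] <= max_mismatch) best[["pos"]] + lp - 1L else 0L
}

#' Build a consensus contig from a forward and a reverse read
#'
#' Reproduces the classic Sanger processing chain: both reads are
#' quality-trimmed, the reverse read is reverse complemented, the two are
#' joined by an overlap (free-end-gap) pairwise alignment, disagreements are
#' resolved by base agreement, then by quality, else `N`; finally the primer
#' sequences are located (exactly or with one mismatch, within 60 bp of the
#' ends) and excised.
#'
#' @param forward,reverse `trace_read` objects.
#' @param primers a [primer_pair()], or `NULL` to skip primer excision.
#' @param quality_threshold,window trimming parameters, see [trim_read()].
#' @param scheme alignment scoring, see [scoring_scheme()].
#' @param min_identity minimum identity over the aligned overlap (default
#'   0.6) below which the reads are declared non-overlapping.
#' @param min_overlap minimum number of aligned overlap columns (default 15);
#'   shorter overlaps are treated as spurious.
#' @param expected_length length window (default `c(600, 700)`, the usual
#'   COI barcode span); a consensus outside it is flagged with a warning,
#'   not an error, so other loci remain usable.
#' @param id id given to the consensus record.
#' @param locus locus tag recorded on the consensus.
#' @return an object of class `consensus_contig`: list with `id`,
#'   `sequence`, `locus`, `overlap_length`, `overlap_identity`,
#'   `length_flag`.
#' @export
build_consensus <- function(forward, reverse, primers = NULL,
                            quality_threshold = 20, window = 10,
                            scheme = scoring_scheme(),
                            min_identity = 0.6, min_overlap = 15,
                            expected_length = c(600, 700),
                            id = "consensus", locus = "COI") {
  stopifnot(inherits(forward, "trace_read"), inherits(reverse, "trace_read"))
  fwd <- trim_read(forward, quality_threshold, window)
  rev_tr <- trim_read(reverse, quality_threshold, window)
  if (!nchar(fwd$bases) || !nchar(rev_tr$bases))
    stop("read empty after trimming", call. = FALSE)
  rc_bases <- reverse_complement(rev_tr$bases)
  rc_quals <- if (is.null(rev_tr$qualities)) NULL else rev(rev_tr$qualities)

  aln <- pairwise_global(fwd$bases, rc_bases, scheme, mode = "overlap")
  ra <- strsplit(aln$alignment[[1L]], "")[[1L]]
  rb <- strsplit(aln$alignment[[2L]], "")[[1L]]
  ia <- cumsum(ra != "-")   # source position in fwd for each column
  ib <- cumsum(rb != "-")
  both <- ra != "-" & rb != "-"
  n_overlap <- sum(both)
  agree <- both & (bitwAnd(iupac_masks_cpp(aln$alignment[[1L]]),
                           iupac_masks_cpp(aln$alignment[[2L]])) > 0L)
  identity <- if (n_overlap) sum(agree) / n_overlap else 0
  if (n_overlap < min_overlap || identity < min_identity)
    stop(sprintf(paste0("reads do not overlap (aligned overlap %d columns, ",
                        "identity %.1f%%)"), n_overlap, 100 * identity),
         call. = FALSE)

  qa <- fwd$qualities
  qb <- rc_quals
  cons <- character(length(ra))
  for (k in seq_along(ra)) {
    if (ra[k] == "-") cons[k] <- rb[k]
    else if (rb[k] == "-") cons[k] <- ra[k]
    else if (ra[k] == rb[k]) cons[k] <- ra[k]
    else {
      q1 <- if (is.null(qa)) NA_integer_ else qa[ia[k]]
      q2 <- if (is.null(qb)) NA_integer_ else qb[ib[k]]
      cons[k] <- if (!is.na(q1) && !is.na(q2) && q1 != q2) {
        if (q1 > q2) ra[k] else rb[k]
      } else "N"
    }
  }
  consensus <- paste(cons, collapse = "")

  if (!is.null(primers)) {
    stopifnot(inherits(primers, "primer_pair"))
    e <- match_primer_start(consensus, primers$forward_primer)
    if (e > 0L) consensus <- substr(consensus, e + 1L, nchar(consensus))
    s <- match_primer_start(reverse_complement(consensus),
                            primers$reverse_primer)
    if (s > 0L) consensus <- substr(consensus, 1L, nchar(consensus) - s)
    if (!nzchar(consensus))
      stop("consensus empty after primer excision", call. = FALSE)
  }

  len_ok <- nchar(consensus) >= expected_length[1L] &&
    nchar(consensus) <= expected_length[2L]
  if (!len_ok)
    warning(sprintf("consensus length %d bp outside expected window [%d, %d]",
                    nchar(consensus), expected_length[1L],
                    expected_length[2L]), call. = FALSE)
  structure(list(id = id, sequence = consensus, locus = locus,
                 overlap_length = n_overlap, overlap_identity = identity,
                 length_flag = !len_ok),
            class = "consensus_contig")
}

#' @export
print.consensus_contig <- function(x, ...) {
  cat(sprintf("consensus_contig '%s' (%s): %d bp, overlap %d cols (%.1f%% id)%s\n",
              x$id, x$locus, nchar(x$sequence), x$overlap_length,
              100 * x$overlap_identity,
              if (x$length_flag) " [length flag]" else ""))
  invisible(x)
}
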