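# Pairwise global/overlap alignment and a small progressive multiple
# aligner.  The built-in aligner keeps the pipeline self-contained for
# simulation and testing; externally aligned FASTA (read_alignment) is the
# recommended path for publication-grade work.

#' Alignment scoring scheme
#'
#' Affine gap model: a gap run of length L costs
#' `gap_open + (L - 1) * gap_extend`.  The default gap opening of -5 is
#' deliberately stiff: length-conserved barcodes such as COI carry no real
#' indels, and a cheaper opening (e.g. -2) lets chance off-by-one matches
#' between divergent 640 bp sequences out-score the true gap-free
#' alignment, introducing spurious gap columns.
#'
#' @param match,mismatch per-column scores; `match` must exceed `mismatch`.
#' @param gap_open,gap_extend non-positive gap penalties.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1,
                           gap_open = -5, gap_extend = -2) {
  if (match <= mismatch) stop("match score must exceed mismatch", call. = FALSE)
  if (gap_open > 0 || gap_extend > 0)
    stop("gap penalties must be <= 0", call. = FALSE)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Pairwise global or overlap alignment (Needleman-Wunsch)
#'
#' Ambiguity codes score as a match whenever their base sets intersect
#' (e.g. `R` vs `A`).  Tie-breaking is deterministic: diagonal, then up,
#' then left.  In `overlap` mode terminal gaps are free, which is the mode
#' used to join forward and reverse Sanger reads.
#'
#' @param a,b IUPAC nucleotide strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @param mode `"global"` or `"overlap"`.
#' @return list with `alignment` (character vector of the two padded rows)
#'   and `score`.
#' @examples
#' pairwise_global("ACGT", "AGT")$score
#' @export
pairwise_global <- function(a, b, scheme = scoring_scheme(),
                            mode = c("global", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "scoring_scheme"))
  if (!is.character(a) || !is.character(b) || !nzchar(a) || !nzchar(b))
    stop("both sequences must be non-empty strings", call. = FALSE)
  a <- normalize_seq(a, what = "sequence a")
  b <- normalize_seq(b, what = "sequence b")
  res <- nw_align_cpp(a, b, scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend,
                      if (mode == "overlap") 1L else 0L)
  list(alignment = c(a = res$a, b = res$b), score = res$score, mode = mode)
}

#' Construct a multiple alignment
#'
#' @param rows named character vector of equal-length IUPAC strings
#'   (gaps `-` allowed); names are unique row ids.
#' @return an object of class `barcode_aln` (named character vector with
#'   attribute `n_columns`).
#' @export
barcode_aln <- function(rows) {
  ids <- names(rows)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("alignment rows need unique non-empty ids", call. = FALSE)
  rows <- vapply(seq_along(rows), function(i)
    normalize_seq(rows[[i]], allow_gap = TRUE,
                  what = paste0("row '", ids[i], "'")), character(1))
  names(rows) <- ids
  len <- nchar(rows)
  if (length(unique(len)) != 1L) {
    off <- ids[len != len[1L]][1L]
    stop("ragged alignment: row '", off, "' has length ", len[ids == off][1L],
         ", expected ", len[1L], call. = FALSE)
  }
  if (len[1L] == 0L) stop("alignment has zero columns", call. = FALSE)
  m <- aln_matrix(rows)
  if (any(colSums(m != "-") == 0L))
    stop("alignment contains an all-gap column", call. = FALSE)
  structure(rows, n_columns = unname(len[1L]), class = "barcode_aln")
}

# character matrix view (rows x columns) of an alignment
aln_matrix <- function(rows) {
  do.call(rbind, strsplit(unclass(rows), ""))
}

#' @export
print.barcode_aln <- function(x, ...) {
  cat(sprintf("barcode_aln: %d sequences x %d columns\n",
              length(x), attr(x, "n_columns")))
  invisible(x)
}

#' Remove gaps from alignment rows
#' @param aln a `barcode_aln` (or named character vector).
#' @return named character vector of de-gapped sequences.
#' @export
degap <- function(aln) {
  setNames(gsub("-", "", unclass(aln), fixed = TRUE), names(aln))
}

# 5 x L frequency profile (A,C,G,T,gap) of a set of aligned rows; ambiguity
# codes spread fractionally over their base sets.
profile_of <- function(rows) {
  m <- aln_matrix(rows)
  L <- ncol(m)
  prof <- matrix(0, 5L, L)
  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  for (r in seq_len(nrow(m))) {
    masks <- iupac_masks_cpp(paste(m[r, ], collapse = ""))
    isgap <- m[r, ] == "-"
    prof[5L, isgap] <- prof[5L, isgap] + 1
    nb <- (bitwAnd(masks, 1L) > 0) + (bitwAnd(masks, 2L) > 0) +
      (bitwAnd(masks, 4L) > 0) + (bitwAnd(masks, 8L) > 0)
    for (x in 1:4) {
      w <- !isgap & bitwAnd(masks, base_bit[x]) > 0
      prof[x, w] <- prof[x, w] + 1 / nb[w]
    }
  }
  prof / nrow(m)
}

# merge two sub-alignments by profile-profile alignment
merge_profiles <- function(rows_a, rows_b, scheme) {
  res <- profile_align_cpp(profile_of(rows_a), profile_of(rows_b),
                           scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend)
  ops <- res$ops
  idx_a <- integer(length(ops)); idx_b <- integer(length(ops))
  ia <- 0L; ib <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] != 2L) ia <- ia + 1L
    if (ops[k] != 1L) ib <- ib + 1L
    idx_a[k] <- if (ops[k] == 2L) 0L else ia
    idx_b[k] <- if (ops[k] == 1L) 0L else ib
  }
  expand <- function(rows, idx) {
    m <- aln_matrix(rows)
    out <- matrix("-", nrow(m), length(idx))
    out[, idx > 0L] <- m[, idx[idx > 0L], drop = FALSE]
    setNames(apply(out, 1L, paste, collapse = ""), names(rows))
  }
  c(expand(rows_a, idx_a), expand(rows_b, idx_b))
}

#' Progressive multiple sequence alignment
#'
#' A basic progressive aligner: a guide tree is built by neighbour joining
#' on p-distances of all pairwise alignments, then profiles are merged
#' leaf-to-root by profile-profile global alignment.  De-gapping any output
#' row recovers its input sequence exactly.  Intended for low-divergence,
#' length-conserved barcode sets; supply an external alignment via
#' [read_alignment()] for anything harder.
#'
#' @param x a [barcode_set()] or named character vector of sequences (>= 2).
#' @param scheme a [scoring_scheme()].
#' @return a [barcode_aln()].
#' @export
progressive_msa <- function(x, scheme = scoring_scheme()) {
  seqs <- if (inherits(x, "barcode_set")) x$seq else x
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences to align", call. = FALSE)
  ids <- names(seqs)
  if (n == 2L) {
    pa <- pairwise_global(seqs[[1L]], seqs[[2L]], scheme)
    return(barcode_aln(setNames(pa$alignment, ids)))
  }
  pd <- matrix(0, n, n, dimnames = list(ids, ids))
  min_ident <- 1
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      pa <- pairwise_global(seqs[[i]], seqs[[j]], scheme)
      ra <- strsplit(pa$alignment[[1L]], "")[[1L]]
      rb <- strsplit(pa$alignment[[2L]], "")[[1L]]
      both <- ra != "-" & rb != "-"
      p <- if (any(both)) sum(ra[both] != rb[both]) / sum(both) else 1
      pd[i, j] <- pd[j, i] <- p
      min_ident <- min(min_ident, 1 - p)
    }
  }
  if (min_ident < 0.5)
    warning(sprintf(paste0("lowest pairwise identity %.0f%% is below 50%%; ",
                           "progressive alignment may be unreliable"),
                    100 * min_ident), call. = FALSE)
  guide <- ape::nj(as.dist(pd))
  guide$edge.length[guide$edge.length < 0] <- 0
  merge_node <- function(node) {
    if (node <= n) return(seqs[guide$tip.label[node]])
    kids <- guide$edge[guide$edge[, 1L] == node, 2L]
    sub <- lapply(kids, merge_node)
    acc <- sub[[1L]]
    for (k in seq_along(sub)[-1L]) acc <- merge_profiles(acc, sub[[k]], scheme)
    acc
  }
  rows <- merge_node(n + 1L)
  # drop any column that ended up all-gap (cannot arise from merges, but be safe)
  m <- aln_matrix(rows)
  keep <- colSums(m != "-") > 0L
  rows <- setNames(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""),
                   names(rows))
  barcode_aln(rows[ids])
}

#' Read an aligned FASTA file
#' @param path aligned FASTA; all rows must have equal length.
#' @return a [barcode_aln()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  check_fasta_structure(path)
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "[ \t]"), `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate ids in alignment: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  barcode_aln(setNames(as.character(x), ids))
}

#' Write an alignment to FASTA (wrapped at 80 columns)
#' @param aln a `barcode_aln`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "barcode_aln"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(unclass(aln)), path,
                              width = 80L)
  invisible(path)
}
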