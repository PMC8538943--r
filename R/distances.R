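# p-distance, percent similarity and Kimura-2-parameter distances with
# pairwise deletion; the numerical core of the barcode-gap analysis and the
# similarity-threshold identification.

# integer-code aligned rows: A=0, C=1, G=2, T=3 (transitions preserve
# parity), anything else (gap or ambiguity) = -1 and is excluded from
# comparable sites (pairwise deletion).
encode_acgt <- function(rows) {
  m <- aln_matrix(rows)
  out <- matrix(-1L, nrow(m), ncol(m))
  out[m == "A"] <- 0L; out[m == "C"] <- 1L
  out[m == "G"] <- 2L; out[m == "T"] <- 3L
  rownames(out) <- names(rows)
  out
}

#' Count substitutions between two aligned rows
#'
#' Columns where either row holds a gap or an ambiguity code are excluded
#' (pairwise deletion).  Transitions are A<->G and C<->T; all other
#' differing pairs are transversions.
#'
#' @param row_a,row_b aligned IUPAC strings of equal length.
#' @return object of class `subst_counts`: list with `sites_compared`,
#'   `transitions`, `transversions`, and the proportions `P` and `Q`.
#' @examples
#' count_substitutions("ACGT", "GCGT")  # one transition
#' @export
count_substitutions <- function(row_a, row_b) {
  row_a <- normalize_seq(row_a, allow_gap = TRUE, what = "row_a")
  row_b <- normalize_seq(row_b, allow_gap = TRUE, what = "row_b")
  if (nchar(row_a) != nchar(row_b))
    stop("aligned rows must have equal length", call. = FALSE)
  cc <- subst_count_cpp(encode_acgt(c(a = row_a, b = row_b)))
  ns <- cc$sites[1L, 2L]
  if (ns == 0L) stop("no comparable sites between the two rows", call. = FALSE)
  structure(list(sites_compared = ns,
                 transitions = cc$transitions[1L, 2L],
                 transversions = cc$transversions[1L, 2L],
                 P = cc$transitions[1L, 2L] / ns,
                 Q = cc$transversions[1L, 2L] / ns),
            class = "subst_counts")
}

#' @export
print.subst_counts <- function(x, ...) {
  cat(sprintf("subst_counts: %d sites, %d transitions (P=%.4f), %d transversions (Q=%.4f)\n",
              x$sites_compared, x$transitions, x$P, x$transversions, x$Q))
  invisible(x)
}

#' Proportion of differing sites (p-distance)
#' @inheritParams count_substitutions
#' @return number in \[0, 1\].
#' @export
p_distance <- function(row_a, row_b) {
  cc <- count_substitutions(row_a, row_b)
  cc$P + cc$Q
}

#' Percent sequence similarity
#'
#' `100 * (1 - p_distance)`; the scale on which the similarity threshold
#' (91.25 by default in [assignment_config()]) is expressed.
#'
#' @inheritParams count_substitutions
#' @return number in \[0, 100\].
#' @export
percent_similarity <- function(row_a, row_b) {
  100 * (1 - p_distance(row_a, row_b))
}

#' Kimura-2-parameter distance from transition/transversion proportions
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.  When an argument of a
#' logarithm is non-positive the distance is undefined (saturation) and an
#' error carrying P and Q is raised rather than silently clamping.
#'
#' @param P,Q transition and transversion proportions.
#' @return non-negative K2P distance.
#' @export
k2p_from_pq <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0)
    stop(sprintf("K2P distance undefined (saturation): P=%.4f, Q=%.4f", P, Q),
         call. = FALSE)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Kimura-2-parameter distance between two aligned rows
#' @inheritParams count_substitutions
#' @return non-negative K2P distance.
#' @seealso [k2p_from_pq()]
#' @export
k2p_distance <- function(row_a, row_b) {
  cc <- count_substitutions(row_a, row_b)
  k2p_from_pq(cc$P, cc$Q)
}

#' Pairwise distance matrix over an alignment
#'
#' @param aln a [barcode_aln()] (>= 2 rows).
#' @param metric `"k2p"`, `"p"`, or `"similarity_percent"`.
#' @return an object of class `barcode_dist`: a symmetric numeric matrix
#'   with zero diagonal (100 for `similarity_percent`) and attribute
#'   `metric`.  Row order follows the alignment; no sorting.
#' @export
distance_matrix <- function(aln, metric = c("k2p", "p", "similarity_percent")) {
  metric <- match.arg(metric)
  stopifnot(inherits(aln, "barcode_aln"))
  n <- length(aln)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  cc <- subst_count_cpp(encode_acgt(aln))
  ids <- names(aln)
  sites <- cc$sites; ts <- cc$transitions; tv <- cc$transversions
  off <- upper.tri(sites)
  if (any(sites[off] == 0L)) {
    bad <- which(sites == 0L & off, arr.ind = TRUE)[1L, ]
    stop(sprintf("no comparable sites between '%s' and '%s'",
                 ids[bad[1L]], ids[bad[2L]]), call. = FALSE)
  }
  P <- ts / pmax(sites, 1L)
  Q <- tv / pmax(sites, 1L)
  vals <- switch(metric,
    p = P + Q,
    similarity_percent = 100 * (1 - (P + Q)),
    k2p = {
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      if (any(a1[off] <= 0 | a2[off] <= 0)) {
        bad <- which((a1 <= 0 | a2 <= 0) & off, arr.ind = TRUE)[1L, ]
        stop(sprintf(
          "K2P distance undefined (saturation) between '%s' and '%s': P=%.4f, Q=%.4f",
          ids[bad[1L]], ids[bad[2L]], P[bad[1L], bad[2L]], Q[bad[1L], bad[2L]]),
          call. = FALSE)
      }
      -0.5 * log(a1) - 0.25 * log(a2)
    })
  diag(vals) <- if (metric == "similarity_percent") 100 else 0
  dimnames(vals) <- list(ids, ids)
  structure(vals, metric = metric, class = c("barcode_dist", "matrix"))
}

#' @export
print.barcode_dist <- function(x, ...) {
  cat(sprintf("barcode_dist (%s): %d x %d\n", attr(x, "metric"),
              nrow(x), ncol(x)))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))],
        digits = 4)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Convert a similarity matrix to its distance complement (and back)
#' @param x a `barcode_dist` with metric `similarity_percent` (or `p`).
#' @return a `barcode_dist` on the complementary scale.
#' @export
similarity_to_p <- function(x) {
  stopifnot(inherits(x, "barcode_dist"))
  met <- attr(x, "metric")
  if (met == "similarity_percent") {
    out <- (100 - unclass(x)) / 100
    structure(out, metric = "p", class = c("barcode_dist", "matrix"))
  } else if (met == "p") {
    out <- 100 * (1 - unclass(x))
    structure(out, metric = "similarity_percent",
              class = c("barcode_dist", "matrix"))
  } else stop("metric must be 'similarity_percent' or 'p'", call. = FALSE)
}

#' Write / read a square distance matrix as CSV
#' @param x a `barcode_dist`.
#' @param path CSV file (header row and row-name column).
#' @return `path` invisibly / a `barcode_dist`.
#' @export
write_distance_csv <- function(x, path) {
  stopifnot(inherits(x, "barcode_dist"))
  df <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @param metric metric recorded on the matrix read back.
#' @export
read_distance_csv <- function(path, metric = "k2p") {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  structure(m, metric = metric, class = c("barcode_dist", "matrix"))
}

#' Average percent similarity of a query to each species
#'
#' Compares the query row to every labelled reference row (the query's own
#' row is excluded) and averages percent similarity within species.
#'
#' @param query_id id of the query row in `aln`.
#' @param aln a [barcode_aln()] containing query and references.
#' @param labels named character vector id -> species; empty strings and
#'   `NA` mark unlabelled rows.
#' @return named numeric vector species -> mean percent similarity, sorted
#'   decreasingly.
#' @export
avg_similarity_by_species <- function(query_id, aln, labels) {
  stopifnot(inherits(aln, "barcode_aln"))
  if (!query_id %in% names(aln))
    stop("query '", query_id, "' not present in the alignment", call. = FALSE)
  labels <- labels[!is.na(labels) & nzchar(labels)]
  ref_ids <- setdiff(intersect(names(labels), names(aln)), query_id)
  if (!length(ref_ids))
    stop("no labelled reference rows in the alignment", call. = FALSE)
  sims <- vapply(ref_ids, function(r)
    percent_similarity(aln[[query_id]], aln[[r]]), numeric(1))
  out <- tapply(sims, labels[ref_ids], mean)
  sort(c(out), decreasing = TRUE)
}
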