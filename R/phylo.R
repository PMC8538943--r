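# Neighbour-joining trees with nonparametric bootstrap support, clade
# queries and Newick I/O.  Trees are ape "phylo" objects, stored unrooted
# with a trifurcating root; internal node labels carry integer percent
# bootstrap support.

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]).  Negative branch-length
#' estimates are clamped to zero; the number of clamped edges is recorded in
#' the attribute `clamped_edges`.
#'
#' @param dm a [distance_matrix()] result (metric `k2p` or `p`) or a plain
#'   symmetric matrix with labels; a similarity matrix is rejected — convert
#'   it first with [similarity_to_p()].
#' @return an unrooted `phylo` tree whose tip set equals the matrix labels.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "barcode_dist") &&
      identical(attr(dm, "metric"), "similarity_percent"))
    stop("neighbor joining needs a distance, not a similarity matrix; ",
         "convert with similarity_to_p()", call. = FALSE)
  m <- unclass(dm)
  if (is.null(rownames(m))) stop("distance matrix must have labels",
                                 call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tr <- ape::nj(as.dist(m))
  n_clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped_edges") <- n_clamped
  tr
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree.
# Each bipartition is represented by the side NOT containing the
# lexicographically smallest tip label, so keys are comparable across trees
# on the same leaf set.
tree_bipartitions <- function(phy) {
  tips <- phy$tip.label
  n <- length(tips)
  ref <- sort(tips)[1L]
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keys <- character(0)
  sides <- list()
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) <= 1L || length(side) >= n) next
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1L || length(side) >= n) next  # trivial after flip
    key <- paste(sort(side), collapse = "\r")
    if (!key %in% keys) {
      keys <- c(keys, key)
      sides[[length(sides) + 1L]] <- sort(side)
    }
  }
  names(sides) <- keys
  sides
}

# map each internal node (> n tips) to its bipartition key ("" for trivial)
node_bipartition_keys <- function(phy) {
  tips <- phy$tip.label
  n <- length(tips)
  ref <- sort(tips)[1L]
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  keys <- character(length(pp))
  for (i in seq_along(pp)) {
    side <- labs[pp[[i]]]
    if (length(side) >= n) { keys[i] <- ""; next }
    if (ref %in% side) side <- setdiff(tips, side)
    keys[i] <- if (length(side) <= 1L || length(side) >= n) "" else
      paste(sort(side), collapse = "\r")
  }
  keys  # keys[i] belongs to internal node n + i
}

#' Neighbour-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement `n_replicates` times;
#' a tree is rebuilt per replicate and each internal edge of the original
#' tree receives as support the percentage of replicates containing the same
#' bipartition.  Replicates whose distances are undefined (saturation or no
#' comparable sites) are skipped and counted; a warning is raised if more
#' than 10% are skipped.
#'
#' @param aln a [barcode_aln()].
#' @param metric distance metric, `"k2p"` (default) or `"p"`.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param seed integer seed making the resampling reproducible.
#' @return a `phylo` tree with integer percent supports in `node.label`
#'   (empty for the root and other trivial nodes) and attributes
#'   `n_replicates`, `n_skipped`.
#' @export
bootstrap_tree <- function(aln, metric = c("k2p", "p"), n_replicates = 100L,
                           seed = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(aln, "barcode_aln"))
  if (n_replicates < 1L) stop("n_replicates must be >= 1", call. = FALSE)
  dm <- distance_matrix(aln, metric)
  phy <- neighbor_joining(dm)
  nc <- attr(aln, "n_columns")
  mat <- aln_matrix(aln)
  ids <- names(aln)

  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  counts <- integer(0)
  keys0 <- names(tree_bipartitions(phy))
  counts <- setNames(integer(length(keys0)), keys0)
  n_ok <- 0L; n_skip <- 0L
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    rows <- setNames(apply(mat[, cols, drop = FALSE], 1L, paste, collapse = ""),
                     ids)
    rep_dm <- tryCatch(
      distance_matrix(barcode_aln(rows), metric),
      error = function(e) NULL)
    if (is.null(rep_dm)) { n_skip <- n_skip + 1L; next }
    rep_tr <- neighbor_joining(rep_dm)
    n_ok <- n_ok + 1L
    hit <- keys0 %in% names(tree_bipartitions(rep_tr))
    counts[hit] <- counts[hit] + 1L
  }
  if (n_skip > 0.1 * n_replicates)
    warning(sprintf("%d of %d bootstrap replicates skipped (undefined distances)",
                    n_skip, n_replicates), call. = FALSE)
  if (n_ok == 0L) stop("all bootstrap replicates failed", call. = FALSE)
  support <- round(100 * counts / n_ok)
  node_keys <- node_bipartition_keys(phy)
  phy$node.label <- ifelse(node_keys == "", "",
                           as.character(support[node_keys]))
  attr(phy, "n_replicates") <- n_replicates
  attr(phy, "n_skipped") <- n_skip
  attr(phy, "clamped_edges") <- attr(phy, "clamped_edges")
  phy
}

# support (integer percent or NA) of the bipartition given by a set of tips
bipartition_support <- function(phy, side) {
  if (is.null(phy$node.label)) return(NA_integer_)
  tips <- phy$tip.label
  ref <- sort(tips)[1L]
  if (ref %in% side) side <- setdiff(tips, side)
  key <- paste(sort(side), collapse = "\r")
  node_keys <- node_bipartition_keys(phy)
  hit <- which(node_keys == key)
  if (!length(hit)) return(NA_integer_)
  val <- phy$node.label[hit[1L]]
  if (is.na(val) || !nzchar(val)) NA_integer_ else as.integer(round(as.numeric(val)))
}

#' Monophyly test and smallest containing clade
#'
#' In the unrooted sense: a leaf subset is monophyletic iff some edge
#' bipartition separates exactly that subset from all other leaves
#' (singletons and the full leaf set are trivially monophyletic).  The
#' smallest clade (bipartition side) containing the subset is returned
#' regardless, together with its bootstrap support when present.
#'
#' @param tree a `phylo` tree.
#' @param leaf_subset non-empty character vector of tip labels.
#' @return list with `monophyletic` (logical), `clade` (tip labels of the
#'   smallest containing clade) and `support` (integer percent or `NA`).
#' @export
is_monophyletic <- function(tree, leaf_subset) {
  tips <- tree$tip.label
  if (!length(leaf_subset)) stop("leaf_subset is empty", call. = FALSE)
  unknown <- setdiff(leaf_subset, tips)
  if (length(unknown))
    stop("unknown tip id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  leaf_subset <- unique(leaf_subset)
  k <- length(leaf_subset)
  n <- length(tips)
  if (k == 1L || k == n) {
    return(list(monophyletic = TRUE, clade = sort(leaf_subset),
                support = NA_integer_))
  }
  bip <- tree_bipartitions(tree)
  # candidate clades: both sides of every bipartition, plus the whole tree
  cand <- c(bip, lapply(bip, function(s) sort(setdiff(tips, s))))
  sizes <- vapply(cand, length, integer(1))
  contains <- vapply(cand, function(s) all(leaf_subset %in% s), logical(1))
  mono <- any(contains & sizes == k)
  inside <- which(contains)
  if (!length(inside)) {
    clade <- sort(tips)       # only the whole tree contains the subset
    supp <- NA_integer_
  } else {
    best <- inside[order(sizes[inside],
                         vapply(cand[inside], paste, character(1),
                                collapse = "\r"))][1L]
    clade <- cand[[best]]
    supp <- bipartition_support(tree, clade)
  }
  list(monophyletic = mono, clade = clade, support = supp)
}

#' Write / read trees in Newick format
#'
#' Bootstrap supports travel as internal node labels.  Round-tripping
#' preserves topology, branch lengths (6 decimals) and supports.
#'
#' @param tree a `phylo` tree.
#' @param path file path.
#' @return `path` invisibly / a `phylo` tree.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("Newick parse error: unbalanced ')' at position ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth, " unclosed '(' at end of input",
         call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e)
                   stop("Newick parse error: ", conditionMessage(e),
                        call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree in file", call. = FALSE)
  tr
}
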