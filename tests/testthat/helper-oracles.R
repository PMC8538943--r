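# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: alignment scores come from exhaustive path
# enumeration, distances from per-column loops, trees from the generating
# topology.

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

chars_match <- function(x, y) {
  length(intersect(iupac_sets[[x]], iupac_sets[[y]])) > 0
}

# score an explicit alignment path (ops: "D" diagonal, "U" consume a,
# "L" consume b) under gap run cost open + (len-1) * extend; in overlap
# mode the leading and trailing gap runs are free.
score_ops <- function(ops, av, bv, match, mismatch, open, ext,
                      overlap = FALSE) {
  runs <- rle(ops)
  free_head <- overlap && runs$values[1] != "D"
  free_tail <- overlap && runs$values[length(runs$values)] != "D"
  i <- 0; j <- 0; s <- 0
  for (r in seq_along(runs$values)) {
    op <- runs$values[r]; len <- runs$lengths[r]
    if (op == "D") {
      for (k in seq_len(len)) {
        i <- i + 1; j <- j + 1
        s <- s + if (chars_match(av[i], bv[j])) match else mismatch
      }
    } else {
      if (op == "U") i <- i + len else j <- j + len
      free <- (r == 1 && free_head) || (r == length(runs$values) && free_tail)
      if (!free) s <- s + open + (len - 1) * ext
    }
  }
  s
}

# exhaustive optimal alignment score by enumerating every path (fine for
# |a|, |b| <= 6: Delannoy(6,6) = 8989 paths)
brute_force_align_score <- function(a, b, match = 1, mismatch = -1,
                                    open = -5, ext = -2, overlap = FALSE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  rec <- function(i, j, ops) {
    if (i == na && j == nb) {
      best <<- max(best, score_ops(ops, av, bv, match, mismatch, open, ext,
                                   overlap))
      return(invisible(NULL))
    }
    if (i < na) rec(i + 1, j, c(ops, "U"))
    if (j < nb) rec(i, j + 1, c(ops, "L"))
    if (i < na && j < nb) rec(i + 1, j + 1, c(ops, "D"))
  }
  rec(0, 0, character(0))
  best
}

# per-column substitution-count oracle with pairwise deletion
loop_count_oracle <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  acgt <- c("A", "C", "G", "T")
  sites <- 0; ts <- 0; tv <- 0
  for (k in seq_along(av)) {
    if (!(av[k] %in% acgt) || !(bv[k] %in% acgt)) next
    sites <- sites + 1
    if (av[k] != bv[k]) {
      pur <- c("A", "G")
      same_class <- (av[k] %in% pur) == (bv[k] %in% pur)
      if (same_class) ts <- ts + 1 else tv <- tv + 1
    }
  }
  list(sites = sites, ts = ts, tv = tv)
}

# unrooted topology equality via ape's Robinson-Foulds distance
same_topology <- function(t1, t2) {
  ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small labelled complex + alignment reused by identification tests
make_test_complex <- function(seed = 42, n_refs = 3, n_queries = 2) {
  cx <- simulate_reference_complex(
    complex_config(n_refs_per_species = n_refs,
                   n_queries_per_species = n_queries, seed = seed))
  aln <- progressive_msa(c(cx$references, cx$queries))
  list(cx = cx, aln = aln, labels = species_labels(cx$references))
}
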