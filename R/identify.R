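# Species assignment of unknown larval sequences by (1) average-similarity
# thresholding and (2) supported-clade tree placement, plus barcode-gap
# analysis validating that assignment is justified at all.

#' Assignment configuration
#'
#' @param similarity_threshold percent similarity a species mean must reach
#'   before the species is a candidate (default 91.25, the COI threshold
#'   calibrated on the most variable billbug species).
#' @param clade_support_threshold bootstrap percent a clade must exceed
#'   (strictly) for a tree-based call (default 70).
#' @param bootstrap_replicates replicates used when a tree has to be built
#'   (default 1000).
#' @param conflict_policy how to combine the two methods:
#'   `"require_agreement"` (default; disagreement gives `"conflict"`, a
#'   single unassigned method defers to the other), `"similarity_wins"`, or
#'   `"tree_wins"`.
#' @param near_tie_margin percentage-point margin under which the two best
#'   candidate species are flagged as a near tie (default 0.5).
#' @return object of class `assignment_config`.
#' @export
assignment_config <- function(similarity_threshold = 91.25,
                              clade_support_threshold = 70,
                              bootstrap_replicates = 1000L,
                              conflict_policy = c("require_agreement",
                                                  "similarity_wins",
                                                  "tree_wins"),
                              near_tie_margin = 0.5) {
  conflict_policy <- match.arg(conflict_policy)
  if (similarity_threshold <= 0 || similarity_threshold > 100 ||
      clade_support_threshold <= 0 || clade_support_threshold > 100)
    stop("thresholds must lie in (0, 100]", call. = FALSE)
  structure(list(similarity_threshold = similarity_threshold,
                 clade_support_threshold = clade_support_threshold,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 conflict_policy = conflict_policy,
                 near_tie_margin = near_tie_margin),
            class = "assignment_config")
}

#' Assign a species to a query by average percent similarity
#'
#' Species whose mean similarity to the query reaches the threshold are
#' candidates; the call is the candidate with the highest mean (or
#' `"unassigned"` if there is none).  Two candidates within
#' `near_tie_margin` percentage points are flagged in `notes`.
#'
#' @param query_id id of the query row.
#' @param aln a [barcode_aln()] with query and labelled references.
#' @param labels named character vector id -> species (unlabelled: `""`).
#' @param config an [assignment_config()].
#' @return list with `query_id`, `similarity_call`, `similarity_scores`,
#'   `notes`.
#' @export
assign_by_similarity <- function(query_id, aln, labels,
                                 config = assignment_config()) {
  scores <- avg_similarity_by_species(query_id, aln, labels)
  cand <- scores[scores >= config$similarity_threshold]
  notes <- character(0)
  if (!length(cand)) {
    call <- "unassigned"
  } else {
    call <- names(cand)[1L]
    if (length(cand) >= 2L && cand[1L] - cand[2L] < config$near_tie_margin)
      notes <- c(notes, sprintf("near tie: %s (%.2f) vs %s (%.2f)",
                                names(cand)[1L], cand[1L],
                                names(cand)[2L], cand[2L]))
  }
  list(query_id = query_id, similarity_call = call,
       similarity_scores = scores, notes = notes)
}

#' Assign a species to a query by supported-clade placement
#'
#' Finds the smallest *well-supported* clade (unrooted bipartition side
#' with bootstrap support strictly above the threshold) that contains the
#' query and at least one labelled reference; the full leaf set, trivially
#' present in every replicate, serves as the last-resort clade.  If every
#' labelled reference in that clade belongs to one species, that species
#' is called; otherwise `"unassigned"` (mixed clade).  Looking for the
#' smallest supported clade, rather than gating the very smallest clade on
#' its support, mirrors how larvae are read off a bootstrap tree: shallow
#' intraspecific nodes are rarely supported, yet the species clade is.
#'
#' @inheritParams assign_by_similarity
#' @param tree optional pre-built bootstrap tree over `aln` (see
#'   [bootstrap_tree()]); built on the fly when `NULL`.
#' @param seed seed used if the tree must be built.
#' @return list with `query_id`, `tree_call`, `clade_support`, `notes`.
#' @export
assign_by_tree <- function(query_id, aln, labels,
                           config = assignment_config(), tree = NULL,
                           seed = NULL) {
  stopifnot(inherits(aln, "barcode_aln"))
  if (!query_id %in% names(aln))
    stop("query '", query_id, "' not present in the alignment", call. = FALSE)
  if (length(aln) < 3L)
    stop("need at least 3 sequences for tree-based assignment", call. = FALSE)
  if (is.null(tree))
    tree <- bootstrap_tree(aln, "k2p", config$bootstrap_replicates, seed)
  labels <- labels[!is.na(labels) & nzchar(labels)]
  ref_ids <- setdiff(intersect(names(labels), tree$tip.label), query_id)
  if (!length(ref_ids)) stop("no labelled references in the tree", call. = FALSE)

  tips <- tree$tip.label
  bip <- tree_bipartitions(tree)
  # one support lookup per bipartition key, shared by both sides
  node_keys <- node_bipartition_keys(tree)
  supp_by_key <- setNames(rep(-1L, length(bip)), names(bip))
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    for (i in seq_along(node_keys)) {
      if (nzchar(node_keys[i]) && !is.na(lab[i]) &&
          node_keys[i] %in% names(supp_by_key))
        supp_by_key[node_keys[i]] <- as.integer(round(lab[i]))
    }
  }
  cand <- c(bip, lapply(bip, function(s) sort(setdiff(tips, s))))
  supports <- unname(supp_by_key[rep(names(bip), 2L)])
  # the full leaf set is present in every replicate by construction
  cand <- c(cand, list(sort(tips)))
  supports <- c(supports, 100L)
  has_query <- vapply(cand, function(s) query_id %in% s, logical(1))
  n_ref <- vapply(cand, function(s) sum(ref_ids %in% s), integer(1))
  ok <- which(has_query & n_ref > 0L &
                supports > config$clade_support_threshold)
  notes <- character(0)
  if (!length(ok)) {
    return(list(query_id = query_id, tree_call = "unassigned",
                clade_support = NA_integer_,
                notes = "no supported clade joins query and references"))
  }
  sizes <- vapply(cand[ok], length, integer(1))
  minimal <- ok[sizes == min(sizes)]
  # species carried by each minimal supported clade; several minimal clades
  # that disagree (possible in unrooted trees, where a clade can be the
  # complement of a cohesive group elsewhere) mean the placement is
  # ambiguous, not a call
  sp_sets <- lapply(cand[minimal],
                    function(s) unique(unname(labels[intersect(s, ref_ids)])))
  sp_all <- unique(unlist(sp_sets))
  supp <- max(supports[minimal])
  if (length(sp_all) == 1L) {
    call <- sp_all
  } else {
    call <- "unassigned"
    notes <- c(notes,
               paste("supported placement ambiguous or mixed:",
                     paste(sp_all, collapse = ", ")))
  }
  list(query_id = query_id, tree_call = call, clade_support = supp,
       notes = notes)
}

#' Assign a species to a query by both methods
#'
#' Runs [assign_by_similarity()] and [assign_by_tree()] and combines the
#' calls according to `conflict_policy`.
#'
#' @inheritParams assign_by_tree
#' @return object of class `assignment_result`: list with `query_id`,
#'   `similarity_call`, `similarity_scores`, `tree_call`, `clade_support`,
#'   `final_call` (a species, `"unassigned"`, or `"conflict"`), `notes`.
#' @export
assign_species <- function(query_id, aln, labels,
                           config = assignment_config(), tree = NULL,
                           seed = NULL) {
  s <- assign_by_similarity(query_id, aln, labels, config)
  t <- assign_by_tree(query_id, aln, labels, config, tree, seed)
  combined <- combine_calls(s$similarity_call, t$tree_call,
                            config$conflict_policy)
  structure(list(query_id = query_id,
                 similarity_call = s$similarity_call,
                 similarity_scores = s$similarity_scores,
                 tree_call = t$tree_call,
                 clade_support = t$clade_support,
                 final_call = combined$call,
                 notes = c(s$notes, t$notes, combined$notes)),
            class = "assignment_result")
}

combine_calls <- function(sim, tre, policy) {
  notes <- character(0)
  if (sim == tre) return(list(call = sim, notes = notes))
  if (policy == "require_agreement") {
    if (sim == "unassigned") {
      notes <- "similarity method unassigned; using tree call"
      call <- tre
    } else if (tre == "unassigned") {
      notes <- "tree method unassigned; using similarity call"
      call <- sim
    } else {
      notes <- sprintf("methods disagree: similarity=%s, tree=%s", sim, tre)
      call <- "conflict"
    }
  } else if (policy == "similarity_wins") {
    call <- if (sim != "unassigned") sim else tre
    notes <- sprintf("methods differ (similarity=%s, tree=%s); policy %s",
                     sim, tre, policy)
  } else {
    call <- if (tre != "unassigned") tre else sim
    notes <- sprintf("methods differ (similarity=%s, tree=%s); policy %s",
                     sim, tre, policy)
  }
  list(call = call, notes = notes)
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("assignment '%s': final=%s (similarity=%s, tree=%s%s)\n",
              x$query_id, x$final_call, x$similarity_call, x$tree_call,
              if (!is.na(x$clade_support))
                sprintf(", support %d%%", x$clade_support) else ""))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Assign species to every unlabelled sequence in an alignment
#'
#' Builds one bootstrap tree over the full alignment and places every
#' query in it, so a batch costs a single tree.
#'
#' @param aln a [barcode_aln()] containing references and queries.
#' @param labels named character vector id -> species; rows with empty
#'   labels are treated as queries.
#' @param config an [assignment_config()].
#' @param seed seed for the bootstrap resampling.
#' @param query_ids optional explicit query set (default: all unlabelled
#'   rows).
#' @return data frame of class `assignment_report` with one row per query:
#'   `query_id`, `similarity_call`, `best_score`, `second_best_species`,
#'   `second_best_score`, `tree_call`, `clade_support`, `final_call`,
#'   `notes`.
#' @export
assign_batch <- function(aln, labels, config = assignment_config(),
                         seed = NULL, query_ids = NULL) {
  stopifnot(inherits(aln, "barcode_aln"))
  labels_full <- labels
  if (is.null(query_ids)) {
    lab <- labels[names(aln)]
    query_ids <- names(aln)[is.na(lab) | !nzchar(lab)]
  }
  if (!length(query_ids)) stop("no query sequences found", call. = FALSE)
  tree <- bootstrap_tree(aln, "k2p", config$bootstrap_replicates, seed)
  rows <- lapply(query_ids, function(q) {
    r <- assign_species(q, aln, labels_full, config, tree = tree)
    sc <- r$similarity_scores
    data.frame(query_id = q,
               similarity_call = r$similarity_call,
               best_score = unname(sc[1L]),
               second_best_species = if (length(sc) >= 2L) names(sc)[2L] else NA,
               second_best_score = if (length(sc) >= 2L) unname(sc[2L]) else NA,
               tree_call = r$tree_call,
               clade_support = r$clade_support,
               final_call = r$final_call,
               notes = paste(r$notes, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assignment_report", "data.frame")
  attr(out, "tree") <- tree
  out
}

#' Barcode-gap analysis
#'
#' Splits all pairwise distances into intraspecific (same label) and
#' interspecific (different labels) sets; for each species reports the
#' maximum intraspecific distance, the minimum interspecific distance to
#' any other species, their difference (`gap_size`) and whether a gap is
#' present (`gap_size > 0`).  Non-overlap of the pooled distributions is
#' the classic indication of clear species boundaries.
#'
#' @param dm a [distance_matrix()] with metric `k2p` (default) or `p`.
#' @param labels named character vector id -> species; unlabelled ids are
#'   ignored.
#' @param n_bins number of shared histogram bins over the pooled range
#'   (default 30).
#' @return object of class `barcode_gap`: list with `per_species` (data
#'   frame), `intra`, `inter` (numeric vectors of pooled distances),
#'   `breaks`, `intra_counts`, `inter_counts`, `metric`.
#' @export
barcode_gap_analysis <- function(dm, labels, n_bins = 30L) {
  stopifnot(inherits(dm, "barcode_dist"))
  metric <- attr(dm, "metric")
  if (metric == "similarity_percent")
    stop("barcode gap analysis needs a distance metric (k2p or p)",
         call. = FALSE)
  labels <- labels[!is.na(labels) & nzchar(labels)]
  ids <- intersect(rownames(dm), names(labels))
  if (length(unique(labels[ids])) < 2L)
    stop("need >= 2 species for barcode gap analysis", call. = FALSE)
  m <- unclass(dm)[ids, ids, drop = FALSE]
  sp <- labels[ids]
  same <- outer(sp, sp, "==")
  ut <- upper.tri(m)
  intra <- m[ut & same]
  inter <- m[ut & !same]
  species <- sort(unique(sp))
  per <- do.call(rbind, lapply(species, function(s) {
    mine <- sp == s
    intra_s <- m[mine, mine, drop = FALSE]
    max_intra <- if (sum(mine) >= 2L)
      max(intra_s[upper.tri(intra_s)]) else NA_real_
    min_inter <- min(m[mine, !mine, drop = FALSE])
    gap <- min_inter - max_intra
    data.frame(species = s, n = sum(mine), max_intra = max_intra,
               min_inter = min_inter, gap_size = gap,
               gap_present = !is.na(gap) & gap > 0,
               stringsAsFactors = FALSE)
  }))
  pooled <- c(intra, inter)
  breaks <- seq(min(pooled), max(pooled), length.out = n_bins + 1L)
  if (breaks[1L] == breaks[length(breaks)])
    breaks <- breaks + seq(0, 1e-9, length.out = n_bins + 1L)
  hcount <- function(v) if (length(v))
    hist(v, breaks = breaks, plot = FALSE, include.lowest = TRUE,
         right = TRUE)$counts else integer(n_bins)
  structure(list(per_species = per, intra = intra, inter = inter,
                 breaks = breaks, intra_counts = hcount(intra),
                 inter_counts = hcount(inter), metric = metric),
            class = "barcode_gap")
}

#' @export
print.barcode_gap <- function(x, ...) {
  cat(sprintf("barcode_gap (%s): %d intra / %d inter pairwise distances\n",
              x$metric, length(x$intra), length(x$inter)))
  print(x$per_species, row.names = FALSE, digits = 4)
  n_gap <- sum(x$per_species$gap_present, na.rm = TRUE)
  cat(sprintf("gap present for %d of %d species\n", n_gap,
              nrow(x$per_species)))
  invisible(x)
}

#' Write a barcode-gap report (per-species table + histogram) to CSV
#' @param x a `barcode_gap`.
#' @param path per-species CSV path; the histogram table goes to
#'   `paste0(path, ".hist.csv")` unless `hist_path` is given.
#' @param hist_path optional histogram CSV path.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(x, path, hist_path = NULL) {
  stopifnot(inherits(x, "barcode_gap"))
  write.csv(x$per_species, path, row.names = FALSE)
  if (is.null(hist_path)) hist_path <- paste0(path, ".hist.csv")
  write.csv(data.frame(bin_lower = x$breaks[-length(x$breaks)],
                       bin_upper = x$breaks[-1L],
                       intra_count = x$intra_counts,
                       inter_count = x$inter_counts), hist_path,
            row.names = FALSE)
  invisible(path)
}
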