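# Similarity-threshold and tree-placement assignment, barcode-gap analysis.

test_that("similarity assignment calls exact matches and respects the threshold", {
  aln <- barcode_aln(c(q = strrep("ACGT", 10),
                       x1 = strrep("ACGT", 10), x2 = strrep("ACGT", 10),
                       y1 = paste0(strrep("TGCA", 5), strrep("ACGT", 5))))
  labels <- c(x1 = "X", x2 = "X", y1 = "Y")
  r <- assign_by_similarity("q", aln, labels)
  expect_identical(r$similarity_call, "X")
  expect_equal(r$similarity_scores[["X"]], 100)

  # all species below threshold -> unassigned
  aln2 <- barcode_aln(c(q = strrep("A", 40),
                        x1 = paste0(strrep("A", 30), strrep("C", 10)),
                        y1 = paste0(strrep("C", 10), strrep("A", 30))))
  r2 <- assign_by_similarity("q", aln2, c(x1 = "X", y1 = "Y"))
  expect_identical(r2$similarity_call, "unassigned")  # 75% < 91.25
  expect_error(assign_by_similarity("ghost", aln, labels), "not present")
})

test_that("near ties within 0.5 points are flagged but still called", {
  # X at 95%, Y at 94.75% over 400 sites (20 vs 21 diffs)
  base <- strrep("A", 400)
  mk <- function(k) paste0(strrep("C", k), strrep("A", 400 - k))
  aln <- barcode_aln(c(q = base, x1 = mk(20), y1 = mk(21)))
  r <- assign_by_similarity("q", aln, c(x1 = "X", y1 = "Y"))
  expect_identical(r$similarity_call, "X")
  expect_match(paste(r$notes, collapse = " "), "near tie")
})

test_that("raising the similarity threshold never creates a call", {
  tc <- make_test_complex(seed = 37)
  queries <- tc$cx$truth$id[tc$cx$truth$role == "query"]
  thresholds <- c(85, 91.25, 95, 99, 99.9)
  calls <- sapply(thresholds, function(th) {
    cfg <- assignment_config(similarity_threshold = th)
    vapply(queries, function(q)
      assign_by_similarity(q, tc$aln, tc$labels, cfg)$similarity_call,
      character(1))
  })
  for (k in seq_along(thresholds)[-1]) {
    was_unassigned <- calls[, k - 1] == "unassigned"
    expect_true(all(calls[was_unassigned, k] == "unassigned"))
  }
})

test_that("tree placement works for a 3-sequence degenerate input", {
  aln <- barcode_aln(c(q = strrep("ACGT", 10),
                       x1 = strrep("ACGT", 10),
                       x2 = paste0("T", substr(strrep("ACGT", 10), 2, 40))))
  r <- assign_by_tree("q", aln, c(x1 = "X", x2 = "X"),
                      assignment_config(bootstrap_replicates = 20), seed = 1)
  expect_identical(r$tree_call, "X")
})

test_that("a query between two species stays unassigned by tree placement", {
  set.seed(41)
  ancA <- random_acgt(300)
  ancB <- mutate_k2p(ancA, 0.3, 4)
  # exact midpoint: the query shares exactly half of the differing sites
  # with each species, so column resampling flips its placement
  av <- strsplit(ancA, "")[[1]]; bv <- strsplit(ancB, "")[[1]]
  diffpos <- which(av != bv)
  diffpos <- diffpos[seq_len(2 * (length(diffpos) %/% 2))]
  mid <- av; take <- diffpos[seq_along(diffpos) %% 2 == 0]
  mid[take] <- bv[take]
  rows <- c(q = paste(mid, collapse = ""),
            a1 = ancA, a2 = ancA, b1 = ancB, b2 = ancB)
  aln <- barcode_aln(rows)
  labels <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  r <- assign_by_tree("q", aln, labels,
                      assignment_config(bootstrap_replicates = 50), seed = 2)
  expect_identical(r$tree_call, "unassigned")
})

test_that("conflict policies combine the two methods as documented", {
  expect_identical(larvalID:::combine_calls("X", "X", "require_agreement")$call,
                   "X")
  expect_identical(
    larvalID:::combine_calls("X", "unassigned", "require_agreement")$call, "X")
  expect_identical(
    larvalID:::combine_calls("unassigned", "Y", "require_agreement")$call, "Y")
  expect_identical(
    larvalID:::combine_calls("X", "Y", "require_agreement")$call, "conflict")
  expect_identical(larvalID:::combine_calls("X", "Y", "similarity_wins")$call,
                   "X")
  expect_identical(larvalID:::combine_calls("X", "Y", "tree_wins")$call, "Y")
  expect_identical(
    larvalID:::combine_calls("unassigned", "Y", "similarity_wins")$call, "Y")
})

test_that("require_agreement never invents a species neither method called", {
  tc <- make_test_complex(seed = 61)
  rep <- assign_batch(tc$aln, tc$labels,
                      assignment_config(bootstrap_replicates = 30), seed = 4)
  for (i in seq_len(nrow(rep))) {
    fc <- rep$final_call[i]
    if (!fc %in% c("unassigned", "conflict"))
      expect_true(fc %in% c(rep$similarity_call[i], rep$tree_call[i]))
  }
})

test_that("barcode gap analysis splits pairs exhaustively and finds planted gaps", {
  # two species, two identical members each, interspecific distance planted
  rows <- c(x1 = strrep("A", 100), x2 = strrep("A", 100),
            y1 = paste0(strrep("C", 10), strrep("A", 90)),
            y2 = paste0(strrep("C", 10), strrep("A", 90)))
  dm <- distance_matrix(barcode_aln(rows), "p")
  gap <- barcode_gap_analysis(dm, c(x1 = "X", x2 = "X", y1 = "Y", y2 = "Y"))
  expect_equal(length(gap$intra) + length(gap$inter), 4 * 3 / 2)
  expect_true(all(gap$per_species$gap_present))
  expect_equal(gap$per_species$gap_size, c(0.1, 0.1))

  expect_error(
    barcode_gap_analysis(dm, c(x1 = "X", x2 = "X", y1 = "X", y2 = "X")),
    ">= 2 species")
})

test_that("single-member species report no intraspecific maximum", {
  rows <- c(x1 = strrep("A", 50), x2 = strrep("A", 50),
            z1 = paste0(strrep("G", 8), strrep("A", 42)))
  dm <- distance_matrix(barcode_aln(rows), "p")
  gap <- barcode_gap_analysis(dm, c(x1 = "X", x2 = "X", z1 = "Z"))
  z <- gap$per_species[gap$per_species$species == "Z", ]
  expect_true(is.na(z$max_intra))
  expect_false(z$gap_present)
  x <- gap$per_species[gap$per_species$species == "X", ]
  expect_true(x$gap_present)
})

test_that("simulated complexes show a clean barcode gap and disjoint pools", {
  tc <- make_test_complex(seed = 29, n_refs = 4, n_queries = 0)
  dm <- distance_matrix(tc$aln, "k2p")
  gap <- barcode_gap_analysis(dm, tc$labels)
  expect_true(all(gap$per_species$gap_present))
  expect_gt(min(gap$inter), max(gap$intra))
  n <- length(tc$aln)
  expect_equal(length(gap$intra) + length(gap$inter), n * (n - 1) / 2)
  f <- tempfile(fileext = ".csv")
  write_gap_report(gap, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".hist.csv")))
  hist_tab <- read.csv(paste0(f, ".hist.csv"))
  expect_equal(sum(hist_tab$intra_count), length(gap$intra))
  expect_equal(sum(hist_tab$inter_count), length(gap$inter))
})
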