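# Substitution counting, p / similarity / K2P distances, matrices.

test_that("substitution counts follow pairwise deletion", {
  cc <- count_substitutions("ACGT", "ACGT")
  expect_equal(cc$sites_compared, 4)
  expect_equal(cc$transitions + cc$transversions, 0)

  cc2 <- count_substitutions("ACGT", "GCGT")
  expect_equal(cc2$transitions, 1)   # A<->G
  expect_equal(cc2$transversions, 0)

  cc3 <- count_substitutions("AC-TN", "ACGTA")
  expect_equal(cc3$sites_compared, 3)  # positions 1, 2, 4
  expect_equal(cc3$transitions + cc3$transversions, 0)

  expect_error(count_substitutions("---", "AC-"), "no comparable sites")
  expect_error(count_substitutions("ACG", "AC"), "equal length")
})

test_that("p-distance and similarity match a per-column loop oracle", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(percent_similarity("ACGT", "ACGT"), 100)
  set.seed(4)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    a <- paste(sample(c("A", "C", "G", "T", "N", "-"), n, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N", "-"), n, replace = TRUE,
                      prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    want <- loop_count_oracle(a, b)
    if (want$sites == 0) next
    cc <- count_substitutions(a, b)
    expect_equal(cc$sites_compared, want$sites)
    expect_equal(cc$transitions, want$ts)
    expect_equal(cc$transversions, want$tv)
    expect_equal(p_distance(a, b), (want$ts + want$tv) / want$sites)
  }
})

test_that("the similarity threshold corresponds to p = 0.0875", {
  # 91.25% similarity as a p-distance: 100 * (1 - 0.0875) = 91.25
  a <- paste(rep("A", 10000), collapse = "")
  bv <- rep("A", 10000); bv[seq_len(875)] <- "C"
  expect_equal(percent_similarity(a, paste(bv, collapse = "")), 91.25)
  bv2 <- rep("A", 10); bv2[1:5] <- "G"
  expect_equal(percent_similarity(a1 <- "AAAAAAAAAA",
                                  paste(bv2, collapse = "")), 50)
})

test_that("K2P distance matches direct evaluation and reduces to Jukes-Cantor", {
  expect_equal(k2p_from_pq(0, 0), 0)
  expect_equal(k2p_from_pq(0.2, 0.1), -0.5 * log(0.5) - 0.25 * log(0.8),
               tolerance = 1e-12)
  # Q = 2P: K2P equals JC -(3/4) log(1 - 4p/3) with p = P + Q
  for (P in seq(0.005, 0.11, by = 0.005)) {
    p <- 3 * P
    expect_equal(k2p_from_pq(P, 2 * P), -0.75 * log(1 - 4 * p / 3),
                 tolerance = 1e-12)
  }
  # correction never shrinks the distance
  for (P in seq(0, 0.2, by = 0.02)) {
    for (Q in seq(0, 0.2, by = 0.02)) {
      if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) next
      expect_gte(k2p_from_pq(P, Q), P + Q - 1e-12)
    }
  }
  expect_error(k2p_from_pq(0.45, 0.2), "saturation")
})

test_that("K2P agrees with ape::dist.dna on clean alignments", {
  set.seed(12)
  root <- random_acgt(400)
  rows <- vapply(1:8, function(i) mutate_k2p(root, 0.1, 4), character(1))
  names(rows) <- paste0("s", 1:8)
  aln <- barcode_aln(rows)
  mine <- distance_matrix(aln, "k2p")
  bin <- ape::as.DNAbin(t(sapply(strsplit(rows, ""), identity)))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(unclass(mine)[names(rows), names(rows)],
               ref[names(rows), names(rows)], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("distance matrices are symmetric, metric-tagged and per-pair consistent", {
  set.seed(6)
  root <- random_acgt(150)
  rows <- vapply(1:6, function(i) mutate_k2p(root, 0.12, 4), character(1))
  names(rows) <- paste0("x", 1:6)
  aln <- barcode_aln(rows)
  for (metric in c("p", "k2p", "similarity_percent")) {
    dm <- distance_matrix(aln, metric)
    expect_identical(attr(dm, "metric"), metric)
    expect_lt(max(abs(unclass(dm) - t(unclass(dm)))), 1e-12)
    expect_equal(unname(diag(unclass(dm))),
                 rep(if (metric == "similarity_percent") 100 else 0, 6))
  }
  dm <- distance_matrix(aln, "k2p")
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(dm[i, j], k2p_distance(rows[[i]], rows[[j]]))
})

test_that("inserting a shared all-gap column changes no distance", {
  set.seed(17)
  a <- random_acgt(80); b <- mutate_k2p(a, 0.1, 4)
  a2 <- paste0(substr(a, 1, 40), "-", substr(a, 41, 80))
  b2 <- paste0(substr(b, 1, 40), "-", substr(b, 41, 80))
  expect_equal(k2p_distance(a, b), k2p_distance(a2, b2))
  expect_equal(p_distance(a, b), p_distance(a2, b2))
})

test_that("similarity conversion round-trips and CSV export preserves values", {
  set.seed(19)
  root <- random_acgt(100)
  rows <- setNames(vapply(1:4, function(i) mutate_k2p(root, 0.1, 4),
                          character(1)), paste0("r", 1:4))
  aln <- barcode_aln(rows)
  sim <- distance_matrix(aln, "similarity_percent")
  p <- similarity_to_p(sim)
  expect_identical(attr(p, "metric"), "p")
  expect_equal(unclass(p), (100 - unclass(sim)) / 100, ignore_attr = TRUE)
  f <- tempfile(fileext = ".csv")
  write_distance_csv(p, f)
  back <- read_distance_csv(f, "p")
  expect_equal(unclass(back), unclass(p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("per-species average similarity ranks the true species first", {
  expect_error(avg_similarity_by_species("q", barcode_aln(c(q = "ACGT")),
                                         c(q = "")), "no labelled")
  # query identical to single member of species X
  aln <- barcode_aln(c(q = "ACGTACGT", x1 = "ACGTACGT", y1 = "TTTTACGT"))
  sc <- avg_similarity_by_species("q", aln, c(x1 = "X", y1 = "Y"))
  expect_equal(sc[["X"]], 100)
  # equal p = 0.25 to two members of X -> mean of equal values
  aln2 <- barcode_aln(c(q = "AAAATTTT", x1 = "AAAATTAA", x2 = "AATTTTTT"))
  sc2 <- avg_similarity_by_species("q", aln2, c(x1 = "X", x2 = "X"))
  expect_equal(sc2[["X"]], 75)
  # simulated complex: own species mean exceeds all others
  tc <- make_test_complex(seed = 23)
  q <- tc$cx$truth$id[tc$cx$truth$role == "query"][1]
  truth_sp <- tc$cx$truth$species[tc$cx$truth$id == q]
  sc3 <- avg_similarity_by_species(q, tc$aln, tc$labels)
  expect_identical(names(sc3)[1], truth_sp)
  expect_gt(sc3[1] - sc3[2], 3)
})
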