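# The synthetic-data generators: K2P mutator, reference complexes, read
# pairs, larval seasons.

test_that("mutate_k2p hits its target distance and kappa in expectation", {
  set.seed(44)
  s <- random_seq(10000)
  expect_identical(mutate_k2p(s, 0), s)
  m <- mutate_k2p(s, 0.10, 4)
  expect_equal(nchar(m), 10000)
  d <- k2p_distance(s, m)
  expect_gt(d, 0.08); expect_lt(d, 0.12)
  # large kappa: transversions vanish
  m2 <- mutate_k2p(s, 0.10, 1e6)
  cc <- count_substitutions(s, m2)
  expect_lte(cc$transversions, 2)
  expect_gt(cc$transitions, 500)
  expect_error(mutate_k2p(s, -0.1), ">= 0")
})

test_that("measured K2P distances are unbiased across targets", {
  set.seed(90)
  s <- random_seq(10000)
  for (target in c(0.02, 0.06, 0.15)) {
    d <- mean(replicate(5, k2p_distance(s, mutate_k2p(s, target, 4))))
    expect_equal(d, target, tolerance = 0.12)
  }
})

test_that("a degenerate single-species complex is monomorphic", {
  cc <- complex_config(n_species = 1, intraspecific_k2p = 0,
                       subclade_species = NA, interspecific_k2p = 0.1,
                       n_refs_per_species = 4, seed = 3)
  cx <- simulate_reference_complex(cc)
  expect_equal(length(unique(cx$references$seq)), 1L)
})

test_that("the default complex reproduces the published similarity structure", {
  cx <- simulate_reference_complex(
    complex_config(n_refs_per_species = 4, seed = 101))
  aln <- barcode_aln(cx$references$seq)  # no indels: already aligned
  sim <- distance_matrix(aln, "similarity_percent")
  sp <- cx$truth$species[match(rownames(sim), cx$truth$id)]
  same <- outer(sp, sp, "==") & upper.tri(sim)
  diff <- !outer(sp, sp, "==") & upper.tri(sim)
  # intraspecific similarity above the 91.25 threshold, interspecific below
  expect_gt(min(sim[same]), 91.25)
  expect_lt(max(sim[diff]), 91.25)
  # the variable species spans deeper variation than the rest
  varsp <- sim[same & outer(sp == "species_A", sp == "species_A", "&")]
  othersp <- sim[same & outer(sp != "species_A", sp != "species_A", "&")]
  expect_lt(min(varsp), min(othersp))
  # subclades recorded for the variable species only
  expect_setequal(unique(cx$truth$subclade[cx$truth$species == "species_A"]),
                  c("sub1", "sub2"))
  expect_true(all(cx$truth$subclade[cx$truth$species != "species_A"] == ""))
})

test_that("simulators are bit-reproducible given their seeds", {
  c1 <- simulate_reference_complex(complex_config(seed = 7))
  c2 <- simulate_reference_complex(complex_config(seed = 7))
  expect_identical(c1$references$seq, c2$references$seq)
  s1 <- simulate_larval_season(c1, season_config(seed = 9, n_collections = 3,
                                                 n_per_collection = 2))
  s2 <- simulate_larval_season(c2, season_config(seed = 9, n_collections = 3,
                                                 n_per_collection = 2))
  expect_identical(s1$queries$seq, s2$queries$seq)
  expect_identical(s1$records, s2$records)
  c3 <- simulate_reference_complex(complex_config(seed = 8))
  expect_false(identical(c1$references$seq, c3$references$seq))
})

test_that("config invariants are enforced", {
  expect_error(complex_config(interspecific_k2p = 0.05,
                              intraspecific_k2p = 0.06), "exceed")
  expect_error(season_config(start = "2018-07-01", end = "2018-06-01"),
               "window")
  sites <- data.frame(site_code = "S", grass_type = "cool_season")
  sites$mixture <- list(c(species_A = 0.5))
  expect_error(season_config(sites = sites), "sum to 1")
})

test_that("simulated read pairs carry primers, tails and placed errors", {
  set.seed(30)
  primers <- primer_pair("GGTCAACAAATCATAAAGATATTGG",
                         "TAAACTTCAGGGTGACCAAAAAATCA")
  tpl <- random_seq(640)
  rd <- simulate_reads(tpl, primers, read_length = 450)
  expect_identical(substr(rd$forward$bases, 1, 25), primers$forward_primer)
  expect_identical(substr(rd$reverse$bases, 1, 26), primers$reverse_primer)
  expect_equal(tail(rd$forward$qualities, 1), 5L)
  expect_equal(rd$forward$qualities[1], 50L)

  # tail-placed errors only touch the low-quality tail
  rd2 <- simulate_reads(tpl, primers, read_length = 450, error_rate = 0.5,
                        error_placement = "tail")
  good <- substr(rd2$forward$bases, 1, 450 - 30)
  expect_identical(good, substr(rd$forward$bases, 1, 420))
  expect_error(simulate_reads(tpl, primers, read_length = 5000), "amplicon")
})

test_that("seasonal simulation follows mixtures and instar progression", {
  cx <- simulate_reference_complex(complex_config(seed = 5))
  sites <- data.frame(site_code = "S1", grass_type = "cool_season",
                      stringsAsFactors = FALSE)
  sites$mixture <- list(c(species_B = 1))
  sn <- simulate_larval_season(cx, season_config(
    sites = sites, n_collections = 6, n_per_collection = 10,
    progression_sd = 0.2, seed = 12))
  expect_true(all(sn$records$true_species == "species_B"))
  cs <- composition_summary(
    transform(sn$records, species = true_species), "grass_type")
  expect_equal(cs$pct, 100)
  # median width rises across the season (tight progression schedule)
  med <- tapply(sn$records$head_capsule_mm, sn$records$collection_date,
                median)
  expect_true(all(diff(med[order(names(med))]) > -0.05))
  expect_gt(med[length(med)], med[1])

  # mixture recovery within binomial error at n = 41 per the classic split
  sites2 <- data.frame(site_code = "S2", grass_type = "cool_season",
                       stringsAsFactors = FALSE)
  sites2$mixture <- list(c(species_A = 0.68, species_B = 0.12,
                           species_C = 0.20))
  sn2 <- simulate_larval_season(cx, season_config(
    sites = sites2, n_collections = 7, n_per_collection = 6, seed = 33))
  prop <- table(sn2$records$true_species) / nrow(sn2$records)
  expect_lt(abs(prop[["species_A"]] - 0.68), 0.18)
})
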