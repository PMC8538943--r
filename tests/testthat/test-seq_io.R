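# Sequence ingest, reverse complement, trimming and consensus assembly.

test_that("FASTA ingest normalises case and joins metadata by id", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">q1", "ACGT", ">q2", "acgt"), fa)
  bs <- read_barcode_fasta(fa)
  expect_identical(unname(bs$seq), c("ACGT", "ACGT"))
  expect_identical(names(bs$seq), c("q1", "q2"))

  # metadata join on a simulated labelled reference set
  cx <- simulate_reference_complex(
    complex_config(n_refs_per_species = 4, seed = 5))
  fa2 <- tempfile(fileext = ".fasta")
  csv <- tempfile(fileext = ".csv")
  write_barcode_fasta(cx$references, fa2)
  write.csv(data.frame(id = cx$truth$id, species = cx$truth$species,
                       stage = "adult", location = "UT"),
            csv, row.names = FALSE)
  bs2 <- read_barcode_fasta(fa2, metadata = csv)
  expect_equal(length(bs2), 24)
  expect_true(all(nzchar(bs2$meta$species)))
  expect_true(all(bs2$meta$location == "UT"))
  expect_identical(bs2$meta$species,
                   cx$truth$species[match(bs2$meta$id, cx$truth$id)])
})

test_that("malformed FASTA and duplicate ids raise informative errors", {
  bad1 <- tempfile(); writeLines(c("ACGT", ">x", "ACGT"), bad1)
  expect_error(read_barcode_fasta(bad1), "line 1")
  bad2 <- tempfile(); writeLines(c(">a", "ACGT", ">b", ">c", "ACGT"), bad2)
  expect_error(read_barcode_fasta(bad2), "empty sequence")
  dup <- tempfile(); writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_barcode_fasta(dup), "duplicate ids: a")
  expect_error(read_barcode_fasta(tempfile()), "not found")
})

test_that("metadata ids absent from the FASTA warn but do not fail", {
  fa <- tempfile(); writeLines(c(">a", "ACGT"), fa)
  csv <- tempfile()
  write.csv(data.frame(id = c("a", "ghost"), species = c("x", "y")), csv,
            row.names = FALSE)
  expect_warning(bs <- read_barcode_fasta(fa, metadata = csv), "ghost")
  expect_identical(bs$meta$species, "x")
})

test_that("FASTA round-trip is lossless for ids and sequences", {
  cx <- simulate_reference_complex(complex_config(seed = 11))
  fa <- tempfile(fileext = ".fasta")
  write_barcode_fasta(cx$references, fa)
  back <- read_barcode_fasta(fa)
  expect_identical(back$seq, cx$references$seq)

  one <- barcode_set(c(solo = "ACGTNRY"))
  write_barcode_fasta(one, fa)
  expect_identical(read_barcode_fasta(fa)$seq, one$seq)

  gappy <- barcode_set(c(g = "ACGT"))
  gappy$seq[["g"]] <- "AC-T"
  expect_error(write_barcode_fasta(gappy, fa), "gaps")
})

test_that("reverse_complement maps IUPAC codes and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAN"), "NTT")
  expect_identical(reverse_complement("RYSWKMBDHVN"),
                   paste(rev(strsplit("YRSWMKVHDBN", "")[[1]]), collapse = ""))
  expect_error(reverse_complement("ACXT"), "position 3")
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "R", "Y", "N", "W", "K"), 30,
                      replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("quality trimming removes low-quality ends only", {
  r <- trace_read(strrep("A", 40), rep(60L, 40))
  expect_identical(trim_read(r, 20, 5), r)

  # 10 leading quality-2 bases, then quality-50: leading 10 removed
  r2 <- trace_read(paste0(strrep("C", 10), strrep("A", 30)),
                   c(rep(2L, 10), rep(50L, 30)))
  t2 <- trim_read(r2, 20, 5)
  expect_identical(t2$bases, strrep("A", 30))
  expect_identical(t2$qualities, rep(50L, 30))

  expect_error(trim_read(trace_read("ACGTACGT", rep(2L, 8)), 20, 5),
               "below threshold")
  # no qualities: identity
  r3 <- trace_read("ACGT")
  expect_identical(trim_read(r3), r3)
})

test_that("consensus of perfectly agreeing reads is the common sequence", {
  set.seed(3)
  tpl <- random_acgt(120)
  f <- trace_read(tpl, rep(50L, 120), "forward")
  r <- trace_read(reverse_complement(tpl), rep(50L, 120), "reverse")
  cc <- build_consensus(f, r, primers = NULL,
                        expected_length = c(100, 200))
  expect_identical(cc$sequence, tpl)
  expect_equal(cc$overlap_identity, 1)
})

test_that("consensus disagreements resolve by quality, else N", {
  tpl <- strrep("ACGTT", 6)                       # 30 bp
  mut <- paste0("G", substr(tpl, 2, 30))          # pos 1: A->G
  f <- trace_read(tpl, rep(50L, 30), "forward")
  # read position 30 of the reverse read covers template position 1
  r <- trace_read(reverse_complement(mut), c(rep(50L, 29), 10L), "reverse")
  cc <- build_consensus(f, r, expected_length = c(10, 50))
  expect_identical(substr(cc$sequence, 1, 1), "A")   # forward quality wins

  # equal qualities: N
  r2 <- trace_read(reverse_complement(mut), rep(50L, 30), "reverse")
  cc2 <- build_consensus(f, r2, expected_length = c(10, 50))
  expect_identical(substr(cc2$sequence, 1, 1), "N")
  expect_identical(substr(cc2$sequence, 2, 30), substr(tpl, 2, 30))
})

test_that("simulated read pairs reassemble the template exactly", {
  set.seed(21)
  primers <- primer_pair("GGTCAACAAATCATAAAGATATTGG",
                         "TAAACTTCAGGGTGACCAAAAAATCA")
  n_exact <- 0L
  for (i in 1:20) {
    tpl <- random_acgt(640)
    rd <- simulate_reads(tpl, primers, read_length = 450)
    cc <- build_consensus(rd$forward, rd$reverse, primers)
    if (identical(cc$sequence, tpl)) n_exact <- n_exact + 1L
  }
  expect_equal(n_exact, 20L)
})

test_that("non-overlapping reads raise the overlap error", {
  set.seed(9)
  primers <- primer_pair("ACGTACGTAC", "TGCATGCATG")
  tpl <- random_acgt(640)
  rd <- simulate_reads(tpl, primers, read_length = 150)  # 150+150 << 660
  expect_error(build_consensus(rd$forward, rd$reverse, primers),
               "do not overlap")
})

test_that("FASTQ trace reads round-trip with Sanger qualities", {
  set.seed(2)
  reads <- list(r1 = trace_read("ACGTACGT", c(40L, 40L, 2L, 60L, 0L, 33L, 20L, 5L)),
                r2 = trace_read("GGGTTT", rep(30L, 6)))
  fq <- tempfile(fileext = ".fastq")
  write_trace_fastq(reads, fq)
  back <- read_trace_fastq(fq, "forward")
  expect_identical(back$r1$bases, reads$r1$bases)
  expect_identical(back$r1$qualities, reads$r1$qualities)
  expect_identical(back$r2$qualities, reads$r2$qualities)
})
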