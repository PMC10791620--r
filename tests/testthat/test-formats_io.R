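test_that("FASTA round-trips, wraps, and rejects malformed input", {
  p <- withr::local_tempfile(fileext = ".fasta")
  recs <- c(g1 = "ATGAAA", g2 = paste(rep("ACGTN", 30), collapse = ""))
  write_fasta(recs, p)
  expect_identical(read_fasta(p), recs)
  # wrapped at 60 columns
  expect_true(all(nchar(readLines(p)) <= 61))

  writeLines(character(0), p)
  expect_length(read_fasta(p), 0)

  writeLines(c(">g1", "ATGXAA"), p)
  expect_error(read_fasta(p), "illegal character 'X' at line 2")
  writeLines(c(">", "ATG"), p)
  expect_error(read_fasta(p), "line 1")

  # property: random records round-trip bit-identically
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    recs <- stats::setNames(
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T", "N"), sample(1:200, 1), TRUE),
              collapse = ""), character(1)),
      paste0("seq", seq_len(n)))
    write_fasta(recs, p, width = sample(c(10, 60, 80), 1))
    expect_identical(read_fasta(p), recs)
  }
})

test_that("VCF dialect parses, maps genotypes, and skips out-of-dialect records", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "g1\t10\t.\tA\tG\t900\t.\t.\tGT\t0/1\t0/0",
    "g1\t11\t.\tA\tG,T\t900\t.\t.\tGT\t0/1\t0/0",
    "g1\t12\t.\tAT\tA\t900\t.\t.\tGT\t0/1\t0/0",
    "g1\t13\t.\tC\tT\t700\t.\t.\tGT\t1/1\t./."
  ), p)
  vs <- read_vcf(p, c("s1", "s2"))
  expect_equal(n_sites(vs), 2)
  expect_equal(attr(vs, "n_skipped"), 2)  # multi-allelic + indel
  expect_equal(vs$sites$cds_pos, c(10L, 13L))
  expect_equal(vs$sites$ref[1], "A")
  expect_equal(vs$sites$alt[1], "G")
  expect_equal(vs$sites$quality[1], 900)
  expect_equal(unname(vs$geno[1, ]), c("het", "hom_ref"))
  expect_equal(unname(vs$geno[2, ]), c("hom_alt", "missing"))

  expect_error(read_vcf(p, c("s1", "sX")), "sample columns")

  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "g1\t10\t.\tA\tG\thigh\t.\t.\tGT\t0/1"), p)
  expect_error(read_vcf(p, "s1"), "non-numeric QUAL")
})

test_that("VCF writer round-trips a variant set", {
  set.seed(3)
  samples <- c("father", "mother", "son01")
  sites <- data.frame(
    gene_id = rep("g1", 5), cds_pos = sort(sample(1:300, 5)),
    ref = rep("A", 5), alt = sample(c("C", "G", "T"), 5, TRUE),
    quality = round(runif(5, 10, 2999), 3), stringsAsFactors = FALSE)
  geno <- matrix(sample(c("hom_ref", "het", "hom_alt", "missing"), 15, TRUE),
                 5, 3, dimnames = list(NULL, samples))
  vs <- variant_set(sites, geno)
  p <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, p)
  back <- read_vcf(p, samples)
  expect_equal(back$sites, vs$sites)
  expect_identical(back$geno, vs$geno)
})

test_that("SAM-like read dialect enforces its invariants", {
  p <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "r1\ts1\tg1\t1\t50M\t" |> paste0(strrep("A", 50)),
    "r2\ts1\tg1\t260\t50M\t" |> paste0(strrep("A", 50)),   # overhangs 300bp CDS
    "r3\ts1\tg1\t5\t20M5I25M\t" |> paste0(strrep("A", 50)) # out of dialect
  ), p)
  reads <- read_sam_reads(p, cds_len = c(g1 = 300L))
  expect_equal(reads$read_id, "r1")
  expect_equal(attr(reads, "n_rejected"), 2)

  # round trip
  p2 <- withr::local_tempfile(fileext = ".sam")
  write_sam_reads(reads, p2)
  back <- read_sam_reads(p2, cds_len = c(g1 = 300L))
  attr(reads, "n_rejected") <- NULL
  attr(back, "n_rejected") <- NULL
  expect_identical(back, reads)
})

test_that("evidence table fixture loads with contracts intact", {
  ev <- load_evidence_table(evidence_fixture_path())
  expect_false(is.unsorted(ev$pos_kb))
  expect_true(all(ev$stratum %in% c("PAR", "Str3", "Str2")))

  # gene 1129 opens stratum 3 at 27,082 kb with counts from both cohorts
  r <- ev[ev$gene_id == "1129", ]
  expect_equal(r$pos_kb, 27082)
  expect_equal(r$stratum, "Str3")
  expect_equal(r$n_segr, 2L)
  expect_equal(r$n_lat, 1L)
  expect_true(is.na(r$n_dio))

  # 46 stratum-3 genes carry a reconstructed Y-CDS
  expect_equal(sum(ev$stratum == "Str3" & !is.na(ev$ycds_bp)), 46L)

  # blank optional cells are absent, not zero
  expect_true(is.na(ev$ks[ev$gene_id == "1007"]))

  # exactly one contiguous block per stratum along pos_kb
  runs <- rle(ev$stratum)
  expect_equal(runs$values, c("PAR", "Str3", "Str2"))

  # duplicate gene ids are rejected
  p <- withr::local_tempfile(fileext = ".tsv")
  lines <- readLines(evidence_fixture_path())
  writeLines(c(lines, lines[[length(lines)]]), p)
  expect_error(load_evidence_table(p), "duplicate gene_id")
})
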