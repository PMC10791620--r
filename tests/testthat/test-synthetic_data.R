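test_that("coalescent simulator matches neutral expectations", {
  set.seed(101)
  # theta = 0: all haplotypes identical
  h <- simulate_x_haplotypes(5, 50, 0)
  expect_true(all(apply(h, 2, function(col) length(unique(col)) == 1)))
  expect_error(simulate_x_haplotypes(5, 0, 0.01), "L must be")

  # Watterson's expectation E[S] = theta * L * a_n as oracle
  n <- 8; L <- 200; theta <- 0.02
  a_n <- sum(1 / seq_len(n - 1))
  S <- replicate(600, length(attr(simulate_x_haplotypes(n, L, theta), "positions")))
  expect_equal(mean(S), theta * L * a_n, tolerance = 0.07)

  # E[pi] = theta per site
  pis <- replicate(600, nucleotide_diversity(simulate_x_haplotypes(6, 150, theta))$pi)
  expect_equal(mean(pis), theta, tolerance = 0.08)
})

test_that("gametolog simulation places synonymous divergence at rate d", {
  set.seed(202)
  cds <- ystrata:::random_cds(120)
  f <- ystrata:::cds_syn_fractions(cds)
  S <- sum(f, na.rm = TRUE)
  n_low <- replicate(150, length(simulate_gametologs(cds, 0.01, 2, 0)$y_sub_pos))
  n_high <- replicate(150, length(simulate_gametologs(cds, 0.08, 2, 0)$y_sub_pos))
  expect_equal(mean(n_low), 0.01 * S, tolerance = 0.25)
  expect_equal(mean(n_high), 0.08 * S, tolerance = 0.15)

  # PAR gene: Y is exchangeable with the pool, Ks not elevated
  gam <- simulate_gametologs(cds, 0, 4, 0.002)
  expect_length(gam$y_sub_pos, 0)
  dv <- pairwise_divergence(ystrata:::hap_to_seq(gam$x_haps[1, ]),
                            ystrata:::hap_to_seq(gam$y_hap))
  expect_lt(ifelse(is.na(dv$ks), 0, dv$ks), 0.05)
})

test_that("cross transmission obeys the stated model", {
  set.seed(303)
  cds <- ystrata:::random_cds(80)
  gam <- simulate_gametologs(cds, 0.05, 4, 0.01)

  # par_recomb_prob = 0: every son's paternal allele is the father's Y and no
  # daughter carries a Y-specific allele at any fixed difference
  cr <- simulate_cross(gam$x_haps[3, ], gam$y_hap, gam$x_haps[1, ], gam$x_haps[2, ],
                       n_sons = 21, n_daughters = 32, par_recomb_prob = 0)
  expect_true(all(vapply(cr$sons, function(h) identical(h[[1]], gam$y_hap), logical(1))))
  for (p in gam$fixed_diffs) {
    carried <- vapply(cr$daughters, function(h)
      gam$y_hap[[p]] %in% c(h[[1]][[p]], h[[2]][[p]]), logical(1))
    expect_false(any(carried))
  }

  # par_recomb_prob = 0.5: about half the sons swap to X_f (binomial check)
  swaps <- replicate(60, sum(simulate_cross(
    gam$x_haps[3, ], gam$y_hap, gam$x_haps[1, ], gam$x_haps[2, ],
    21, 32, par_recomb_prob = 0.5)$son_swapped))
  expect_equal(mean(swaps) / 21, 0.5, tolerance = 0.1)
})

test_that("read emission has the promised coverage and error structure", {
  set.seed(404)
  cds <- ystrata:::random_cds(100)  # 300 bp
  hap <- strsplit(cds, "")[[1]]
  hap2 <- hap; hap2[[10]] <- setdiff(c("A", "C", "G", "T"), hap[[10]])[1]

  # err = 0, deep: pileup contains only the two true alleles
  reads <- emit_reads(list(hap, hap2), "g1", "s1", depth = 60, read_len = 50, err = 0)
  bases10 <- vapply(seq_len(nrow(reads)), function(i) {
    off <- 10 - reads$start[[i]] + 1
    if (off >= 1 && off <= 50) substr(reads$seq[[i]], off, off) else NA_character_
  }, character(1))
  expect_true(all(stats::na.omit(bases10) %in% c(hap[[10]], hap2[[10]])))

  # mean coverage per site approximately equals depth
  cov <- numeric(300)
  for (i in seq_len(nrow(reads))) {
    idx <- reads$start[[i]]:(reads$start[[i]] + 49)
    cov[idx] <- cov[idx] + 1
  }
  expect_equal(mean(cov), 60, tolerance = 0.15)

  # read_len > L: full-length reads, logged
  expect_message(r2 <- emit_reads(list(hap, hap2), "g1", "s1", 10, 500, 0),
                 "full-length")
  expect_true(all(nchar(r2$seq) == 300))
})

test_that("naive caller emits sites and genotypes per its thresholds", {
  cds <- strrep("ATGAAA", 10)  # 60 bp
  ref_reads <- data.frame(
    read_id = paste0("r", 1:10), sample_id = "s1", gene_id = "g1",
    start = 1L, seq = strrep("ATGAAA", 5), stringsAsFactors = FALSE)
  # ref-only sample: no site emitted
  vs <- naive_genotype_caller(ref_reads, cds, samples = "s1")
  expect_equal(n_sites(vs), 0)

  alt_seq <- paste0("ATGACA", strrep("ATGAAA", 4))  # alt C at pos 5
  mixed <- rbind(ref_reads,
                 within(ref_reads, { read_id <- paste0("a", 1:10); seq <- alt_seq }))
  vs <- naive_genotype_caller(mixed, cds, samples = "s1")
  expect_equal(n_sites(vs), 1)
  expect_equal(vs$sites$cds_pos, 5L)
  expect_equal(unname(vs$geno[1, "s1"]), "het")  # 10 alt / 20 total
  expect_equal(vs$sites$quality, 500)            # 50 * 10 alt reads

  # coverage 4 -> missing genotype
  low <- mixed[c(1:2, 11:12), ]
  vs <- naive_genotype_caller(low, cds, samples = "s1")
  expect_equal(unname(vs$geno[1, "s1"]), "missing")
})

test_that("generate_dataset is deterministic and honours its contracts", {
  cfg <- sim_config(seed = 9, n_genes = 4, cds_codons = c(60, 80),
                    n_sons = 6, n_daughters = 6, depth = 8)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, d1, force = TRUE)
  generate_dataset(cfg, d2, force = TRUE)
  for (f in setdiff(list.files(d1), "manifest.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  expect_true(file.exists(file.path(d1, "manifest.tsv")))
  expect_error(generate_dataset(cfg, d1), "not empty")

  # n_genes = 0: valid empty dataset with manifest
  d0 <- withr::local_tempdir()
  generate_dataset(sim_config(seed = 1, n_genes = 0), d0, force = TRUE)
  expect_true(file.exists(file.path(d0, "manifest.tsv")))
  expect_equal(nrow(read.table(file.path(d0, "genes.tsv"), header = TRUE,
                               sep = "\t")), 0)
})
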