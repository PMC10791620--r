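samples <- make_samples()
cross_ids <- samples$sample_id[samples$role != "wild"]
wild_ids <- samples$sample_id[samples$role == "wild"]

test_that("quality filter is strictly greater-than and order preserving", {
  vs <- make_vs("g1", c(5L, 9L, 20L), "A", "G", c(500, 500.01, 900),
                list(s1 = c("het", "het", "het")))
  out <- quality_filter(vs, 500)
  expect_equal(out$sites$cds_pos, c(9L, 20L))
  expect_equal(n_sites(quality_filter(subset_sites(vs, integer(0)))), 0)
})

test_that("candidate parental sites require father het, mother hom_ref", {
  vs <- make_vs("g1", 1:4, "A", "G", 900, list(
    father = c("het", "hom_alt", "het", "het"),
    mother = c("hom_ref", "hom_ref", "missing", "hom_alt")))
  out <- candidate_parental_sites(vs, "father", "mother")
  expect_equal(out$sites$cds_pos, 1L)
  expect_error(candidate_parental_sites(vs, "dad", "mother"), "unknown parent")
})

test_that("segregation filter applies the three progeny criteria", {
  mk <- function(...) make_vs("g1", 1L, "A", "G", 900,
                              list(geno_row(cross_ids, ...)))
  # ideal Y-SNP: all sons het, all daughters hom_ref, no missing
  ideal <- mk(son = "het", father = "het")
  expect_true(segregation_filter(ideal, samples)$passes_segregation)

  # one daughter carrying the alt allele fails
  vs <- mk(son = "het", father = "het", dau01 = "het")
  expect_false(segregation_filter(vs, samples)$passes_segregation)

  # only 9 sons with alt fails (threshold 10)
  g <- geno_row(cross_ids, father = "het")
  g[1, sprintf("son%02d", 1:9)] <- "het"
  expect_false(segregation_filter(make_vs("g1", 1L, "A", "G", 900, list(g)),
                                  samples)$passes_segregation)
  g[1, sprintf("son%02d", 1:10)] <- "het"
  expect_true(segregation_filter(make_vs("g1", 1L, "A", "G", 900, list(g)),
                                 samples)$passes_segregation)

  # missing-data bound is strict <: 10 missing progeny fails, 9 passes
  g <- geno_row(cross_ids, son = "het", father = "het")
  g[1, sprintf("dau%02d", 1:10)] <- "missing"
  expect_false(segregation_filter(make_vs("g1", 1L, "A", "G", 900, list(g)),
                                  samples)$passes_segregation)
  g[1, "dau10"] <- "hom_ref"
  expect_true(segregation_filter(make_vs("g1", 1L, "A", "G", 900, list(g)),
                                 samples)$passes_segregation)

  no_sons <- samples[samples$role != "son", ]
  expect_error(segregation_filter(ideal, no_sons), "no sons")
})

test_that("population filter requires min males with alt and zero females", {
  mk <- function(...) make_vs("g1", 1L, "A", "G", 900,
                              list(geno_row(wild_ids, ...)))
  expect_true(population_filter(mk(latM = "het"), samples,
                                "latifolia")$passes_population)
  # one female with alt fails even with 6 males
  g <- geno_row(wild_ids)
  g[1, sprintf("latM%d", 1:6)] <- "het"
  g[1, "latF3"] <- "het"
  expect_false(population_filter(make_vs("g1", 1L, "A", "G", 900, list(g)),
                                 samples, "latifolia")$passes_population)
  # 5 males below threshold fails
  g <- geno_row(wild_ids)
  g[1, sprintf("latM%d", 1:5)] <- "het"
  expect_false(population_filter(make_vs("g1", 1L, "A", "G", 900, list(g)),
                                 samples, "latifolia")$passes_population)
  # unsatisfiable criterion errors
  few <- make_samples(n_wild_m = 5)
  vs <- make_vs("g1", 1L, "A", "G", 900,
                list(geno_row(few$sample_id[few$role == "wild"])))
  expect_error(population_filter(vs, few, "latifolia"), "at least 6")
})

test_that("population filter is monotone in the male threshold", {
  set.seed(77)
  for (rep in 1:30) {
    g <- geno_row(wild_ids)
    g[1, sprintf("latM%d", 1:7)] <- sample(c("het", "hom_alt"), 7, TRUE)
    vs <- make_vs("g1", 1L, "A", "G", 900, list(g))
    p7 <- population_filter(vs, samples, "latifolia", min_males = 7)
    p6 <- population_filter(vs, samples, "latifolia", min_males = 6)
    if (p7$passes_population) expect_true(p6$passes_population)
  }
})

test_that("per-gene counts distinguish zero from absent", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), pos_kb = c(1, 2, 3))
  segr <- data.frame(gene_id = c("g1", "g1", "g2"), cds_pos = 1:3,
                     passes_segregation = c(TRUE, TRUE, FALSE))
  lat <- data.frame(gene_id = "g1", cds_pos = 1L, passes_population = TRUE)
  out <- per_gene_ysnp_counts(genes, segr = segr, lat = lat)
  expect_equal(out$n_segr, c(2L, 0L, NA_integer_))
  expect_equal(out$n_lat, c(1L, NA_integer_, NA_integer_))
  expect_true(all(is.na(out$n_dio)))
  expect_true(all(out$n_segr >= 0, na.rm = TRUE))
})

test_that("simulated crosses: fixed X-Y differences detected, free PAR rejected", {
  for (seed in c(5, 17)) {
    cfg <- sim_config(seed = seed, n_genes = 6, theta_per_site = 0.01,
                      par_recomb_prob = 0.5, par_recomb_prob_near = 0.5,
                      frac_silent_genes = 0, cds_codons = c(80, 150))
    tr <- simulate_dataset(cfg)
    segr <- segregation_filter(
      candidate_parental_sites(quality_filter(tr$cross_vs)), tr$samples)
    for (i in seq_len(nrow(tr$genes))) {
      g <- tr$genes$gene_id[[i]]
      pg <- tr$per_gene[[i]]
      ref <- strsplit(pg$cds, "")[[1]]
      pass_pos <- segr$cds_pos[segr$gene_id == g & segr$passes_segregation]
      if (tr$genes$stratum[[i]] == "PAR") {
        # freely recombining PAR gene (p = 0.5): nothing passes segregation
        expect_length(pass_pos, 0)
      } else {
        detectable <- Filter(function(p) {
          pg$y_hap[[p]] != ref[[p]] &&
            all(c(pg$hap_pairs$father[[1]][[p]],
                  pg$hap_pairs$mother[[1]][[p]],
                  pg$hap_pairs$mother[[2]][[p]]) == ref[[p]])
        }, pg$fixed_diffs)
        expect_true(all(detectable %in% pass_pos))
      }
    }
  }
})
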