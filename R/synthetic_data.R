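# Synthetic data generator. Emulates the statistical structure the strata
# analysis assumes: neutral X polymorphism, fixed X-Y differences in
# non-recombining strata (with a proximal divergence gradient in the youngest
# stratum), shared polymorphism in the PAR, father-to-son transmission of Y
# alleles in a genetic cross, wild diploid samples from two species, and
# sequencing reads with error. Ground truth is retained for recovery tests.

#' Simulation configuration
#'
#' Defaults state the study design the package targets: a cross with 21 sons
#' and 32 daughters, 7 wild males and 7 wild females per species, a
#' pseudoautosomal region up to ~27 Mb, a young stratum with synonymous
#' divergence rising proximally from 0.01 to 0.08, and an older stratum at a
#' constant 0.064.
#'
#' @param seed integer RNG seed
#' @param n_genes number of genes to simulate
#' @param chrom_span_kb (min, max) genomic positions in kb
#' @param boundaries_kb named or plain numeric of length 3:
#'   (segregation detection limit, PAR/Str3 boundary, Str3/Str2 boundary)
#' @param theta_per_site population mutation parameter per site
#' @param divergence_profile list with elements `PAR` (constant), `Str3`
#'   (length-2: divergence at the distal and proximal ends, linearly
#'   interpolated) and `Str2` (constant), in expected substitutions per
#'   synonymous site
#' @param par_recomb_prob per-meiosis probability that a son's allele at a
#'   distal PAR gene recombines off the Y background
#' @param par_recomb_prob_near same, for PAR genes proximal to the
#'   segregation detection limit (rare recombination near the boundary)
#' @param n_sons,n_daughters cross progeny counts
#' @param n_wild_males,n_wild_females wild sample counts per species
#' @param depth mean read depth per expressed gene
#' @param read_len read length in bp
#' @param err per-base sequencing error probability
#' @param frac_silent_genes fraction of genes with fpkm < 1 (no reads)
#' @param cds_codons (min, max) CDS length range in codons
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 24L,
                       chrom_span_kb = c(22000, 45000),
                       boundaries_kb = c(24843, 27082, 41500),
                       theta_per_site = 0.02,
                       divergence_profile = list(PAR = 0,
                                                 Str3 = c(0.01, 0.08),
                                                 Str2 = 0.064),
                       par_recomb_prob = 0.5,
                       par_recomb_prob_near = 0.02,
                       n_sons = 21L, n_daughters = 32L,
                       n_wild_males = 7L, n_wild_females = 7L,
                       depth = 30, read_len = 100L, err = 0.001,
                       frac_silent_genes = 0.2,
                       cds_codons = c(100L, 300L)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              chrom_span_kb = chrom_span_kb, boundaries_kb = boundaries_kb,
              theta_per_site = theta_per_site,
              divergence_profile = divergence_profile,
              par_recomb_prob = par_recomb_prob,
              par_recomb_prob_near = par_recomb_prob_near,
              n_sons = as.integer(n_sons), n_daughters = as.integer(n_daughters),
              n_wild_males = as.integer(n_wild_males),
              n_wild_females = as.integer(n_wild_females),
              depth = depth, read_len = as.integer(read_len), err = err,
              frac_silent_genes = frac_silent_genes,
              cds_codons = as.integer(cds_codons))
  probs <- c(cfg$par_recomb_prob, cfg$par_recomb_prob_near, cfg$err,
             cfg$frac_silent_genes)
  stopifnot(all(probs >= 0 & probs <= 1),
            cfg$theta_per_site >= 0,
            length(cfg$boundaries_kb) == 3L,
            !is.unsorted(cfg$boundaries_kb),
            all(unlist(cfg$divergence_profile) >= 0),
            cfg$n_genes >= 0L)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate haplotypes under the standard neutral coalescent
#'
#' No intragenic recombination. Coalescence times are exponential with rate
#' k(k-1)/2 in units of 2N generations; mutations fall on branches as a
#' Poisson process at rate theta*L/2 per lineage per unit time and are placed
#' on distinct positions (infinite sites mapped to L sites). Under this model
#' the expected pairwise diversity per site is theta and the expected number
#' of segregating sites is theta*L*sum(1/i, i<n).
#'
#' @param n number of haplotypes (>= 2)
#' @param L number of sites (>= 1)
#' @param theta_per_site population mutation parameter per site
#' @param ancestral optional ancestral sequence (single string or character
#'   vector of length L); random bases when NULL
#' @return character matrix (n x L) of bases, with attribute `positions`
#'   (mutated site indices)
#' @export
simulate_x_haplotypes <- function(n, L, theta_per_site, ancestral = NULL) {
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (n < 2L) stop("n must be >= 2", call. = FALSE)
  if (is.null(ancestral)) {
    anc <- sample(BASES, L, replace = TRUE)
  } else {
    anc <- if (length(ancestral) == 1L && nchar(ancestral[[1L]]) > 1L)
      strsplit(ancestral, "")[[1L]] else ancestral
    stopifnot(length(anc) == L)
  }
  # mutations per epoch: with k lineages of duration t_k the total branch
  # length is k*t_k, so counts are Poisson(theta*L/2 * k * t_k)
  lineages <- lapply(seq_len(n), identity)  # leaf sets
  mut_sets <- list()
  k <- n
  while (k >= 2L) {
    t_k <- stats::rexp(1L, rate = k * (k - 1) / 2)
    m <- stats::rpois(1L, theta_per_site * L / 2 * k * t_k)
    if (m > 0L) {
      hit <- sample.int(k, m, replace = TRUE)
      mut_sets <- c(mut_sets, lineages[hit])
    }
    pair <- sample.int(k, 2L)
    lineages[[pair[[1L]]]] <- c(lineages[[pair[[1L]]]], lineages[[pair[[2L]]]])
    lineages[[pair[[2L]]]] <- NULL
    k <- k - 1L
  }
  m <- length(mut_sets)
  if (m > L) {
    stop("more mutations (", m, ") than sites (", L,
         "); theta_per_site too large for infinite-sites placement",
         call. = FALSE)
  }
  haps <- matrix(rep(anc, each = n), nrow = n)
  pos <- if (m > 0L) sample.int(L, m) else integer(0)
  for (j in seq_len(m)) {
    p <- pos[[j]]
    derived <- sample(setdiff(BASES, anc[[p]]), 1L)
    haps[mut_sets[[j]], p] <- derived
  }
  attr(haps, "positions") <- sort(pos)
  haps
}

hap_to_seq <- function(hap_row) paste(hap_row, collapse = "")

# Random CDS: ATG start, internal non-stop codons, TAA terminal stop.
random_cds <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  non_stop <- setdiff(names(.codon_table), STOP_CODONS)
  paste0("ATG",
         paste(sample(non_stop, n_codons - 2L, replace = TRUE), collapse = ""),
         "TAA")
}

#' Simulate an X haplotype pool and a Y gametolog for one gene
#'
#' The Y haplotype is one extra draw from the same coalescent pool; when the
#' gene lies in a non-recombining stratum (d > 0), Poisson(d * S) synonymous
#' substitutions are added on the Y branch, where S is the Nei-Gojobori
#' synonymous site count of the source haplotype, so that downstream Ks
#' estimates recover d. In the PAR (d = 0) the Y is exchangeable with the X
#' pool by construction.
#'
#' @param cds reference CDS string (in frame)
#' @param d expected synonymous divergence on the Y branch
#' @param n_x number of X haplotypes to return (the pool)
#' @param theta_per_site population mutation parameter per site
#' @return list with `x_haps` (n_x x L base matrix), `y_hap` (length-L base
#'   vector), `y_sub_pos` (positions substituted on the Y branch) and
#'   `fixed_diffs` (positions where the Y differs from every X haplotype)
#' @export
simulate_gametologs <- function(cds, d, n_x, theta_per_site) {
  L <- nchar(cds)
  haps <- simulate_x_haplotypes(n_x + 1L, L, theta_per_site, ancestral = cds)
  y <- haps[n_x + 1L, ]
  x <- haps[seq_len(n_x), , drop = FALSE]
  sub_pos <- integer(0)
  if (d > 0) {
    f <- cds_syn_fractions(hap_to_seq(y))
    S <- sum(f, na.rm = TRUE)
    n_sub <- stats::rpois(1L, d * S)
    for (s in seq_len(n_sub)) {
      f <- cds_syn_fractions(hap_to_seq(y))
      f[is.na(f)] <- 0
      if (sum(f) == 0) break
      p <- sample.int(L, 1L, prob = f)
      codon_i <- (p - 1L) %/% 3L
      codon <- paste(y[codon_i * 3L + 1:3], collapse = "")
      alts <- synonymous_alternatives(codon, p - codon_i * 3L)
      if (length(alts) == 0L) next
      y[[p]] <- sample(alts, 1L)
      sub_pos <- c(sub_pos, p)
    }
  }
  fixed <- which(vapply(seq_len(L), function(p) all(x[, p] != y[[p]]), logical(1)))
  list(x_haps = x, y_hap = y, y_sub_pos = sort(unique(sub_pos)),
       fixed_diffs = fixed)
}

#' Simulate transmission in a genetic cross for one gene
#'
#' The father carries (X_f, Y) and the mother (X_1, X_2). Paternal
#' transmission is symmetric under recombination: each son receives the Y,
#' swapped for X_f with probability `par_recomb_prob`, and each daughter
#' receives X_f, swapped for the Y with the same probability (a crossover in
#' the PAR moves alleles off the Y background in both directions). With
#' `par_recomb_prob = 0` no daughter can ever carry a Y-specific allele.
#' Every offspring also receives one maternal X.
#'
#' @param father_x,y,mother_x1,mother_x2 length-L base vectors
#' @param n_sons,n_daughters progeny counts
#' @param par_recomb_prob per-meiosis probability the paternal allele swaps
#' @return list with `sons`, `daughters` (lists of 2-element haplotype lists;
#'   element 1 is the paternal allele) and `son_swapped`, `daughter_swapped`
#'   (logical vectors)
#' @export
simulate_cross <- function(father_x, y, mother_x1, mother_x2,
                           n_sons, n_daughters, par_recomb_prob = 0) {
  swapped <- stats::runif(n_sons) < par_recomb_prob
  sons <- lapply(seq_len(n_sons), function(i) {
    pat <- if (swapped[[i]]) father_x else y
    mat <- if (stats::runif(1) < 0.5) mother_x1 else mother_x2
    list(pat, mat)
  })
  d_swapped <- stats::runif(n_daughters) < par_recomb_prob
  daughters <- lapply(seq_len(n_daughters), function(i) {
    pat <- if (d_swapped[[i]]) y else father_x
    mat <- if (stats::runif(1) < 0.5) mother_x1 else mother_x2
    list(pat, mat)
  })
  list(sons = sons, daughters = daughters, son_swapped = swapped,
       daughter_swapped = d_swapped)
}

#' Emit sequencing reads for one individual at one gene
#'
#' Read count is Poisson(depth * L / read_len); each read is drawn from one of
#' the two haplotypes with equal probability, starts uniformly, and suffers
#' independent per-base substitution errors at rate `err`. When
#' `read_len > L`, full-length reads are emitted instead (count
#' Poisson(depth)) and a message is logged.
#'
#' @param haps list of two length-L base vectors
#' @param gene_id,sample_id identifiers for the emitted records
#' @param depth mean coverage; `read_len` read length; `err` per-base error
#' @return data.frame(read_id, sample_id, gene_id, start, seq)
#' @export
emit_reads <- function(haps, gene_id, sample_id, depth, read_len, err = 0) {
  L <- length(haps[[1L]])
  if (read_len > L) {
    message("read_len > CDS length for gene ", gene_id,
            "; emitting full-length reads")
    read_len <- L
    n_reads <- stats::rpois(1L, depth)
  } else {
    n_reads <- stats::rpois(1L, depth * L / read_len)
  }
  if (n_reads == 0L) {
    return(data.frame(read_id = character(0), sample_id = character(0),
                      gene_id = character(0), start = integer(0),
                      seq = character(0)))
  }
  starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
  which_hap <- sample.int(2L, n_reads, replace = TRUE)
  seqs <- vapply(seq_len(n_reads), function(i) {
    b <- haps[[which_hap[[i]]]][starts[[i]]:(starts[[i]] + read_len - 1L)]
    if (err > 0) {
      hit <- which(stats::runif(read_len) < err)
      for (p in hit) b[[p]] <- sample(setdiff(BASES, b[[p]]), 1L)
    }
    paste(b, collapse = "")
  }, character(1))
  data.frame(read_id = sprintf("%s_%s_r%04d", sample_id, gene_id, seq_len(n_reads)),
             sample_id = sample_id, gene_id = gene_id,
             start = starts, seq = seqs, stringsAsFactors = FALSE)
}

#' Naive genotype caller for synthetic end-to-end tests
#'
#' Stands in for an external variant caller when closing the loop on simulated
#' reads. A site is emitted when at least one sample supports a non-reference
#' allele with >= 2 reads making up >= 20% of its coverage. Per sample, the
#' genotype is hom_ref (< 20% alt), het (20-80%), hom_alt (> 80%), or missing
#' when coverage < 5 (mirroring an FMT/DP < 5 exclusion). Quality is 50 times
#' the total alt-supporting read count, capped at 3000.
#'
#' @param reads data.frame of reads (single gene) as from [emit_reads()]
#' @param ref_cds the gene's reference CDS string
#' @param samples character vector of sample ids (VCF column order)
#' @param min_cov coverage below which a genotype is missing
#' @return `variant_set`
#' @export
naive_genotype_caller <- function(reads, ref_cds, samples, min_cov = 5L) {
  L <- nchar(ref_cds)
  ref <- strsplit(ref_cds, "")[[1L]]
  gene_id <- if (nrow(reads) > 0L) reads$gene_id[[1L]] else NA_character_
  counts <- array(0L, dim = c(length(samples), 4L, L),
                  dimnames = list(samples, BASES, NULL))
  for (i in seq_len(nrow(reads))) {
    b <- strsplit(reads$seq[[i]], "")[[1L]]
    pos <- reads$start[[i]] + seq_along(b) - 1L
    ok <- b %in% BASES
    s <- reads$sample_id[[i]]
    for (j in which(ok)) counts[s, b[[j]], pos[[j]]] <- counts[s, b[[j]], pos[[j]]] + 1L
  }
  rows <- list(); genos <- list()
  for (p in seq_len(L)) {
    cm <- counts[, , p, drop = TRUE]
    if (is.null(dim(cm))) cm <- matrix(cm, nrow = 1L, dimnames = list(samples, BASES))
    tot_by_base <- colSums(cm)
    nonref <- setdiff(BASES, ref[[p]])
    if (all(tot_by_base[nonref] == 0L)) next
    alt <- nonref[which.max(tot_by_base[nonref])]
    cov <- rowSums(cm)
    altc <- cm[, alt]
    emit <- any(altc >= 2L & cov > 0 & altc / pmax(cov, 1L) >= 0.2)
    if (!emit) next
    frac <- ifelse(cov > 0, altc / cov, 0)
    g <- rep("missing", length(samples))
    called <- cov >= min_cov
    g[called & frac < 0.2] <- "hom_ref"
    g[called & frac >= 0.2 & frac <= 0.8] <- "het"
    g[called & frac > 0.8] <- "hom_alt"
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, cds_pos = p, ref = ref[[p]], alt = alt,
      quality = min(50 * sum(altc), 3000), stringsAsFactors = FALSE)
    genos[[length(genos) + 1L]] <- g
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), cds_pos = integer(0), ref = character(0),
               alt = character(0), quality = numeric(0))
  geno <- matrix("missing", nrow(sites), length(samples),
                 dimnames = list(NULL, samples))
  if (length(genos)) geno[] <- do.call(rbind, genos)
  variant_set(sites, geno)
}

# ---------------------------------------------------------------------------
# Whole-dataset simulation

sample_table <- function(cfg) {
  ids <- c("father", "mother",
           sprintf("son%02d", seq_len(cfg$n_sons)),
           sprintf("dau%02d", seq_len(cfg$n_daughters)),
           sprintf("latM%d", seq_len(cfg$n_wild_males)),
           sprintf("latF%d", seq_len(cfg$n_wild_females)),
           sprintf("dioM%d", seq_len(cfg$n_wild_males)),
           sprintf("dioF%d", seq_len(cfg$n_wild_females)))
  data.frame(
    sample_id = ids,
    species = c(rep("latifolia", 2L + cfg$n_sons + cfg$n_daughters +
                      cfg$n_wild_males + cfg$n_wild_females),
                rep("dioica", cfg$n_wild_males + cfg$n_wild_females)),
    sex = c("M", "F", rep("M", cfg$n_sons), rep("F", cfg$n_daughters),
            rep("M", cfg$n_wild_males), rep("F", cfg$n_wild_females),
            rep("M", cfg$n_wild_males), rep("F", cfg$n_wild_females)),
    role = c("father", "mother", rep("son", cfg$n_sons),
             rep("daughter", cfg$n_daughters),
             rep("wild", 2L * (cfg$n_wild_males + cfg$n_wild_females))),
    stringsAsFactors = FALSE
  )
}

stratum_of <- function(pos_kb, boundaries_kb) {
  ifelse(pos_kb < boundaries_kb[[2L]], "PAR",
         ifelse(pos_kb < boundaries_kb[[3L]], "Str3", "Str2"))
}

divergence_at <- function(pos_kb, stratum, cfg, species = "latifolia") {
  if (species == "dioica") {
    # stratum 3 is still pseudoautosomal in the sister species
    return(if (stratum == "Str2") cfg$divergence_profile$Str2 else 0)
  }
  prof <- cfg$divergence_profile[[stratum]]
  if (stratum == "Str3" && length(prof) == 2L) {
    b <- cfg$boundaries_kb
    w <- (pos_kb - b[[2L]]) / (b[[3L]] - b[[2L]])
    prof[[1L]] + w * (prof[[2L]] - prof[[1L]])
  } else {
    prof[[1L]]
  }
}

# Perfect genotype calls from true haplotype pairs: stands in for an
# error-free caller. `hap_pairs` is a named list sample_id -> list(h1, h2).
# Multi-allelic positions (rare under low theta) are skipped and counted.
perfect_calls <- function(hap_pairs, ref_cds, gene_id, quality = 1000) {
  samples <- names(hap_pairs)
  ref <- strsplit(ref_cds, "")[[1L]]
  L <- length(ref)
  allele1 <- do.call(rbind, lapply(hap_pairs, `[[`, 1L))
  allele2 <- do.call(rbind, lapply(hap_pairs, `[[`, 2L))
  var_pos <- which(vapply(seq_len(L), function(p) {
    any(allele1[, p] != ref[[p]]) || any(allele2[, p] != ref[[p]])
  }, logical(1)))
  rows <- list(); genos <- list(); n_multi <- 0L
  for (p in var_pos) {
    alleles <- c(allele1[, p], allele2[, p])
    alts <- setdiff(unique(alleles), ref[[p]])
    if (length(alts) > 1L) { n_multi <- n_multi + 1L; next }
    alt <- alts[[1L]]
    n_alt <- (allele1[, p] == alt) + (allele2[, p] == alt)
    g <- c("hom_ref", "het", "hom_alt")[n_alt + 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, cds_pos = p, ref = ref[[p]], alt = alt,
      quality = quality, stringsAsFactors = FALSE)
    genos[[length(genos) + 1L]] <- g
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), cds_pos = integer(0), ref = character(0),
               alt = character(0), quality = numeric(0))
  geno <- matrix("missing", nrow(sites), length(samples),
                 dimnames = list(NULL, samples))
  if (length(genos)) geno[] <- do.call(rbind, genos)
  vs <- variant_set(sites, geno)
  attr(vs, "n_multiallelic_skipped") <- n_multi
  vs
}

bind_variant_sets <- function(vss) {
  vss <- Filter(function(v) n_sites(v) > 0L, vss)
  if (length(vss) == 0L) {
    return(variant_set(
      data.frame(gene_id = character(0), cds_pos = integer(0),
                 ref = character(0), alt = character(0), quality = numeric(0)),
      matrix(character(0), 0L, 0L, dimnames = list(NULL, character(0)))))
  }
  variant_set(do.call(rbind, lapply(vss, function(v) v$sites)),
              do.call(rbind, lapply(vss, function(v) v$geno)))
}

#' Simulate a complete dataset in memory
#'
#' Produces true haplotypes for every individual at every gene, perfect-call
#' variant sets for the cross and the wild cohorts, and a truth bundle for
#' recovery tests. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()]
#' @return list with `config`, `samples`, `genes` (gene_id, pos_kb, stratum,
#'   d, fpkm, cds), `per_gene` truth (haplotype pairs, Y haplotype, fixed X-Y
#'   differences, son swap flags), `cross_vs`, `wild_vs`
#' @export
simulate_dataset <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  set.seed(cfg$seed)
  samples <- sample_table(cfg)
  cross_ids <- samples$sample_id[samples$role != "wild"]
  wild <- samples[samples$role == "wild", ]
  n <- cfg$n_genes
  if (n == 0L) {
    return(list(config = cfg, samples = samples,
                genes = data.frame(gene_id = character(0), pos_kb = numeric(0),
                                   stratum = character(0), d = numeric(0),
                                   fpkm = numeric(0), cds = character(0)),
                per_gene = list(),
                cross_vs = NULL, wild_vs = NULL))
  }
  pos_kb <- sort(stats::runif(n, cfg$chrom_span_kb[[1L]], cfg$chrom_span_kb[[2L]]))
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n)),
    pos_kb = pos_kb,
    stratum = stratum_of(pos_kb, cfg$boundaries_kb),
    stringsAsFactors = FALSE
  )
  genes$d <- vapply(seq_len(n), function(i)
    divergence_at(genes$pos_kb[[i]], genes$stratum[[i]], cfg), numeric(1))
  silent <- stats::runif(n) < cfg$frac_silent_genes
  genes$fpkm <- ifelse(silent, stats::runif(n, 0, 0.99), stats::runif(n, 2, 100))
  genes$cds <- vapply(seq_len(n), function(i)
    random_cds(sample(seq(cfg$cds_codons[[1L]], cfg$cds_codons[[2L]]), 1L)),
    character(1))

  per_gene <- vector("list", n)
  names(per_gene) <- genes$gene_id
  cross_vss <- vector("list", n)
  wild_vss <- vector("list", n)
  n_lat_f <- cfg$n_wild_females; n_lat_m <- cfg$n_wild_males
  for (i in seq_len(n)) {
    cds <- genes$cds[[i]]
    # latifolia pool: mother (2) + father X (1) + wild females (2 each) +
    # wild males' X (1 each) + extra draws for wild-male second alleles when
    # the gene is pseudoautosomal
    n_x <- 3L + 2L * n_lat_f + 2L * n_lat_m
    gam <- simulate_gametologs(cds, genes$d[[i]], n_x, cfg$theta_per_site)
    x <- gam$x_haps
    mother_x1 <- x[1L, ]; mother_x2 <- x[2L, ]; father_x <- x[3L, ]
    prp <- if (genes$stratum[[i]] != "PAR") 0
      else if (genes$pos_kb[[i]] >= cfg$boundaries_kb[[1L]]) cfg$par_recomb_prob_near
      else cfg$par_recomb_prob
    cross <- simulate_cross(father_x, gam$y_hap, mother_x1, mother_x2,
                            cfg$n_sons, cfg$n_daughters, prp)
    hap_pairs <- c(
      list(father = list(father_x, gam$y_hap),
           mother = list(mother_x1, mother_x2)),
      stats::setNames(cross$sons, sprintf("son%02d", seq_len(cfg$n_sons))),
      stats::setNames(cross$daughters, sprintf("dau%02d", seq_len(cfg$n_daughters)))
    )
    # wild latifolia: females two pool draws; males one X draw plus the
    # shared species Y when sex-linked, or an independent pool draw in the PAR
    off <- 3L
    lat_pairs <- list()
    for (f in seq_len(n_lat_f)) {
      lat_pairs[[sprintf("latF%d", f)]] <- list(x[off + 2L * f - 1L, ], x[off + 2L * f, ])
    }
    off <- off + 2L * n_lat_f
    sexlinked <- genes$d[[i]] > 0
    for (m in seq_len(n_lat_m)) {
      second <- if (sexlinked) gam$y_hap else x[off + 2L * m, ]
      lat_pairs[[sprintf("latM%d", m)]] <- list(x[off + 2L * m - 1L, ], second)
    }
    # dioica: independent pool from the same reference; own Y, sex-linked in
    # the old stratum only
    d_dio <- divergence_at(genes$pos_kb[[i]], genes$stratum[[i]], cfg, "dioica")
    gam_d <- simulate_gametologs(cds, d_dio, 2L * n_lat_f + 2L * n_lat_m,
                                 cfg$theta_per_site)
    xd <- gam_d$x_haps
    dio_pairs <- list()
    for (f in seq_len(n_lat_f)) {
      dio_pairs[[sprintf("dioF%d", f)]] <- list(xd[2L * f - 1L, ], xd[2L * f, ])
    }
    offd <- 2L * n_lat_f
    for (m in seq_len(n_lat_m)) {
      second <- if (d_dio > 0) gam_d$y_hap else xd[offd + 2L * m, ]
      dio_pairs[[sprintf("dioM%d", m)]] <- list(xd[offd + 2L * m - 1L, ], second)
    }
    cross_vss[[i]] <- perfect_calls(hap_pairs[cross_ids], cds, genes$gene_id[[i]])
    wild_pairs <- c(lat_pairs, dio_pairs)[wild$sample_id]
    wild_vss[[i]] <- perfect_calls(wild_pairs, cds, genes$gene_id[[i]])
    per_gene[[i]] <- list(
      cds = cds, stratum = genes$stratum[[i]], d = genes$d[[i]],
      y_hap = gam$y_hap, y_sub_pos = gam$y_sub_pos,
      fixed_diffs = gam$fixed_diffs,
      hap_pairs = c(hap_pairs, lat_pairs, dio_pairs),
      son_swapped = cross$son_swapped,
      daughter_swapped = cross$daughter_swapped,
      par_recomb_prob = prp
    )
  }
  list(config = cfg, samples = samples, genes = genes, per_gene = per_gene,
       cross_vs = bind_variant_sets(cross_vss),
       wild_vs = bind_variant_sets(wild_vss))
}

#' Emit reads for every individual and gene of a simulated dataset
#'
#' Genes with fpkm < 1 are silent and emit no reads.
#'
#' @param truth result of [simulate_dataset()]
#' @param samples optional subset of sample ids
#' @return data.frame of reads
#' @export
dataset_reads <- function(truth, samples = NULL) {
  cfg <- truth$config
  ids <- if (is.null(samples)) truth$samples$sample_id else samples
  out <- list()
  for (i in seq_len(nrow(truth$genes))) {
    if (truth$genes$fpkm[[i]] < 1) next
    pg <- truth$per_gene[[i]]
    for (s in ids) {
      out[[length(out) + 1L]] <- emit_reads(
        pg$hap_pairs[[s]], truth$genes$gene_id[[i]], s,
        cfg$depth, cfg$read_len, cfg$err)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(read_id = character(0), sample_id = character(0),
                      gene_id = character(0), start = integer(0),
                      seq = character(0)))
  }
  do.call(rbind, out)
}

#' Write a simulated dataset to disk
#'
#' Writes the reference CDS FASTA, gene table, sample table, cross and wild
#' VCFs, reads in the SAM dialect, a truth JSON and a manifest. Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory
#' @param force overwrite a non-empty existing directory
#' @param write_reads also emit per-individual reads (can be slow)
#' @return invisibly, the truth bundle
#' @export
generate_dataset <- function(config, out_dir, force = FALSE, write_reads = TRUE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stop("output directory ", out_dir, " is not empty (use force = TRUE)",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_dataset(config)
  cfg <- truth$config
  paths <- c(ref = "ref.fasta", genes = "genes.tsv", samples = "samples.tsv",
             cross = "cross.vcf", wild = "wild.vcf", truth = "truth.json",
             config = "config.json")
  if (write_reads) paths <- c(paths, reads = "reads.sam")
  full <- file.path(out_dir, paths)
  names(full) <- names(paths)
  write_fasta(stats::setNames(truth$genes$cds, truth$genes$gene_id), full[["ref"]])
  utils::write.table(truth$genes[, c("gene_id", "pos_kb", "stratum", "d", "fpkm")],
                     full[["genes"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$samples, full[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth$cross_vs)) write_vcf(truth$cross_vs, full[["cross"]])
  if (!is.null(truth$wild_vs)) write_vcf(truth$wild_vs, full[["wild"]])
  if (write_reads) write_sam_reads(dataset_reads(truth), full[["reads"]])
  truth_json <- list(
    boundaries_kb = cfg$boundaries_kb,
    genes = truth$genes[, c("gene_id", "pos_kb", "stratum", "d", "fpkm")],
    y_haplotypes = lapply(truth$per_gene, function(pg) hap_to_seq(pg$y_hap)),
    fixed_diffs = lapply(truth$per_gene, function(pg) pg$fixed_diffs)
  )
  jsonlite::write_json(truth_json, full[["truth"]], auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(cfg), full[["config"]], auto_unbox = TRUE, digits = NA)
  manifest <- data.frame(file = unname(paths),
                         bytes = file.size(full), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(truth)
}
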