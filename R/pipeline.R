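# End-to-end orchestration: simulate or load inputs, detect Y-linked SNPs,
# assemble Y gametologs, compute per-gene statistics, and map stratum
# boundaries, writing a run directory with manifest and stage log. Stages
# compute in memory and files are written only after all requested stages
# succeed, so a failed run never leaves a mixture of fresh and stale outputs.

#' Per-gene nucleotide diversity from genotypes
#'
#' pi at fourfold-degenerate sites of `cds` computed from unphased genotypes:
#' at each masked site the per-site pairwise diversity is 2p(1-p) n/(n-1) with
#' p the alt-allele frequency among the 2 x (called samples) alleles;
#' monomorphic masked sites contribute 0.
#'
#' @param vs `variant_set` for one gene
#' @param sample_ids samples (columns) to use
#' @param cds reference CDS of the gene
#' @return list(pi, n_sites, n_segregating)
#' @export
pi_from_genotypes <- function(vs, sample_ids, cds) {
  mask <- fourfold_mask(cds)
  if (length(mask) == 0L) return(list(pi = NA_real_, n_sites = 0L, n_segregating = 0L))
  g <- vs$geno[, sample_ids, drop = FALSE]
  per_site <- numeric(length(mask))
  seg <- 0L
  for (k in seq_along(mask)) {
    p <- mask[[k]]
    i <- which(vs$sites$cds_pos == p)
    if (length(i) == 0L) next
    gg <- g[i[[1L]], ]
    called <- gg != "missing"
    n_alleles <- 2L * sum(called)
    if (n_alleles < 2L) { per_site[[k]] <- NA_real_; next }
    alt <- sum(gg[called] == "het") + 2L * sum(gg[called] == "hom_alt")
    pfreq <- alt / n_alleles
    per_site[[k]] <- 2 * pfreq * (1 - pfreq) * n_alleles / (n_alleles - 1)
    if (alt > 0L && alt < n_alleles) seg <- seg + 1L
  }
  usable <- !is.na(per_site)
  list(pi = mean(per_site[usable]), n_sites = sum(usable), n_segregating = seg)
}

#' Genotype dosage matrix for ZnS
#'
#' Alt-allele dosage (0/1/2, NA for missing) per sample at each site of a
#' gene's variant set, restricted to sites segregating among the chosen
#' samples.
#'
#' @param vs `variant_set` for one gene
#' @param sample_ids samples to use
#' @return numeric matrix samples x segregating sites (may have 0 columns)
#' @export
genotype_dosage <- function(vs, sample_ids) {
  g <- vs$geno[, sample_ids, drop = FALSE]
  dos <- matrix(NA_real_, nrow = length(sample_ids), ncol = n_sites(vs),
                dimnames = list(sample_ids, NULL))
  dos[t(g) == "hom_ref"] <- 0
  dos[t(g) == "het"] <- 1
  dos[t(g) == "hom_alt"] <- 2
  seg <- apply(dos, 2L, function(x) {
    v <- stats::var(x, na.rm = TRUE)
    !is.na(v) && v > 0
  })
  dos[, seg, drop = FALSE]
}

validate_run_config <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(min_qual = 500, max_missing = 10L, min_sons = 10L,
                   min_males = 6L, seed = 1L, n_permutations = 9999L,
                   stages = c("detect", "assemble", "stats", "map"))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  stopifnot(config$min_qual > 0, config$max_missing > 0,
            config$min_sons > 0, config$min_males > 0)
  path_keys <- c("ref_fasta", "genes_tsv", "samples_tsv", "cross_vcf",
                 "wild_vcf", "reads_sam", "evidence_tsv")
  for (k in intersect(path_keys, names(config))) {
    if (!is.null(config[[k]]) && !file.exists(config[[k]])) {
      stop("input file for '", k, "' does not exist: ", config[[k]],
           call. = FALSE)
    }
  }
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  config
}

#' Run the full strata-mapping pipeline
#'
#' Two modes. Evidence-only: `config$evidence_tsv` points at a per-gene
#' evidence table; only boundary inference and the gradient test run. Full:
#' `config` carries paths for ref_fasta, genes_tsv, samples_tsv, cross_vcf,
#' wild_vcf and (optionally) reads_sam; Y-SNPs are detected in both cohorts,
#' Y gametologs assembled from reads, per-gene statistics computed, and
#' boundaries inferred from the derived evidence table. All inputs are
#' validated before any stage executes; outputs are written to
#' `config$out_dir` together with `manifest.tsv` and `run_log.txt`.
#'
#' @param config named list; see Details
#' @return invisibly, a list of stage results (evidence table, boundaries,
#'   gradient, consensus report, stats)
#' @export
run_all <- function(config) {
  config <- validate_run_config(config)
  log_lines <- character(0)
  log_msg <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  results <- list()

  if (!is.null(config$evidence_tsv)) {
    log_msg("evidence-only mode: ", config$evidence_tsv)
    evidence <- load_evidence_table(config$evidence_tsv)
  } else {
    for (k in c("ref_fasta", "genes_tsv", "samples_tsv", "cross_vcf", "wild_vcf")) {
      if (is.null(config[[k]])) stop("config$", k, " is required", call. = FALSE)
    }
    cds <- read_fasta(config$ref_fasta)
    genes <- utils::read.table(config$genes_tsv, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    samples <- utils::read.table(config$samples_tsv, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    cross_ids <- samples$sample_id[samples$role != "wild"]
    wild_ids <- samples$sample_id[samples$role == "wild"]
    cross_vs <- read_vcf(config$cross_vcf, cross_ids)
    wild_vs <- read_vcf(config$wild_vcf, wild_ids)
    log_msg("loaded ", n_sites(cross_vs), " cross sites (",
            attr(cross_vs, "n_skipped"), " skipped), ",
            n_sites(wild_vs), " wild sites")

    # stage: detect
    cq <- quality_filter(cross_vs, config$min_qual)
    log_msg("cross quality > ", config$min_qual, ": ", n_sites(cq), "/",
            n_sites(cross_vs))
    cand <- candidate_parental_sites(cq)
    log_msg("father-het / mother-hom_ref candidates: ", n_sites(cand))
    segr <- segregation_filter(cand, samples, config$max_missing,
                               config$min_sons)
    log_msg("segregation passes: ", sum(segr$passes_segregation))
    wq <- quality_filter(wild_vs, config$min_qual)
    lat <- population_filter(wq, samples, "latifolia", config$min_males)
    dio <- population_filter(wq, samples, "dioica", config$min_males)
    log_msg("population passes: latifolia ", sum(lat$passes_population),
            ", dioica ", sum(dio$passes_population))
    counts <- per_gene_ysnp_counts(genes, segr, lat, dio)
    results$segr <- segr; results$lat <- lat; results$dio <- dio

    # stage: assemble (needs reads)
    assembly <- NULL
    if ("assemble" %in% config$stages && !is.null(config$reads_sam)) {
      reads <- read_sam_reads(config$reads_sam,
                              cds_len = stats::setNames(nchar(cds), names(cds)))
      ysnp_tab <- rbind(
        cq$sites[segr$passes_segregation, c("gene_id", "cds_pos", "alt")],
        wq$sites[lat$passes_population, c("gene_id", "cds_pos", "alt")]
      )
      ysnp_tab <- unique(ysnp_tab)
      assembly <- assemble_y_genes(reads, ysnp_tab, cds)
      log_msg("assembled Y consensus for ", nrow(assembly$report), " genes")
      results$assembly <- assembly
    }

    # stage: stats
    stats_tab <- NULL
    if ("stats" %in% config$stages) {
      females <- samples$sample_id[samples$role == "wild" &
                                     samples$species == "latifolia" &
                                     samples$sex == "F"]
      stats_rows <- lapply(seq_len(nrow(genes)), function(i) {
        g <- genes$gene_id[[i]]
        gvs <- subset_sites(wild_vs, wild_vs$sites$gene_id == g)
        pv <- pi_from_genotypes(gvs, females, cds[[g]])
        dose <- genotype_dosage(gvs, females)
        zns <- if (ncol(dose) >= 2L) kelly_zns(dose) else NA_real_
        ks <- ka <- NA_real_
        if (!is.null(assembly) && g %in% names(assembly$consensus)) {
          dv <- pairwise_divergence(cds[[g]], assembly$consensus[[g]]$seq, g)
          ks <- dv$ks; ka <- dv$ka
        }
        data.frame(gene_id = g, pos_kb = genes$pos_kb[[i]],
                   pi_4fold = pv$pi, n_4fold_sites = pv$n_sites,
                   n_segregating = pv$n_segregating, zns = zns,
                   ks = ks, ka = ka, stringsAsFactors = FALSE)
      })
      stats_tab <- do.call(rbind, stats_rows)
      results$stats <- stats_tab
      log_msg("per-gene stats computed for ", nrow(stats_tab), " genes")
    }

    evidence <- counts
    evidence$ks <- if (!is.null(stats_tab)) stats_tab$ks else NA_real_
    if (!is.null(assembly)) {
      m <- match(evidence$gene_id, assembly$report$gene_id)
      evidence$ycds_bp <- assembly$report$ycds_bp[m]
      evidence$ycds_pct <- assembly$report$ycds_pct[m]
    } else {
      evidence$ycds_bp <- NA_integer_
      evidence$ycds_pct <- NA_real_
    }
    evidence$stratum <- if ("stratum" %in% names(genes)) genes$stratum else "unknown"
    evidence <- evidence[order(evidence$pos_kb), , drop = FALSE]
  }
  results$evidence <- evidence

  boundaries <- infer_all_boundaries(evidence)
  log_msg("boundaries (kb): segr=", boundaries$segregation_boundary_kb,
          " par/str3=", boundaries$par_str3_boundary_kb,
          " str3/str2=", boundaries$str3_str2_boundary_kb)
  gradient <- gradient_test(evidence, "Str3",
                            n_permutations = config$n_permutations,
                            seed = config$seed)
  results$boundaries <- boundaries
  results$gradient <- gradient
  results$stratum3_length_mb <- stratum_length_mb(boundaries)

  # write phase: nothing has touched out_dir before this point
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  wt <- function(df, name) {
    p <- file.path(out, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, name)
  }
  wt(evidence, "evidence.tsv")
  bdf <- data.frame(boundary = c("segregation", "par_str3", "str3_str2"),
                    pos_kb = c(boundaries$segregation_boundary_kb,
                               boundaries$par_str3_boundary_kb,
                               boundaries$str3_str2_boundary_kb),
                    gene_id = c(boundaries$segregation_gene,
                                boundaries$par_str3_gene,
                                boundaries$str3_str2_gene))
  wt(bdf, "boundaries.tsv")
  gdf <- data.frame(stratum = "Str3", slope_per_kb = gradient$slope,
                    p_perm = gradient$p_perm, n_genes = gradient$n_genes,
                    n_permutations = gradient$n_permutations,
                    stratum3_length_mb = as.numeric(results$stratum3_length_mb))
  wt(gdf, "gradient.tsv")
  if (!is.null(results$stats)) wt(results$stats, "stats.tsv")
  if (!is.null(results$assembly)) {
    wt(results$assembly$report, "ycds_report.tsv")
    fa <- file.path(out, "yconsensus.fasta")
    write_fasta(vapply(results$assembly$consensus, function(x) x$seq,
                       character(1)), fa)
    written <- c(written, "yconsensus.fasta")
  }
  jsonlite::write_json(config[setdiff(names(config), "stages")],
                       file.path(out, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  written <- c(written, "config.json")
  writeLines(log_lines, file.path(out, "run_log.txt"))
  written <- c(written, "run_log.txt")
  utils::write.table(
    data.frame(file = written, bytes = file.size(file.path(out, written))),
    file.path(out, "manifest.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(results)
}
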