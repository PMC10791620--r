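# Y-linked SNP detection from two evidence classes: segregation in a genetic
# cross (alleles transmitted father-to-son and never to daughters) and
# male-specificity among wild unrelated samples.

geno_has_alt <- function(g) g %in% c("het", "hom_alt")

#' Filter variant sites on caller quality
#'
#' Retains sites with quality strictly greater than `min_qual`; order is
#' preserved.
#'
#' @param vs a `variant_set`
#' @param min_qual quality threshold (strict >)
#' @return filtered `variant_set`
#' @export
quality_filter <- function(vs, min_qual = 500) {
  if (any(is.na(vs$sites$quality))) stop("missing quality on some sites", call. = FALSE)
  subset_sites(vs, vs$sites$quality > min_qual)
}

#' Select candidate parental sites
#'
#' Retains sites where the father is heterozygous and the mother homozygous
#' for the reference allele; a missing genotype in either parent excludes the
#' site.
#'
#' @param vs a `variant_set`
#' @param father_id,mother_id parent sample ids (must be genotype columns)
#' @return filtered `variant_set`
#' @export
candidate_parental_sites <- function(vs, father_id = "father",
                                     mother_id = "mother") {
  if (!all(c(father_id, mother_id) %in% vs$samples)) {
    stop("unknown parent sample id", call. = FALSE)
  }
  keep <- vs$geno[, father_id] == "het" & vs$geno[, mother_id] == "hom_ref"
  subset_sites(vs, keep)
}

#' Segregation filter for Y-linked SNPs
#'
#' A site passes when, over all progeny jointly, fewer than `max_missing`
#' genotypes are missing, no daughter's genotype contains the alt allele, and
#' at least `min_males_with_alt` sons' genotypes contain the alt allele
#' ("contains" = het or hom_alt).
#'
#' @param vs a `variant_set` of candidate parental sites
#' @param samples sample table (sample_id, sex, role)
#' @param max_missing strict upper bound on missing progeny genotypes
#' @param min_males_with_alt minimum sons carrying the alt allele
#' @return data.frame, one row per site: gene_id, cds_pos, n_sons_alt,
#'   n_daughters_alt, n_missing, passes_segregation
#' @export
segregation_filter <- function(vs, samples, max_missing = 10L,
                               min_males_with_alt = 10L) {
  sons <- samples$sample_id[samples$role == "son"]
  daughters <- samples$sample_id[samples$role == "daughter"]
  if (length(sons) == 0L) stop("pedigree has no sons", call. = FALSE)
  if (!all(c(sons, daughters) %in% vs$samples)) {
    stop("progeny missing from genotype columns", call. = FALSE)
  }
  g_son <- vs$geno[, sons, drop = FALSE]
  g_dau <- vs$geno[, daughters, drop = FALSE]
  n_sons_alt <- rowSums(matrix(geno_has_alt(g_son), nrow = n_sites(vs)))
  n_dau_alt <- rowSums(matrix(geno_has_alt(g_dau), nrow = n_sites(vs)))
  n_missing <- rowSums(matrix(g_son == "missing", nrow = n_sites(vs))) +
    rowSums(matrix(g_dau == "missing", nrow = n_sites(vs)))
  data.frame(
    gene_id = vs$sites$gene_id,
    cds_pos = vs$sites$cds_pos,
    n_sons_alt = n_sons_alt,
    n_daughters_alt = n_dau_alt,
    n_missing = n_missing,
    passes_segregation = n_missing < max_missing & n_dau_alt == 0L &
      n_sons_alt >= min_males_with_alt,
    stringsAsFactors = FALSE
  )
}

#' Population filter for male-specific SNPs in wild samples
#'
#' A site passes for a species when at least `min_males` wild males of that
#' species carry the alt allele and no wild female of that species does.
#'
#' @param vs a `variant_set` over wild samples
#' @param samples sample table (sample_id, species, sex, role)
#' @param species species to test
#' @param min_males minimum males carrying the alt allele
#' @return data.frame per site: gene_id, cds_pos, n_males_alt, n_females_alt,
#'   passes_population
#' @export
population_filter <- function(vs, samples, species, min_males = 6L) {
  w <- samples[samples$role == "wild" & samples$species == species, ]
  males <- w$sample_id[w$sex == "M"]
  females <- w$sample_id[w$sex == "F"]
  if (length(males) < min_males) {
    stop("only ", length(males), " wild males available for ", species,
         "; criterion requires at least ", min_males, call. = FALSE)
  }
  if (!all(c(males, females) %in% vs$samples)) {
    stop("wild samples missing from genotype columns", call. = FALSE)
  }
  g_m <- vs$geno[, males, drop = FALSE]
  g_f <- vs$geno[, females, drop = FALSE]
  n_m <- rowSums(matrix(geno_has_alt(g_m), nrow = n_sites(vs)))
  n_f <- rowSums(matrix(geno_has_alt(g_f), nrow = n_sites(vs)))
  data.frame(
    gene_id = vs$sites$gene_id,
    cds_pos = vs$sites$cds_pos,
    n_males_alt = n_m,
    n_females_alt = n_f,
    passes_population = n_m >= min_males & n_f == 0L,
    stringsAsFactors = FALSE
  )
}

#' Per-gene Y-SNP counts by evidence class
#'
#' Counts passing sites per gene for the segregation class and the two wild
#' population classes. Genes with at least one variant site in any cohort get
#' integer counts (zero recorded as zero); genes with no variant sites at all
#' get NA counts.
#'
#' @param genes data.frame with at least gene_id (and optionally pos_kb)
#' @param segr result of [segregation_filter()] (or NULL)
#' @param lat,dio results of [population_filter()] per species (or NULL)
#' @return data.frame: gene_id, (pos_kb), n_segr, n_lat, n_dio
#' @export
per_gene_ysnp_counts <- function(genes, segr = NULL, lat = NULL, dio = NULL) {
  count_for <- function(ev, pass_col) {
    if (is.null(ev) || nrow(ev) == 0L) {
      return(stats::setNames(rep(NA_integer_, nrow(genes)), genes$gene_id))
    }
    tab <- tapply(ev[[pass_col]], ev$gene_id, function(x) sum(x))
    out <- rep(NA_integer_, nrow(genes))
    names(out) <- genes$gene_id
    seen <- intersect(genes$gene_id, names(tab))
    out[seen] <- as.integer(tab[seen])
    out
  }
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  if ("pos_kb" %in% names(genes)) out$pos_kb <- genes$pos_kb
  out$n_segr <- count_for(segr, "passes_segregation")
  out$n_lat <- count_for(lat, "passes_population")
  out$n_dio <- count_for(dio, "passes_population")
  out
}
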