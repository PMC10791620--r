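# Independent oracles and small fixture builders used across the suite.

# --- independent Nei-Gojobori oracle -----------------------------------------
# Translation comes from Biostrings' genetic-code table (not the package's own
# table); site counting and pathway enumeration are written as direct
# recursion, independent of the implementation under test.

oracle_translate <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  if (grepl("[^ACGT]", codon)) return(NA_character_)
  unname(gc[[codon]])
}

oracle_codon_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracle_translate(codon)
  s <- 0
  for (i in 1:3) {
    for (b in setdiff(bases, substr(codon, i, i))) {
      mut <- codon
      substr(mut, i, i) <- b
      aa2 <- oracle_translate(mut)
      if (aa2 == aa && aa2 != "*") s <- s + 1 / 3
    }
  }
  s
}

# all orderings of the differing positions, by recursion
oracle_paths <- function(pos) {
  if (length(pos) <= 1L) return(list(pos))
  out <- list()
  for (k in seq_along(pos)) {
    for (tail in oracle_paths(pos[-k])) out[[length(out) + 1L]] <- c(pos[[k]], tail)
  }
  out
}

oracle_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (length(pos) == 0L) return(c(0, 0))
  paths <- oracle_paths(pos)
  res <- lapply(paths, function(ord) {
    cur <- c1
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracle_translate(nxt) == "*") blocked <- TRUE
      if (oracle_translate(cur) == oracle_translate(nxt)) syn <- syn + 1
      else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    list(sd = syn, nd = nonsyn, blocked = blocked)
  })
  ok <- !vapply(res, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(res))
  c(mean(vapply(res[ok], `[[`, numeric(1), "sd")),
    mean(vapply(res[ok], `[[`, numeric(1), "nd")))
}

oracle_ng <- function(x_cds, y_cds) {
  cx <- substring(x_cds, seq(1, nchar(x_cds), 3), seq(3, nchar(x_cds), 3))
  cy <- substring(y_cds, seq(1, nchar(y_cds), 3), seq(3, nchar(y_cds), 3))
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(cx)) {
    if (grepl("[^ACGT]", cx[[i]]) || grepl("[^ACGT]", cy[[i]])) next
    if (oracle_translate(cx[[i]]) == "*" || oracle_translate(cy[[i]]) == "*") next
    s_i <- (oracle_codon_sites(cx[[i]]) + oracle_codon_sites(cy[[i]])) / 2
    S <- S + s_i
    N <- N + 3 - s_i
    d <- oracle_pair_diffs(cx[[i]], cy[[i]])
    Sd <- Sd + d[[1L]]
    Nd <- Nd + d[[2L]]
  }
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ks = jc(if (S > 0) Sd / S else NA), ka = jc(if (N > 0) Nd / N else NA),
       s_sites = S, n_sites = N, sd = Sd, nd = Nd)
}

# --- fixture builders --------------------------------------------------------

random_codon_pair <- function() {
  bases <- c("A", "C", "G", "T")
  repeat {
    c1 <- paste(sample(bases, 3, replace = TRUE), collapse = "")
    nd <- sample(0:3, 1)
    c2 <- c1
    for (p in sample(1:3, nd)) {
      substr(c2, p, p) <- sample(setdiff(bases, substr(c2, p, p)), 1)
    }
    if (oracle_translate(c1) != "*" && oracle_translate(c2) != "*") {
      return(c(c1, c2))
    }
  }
}

# a minimal variant_set: genotypes given as a named list sample -> code vector
make_vs <- function(gene_id, cds_pos, ref, alt, quality, geno_list) {
  geno <- do.call(cbind, geno_list)
  variant_set(
    data.frame(gene_id = gene_id, cds_pos = cds_pos, ref = ref, alt = alt,
               quality = quality, stringsAsFactors = FALSE),
    geno
  )
}

# pedigree/sample table for a cross plus wild samples
make_samples <- function(n_sons = 21, n_daughters = 32,
                         n_wild_m = 7, n_wild_f = 7) {
  cfg <- sim_config(n_sons = n_sons, n_daughters = n_daughters,
                    n_wild_males = n_wild_m, n_wild_females = n_wild_f)
  ystrata:::sample_table(cfg)
}

# single-row genotype matrix helper: one site across many samples
geno_row <- function(samples, default = "hom_ref", ...) {
  g <- stats::setNames(rep(default, length(samples)), samples)
  over <- list(...)
  for (nm in names(over)) g[grep(nm, names(g))] <- over[[nm]]
  matrix(g, nrow = 1, dimnames = list(NULL, samples))
}
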