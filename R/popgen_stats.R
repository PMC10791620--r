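# Per-gene population-genetic statistics: fourfold-degenerate site masking,
# nucleotide diversity, Kelly's ZnS linkage disequilibrium, and pairwise
# synonymous / non-synonymous divergence by Nei-Gojobori (1986) counting with
# Jukes-Cantor correction.

seqs_to_matrix <- function(seqs) {
  if (is.matrix(seqs)) return(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences differ in length", call. = FALSE)
  do.call(rbind, strsplit(toupper(seqs), ""))
}

#' Fourfold-degenerate column mask for an alignment of CDS
#'
#' A third-codon-position column is kept iff every sequence with a fully
#' resolved codon at that codon (no N) has identical first two bases and those
#' two bases place the codon in a fourfold-degenerate family of the standard
#' genetic code. Codons unresolved in all sequences are dropped.
#'
#' @param seqs character vector of equal-length in-frame sequences, or a base
#'   matrix (rows = sequences)
#' @return integer vector of kept alignment column indices (third positions)
#' @export
fourfold_mask <- function(seqs) {
  m <- seqs_to_matrix(seqs)
  L <- ncol(m)
  if (L %% 3L != 0L) stop("alignment length not divisible by 3", call. = FALSE)
  fourfold_prefix <- unique(substr(names(.codon_table)[
    vapply(names(.codon_table), function(cod) {
      pre <- substr(cod, 1L, 2L)
      fam <- .codon_table[paste0(pre, BASES)]
      length(unique(fam)) == 1L && !any(fam == "*")
    }, logical(1))], 1L, 2L))
  keep <- integer(0)
  for (c_i in seq_len(L / 3L)) {
    cols <- (c_i - 1L) * 3L + 1:3
    codons <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    resolved <- !grepl("N", codons, fixed = TRUE)
    if (!any(resolved)) next
    prefixes <- unique(substr(codons[resolved], 1L, 2L))
    if (length(prefixes) != 1L) next
    if (prefixes %in% fourfold_prefix) keep <- c(keep, cols[[3L]])
  }
  keep
}

#' Nucleotide diversity over masked sites
#'
#' pi = mean over masked sites of (pairwise differences / pairs compared),
#' with pairwise deletion of N. Reported per site.
#'
#' @param seqs >= 2 equal-length sequences (vector or base matrix)
#' @param mask column indices to use; all columns when NULL
#' @return list(pi, n_sites, n_segregating); pi is NA (with a message) when no
#'   masked site is comparable
#' @export
nucleotide_diversity <- function(seqs, mask = NULL) {
  m <- seqs_to_matrix(seqs)
  if (nrow(m) < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (is.null(mask)) mask <- seq_len(ncol(m))
  if (length(mask) == 0L) {
    message("no sites in mask; pi undefined")
    return(list(pi = NA_real_, n_sites = 0L, n_segregating = 0L))
  }
  per_site <- vapply(mask, function(p) {
    col <- m[, p]
    col <- col[col %in% BASES]
    k <- length(col)
    if (k < 2L) return(NA_real_)
    tab <- table(col)
    pairs <- k * (k - 1) / 2
    same <- sum(tab * (tab - 1) / 2)
    (pairs - same) / pairs
  }, numeric(1))
  usable <- !is.na(per_site)
  if (!any(usable)) {
    message("no comparable masked sites; pi undefined")
    return(list(pi = NA_real_, n_sites = 0L, n_segregating = 0L))
  }
  list(pi = mean(per_site[usable]),
       n_sites = sum(usable),
       n_segregating = sum(per_site[usable] > 0))
}

#' Kelly's ZnS linkage-disequilibrium statistic
#'
#' ZnS = (2 / (S (S - 1))) * sum over site pairs of r^2, where r is the
#' correlation of allele indicators between two segregating sites. On phased
#' haplotypes the indicator is carriage of the alt allele; on unphased
#' genotypes the alt-allele dosage is used as a proxy (both are columns of
#' `allele_mat`).
#'
#' @param allele_mat numeric matrix, rows = haplotypes (0/1) or individuals
#'   (dosage 0/1/2), columns = segregating sites; NA entries are allowed and
#'   handled by pairwise-complete correlation
#' @return ZnS in [0, 1], or NA (with a message) when fewer than 2 sites
#' @export
kelly_zns <- function(allele_mat) {
  S <- ncol(allele_mat)
  if (S < 2L) {
    message("fewer than 2 segregating sites; ZnS undefined")
    return(NA_real_)
  }
  mono <- apply(allele_mat, 2L, function(x) stats::var(x, na.rm = TRUE) == 0)
  if (any(mono, na.rm = TRUE)) stop("monomorphic site in ZnS input", call. = FALSE)
  r2 <- numeric(0)
  for (i in seq_len(S - 1L)) {
    for (j in (i + 1L):S) {
      r <- suppressWarnings(stats::cor(allele_mat[, i], allele_mat[, j],
                                       use = "pairwise.complete.obs"))
      r2 <- c(r2, r^2)
    }
  }
  mean(r2)
}

# ---------------------------------------------------------------------------
# Nei-Gojobori divergence

# memoized per-codon and per-codon-pair quantities: only 64 codons and 64^2
# pairs exist, so caching makes whole-CDS divergence linear-time
.ng_cache <- new.env(parent = emptyenv())

codon_syn_sum <- function(codon) {
  key <- paste0("s_", codon)
  v <- .ng_cache[[key]]
  if (is.null(v)) {
    v <- sum(codon_syn_fractions(codon))
    .ng_cache[[key]] <- v
  }
  v
}

codon_path_diffs_cached <- function(c1, c2) {
  key <- paste0(c1, c2)
  v <- .ng_cache[[key]]
  if (is.null(v)) {
    v <- codon_path_diffs(c1, c2)
    .ng_cache[[key]] <- v
  }
  v
}

# Average synonymous/non-synonymous difference counts between two codons over
# all minimal mutational pathways; pathways passing through a stop codon are
# excluded (when every pathway is blocked, all are used as a fallback).
codon_path_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(pos) else {
    if (nd == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) pos[o])
    }
  }
  eval_path <- function(order) {
    cur <- c1
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      a1 <- translate_codon(cur); a2 <- translate_codon(nxt)
      if (is.na(a2) || a2 == "*") blocked <- TRUE
      if (!is.na(a1) && !is.na(a2) && a1 == a2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, blocked = as.numeric(blocked))
  }
  res <- vapply(perms, eval_path, numeric(3))
  ok <- res["blocked", ] == 0
  if (!any(ok)) ok <- rep(TRUE, ncol(res))  # all pathways blocked: use all
  c(syn = mean(res["syn", ok]), nonsyn = mean(res["nonsyn", ok]))
}

#' Pairwise synonymous and non-synonymous divergence (Nei-Gojobori)
#'
#' Codons containing N in either sequence, stop codons and unresolved codons
#' are excluded. Synonymous (S) and non-synonymous (N) site counts are the
#' Nei-Gojobori fractional counts averaged over the two sequences; difference
#' counts average over minimal mutational pathways with stop-passing pathways
#' excluded. Proportions are Jukes-Cantor corrected,
#' d = -(3/4) log(1 - (4/3) p); p >= 3/4 flags saturation (d = NA).
#'
#' @param x_cds,y_cds equal-length in-frame CDS strings
#' @param gene_id optional identifier carried into the result
#' @return list: gene_id, ks, ka, s_sites, n_sites, n_codons_used, sd, nd,
#'   saturated_s, saturated_n
#' @export
pairwise_divergence <- function(x_cds, y_cds, gene_id = NA_character_) {
  if (nchar(x_cds) != nchar(y_cds)) stop("sequence length mismatch", call. = FALSE)
  cx <- split_codons(toupper(x_cds))
  cy <- split_codons(toupper(y_cds))
  S <- 0; Nn <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (i in seq_along(cx)) {
    c1 <- cx[[i]]; c2 <- cy[[i]]
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    a1 <- translate_codon(c1); a2 <- translate_codon(c2)
    if (is.na(a1) || is.na(a2) || a1 == "*" || a2 == "*") next
    s_i <- (codon_syn_sum(c1) + codon_syn_sum(c2)) / 2
    S <- S + s_i
    Nn <- Nn + (3 - s_i)
    d <- codon_path_diffs_cached(c1, c2)
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["nonsyn"]]
    used <- used + 1L
  }
  jc <- function(p) {
    if (is.na(p)) return(list(d = NA_real_, saturated = FALSE))
    if (p >= 3 / 4) return(list(d = NA_real_, saturated = TRUE))
    list(d = -3 / 4 * log(1 - 4 / 3 * p), saturated = FALSE)
  }
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (Nn > 0) Nd / Nn else NA_real_
  ks <- jc(ps); ka <- jc(pn)
  list(gene_id = gene_id, ks = ks$d, ka = ka$d,
       s_sites = S, n_sites = Nn, n_codons_used = used,
       sd = Sd, nd = Nd,
       saturated_s = ks$saturated, saturated_n = ka$saturated)
}

#' Mean and standard error of a per-gene statistic per stratum
#'
#' @param values numeric per-gene values (NA allowed)
#' @param strata stratum label per gene
#' @return data.frame: stratum, mean, se (NA when n = 1), n; empty strata are
#'   omitted
#' @export
stratum_summary <- function(values, strata) {
  stopifnot(length(values) == length(strata))
  ok <- !is.na(values)
  if (!any(ok)) {
    return(data.frame(stratum = character(0), mean = numeric(0),
                      se = numeric(0), n = integer(0)))
  }
  out <- do.call(rbind, lapply(split(values[ok], strata[ok]), function(v) {
    data.frame(mean = mean(v),
               se = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  out <- data.frame(stratum = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}
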