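# Boundary inference and stratum classification from per-gene Y-SNP evidence,
# plus a permutation test for the proximally increasing divergence gradient.

EVIDENCE_CLASSES <- c(segr = "n_segr", lat = "n_lat", dio = "n_dio")

#' Infer a boundary position from per-gene evidence counts
#'
#' Returns the position of the distal-most (minimum pos_kb) gene whose count
#' for the chosen evidence class reaches `min_count`; absent counts are
#' treated as zero. With `robust = c(k, m)`, the gene must additionally have
#' at least k of the next m more-proximal genes also qualifying.
#'
#' @param rows evidence table (see [load_evidence_table()])
#' @param evidence_class one of "segr", "lat", "dio"
#' @param min_count minimum qualifying count (default 1)
#' @param robust optional c(k, m) corroboration requirement (off by default)
#' @return list(pos_kb, gene_id); both NA (with a message) when no gene
#'   qualifies
#' @export
infer_boundary <- function(rows, evidence_class = c("segr", "lat", "dio"),
                           min_count = 1L, robust = NULL) {
  evidence_class <- match.arg(evidence_class)
  col <- EVIDENCE_CLASSES[[evidence_class]]
  rows <- rows[order(rows$pos_kb), , drop = FALSE]
  counts <- rows[[col]]
  counts[is.na(counts)] <- 0L
  qual <- counts >= min_count
  cand <- which(qual)
  if (!is.null(robust)) {
    k <- robust[[1L]]; m <- robust[[2L]]
    cand <- cand[vapply(cand, function(i) {
      nxt <- qual[seq(i + 1L, min(i + m, length(qual)))]
      sum(nxt) >= k
    }, logical(1))]
  }
  if (length(cand) == 0L) {
    message("no gene qualifies for evidence class '", evidence_class, "'")
    return(list(pos_kb = NA_real_, gene_id = NA_character_))
  }
  i <- cand[[1L]]
  list(pos_kb = rows$pos_kb[[i]], gene_id = rows$gene_id[[i]])
}

#' Classify genes into PAR / stratum 3 / stratum 2
#'
#' PAR: pos_kb < PAR/Str3 boundary; Str3: up to (excluding) the Str3/Str2
#' boundary; Str2 otherwise. Boundaries are gene positions, so the boundary
#' gene itself classifies into the proximal stratum.
#'
#' @param rows evidence table with pos_kb
#' @param boundaries list/vector with par_str3_boundary_kb and
#'   str3_str2_boundary_kb
#' @return character vector of labels, one per row of `rows`
#' @export
classify_strata <- function(rows, boundaries) {
  b1 <- boundaries[["par_str3_boundary_kb"]]
  b2 <- boundaries[["str3_str2_boundary_kb"]]
  stopifnot(is.finite(b1), is.finite(b2), b1 <= b2)
  ifelse(rows$pos_kb < b1, "PAR", ifelse(rows$pos_kb < b2, "Str3", "Str2"))
}

#' Infer all three boundaries from an evidence table
#'
#' @param rows evidence table
#' @param min_count,robust passed to [infer_boundary()]
#' @return list: segregation_boundary_kb, par_str3_boundary_kb,
#'   str3_str2_boundary_kb, plus the qualifying gene ids; warns (not errors)
#'   when the expected ordering segregation <= par_str3 <= str3_str2 is
#'   violated
#' @export
infer_all_boundaries <- function(rows, min_count = 1L, robust = NULL) {
  segr <- infer_boundary(rows, "segr", min_count, robust)
  lat <- infer_boundary(rows, "lat", min_count, robust)
  dio <- infer_boundary(rows, "dio", min_count, robust)
  b <- list(segregation_boundary_kb = segr$pos_kb,
            par_str3_boundary_kb = lat$pos_kb,
            str3_str2_boundary_kb = dio$pos_kb,
            segregation_gene = segr$gene_id,
            par_str3_gene = lat$gene_id,
            str3_str2_gene = dio$gene_id)
  ord <- c(b$segregation_boundary_kb, b$par_str3_boundary_kb,
           b$str3_str2_boundary_kb)
  if (!any(is.na(ord)) && is.unsorted(ord)) {
    warning("boundary ordering violated: segregation <= PAR/Str3 <= Str3/Str2 expected")
  }
  b
}

#' Stratum 3 length in whole megabases
#'
#' floor(Str3/Str2 boundary / 1000) - floor(PAR/Str3 boundary / 1000):
#' whole-Mb truncation of both boundary positions, mirroring headline
#' reporting conventions. The exact kb length is returned as an attribute.
#'
#' @param boundaries list with par_str3_boundary_kb, str3_str2_boundary_kb
#' @return length in Mb (integer-valued numeric), NA when a boundary is absent
#' @export
stratum_length_mb <- function(boundaries) {
  b1 <- boundaries[["par_str3_boundary_kb"]]
  b2 <- boundaries[["str3_str2_boundary_kb"]]
  if (is.null(b1) || is.null(b2) || is.na(b1) || is.na(b2)) return(NA_real_)
  out <- floor(b2 / 1000) - floor(b1 / 1000)
  attr(out, "exact_kb") <- b2 - b1
  out
}

#' Permutation test for a proximally increasing divergence gradient
#'
#' Ordinary least-squares slope of ks on pos_kb within one stratum, with a
#' one-sided permutation p-value for slope > 0:
#' p = (1 + #\{permuted slopes >= observed\}) / (1 + n_permutations).
#'
#' @param rows evidence table with pos_kb, stratum and ks
#' @param stratum stratum label to test (default "Str3")
#' @param n_permutations number of ks permutations (>= 999)
#' @param seed RNG seed (mandatory for reproducibility)
#' @return list: slope (per kb), p_perm, n_genes, n_permutations; NULL slope
#'   and NA p (with a message) when fewer than 3 genes have defined ks
#' @export
gradient_test <- function(rows, stratum = "Str3", n_permutations = 9999L,
                          seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  stopifnot(n_permutations >= 999L)
  sub <- rows[rows$stratum == stratum & !is.na(rows$ks), , drop = FALSE]
  n <- nrow(sub)
  if (n < 3L) {
    message("fewer than 3 genes with defined ks in ", stratum)
    return(list(slope = NA_real_, p_perm = NA_real_, n_genes = n,
                n_permutations = as.integer(n_permutations)))
  }
  ols_slope <- function(x, y) {
    xc <- x - mean(x)
    sum(xc * y) / sum(xc^2)
  }
  obs <- ols_slope(sub$pos_kb, sub$ks)
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations), function(i)
    ols_slope(sub$pos_kb, sample(sub$ks)), numeric(1))
  p <- (1 + sum(perm >= obs)) / (1 + n_permutations)
  list(slope = obs, p_perm = p, n_genes = n,
       n_permutations = as.integer(n_permutations))
}
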