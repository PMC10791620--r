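# Y gametolog reconstruction: reads carrying the alt allele at one or more
# Y-linked SNPs are assigned wholesale to the Y haplotype; a per-position
# majority consensus over the selected reads gives the Y-linked CDS, with N
# at uncovered or tied positions.

#' Select reads carrying Y-linked alleles
#'
#' A read is selected iff it overlaps at least one Y-SNP position and its
#' base at at least one such position equals that site's alt allele. Reads
#' overlapping Y-SNPs but showing only reference alleles are excluded, as are
#' reads overlapping no Y-SNP.
#'
#' @param reads data.frame of reads (read_id, sample_id, gene_id, start, seq)
#' @param ysnps data.frame with gene_id, cds_pos, alt
#' @return subset of `reads`
#' @export
select_y_reads <- function(reads, ysnps) {
  if (nrow(reads) == 0L || nrow(ysnps) == 0L) return(reads[0, , drop = FALSE])
  keep <- vapply(seq_len(nrow(reads)), function(i) {
    snps <- ysnps[ysnps$gene_id == reads$gene_id[[i]], , drop = FALSE]
    if (nrow(snps) == 0L) return(FALSE)
    start <- reads$start[[i]]
    end <- start + nchar(reads$seq[[i]]) - 1L
    ov <- snps$cds_pos >= start & snps$cds_pos <= end
    if (!any(ov)) return(FALSE)
    base_at <- substring(reads$seq[[i]], snps$cds_pos[ov] - start + 1L,
                         snps$cds_pos[ov] - start + 1L)
    any(base_at == snps$alt[ov])
  }, logical(1))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call a Y consensus sequence from selected reads
#'
#' Per CDS position the majority base among covering reads is called (N bases
#' in reads are ignored); zero coverage, coverage below `min_depth`, and
#' exact ties all yield N. An empty read set yields an all-N consensus.
#'
#' @param y_reads selected reads for one gene (see [select_y_reads()])
#' @param cds the gene's X-linked reference CDS (defines the length)
#' @param gene_id gene identifier for the result
#' @param min_depth minimum covering reads for a call (default 1)
#' @return list of class `y_consensus`: gene_id, seq, completeness_pct,
#'   premature_stop, stop_codons, n_supporting_reads
#' @export
call_consensus <- function(y_reads, cds, gene_id, min_depth = 1L) {
  L <- nchar(cds)
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(BASES, NULL))
  for (i in seq_len(nrow(y_reads))) {
    b <- strsplit(y_reads$seq[[i]], "")[[1L]]
    pos <- y_reads$start[[i]] + seq_along(b) - 1L
    ok <- b %in% BASES & pos <= L
    for (j in which(ok)) counts[b[[j]], pos[[j]]] <- counts[b[[j]], pos[[j]]] + 1L
  }
  cons <- vapply(seq_len(L), function(p) {
    cv <- counts[, p]
    tot <- sum(cv)
    if (tot < min_depth || tot == 0L) return("N")
    mx <- max(cv)
    top <- BASES[cv == mx]
    if (length(top) > 1L) "N" else top  # tie -> neither allele trusted
  }, character(1))
  seq <- paste(cons, collapse = "")
  stops <- check_premature_stops(seq)
  structure(list(
    gene_id = gene_id,
    seq = seq,
    completeness_pct = completeness_report(seq),
    premature_stop = stops$premature_stop,
    stop_codons = stops$positions,
    n_supporting_reads = nrow(y_reads)
  ), class = "y_consensus")
}

#' @export
print.y_consensus <- function(x, ...) {
  cat(sprintf("y_consensus %s: %d bp, %.1f%% complete, %d reads%s\n",
              x$gene_id, nchar(x$seq), x$completeness_pct,
              x$n_supporting_reads,
              if (x$premature_stop) ", PREMATURE STOP" else ""))
  invisible(x)
}

#' Consensus completeness
#'
#' @param seq consensus sequence (string over A,C,G,T,N)
#' @return 100 * (non-N positions) / length
#' @export
completeness_report <- function(seq) {
  L <- nchar(seq)
  if (L == 0L) return(0)
  n_count <- nchar(gsub("[^N]", "", seq))
  100 * (L - n_count) / L
}

#' Check a CDS for premature stop codons
#'
#' Codons containing N are skipped; only in-frame TAA/TAG/TGA before the final
#' codon count.
#'
#' @param seq in-frame CDS string, length divisible by 3
#' @return list(premature_stop = logical, positions = codon indices)
#' @export
check_premature_stops <- function(seq) {
  codons <- split_codons(seq)
  n <- length(codons)
  if (n <= 1L) return(list(premature_stop = FALSE, positions = integer(0)))
  internal <- codons[seq_len(n - 1L)]
  resolved <- !grepl("N", internal, fixed = TRUE)
  hits <- which(resolved & internal %in% STOP_CODONS)
  list(premature_stop = length(hits) > 0L, positions = hits)
}

#' Assemble Y consensus sequences for many genes
#'
#' Convenience wrapper: selects Y-carrying reads per gene and calls each
#' consensus, returning a per-gene report in the shape of the evidence table's
#' Y-CDS columns.
#'
#' @param reads read data.frame (possibly many genes)
#' @param ysnps data.frame gene_id, cds_pos, alt of Y-linked SNPs
#' @param cds named character vector of reference CDS per gene
#' @param min_depth minimum depth for a consensus call
#' @return list with `consensus` (named list of `y_consensus`) and `report`
#'   (data.frame gene_id, ycds_bp, ycds_pct, premature_stop, n_reads)
#' @export
assemble_y_genes <- function(reads, ysnps, cds, min_depth = 1L) {
  y_reads <- select_y_reads(reads, ysnps)
  gene_ids <- intersect(names(cds), unique(ysnps$gene_id))
  cons <- lapply(gene_ids, function(g) {
    call_consensus(y_reads[y_reads$gene_id == g, , drop = FALSE],
                   cds[[g]], g, min_depth = min_depth)
  })
  names(cons) <- gene_ids
  report <- data.frame(
    gene_id = gene_ids,
    ycds_bp = vapply(cons, function(cc)
      nchar(cc$seq) - nchar(gsub("[^N]", "", cc$seq)), integer(1)),
    ycds_pct = vapply(cons, function(cc) cc$completeness_pct, numeric(1)),
    premature_stop = vapply(cons, function(cc) cc$premature_stop, logical(1)),
    n_reads = vapply(cons, function(cc) cc$n_supporting_reads, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(consensus = cons, report = report)
}
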