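# Readers and writers for the external formats the pipeline touches: FASTA
# (wrapped at 60 columns), a minimal multi-sample VCF dialect in CDS
# coordinates, a SAM-like tab-separated read dialect, and the per-gene
# evidence table. All are deliberately strict: these are pipeline interchange
# files, not arbitrary third-party data.

FASTA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Read a FASTA file
#'
#' Sequences must be over \{A,C,G,T,N\} (case-insensitive on input, stored
#' upper-case). Malformed headers or illegal characters raise an error naming
#' the offending line.
#'
#' @param path file path
#' @return named character vector of sequences (names = record ids); empty
#'   file yields an empty vector
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  ids <- character(0)
  seqs <- character(0)
  buf <- character(0)
  flush <- function() {
    if (length(ids) > length(seqs)) seqs[[length(ids)]] <<- paste(buf, collapse = "")
    buf <<- character(0)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "") next
    if (startsWith(ln, ">")) {
      flush()
      id <- trimws(sub("^>", "", ln))
      if (id == "") stop("malformed FASTA header at line ", i, " of ", path, call. = FALSE)
      ids <- c(ids, id)
    } else {
      if (length(ids) == 0L) {
        stop("sequence before any header at line ", i, " of ", path, call. = FALSE)
      }
      ln <- toupper(ln)
      bad <- setdiff(unique(strsplit(ln, "")[[1L]]), FASTA_ALPHABET)
      if (length(bad) > 0L) {
        stop("illegal character '", bad[[1L]], "' at line ", i, " of ", path, call. = FALSE)
      }
      buf <- c(buf, ln)
    }
  }
  flush()
  stats::setNames(seqs, ids)
}

#' Write a FASTA file
#'
#' @param seqs named character vector of sequences
#' @param path output path
#' @param width line-wrap width (default 60)
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)) || length(seqs) == 0L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[[i]]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq(1L, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Variant sites

GENO_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Construct a variant set
#'
#' A `variant_set` couples a site table (one biallelic SNP per row, in CDS
#' coordinates of its gene) with a genotype matrix (sites x samples) over
#' \code{hom_ref, het, hom_alt, missing}.
#'
#' @param sites data.frame with columns gene_id, cds_pos, ref, alt, quality
#' @param geno character matrix, one row per site, named sample columns
#' @return object of class `variant_set`
#' @export
variant_set <- function(sites, geno) {
  stopifnot(
    is.data.frame(sites),
    all(c("gene_id", "cds_pos", "ref", "alt", "quality") %in% names(sites)),
    is.matrix(geno), nrow(geno) == nrow(sites), !is.null(colnames(geno))
  )
  if (nrow(sites) > 0L) {
    if (any(sites$ref == sites$alt)) stop("ref == alt at some site", call. = FALSE)
    if (!all(geno %in% GENO_LEVELS)) stop("invalid genotype code", call. = FALSE)
    if (any(sites$quality < 0)) stop("negative quality", call. = FALSE)
  }
  structure(list(sites = sites, geno = geno, samples = colnames(geno)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  invisible(x)
}

#' Number of sites in a variant set
#' @param vs a `variant_set`
#' @export
n_sites <- function(vs) nrow(vs$sites)

#' Subset a variant set by site index
#' @param vs a `variant_set`
#' @param idx logical or integer row index
#' @export
subset_sites <- function(vs, idx) {
  variant_set(vs$sites[idx, , drop = FALSE], vs$geno[idx, , drop = FALSE])
}

#' Read the multi-sample VCF dialect
#'
#' CHROM holds the gene id and POS the 1-based CDS position (reads are mapped
#' per-gene to CDS, not to the genome). Multi-allelic and indel records are
#' skipped and counted (attribute `n_skipped`); genotypes are mapped
#' 0/0 -> hom_ref, 0/1 or 1/0 -> het, 1/1 -> hom_alt, ./. -> missing.
#'
#' @param path VCF path
#' @param samples expected sample ids, in column order
#' @return `variant_set` with attribute `n_skipped`
#' @export
read_vcf <- function(path, samples) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##") & lines != ""]
  hdr_i <- which(startsWith(body, "#CHROM"))
  if (length(hdr_i) != 1L) stop("missing #CHROM header line in ", path, call. = FALSE)
  hdr <- strsplit(body[[hdr_i]], "\t", fixed = TRUE)[[1L]]
  vcf_samples <- hdr[-(1:9)]
  if (!identical(vcf_samples, as.character(samples))) {
    stop("VCF sample columns do not match expected samples", call. = FALSE)
  }
  recs <- body[-seq_len(hdr_i)]
  n_skipped <- 0L
  rows <- vector("list", length(recs))
  genos <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    f <- strsplit(recs[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L + length(samples)) {
      stop("bad field count in VCF record ", k, call. = FALSE)
    }
    ref <- f[[4]]; alt <- f[[5]]
    if (nchar(ref) != 1L || nchar(alt) != 1L || grepl(",", alt, fixed = TRUE)) {
      n_skipped <- n_skipped + 1L
      next
    }
    qual <- suppressWarnings(as.numeric(f[[6]]))
    if (is.na(qual)) stop("non-numeric QUAL in VCF record ", k, call. = FALSE)
    gt <- sub(":.*$", "", f[-(1:9)])
    g <- rep("missing", length(gt))
    g[gt %in% c("0/0", "0|0")] <- "hom_ref"
    g[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- "het"
    g[gt %in% c("1/1", "1|1")] <- "hom_alt"
    rows[[k]] <- data.frame(
      gene_id = f[[1]], cds_pos = as.integer(f[[2]]),
      ref = ref, alt = alt, quality = qual, stringsAsFactors = FALSE
    )
    genos[[k]] <- g
  }
  keep <- !vapply(rows, is.null, logical(1))
  sites <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(gene_id = character(0), cds_pos = integer(0), ref = character(0),
               alt = character(0), quality = numeric(0))
  geno <- matrix("missing", nrow(sites), length(samples),
                 dimnames = list(NULL, as.character(samples)))
  if (any(keep)) geno[] <- do.call(rbind, genos[keep])
  vs <- variant_set(sites, geno)
  attr(vs, "n_skipped") <- n_skipped
  vs
}

#' Write the VCF dialect
#' @param vs a `variant_set`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_vcf <- function(vs, path) {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", vs$samples), collapse = "\t"), con)
  if (n_sites(vs) > 0L) {
    qual <- format(vs$sites$quality, trim = TRUE, scientific = FALSE, digits = 15)
    body <- paste(vs$sites$gene_id, vs$sites$cds_pos, ".", vs$sites$ref,
                  vs$sites$alt, qual, ".", ".", "GT", sep = "\t")
    gts <- apply(vs$geno, 1L, function(g) paste(gt_code[g], collapse = "\t"))
    writeLines(paste(body, gts, sep = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# SAM-like read dialect

#' Read the SAM-like read dialect
#'
#' Tab-separated records: read_id, sample_id, gene_id, start (1-based CDS
#' offset), CIGAR, sequence. Only all-match CIGARs ("<len>M") are in dialect;
#' other records are rejected and counted in attribute `n_rejected`. When
#' `cds_len` (named vector of CDS lengths) is supplied, reads overhanging
#' their CDS are rejected too.
#'
#' @param path file path
#' @param cds_len optional named integer vector of CDS lengths per gene
#' @return data.frame(read_id, sample_id, gene_id, start, seq) with attribute
#'   `n_rejected`
#' @export
read_sam_reads <- function(path, cds_len = NULL) {
  lines <- readLines(path)
  lines <- lines[lines != "" & !startsWith(lines, "@")]
  n_rejected <- 0L
  keep <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 6L) stop("bad field count at line ", i, " of ", path, call. = FALSE)
    start <- as.integer(f[[4]])
    seq <- toupper(f[[6]])
    len <- nchar(seq)
    if (!grepl("^[0-9]+M$", f[[5]]) || as.integer(sub("M$", "", f[[5]])) != len) {
      n_rejected <- n_rejected + 1L  # indel/clip-containing reads are out of dialect
      next
    }
    if (is.na(start) || start < 1L ||
        grepl("[^ACGTN]", seq) ||
        (!is.null(cds_len) && (!f[[3]] %in% names(cds_len) ||
                               start + len - 1L > cds_len[[f[[3]]]]))) {
      n_rejected <- n_rejected + 1L
      next
    }
    keep[[i]] <- data.frame(read_id = f[[1]], sample_id = f[[2]], gene_id = f[[3]],
                            start = start, seq = seq, stringsAsFactors = FALSE)
  }
  ok <- !vapply(keep, is.null, logical(1))
  out <- if (any(ok)) do.call(rbind, keep[ok]) else
    data.frame(read_id = character(0), sample_id = character(0),
               gene_id = character(0), start = integer(0), seq = character(0))
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write the SAM-like read dialect
#' @param reads data.frame as returned by [read_sam_reads()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_sam_reads <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0L) {
    writeLines(paste(reads$read_id, reads$sample_id, reads$gene_id, reads$start,
                     paste0(nchar(reads$seq), "M"), reads$seq, sep = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Evidence table

STRATUM_LEVELS <- c("PAR", "Str3", "Str2", "Str1", "unknown")

#' Load a per-gene Y-SNP evidence table
#'
#' TSV with header columns gene_id, pos_kb, map_f_cM, map_m_cM, stratum,
#' n_segr, n_lat, n_dio, ks, ycds_bp, ycds_pct (an optional trailing
#' `uncertain` column flagging ambiguous transcriptions is preserved). Blank
#' cells become NA, never zero. Rows are returned sorted by pos_kb; `#`
#' comment lines are ignored.
#'
#' @param path TSV path
#' @return data.frame sorted by pos_kb, with attribute `stratum_counts`
#' @export
load_evidence_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", fill = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_id", "pos_kb", "map_f_cM", "map_m_cM", "stratum",
            "n_segr", "n_lat", "n_dio", "ks", "ycds_bp", "ycds_pct")
  if (!all(need %in% names(df))) {
    stop("evidence table missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in evidence table: ",
         df$gene_id[duplicated(df$gene_id)][[1L]], call. = FALSE)
  }
  blank_na <- function(x) ifelse(is.na(x) | trimws(x) == "", NA, trimws(x))
  num <- function(x) as.numeric(blank_na(x))
  int <- function(x) as.integer(blank_na(x))
  out <- data.frame(
    gene_id = df$gene_id,
    pos_kb = num(df$pos_kb),
    map_f_cM = num(df$map_f_cM),
    map_m_cM = num(df$map_m_cM),
    stratum = blank_na(df$stratum),
    n_segr = int(df$n_segr),
    n_lat = int(df$n_lat),
    n_dio = int(df$n_dio),
    ks = num(df$ks),
    ycds_bp = int(df$ycds_bp),
    ycds_pct = num(df$ycds_pct),
    stringsAsFactors = FALSE
  )
  if ("uncertain" %in% names(df)) out$uncertain <- blank_na(df$uncertain)
  out$stratum[is.na(out$stratum)] <- "unknown"
  if (!all(out$stratum %in% STRATUM_LEVELS)) {
    stop("unknown stratum label: ",
         setdiff(out$stratum, STRATUM_LEVELS)[[1L]], call. = FALSE)
  }
  if (any(is.na(out$pos_kb) | out$pos_kb <= 0)) {
    stop("pos_kb must be present and positive for every gene", call. = FALSE)
  }
  out <- out[order(out$pos_kb), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stratum_counts") <- table(out$stratum)
  out
}

#' Path to the bundled evidence-table fixture
#'
#' A hand-transcribed per-gene Y-SNP evidence table for the distal arm of the
#' S. latifolia X reference (PAR, stratum 3 and adjacent stratum 2 genes).
#' @return file path
#' @export
evidence_fixture_path <- function() {
  system.file("extdata", "table1_evidence.tsv", package = "ystrata",
              mustWork = TRUE)
}
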