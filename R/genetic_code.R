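# Standard genetic code and codon-level utilities shared by the simulator and
# the divergence/diversity estimators.

BASES <- c("T", "C", "A", "G")

.codon_table <- local({
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    ""
  )[[1L]]
  # codons in first-base-slowest order, matching the canonical table string
  codons <- paste0(
    rep(BASES, each = 16L),
    rep(rep(BASES, each = 4L), times = 4L),
    rep(BASES, times = 16L)
  )
  stats::setNames(aa, codons)
})

STOP_CODONS <- names(.codon_table)[.codon_table == "*"]

#' Translate a codon under the standard genetic code
#'
#' @param codon character vector of 3-letter codons over \{A,C,G,T\}; codons
#'   containing any other character (e.g. \code{N}) translate to \code{NA}.
#' @return character vector of one-letter amino acids, \code{"*"} for stops,
#'   \code{NA} for unresolved codons.
#' @export
translate_codon <- function(codon) {
  out <- unname(.codon_table[codon])
  out
}

#' @rdname translate_codon
#' @export
is_stop_codon <- function(codon) {
  !is.na(translate_codon(codon)) & translate_codon(codon) == "*"
}

#' Split a CDS string into codons
#' @param seq single CDS string, length divisible by 3
#' @return character vector of codons
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("CDS length (", n, ") is not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Per-site synonymous fraction of a codon: for each of the 3 positions, the
# fraction of the 3 possible point mutations that leave the amino acid
# unchanged (Nei-Gojobori site counting; changes to stop codons count as
# non-synonymous). Stop codons and unresolved codons return NA.
.syn_cache <- new.env(parent = emptyenv())

codon_syn_fractions <- function(codon) {
  hit <- .syn_cache[[codon]]
  if (!is.null(hit)) return(hit)
  out <- codon_syn_fractions_impl(codon)
  if (!grepl("[^ACGT]", codon)) .syn_cache[[codon]] <- out
  out
}

codon_syn_fractions_impl <- function(codon) {
  aa <- translate_codon(codon)
  if (is.na(aa) || aa == "*") return(rep(NA_real_, 3L))
  vapply(1:3, function(i) {
    from <- substr(codon, i, i)
    muts <- setdiff(BASES, from)
    alt <- vapply(muts, function(b) {
      cod <- codon
      substr(cod, i, i) <- b
      translate_codon(cod)
    }, character(1))
    mean(alt == aa & alt != "*")
  }, numeric(1))
}

# Synonymous fraction per site along a CDS (vector of length nchar(cds));
# NA at sites inside stop or unresolved codons.
cds_syn_fractions <- function(cds) {
  codons <- split_codons(cds)
  as.vector(vapply(codons, codon_syn_fractions, numeric(3)))
}

# Synonymous alternatives for position i of a codon (bases that keep the amino
# acid and do not create a stop); character(0) when none.
synonymous_alternatives <- function(codon, i) {
  aa <- translate_codon(codon)
  if (is.na(aa) || aa == "*") return(character(0))
  from <- substr(codon, i, i)
  muts <- setdiff(BASES, from)
  keep <- vapply(muts, function(b) {
    cod <- codon
    substr(cod, i, i) <- b
    a2 <- translate_codon(cod)
    !is.na(a2) && a2 == aa
  }, logical(1))
  muts[keep]
}
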