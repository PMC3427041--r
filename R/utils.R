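# Shared sequence utilities: base coding, genetic code lookups, small helpers.

BASES <- c("A", "C", "G", "T")

# 64-codon amino-acid lookup, names "AAA".."TTT"; stops are "*"
codon_table <- local({
  codons <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  codons <- sort(codons)
  aa <- as.character(Biostrings::GENETIC_CODE[codons])
  setNames(aa, codons)
})

translate_codon <- function(codon) unname(codon_table[codon])

#' Split a sequence string into a character vector of single bases
#' @noRd
seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Encode bases A/C/G/T as 1..4, anything else (mask, gap) as NA
#' @noRd
encode_bases <- function(chars) {
  m <- match(chars, BASES)
  m
}

assert_acgt <- function(seq, what = "sequence") {
  if (grepl("[^ACGT]", seq)) {
    abort(sprintf("%s contains non-ACGT characters", what))
  }
  invisible(seq)
}

# Lower-of-middle-pair median for even-length inputs (integer summaries of
# counts, e.g. reads per contig); equals the usual median for odd lengths.
median_low <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[ceiling(n / 2)]
}

#' Per-codon fraction of single-base changes that are synonymous, position by
#' position. Returns a single number: the number of synonymous sites in the
#' codon (sum over the three positions of the synonymous fraction).
#' Changes to or from stop codons count as nonsynonymous unless both are stops.
#' @noRd
codon_syn_sites <- function(codon) {
  syn_sites_table[[codon]]
}

syn_sites_table <- local({
  codons <- names(codon_table)
  vals <- vapply(codons, function(cd) {
    chars <- strsplit(cd, "")[[1]]
    aa0 <- codon_table[[cd]]
    s <- 0
    for (pos in 1:3) {
      for (b in BASES) {
        if (b == chars[pos]) next
        mut <- chars
        mut[pos] <- b
        aa1 <- codon_table[[paste(mut, collapse = "")]]
        if (identical(aa1, aa0)) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  as.list(setNames(vals, codons))
})
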