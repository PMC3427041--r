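# Per-contig multi-species read alignments and column-wise base counting.
#
# Reads are kept in a plain tibble (read_id, contig_id, species, platform,
# start, bases, quals) with 0-based half-open coordinates throughout;
# sequences are reference-oriented strings in which "-" marks a deletion
# column and "N" an ambiguous base (neither contributes to column counts).

#' Construct a contig alignment collection
#'
#' Bundles a reads tibble with per-contig lengths. Reads must fall within
#' their contig.
#'
#' @param reads Tibble with columns `read_id`, `contig_id`, `species`,
#'   `platform`, `start` (0-based), `bases`, and optionally `quals`
#'   (phred+33 strings) -- extra columns are kept.
#' @param contigs Tibble with `contig_id` and `length`; inferred from read
#'   extents when omitted.
#' @return A `contig_alignment` list with elements `contigs` and `reads`.
#' @export
contig_alignment <- function(reads, contigs = NULL) {
  req <- c("read_id", "contig_id", "species", "platform", "start", "bases")
  missing_cols <- setdiff(req, names(reads))
  if (length(missing_cols)) {
    abort(paste("reads is missing columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!"quals" %in% names(reads)) reads$quals <- NA_character_
  reads$start <- as.integer(reads$start)
  if (any(reads$start < 0)) abort("read starts must be >= 0")
  if (is.null(contigs)) {
    contigs <- reads |>
      group_by(.data$contig_id) |>
      summarise(length = max(.data$start + nchar(.data$bases)), .groups = "drop")
  }
  contigs$length <- as.integer(contigs$length)
  ext <- reads |>
    left_join(contigs, by = "contig_id") |>
    mutate(end = .data$start + nchar(.data$bases))
  if (anyNA(ext$length)) abort("reads reference contigs absent from `contigs`")
  if (any(ext$end > ext$length)) {
    bad <- ext$read_id[ext$end > ext$length]
    abort(paste("reads extend past contig end:", paste(head(bad, 5), collapse = ", ")))
  }
  structure(list(contigs = as_tibble(contigs), reads = as_tibble(reads)),
            class = "contig_alignment")
}

#' @export
print.contig_alignment <- function(x, ...) {
  cat(sprintf("<contig_alignment> %d contigs, %d reads (%s)\n",
              nrow(x$contigs), nrow(x$reads),
              paste(sprintf("%s: %d", names(table(x$reads$species)),
                            table(x$reads$species)), collapse = ", ")))
  invisible(x)
}

#' Column-wise base counts for one contig
#'
#' Tabulates A/C/G/T occurrences per reference column over a set of reads
#' from a single contig. Gap ("-") and ambiguous ("N") characters do not
#' count; bases outside `[0, contig_len)` are ignored.
#'
#' @param bases Character vector of reference-oriented read strings.
#' @param starts Integer vector of 0-based read starts.
#' @param contig_len Contig length in bp.
#' @return A 4 x `contig_len` integer matrix with rows A, C, G, T; columns
#'   index 0-based positions `0 .. contig_len - 1`.
#' @export
pileup_counts <- function(bases, starts, contig_len) {
  contig_len <- as.integer(contig_len)
  if (!length(bases)) {
    return(matrix(0L, nrow = 4L, ncol = contig_len, dimnames = list(BASES, NULL)))
  }
  stopifnot(length(bases) == length(starts))
  big <- paste(bases, collapse = "")
  code <- match(seq_chars(big), BASES)
  lens <- nchar(bases)
  pos <- sequence(lens) - 1L + rep.int(as.integer(starts), lens)
  ok <- !is.na(code) & pos >= 0L & pos < contig_len
  counts <- tabulate(pos[ok] * 4L + code[ok], nbins = 4L * contig_len)
  matrix(as.integer(counts), nrow = 4L, dimnames = list(BASES, NULL))
}

#' Base counts at one column
#'
#' @param aln A `contig_alignment`.
#' @param contig_id Contig to inspect.
#' @param pos 0-based column index.
#' @param group Optional species filter (character vector of species labels).
#' @return Named integer vector of counts for the bases observed at the
#'   column (empty when no read covers it with an unambiguous base).
#' @export
column_counts <- function(aln, contig_id, pos, group = NULL) {
  stopifnot(inherits(aln, "contig_alignment"))
  clen <- aln$contigs$length[match(contig_id, aln$contigs$contig_id)]
  if (is.na(clen)) abort(sprintf("unknown contig '%s'", contig_id))
  if (pos < 0 || pos >= clen) abort("pos out of range")
  r <- aln$reads[aln$reads$contig_id == contig_id, ]
  if (!is.null(group)) r <- r[r$species %in% group, ]
  cover <- r$start <= pos & pos < r$start + nchar(r$bases)
  r <- r[cover, ]
  b <- substr(r$bases, pos - r$start + 1L, pos - r$start + 1L)
  b <- b[b %in% BASES]
  if (!length(b)) return(setNames(integer(0), character(0)))
  tab <- table(factor(b, levels = BASES))
  c(tab[tab > 0])
}

#' Phred values for one read string
#' @noRd
phred_vector <- function(qual_string) {
  if (is.na(qual_string)) return(NULL)
  as.integer(charToRaw(qual_string)) - 33L
}
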