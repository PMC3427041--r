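# Dataset and alignment I/O: FASTA/FASTQ via Biostrings/ShortRead, SAM via
# Rsamtools/GenomicAlignments, and a documented TSV placement dialect.
#
# TSV placement dialect (tab-separated, header row): read_id, contig_id,
# species, platform, start (0-based), bases, quals (phred+33 or NA). The
# same dialect is accepted by load_alignment().

#' Write a synthetic dataset to plain-text files
#'
#' Emits `reference.fasta` (ancestral contig sequences), `genomes.fasta`
#' (truth lineage sequences, ids `contig|lineage`), `reads_long.fasta`,
#' `reads_short.fastq`, `placement.tsv` (full TSV alignment dialect),
#' `truth_snps.tsv`, `truth_nrhr.tsv`, `contigs.tsv` and `config.yaml`.
#'
#' @param sim A `cotton_sim` from [sim_dataset()].
#' @param dir Output directory (created if needed).
#' @param sam Also write `alignment.sam` with all reads.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, sam = FALSE) {
  stopifnot(inherits(sim, "cotton_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- sim$truth$genomes

  ref <- Biostrings::DNAStringSet(setNames(g$ancestor, g$contig_id))
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"))

  lin_long <- g |>
    select("contig_id", all_of(LINEAGES)) |>
    pivot_longer(all_of(LINEAGES), names_to = "lineage", values_to = "seq")
  gs <- Biostrings::DNAStringSet(
    setNames(lin_long$seq, paste(lin_long$contig_id, lin_long$lineage, sep = "|")))
  Biostrings::writeXStringSet(gs, file.path(dir, "genomes.fasta"))

  long_reads <- sim$reads[sim$reads$platform == "long", ]
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(long_reads$bases, long_reads$read_id)),
    file.path(dir, "reads_long.fasta"))

  short_reads <- sim$reads[sim$reads$platform == "short", ]
  fq <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(short_reads$bases),
    quality = Biostrings::BStringSet(short_reads$quals),
    id = Biostrings::BStringSet(short_reads$read_id))
  fq_path <- file.path(dir, "reads_short.fastq")
  if (file.exists(fq_path)) unlink(fq_path)
  ShortRead::writeFastq(fq, fq_path, compress = FALSE)

  readr::write_tsv(sim$reads, file.path(dir, "placement.tsv"))
  readr::write_tsv(sim$truth$snps, file.path(dir, "truth_snps.tsv"))
  readr::write_tsv(sim$truth$nrhr, file.path(dir, "truth_nrhr.tsv"))
  readr::write_tsv(g |> select("contig_id", "length", "frame"),
                   file.path(dir, "contigs.tsv"))
  cfg_out <- unclass(sim$config)
  for (f in c("branch_ds", "nrhr_species_weights")) {
    cfg_out[[f]] <- as.list(cfg_out[[f]])  # keep names through YAML
  }
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  if (sam) {
    write_sam(sim$reads, g |> select("contig_id", "length"),
              file.path(dir, "alignment.sam"))
  }
  invisible(dir)
}

#' Reload a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `cotton_sim` equivalent to the one written.
#' @export
read_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  for (f in c("branch_ds", "nrhr_species_weights", "long_read_range")) {
    cfg[[f]] <- unlist(cfg[[f]])
  }
  cfg <- do.call(sim_config, cfg)
  tsv <- function(f, types) readr::read_tsv(file.path(dir, f), col_types = types)
  genomes_fa <- Biostrings::readDNAStringSet(file.path(dir, "genomes.fasta"))
  lin <- tibble(
    id = names(genomes_fa),
    seq = as.character(genomes_fa)
  ) |>
    tidyr::separate_wider_delim("id", "|", names = c("contig_id", "lineage")) |>
    pivot_wider(names_from = "lineage", values_from = "seq")
  contigs <- tsv("contigs.tsv", "cii")
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))
  genomes <- contigs |>
    mutate(ancestor = unname(as.character(ref)[.data$contig_id])) |>
    left_join(lin, by = "contig_id")
  ord <- c("contig_id", "length", "frame", "ancestor",
           "A2", "AD1_A", "AD2_A", "D5", "AD1_D", "AD2_D")
  genomes <- genomes[, intersect(ord, names(genomes))]
  for (cl in names(genomes)) genomes[[cl]] <- unname(genomes[[cl]])
  truth <- structure(
    list(
      genomes = genomes,
      snps = tsv("truth_snps.tsv", "cicc"),
      nrhr = tsv("truth_nrhr.tsv", "ccccii")
    ),
    class = "homeo_truth"
  )
  reads <- readr::read_tsv(
    file.path(dir, "placement.tsv"),
    col_types = readr::cols(
      read_id = "c", contig_id = "c", species = "c", subgenome = "c",
      platform = "c", start = "i", bases = "c", quals = "c"))
  structure(list(config = cfg, truth = truth, reads = reads),
            class = "cotton_sim")
}

#' Write reads as a minimal SAM file
#'
#' Mandatory fields only; reads are assumed reference-oriented and gap-free
#' (CIGAR `<len>M`). Quality is `*` when absent.
#'
#' @param reads Reads tibble (TSV placement dialect columns).
#' @param contigs Tibble with `contig_id`, `length` for the `@SQ` header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, contigs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id, contigs$length))
  qual <- ifelse(is.na(reads$quals), "*", reads$quals)
  body <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                  reads$read_id, reads$contig_id, reads$start + 1L,
                  nchar(reads$bases), reads$bases, qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

resolve_species <- function(read_id, species_map) {
  if (is.null(species_map)) {
    # default naming convention "contig|lineage|..." as written by write_dataset
    parts <- strsplit(read_id, "|", fixed = TRUE)
    sp <- map_chr(parts, function(p) {
      if (length(p) >= 2) sub("_.*$", "", p[2]) else NA_character_
    })
    sp[!sp %in% SPECIES] <- NA_character_
    return(sp)
  }
  if (is.function(species_map)) return(as.character(species_map(read_id)))
  if (is.data.frame(species_map)) {
    return(species_map$species[match(read_id, species_map$read_id)])
  }
  # named vector: names are regexes tried in order
  sp <- rep(NA_character_, length(read_id))
  for (i in seq_along(species_map)) {
    hit <- is.na(sp) & grepl(names(species_map)[i], read_id)
    sp[hit] <- species_map[[i]]
  }
  sp
}

#' Load a read alignment from SAM or placement TSV
#'
#' SAM input is converted with `Rsamtools::asBam()` and laid out on reference
#' coordinates with `GenomicAlignments::sequenceLayer()`: soft clips and
#' insertions are excluded, deletion columns become `-` (which never count in
#' pileups). TSV input must follow the placement dialect documented in this
#' file. Coordinates are normalised to 0-based half-open.
#'
#' @param path SAM (`.sam`) or TSV file.
#' @param species_map How to resolve each read to a species: `NULL` (parse
#'   the `contig|lineage|...` id convention), a named character vector of
#'   regex -> species, a function of read ids, or a data frame with
#'   `read_id`/`species`. Unresolvable reads are an error.
#' @param platform Platform label for SAM input (TSV carries its own).
#' @return A `contig_alignment`.
#' @export
load_alignment <- function(path, species_map = NULL, platform = "long") {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    load_alignment_sam(path, species_map, platform)
  } else {
    load_alignment_tsv(path, species_map)
  }
}

load_alignment_tsv <- function(path, species_map = NULL) {
  reads <- readr::read_tsv(path, col_types = readr::cols(
    read_id = "c", contig_id = "c", species = "c", platform = "c",
    start = "i", bases = "c", quals = "c", .default = "c"))
  if (!"species" %in% names(reads) || !is.null(species_map)) {
    reads$species <- resolve_species(reads$read_id, species_map)
  }
  check_species(reads)
  contig_alignment(reads)
}

load_alignment_sam <- function(path, species_map = NULL, platform = "long") {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "seq", "qual")))
  mc <- S4Vectors::mcols(ga)
  seq_ref <- GenomicAlignments::sequenceLayer(
    mc$seq, GenomicAlignments::cigar(ga), from = "query", to = "reference")
  qual_chr <- as.character(mc$qual)
  have_qual <- !qual_chr %in% c("*", "")
  qual_ref <- rep(NA_character_, length(ga))
  if (any(have_qual)) {
    ql <- GenomicAlignments::sequenceLayer(
      Biostrings::BStringSet(qual_chr[have_qual]),
      GenomicAlignments::cigar(ga)[have_qual],
      from = "query", to = "reference")
    qual_ref[have_qual] <- as.character(ql)
  }
  reads <- tibble(
    read_id = mc$qname,
    contig_id = as.character(GenomeInfoDb::seqnames(ga)),
    species = resolve_species(mc$qname, species_map),
    platform = platform,
    start = BiocGenerics::start(ga) - 1L,
    bases = as.character(seq_ref),
    quals = qual_ref
  )
  check_species(reads)
  sl <- GenomeInfoDb::seqlengths(ga)
  contigs <- tibble(contig_id = names(sl), length = as.integer(sl))
  contig_alignment(reads, contigs)
}

check_species <- function(reads) {
  bad <- is.na(reads$species)
  if (any(bad)) {
    abort(paste0("reads with unresolved species: ",
                 paste(head(reads$read_id[bad], 10), collapse = ", "),
                 if (sum(bad) > 10) sprintf(" (+%d more)", sum(bad) - 10) else ""))
  }
  invisible(reads)
}
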