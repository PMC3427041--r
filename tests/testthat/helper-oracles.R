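# Independent brute-force oracles and tiny fixture builders.
# These deliberately re-derive everything from first principles (their own
# genetic-code lookup, recursive pathway enumeration, naive pileups) so they
# share no code path with the implementation they check.

oracle_aa <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

# synonymous site count of one codon: per position, fraction of the three
# alternative bases preserving the amino acid
oracle_syn_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == chars[p]) next
      alt <- chars
      alt[p] <- b
      if (oracle_aa(paste(alt, collapse = "")) == oracle_aa(codon)) s <- s + 1 / 3
    }
  }
  s
}

# recursive enumeration of every ordering of single-base steps from x to y,
# averaging synonymous/nonsynonymous step counts with equal weights
oracle_pathways <- function(x, y) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  dif <- which(cx != cy)
  if (!length(dif)) return(c(sd = 0, nd = 0))
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- cy[p]
      step_syn <- oracle_aa(paste(nxt, collapse = "")) ==
        oracle_aa(paste(cur, collapse = ""))
      for (tail_counts in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- tail_counts + if (step_syn) c(1, 0) else c(0, 1)
      }
    }
    out
  }
  paths <- walk(cx, dif)
  m <- colMeans(do.call(rbind, paths))
  c(sd = m[1], nd = m[2])
}

# full NG86 on two equal-length in-frame coding strings
oracle_ng86 <- function(x, y) {
  cx <- substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  cy <- substring(y, seq(1, nchar(y), 3), seq(3, nchar(y), 3))
  S <- sum((vapply(cx, oracle_syn_sites, 0) + vapply(cy, oracle_syn_sites, 0)) / 2)
  N <- 3 * length(cx) - S
  d <- rowSums(vapply(seq_along(cx),
                      function(i) oracle_pathways(cx[i], cy[i]), numeric(2)))
  list(S = S, N = N, Sd = unname(d[1]), Nd = unname(d[2]))
}

# random sense-codon string
random_codons <- function(n_codons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# minimal reads tibble builder
make_reads <- function(contig_id, species, starts, bases,
                       platform = "long", quals = NA_character_) {
  tibble::tibble(
    read_id = sprintf("%s|r%03d", contig_id, seq_along(starts)),
    contig_id = contig_id, species = species, platform = platform,
    start = as.integer(starts), bases = bases, quals = quals
  )
}

# small simulated dataset shared across tests (cached per session)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- sim_dataset(sim_config(n_contigs = 12, seed = 7))
    }
    cache
  }
})

sim_alignment <- function(sim) {
  contig_alignment(sim$reads, sim$truth$genomes[, c("contig_id", "length")])
}

snp_key <- function(d) paste(d$contig_id, d$pos)
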