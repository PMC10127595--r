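# Shared fixture builders. Everything is generated in code at test time;
# the scaled-down default profile (background 5, flank 100, core 5000) keeps
# the fold ratios of a paper-like lysogen while staying desk-scale.

make_track <- function(values, id = "chr", circular = TRUE) {
  coverage_track(values, replicon_id = id, circular = circular)
}

## idealised step track: background with one or more rectangular cores
step_track <- function(n, bg = 35, cores = list(), flanks = list(),
                       id = "chr") {
  v <- rep(bg, n)
  for (f in flanks) v[(f[1] + 1):f[2]] <- f[3]
  for (co in cores) v[(co[1] + 1):co[2]] <- co[3]
  make_track(v, id = id)
}

## small lysogen with one prophage (right flank) for track-level tests
fixture_genome_small <- function(seed = 42, core_rate = 5000,
                                 flank_rate = 100) {
  simulate_genome(
    60000, gc = 0.6,
    prophage_specs = list(prophage_spec(
      20000, 28000, core_rate = core_rate, flank_side = "right",
      flank_rate = flank_rate, flank_extent = 3000)),
    seed = seed)
}

## tiny repeat-free genome for mapper oracle tests
fixture_genome_plain <- function(seed = 7, len = 30000) {
  simulate_genome(len, gc = 0.5, seed = seed)
}

## directly cut error-free reads from a replicon (both strands)
cut_reads <- function(genome, starts, L = 100, strand = NULL,
                      prefix = "cut") {
  rep <- genome$replicons[[1]]
  ext <- paste0(rep$seq, substr(rep$seq, 1, L - 1))
  seqs <- substring(ext, starts + 1, starts + L)
  if (is.null(strand)) strand <- rep("+", length(starts))
  mi <- strand == "-"
  if (any(mi)) {
    seqs[mi] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[mi])))
  }
  reads <- tibble::tibble(
    id = paste0(prefix, seq_along(starts)), seq = seqs,
    label = "background", src_replicon = rep$id, src_start = starts,
    src_strand = strand)
  structure(reads, read_length = L, class = c("read_set", class(reads)))
}

## brute-force best-locus search via exact substring matching, both strands
brute_force_loci <- function(read_seq, genome, L = nchar(read_seq)) {
  rep <- genome$replicons[[1]]
  n <- nchar(rep$seq)
  ext <- paste0(rep$seq, substr(rep$seq, 1, L - 1))
  subject <- Biostrings::DNAString(ext)
  hits <- list()
  fwd <- Biostrings::matchPattern(read_seq, subject)
  for (s in BiocGenerics::start(fwd)) {
    hits[[length(hits) + 1]] <- c(start = (s - 1) %% n, strand = "+")
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read_seq)))
  rev <- Biostrings::matchPattern(rc, subject)
  for (s in BiocGenerics::start(rev)) {
    hits[[length(hits) + 1]] <- c(start = (s - 1) %% n, strand = "-")
  }
  if (!length(hits)) return(data.frame(start = integer(), strand = character()))
  df <- unique(data.frame(
    start = as.integer(vapply(hits, `[[`, character(1), "start")),
    strand = vapply(hits, `[[`, character(1), "strand")))
  df[order(df$start, df$strand), ]
}

## independent per-position coverage recount from placements
recount_coverage <- function(placements, n, L, circular = TRUE) {
  v <- numeric(n)
  pl <- placements$placements
  for (i in seq_len(nrow(pl))) {
    pos <- (pl$start[i] + seq_len(L) - 1L) %% n
    v[pos + 1L] <- v[pos + 1L] + pl$weight[i]
  }
  v
}
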