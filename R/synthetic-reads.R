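#' Read-simulation parameters for the phage fraction
#'
#' @param read_length read length L in bp.
#' @param error_rate per-base substitution probability (`0 <= e < 0.1`);
#'   substitutions only, no indels.
#' @param background_rate expected per-base coverage of non-prophage host
#'   DNA in the phage fraction (the "background" the caller estimates).
#' @param contaminant_fraction expected proportion of reads drawn from an
#'   unrelated random sequence that maps nowhere (sequencing-kit
#'   contaminants).
#' @param paired if `TRUE`, each read gets a mate from the opposite strand
#'   at a fixed insert size; mates are mapped as independent singletons.
#' @param insert_size outer distance between paired read starts.
#' @param max_reads refusal cap on the expected total read count, guarding
#'   against accidentally huge simulations.
#' @param seed integer seed.
#' @return A `read_sim_params` list.
#' @export
read_sim_params <- function(read_length = 100, error_rate = 0.005,
                            background_rate = 35, contaminant_fraction = 0,
                            paired = FALSE, insert_size = 300,
                            max_reads = 2e6, seed = 1) {
  if (error_rate < 0 || error_rate >= 0.1) stopf("need 0 <= error_rate < 0.1")
  if (background_rate < 0) stopf("background_rate must be >= 0")
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stopf("need 0 <= contaminant_fraction < 1")
  }
  list(read_length = as.integer(read_length), error_rate = error_rate,
       background_rate = background_rate,
       contaminant_fraction = contaminant_fraction, paired = paired,
       insert_size = as.integer(insert_size), max_reads = max_reads,
       seed = as.integer(seed))
}

## fixed-seed 50-kb decoy sequence shared by all simulations: stands for
## kit contaminants unrelated to the host genome
contaminant_sequence <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      old <- .Random.seed_save()
      set.seed(190750L)
      cache <<- random_dna(50000L, 0.55)
      .Random.seed_restore(old)
    }
    cache
  }
})

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

## draw read start counts per position at rate profile/L and materialise
## sequences; labels positions by feature class
sample_reads_from_profile <- function(rep, profile, classes, L, e,
                                      prefix = "r") {
  n <- nchar(rep$seq)
  rate <- profile / L
  counts <- rpois(n, rate)
  starts <- base::rep.int(seq_len(n) - 1L, counts)  # 0-based
  n_reads <- length(starts)
  if (n_reads == 0L) {
    return(tibble::tibble(id = character(), seq = character(),
                          label = character(), src_replicon = character(),
                          src_start = integer(), src_strand = character()))
  }
  ext <- if (rep$circular) paste0(rep$seq, substr(rep$seq, 1L, L - 1L)) else rep$seq
  if (!rep$circular) starts <- starts[starts + L <= n]
  n_reads <- length(starts)
  seqs <- substring(ext, starts + 1L, starts + L)
  strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
  mi <- strand == "-"
  if (any(mi)) seqs[mi] <- revcomp(seqs[mi])
  seqs <- apply_substitutions(seqs, L, e)
  tibble::tibble(
    id = paste0(prefix, seq_len(n_reads)),
    seq = seqs,
    label = classes[starts + 1L],
    src_replicon = rep$id,
    src_start = starts,
    src_strand = strand)
}

## per-base substitution errors; an error replaces the base with one of the
## three other bases uniformly
apply_substitutions <- function(seqs, L, e) {
  if (e <= 0 || length(seqs) == 0L) return(seqs)
  k <- rbinom(length(seqs), L, e)
  hit <- which(k > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    at <- sample.int(L, k[i])
    s <- seqs[i]
    for (p in at) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(bases, cur), 1L)
    }
    seqs[i] <- s
  }
  seqs
}

## per-position feature-class labels for one replicon
position_classes <- function(genome, rep_id, n) {
  cls <- base::rep("background", n)
  pp <- genome$prophages[genome$prophages$replicon_id == rep_id, , drop = FALSE]
  for (i in seq_len(nrow(pp))) {
    p <- pp[i, ]
    if (p$flank_side == "right" && p$end < n) {
      cls[(p$end + 1L):min(n, p$end + p$flank_extent)] <- "flank"
    } else if (p$flank_side == "left" && p$start > 0) {
      cls[(max(0L, p$start - p$flank_extent) + 1L):p$start] <- "flank"
    }
    cls[(p$start + 1L):p$end] <- "core"
  }
  cls
}

#' Simulate induced-phage-fraction reads
#'
#' Read starts are Poisson-sampled with per-base rate equal to the expected
#' coverage profile divided by the read length, so cores come out
#' `core_rate`-fold covered, flanks follow the flank profile, and the rest
#' of the genome sits at `background_rate`. Circular replicons wrap.
#' Substitution errors are applied at `error_rate`, contaminant reads drawn
#' from a fixed unrelated sequence are appended at the requested expected
#' proportion, and every read carries a ground-truth origin label.
#'
#' @param genome a `genome_model`.
#' @param params a [read_sim_params()].
#' @return A `read_set`: tibble with columns `id`, `seq`, optional `mate`,
#'   `label` (`core`/`flank`/`background`/`contaminant`), `src_replicon`,
#'   `src_start`, `src_strand`; attribute `read_length`.
#' @export
simulate_phage_reads <- function(genome, params) {
  set.seed(params$seed)
  L <- params$read_length
  expected <- 0
  pieces <- list()
  for (rep in genome$replicons) {
    prof <- expected_coverage_profile(genome, params$background_rate,
                                      replicon = rep$id)$values
    expected <- expected + sum(prof) / L
  }
  expected_total <- expected / max(1 - params$contaminant_fraction, 1e-9)
  if (expected_total > params$max_reads) {
    stopf("expected read count %.0f exceeds max_reads = %.0f; lower the rates or raise the cap",
          expected_total, params$max_reads)
  }
  for (rep in genome$replicons) {
    prof <- expected_coverage_profile(genome, params$background_rate,
                                      replicon = rep$id)$values
    cls <- position_classes(genome, rep$id, nchar(rep$seq))
    pieces[[rep$id]] <- sample_reads_from_profile(
      rep, prof, cls, L, params$error_rate,
      prefix = paste0("phage_", rep$id, "_"))
  }
  reads <- do.call(rbind, pieces)
  if (params$contaminant_fraction > 0) {
    n_genuine <- nrow(reads)
    n_cont <- rpois(1, n_genuine * params$contaminant_fraction /
                       (1 - params$contaminant_fraction))
    if (n_cont > 0) {
      cseq <- contaminant_sequence()
      cs <- sample.int(nchar(cseq) - L, n_cont, replace = TRUE) - 1L
      creads <- tibble::tibble(
        id = paste0("contam_", seq_len(n_cont)),
        seq = apply_substitutions(substring(cseq, cs + 1L, cs + L), L,
                                  params$error_rate),
        label = "contaminant", src_replicon = NA_character_,
        src_start = cs, src_strand = "+")
      reads <- rbind(reads, creads)
    }
  }
  if (params$paired) reads <- add_mates(reads, genome, params)
  structure(reads, read_length = L, class = c("read_set", class(reads)))
}

## mate = opposite-strand read insert_size away (truth labels shared)
add_mates <- function(reads, genome, params) {
  L <- params$read_length
  mates <- base::rep(NA_character_, nrow(reads))
  for (rep in genome$replicons) {
    idx <- which(reads$src_replicon %in% rep$id)
    if (!length(idx)) next
    n <- nchar(rep$seq)
    ext <- paste0(rep$seq, substr(rep$seq, 1L, params$insert_size))
    ms <- (reads$src_start[idx] + params$insert_size - L) %% n
    m <- substring(ext, ms + 1L, ms + L)
    mates[idx] <- revcomp(m)
  }
  reads$mate <- apply_substitutions(mates, L, params$error_rate)
  reads
}

#' Simulate host-control reads
#'
#' Uniform expected coverage `depth` across the whole replicon, with no
#' prophage enrichment: the negative control for the delineation analysis.
#'
#' @param genome a `genome_model`.
#' @param depth expected fold coverage (> 0).
#' @param read_length,error_rate,seed as in [read_sim_params()].
#' @param max_reads refusal cap on the expected read count.
#' @return A `read_set` (all labels `"background"`).
#' @export
simulate_host_reads <- function(genome, depth, read_length = 100,
                                error_rate = 0.005, seed = 1,
                                max_reads = 2e6) {
  if (depth <= 0) stopf("depth must be > 0")
  set.seed(seed)
  L <- as.integer(read_length)
  total_len <- sum(vapply(genome$replicons, function(r) nchar(r$seq), numeric(1)))
  if (depth * total_len / L > max_reads) {
    stopf("expected read count %.0f exceeds max_reads = %.0f",
          depth * total_len / L, max_reads)
  }
  pieces <- lapply(genome$replicons, function(rep) {
    n <- nchar(rep$seq)
    sample_reads_from_profile(rep, base::rep(depth, n),
                              base::rep("background", n), L, error_rate,
                              prefix = paste0("host_", rep$id, "_"))
  })
  reads <- do.call(rbind, pieces)
  structure(reads, read_length = L, class = c("read_set", class(reads)))
}

#' Poisson-sample a coverage track from an expected profile
#'
#' Draws per-position read-start counts at rate `profile/read_length` and
#' convolves with the read length, giving a coverage track with the same
#' sampling structure as mapped simulated reads (including ~read-length
#' ramps at sharp profile edges) without materialising sequences. This is
#' the desk-scale route to paper-scale depths, where enumerating tens of
#' millions of reads would be pointless for a coverage-level analysis.
#'
#' @param profile a [coverage_track()] of expected per-base coverage.
#' @param read_length read length used for the convolution.
#' @param seed integer seed.
#' @return A [coverage_track()] of sampled integer coverage.
#' @export
simulate_poisson_coverage <- function(profile, read_length = 100, seed = 1) {
  stopifnot(inherits(profile, "coverage_track"))
  set.seed(seed)
  L <- as.integer(read_length)
  n <- length(profile$values)
  starts <- rpois(n, profile$values / L)
  if (profile$circular) {
    padded <- c(tail(starts, L - 1L), starts)
    cs <- cumsum(padded)
    cov <- cs[seq.int(L, n + L - 1L)] - c(0, cs[seq_len(n - 1L)])
  } else {
    cs <- cumsum(starts)
    cov <- cs - c(base::rep(0, L), head(cs, n - L))
  }
  coverage_track(cov, replicon_id = profile$replicon_id,
                 circular = profile$circular)
}

#' Write a read set as FASTQ
#'
#' Constant phred quality; paired sets are written interleaved with
#' `/1`/`/2` suffixes.
#'
#' @param reads a `read_set`.
#' @param path output FASTQ path.
#' @param quality_char constant quality character (default `"I"`, Q40).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  L <- attr(reads, "read_length")
  qual <- strrep(quality_char, L)
  if ("mate" %in% names(reads) && !all(is.na(reads$mate))) {
    lines <- as.vector(rbind(
      paste0("@", reads$id, "/1"), reads$seq, "+", qual,
      paste0("@", reads$id, "/2"), reads$mate, "+", qual))
  } else {
    lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  }
  writeLines(lines, path)
  invisible(path)
}
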