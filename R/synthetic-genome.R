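#' Specify a prophage to plant in a synthetic lysogen genome
#'
#' Coordinates are 0-based half-open. `core_rate` is the expected per-base
#' read coverage of the prophage core in the phage fraction; active
#' prophages sit orders of magnitude above the host background. An optional
#' one-sided flank models lower-frequency over-packaging of host DNA
#' adjacent to the prophage (specialized/lateral transduction): coverage
#' `flank_rate` over `flank_extent` bp on `flank_side`, either flat or
#' decaying geometrically with distance from the prophage edge.
#'
#' @param start,end 0-based half-open core interval.
#' @param core_rate expected per-base phage-fraction coverage of the core.
#' @param flank_side `"none"`, `"left"` or `"right"`.
#' @param flank_rate expected coverage at the prophage edge of the flank;
#'   must satisfy `core_rate > flank_rate > 0` when a flank is present.
#' @param flank_extent flank length in bp.
#' @param flank_decay `"flat"` (constant `flank_rate`) or `"geometric"`
#'   (`flank_rate * decay_per_kb^(d/1000)` at distance `d` from the edge).
#' @param decay_per_kb geometric decay multiplier per kb.
#' @return A `prophage_spec` list.
#' @export
prophage_spec <- function(start, end, core_rate = 70000,
                          flank_side = c("none", "left", "right"),
                          flank_rate = 1000, flank_extent = 10000,
                          flank_decay = c("flat", "geometric"),
                          decay_per_kb = 0.5) {
  flank_side <- match.arg(flank_side)
  flank_decay <- match.arg(flank_decay)
  if (end <= start) stopf("prophage end (%d) must exceed start (%d)", end, start)
  if (core_rate <= 0) stopf("core_rate must be positive")
  if (flank_side != "none" && !(core_rate > flank_rate && flank_rate > 0)) {
    stopf("need core_rate > flank_rate > 0 when a flank is present")
  }
  list(start = as.integer(start), end = as.integer(end),
       core_rate = core_rate, flank_side = flank_side,
       flank_rate = flank_rate, flank_extent = as.integer(flank_extent),
       flank_decay = flank_decay, decay_per_kb = decay_per_kb)
}

#' Specify an insertion-sequence family to plant
#'
#' All copies of one family get the identical sequence, which is what makes
#' their reads multi-map and creates spurious coverage peaks away from the
#' prophage.
#'
#' @param family family label (e.g. `"IS66"`).
#' @param length element length in bp.
#' @param starts integer vector of 0-based copy start positions.
#' @return An `is_spec` list.
#' @export
is_spec <- function(family, length, starts) {
  if (length < 100) stopf("IS elements shorter than 100 bp are not supported")
  list(family = family, length = as.integer(length),
       starts = as.integer(starts))
}

#' Simulate a lysogen genome with planted features
#'
#' Generates a uniformly random replicon at the requested GC content,
#' overwrites the planted insertion-sequence copies with one shared random
#' sequence per family, and records full ground truth. Deterministic for a
#' fixed seed.
#'
#' @param length replicon length in bp (>= 10 kb).
#' @param gc GC fraction of the random background sequence.
#' @param prophage_specs list of [prophage_spec()] objects; cores must not
#'   overlap.
#' @param is_specs list of [is_spec()] objects.
#' @param seed integer seed.
#' @param replicon_id replicon name.
#' @param circular logical; simulated replicons are circular by default.
#' @return A `genome_model`: `replicons` (list of id/seq/circular),
#'   `prophages` and `is_copies` ground-truth data frames (0-based
#'   half-open), and the seed.
#' @export
simulate_genome <- function(length, gc = 0.5, prophage_specs = list(),
                            is_specs = list(), seed = 1,
                            replicon_id = "chr", circular = TRUE) {
  len <- as.integer(length)
  rm(length)  # let base::length resolve below
  if (len < 10000L) stopf("replicon length must be >= 10 kb")
  pp <- prophage_specs
  if (length(pp) > 0 && !is.null(pp$start)) pp <- list(pp)  # single spec given bare
  for (p in pp) {
    if (p$end > len) {
      stopf("prophage [%d,%d) exceeds replicon length %d", p$start, p$end, len)
    }
  }
  if (length(pp) > 1) {
    o <- order(vapply(pp, `[[`, integer(1), "start"))
    pp <- pp[o]
    for (i in seq_len(length(pp) - 1)) {
      if (pp[[i + 1]]$start < pp[[i]]$end) {
        stopf("prophage intervals [%d,%d) and [%d,%d) overlap",
              pp[[i]]$start, pp[[i]]$end, pp[[i + 1]]$start, pp[[i + 1]]$end)
      }
    }
  }
  set.seed(seed)
  seq <- random_dna(len, gc)

  is_rows <- list()
  for (spec in is_specs) {
    elt <- random_dna(spec$length, gc)
    for (s in spec$starts) {
      if (s + spec$length > len) {
        stopf("IS copy [%d,%d) exceeds replicon length %d",
              s, s + spec$length, len)
      }
      substr(seq, s + 1L, s + spec$length) <- elt
      inside <- any(vapply(pp, function(p) s >= p$start && s + spec$length <= p$end,
                           logical(1)))
      is_rows[[length(is_rows) + 1L]] <- data.frame(
        replicon_id = replicon_id, start = s, end = s + spec$length,
        family = spec$family, inside_prophage = inside,
        stringsAsFactors = FALSE)
    }
  }
  is_copies <- if (length(is_rows)) do.call(rbind, is_rows) else
    data.frame(replicon_id = character(), start = integer(), end = integer(),
               family = character(), inside_prophage = logical())
  is_copies$id <- if (nrow(is_copies)) paste0("IS_", seq_len(nrow(is_copies))) else character()

  prophages <- if (length(pp)) {
    do.call(rbind, lapply(seq_along(pp), function(i) {
      p <- pp[[i]]
      data.frame(replicon_id = replicon_id, start = p$start, end = p$end,
                 core_rate = p$core_rate, flank_side = p$flank_side,
                 flank_rate = p$flank_rate, flank_extent = p$flank_extent,
                 flank_decay = p$flank_decay, decay_per_kb = p$decay_per_kb,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(replicon_id = character(), start = integer(), end = integer(),
               core_rate = numeric(), flank_side = character(),
               flank_rate = numeric(), flank_extent = integer(),
               flank_decay = character(), decay_per_kb = numeric())
  }

  structure(
    list(replicons = list(list(id = replicon_id, seq = seq, circular = circular)),
         prophages = prophages, is_copies = is_copies, seed = seed),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  lens <- vapply(x$replicons, function(r) nchar(r$seq), numeric(1))
  cat(sprintf("<genome_model> %d replicon(s), %s bp total; %d prophage(s), %d IS cop(ies)\n",
              length(x$replicons), format(sum(lens), big.mark = ","),
              nrow(x$prophages), nrow(x$is_copies)))
  invisible(x)
}

genome_replicon <- function(genome, replicon = NULL) {
  ids <- vapply(genome$replicons, `[[`, character(1), "id")
  if (is.null(replicon)) {
    return(genome$replicons[[1L]])
  }
  i <- match(replicon, ids)
  if (is.na(i)) stopf("unknown replicon '%s'", replicon)
  genome$replicons[[i]]
}

#' Analytic expected coverage profile of the phage fraction
#'
#' The deterministic per-base expectation against which the read simulator
#' and the caller are checked: background `background_rate` everywhere, the
#' flank profile over flanks, and `core_rate` over prophage cores. No
#' sampling is involved.
#'
#' @param genome a `genome_model`.
#' @param background_rate expected coverage of non-enriched host DNA in the
#'   phage fraction.
#' @param replicon which replicon (default first).
#' @return A [coverage_track()] of expectations.
#' @export
expected_coverage_profile <- function(genome, background_rate = 35,
                                      replicon = NULL) {
  rep <- genome_replicon(genome, replicon)
  n <- nchar(rep$seq)
  v <- base::rep(background_rate, n)
  pp <- genome$prophages[genome$prophages$replicon_id == rep$id, , drop = FALSE]
  for (i in seq_len(nrow(pp))) {
    p <- pp[i, ]
    has_room <- (p$flank_side == "right" && p$end < n) ||
                (p$flank_side == "left" && p$start > 0)
    if (p$flank_side != "none" && p$flank_extent > 0 && has_room) {
      if (p$flank_side == "right") {
        idx <- seq.int(p$end, min(n, p$end + p$flank_extent) - 1L)
        d <- idx - p$end
      } else {
        idx <- seq.int(max(0L, p$start - p$flank_extent), p$start - 1L)
        d <- p$start - 1L - idx
      }
      fv <- if (p$flank_decay == "flat") base::rep(p$flank_rate, length(idx))
            else p$flank_rate * p$decay_per_kb^(d / 1000)
      v[idx + 1L] <- fv
    }
    v[(p$start + 1L):p$end] <- p$core_rate
  }
  coverage_track(v, replicon_id = rep$id, circular = rep$circular)
}

#' Write genome FASTA
#'
#' @param genome a `genome_model`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genome$replicons, `[[`, character(1), "seq"))
  names(seqs) <- vapply(genome$replicons, `[[`, character(1), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write ground truth as BED6 and JSON manifest
#'
#' BED rows are 0-based half-open with the feature class in the name column
#' (`prophage_core`, `flank`, `IS:<family>`); the JSON manifest carries the
#' full simulation parameters.
#'
#' @param genome a `genome_model`.
#' @param bed_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, a data frame of the BED rows.
#' @export
write_truth <- function(genome, bed_path = NULL, json_path = NULL) {
  rows <- list()
  pp <- genome$prophages
  for (i in seq_len(nrow(pp))) {
    p <- pp[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = p$replicon_id, start = p$start, end = p$end,
      name = "prophage_core", score = 0, strand = ".")
    if (p$flank_side == "right") {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = p$replicon_id, start = p$end, end = p$end + p$flank_extent,
        name = "flank", score = 0, strand = ".")
    } else if (p$flank_side == "left") {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = p$replicon_id, start = p$start - p$flank_extent, end = p$start,
        name = "flank", score = 0, strand = ".")
    }
  }
  ic <- genome$is_copies
  for (i in seq_len(nrow(ic))) {
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ic$replicon_id[i], start = ic$start[i], end = ic$end[i],
      name = paste0("IS:", ic$family[i]), score = 0, strand = ".")
  }
  bed <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character())
  if (!is.null(bed_path)) {
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(json_path)) {
    manifest <- list(
      seed = genome$seed,
      replicons = lapply(genome$replicons, function(r)
        list(id = r$id, length = nchar(r$seq), circular = r$circular)),
      prophages = genome$prophages, is_copies = genome$is_copies)
    jsonlite::write_json(manifest, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(bed)
}
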