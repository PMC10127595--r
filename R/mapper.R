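#' Build a k-mer index of replicon sequences
#'
#' Indexes every position of both strands: a plus-strand entry stores the
#' forward k-mer starting at `pos`, a minus-strand entry the reverse
#' complement of the same k-mer. Circular replicons are indexed across the
#' origin. The built-in mapper exists so the pipeline is self-contained and
#' testable end to end; externally produced BedGraph coverage is an equally
#' valid entry point to the caller.
#'
#' @param replicons list of `list(id, seq, circular)` (as in a
#'   `genome_model`), or a `genome_model`.
#' @param k k-mer size, odd, in `[11, 31]`.
#' @return A `kmer_index`.
#' @export
build_index <- function(replicons, k = 21) {
  if (inherits(replicons, "genome_model")) replicons <- replicons$replicons
  k <- as.integer(k)
  if (k < 11L || k > 31L || k %% 2L == 0L) {
    stopf("k must be odd and in [11, 31], got %d", k)
  }
  tabs <- list()
  meta <- list()
  for (rep in replicons) {
    n <- nchar(rep$seq)
    if (n < k) next
    npos <- if (rep$circular) n else n - k + 1L
    ext <- if (rep$circular) paste0(rep$seq, substr(rep$seq, 1L, k - 1L)) else rep$seq
    starts <- seq_len(npos)
    fwd <- substring(ext, starts, starts + k - 1L)
    rc <- revcomp(fwd)
    tabs[[length(tabs) + 1L]] <- data.table::data.table(
      kmer = c(fwd, rc),
      replicon_id = rep$id,
      pos0 = c(starts, starts) - 1L,
      strand = base::rep(c("+", "-"), each = npos))
    meta[[length(meta) + 1L]] <- data.frame(
      id = rep$id, length = n, circular = rep$circular,
      stringsAsFactors = FALSE)
  }
  dt <- if (length(tabs)) data.table::rbindlist(tabs) else
    data.table::data.table(kmer = character(), replicon_id = character(),
                           pos0 = integer(), strand = character())
  data.table::setkey(dt, kmer)
  structure(
    list(k = k, entries = dt,
         replicons = if (length(meta)) do.call(rbind, meta) else
           data.frame(id = character(), length = integer(), circular = logical()),
         seqs = setNames(lapply(replicons, `[[`, "seq"),
                         vapply(replicons, `[[`, character(1), "id"))),
    class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %s entries over %d replicon(s)\n",
              x$k, format(nrow(x$entries), big.mark = ","),
              nrow(x$replicons)))
  invisible(x)
}

## extract the verification target substring for a candidate locus,
## honouring circular wrap; returns NA for out-of-range linear candidates
candidate_targets <- function(index, cand, L) {
  out <- character(nrow(cand))
  for (rid in unique(cand$replicon_id)) {
    i <- which(cand$replicon_id == rid)
    seq <- index$seqs[[rid]]
    meta <- index$replicons[index$replicons$id == rid, ]
    n <- meta$length
    s <- cand$start0[i]
    if (meta$circular) {
      ext <- paste0(seq, substr(seq, 1L, L - 1L))
      s <- s %% n
      out[i] <- substring(ext, s + 1L, s + L)
    } else {
      ok <- s >= 0L & s + L <= n
      out[i] <- NA_character_
      out[i][ok] <- substring(seq, s[ok] + 1L, s[ok] + L)
    }
  }
  out
}

## vectorised Hamming distance between equal-length string pairs
hamming <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (!length(a)) return(integer())
  cmp <- Biostrings::compareStrings(a, b)
  nchar(cmp) - nchar(gsub("?", "", cmp, fixed = TRUE))
}

#' Map reads by seeded exact k-mer anchoring and full-read verification
#'
#' Each read is anchored by exact k-mer lookup at `max_mismatches + 1`
#' evenly spaced offsets (pigeonhole: a read with at most `max_mismatches`
#' substitutions has at least one error-free anchor when the offsets are
#' `>= k` apart), candidate loci are verified against the full read with at
#' most `max_mismatches` substitutions, and all equally best loci are
#' collected. One locus per read is then chosen by the multi-map policy:
#' \describe{
#'   \item{`random_best`}{a uniformly random best locus (seeded); the
#'     default, and the semantics under which identical repeat copies split
#'     a repeat's reads evenly and produce spurious peaks at every copy.}
#'   \item{`unique`}{only uniquely best reads are placed.}
#'   \item{`all_weighted`}{every best locus is emitted with weight
#'     `1/n_best`.}
#' }
#' Paired reads are flattened into independent singletons. Unplaceable
#' reads are reported as unmapped, not errors.
#'
#' @param reads a `read_set` (or tibble with `id` and `seq`).
#' @param index a [build_index()] result.
#' @param max_mismatches maximum substitutions allowed in a placement.
#' @param policy multi-map policy, see above.
#' @param seed seed for `random_best` tie-breaking.
#' @return A `placement_set`: `placements` tibble (`read_id`,
#'   `replicon_id`, `start` 0-based, `strand`, `n_best`, `n_mismatch`,
#'   `weight`), `unmapped` read ids, `n_reads`, `policy`, `read_length`.
#' @export
map_reads <- function(reads, index, max_mismatches = 2,
                      policy = c("random_best", "unique", "all_weighted"),
                      seed = 1) {
  policy <- match.arg(policy)
  k <- index$k
  ids <- reads$id
  seqs <- reads$seq
  if ("mate" %in% names(reads) && !all(is.na(reads$mate))) {
    ids <- c(paste0(ids, "/1"), paste0(ids, "/2"))
    seqs <- c(seqs, reads$mate)
  }
  if (length(seqs) == 0L) {
    return(empty_placement_set(character(), policy,
                               attr(reads, "read_length") %||% NA_integer_))
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stopf("reads must have a single common length")
  if (L < k) stopf("read length %d is shorter than k = %d", L, k)

  n_anchor <- max_mismatches + 1L
  offsets <- unique(as.integer(round(seq(0L, L - k, length.out = n_anchor))))

  rc <- revcomp(seqs)
  qdt <- data.table::rbindlist(lapply(offsets, function(off) {
    data.table::data.table(
      read_idx = seq_along(seqs),
      off = off,
      kmer = substring(seqs, off + 1L, off + k))
  }))
  hits <- index$entries[qdt, on = "kmer", allow.cartesian = TRUE, nomatch = NULL]
  if (nrow(hits) == 0L) {
    return(empty_placement_set(ids, policy, L))
  }
  ## locus arithmetic: plus-strand anchor at read offset `off` sits at
  ## genome pos0, so the read starts at pos0-off; a minus-strand entry at
  ## pos0 matches read offset `off` when the read start is pos0+k+off-L
  hits[, start0 := ifelse(strand == "+", pos0 - off, pos0 + k + off - L)]
  ## normalise circular loci so anchor offsets agree on one canonical start
  lens <- setNames(index$replicons$length, index$replicons$id)
  circs <- setNames(index$replicons$circular, index$replicons$id)
  hits[, start0 := ifelse(circs[replicon_id],
                          start0 %% lens[replicon_id], start0)]
  cand <- unique(hits[, .(read_idx, replicon_id, start0, strand)])

  target <- candidate_targets(index, cand, L)
  query <- ifelse(cand$strand == "+", seqs[cand$read_idx], rc[cand$read_idx])
  keep <- !is.na(target)
  cand <- cand[keep]
  cand[, nm := hamming(query[keep], target[keep])]
  cand <- cand[nm <= max_mismatches]
  if (nrow(cand) == 0L) {
    return(empty_placement_set(ids, policy, L))
  }
  cand[, best := min(nm), by = read_idx]
  cand <- cand[nm == best]
  cand[, n_best := .N, by = read_idx]
  data.table::setorder(cand, read_idx, replicon_id, start0, strand)

  if (policy == "all_weighted") {
    placed <- cand
    placed[, weight := 1 / n_best]
  } else if (policy == "unique") {
    placed <- cand[n_best == 1L]
    placed[, weight := 1]
  } else {
    set.seed(seed)
    cand[, u := runif(.N)]
    placed <- cand[cand[, .I[which.max(u)], by = read_idx]$V1]
    placed[, weight := 1]
  }
  mapped_idx <- unique(cand$read_idx)
  placements <- tibble::tibble(
    read_id = ids[placed$read_idx],
    replicon_id = placed$replicon_id,
    start = placed$start0,
    strand = placed$strand,
    n_best = placed$n_best,
    n_mismatch = placed$nm,
    weight = placed$weight)
  structure(
    list(placements = placements,
         unmapped = ids[setdiff(seq_along(ids), mapped_idx)],
         n_reads = length(ids), policy = policy, read_length = L),
    class = "placement_set")
}

empty_placement_set <- function(ids, policy, L) {
  structure(
    list(placements = tibble::tibble(
           read_id = character(), replicon_id = character(),
           start = integer(), strand = character(), n_best = integer(),
           n_mismatch = integer(), weight = numeric()),
         unmapped = ids, n_reads = length(ids), policy = policy,
         read_length = L),
    class = "placement_set")
}

#' @export
print.placement_set <- function(x, ...) {
  cat(sprintf(
    "<placement_set> %s/%s reads mapped (policy %s); %s multi-mapped\n",
    format(x$n_reads - length(x$unmapped), big.mark = ","),
    format(x$n_reads, big.mark = ","), x$policy,
    format(length(unique(x$placements$read_id[x$placements$n_best > 1L])),
           big.mark = ",")))
  invisible(x)
}

#' Fraction of reads that mapped
#'
#' @param placements a `placement_set`.
#' @return mapped / total, in `[0, 1]`.
#' @export
mapped_fraction <- function(placements) {
  stopifnot(inherits(placements, "placement_set"))
  if (placements$n_reads == 0L) stopf("empty read set")
  1 - length(placements$unmapped) / placements$n_reads
}

#' Accumulate placements into per-replicon coverage tracks
#'
#' Each placement adds its weight (1, or `1/n_best` under `all_weighted`)
#' to the `read_length` positions it covers; circular replicons wrap across
#' the origin. Under `all_weighted` the track total equals the total placed
#' bases exactly.
#'
#' @param placements a `placement_set`.
#' @param replicon_lengths named vector of replicon lengths, or a
#'   `kmer_index` / `genome_model` to take them from.
#' @param circular named logical vector (default `TRUE` for all).
#' @return Named list of [coverage_track()]s.
#' @export
coverage_from_placements <- function(placements, replicon_lengths,
                                     circular = NULL) {
  stopifnot(inherits(placements, "placement_set"))
  if (inherits(replicon_lengths, "kmer_index")) {
    meta <- replicon_lengths$replicons
    circular <- setNames(meta$circular, meta$id)
    replicon_lengths <- setNames(meta$length, meta$id)
  } else if (inherits(replicon_lengths, "genome_model")) {
    g <- replicon_lengths
    replicon_lengths <- setNames(
      vapply(g$replicons, function(r) nchar(r$seq), numeric(1)),
      vapply(g$replicons, `[[`, character(1), "id"))
    circular <- setNames(vapply(g$replicons, `[[`, logical(1), "circular"),
                         names(replicon_lengths))
  }
  L <- placements$read_length
  pl <- placements$placements
  out <- list()
  for (rid in names(replicon_lengths)) {
    n <- as.integer(replicon_lengths[[rid]])
    circ <- if (is.null(circular)) TRUE else isTRUE(circular[[rid]])
    sub <- pl[pl$replicon_id == rid, ]
    d <- numeric(n + 1L)
    if (nrow(sub)) {
      s <- sub$start
      e <- s + L
      if (any(s < 0L | s >= n)) stopf("placement start outside replicon '%s'", rid)
      if (!circ && any(e > n)) {
        stopf("placement beyond the end of linear replicon '%s'", rid)
      }
      wrap <- e > n
      ## difference-array accumulation, wrapped part added separately
      add <- function(pos, w) {
        a <- rowsum(w, pos)
        d[as.integer(rownames(a)) + 1L] <<- d[as.integer(rownames(a)) + 1L] + a[, 1L]
      }
      add(s, sub$weight)
      add(pmin(e, n), -sub$weight)
      if (any(wrap)) {
        add(base::rep(0L, sum(wrap)), sub$weight[wrap])
        add(e[wrap] - n, -sub$weight[wrap])
      }
    }
    out[[rid]] <- coverage_track(pmax(cumsum(d[seq_len(n)]), 0),
                                 replicon_id = rid, circular = circ)
  }
  out
}

#' Mapping summary table
#'
#' @param placements a `placement_set`.
#' @return One-row tibble: total, mapped, unique, multi, unmapped counts
#'   and the mapped fraction.
#' @export
mapping_summary <- function(placements) {
  pl <- placements$placements
  per_read <- pl[!duplicated(pl$read_id), ]
  tibble::tibble(
    total = placements$n_reads,
    mapped = placements$n_reads - length(placements$unmapped),
    unique = sum(per_read$n_best == 1L),
    multi = sum(per_read$n_best > 1L),
    unmapped = length(placements$unmapped),
    mapped_fraction = mapped_fraction(placements))
}
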