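## IS family -> catalytic class. IS110 is the single DEDD family, IS91 the
## single HUH family, ISCNY is not yet classified; everything else in these
## genomes is a DDE-type transposase.
is_family_class_table <- c(IS110 = "DEDD", IS91 = "HUH", ISCNY = "NA")

#' Catalytic class of an IS family
#'
#' @param family character vector of family labels.
#' @return `"DDE"`, `"DEDD"`, `"HUH"` or `"NA"` per family.
#' @export
is_family_class <- function(family) {
  cls <- is_family_class_table[family]
  cls[is.na(cls)] <- "DDE"
  unname(cls)
}

#' Insertion-sequence totals and densities
#'
#' Counts and densities (IS per Mb) per replicon and genome-wide (summed
#' counts over summed lengths). Rounding is applied only at reporting and
#' the convention used is recorded in the result.
#'
#' @param annotations data frame of IS intervals: `replicon_id`, `start`,
#'   `end` (0-based half-open), `family`.
#' @param replicon_lengths named vector of replicon lengths in bp.
#' @param rounding `"none"` or `"nearest"` (density reported to the
#'   nearest integer).
#' @return A `mobilome_summary`: `per_replicon` tibble, `genome` one-row
#'   tibble, `rounding`.
#' @export
is_totals_and_density <- function(annotations, replicon_lengths,
                                  rounding = c("none", "nearest")) {
  rounding <- match.arg(rounding)
  unknown <- setdiff(unique(annotations$replicon_id), names(replicon_lengths))
  if (length(unknown)) stopf("unknown replicon id: %s", unknown[1L])
  rnd <- if (rounding == "nearest") function(x) round(x) else identity
  counts <- table(factor(annotations$replicon_id, levels = names(replicon_lengths)))
  per <- tibble::tibble(
    replicon_id = names(replicon_lengths),
    is_count = as.integer(counts),
    length_bp = as.numeric(replicon_lengths),
    density_per_mb = rnd(as.integer(counts) / (as.numeric(replicon_lengths) / 1e6)))
  genome <- tibble::tibble(
    is_count = nrow(annotations),
    length_bp = sum(as.numeric(replicon_lengths)),
    density_per_mb = rnd(nrow(annotations) / (sum(as.numeric(replicon_lengths)) / 1e6)))
  structure(list(per_replicon = per, genome = genome, rounding = rounding),
            class = "mobilome_summary")
}

#' @export
print.mobilome_summary <- function(x, ...) {
  cat(sprintf("<mobilome_summary> %d IS over %s bp (%s/Mb, rounding: %s)\n",
              x$genome$is_count, format(x$genome$length_bp, big.mark = ","),
              format(x$genome$density_per_mb), x$rounding))
  print(x$per_replicon)
  invisible(x)
}

#' Windowed IS density track
#'
#' Counts per fixed window the IS elements whose midpoint falls in the
#' window; the midpoint rule makes windows a partition, so window counts
#' always sum to the total count. Optionally normalised as a proportion of
#' the maximum window density.
#'
#' @param annotations IS interval data frame (single replicon).
#' @param replicon_length replicon length in bp.
#' @param window window size in bp (>= 100).
#' @param normalize divide counts by the maximum count.
#' @return Tibble: `window_start`, `window_end` (0-based half-open),
#'   `count` (or normalised `density`).
#' @export
windowed_density <- function(annotations, replicon_length, window = 10000,
                             normalize = FALSE) {
  window <- as.integer(window)
  if (window < 100L) stopf("window must be >= 100 bp")
  n_win <- ceiling(replicon_length / window)
  mids <- (annotations$start + annotations$end) %/% 2L
  win <- pmin(mids %/% window, n_win - 1L) + 1L
  counts <- tabulate(win, nbins = n_win)
  out <- tibble::tibble(
    window_start = (seq_len(n_win) - 1L) * window,
    window_end = pmin(seq_len(n_win) * window, as.integer(replicon_length)),
    count = counts)
  if (normalize) {
    out$density <- if (max(counts) > 0) counts / max(counts) else counts
  }
  out
}

#' Log-normalised IS family abundance per Mb
#'
#' `log10(1 + count / (length / 1e6))` per family, with the catalytic
#' class attached; absent families score 0.
#'
#' @param annotations IS interval data frame with a `family` column.
#' @param total_length total sequence length in bp.
#' @param families optional family universe (absent families reported as 0).
#' @return Tibble: `family`, `count`, `abundance_per_mb`,
#'   `log_abundance`, `type_class`.
#' @export
family_abundance <- function(annotations, total_length, families = NULL) {
  counts <- table(annotations$family)
  fams <- families %||% names(counts)
  cnt <- as.integer(counts[fams])
  cnt[is.na(cnt)] <- 0L
  per_mb <- cnt / (total_length / 1e6)
  tibble::tibble(
    family = fams,
    count = cnt,
    abundance_per_mb = per_mb,
    log_abundance = log10(1 + per_mb),
    type_class = is_family_class(fams))
}

#' Count consecutive same-family IS duplicates
#'
#' Annotations are sorted by (replicon, start); adjacent pairs in genomic
#' order with the same family and an intervening gap of at most `max_gap`
#' bp count as one duplicate pair, so a run of n same-family elements
#' contributes n - 1 pairs. An element of a different family between two
#' copies breaks the run. Input order does not matter.
#'
#' @param annotations IS interval data frame (`replicon_id`, `start`,
#'   `end`, `family`).
#' @param max_gap maximum intervening gap in bp.
#' @return Tibble: `family`, `n_pairs`.
#' @export
consecutive_duplicates <- function(annotations, max_gap = 500) {
  if (!nrow(annotations)) return(tibble::tibble(family = character(),
                                                n_pairs = integer()))
  a <- annotations[order(annotations$replicon_id, annotations$start), ]
  n <- nrow(a)
  same <- a$replicon_id[-n] == a$replicon_id[-1L] &
          a$family[-n] == a$family[-1L] &
          (a$start[-1L] - a$end[-n]) <= max_gap
  fams <- a$family[-n][same]
  if (!length(fams)) return(tibble::tibble(family = character(),
                                           n_pairs = integer()))
  tab <- table(fams)
  tibble::tibble(family = names(tab), n_pairs = as.integer(tab))
}

#' Screen gene annotations for plasmid backbone operons
#'
#' Token-based, case-insensitive screen of gene ids and product strings
#' for a repABC replication operon (repA, repB and repC all present),
#' conjugal-transfer (tra*) genes and partition (par*) genes.
#'
#' @param genes data frame with `id` and `product` columns (intervals
#'   optional: `start`, `end`).
#' @return List: `repABC_present`, `tra_present`, `par_present` flags and
#'   `matches` tibble of matched genes and which screen they satisfied.
#' @export
plasmid_feature_screen <- function(genes) {
  txt <- tolower(paste(genes$id %||% "", genes$product %||% ""))
  tokens <- lapply(strsplit(txt, "[^a-z0-9]+"), function(x) x[nzchar(x)])
  has_token <- function(pattern) {
    vapply(tokens, function(tk) any(grepl(pattern, tk)), logical(1))
  }
  rep_hits <- list(repA = has_token("^repa$"), repB = has_token("^repb$"),
                   repC = has_token("^repc$"))
  ## gene-name shapes only (tra, traG, parA2, ...), so free text such as
  ## "transposase" or "partial" does not hit
  tra <- has_token("^tra([a-z][0-9]*)?$")
  par <- has_token("^par([a-z][0-9]*)?$")
  match_rows <- list()
  add_match <- function(which_flag, hits) {
    idx <- which(hits)
    if (length(idx)) {
      match_rows[[length(match_rows) + 1L]] <<- tibble::tibble(
        screen = which_flag, id = as.character(genes$id[idx]),
        product = as.character(genes$product[idx]))
    }
  }
  add_match("repA", rep_hits$repA); add_match("repB", rep_hits$repB)
  add_match("repC", rep_hits$repC)
  add_match("tra", tra); add_match("par", par)
  list(
    repABC_present = all(vapply(rep_hits, any, logical(1))),
    tra_present = any(tra),
    par_present = any(par),
    matches = if (length(match_rows)) do.call(rbind, match_rows) else
      tibble::tibble(screen = character(), id = character(),
                     product = character()))
}
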