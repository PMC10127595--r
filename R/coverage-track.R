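#' Per-base coverage track
#'
#' The central intermediate of the pipeline: one non-negative value per
#' genome position of a single replicon. Positions are 0-based internally;
#' `values[i]` is the coverage of position `i - 1`.
#'
#' @param values numeric vector of per-position coverage, all `>= 0`.
#' @param replicon_id replicon name (single string).
#' @param circular logical; whether the replicon is circular. Tracks are
#'   stored linearly either way; circularity matters to simulation and
#'   coverage accumulation, which may wrap reads across the origin.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, replicon_id = "chr", circular = TRUE) {
  values <- as.numeric(values)
  if (length(values) == 0L) stopf("coverage track must have length >= 1")
  if (anyNA(values) || any(values < 0)) {
    stopf("coverage values must be non-negative and non-missing")
  }
  structure(
    list(replicon_id = replicon_id, values = values, circular = circular),
    class = "coverage_track"
  )
}

#' @export
length.coverage_track <- function(x) length(x$values)

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %s: %s bp (%s), mean %.2f, median %.1f, max %.1f\n",
    x$replicon_id, format(length(x$values), big.mark = ","),
    if (x$circular) "circular" else "linear",
    mean(x$values), stats::median(x$values), max(x$values)
  ))
  invisible(x)
}

#' Write a coverage track as BedGraph
#'
#' Runs of equal value are merged into single 0-based half-open BedGraph
#' intervals; zero-valued runs are written too, so the file round-trips to
#' the identical track.
#'
#' @param track a [coverage_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  r <- rle(track$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  lines <- sprintf("%s\t%d\t%d\t%s", track$replicon_id, starts, ends,
                   format(r$values, trim = TRUE, scientific = FALSE,
                          digits = 15))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BedGraph coverage track
#'
#' Entry point for coverage produced by external mappers. Intervals are
#' 0-based half-open and must not overlap; uncovered positions are filled
#' with zero.
#'
#' @param path BedGraph file.
#' @param length replicon length in bp; defaults to the largest interval
#'   end in the file. Intervals beyond a declared length are an error.
#' @param replicon_id restrict to this replicon; required when the file
#'   contains several.
#' @param circular passed through to the returned track.
#' @return A [coverage_track()].
#' @export
read_bedgraph <- function(path, length = NULL, replicon_id = NULL,
                          circular = TRUE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!is.null(replicon_id)) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == replicon_id]
    if (length(gr) == 0L) stopf("no intervals for replicon '%s'", replicon_id)
  } else {
    ids <- unique(as.character(GenomicRanges::seqnames(gr)))
    if (length(ids) != 1L) {
      stopf("file contains %d replicons; pass `replicon_id`", length(ids))
    }
    replicon_id <- ids
  }
  ## back to 0-based half-open
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  val <- as.numeric(S4Vectors::mcols(gr)$score)
  if (any(val < 0)) {
    stopf("negative coverage value at interval %d", which(val < 0)[1L])
  }
  o <- order(s0)
  if (any(s0[o][-1L] < e0[o][-length(e0)])) {
    bad <- which(s0[o][-1L] < e0[o][-length(e0)])[1L]
    stopf("overlapping intervals at lines %d and %d (file order)",
          o[bad], o[bad + 1L])
  }
  n <- if (is.null(length)) max(e0) else as.integer(length)
  if (max(e0) > n) {
    stopf("interval %d ends at %d, beyond declared length %d",
          which.max(e0), max(e0), n)
  }
  values <- numeric(n)
  widths <- e0 - s0
  values[sequence(widths, from = s0 + 1L)] <- rep(val, widths)
  coverage_track(values, replicon_id = replicon_id, circular = circular)
}
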