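#' Segmentation parameters for prophage delineation
#'
#' The decision rule is magnitude-based: positions are classified by their
#' fold enrichment over the background coverage of the phage fraction.
#' Active prophage cores in induced-phage sequencing sit roughly three to
#' four orders of magnitude above background, over-packaged flanks one to
#' two; the default thresholds sit between those regimes with wide margins
#' on both sides.
#'
#' @param core_fold fold over background above which a position counts as
#'   enriched (prophage-core level).
#' @param flank_fold fold over background above which a position counts as
#'   elevated (flank level); `core_fold > flank_fold > 1`.
#' @param min_core_len minimum length (bp) for an enriched segment to be
#'   called a prophage core.
#' @param min_peak_len minimum segment length (bp) kept after merging;
#'   shorter blips are dropped.
#' @param merge_gap maximum gap (bp) of lower-level coverage bridged when
#'   merging same-level segments — this is what rides over the internal
#'   coverage dip an IS inside a prophage causes, without fusing distinct
#'   prophages.
#' @param smooth_window running-median window (bp, odd) applied before
#'   thresholding.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(core_fold = 500, flank_fold = 10,
                                min_core_len = 5000, min_peak_len = 200,
                                merge_gap = 2000, smooth_window = 201) {
  if (!(core_fold > flank_fold && flank_fold > 1)) {
    stopf("need core_fold > flank_fold > 1")
  }
  if (min_core_len <= min_peak_len) stopf("need min_core_len > min_peak_len")
  if (smooth_window %% 2 == 0) stopf("smooth_window must be odd")
  list(core_fold = core_fold, flank_fold = flank_fold,
       min_core_len = as.integer(min_core_len),
       min_peak_len = as.integer(min_peak_len),
       merge_gap = as.integer(merge_gap),
       smooth_window = as.integer(smooth_window))
}

#' Estimate the background coverage of a phage-fraction track
#'
#' Global median over all positions (zeros included). Prophages, flanks
#' and repeat artifacts occupy far less than half of a bacterial genome,
#' so the median is insensitive to them. Caller-supplied masked intervals
#' (0-based half-open data frame with `start`/`end`) are excluded.
#'
#' @param track a [coverage_track()].
#' @param mask optional data frame of intervals to exclude.
#' @return A `background_estimate`: `value`, `method`, `n_positions_used`.
#' @export
estimate_background <- function(track, mask = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  v <- track$values
  method <- "global median"
  if (!is.null(mask) && nrow(mask)) {
    drop <- logical(length(v))
    for (i in seq_len(nrow(mask))) {
      drop[(mask$start[i] + 1L):mask$end[i]] <- TRUE
    }
    v <- v[!drop]
    method <- "masked median"
  }
  if (!length(v) || all(v == 0)) stopf("no background signal: track is all zero")
  m <- stats::median(v)
  if (m == 0) stopf("no background signal: median coverage is zero")
  structure(list(value = m, method = method, n_positions_used = length(v)),
            class = "background_estimate")
}

#' @export
print.background_estimate <- function(x, ...) {
  cat(sprintf("<background_estimate> %.2fx (%s, %s positions)\n",
              x$value, x$method, format(x$n_positions_used, big.mark = ",")))
  invisible(x)
}

#' Running-median smoothing of a coverage track
#'
#' Noise control before thresholding. Edges are handled by shrinking the
#' window (Tukey endpoint rule); `window = 1` is the identity.
#'
#' @param track a [coverage_track()].
#' @param window odd window width in bp.
#' @return A smoothed [coverage_track()].
#' @export
smooth_track <- function(track, window = 201) {
  stopifnot(inherits(track, "coverage_track"))
  window <- as.integer(window)
  if (window %% 2L == 0L || window < 1L) stopf("window must be odd and >= 1")
  if (window == 1L) return(track)
  sm <- stats::runmed(track$values, window, endrule = "median")
  coverage_track(as.numeric(sm), replicon_id = track$replicon_id,
                 circular = track$circular)
}

## run-length decomposition of the per-position level vector into segments
level_runs <- function(lvl) {
  r <- rle(lvl)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths, end = ends, level = r$values)
}

## merge same-level runs across strictly-lower-level gaps <= merge_gap;
## returns merged segments with the bridged gaps recorded as dips
merge_level <- function(runs, level, merge_gap) {
  mine <- runs[runs$level == level, , drop = FALSE]
  if (!nrow(mine)) {
    return(data.frame(start = integer(), end = integer(), level = integer(),
                      dips = I(list())))
  }
  higher_runs <- runs[runs$level > level, , drop = FALSE]
  segs <- list()
  cur <- list(start = mine$start[1L], end = mine$end[1L], dips = list())
  for (i in seq_len(nrow(mine))[-1L]) {
    gap_s <- cur$end
    gap_e <- mine$start[i]
    gap_has_higher <- nrow(higher_runs) &&
      any(higher_runs$start < gap_e & higher_runs$end > gap_s)
    if (gap_e - gap_s <= merge_gap && !gap_has_higher) {
      cur$dips[[length(cur$dips) + 1L]] <- c(gap_s, gap_e)
      cur$end <- mine$end[i]
    } else {
      segs[[length(segs) + 1L]] <- cur
      cur <- list(start = mine$start[i], end = mine$end[i], dips = list())
    }
  }
  segs[[length(segs) + 1L]] <- cur
  data.frame(
    start = vapply(segs, `[[`, numeric(1), "start"),
    end = vapply(segs, `[[`, numeric(1), "end"),
    level = level,
    dips = I(lapply(segs, `[[`, "dips")))
}

#' Threshold and segment a coverage track by fold enrichment
#'
#' Each position is classified by `fold = value / background` into
#' background (`< flank_fold`), elevated (`>= flank_fold`) or enriched
#' (`>= core_fold`); maximal same-level runs become raw segments;
#' same-level segments separated by at most `merge_gap` bp of
#' strictly-lower-level positions are merged (bridging, for example, the
#' internal coverage dip over an IS inside a prophage); merged-over gaps
#' are kept as `dips`; segments shorter than `min_peak_len` are dropped.
#'
#' @param track a (typically smoothed) [coverage_track()].
#' @param background background coverage (a number or a
#'   `background_estimate`).
#' @param params a [segmentation_params()].
#' @return Data frame of segments: `start`, `end` (0-based half-open),
#'   `level` (`"elevated"`/`"enriched"`), `dips` (list column of bridged
#'   gap intervals).
#' @export
segment_coverage <- function(track, background, params = segmentation_params()) {
  stopifnot(inherits(track, "coverage_track"))
  bg <- if (inherits(background, "background_estimate")) background$value
        else background
  if (bg <= 0) stopf("background must be > 0")
  fold <- track$values / bg
  lvl <- ifelse(fold >= params$core_fold, 2L,
                ifelse(fold >= params$flank_fold, 1L, 0L))
  runs <- level_runs(lvl)
  enr <- merge_level(runs, 2L, params$merge_gap)
  ele <- merge_level(runs, 1L, params$merge_gap)
  ## elevated runs absorbed into a merged enriched segment are its dips,
  ## not standalone segments
  if (nrow(ele) && nrow(enr)) {
    inside <- vapply(seq_len(nrow(ele)), function(i) {
      any(ele$start[i] >= enr$start & ele$end[i] <= enr$end)
    }, logical(1))
    ele <- ele[!inside, , drop = FALSE]
  }
  segs <- rbind(enr, ele)
  segs <- segs[segs$end - segs$start >= params$min_peak_len, , drop = FALSE]
  segs <- segs[order(segs$start), , drop = FALSE]
  segs$level <- ifelse(segs$level == 2L, "enriched", "elevated")
  rownames(segs) <- NULL
  segs
}

#' Refine segment boundaries against the smoothed track
#'
#' The plateau level is the median coverage of the segment interior
#' (trimming half a smoothing window at each end when the segment is long
#' enough); boundaries are moved to the outermost positions where the
#' smoothed coverage is at least `max(core_fold * background, plateau /
#' 2)`, never extending the segment by more than `smooth_window`. A
#' degenerate segment whose plateau does not exceed the background is
#' returned unchanged and flagged.
#'
#' @param track the smoothed [coverage_track()] used for segmentation.
#' @param segment one segment (list/row with `start`, `end`, 0-based
#'   half-open).
#' @param background background coverage (number or `background_estimate`).
#' @param params a [segmentation_params()].
#' @return `list(start, end, flagged)`.
#' @export
refine_boundaries <- function(track, segment, background,
                              params = segmentation_params()) {
  bg <- if (inherits(background, "background_estimate")) background$value
        else background
  v <- track$values
  n <- length(v)
  s <- as.integer(segment$start)
  e <- as.integer(segment$end)
  w <- params$smooth_window
  trim <- if (e - s > 2L * w) w %/% 2L else 0L
  plateau <- stats::median(v[(s + trim + 1L):(e - trim)])
  if (plateau <= bg) {
    return(list(start = s, end = e, flagged = TRUE))
  }
  thr <- max(params$core_fold * bg, plateau / 2)
  ## expand outward while above threshold (bounded), then contract inward
  ns <- s
  while (ns > 0L && ns > s - w && v[ns] >= thr) ns <- ns - 1L
  while (ns < e - 1L && v[ns + 1L] < thr) ns <- ns + 1L
  ne <- e
  while (ne < n && ne < e + w && v[ne + 1L] >= thr) ne <- ne + 1L
  while (ne > ns + 1L && v[ne] < thr) ne <- ne - 1L
  list(start = ns, end = ne, flagged = FALSE)
}

#' Classify segments as prophage core, flank, or artifact
#'
#' Enriched segments at least `min_core_len` long become cores. Elevated
#' segments within `merge_gap` of a core become that core's flank (the
#' over-packaged host DNA adjacent to a prophage; reported separately and
#' never extending the core's coordinates). Remaining segments that
#' overlap an IS annotation by at least 1 bp and are at most twice the IS
#' length become repeat artifacts listing the overlapping annotations;
#' anything left is an artifact with an `"unexplained"` note.
#'
#' @param segments output of [segment_coverage()] (optionally refined).
#' @param background background coverage (number or `background_estimate`).
#' @param is_annotations optional data frame of IS intervals (`start`,
#'   `end` 0-based half-open, optional `id`, `family`).
#' @param params a [segmentation_params()].
#' @param track optional raw [coverage_track()] for per-region statistics.
#' @param replicon_id reported replicon name.
#' @return Tibble of regions with 1-based inclusive `start`/`end`,
#'   `klass`, coverage statistics, `attached_core`, `overlapping_is` and
#'   `internal_dips` list columns, and `note`.
#' @export
classify_segments <- function(segments, background, is_annotations = NULL,
                              params = segmentation_params(), track = NULL,
                              replicon_id = "chr") {
  bg <- if (inherits(background, "background_estimate")) background$value
        else background
  n_seg <- nrow(segments)
  if (!n_seg) {
    return(tibble::tibble(
      replicon_id = character(), start = integer(), end = integer(),
      klass = character(), mean_cov = numeric(), max_cov = numeric(),
      fold_over_background = numeric(), attached_core = character(),
      overlapping_is = list(), internal_dips = list(), note = character()))
  }
  len <- segments$end - segments$start
  klass <- base::rep("artifact", n_seg)
  core_idx <- which(segments$level == "enriched" & len >= params$min_core_len)
  klass[core_idx] <- "core"
  core_ids <- setNames(paste0("core_", seq_along(core_idx)), core_idx)

  attached <- base::rep(NA_character_, n_seg)
  for (i in setdiff(which(segments$level == "elevated"), core_idx)) {
    if (!length(core_idx)) break
    gaps <- interval_gap(segments$start[i], segments$end[i],
                         segments$start[core_idx], segments$end[core_idx])
    j <- which.min(gaps)
    if (gaps[j] <= params$merge_gap) {
      klass[i] <- "flank"
      attached[i] <- core_ids[[as.character(core_idx[j])]]
    }
  }

  overlapping <- base::rep(list(character()), n_seg)
  note <- base::rep("", n_seg)
  for (i in which(klass == "artifact")) {
    hit <- character()
    if (!is.null(is_annotations) && nrow(is_annotations)) {
      ov <- overlap_width(segments$start[i], segments$end[i],
                          is_annotations$start, is_annotations$end)
      is_len <- is_annotations$end - is_annotations$start
      j <- which(ov > 0 & len[i] <= 2 * is_len)
      if (length(j)) {
        hit <- if (!is.null(is_annotations$id)) as.character(is_annotations$id[j])
               else paste0("IS_", j)
      }
    }
    overlapping[[i]] <- hit
    if (!length(hit)) note[i] <- "unexplained"
  }

  mean_cov <- max_cov <- base::rep(NA_real_, n_seg)
  if (!is.null(track)) {
    for (i in seq_len(n_seg)) {
      v <- track$values[(segments$start[i] + 1L):segments$end[i]]
      mean_cov[i] <- mean(v)
      max_cov[i] <- max(v)
    }
  }
  dips <- if (!is.null(segments$dips)) segments$dips else base::rep(list(list()), n_seg)
  region_id <- base::rep(NA_character_, n_seg)
  region_id[core_idx] <- core_ids
  tibble::tibble(
    replicon_id = replicon_id,
    start = segments$start + 1L,  # report 1-based inclusive
    end = segments$end,
    klass = klass,
    mean_cov = mean_cov,
    max_cov = max_cov,
    fold_over_background = mean_cov / bg,
    region_id = region_id,
    attached_core = attached,
    overlapping_is = overlapping,
    internal_dips = as.list(dips),
    note = note)
}

#' Call and classify prophage regions from a phage-fraction coverage track
#'
#' The full delineation pipeline: estimate the background (global median),
#' smooth (running median), segment by fold enrichment, refine core
#' boundaries to the outermost positions holding at least half the plateau
#' coverage, and classify segments into prophage cores, over-packaged
#' flanks and repeat artifacts. Coordinates in the report are 1-based
#' inclusive.
#'
#' @param track a [coverage_track()] (raw; smoothing is internal).
#' @param is_annotations optional IS annotation data frame (0-based
#'   half-open `start`/`end`, optional `id`/`family`) used to explain
#'   artifact peaks.
#' @param params a [segmentation_params()].
#' @param mask optional masked intervals passed to [estimate_background()].
#' @return A `delineation_report`: `background`, `regions` tibble,
#'   `params`, `replicon_id`, `n_positions`, `flagged_segments`.
#' @export
call_prophages <- function(track, is_annotations = NULL,
                           params = segmentation_params(), mask = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  bg <- estimate_background(track, mask = mask)
  sm <- smooth_track(track, params$smooth_window)
  segs <- segment_coverage(sm, bg, params)
  flagged <- integer()
  for (i in which(segs$level == "enriched")) {
    r <- refine_boundaries(sm, segs[i, ], bg, params)
    if (r$flagged) flagged <- c(flagged, i)
    segs$start[i] <- r$start
    segs$end[i] <- r$end
  }
  regions <- classify_segments(segs, bg, is_annotations, params,
                               track = track, replicon_id = track$replicon_id)
  structure(
    list(background = bg, regions = regions, params = params,
         replicon_id = track$replicon_id, n_positions = length(track$values),
         flagged_segments = flagged),
    class = "delineation_report")
}

#' @export
print.delineation_report <- function(x, ...) {
  r <- x$regions
  cat(sprintf("<delineation_report> %s (%s bp): background %.2fx\n",
              x$replicon_id, format(x$n_positions, big.mark = ","),
              x$background$value))
  cat(sprintf("  %d core, %d flank, %d artifact region(s)\n",
              sum(r$klass == "core"), sum(r$klass == "flank"),
              sum(r$klass == "artifact")))
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-8s %s:%s-%s  (%s bp, %.0fx fold)%s\n",
                r$klass[i], r$replicon_id[i],
                format(r$start[i], big.mark = ","),
                format(r$end[i], big.mark = ","),
                format(r$end[i] - r$start[i] + 1L, big.mark = ","),
                r$fold_over_background[i],
                ifelse(nzchar(r$note[i]), paste0(" [", r$note[i], "]"), "")))
  }
  invisible(x)
}

#' Write called regions as BED6
#'
#' Class in the name column, fold over background in the score column
#' (capped at 1000, BED convention); coordinates back to 0-based half-open.
#'
#' @param report a `delineation_report`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(report, path) {
  r <- report$regions
  bed <- data.frame(
    chrom = r$replicon_id, start = r$start - 1L, end = r$end,
    name = r$klass, score = round(pmin(r$fold_over_background, 1000)),
    strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a delineation report as JSON
#'
#' @param report a `delineation_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    replicon_id = report$replicon_id,
    n_positions = report$n_positions,
    background = list(value = report$background$value,
                      method = report$background$method,
                      n_positions_used = report$background$n_positions_used),
    params = report$params,
    coordinate_convention = "1-based inclusive",
    regions = report$regions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
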