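#' Load prophage-prediction intervals from BED or GFF3
#'
#' Coordinates are normalised to 0-based half-open (BED is already; GFF3
#' start is shifted by one). The tool label is taken from the GFF3 source
#' column when present, else from the `tool` argument.
#'
#' @param path interval file.
#' @param format `"bed"` or `"gff3"` (default guessed from the extension).
#' @param tool tool name recorded on each interval.
#' @return Tibble of prediction intervals: `replicon_id`, `start`, `end`
#'   (0-based half-open), `tool`, `label`.
#' @export
load_intervals <- function(path, format = c("auto", "bed", "gff3"),
                           tool = NA_character_) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) stopf("malformed %s file '%s': %s", format, path,
                              conditionMessage(e)))
  if (length(gr) == 0L) {
    return(tibble::tibble(replicon_id = character(), start = integer(),
                          end = integer(), tool = character(),
                          label = character()))
  }
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  if (any(e0 <= s0)) {
    stopf("interval %d has end <= start after normalisation",
          which(e0 <= s0)[1L])
  }
  mc <- S4Vectors::mcols(gr)
  tool_col <- if (format == "gff3" && "source" %in% names(mc)) {
    as.character(mc$source)
  } else {
    base::rep(tool, length(gr))
  }
  label <- if ("name" %in% names(mc)) as.character(mc$name)
           else if ("type" %in% names(mc)) as.character(mc$type)
           else base::rep(NA_character_, length(gr))
  tibble::tibble(
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = s0, end = e0,
    tool = ifelse(is.na(tool_col), tool, tool_col),
    label = label)
}

#' Compare called prophage regions against external predictions
#'
#' Each prediction is matched to the called core region with the greatest
#' base overlap on the same replicon (ties broken by smaller summed
#' boundary offset, then leftmost core); multiple predictions may match
#' one core, reflecting the fragmented predictions external tools emit.
#' Per match it reports the Jaccard index `|intersection| / |union|`,
#' base-level precision `|intersection| / |prediction|` and recall
#' `|intersection| / |core|`, and signed left/right boundary offsets
#' (prediction minus core, bp). Predictions overlapping no core are
#' counted per tool as unmatched.
#'
#' @param called a `delineation_report` or its `regions` tibble (1-based
#'   inclusive coordinates, as reported).
#' @param predictions tibble from [load_intervals()] (0-based half-open).
#' @return An `overlap_report`: `matches` tibble and `unmatched_per_tool`
#'   tibble.
#' @export
compare_intervals <- function(called, predictions) {
  regions <- if (inherits(called, "delineation_report")) called$regions else called
  cores <- regions[regions$klass == "core", , drop = FALSE]
  ## back to 0-based half-open for the arithmetic
  cs <- cores$start - 1L
  ce <- cores$end
  core_id <- if (!is.null(cores$region_id) && !all(is.na(cores$region_id))) {
    cores$region_id
  } else {
    paste0("core_", seq_len(nrow(cores)))
  }
  n_pred <- nrow(predictions)
  rows <- vector("list", n_pred)
  matched <- logical(n_pred)
  for (i in seq_len(n_pred)) {
    p <- predictions[i, ]
    same <- which(cores$replicon_id == p$replicon_id)
    if (!length(same)) next
    ov <- overlap_width(p$start, p$end, cs[same], ce[same])
    if (all(ov == 0)) next
    cand <- same[ov == max(ov)]
    if (length(cand) > 1L) {
      offsum <- abs(p$start - cs[cand]) + abs(p$end - ce[cand])
      cand <- cand[offsum == min(offsum)]
      cand <- cand[which.min(cs[cand])]
    }
    j <- cand[1L]
    inter <- overlap_width(p$start, p$end, cs[j], ce[j])
    uni <- (p$end - p$start) + (ce[j] - cs[j]) - inter
    matched[i] <- TRUE
    rows[[i]] <- tibble::tibble(
      tool = p$tool, label = p$label, replicon_id = p$replicon_id,
      pred_start = p$start, pred_end = p$end,
      core = core_id[j], core_start = cs[j], core_end = ce[j],
      jaccard = inter / uni,
      precision = inter / (p$end - p$start),
      recall = inter / (ce[j] - cs[j]),
      left_offset = p$start - cs[j],
      right_offset = p$end - ce[j])
  }
  matches <- if (any(matched)) do.call(rbind, rows[matched]) else
    tibble::tibble(tool = character(), label = character(),
                   replicon_id = character(), pred_start = integer(),
                   pred_end = integer(), core = character(),
                   core_start = integer(), core_end = integer(),
                   jaccard = numeric(), precision = numeric(),
                   recall = numeric(), left_offset = integer(),
                   right_offset = integer())
  unmatched <- predictions[!matched, , drop = FALSE]
  per_tool <- if (nrow(unmatched)) {
    agg <- table(unmatched$tool, useNA = "ifany")
    tibble::tibble(tool = names(agg), n_unmatched = as.integer(agg))
  } else {
    tibble::tibble(tool = character(), n_unmatched = integer())
  }
  structure(list(matches = matches, unmatched_per_tool = per_tool,
                 n_predictions = n_pred, n_cores = nrow(cores)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> %d prediction(s) vs %d core(s): %d matched\n",
              x$n_predictions, x$n_cores, nrow(x$matches)))
  if (nrow(x$matches)) {
    print(x$matches[, c("tool", "core", "jaccard", "precision", "recall")])
  }
  if (nrow(x$unmatched_per_tool)) {
    cat("unmatched per tool:\n")
    print(x$unmatched_per_tool)
  }
  invisible(x)
}
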