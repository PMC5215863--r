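# GRanges helpers: tibbles are 0-based half-open, GRanges 1-based closed
.as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

# merge overlapping/adjacent intervals so reference units are not
# double-counted
.flatten_regions <- function(x) {
  if (!nrow(x)) return(x[, c("chrom", "start", "end")])
  g <- GenomicRanges::reduce(.as_granges(x))
  tibble::tibble(chrom = as.character(GenomicRanges::seqnames(g)),
                 start = GenomicRanges::start(g) - 1,
                 end = GenomicRanges::end(g))
}

# logical: does each interval of x overlap >= min_overlap bp of y?
.overlaps_any <- function(x, y, min_overlap = 1) {
  if (!nrow(x)) return(logical(0))
  if (!nrow(y)) return(rep(FALSE, nrow(x)))
  gx <- .as_granges(x); gy <- GenomicRanges::reduce(.as_granges(y))
  hits <- GenomicRanges::findOverlaps(gx, gy, minoverlap = min_overlap)
  out <- rep(FALSE, nrow(x))
  out[unique(S4Vectors::queryHits(hits))] <- TRUE
  out
}

# per-bin view of an annotation against a reference: returns a tibble with
# the state of every bin and whether the bin overlaps the reference
.bin_view <- function(annotation, reference, genome) {
  state <- segments_to_path(annotation, genome)
  truth <- rep(FALSE, genome$n_bins)
  ref <- .flatten_regions(reference)
  if (nrow(ref))
    truth[.interval_bins(genome, ref$chrom, ref$start, ref$end)] <- TRUE
  tibble::tibble(state = state, true = truth)
}

#' Rank chromatin states by precision against a reference
#'
#' Segment level: a state's precision is the fraction of its segments
#' overlapping at least `min_overlap` bp of the reference. Bin level: the
#' fraction of the state's bins that overlap the reference ("true
#' condition" bins). States are ranked by decreasing precision; ties keep
#' state-label order.
#'
#' @param annotation segment tibble.
#' @param reference reference region tibble (`chrom`, `start`, `end`).
#' @param genome a [binned_genome()] (needed at bin level).
#' @param level `"segment"` or `"bin"`.
#' @param min_overlap minimum overlap (bp) for the segment-level predicate.
#' @return A tibble (`state`, `precision`, `rank`), ordered by rank.
#' @export
state_precision_ranking <- function(annotation, reference, genome = NULL,
                                    level = c("segment", "bin"),
                                    min_overlap = 1) {
  level <- match.arg(level)
  if (!nrow(annotation)) stop("empty annotation")
  if (level == "segment") {
    hit <- .overlaps_any(annotation, reference, min_overlap)
    prec <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(state = as.character(annotation$state), hit = hit),
                      .data$state),
      precision = mean(.data$hit), .groups = "drop")
  } else {
    stopifnot(inherits(genome, "binned_genome"))
    bv <- .bin_view(annotation, reference, genome)
    prec <- dplyr::summarise(dplyr::group_by(bv, .data$state),
                             precision = mean(.data$true), .groups = "drop")
  }
  prec <- prec[order(-prec$precision, prec$state), ]
  prec$rank <- seq_len(nrow(prec))
  prec
}

#' Cumulative recall / FDR curve over precision-ranked states
#'
#' States are added in order of decreasing precision (equivalently,
#' increasing per-state FDR). After adding the top k states: recall is the
#' fraction of reference units (merged reference regions at segment level;
#' true bins at bin level) overlapped by the union of those states, and
#' FDR the fraction of predicted units (their segments, or their bins) not
#' overlapping the reference.
#'
#' @inheritParams state_precision_ranking
#' @param ranking optional precomputed [state_precision_ranking()].
#' @return A tibble of class `countseg_curve` (`state`, `precision`,
#'   `rank`, `recall`, `fdr`).
#' @export
cumulative_recall_fdr <- function(annotation, reference, genome = NULL,
                                  level = c("segment", "bin"),
                                  ranking = NULL, min_overlap = 1) {
  level <- match.arg(level)
  if (is.null(ranking))
    ranking <- state_precision_ranking(annotation, reference, genome, level,
                                       min_overlap)
  ref <- .flatten_regions(reference)
  if (level == "segment") {
    seg_hit <- .overlaps_any(annotation, ref, min_overlap)
    pts <- purrr::map_dfr(seq_len(nrow(ranking)), function(k) {
      top <- ranking$state[seq_len(k)]
      inset <- as.character(annotation$state) %in% top
      rec <- if (nrow(ref)) mean(.overlaps_any(ref, annotation[inset, ], min_overlap)) else 0
      tibble::tibble(recall = rec,
                     fdr = if (any(inset)) mean(!seg_hit[inset]) else 0)
    })
  } else {
    stopifnot(inherits(genome, "binned_genome"))
    bv <- .bin_view(annotation, reference, genome)
    n_true <- sum(bv$true)
    pts <- purrr::map_dfr(seq_len(nrow(ranking)), function(k) {
      inset <- bv$state %in% ranking$state[seq_len(k)]
      tibble::tibble(
        recall = if (n_true) sum(bv$true & inset) / n_true else 0,
        fdr = if (any(inset)) mean(!bv$true[inset]) else 0)
    })
  }
  out <- dplyr::bind_cols(ranking, pts)
  class(out) <- c("countseg_curve", class(out))
  out
}

#' Bin-level AUC of a precision-ranked annotation
#'
#' The segmentation is turned into a binary classifier: every bin is
#' scored by its state's precision rank (most precise state = highest
#' score) and bins overlapping the reference are the positive condition.
#' The AUC uses the standard midrank (tie-aware) formula, i.e. it equals
#' `P(score_pos > score_neg) + 0.5 * P(score_pos == score_neg)` over all
#' positive/negative bin pairs.
#'
#' @inheritParams state_precision_ranking
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(annotation, reference, genome,
                      ranking = NULL) {
  stopifnot(inherits(genome, "binned_genome"))
  if (is.null(ranking))
    ranking <- state_precision_ranking(annotation, reference, genome, "bin")
  bv <- .bin_view(annotation, reference, genome)
  n_pos <- sum(bv$true); n_neg <- sum(!bv$true)
  if (n_pos == 0 || n_neg == 0)
    stop("degenerate condition: reference covers none or all of the bins")
  # higher score = better rank (rank 1 is most precise)
  score <- -ranking$rank[match(bv$state, ranking$state)]
  r <- rank(score) # midranks handle tied score groups
  (sum(r[bv$true]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' @exportS3Method ggplot2::autoplot
autoplot.countseg_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fdr, y = .data$recall)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$state), vjust = -0.6, size = 3) +
    ggplot2::labs(x = "cumulative FDR", y = "cumulative recall",
                  title = "States added in order of decreasing precision") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1))
}
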