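#' Turn a per-bin state path into genomic segments
#'
#' Maximal runs of constant state become segments with bin-aligned,
#' 0-based half-open coordinates (the terminal segment of a chromosome is
#' truncated at the chromosome end, like the terminal bin). The segments
#' partition the binned genome.
#'
#' @param path integer state path, one entry per bin of `genome` (in
#'   [bin_table()] order).
#' @param genome a [binned_genome()].
#' @param state_labels optional character labels; default `"S1".."SK"`.
#' @return Segment tibble (`chrom`, `start`, `end`, `state`).
#' @examples
#' g <- binned_genome(data.frame(chrom = "c", length = 1200), 200)
#' path_to_segments(c(1, 1, 2, 2, 2, 1), g)
#' @export
path_to_segments <- function(path, genome, state_labels = NULL) {
  stopifnot(inherits(genome, "binned_genome"))
  if (length(path) != genome$n_bins)
    stop("path length (", length(path), ") does not match bin count (",
         genome$n_bins, ")")
  bins <- bin_table(genome)
  run <- cumsum(c(TRUE, path[-1] != path[-length(path)] |
                    bins$chrom[-1] != bins$chrom[-nrow(bins)]))
  seg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(run = run, chrom = bins$chrom,
                                   start = bins$start, end = bins$end,
                                   state = path), .data$run),
    chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
    state = .data$state[1], .groups = "drop")[, -1]
  if (is.null(state_labels)) state_labels <- paste0("S", sort(unique(path)))
  lv <- sort(unique(path))
  seg$state <- state_labels[match(seg$state, lv)]
  seg
}

#' Recover the per-bin state path from a segment annotation
#'
#' Inverse of [path_to_segments()]: every bin gets the state of the
#' segment covering it.
#'
#' @param annotation segment tibble.
#' @param genome a [binned_genome()].
#' @return Character vector of state labels, one per bin.
#' @export
segments_to_path <- function(annotation, genome) {
  bins <- bin_table(genome)
  path <- rep(NA_character_, nrow(bins))
  for (i in seq_len(nrow(annotation))) {
    idx <- .interval_bins(genome, annotation$chrom[i],
                          annotation$start[i], annotation$end[i])
    path[idx] <- as.character(annotation$state[i])
  }
  path
}

#' Per-state summary statistics of an annotation
#'
#' For every state: segment count, median segment width, median per-track
#' read coverage (median over segments of the segment's mean bin count)
#' and median unsigned distance from segment midpoints to the nearest
#' reference TSS (0 when the midpoint lies inside / at a TSS interval).
#'
#' @param annotation segment tibble.
#' @param genome a [binned_genome()].
#' @param counts optional count tibble on `genome` for the coverage
#'   medians.
#' @param tss optional TSS region tibble (`chrom`, `start`, `end`).
#' @return A tibble with one row per state.
#' @export
summarize_states <- function(annotation, genome, counts = NULL, tss = NULL) {
  states <- sort(unique(as.character(annotation$state)))
  track_names <- if (!is.null(counts))
    setdiff(names(counts), c("chrom", "start", "end")) else character()
  out <- purrr::map_dfr(states, function(s) {
    seg <- annotation[annotation$state == s, ]
    row <- tibble::tibble(state = s, n_segments = nrow(seg),
                          median_width = median(seg$end - seg$start))
    for (tr in track_names) {
      cov <- vapply(seq_len(nrow(seg)), function(i) {
        idx <- .interval_bins(genome, seg$chrom[i], seg$start[i], seg$end[i])
        mean(counts[[tr]][idx])
      }, 0.0)
      row[[paste0("median_coverage_", tr)]] <- median(cov)
    }
    if (!is.null(tss) && nrow(tss)) {
      mid <- (seg$start + seg$end) / 2
      dist <- vapply(seq_len(nrow(seg)), function(i) {
        on <- tss[tss$chrom == seg$chrom[i], ]
        if (!nrow(on)) return(NA_real_)
        inside <- mid[i] >= on$start & mid[i] < on$end
        if (any(inside)) 0 else min(pmin(abs(mid[i] - on$start),
                                         abs(mid[i] - (on$end - 1))))
      }, 0.0)
      row$median_tss_distance <- median(dist, na.rm = TRUE)
    }
    row
  })
  empty <- setdiff(states, annotation$state)
  if (length(empty)) message("state(s) with no segments: ", paste(empty, collapse = ", "))
  out
}
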