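#' Estimate the fragment half-shift by strand cross-correlation
#'
#' ChIP-seq reads are sequenced from fragment ends, so plus- and
#' minus-strand 5'-end coverage profiles are offset by roughly the fragment
#' length f. The estimator computes the cross-correlation between the two
#' 5'-end coverage vectors at 1 bp resolution over lags `0..max_shift` and
#' returns `f/2` (integer division) for the lag f maximizing it, ties going
#' to the smallest lag. Reads are then shifted by this half-fragment amount
#' towards their midpoints before binning.
#'
#' @param reads read tibble with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open; the minus-strand 5' end is `end - 1`).
#' @param max_shift largest fragment length (lag, bp) scanned.
#' @return Integer half-fragment shift in bp.
#' @export
estimate_fragment_shift <- function(reads, max_shift = 500) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(reads)))
  if (max_shift < 1) stop("`max_shift` must be >= 1")
  plus <- reads[reads$strand == "+", ]
  minus <- reads[reads$strand == "-", ]
  if (!nrow(plus) || !nrow(minus))
    stop("cannot estimate shift: reads must contain both strands")
  lags <- 0:max_shift
  cc <- numeric(length(lags))
  for (ch in unique(reads$chrom)) {
    p5 <- plus$start[plus$chrom == ch]
    m5 <- minus$end[minus$chrom == ch] - 1
    if (!length(p5) || !length(m5)) next
    pt <- table(p5)
    mt <- table(m5)
    ppos <- as.numeric(names(pt)); pn <- as.numeric(pt)
    mpos <- as.numeric(names(mt)); mn <- as.numeric(mt)
    for (i in seq_along(lags)) {
      j <- match(ppos + lags[i], mpos)
      hit <- !is.na(j)
      if (any(hit)) cc[i] <- cc[i] + sum(pn[hit] * mn[j[hit]])
    }
  }
  f <- lags[which.max(cc)] # which.max takes the first (smallest) lag on ties
  as.integer(f %/% 2)
}

#' Bin reads into fragment-midpoint counts
#'
#' Each read is shifted towards its fragment midpoint (`start + shift` on
#' the plus strand, `end - 1 - shift` on the minus strand), the shifted
#' position is clipped into its chromosome, and the bin containing it is
#' incremented. Column sums therefore equal the number of retained reads.
#'
#' @param reads read tibble (`chrom`, `start`, `end`, optional `strand`;
#'   strandless reads are treated as plus-strand).
#' @param genome a [binned_genome()].
#' @param shift half-fragment shift in bp (see
#'   [estimate_fragment_shift()]); default 0.
#' @return Integer vector of length `genome$n_bins` (one count per bin, in
#'   [bin_table()] order).
#' @export
bin_counts <- function(reads, genome, shift = 0) {
  stopifnot(inherits(genome, "binned_genome"))
  if (shift < 0) stop("`shift` must be >= 0")
  keep <- reads$chrom %in% genome$chrom$chrom
  if (any(!keep)) {
    message("dropped ", sum(!keep), " read(s) on unknown chromosomes")
    reads <- reads[keep, , drop = FALSE]
  }
  out <- integer(genome$n_bins)
  if (!nrow(reads)) return(out)
  strand <- if ("strand" %in% names(reads)) reads$strand else rep("+", nrow(reads))
  pos <- ifelse(strand == "-", reads$end - 1 - shift, reads$start + shift)
  len <- genome$chrom$length[match(reads$chrom, genome$chrom$chrom)]
  clipped <- sum(pos < 0 | pos > len - 1)
  if (clipped > 0) message(clipped, " shifted read(s) clipped to chromosome ends")
  pos <- pmax(0, pmin(pos, len - 1))
  idx <- .pos_to_bin(genome, reads$chrom, pos)
  tab <- tabulate(idx, nbins = genome$n_bins)
  as.integer(tab)
}

#' Total-count library-size factors
#'
#' For track d in cell type l with library size (total read count)
#' `r[d,l]`, the total-count size factor is
#' `s[d,l] = (1 / r[d,l]) * mean over cell types of r[d,.]`,
#' i.e. the multiplier that scales each library to the track's average
#' depth (`s[d,l] * r[d,l]` is constant across cell types). In the HMM
#' likelihood the emission mean of a state is scaled per cell type by the
#' depth-relative factor `1/s[d,l]` (see [emission_factors()]), so emission
#' means are expressed in reads per bin at the average library size.
#'
#' @param counts_by_cell_type named list (names = cell types) of count
#'   tibbles sharing the same track columns.
#' @return A tibble with columns `track`, `cell_type`, `library_size`,
#'   `size_factor`.
#' @examples
#' g <- binned_genome(data.frame(chrom = "c", length = 1000), 200)
#' a <- tibble::tibble(chrom = "c", start = 0, end = 200, H3K4me3 = 10L)
#' b <- tibble::tibble(chrom = "c", start = 0, end = 200, H3K4me3 = 30L)
#' compute_size_factors(list(A = a, B = b))
#' @export
compute_size_factors <- function(counts_by_cell_type) {
  stopifnot(is.list(counts_by_cell_type), length(counts_by_cell_type) >= 1)
  if (is.null(names(counts_by_cell_type)))
    names(counts_by_cell_type) <- paste0("cell", seq_along(counts_by_cell_type))
  tracks <- lapply(counts_by_cell_type, function(x)
    setdiff(names(x), c("chrom", "start", "end")))
  if (!all(vapply(tracks, function(t) identical(t, tracks[[1]]), TRUE)))
    stop("every cell type must provide the same tracks")
  lib <- purrr::imap_dfr(counts_by_cell_type, function(x, l)
    tibble::tibble(track = tracks[[1]], cell_type = l,
                   library_size = vapply(tracks[[1]], function(d)
                     sum(x[[d]]), 0, USE.NAMES = FALSE)))
  if (any(lib$library_size == 0))
    stop("empty library: track ",
         lib$track[lib$library_size == 0][1], " in cell type ",
         lib$cell_type[lib$library_size == 0][1])
  dplyr::mutate(dplyr::group_by(lib, .data$track),
                size_factor = mean(.data$library_size) / .data$library_size) |>
    dplyr::ungroup()
}

#' Depth-relative emission multipliers from size factors
#'
#' Converts total-count size factors (which scale each library *to* the
#' average depth) into the per-cell-type multipliers applied to emission
#' means (which scale the average-depth mean *to* each library's depth):
#' simply `1 / size_factor`.
#'
#' @param size_factors output of [compute_size_factors()].
#' @return The same tibble with an `emission_factor` column.
#' @export
emission_factors <- function(size_factors) {
  dplyr::mutate(size_factors, emission_factor = 1 / .data$size_factor)
}
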