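#' Fixed-width bin partition of a genome
#'
#' A `binned_genome` is the coordinate frame for every count matrix,
#' segmentation and benchmark in the package: each chromosome is tiled by
#' consecutive `bin_width`-bp bins (0-based, half-open), the last bin
#' truncated at the chromosome end.
#'
#' @param chrom_sizes data frame with columns `chrom` and `length`
#'   (base pairs), one row per chromosome, in the desired order.
#' @param bin_width bin width in base pairs (default 200, the standard
#'   resolution for chromatin-state segmentation).
#' @return An object of class `binned_genome`: a list with `chrom` (a tibble
#'   of `chrom`, `length`, `n_bins`, `offset`), `bin_width`, `n_bins` (total)
#'   and `genome_length` (total bp, the genome-length term of the
#'   enrichment statistic).
#' @examples
#' g <- binned_genome(data.frame(chrom = "chrI", length = 1000), bin_width = 200)
#' g$n_bins
#' @export
binned_genome <- function(chrom_sizes, bin_width = 200) {
  stopifnot(is.data.frame(chrom_sizes), all(c("chrom", "length") %in% names(chrom_sizes)))
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0)
    stop("`bin_width` must be a single positive number")
  if (anyDuplicated(chrom_sizes$chrom)) stop("duplicated chromosome names")
  if (any(chrom_sizes$length <= 0)) stop("chromosome lengths must be positive")
  chrom <- tibble::tibble(
    chrom = as.character(chrom_sizes$chrom),
    length = as.numeric(chrom_sizes$length),
    n_bins = as.integer(ceiling(.data$length / bin_width))
  )
  chrom$offset <- cumsum(c(0L, chrom$n_bins[-nrow(chrom)]))
  structure(
    list(chrom = chrom, bin_width = as.integer(bin_width),
         n_bins = sum(chrom$n_bins), genome_length = sum(chrom$length)),
    class = "binned_genome"
  )
}

#' @export
print.binned_genome <- function(x, ...) {
  cat("<binned_genome> ", nrow(x$chrom), " chromosome(s), ",
      x$n_bins, " bins of ", x$bin_width, " bp (",
      format(x$genome_length, big.mark = ","), " bp total)\n", sep = "")
  invisible(x)
}

#' Enumerate the bins of a binned genome
#'
#' @param genome a [binned_genome()].
#' @return A tibble with one row per bin: `chrom`, `start`, `end`
#'   (0-based half-open; the terminal bin of each chromosome is truncated
#'   at the chromosome end) and the global `bin` index (1-based).
#' @export
bin_table <- function(genome) {
  stopifnot(inherits(genome, "binned_genome"))
  w <- genome$bin_width
  out <- purrr::pmap_dfr(genome$chrom, function(chrom, length, n_bins, offset) {
    start <- (seq_len(n_bins) - 1) * w
    tibble::tibble(chrom = chrom, start = start,
                   end = pmin(start + w, length))
  })
  out$bin <- seq_len(nrow(out))
  out
}

#' Read a two-column chrom.sizes table
#'
#' @param path path to a tab-separated file with chromosome name and length.
#' @return A tibble with columns `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2)
  if (length(bad)) stop("malformed chrom.sizes line ", bad[1])
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  if (anyNA(len)) stop("non-numeric length at line ", which(is.na(len))[1])
  tibble::tibble(chrom = vapply(fields, `[[`, "", 1), length = len)
}

# map 0-based positions to global 1-based bin indices; positions are
# assumed clipped into [0, chrom length)
.pos_to_bin <- function(genome, chrom, pos) {
  i <- match(chrom, genome$chrom$chrom)
  genome$chrom$offset[i] + pmin(pos %/% genome$bin_width,
                                genome$chrom$n_bins[i] - 1L) + 1L
}

# global bin indices overlapped by 0-based half-open intervals (list column
# free: returns a vector of bin indices, possibly with duplicates removed)
.interval_bins <- function(genome, chrom, start, end) {
  i <- match(chrom, genome$chrom$chrom)
  keep <- !is.na(i) & end > 0 & start < genome$chrom$length[i]
  i <- i[keep]; start <- pmax(start[keep], 0); end <- end[keep]
  if (!length(i)) return(integer())
  w <- genome$bin_width
  first <- start %/% w
  last <- pmin((end - 1) %/% w, genome$chrom$n_bins[i] - 1L)
  unique(unlist(Map(function(f, l, o) o + seq.int(f, l) + 1L,
                    first, last, genome$chrom$offset[i])))
}
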