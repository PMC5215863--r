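#' Read an interval file (BED or tagAlign)
#'
#' Parses aligned-read or region intervals into a tibble with 0-based
#' half-open coordinates. tagAlign is the 6-column BED dialect used for
#' preprocessed ChIP-seq reads; its 6th column carries the strand.
#'
#' @param path path to the file.
#' @param format `"bed"` (3+ columns; column 4, when present, is kept as
#'   `name`) or `"tagAlign"` (6 columns, strand in column 6).
#' @param genome optional [binned_genome()]; records on chromosomes absent
#'   from it are dropped with a message reporting how many.
#' @return A tibble with columns `chrom`, `start`, `end` and, depending on
#'   the input, `name` and/or `strand`.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t200", tf)
#' read_intervals(tf)
#' @export
read_intervals <- function(path, format = c("bed", "tagAlign"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
    if (format == "tagAlign") out$strand <- character()
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  need <- if (format == "tagAlign") 6L else 3L
  bad <- which(nf < need)
  if (length(bad))
    stop("malformed ", format, " line ", lineno[bad[1]], ": expected >= ",
         need, " tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop("non-numeric coordinates at line ", lineno[bad[1]])
  bad <- which(start < 0 | end < 0)
  if (length(bad)) stop("negative coordinate at line ", lineno[bad[1]])
  bad <- which(start >= end)
  if (length(bad)) stop("empty or inverted interval at line ", lineno[bad[1]])
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (format == "tagAlign") {
    strand <- vapply(fields, `[[`, "", 6)
    bad <- which(!strand %in% c("+", "-"))
    if (length(bad)) stop("invalid strand at line ", lineno[bad[1]])
    out$strand <- strand
  } else if (any(nf >= 4)) {
    out$name <- ifelse(nf >= 4, vapply(fields, function(f)
      if (length(f) >= 4) f[[4]] else NA_character_, ""), NA_character_)
  }
  if (!is.null(genome)) {
    drop <- !out$chrom %in% genome$chrom$chrom
    if (any(drop)) {
      message("dropped ", sum(drop), " record(s) on chromosomes absent from the genome")
      out <- out[!drop, , drop = FALSE]
    }
  }
  out
}

#' Write a binned count matrix to a tab-separated file
#'
#' The on-disk format is a plain TSV: `#`-prefixed header lines recording
#' the bin width and cell-type label, then a column header
#' `chrom start end <track...>` and one row per bin. `read_counts()` of the
#' written file reproduces the input exactly.
#'
#' @param counts count tibble as produced by [bin_counts()] /
#'   [simulate_hmm_counts()]: columns `chrom`, `start`, `end` then one
#'   integer column per track.
#' @param path output path.
#' @param bin_width,cell_type recorded in the header; `bin_width` defaults
#'   to the modal bin width of the table.
#' @export
write_counts <- function(counts, path, bin_width = NULL, cell_type = NA) {
  stopifnot(all(c("chrom", "start", "end") %in% names(counts)))
  if (is.null(bin_width)) {
    w <- counts$end - counts$start
    bin_width <- if (nrow(counts)) max(w) else NA
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#countseg_counts\tv1"),
               paste0("#bin_width\t", bin_width),
               paste0("#cell_type\t", cell_type)), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a binned count matrix written by [write_counts()]
#'
#' @param path path to the TSV.
#' @param genome optional [binned_genome()]; when supplied, the file's bin
#'   grid must match the genome's exactly, otherwise an error is raised.
#' @return The count tibble; attributes `bin_width` and `cell_type` carry
#'   the header metadata.
#' @export
read_counts <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("no count table in ", path)
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(tab)))
    stop("count table must have chrom/start/end columns")
  out <- tibble::as_tibble(tab)
  meta <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)
  kv <- setNames(vapply(meta, function(f) if (length(f) > 1) f[[2]] else NA_character_, ""),
                 vapply(meta, `[[`, "", 1))
  attr(out, "bin_width") <- suppressWarnings(as.numeric(unname(kv["bin_width"])))
  attr(out, "cell_type") <- unname(kv["cell_type"])
  if (!is.null(genome)) {
    ref <- bin_table(genome)
    if (nrow(out) != nrow(ref) ||
        !all(out$chrom == ref$chrom & out$start == ref$start & out$end == ref$end))
      stop("bin grid in ", path, " does not match the supplied genome")
  }
  out
}

# deterministic state -> RGB palette (recycled beyond 12 states)
.state_palette <- function(labels) {
  base <- c("228,26,28", "55,126,184", "77,175,74", "152,78,163",
            "255,127,0", "255,255,51", "166,86,40", "247,129,191",
            "153,153,153", "102,194,165", "252,141,98", "141,160,203")
  setNames(base[(seq_along(labels) - 1) %% length(base) + 1], labels)
}

#' Write a state annotation as BED9
#'
#' Column 4 holds the state label; column 9 a deterministic per-state RGB
#' colour so repeated writes are byte-identical.
#'
#' @param annotation segment tibble (`chrom`, `start`, `end`, `state`) as
#'   produced by [path_to_segments()].
#' @param path output path.
#' @param header optional character vector of `#`-prefixed provenance lines
#'   written before the records.
#' @export
write_annotation <- function(annotation, path, header = NULL) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(annotation)))
  pal <- .state_palette(sort(unique(as.character(annotation$state))))
  bed <- data.frame(
    chrom = annotation$chrom,
    start = format(annotation$start, scientific = FALSE, trim = TRUE),
    end = format(annotation$end, scientific = FALSE, trim = TRUE),
    name = as.character(annotation$state),
    score = 0L, strand = ".",
    thickStart = format(annotation$start, scientific = FALSE, trim = TRUE),
    thickEnd = format(annotation$end, scientific = FALSE, trim = TRUE),
    itemRgb = pal[as.character(annotation$state)]
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(bed, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED9 state annotation
#'
#' Records are sorted, and adjacent same-state records on a chromosome are
#' merged, so `read_annotation(write_annotation(x))` is the identity for a
#' normalized annotation.
#'
#' @param path path to a BED file with the state label in column 4.
#' @return A segment tibble (`chrom`, `start`, `end`, `state`).
#' @export
read_annotation <- function(path) {
  x <- read_intervals(path, format = "bed")
  if (!"name" %in% names(x)) stop("annotation BED needs a state label in column 4")
  seg <- tibble::tibble(chrom = x$chrom, start = x$start, end = x$end,
                        state = x$name)
  seg <- dplyr::arrange(seg, .data$chrom, .data$start)
  # merge adjacent same-state runs
  grp <- cumsum(!(seg$chrom == dplyr::lag(seg$chrom, default = "") &
                    seg$state == dplyr::lag(seg$state, default = "") &
                    seg$start == dplyr::lag(seg$end, default = -1)))
  dplyr::summarise(dplyr::group_by(seg, grp = grp),
                   chrom = .data$chrom[1], start = min(.data$start),
                   end = max(.data$end), state = .data$state[1],
                   .groups = "drop")[, c("chrom", "start", "end", "state")]
}
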