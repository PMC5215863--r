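# nucleotides of overlap between two region tibbles (after merging x)
.overlap_nt <- function(x, y) {
  if (!nrow(x) || !nrow(y)) return(0)
  gx <- GenomicRanges::reduce(.as_granges(x))
  gy <- GenomicRanges::reduce(.as_granges(y))
  sum(GenomicRanges::width(GenomicRanges::intersect(gx, gy)))
}

.region_nt <- function(x) {
  if (!nrow(x)) return(0)
  sum(GenomicRanges::width(GenomicRanges::reduce(.as_granges(x))))
}

#' Transcription-factor enrichment in chromatin states
#'
#' For a TF with `TF_nt` total peak nucleotides, of which `TFs_nt` fall in
#' state s (covering `s_nt` of a genome of length l), the enrichment is
#' `(TFs_nt / TF_nt) / (s_nt / l)` — the TF's coverage density in the
#' state relative to the genome average. Per TF, enrichments are also
#' normalized to sum to 1 across the annotation's states.
#'
#' @param tf_peaks peak tibble (`chrom`, `start`, `end`), optionally with a
#'   `tf` column to process several factors at once.
#' @param annotation segment tibble.
#' @param genome a [binned_genome()] (provides the genome length l).
#' @return A tibble (`tf`, `state`, `enrichment`, `norm_enrichment`).
#' @export
tf_state_enrichment <- function(tf_peaks, annotation, genome) {
  stopifnot(inherits(genome, "binned_genome"))
  if (!nrow(tf_peaks)) stop("empty peak set")
  if (!"tf" %in% names(tf_peaks)) tf_peaks$tf <- "TF"
  l <- genome$genome_length
  states <- sort(unique(as.character(annotation$state)))
  out <- purrr::map_dfr(split(tf_peaks, tf_peaks$tf), function(pk) {
    tf_nt <- .region_nt(pk)
    if (tf_nt == 0) stop("TF ", pk$tf[1], " has zero peak nucleotides")
    e <- vapply(states, function(s) {
      seg <- annotation[annotation$state == s, ]
      s_nt <- .region_nt(seg)
      if (s_nt == 0) return(0)
      (.overlap_nt(pk, seg) / tf_nt) / (s_nt / l)
    }, 0.0)
    tibble::tibble(tf = pk$tf[1], state = states, enrichment = unname(e),
                   norm_enrichment = if (sum(e) > 0) unname(e / sum(e)) else 0)
  })
  out <- tibble::as_tibble(out)
  class(out) <- c("countseg_tf_enrichment", class(out))
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.countseg_tf_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$state, y = .data$tf,
                                       fill = .data$norm_enrichment)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "normalized\nenrichment") +
    ggplot2::labs(x = "chromatin state", y = NULL)
}

#' Co-binding rate (Jaccard index) of two TFs within a state
#'
#' Both peak sets are restricted to peaks intersecting the state's
#' segments; a co-occurrence is a reciprocal >= 1 bp overlap between an A
#' peak and a B peak there. In the default site mode the rate is
#' `co / (|A| + |B| - co)` with `co` the average of the number of A peaks
#' hitting B and B peaks hitting A (the two counts coincide for one-to-one
#' overlaps). `mode = "nt"` uses intersection-over-union of the peak
#' nucleotides within the state instead.
#'
#' @param tf_a,tf_b peak tibbles.
#' @param annotation segment tibble.
#' @param state state label defining the restriction.
#' @param mode `"sites"` (count peaks) or `"nt"` (count nucleotides).
#' @return Jaccard co-binding rate in `[0, 1]`.
#' @export
cobinding_rate <- function(tf_a, tf_b, annotation, state,
                           mode = c("sites", "nt")) {
  mode <- match.arg(mode)
  seg <- annotation[annotation$state == state, ]
  a <- tf_a[.overlaps_any(tf_a, seg), , drop = FALSE]
  b <- tf_b[.overlaps_any(tf_b, seg), , drop = FALSE]
  if (!nrow(a) && !nrow(b)) {
    warning("both peak sets are empty within state ", state)
    return(0)
  }
  if (mode == "nt") {
    inter <- .overlap_nt(a, b)
    uni <- .region_nt(dplyr::bind_rows(a[, c("chrom", "start", "end")],
                                       b[, c("chrom", "start", "end")]))
    return(if (uni > 0) inter / uni else 0)
  }
  co <- (sum(.overlaps_any(a, b)) + sum(.overlaps_any(b, a))) / 2
  co / (nrow(a) + nrow(b) - co)
}

#' GWAS trait enrichment in promoter/enhancer states
#'
#' For every trait with at least `min_variants` catalog SNPs, builds the
#' 2x2 table (trait vs rest-of-catalog) x (inside vs outside the state
#' group's segments) per cell type and applies a one-sided Fisher's exact
#' test in the enrichment direction. P-values are adjusted across all
#' (trait, cell type) tests with the Benjamini-Yekutieli procedure, which
#' is valid under arbitrary dependence between tests.
#'
#' @param catalog SNP tibble with columns `chrom`, `pos` (1-based) and
#'   `trait`.
#' @param annotations a segment tibble, or a named list of them (one per
#'   cell type).
#' @param state_group character vector of state labels forming the group
#'   (e.g. the enhancer states).
#' @param min_variants minimum catalog SNPs for a trait to be tested
#'   (default 20).
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return A tibble with one row per (trait, cell type): the 2x2 counts,
#'   odds ratio, `p_value` and BY-adjusted `p_adj`.
#' @export
gwas_enrichment <- function(catalog, annotations, state_group,
                            min_variants = 20,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!all(c("chrom", "pos", "trait") %in% names(catalog)))
    stop("catalog needs chrom, pos and trait columns")
  if (is.data.frame(annotations)) annotations <- list(all = annotations)
  snps <- tibble::tibble(chrom = catalog$chrom,
                         start = catalog$pos - 1, end = catalog$pos,
                         trait = catalog$trait)
  traits <- names(which(table(snps$trait) >= min_variants))
  out <- purrr::imap_dfr(annotations, function(ann, ct) {
    seg <- ann[as.character(ann$state) %in% state_group, ]
    inside <- .overlaps_any(snps, seg)
    purrr::map_dfr(traits, function(tr) {
      is_tr <- snps$trait == tr
      a <- sum(is_tr & inside); b <- sum(is_tr & !inside)
      c_ <- sum(!is_tr & inside); d <- sum(!is_tr & !inside)
      ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                        alternative = alternative)
      tibble::tibble(trait = tr, cell_type = ct,
                     n_trait = a + b, n_trait_in = a,
                     n_background = c_ + d, n_background_in = c_,
                     odds_ratio = unname(ft$estimate), p_value = ft$p.value)
    })
  })
  out$p_adj <- p.adjust(out$p_value, method = "BY")
  out
}

#' Coverage-controlled SNP recall by segment subsampling
#'
#' Different segmentations predict promoters/enhancers of very different
#' total extent; to compare SNP recall at a fixed footprint, segments of
#' the state group are drawn uniformly without replacement until their
#' cumulative width first reaches `coverage_target` of the genome
#' (overshoot allowed on the final draw). Per sample, recall is the
#' fraction of SNPs falling in the sampled segments and frequency the
#' number of SNPs per sampled bp; medians and empirical 95% intervals are
#' taken over `n_samples` repetitions. If the state group's total
#' coverage is at or below the target, every sample is the full set.
#'
#' @param annotation segment tibble.
#' @param state_group state labels forming the group.
#' @param snps SNP tibble (`chrom`, `pos` 1-based).
#' @param genome a [binned_genome()].
#' @param coverage_target fraction of the genome to sample (e.g. 0.02 for
#'   enhancers, 0.01 for promoters).
#' @param n_samples number of subsampling repetitions (default 100).
#' @param seed RNG seed; same seed, same output.
#' @return A one-row tibble: medians and 2.5/97.5 percentiles of recall
#'   and SNP frequency, plus the sampled coverage.
#' @export
coverage_controlled_recall <- function(annotation, state_group, snps, genome,
                                       coverage_target, n_samples = 100,
                                       seed = 1) {
  stopifnot(inherits(genome, "binned_genome"),
            coverage_target > 0, coverage_target <= 1)
  seg <- annotation[as.character(annotation$state) %in% state_group, ]
  if (!nrow(seg)) stop("no segments in the state group")
  pts <- tibble::tibble(chrom = snps$chrom, start = snps$pos - 1, end = snps$pos)
  widths <- seg$end - seg$start
  target_bp <- coverage_target * genome$genome_length
  n_snps <- nrow(pts)
  # which segment contains each SNP (points, so at most one after reduce-free
  # per-segment assignment; overlapping segments cannot occur in a partition)
  hit_seg <- rep(NA_integer_, n_snps)
  if (n_snps) {
    hits <- GenomicRanges::findOverlaps(.as_granges(pts), .as_granges(seg))
    hit_seg[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  }
  set.seed(seed)
  stats <- purrr::map_dfr(seq_len(n_samples), function(i) {
    if (sum(widths) <= target_bp) {
      take <- seq_len(nrow(seg))
    } else {
      ord <- sample.int(nrow(seg))
      cum <- cumsum(widths[ord])
      take <- ord[seq_len(which(cum >= target_bp)[1])]
    }
    bp <- sum(widths[take])
    rec <- if (n_snps) mean(!is.na(hit_seg) & hit_seg %in% take) else 0
    tibble::tibble(recall = rec, frequency = sum(!is.na(hit_seg) & hit_seg %in% take) / bp,
                   sampled_bp = bp)
  })
  tibble::tibble(
    coverage_target = coverage_target, n_samples = n_samples,
    median_recall = median(stats$recall),
    recall_lo = unname(quantile(stats$recall, 0.025, type = 7)),
    recall_hi = unname(quantile(stats$recall, 0.975, type = 7)),
    median_frequency = median(stats$frequency),
    frequency_lo = unname(quantile(stats$frequency, 0.025, type = 7)),
    frequency_hi = unname(quantile(stats$frequency, 0.975, type = 7)),
    median_sampled_bp = median(stats$sampled_bp))
}
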