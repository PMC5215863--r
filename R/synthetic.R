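#' Simulate binned count tracks from an HMM
#'
#' Draws a state path from the model's initial/transition probabilities
#' and, per cell type, counts from each state's emission with the mean
#' scaled by that cell type's emission factor: negative binomial counts as
#' a Poisson-Gamma mixture (`lambda ~ Gamma(shape = r, mean = mu * s)`,
#' `x ~ Poisson(lambda)`), Poisson-lognormal counts as a Poisson of a
#' lognormal rate. All randomness flows from one seeded stream, so equal
#' seeds give bit-identical output.
#'
#' @param model generating [hmm_model()].
#' @param genome a [binned_genome()].
#' @param cell_types named numeric vector: per-cell-type emission-mean
#'   multipliers (planted relative library depths); default one cell type
#'   at factor 1.
#' @param seed RNG seed.
#' @param share_path draw one state path shared by all cell types (`TRUE`,
#'   default — the cell types are then sequencing replicates of one
#'   underlying chromatin landscape) or an independent path per cell type.
#' @return A list: `counts` (named list of count tibbles), `truth` (list
#'   with the generating model, state path(s), planted factors, seed).
#' @export
simulate_hmm_counts <- function(model, genome, cell_types = c(cell1 = 1),
                                seed = 1, share_path = TRUE) {
  stopifnot(inherits(model, "countseg_hmm"), inherits(genome, "binned_genome"))
  if (is.null(names(cell_types))) stop("`cell_types` must be named")
  set.seed(seed)
  Tn <- genome$n_bins
  draw_path <- function() {
    p <- integer(Tn)
    p[1] <- sample.int(model$K, 1, prob = model$pi)
    for (t in seq_len(Tn - 1))
      p[t + 1] <- sample.int(model$K, 1, prob = model$A[p[t], ])
    p
  }
  shared <- if (share_path) draw_path() else NULL
  bins <- bin_table(genome)[, c("chrom", "start", "end")]
  paths <- list()
  counts <- purrr::imap(cell_types, function(s, l) {
    path <- if (share_path) shared else draw_path()
    paths[[l]] <<- path
    out <- bins
    for (tr in model$track_names) {
      x <- integer(Tn)
      for (k in seq_len(model$K)) {
        idx <- which(path == k)
        if (!length(idx)) next
        p <- model$params[model$params$state == k & model$params$track == tr, ]
        if (model$family == "negbinom") {
          lam <- rgamma(length(idx), shape = p$size, scale = p$mu * s / p$size)
        } else {
          lam <- exp(rnorm(length(idx), p$mu_log + log(s), p$sigma))
        }
        x[idx] <- rpois(length(idx), lam)
      }
      out[[tr]] <- x
    }
    out
  })
  list(counts = counts,
       truth = list(model = model, paths = paths, cell_types = cell_types,
                    seed = seed, share_path = share_path))
}

#' Plant reference regions with a known in-state fraction
#'
#' Places fixed-width reference intervals so that a stated fraction of
#' them falls inside segments of a target state and the rest falls
#' elsewhere — giving benchmark tests a known answer.
#'
#' @param annotation segment tibble (e.g. the true simulated annotation).
#' @param genome a [binned_genome()].
#' @param target_state state label the regions should hit.
#' @param precision_in_state fraction of regions placed inside the target
#'   state.
#' @param n number of regions.
#' @param width region width in bp.
#' @param seed RNG seed.
#' @return Region tibble (`chrom`, `start`, `end`).
#' @export
plant_reference_regions <- function(annotation, genome, target_state,
                                    precision_in_state = 1, n = 100,
                                    width = 50, seed = 1) {
  stopifnot(precision_in_state >= 0, precision_in_state <= 1)
  inside <- annotation[as.character(annotation$state) == target_state, ]
  outside <- annotation[as.character(annotation$state) != target_state, ]
  if (!nrow(inside)) stop("no segments of state ", target_state)
  set.seed(seed)
  n_in <- round(n * precision_in_state)
  place <- function(seg, m) {
    if (!m) return(tibble::tibble(chrom = character(), start = numeric(),
                                  end = numeric()))
    w <- pmax(seg$end - seg$start, 1)
    i <- sample.int(nrow(seg), m, replace = TRUE, prob = w)
    start <- floor(seg$start[i] + runif(m) * pmax(w[i] - width, 1))
    tibble::tibble(chrom = seg$chrom[i], start = start, end = start + width)
  }
  out <- dplyr::bind_rows(place(inside, n_in), place(outside, n - n_in))
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Plant a GWAS catalog with one enriched trait
#'
#' Generates SNPs for `n_traits` traits: the first trait's SNPs are placed
#' with relative density `density_ratio` inside the segments of
#' `enhancer_states` versus elsewhere; the remaining traits are uniform
#' over the genome. At `density_ratio = 1` every trait is null.
#'
#' @param annotation segment tibble.
#' @param genome a [binned_genome()].
#' @param enhancer_states state labels of the enriched compartment.
#' @param density_ratio in-state / out-of-state SNP density for the
#'   enriched trait (>= 0); 1 means no enrichment.
#' @param n_snps SNPs per trait.
#' @param n_traits number of traits (default 5); trait 1 is the enriched
#'   one, named `"trait_enriched"`.
#' @param seed RNG seed.
#' @return Catalog tibble (`chrom`, `pos` 1-based, `trait`).
#' @export
plant_snps <- function(annotation, genome, enhancer_states, density_ratio = 1,
                       n_snps = 100, n_traits = 5, seed = 1) {
  stopifnot(inherits(genome, "binned_genome"), density_ratio >= 0)
  if (n_snps == 0)
    return(tibble::tibble(chrom = character(), pos = numeric(),
                          trait = character()))
  set.seed(seed)
  seg <- annotation
  in_enh <- as.character(seg$state) %in% enhancer_states
  w <- (seg$end - seg$start) * ifelse(in_enh, density_ratio, 1)
  sample_positions <- function(m, weights) {
    i <- sample.int(nrow(seg), m, replace = TRUE, prob = weights)
    pos0 <- floor(seg$start[i] + runif(m) * (seg$end[i] - seg$start[i]))
    tibble::tibble(chrom = seg$chrom[i], pos = pos0 + 1)
  }
  out <- purrr::map_dfr(seq_len(n_traits), function(j) {
    wt <- if (j == 1) w else (seg$end - seg$start)
    cbind(sample_positions(n_snps, wt),
          trait = if (j == 1) "trait_enriched" else paste0("trait_null", j - 1))
  })
  tibble::as_tibble(out)
}
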