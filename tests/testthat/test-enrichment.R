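test_that("TF enrichment follows the nucleotide-density formula", {
  # genome 1e6 bp, state s covers 1e4 nt; TF has 100 nt of peaks, 80 inside
  g <- binned_genome(data.frame(chrom = "c", length = 1e6), 200)
  ann <- tibble::tibble(chrom = "c",
                        start = c(0, 1e4, 2e4),
                        end = c(1e4, 2e4, 1e6),
                        state = c("s", "t", "bg"))
  peaks <- tibble::tibble(chrom = "c",
                          start = c(100, 12000), end = c(180, 12020))
  e <- tf_state_enrichment(peaks, ann, g)
  expect_equal(e$enrichment[e$state == "s"], (80 / 100) / (1e4 / 1e6))
  expect_equal(e$enrichment[e$state == "s"], 80.0)
  expect_equal(sum(e$norm_enrichment), 1)

  # peaks spread proportionally to state coverage: enrichment 1 everywhere
  ann2 <- tibble::tibble(chrom = "c", start = c(0, 4e5), end = c(4e5, 1e6),
                         state = c("x", "y"))
  prop <- tibble::tibble(chrom = "c", start = c(0, 4e5), end = c(4e5, 1e6))
  e2 <- tf_state_enrichment(prop, ann2, g)
  expect_equal(e2$enrichment, c(1, 1))

  # a single whole-genome state is enrichment 1 for any TF
  whole <- tibble::tibble(chrom = "c", start = 0, end = 1e6, state = "all")
  set.seed(18)
  rnd <- tibble::tibble(chrom = "c", start = sort(sample.int(9e5, 50)))
  rnd$end <- rnd$start + 40
  expect_equal(tf_state_enrichment(rnd, whole, g)$enrichment, 1)

  expect_error(tf_state_enrichment(peaks[0, ], ann, g), "empty peak set")
})

test_that("co-binding Jaccard counts reciprocal peak overlaps in a state", {
  g <- binned_genome(data.frame(chrom = "c", length = 1e5), 200)
  ann <- tibble::tibble(chrom = "c", start = c(0, 5e4), end = c(5e4, 1e5),
                        state = c("enh", "bg"))
  a <- tibble::tibble(chrom = "c", start = c(100, 1000, 2000, 3000),
                      end = c(200, 1100, 2100, 3100))
  expect_equal(cobinding_rate(a, a, ann, "enh"), 1)

  b_disjoint <- dplyr::mutate(a, start = .data$start + 10000,
                              end = .data$end + 10000)
  expect_equal(cobinding_rate(a, b_disjoint, ann, "enh"), 0)

  # A: 4 sites, B: 6 sites, exactly 2 reciprocal co-occurrences -> 2/8
  b <- tibble::tibble(chrom = "c",
                      start = c(150, 1050, 20000, 21000, 22000, 23000),
                      end = c(250, 1150, 20100, 21100, 22100, 23100))
  expect_equal(cobinding_rate(a, b, ann, "enh"), 0.25)

  expect_warning(out <- cobinding_rate(a, b, ann, "bg"), "empty")
  expect_equal(out, 0)
})

test_that("GWAS enrichment reproduces the hypergeometric tail", {
  # trait: 20 SNPs, 10 inside; background: 1000 SNPs, 100 inside
  g <- binned_genome(data.frame(chrom = "c", length = 1.02e6), 200)
  enh <- tibble::tibble(chrom = "c", start = 0, end = 1e5, state = "Enh")
  bg <- tibble::tibble(chrom = "c", start = 1e5, end = 1.02e6, state = "bg")
  ann <- dplyr::bind_rows(enh, bg)
  pos_in <- function(n) sample.int(1e5 - 1, n)
  pos_out <- function(n) 1e5 + sample.int(9e5, n)
  set.seed(19)
  catalog <- dplyr::bind_rows(
    tibble::tibble(chrom = "c", pos = c(pos_in(10), pos_out(10)), trait = "T1"),
    tibble::tibble(chrom = "c", pos = c(pos_in(100), pos_out(900)), trait = "bgtrait"))
  res <- gwas_enrichment(catalog, ann, state_group = "Enh", min_variants = 20)
  t1 <- res[res$trait == "T1", ]
  expect_equal(t1$n_trait_in, 10)
  expect_equal(t1$p_value, hyper_tail(10, n_trait = 20, n_in = 110, N = 1020),
               tolerance = 1e-12)

  # a 19-variant trait is excluded
  catalog19 <- dplyr::bind_rows(catalog,
    tibble::tibble(chrom = "c", pos = pos_out(19), trait = "small"))
  res19 <- gwas_enrichment(catalog19, ann, state_group = "Enh")
  expect_false("small" %in% res19$trait)

  expect_error(gwas_enrichment(catalog[, c("chrom", "trait")], ann, "Enh"),
               "pos")
})

test_that("Fisher p-values match explicit hypergeometric sums on small tables", {
  set.seed(20)
  for (i in 1:25) {
    N <- sample(20:200, 1)
    n_in <- sample(1:(N - 1), 1)
    n_trait <- sample(1:(N - 1), 1)
    a <- sample(0:min(n_in, n_trait), 1)
    tab <- matrix(c(a, n_trait - a, n_in - a, N - n_trait - n_in + a), 2,
                  byrow = TRUE)
    if (any(tab < 0)) next
    p_pkg <- stats::fisher.test(tab, alternative = "greater")$p.value
    expect_equal(p_pkg, hyper_tail(a, n_trait, n_in, N), tolerance = 1e-10)
  }
})

test_that("BY adjustment matches its step-up definition and dominates BH", {
  p <- c(0.01, 0.02, 0.04)
  adj <- p.adjust(p, method = "BY")
  expect_equal(adj, c(0.055, 0.055, 0.0733), tolerance = 1e-3)
  expect_equal(adj, by_adjust_oracle(p), tolerance = 1e-12)
  set.seed(22)
  for (i in 1:10) {
    pv <- runif(sample(3:40, 1))
    expect_equal(p.adjust(pv, "BY"), by_adjust_oracle(pv), tolerance = 1e-12)
    expect_true(all(p.adjust(pv, "BY") >= p.adjust(pv, "BH") - 1e-12))
    # monotone in the raw p-values
    o <- order(pv)
    expect_true(all(diff(p.adjust(pv, "BY")[o]) >= -1e-12))
  }
})

test_that("coverage-controlled recall subsamples segments reproducibly", {
  g <- binned_genome(data.frame(chrom = "c", length = 1e6), 200)
  set.seed(23)
  n_seg <- 200
  starts <- sort(sample(seq(0, 1e6 - 400, by = 400), n_seg))
  ann <- tibble::tibble(chrom = "c", start = starts, end = starts + 200,
                        state = "Enh")
  snps <- tibble::tibble(chrom = "c",
                         pos = starts[seq(1, n_seg, by = 4)] + 100)

  # target above the group's coverage: full set, zero-width CI
  full <- coverage_controlled_recall(ann, "Enh", snps, g, coverage_target = 0.5,
                                     n_samples = 20, seed = 1)
  expect_equal(full$median_recall, 1)
  expect_equal(full$recall_lo, full$recall_hi)

  r1 <- coverage_controlled_recall(ann, "Enh", snps, g, coverage_target = 0.01,
                                   n_samples = 50, seed = 5)
  r2 <- coverage_controlled_recall(ann, "Enh", snps, g, coverage_target = 0.01,
                                   n_samples = 50, seed = 5)
  expect_identical(r1, r2)

  # at 1% of a 1e6 genome we can hold ~50 of 200 segments: recall ~ 1/4
  expect_gt(r1$median_recall, 0.1)
  expect_lt(r1$median_recall, 0.45)

  # median recall is non-decreasing in the coverage target
  r_lo <- coverage_controlled_recall(ann, "Enh", snps, g, 0.01,
                                     n_samples = 200, seed = 7)
  r_hi <- coverage_controlled_recall(ann, "Enh", snps, g, 0.02,
                                     n_samples = 200, seed = 7)
  expect_gte(r_hi$median_recall, r_lo$median_recall)
})

test_that("planted SNP density ratios are recovered by subsampling stats", {
  g <- binned_genome(data.frame(chrom = "c", length = 2e6), 200)
  set.seed(24)
  path <- sample(1:2, g$n_bins, replace = TRUE, prob = c(0.9, 0.1))
  ann <- path_to_segments(path, g)
  snps <- plant_snps(ann, g, enhancer_states = "S2", density_ratio = 3,
                     n_snps = 4000, n_traits = 1, seed = 25)
  res <- coverage_controlled_recall(ann, "S2", snps, g,
                                    coverage_target = 0.05, n_samples = 50,
                                    seed = 26)
  genome_avg <- nrow(snps) / g$genome_length
  # enhancer bp weight 3: density in state = 3 / (0.9 + 0.1*3) x average
  expected <- 3 / (0.9 + 0.1 * 3)
  expect_lt(abs(res$median_frequency / genome_avg - expected) / expected, 0.10)
})
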