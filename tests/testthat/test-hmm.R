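test_that("poisson threshold matches brute-force CDF search", {
  expect_equal(poisson_threshold(1), 6L)
  expect_equal(poisson_threshold(0.01), 1L)
  expect_equal(poisson_threshold(0), 1L)
  brute <- function(lambda) {
    n <- 1L
    while (TRUE) {
      tail <- 1 - sum(dpois(0:n, lambda))
      if (tail < 1e-4) return(n)
      n <- n + 1L
    }
  }
  for (lambda in seq(0, 50, by = 2.5))
    expect_equal(poisson_threshold(lambda), brute(lambda))
})

test_that("forward-backward matches exhaustive path enumeration", {
  draws <- 0
  for (seed in 1:12) {
    family <- if (seed %% 2) "negbinom" else "poilog"
    K <- 1 + seed %% 3 + 1 # 2 or 3
    K <- min(K, 3)
    Tn <- 4 + seed %% 5
    m <- random_small_model(K, 2, family, seed)
    cts <- random_counts(Tn, 2, seed + 100)
    fb <- forward_backward(m, cts)
    le <- countseg:::.log_emission_matrix(m, as.matrix(cts[, m$track_names]),
                                          setNames(c(1, 1), m$track_names))
    oracle <- exhaustive_fb(le, m$pi, m$A)
    expect_lt(abs(fb$log_likelihood - oracle$log_likelihood), 1e-10)
    expect_lt(max(abs(fb$gamma - oracle$gamma)), 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, Tn), tolerance = 1e-9)
    draws <- draws + 1
  }
  expect_gte(draws, 12)
})

test_that("single-state models are degenerate as expected", {
  tracks <- "track1"
  m <- hmm_model(pi = 1, A = matrix(1, 1, 1),
                 params = tibble::tibble(state = 1, track = tracks,
                                         mu = 3, size = 2),
                 family = "negbinom", track_names = tracks)
  cts <- random_counts(20, 1, 7)
  fb <- forward_backward(m, cts)
  expect_equal(fb$gamma, matrix(1, 20, 1))
  expect_equal(fb$log_likelihood, sum(nb_log_pmf(cts$track1, 3, 2)))
  expect_equal(posterior_decode(fb), rep(1L, 20))
  expect_equal(viterbi(m, cts), rep(1L, 20))
})

test_that("state relabelling permutes posteriors identically", {
  m <- random_small_model(3, 2, "negbinom", 77)
  cts <- random_counts(30, 2, 78)
  fb <- forward_backward(m, cts)
  perm <- c(3, 1, 2) # new index of old state
  m2 <- hmm_model(pi = m$pi[order(perm)],
                  A = m$A[order(perm), order(perm)],
                  params = dplyr::mutate(m$params, state = perm[.data$state]),
                  family = m$family, track_names = m$track_names)
  fb2 <- forward_backward(m2, cts)
  expect_equal(fb2$gamma[, perm], fb$gamma, tolerance = 1e-12)
  expect_equal(fb2$log_likelihood, fb$log_likelihood, tolerance = 1e-12)
})

test_that("viterbi matches the exhaustive argmax and beats posterior paths", {
  for (seed in c(5, 6, 7)) {
    m <- random_small_model(2, 1, "negbinom", seed)
    cts <- random_counts(5, 1, seed + 50)
    vp <- viterbi(m, cts)
    le <- countseg:::.log_emission_matrix(m, as.matrix(cts[, m$track_names]),
                                          setNames(1, m$track_names))
    oracle <- exhaustive_fb(le, m$pi, m$A)
    expect_equal(vp, unname(oracle$best_path))

    score <- function(p) {
      lp <- log(m$pi[p[1]]) + le[1, p[1]]
      for (t in seq_len(length(p) - 1))
        lp <- lp + log(m$A[p[t], p[t + 1]]) + le[t + 1, p[t + 1]]
      lp
    }
    pd <- posterior_decode(forward_backward(m, cts))
    expect_gte(score(vp), score(pd) - 1e-12)
  }
})

test_that("posterior decoding is the row argmax with low-index ties", {
  gamma <- matrix(c(0.2, 0.5, 0.5,
                    0.8, 0.5, 0.1), ncol = 2)
  post <- structure(list(gamma = gamma), class = "countseg_posterior")
  expect_equal(posterior_decode(post), c(2L, 1L, 1L))
})

test_that("posterior and viterbi decodes agree on near-deterministic chains", {
  K <- 2
  A <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, byrow = TRUE)
  params <- tibble::tibble(state = rep(1:2, each = 1), track = "track1",
                           mu = c(0.5, 30), size = 5)
  m <- hmm_model(pi = c(0.5, 0.5), A = A, params = params,
                 family = "negbinom", track_names = "track1")
  g <- binned_genome(data.frame(chrom = "c", length = 4e5), 200)
  sim <- simulate_hmm_counts(m, g, seed = 9)
  cts <- sim$counts[[1]]
  pd <- posterior_decode(forward_backward(m, cts))
  vp <- viterbi(m, cts)
  expect_gte(mean(pd == vp), 0.99)
})

test_that("initialization thresholds, clusters and uniform probabilities", {
  g <- binned_genome(data.frame(chrom = "c", length = 1e6), 200)
  zero <- bin_table(g)[, c("chrom", "start", "end")]
  zero$track1 <- 0L
  expect_error(initialize_hmm(zero, K = 3), "insufficient signal")

  # planted 3-group data: background plus two well-separated NB clusters
  set.seed(44)
  n_bg <- 3500; n_sig <- 750
  counts <- tibble::tibble(
    chrom = "c", start = (seq_len(n_bg + 2 * n_sig) - 1) * 200,
    end = seq_len(n_bg + 2 * n_sig) * 200,
    track1 = c(rnbinom(n_bg, mu = 0.1, size = 5),
               rnbinom(n_sig, mu = 30, size = 5),
               rnbinom(n_sig, mu = 0.1, size = 5)),
    track2 = c(rnbinom(n_bg, mu = 0.1, size = 5),
               rnbinom(n_sig, mu = 0.2, size = 5),
               rnbinom(n_sig, mu = 40, size = 5)))
  shuffle <- sample.int(nrow(counts))
  counts[, c("track1", "track2")] <- counts[shuffle, c("track1", "track2")]
  truth_grp <- rep(1:3, c(n_bg, n_sig, n_sig))[shuffle]
  init <- initialize_hmm(counts, K = 3, family = "negbinom", seed = 2)
  expect_equal(init$pi, rep(1 / 3, 3))
  expect_equal(init$A, matrix(1 / 3, 3, 3))
  # the two signal clusters sit near their planted hot-track means
  td <- tidy(init)
  hot <- c(`2` = 30, `3` = 40)
  for (k in 2:3) {
    tr <- paste0("track", k - 1)
    got <- td$mean[td$track == tr]
    expect_lt(min(abs(got - hot[[as.character(k)]])) / hot[[as.character(k)]],
              0.10)
  }
})

test_that("EM increases the likelihood and recovers planted parameters", {
  g <- binned_genome(data.frame(chrom = "c", length = 6e5), 200)
  for (seed in 1:3) {
    family <- if (seed %% 2) "negbinom" else "poilog"
    m <- example_model(2, 1, family, signal_mean = 15)
    sim <- simulate_hmm_counts(m, g, seed = seed)
    init <- initialize_hmm(sim$counts[[1]], K = 2, family = family, seed = seed)
    fit <- baum_welch(init, sim$counts[[1]], max_iter = 15, tol = 0)
    expect_true(all(diff(fit$trace$log_likelihood) > -1e-6))
  }

  m <- example_model(3, 2, "negbinom")
  sim <- simulate_hmm_counts(m, binned_genome(data.frame(chrom = "c", length = 3e6), 200),
                             seed = 31)
  init <- initialize_hmm(sim$counts[[1]], K = 3, family = "negbinom", seed = 1)
  fit <- baum_welch(init, sim$counts[[1]], max_iter = 50, tol = 1e-6)
  perm <- match_states_by_mean(fit, m)
  td <- tidy(fit)
  tm <- tidy(m)
  for (i in seq_len(nrow(td))) {
    truth <- tm$mean[tm$state == perm[td$state[i]] & tm$track == td$track[i]]
    expect_lt(abs(td$mean[i] - truth) / truth, 0.15)
  }
})

test_that("relabelled initializations yield identically relabelled fits", {
  m0 <- random_small_model(2, 1, "negbinom", 91)
  cts <- random_counts(300, 1, 92, lambda = 4)
  fit1 <- baum_welch(m0, cts, max_iter = 5, tol = 0)
  perm <- c(2, 1)
  m0p <- hmm_model(pi = m0$pi[perm], A = m0$A[perm, perm],
                   params = dplyr::mutate(m0$params, state = ifelse(.data$state == 1, 2, 1)),
                   family = m0$family, track_names = m0$track_names)
  fit2 <- baum_welch(m0p, cts, max_iter = 5, tol = 0)
  expect_equal(fit2$pi[perm], fit1$pi, tolerance = 1e-8)
  expect_equal(fit2$A[perm, perm], fit1$A, tolerance = 1e-8)
  expect_equal(fit2$trace$log_likelihood, fit1$trace$log_likelihood,
               tolerance = 1e-8)
})

test_that("multi-cell-type fits use grouped size factors", {
  g <- binned_genome(data.frame(chrom = "c", length = 6e5), 200)
  m <- example_model(2, 1, "negbinom", signal_mean = 12)
  sim <- simulate_hmm_counts(m, g, cell_types = c(A = 1, B = 3), seed = 17)
  sf <- compute_size_factors(sim$counts)
  # planted 3x depth is recovered by the total-count formula
  fA <- sf$size_factor[sf$cell_type == "A"]
  fB <- sf$size_factor[sf$cell_type == "B"]
  expect_equal(unname(fA / fB), 3, tolerance = 0.05)
  init <- initialize_hmm(sim$counts$A, K = 2, family = "negbinom", seed = 3)
  fit <- baum_welch(init, sim$counts, size_factors = sf, max_iter = 20,
                    tol = 1e-6)
  expect_true(all(diff(fit$trace$log_likelihood) > -1e-6))
})

test_that("model files round-trip bit-for-bit", {
  m <- random_small_model(3, 2, "poilog", 7)
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(m2$pi, m$pi)
  expect_identical(m2$A, m$A)
  expect_identical(as.data.frame(m2$params), as.data.frame(m$params))
  expect_identical(m2$family, m$family)

  writeLines("{\"format\": \"countseg_model\", \"version\": 99}", f)
  expect_error(load_model(f), "version")
  writeLines("not json at all {", f)
  expect_error(load_model(f), "corrupted|not a countseg")
})
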