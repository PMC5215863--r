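# Independent oracles used across the suite. These deliberately avoid the
# package's own recursions: exhaustive path enumeration, closed forms and
# plain summation only.

# exhaustive forward-backward: enumerate all K^T paths
exhaustive_fb <- function(log_emis, pi, A) {
  Tn <- nrow(log_emis); K <- ncol(log_emis)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  logp <- apply(paths, 1, function(p) {
    lp <- log(pi[p[1]]) + log_emis[1, p[1]]
    for (t in seq_len(Tn - 1))
      lp <- lp + log(A[p[t], p[t + 1]]) + log_emis[t + 1, p[t + 1]]
    lp
  })
  ll <- max(logp) + log(sum(exp(logp - max(logp))))
  w <- exp(logp - ll)
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k])
  # best path with lexicographic (lower-state-first) tie-break
  ord <- order(-logp, apply(paths, 1, paste, collapse = ""))
  list(gamma = gamma, log_likelihood = ll, best_path = paths[ord[1], ],
       path_logp = logp, paths = paths)
}

# random small HMM for oracle comparisons
random_small_model <- function(K, D, family, seed) {
  set.seed(seed)
  pi <- as.numeric(rexp(K)); pi <- pi / sum(pi)
  A <- matrix(rexp(K * K), K); A <- A / rowSums(A)
  tracks <- paste0("track", seq_len(D))
  params <- purrr::map_dfr(seq_len(K), function(k)
    purrr::map_dfr(seq_len(D), function(d) {
      if (family == "negbinom") {
        tibble::tibble(state = k, track = tracks[d],
                       mu = runif(1, 0.5, 20), size = runif(1, 0.5, 10))
      } else {
        tibble::tibble(state = k, track = tracks[d],
                       mu_log = runif(1, -1, 3), sigma = runif(1, 0.2, 1.5))
      }
    }))
  hmm_model(pi = pi, A = A, params = params, family = family,
            track_names = tracks, bin_width = 200)
}

random_counts <- function(Tn, D, seed, lambda = 5) {
  set.seed(seed)
  out <- tibble::tibble(chrom = "c", start = (seq_len(Tn) - 1) * 200,
                        end = seq_len(Tn) * 200)
  for (d in seq_len(D)) out[[paste0("track", d)]] <- rpois(Tn, lambda)
  out
}

# upper-tail hypergeometric sum: P(X >= a) for a 2x2 table with margins
hyper_tail <- function(a, n_trait, n_in, N) {
  k_max <- min(n_trait, n_in)
  if (a > k_max) return(0)
  sum(vapply(a:k_max, function(k)
    exp(lchoose(n_in, k) + lchoose(N - n_in, n_trait - k) - lchoose(N, n_trait)),
    0.0))
}

# Benjamini-Yekutieli step-up oracle: adj_i = min_{j >= i} min(1, m*c(m)*p_(j)/j)
by_adjust_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  adj_sorted <- pmin(1, m * cm * p[o] / seq_len(m))
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) for (pos in 0:(n - 1))
    out[[length(out) + 1]] <- append(p, n, after = pos)
  out
}

# match fitted states to true states by emission-mean profiles: returns
# perm with perm[fitted_state] = true_state, minimizing total log-mean
# distance; perm[fitted_path] then relabels a decoded path in true labels
match_states_by_mean <- function(fit, truth) {
  mean_profile <- function(m) {
    td <- generics::tidy(m)[, c("state", "track", "mean")]
    pw <- tidyr::pivot_wider(td, names_from = "track", values_from = "mean")
    log(as.matrix(pw[order(pw$state), -1]) + 1e-6)
  }
  mf <- mean_profile(fit)
  mt <- mean_profile(truth)
  perms <- all_perms(nrow(mf))
  cost <- vapply(perms, function(p)
    sum(abs(mf - mt[p, , drop = FALSE])), 0.0)
  unlist(perms[[which.min(cost)]])
}
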