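#' Poisson signal-enrichment threshold
#'
#' The smallest integer `n > 0` such that `Pr(X > n) < 1e-4` for a Poisson
#' variable X with mean `lambda` — the per-track binarization threshold
#' used to suppress background counts before k-means initialization.
#'
#' @param lambda track mean count per bin (>= 0).
#' @param p_cut upper-tail cutoff (default 1e-4).
#' @return Integer threshold `n_d >= 1`.
#' @examples
#' poisson_threshold(1) # 6
#' @export
poisson_threshold <- function(lambda, p_cut = 1e-4) {
  if (lambda < 0) stop("`lambda` must be >= 0")
  n <- 1L
  while (ppois(n, lambda, lower.tail = FALSE) >= p_cut) n <- n + 1L
  n
}

#' Construct an HMM model object
#'
#' @param pi initial state probabilities (length K, sums to 1).
#' @param A K x K transition matrix (rows sum to 1).
#' @param params K x D list-matrix style tibble of emission parameters:
#'   columns `state`, `track`, then the family's parameter columns
#'   (`mu`/`size` or `mu_log`/`sigma`).
#' @param family emission family, `"negbinom"` or `"poilog"`.
#' @param track_names ordered track names (length D).
#' @param bin_width bin width provenance (bp).
#' @return An object of class `countseg_hmm`.
#' @export
hmm_model <- function(pi, A, params, family = c("negbinom", "poilog"),
                      track_names, bin_width = 200) {
  family <- match.arg(family)
  K <- length(pi)
  if (K < 1) stop("need at least one state")
  if (abs(sum(pi) - 1) > 1e-8) stop("`pi` must sum to 1")
  if (!is.matrix(A) || nrow(A) != K || ncol(A) != K) stop("`A` must be K x K")
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("rows of `A` must sum to 1")
  if (any(pi < 0) || any(A < 0)) stop("probabilities must be non-negative")
  need <- if (family == "negbinom") c("mu", "size") else c("mu_log", "sigma")
  if (!all(c("state", "track", need) %in% names(params)))
    stop("`params` must have columns state, track, ", paste(need, collapse = ", "))
  if (nrow(params) != K * length(track_names))
    stop("`params` must cover the full K x D grid")
  structure(list(K = K, family = family, pi = as.numeric(pi), A = unname(A),
                 params = tibble::as_tibble(params),
                 track_names = track_names, bin_width = bin_width),
            class = "countseg_hmm")
}

#' @export
print.countseg_hmm <- function(x, ...) {
  cat("<countseg_hmm> ", x$K, " states, ", length(x$track_names),
      " track(s), ", x$family, " emissions, ", x$bin_width, " bp bins\n",
      sep = "")
  if (!is.null(x$trace))
    cat("  fitted: ", length(x$trace$log_likelihood), " EM iterations, logLik ",
        format(tail(x$trace$log_likelihood, 1)),
        if (isTRUE(x$trace$converged)) " (converged)\n" else "\n", sep = "")
  invisible(x)
}

# counts tibble -> plain integer matrix in track order
.count_matrix <- function(counts, track_names) {
  miss <- setdiff(track_names, names(counts))
  if (length(miss)) stop("count table lacks track(s): ", paste(miss, collapse = ", "))
  as.matrix(counts[, track_names, drop = FALSE])
}

# per-bin log emission density matrix (T x K), evaluated on unique counts
# per track and mapped back; sf: named emission multipliers per track
.log_emission_matrix <- function(model, cmat, sf = NULL) {
  Tn <- nrow(cmat); K <- model$K
  out <- matrix(0, Tn, K)
  for (d in seq_along(model$track_names)) {
    tr <- model$track_names[d]
    s <- if (is.null(sf)) 1 else unname(sf[tr])
    ux <- sort(unique(cmat[, d]))
    ix <- match(cmat[, d], ux)
    for (k in seq_len(K)) {
      p <- model$params[model$params$state == k & model$params$track == tr, ]
      lp <- if (model$family == "negbinom") {
        nb_log_pmf(ux, p$mu, p$size, s = s)
      } else {
        poilog_log_pmf(ux, p$mu_log, p$sigma, s = s)
      }
      out[, k] <- out[, k] + pmax(lp, .PROB_FLOOR_LOG)[ix]
    }
  }
  out
}

# resolve the per-track emission multipliers for one cell type from a
# size-factor tibble (or NULL -> all 1)
.emission_sf <- function(size_factors, track_names, cell_type) {
  if (is.null(size_factors)) return(setNames(rep(1, length(track_names)), track_names))
  if (!"emission_factor" %in% names(size_factors))
    size_factors <- emission_factors(size_factors)
  sub <- size_factors[size_factors$cell_type == cell_type, ]
  if (!all(track_names %in% sub$track))
    stop("size factors missing for cell type ", cell_type)
  setNames(sub$emission_factor[match(track_names, sub$track)], track_names)
}

#' Forward-backward posterior state probabilities
#'
#' Log-space forward-backward recursion giving the posterior probability
#' of each state at each bin and the total data log-likelihood.
#'
#' @param model a [hmm_model()].
#' @param counts count tibble with the model's track columns.
#' @param size_factors optional size-factor tibble
#'   ([compute_size_factors()]) plus `cell_type` to select from it.
#' @param cell_type cell-type label of `counts` (used with `size_factors`).
#' @return A list of class `countseg_posterior`: `gamma` (bins x K matrix,
#'   rows summing to 1), `xi_sum` (K x K expected transition counts) and
#'   `log_likelihood`.
#' @export
forward_backward <- function(model, counts, size_factors = NULL,
                             cell_type = NA_character_) {
  cmat <- .count_matrix(counts, model$track_names)
  sf <- .emission_sf(size_factors, model$track_names, cell_type)
  le <- .log_emission_matrix(model, cmat, sf)
  res <- fb_core(le, log(pmax(model$pi, 1e-300)), log(pmax(model$A, 1e-300)))
  structure(res, class = "countseg_posterior")
}

#' Per-bin posterior (MAP-marginal) decoding
#'
#' @param posterior a `countseg_posterior` from [forward_backward()].
#' @return Integer state path (1-based); ties go to the lower state index.
#' @export
posterior_decode <- function(posterior) {
  max.col(posterior$gamma, ties.method = "first")
}

#' Viterbi decoding
#'
#' Exact maximum-a-posteriori state path; ties broken toward the lower
#' state index.
#'
#' @inheritParams forward_backward
#' @return Integer state path (1-based).
#' @export
viterbi <- function(model, counts, size_factors = NULL,
                    cell_type = NA_character_) {
  cmat <- .count_matrix(counts, model$track_names)
  sf <- .emission_sf(size_factors, model$track_names, cell_type)
  le <- .log_emission_matrix(model, cmat, sf)
  as.integer(viterbi_core(le, log(pmax(model$pi, 1e-300)),
                          log(pmax(model$A, 1e-300))))
}

# method-of-moments emission parameters for one cluster x track
.moment_params <- function(x, family) {
  m <- max(mean(x), 1e-3)
  v <- if (length(x) > 1) var(x) else m
  if (family == "negbinom") {
    r <- if (is.finite(v) && v > m) m^2 / (v - m) else 1e4
    c(mu = m, size = min(max(r, 1e-2), 1e4))
  } else {
    s2 <- log(1 + max(v - m, 0) / m^2)
    sig <- min(max(sqrt(s2), 0.05), 5)
    c(mu_log = log(m) - s2 / 2, sigma = sig)
  }
}

#' Threshold / k-means initialization of the HMM
#'
#' Reproduces the standard initialization for count HMMs on chromatin
#' data: (1) a per-track Poisson enrichment threshold `n_d` from the track
#' mean ([poisson_threshold()]); (2) counts below their track's threshold
#' are zeroed in a working copy; (3) bins whose working rows are all zero
#' form a "background" cluster; (4) k-means with K-1 clusters on
#' `log(count + 1)` of the remaining bins (10 restarts, seeded); (5)
#' method-of-moments emission parameters per cluster and track from the
#' raw counts; (6) uniform initial and transition probabilities.
#'
#' @param counts a count tibble or list of count tibbles (cell types),
#'   pooled for clustering.
#' @param K number of states (>= 2); state 1 is the background cluster.
#' @param family emission family.
#' @param bin_width recorded in the model.
#' @param seed RNG seed for k-means restarts.
#' @return An unfitted [hmm_model()].
#' @export
initialize_hmm <- function(counts, K, family = c("negbinom", "poilog"),
                           bin_width = 200, seed = 1) {
  family <- match.arg(family)
  if (K < 2) stop("`K` must be >= 2")
  if (is.data.frame(counts)) counts <- list(counts)
  track_names <- setdiff(names(counts[[1]]), c("chrom", "start", "end"))
  cmat <- do.call(rbind, lapply(counts, .count_matrix, track_names))
  if (!nrow(cmat)) stop("empty count matrix")

  nd <- vapply(seq_along(track_names), function(d)
    poisson_threshold(mean(cmat[, d])), 1L)
  work <- cmat
  for (d in seq_along(track_names)) work[work[, d] < nd[d], d] <- 0L
  bg <- rowSums(work) == 0
  fg <- which(!bg)
  if (length(unique(asplit(work[fg, , drop = FALSE], 1))) < K - 1 ||
      length(fg) < K - 1)
    stop("insufficient signal for ", K, " states: fewer than K-1 distinct ",
         "non-background bins")

  lx <- log(work[fg, , drop = FALSE] + 1)
  set.seed(seed)
  km <- kmeans(lx, centers = K - 1, nstart = 10, iter.max = 50)
  cluster <- integer(nrow(cmat))
  cluster[bg] <- 1L
  cluster[fg] <- km$cluster + 1L

  params <- purrr::map_dfr(seq_len(K), function(k) {
    purrr::map_dfr(seq_along(track_names), function(d) {
      x <- cmat[cluster == k, d]
      if (!length(x)) x <- 0L
      p <- .moment_params(x, family)
      tibble::tibble(state = k, track = track_names[d], !!!as.list(p))
    })
  })
  hmm_model(pi = rep(1 / K, K), A = matrix(1 / K, K, K), params = params,
            family = family, track_names = track_names, bin_width = bin_width)
}

#' Fit the HMM by Baum-Welch (EM) with count-grouping
#'
#' E-step: [forward_backward()] per sequence (cell type). M-step: initial
#' and transition probabilities from pooled expected counts; each state x
#' track emission refitted by [fit_emission()] on posterior-weighted counts
#' pooled across sequences with [group_counts()] (grouping keys include the
#' cell type whenever emission multipliers differ across cell types). The
#' total log-likelihood is non-decreasing across iterations; fitting stops
#' when the relative improvement drops below `tol` or after `max_iter`
#' iterations.
#'
#' @param model initial [hmm_model()] (see [initialize_hmm()]).
#' @param counts a count tibble, or a named list of count tibbles, one per
#'   cell type.
#' @param size_factors optional size-factor tibble covering every
#'   (track, cell type) pair.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood improvement below which EM stops
#'   (default 1e-6).
#' @return The fitted `countseg_hmm`, with a `trace` element (per-iteration
#'   `log_likelihood`, `iterations`, `converged`).
#' @export
baum_welch <- function(model, counts, size_factors = NULL,
                       max_iter = 500, tol = 1e-6) {
  if (is.data.frame(counts)) counts <- list(`1` = counts)
  if (is.null(names(counts))) names(counts) <- as.character(seq_along(counts))
  cmats <- lapply(counts, .count_matrix, model$track_names)
  sfs <- lapply(names(counts), function(l)
    .emission_sf(size_factors, model$track_names, l))
  names(sfs) <- names(counts)
  K <- model$K
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    post <- lapply(names(counts), function(l) {
      le <- .log_emission_matrix(model, cmats[[l]], sfs[[l]])
      fb_core(le, log(pmax(model$pi, 1e-300)), log(pmax(model$A, 1e-300)))
    })
    ll <- sum(vapply(post, `[[`, 0.0, "log_likelihood"))
    if (!is.finite(ll)) stop("non-finite likelihood at EM iteration ", iter)
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - prev_ll) < tol * abs(prev_ll)) {
      converged <- TRUE
      break
    }
    prev_ll <- ll

    pi_new <- rowMeans(vapply(post, function(p) p$gamma[1, ], numeric(K)))
    pi_new <- pi_new / sum(pi_new)
    xi <- Reduce(`+`, lapply(post, `[[`, "xi_sum"))
    A_new <- xi / pmax(rowSums(xi), 1e-300)

    params_new <- purrr::map_dfr(seq_len(K), function(k) {
      purrr::map_dfr(seq_along(model$track_names), function(d) {
        tr <- model$track_names[d]
        col <- unlist(lapply(names(counts), function(l) cmats[[l]][, d]))
        wts <- unlist(lapply(post, function(p) p$gamma[, k]))
        cl <- rep(names(counts), vapply(cmats, nrow, 1L))
        sfd <- vapply(names(counts), function(l) unname(sfs[[l]][tr]), 0.0)
        grouped <- if (any(sfd != 1)) {
          group_counts(col, wts, cell_type = cl)
        } else group_counts(col, wts)
        p0 <- model$params[model$params$state == k & model$params$track == tr, ]
        init <- if (model$family == "negbinom") {
          c(mu = p0$mu, size = p0$size)
        } else c(mu_log = p0$mu_log, sigma = p0$sigma)
        p <- fit_emission(grouped, model$family, init = init,
                          size_factors = sfd)
        tibble::tibble(state = k, track = tr, !!!as.list(unclass(p)[seq_along(init)]))
      })
    })
    model <- hmm_model(pi_new, A_new, params_new, model$family,
                       model$track_names, model$bin_width)
  }
  model$trace <- list(log_likelihood = trace, iterations = length(trace),
                      converged = converged)
  model
}

#' Serialize an HMM model to a plain-text JSON file
#'
#' Numeric values are written as decimal strings at full double precision,
#' so [load_model()] reproduces the model bit-for-bit.
#'
#' @param model a `countseg_hmm`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  obj <- list(
    format = "countseg_model", version = 1L,
    K = model$K, family = model$family,
    track_names = model$track_names, bin_width = model$bin_width,
    pi = num(model$pi),
    A = lapply(seq_len(model$K), function(i) num(model$A[i, ])),
    params = lapply(seq_len(nrow(model$params)), function(i) {
      r <- model$params[i, ]
      c(list(state = r$state, track = r$track),
        lapply(r[setdiff(names(r), c("state", "track"))], num))
    })
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' Load an HMM model written by [save_model()]
#'
#' @param path path to the model JSON.
#' @return A `countseg_hmm`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("corrupted model file: ", conditionMessage(e)))
  if (!identical(obj$format, "countseg_model"))
    stop("not a countseg model file")
  if (!identical(as.integer(obj$version), 1L))
    stop("unsupported model file version: ", obj$version)
  A <- if (is.matrix(obj$A)) {
    matrix(as.numeric(obj$A), nrow = nrow(obj$A))
  } else do.call(rbind, lapply(obj$A, as.numeric))
  params <- tibble::as_tibble(obj$params)
  params$state <- as.integer(params$state)
  for (nm in setdiff(names(params), c("state", "track")))
    params[[nm]] <- as.numeric(params[[nm]])
  hmm_model(pi = as.numeric(obj$pi), A = A, params = params,
            family = obj$family, track_names = obj$track_names,
            bin_width = obj$bin_width)
}
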