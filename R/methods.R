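#' Tidy the emission parameters of a fitted HMM
#'
#' @param x a `countseg_hmm`.
#' @param ... unused.
#' @return One row per (state, track): the family's parameters plus the
#'   implied emission `mean` and `variance` at size factor 1.
#' @exportS3Method generics::tidy
tidy.countseg_hmm <- function(x, ...) {
  p <- x$params
  if (x$family == "negbinom") {
    p$mean <- p$mu
    p$variance <- p$mu + p$mu^2 / p$size
  } else {
    p$mean <- exp(p$mu_log + p$sigma^2 / 2)
    p$variance <- p$mean + p$mean^2 * (exp(p$sigma^2) - 1)
  }
  p
}

#' One-row summary of a fitted HMM
#'
#' @param x a `countseg_hmm`.
#' @param ... unused.
#' @return A one-row tibble: states, tracks, family, final log-likelihood,
#'   EM iterations, convergence flag.
#' @exportS3Method generics::glance
glance.countseg_hmm <- function(x, ...) {
  tibble::tibble(
    n_states = x$K,
    n_tracks = length(x$track_names),
    family = x$family,
    log_likelihood = if (!is.null(x$trace)) tail(x$trace$log_likelihood, 1) else NA_real_,
    iterations = if (!is.null(x$trace)) x$trace$iterations else NA_integer_,
    converged = if (!is.null(x$trace)) x$trace$converged else NA)
}

#' @exportS3Method ggplot2::autoplot
autoplot.countseg_hmm <- function(object, ...) {
  if (is.null(object$trace)) {
    td <- tidy(object)
    return(
      ggplot2::ggplot(td, ggplot2::aes(x = factor(.data$state), y = .data$track,
                                       fill = log10(.data$mean + 1e-3))) +
        ggplot2::geom_tile() +
        ggplot2::scale_fill_viridis_c(name = "log10 mean") +
        ggplot2::labs(x = "state", y = "track"))
  }
  df <- tibble::tibble(iteration = seq_along(object$trace$log_likelihood),
                       log_likelihood = object$trace$log_likelihood)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$log_likelihood)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "EM iteration", y = "log-likelihood")
}
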