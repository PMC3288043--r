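#' Fit cell-cycle fractions to a DNA-content histogram
#'
#' Maximum-likelihood deconvolution of a propidium-iodide histogram into
#' three components: a Gaussian G1 peak at `mu`, a Gaussian G2/M peak
#' constrained to `2 mu` (sd inflated by a broadening factor), and an
#' S-phase plateau modeled as a uniform distribution between the two peak
#' means convolved with the G1 Gaussian. Bin counts are treated as a
#' multinomial sample over the observed bins; the likelihood is maximized
#' by Nelder-Mead over `(log mu, log sigma, log broadening,
#' softmax fractions)` from two starts (the tallest bin taken as the G1 or
#' the G2/M peak), keeping the better optimum.
#'
#' @param hist Tibble with columns `dna_content` (bin centers, equally
#'   spaced) and `count` (nonnegative integers), e.g. from
#'   [simulate_cell_cycle()].
#' @return An object of class `cellcycle_fit` with elements `fractions`
#'   (named `g1`, `s`, `g2m`, summing to 1), `g1_mean`, `sigma`,
#'   `g2_broadening`, `loglik`, `residual_rmse`, `n_events`, `convergence`,
#'   and the input `data`.
#' @examples
#' h <- simulate_cell_cycle(assay_sim_config(rng_seed = 3))
#' fit <- fit_cell_cycle(h)
#' fit$fractions
#' @export
fit_cell_cycle <- function(hist) {
  stopifnot(all(c("dna_content", "count") %in% names(hist)))
  x <- hist$dna_content
  counts <- hist$count
  n <- sum(counts)
  if (length(x) < 2 || sum(counts > 0) < 2) {
    abort("Histogram must span at least two bins with events.",
          class = "mirscreen_fit_error")
  }
  if (n < 100) {
    abort("Need at least 100 events for a stable fit.",
          class = "mirscreen_fit_error")
  }

  peak <- x[which.max(counts)]
  fits <- lapply(c(peak, peak / 2), function(mu0) {
    theta0 <- c(log(mu0), log(0.04 * mu0), log(1.1), log(0.5 / 0.2), log(0.3 / 0.2))
    opt <- optim(theta0, cellcycle_negll, x = x, counts = counts,
                 method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-10))
    opt
  })
  opt <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]

  pars <- cellcycle_unpack(opt$par)
  p <- cellcycle_bin_probs(x, pars)
  fitted_counts <- n * p
  structure(
    list(
      fractions = pars$fractions,
      g1_mean = pars$mu, sigma = pars$sigma, g2_broadening = pars$beta,
      loglik = -opt$value,
      residual_rmse = sqrt(mean((counts - fitted_counts)^2)) / n,
      n_events = n, convergence = opt$convergence,
      data = tibble(dna_content = x, count = counts, fitted = fitted_counts)
    ),
    class = "cellcycle_fit"
  )
}

cellcycle_unpack <- function(theta) {
  w <- exp(c(theta[4], theta[5], 0))
  list(
    mu = exp(theta[1]), sigma = exp(theta[2]), beta = exp(theta[3]),
    fractions = setNames(w / sum(w), c("g1", "s", "g2m"))
  )
}

# per-bin densities of the three components at the bin centers
cellcycle_component_density <- function(x, pars) {
  s_dens <- (pnorm(x, pars$mu, pars$sigma) - pnorm(x, 2 * pars$mu, pars$sigma)) /
    pars$mu
  cbind(
    g1 = stats::dnorm(x, pars$mu, pars$sigma),
    s = pmax(s_dens, 0),
    g2m = stats::dnorm(x, 2 * pars$mu, pars$sigma * pars$beta)
  )
}

cellcycle_bin_probs <- function(x, pars) {
  dens <- cellcycle_component_density(x, pars) %*% pars$fractions
  p <- dens / sum(dens)
  pmax(as.numeric(p), 1e-12)
}

cellcycle_negll <- function(theta, x, counts) {
  if (any(!is.finite(theta)) || theta[2] - theta[1] > 0) return(1e10)
  pars <- cellcycle_unpack(theta)
  -sum(counts * log(cellcycle_bin_probs(x, pars)))
}

#' @export
print.cellcycle_fit <- function(x, ...) {
  cat("<cellcycle_fit> ", x$n_events, " events\n", sep = "")
  cat(sprintf("  fractions: G1 %.3f, S %.3f, G2/M %.3f\n",
              x$fractions["g1"], x$fractions["s"], x$fractions["g2m"]))
  cat(sprintf("  G1 mean %.1f, sd %.2f, G2/M broadening %.2f\n",
              x$g1_mean, x$sigma, x$g2_broadening))
  invisible(x)
}
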