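#' Fit the methyltransferase HMM to double-stranded methylation patterns
#'
#' The model: at each CpG site of each molecule, a hidden triple of
#' association indicators — DNMT1 on the daughter strand, the DNMT3s on
#' the parent and on the daughter strand — evolves along the DNA as three
#' independent two-state Markov chains (per-bp reassociation probability r,
#' dissociation probability d, transition over an L-bp gap given by the
#' per-bp matrix to the L-th power). Associated enzymes methylate the
#' strands according to maintenance/de novo activity probabilities, and the
#' observation passes through a per-strand bisulfite error channel. Which
#' strand is the parent is unknown and marginalized with prior 1/2.
#' Inference is Bayesian: component-wise random-walk Metropolis on the
#' logit scale, forward-algorithm likelihood, posterior summaries as
#' medians with 80% credible intervals.
#'
#' @param patterns A [methyl_patterns()] container (see [read_patterns()]).
#' @param locus A [cpg_locus()].
#' @param variant Model variant, see [model_variants]; default
#'   `"in_vivo_default"`.
#' @param priors A [prior_spec()]; unlisted free parameters get
#'   uniform(0, 1).
#' @param control An [mcmc_control()].
#' @param errors_off Force both bisulfite-error probabilities to 0
#'   (error-free sensitivity mode).
#' @param fix_site_densities Plug in per-site empirical methylation
#'   frequencies instead of sampling the site densities.
#' @param densities Optional fixed density vector used when
#'   `fix_site_densities = TRUE`.
#' @param e_fail Fixed failure-of-conversion probability (default 0.003).
#' @param seed Integer seed for the sampler.
#' @return An object of class `"methylhmm"` with components `samples`
#'   (a `"methylhmm_samples"`), `locus`, `data_summary`, `call`. Methods:
#'   [print()], [summary()], [coef()], [plot()], [simulate()], [logLik()].
#' @examples
#' \donttest{
#' loc <- random_locus(8, start = 100)
#' sim <- simulate_patterns(loc, fmr1_regime_params(8), 40, seed = 1)
#' fit <- methylhmm(sim$patterns, loc, fix_site_densities = TRUE,
#'                  control = mcmc_control(600, 200, 2, n_chains = 1),
#'                  seed = 1)
#' summary(fit)
#' }
#' @export
methylhmm <- function(patterns, locus, variant = "in_vivo_default",
                      priors = prior_spec(), control = mcmc_control(),
                      errors_off = FALSE, fix_site_densities = FALSE,
                      densities = NULL, e_fail = 0.003, seed = 1L) {
  samples <- run_mcmc(patterns, locus, variant = variant, priors = priors,
                      control = control, errors_off = errors_off,
                      fix_site_densities = fix_site_densities,
                      densities = densities, e_fail = e_fail, seed = seed)
  structure(list(samples = samples, locus = locus,
                 data_summary = summarize_patterns(patterns, locus),
                 call = match.call()),
            class = "methylhmm")
}

#' @export
print.methylhmm <- function(x, ...) {
  s <- x$samples
  cat("Methyltransferase HMM fit (variant:", s$variant, ")\n")
  cat(sprintf("  data: %d molecules, %d CpG sites at locus '%s'\n",
              x$data_summary$n_patterns, x$data_summary$n_sites,
              x$locus$name))
  cat(sprintf("  sampler: %d chains x %d iterations, %d retained draws\n",
              s$control$n_chains, s$control$n_iter, nrow(s$draws)))
  med <- apply(s$draws, 2, stats::median)
  show <- intersect(c("r1", "d1", "mu1", "delta1", "e_inap"), names(med))
  if (length(show)) {
    cat("  posterior medians:",
        paste(sprintf("%s = %.3g", show, med[show]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.methylhmm <- function(object, ...) {
  apply(object$samples$draws, 2, stats::median)
}

#' @export
logLik.methylhmm <- function(object, ...) {
  ll <- max(object$samples$loglik)
  attr(ll, "df") <- ncol(object$samples$draws)
  class(ll) <- "logLik"
  ll
}

#' Summarize a fitted methyltransferase HMM
#'
#' Posterior medians and 80% credible intervals (10- and 90-percentiles)
#' for the free parameters and the derived quantities (association tract
#' lengths in bp, average association levels, hemi-preference ratio with a
#' one-sided 80% lower bound), plus convergence diagnostics.
#'
#' @param object A [methylhmm()] fit.
#' @param ... Unused.
#' @return Object of class `"summary.methylhmm"`.
#' @export
summary.methylhmm <- function(object, ...) {
  structure(list(
    table = summarize_posterior(object$samples),
    diagnostics = convergence_diagnostics(object$samples),
    variant = object$samples$variant,
    accept = object$samples$accept,
    data_summary = object$data_summary),
    class = "summary.methylhmm")
}

#' @export
print.summary.methylhmm <- function(x, ...) {
  cat("Posterior summary (median and 80% CI; variant:", x$variant, ")\n")
  tb <- x$table
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.4g", v),
                            ifelse(is.infinite(v), "Inf", ""))
  for (i in seq_len(nrow(tb))) {
    line <- sprintf("  %-26s %s (%s-%s)", tb$parameter[i],
                    fmt(tb$median[i]), fmt(tb$q10[i]), fmt(tb$q90[i]))
    if (!is.na(tb$lower80[i]))
      line <- sprintf("%s [80%% lower bound %s]", line, fmt(tb$lower80[i]))
    cat(line, "\n")
  }
  bad <- x$diagnostics$parameter[x$diagnostics$flag]
  if (length(bad))
    cat("convergence flags:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior densities of the free parameters
#'
#' @param x A [methylhmm()] fit.
#' @param which Character vector of parameter names (default: all non-site
#'   free parameters).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.methylhmm <- function(x, which = NULL, ...) {
  d <- x$samples$draws
  if (is.null(which))
    which <- setdiff(colnames(d), grep("^m[0-9]+$", colnames(d), value = TRUE))
  which <- intersect(which, colnames(d))
  if (!length(which)) stop("no parameters to plot")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in which) {
    dens <- stats::density(d[, nm], from = 0, to = 1)
    graphics::plot(dens, main = nm, xlab = nm, ...)
    graphics::abline(h = 1, lty = 3)  # uniform(0,1) prior density
  }
  invisible(x)
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws parameter vectors from the retained posterior draws and simulates
#' new hairpin-bisulfite datasets of the same size as the fitted data.
#'
#' @param object A [methylhmm()] fit.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param n_patterns Molecules per dataset (default: the fitted dataset's
#'   molecule count).
#' @param ... Unused.
#' @return List of `"methyl_sim"` objects (length `nsim`).
#' @export
simulate.methylhmm <- function(object, nsim = 1, seed = NULL,
                               n_patterns = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$samples
  if (is.null(n_patterns)) n_patterns <- object$data_summary$n_patterns
  idx <- sample(nrow(s$draws), nsim, replace = TRUE)
  lapply(idx, function(i) {
    x <- s$draws[i, ]
    theta <- s$fixed$theta
    dens <- s$fixed$densities
    is_m <- grepl("^m[0-9]+$", names(x))
    theta[names(x)[!is_m]] <- x[!is_m]
    if (any(is_m))
      dens[as.integer(sub("^m", "", names(x)[is_m]))] <- x[is_m]
    params <- theta_to_params(theta, dens, variant = s$variant,
                              errors_off = s$errors_off)
    simulate_patterns(object$locus, params, n_patterns)
  })
}

#' Posterior-median parameter set of a fit
#'
#' Collapses the posterior to its component-wise median and returns a full
#' [model_params()] object, convenient for decoding
#' ([kbest_explanations()], [orientation_posterior()]) at fixed parameters.
#'
#' @param object A [methylhmm()] fit.
#' @return A [model_params()].
#' @export
median_params <- function(object) {
  stopifnot(inherits(object, "methylhmm"))
  s <- object$samples
  med <- apply(s$draws, 2, stats::median)
  theta <- s$fixed$theta
  dens <- s$fixed$densities
  is_m <- grepl("^m[0-9]+$", names(med))
  theta[names(med)[!is_m]] <- med[!is_m]
  if (any(is_m))
    dens[as.integer(sub("^m", "", names(med)[is_m]))] <- med[is_m]
  theta_to_params(theta, dens, variant = s$variant,
                  errors_off = s$errors_off)
}
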