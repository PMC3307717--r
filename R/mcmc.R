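#' Prior specification for the free probabilities
#'
#' Every free parameter of the model is a probability; the default prior is
#' uniform(0, 1). Individual parameters can be given Beta priors or fixed.
#'
#' @param ... Named entries, one per parameter (names as in the sampler:
#'   `r1`, `d1`, `r3p`, `d3p`, `r3d`, `d3d`, `mu1`, `delta1`, `mu3`,
#'   `delta3`, `e_inap`, `m1` ... `mS`). Each entry is created with
#'   [prior_uniform()], [prior_beta()] or [prior_fixed()].
#' @return Named list of priors, class `"prior_spec"`.
#' @examples
#' prior_spec(d1 = prior_beta(1, 9), e_inap = prior_fixed(0.02))
#' @export
prior_spec <- function(...) {
  spec <- list(...)
  if (length(spec) && (is.null(names(spec)) || any(names(spec) == "")))
    stop("all prior entries must be named")
  ok <- vapply(spec, function(p)
    is.list(p) && p$type %in% c("uniform", "beta", "fixed"), logical(1))
  if (any(!ok)) stop("priors must be prior_uniform(), prior_beta() or prior_fixed()")
  structure(spec, class = "prior_spec")
}

#' @rdname prior_spec
#' @export
prior_uniform <- function() list(type = "uniform")

#' @rdname prior_spec
#' @param alpha,beta Beta shape parameters (> 0).
#' @export
prior_beta <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  list(type = "beta", alpha = alpha, beta = beta)
}

#' @rdname prior_spec
#' @param value Fixed value in `[0, 1]`.
#' @export
prior_fixed <- function(value) {
  stopifnot(value >= 0, value <= 1)
  list(type = "fixed", value = value)
}

#' MCMC sampler settings
#'
#' @param n_iter Iterations per chain (after which sampling stops).
#' @param burnin Discarded initial iterations (< `n_iter`). Proposal scales
#'   adapt only during burn-in.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of independent chains.
#' @param proposal_scale Initial random-walk step on the logit scale.
#' @param adapt_interval Iterations between proposal-scale adaptations
#'   during burn-in.
#' @param progress Print progress every `progress` iterations (0 = silent).
#' @return List of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_iter = 6000L, burnin = 2000L, thin = 4L,
                         n_chains = 2L, proposal_scale = 0.8,
                         adapt_interval = 50L, progress = 0L) {
  stopifnot(n_iter > burnin, burnin >= 0, thin >= 1, n_chains >= 1,
            proposal_scale > 0)
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 proposal_scale = proposal_scale,
                 adapt_interval = as.integer(adapt_interval),
                 progress = as.integer(progress)),
            class = "mcmc_control")
}

# free parameter names for a variant
free_param_names <- function(variant, errors_off, fix_site_densities, S) {
  base <- switch(variant,
    in_vivo_default = c("r1", "d1", "r3p", "d3p", "r3d", "d3d",
                        "mu1", "delta1"),
    dnmt3_hemi = c("r1", "d1", "r3p", "d3p", "r3d", "d3d",
                   "mu3", "delta3"),
    in_vitro_dnmt1 = c("r1", "d1", "mu1", "delta1"),
    stop("unknown variant ", variant))
  if (!errors_off) base <- c(base, "e_inap")
  if (!fix_site_densities) base <- c(base, sprintf("m%d", seq_len(S)))
  base
}

# assemble the full theta vector + densities from free values and fixed parts
.make_eval <- function(free_names, fixed_theta, fixed_densities, S) {
  is_m <- grepl("^m[0-9]+$", free_names)
  m_idx <- as.integer(sub("^m", "", free_names[is_m]))
  th_names <- free_names[!is_m]
  function(x) {
    theta <- fixed_theta
    theta[th_names] <- x[!is_m]
    dens <- fixed_densities
    if (any(is_m)) dens[m_idx] <- x[is_m]
    list(theta = theta, densities = dens)
  }
}

.log_prior <- function(x, priors_list) {
  lp <- 0
  for (i in seq_along(x)) {
    p <- priors_list[[i]]
    if (p$type == "beta")
      lp <- lp + stats::dbeta(x[i], p$alpha, p$beta, log = TRUE)
    # uniform contributes 0
  }
  lp
}

#' Run the MCMC sampler
#'
#' Component-wise random-walk Metropolis on logit-transformed free
#' probabilities. The target is the multiplicity-weighted dataset
#' log-likelihood ([dataset_loglik()]) plus the log prior; the logit
#' Jacobian `log p(1-p)` keeps the target correct on the transformed
#' scale. Proposal scales adapt toward a ~40% acceptance rate during
#' burn-in only. Each chain is seeded reproducibly from `seed`.
#'
#' Most users should call [methylhmm()], which wraps this and packages the
#' result.
#'
#' @param patterns A [methyl_patterns()] container.
#' @param locus A [cpg_locus()].
#' @param variant Model variant; see [model_variants].
#' @param priors A [prior_spec()]; unlisted parameters get uniform(0,1).
#' @param control An [mcmc_control()].
#' @param errors_off Force both bisulfite-error probabilities to 0.
#' @param fix_site_densities Plug in the empirical per-site methylation
#'   frequency instead of sampling the site densities.
#' @param densities Optional fixed density vector (overrides the empirical
#'   plug-in when `fix_site_densities` is `TRUE`).
#' @param e_fail Fixed failure-of-conversion probability (default 0.003).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param prior_only If `TRUE` the likelihood is switched off and the
#'   sampler targets the prior alone (sampler validation).
#' @return List of class `"methylhmm_samples"`: `draws` (retained draws x
#'   free parameters), `loglik`, `chain`, `accept` (per-parameter rates),
#'   `free_names`, `fixed` (fixed theta entries and densities), plus the
#'   configuration.
#' @export
run_mcmc <- function(patterns, locus, variant = "in_vivo_default",
                     priors = prior_spec(), control = mcmc_control(),
                     errors_off = FALSE, fix_site_densities = FALSE,
                     densities = NULL, e_fail = 0.003, seed = 1L,
                     prior_only = FALSE) {
  if (!length(patterns$id)) stop("empty dataset")
  S <- n_sites(locus)
  if (ncol(patterns$a) != S)
    stop("pattern width does not match the locus CpG count")
  variant <- match.arg(variant, .variants)

  free <- free_param_names(variant, errors_off, fix_site_densities, S)
  # fixed parts of the theta vector implied by the variant
  fixed_theta <- c(r1 = 0, d1 = 1, r3p = 0, d3p = 1, r3d = 0, d3d = 1,
                   mu1 = 1, delta1 = 0, mu3 = 1, delta3 = 1,
                   e_fail = if (errors_off) 0 else e_fail, e_inap = 0)
  if (variant == "dnmt3_hemi") { fixed_theta["mu1"] <- 1; fixed_theta["delta1"] <- 0 }

  fixed_densities <- if (fix_site_densities) {
    if (!is.null(densities)) {
      stopifnot(length(densities) == S)
      as.numeric(densities)
    } else {
      # plug-in: per-site methylation frequency over both strands
      both <- rbind(patterns$a, patterns$b)
      w <- rep(patterns$mult, 2)
      vapply(seq_len(S), function(i) {
        x <- both[, i]
        ok <- !is.na(x)
        if (!any(ok)) return(0.5)
        stats::weighted.mean(x[ok], w[ok])
      }, numeric(1))
    }
  } else rep(0.5, S)

  # priors: default uniform; fixed priors remove a parameter from sampling
  priors <- as.list(priors)
  unknown <- setdiff(names(priors), free)
  if (length(unknown))
    stop("prior given for non-free parameter(s): ",
         paste(unknown, collapse = ", "))
  fixed_by_prior <- names(priors)[vapply(priors, function(p)
    p$type == "fixed", logical(1))]
  for (nm in fixed_by_prior) {
    v <- priors[[nm]]$value
    if (grepl("^m[0-9]+$", nm))
      fixed_densities[as.integer(sub("^m", "", nm))] <- v
    else fixed_theta[nm] <- v
  }
  free <- setdiff(free, fixed_by_prior)
  if (!length(free)) stop("no free parameters left to sample")
  plist <- lapply(free, function(nm)
    if (!is.null(priors[[nm]])) priors[[nm]] else prior_uniform())

  eval_parts <- .make_eval(free, fixed_theta, fixed_densities, S)
  loglik_fun <- if (prior_only) function(x) 0 else function(x) {
    parts <- eval_parts(x)
    dataset_loglik_cpp(patterns$a, patterns$b, patterns$mult,
                       site_distances(locus), parts$theta, parts$densities)
  }
  # target on the logit scale: loglik + log prior + Jacobian
  log_target <- function(x)
    loglik_fun(x) + .log_prior(x, plist) + sum(log(x) + log1p(-x))

  P <- length(free)
  n_keep <- (control$n_iter - control$burnin) %/% control$thin
  draws <- matrix(NA_real_, n_keep * control$n_chains, P,
                  dimnames = list(NULL, free))
  llout <- numeric(n_keep * control$n_chains)
  chain_id <- integer(n_keep * control$n_chains)
  acc_total <- matrix(0, control$n_chains, P)

  # data-driven starting values: empirical per-site methylation frequency
  # for the densities, moderate values for activities and chain parameters;
  # each chain jitters them on the logit scale
  emp_freq <- {
    both <- rbind(patterns$a, patterns$b)
    w <- rep(patterns$mult, 2)
    vapply(seq_len(S), function(i) {
      xx <- both[, i]; ok <- !is.na(xx)
      if (!any(ok)) 0.5 else stats::weighted.mean(xx[ok], w[ok])
    }, numeric(1))
  }
  start_default <- function(nm) {
    if (grepl("^m[0-9]+$", nm))
      return(min(max(emp_freq[as.integer(sub("^m", "", nm))], 0.05), 0.95))
    switch(nm, r1 = 0.1, d1 = 0.1, r3p = 0.1, d3p = 0.5, r3d = 0.1,
           d3d = 0.5, mu1 = 0.9, delta1 = 0.05, mu3 = 0.9, delta3 = 0.5,
           e_inap = 0.01, 0.5)
  }

  row <- 0L
  for (ch in seq_len(control$n_chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    # jittered data-driven start; fall back to prior draws if impossible
    x <- vapply(seq_along(free), function(i) {
      p <- plist[[i]]
      if (p$type == "beta") return(stats::rbeta(1, p$alpha, p$beta))
      stats::plogis(stats::qlogis(start_default(free[i])) +
                      0.3 * stats::rnorm(1))
    }, numeric(1))
    lt <- log_target(x)
    for (try in 1:50) {
      if (is.finite(lt)) break
      x <- vapply(plist, function(p)
        if (p$type == "beta") stats::rbeta(1, p$alpha, p$beta)
        else stats::runif(1, 0.05, 0.95), numeric(1))
      lt <- log_target(x)
    }
    if (!is.finite(lt))
      stop("could not find a starting point with finite posterior density")
    lx <- stats::qlogis(x)
    scales <- rep(control$proposal_scale, P)
    acc_win <- rep(0, P); acc_run <- rep(0, P)
    # running moments of the logit draws feed an adaptive joint proposal
    # (helps traverse correlated ridges such as de-novo rate vs error rate
    # vs site density); covariance freezes at the end of burn-in
    run_n <- 0; run_mean <- rep(0, P)
    run_cov <- diag(control$proposal_scale^2, P)
    chol_J <- NULL
    for (it in seq_len(control$n_iter)) {
      for (p in seq_len(P)) {
        lxp <- lx
        lxp[p] <- lx[p] + scales[p] * stats::rnorm(1)
        xp <- stats::plogis(lxp)
        ltp <- log_target(xp)
        if (is.finite(ltp) && log(stats::runif(1)) < ltp - lt) {
          lx <- lxp; x <- xp; lt <- ltp
          acc_win[p] <- acc_win[p] + 1; acc_run[p] <- acc_run[p] + 1
        }
      }
      # joint adaptive-metropolis step
      run_n <- run_n + 1
      dlt <- lx - run_mean
      run_mean <- run_mean + dlt / run_n
      if (it <= control$burnin)
        run_cov <- run_cov * (run_n - 1) / run_n +
          tcrossprod(dlt) * (run_n - 1) / run_n^2
      if (it == control$burnin || (is.null(chol_J) && it >= 200)) {
        cj <- try(chol(2.38^2 / P * run_cov + diag(1e-8, P)), silent = TRUE)
        if (!inherits(cj, "try-error")) chol_J <- cj
      }
      if (!is.null(chol_J)) {
        lxp <- lx + as.vector(stats::rnorm(P) %*% chol_J)
        xp <- stats::plogis(lxp)
        ltp <- log_target(xp)
        if (is.finite(ltp) && log(stats::runif(1)) < ltp - lt) {
          lx <- lxp; x <- xp; lt <- ltp
        }
      }
      if (it <= control$burnin && it %% control$adapt_interval == 0) {
        rate <- acc_win / control$adapt_interval
        scales <- pmin(pmax(scales * exp(rate - 0.40), 1e-3), 20)
        acc_win[] <- 0
      }
      if (it > control$burnin &&
          (it - control$burnin) %% control$thin == 0) {
        row <- row + 1L
        draws[row, ] <- x
        llout[row] <- if (prior_only) NA_real_ else loglik_fun(x)
        chain_id[row] <- ch
      }
      if (control$progress > 0 && it %% control$progress == 0)
        message(sprintf("chain %d iteration %d / %d", ch, it, control$n_iter))
    }
    acc_total[ch, ] <- acc_run / control$n_iter
  }

  structure(list(
    draws = draws, loglik = llout, chain = chain_id,
    accept = colMeans(acc_total), free_names = free,
    fixed = list(theta = fixed_theta, densities = fixed_densities,
                 fix_site_densities = fix_site_densities),
    variant = variant, errors_off = errors_off,
    priors = priors, control = control, seed = as.integer(seed),
    prior_only = prior_only),
    class = "methylhmm_samples")
}

#' @export
print.methylhmm_samples <- function(x, ...) {
  cat(sprintf("posterior samples: %d draws x %d free parameters (%d chains)\n",
              nrow(x$draws), ncol(x$draws), x$control$n_chains))
  invisible(x)
}

# quantile on the extended half-line [0, Inf]: type-7 interpolation between
# finite order statistics; any interpolation touching Inf returns Inf
# (or the finite lower neighbour when the weight on Inf is zero)
.quantile_ext <- function(x, probs) {
  x <- sort(x)  # Inf sorts last; NA absent by construction
  n <- length(x)
  vapply(probs, function(p) {
    h <- (n - 1) * p
    lo <- x[floor(h) + 1]; hi <- x[ceiling(h) + 1]
    g <- h - floor(h)
    if (!is.finite(hi)) { if (g == 0) lo else Inf }
    else lo + g * (hi - lo)
  }, numeric(1))
}

#' Derived scientific quantities per posterior draw
#'
#' For every retained draw: mean association tract length `1/d` and mean
#' non-association tract length `1/r` per process (bp), average association
#' level `f = r/(r+d)`, and the hemi-preference ratio `mu/delta` of the
#' daughter-strand enzyme whose activities the variant leaves free. Draws
#' with a zero denominator give `Inf`; summaries handle these on the
#' extended scale.
#'
#' @param samples A `"methylhmm_samples"` (or [methylhmm()] fit).
#' @return Numeric matrix, one row per draw.
#' @export
derived_quantities <- function(samples) {
  if (inherits(samples, "methylhmm")) samples <- samples$samples
  d <- samples$draws
  full <- function(nm) if (nm %in% colnames(d)) d[, nm] else
    rep(samples$fixed$theta[[nm]], nrow(d))
  r1 <- full("r1"); d1 <- full("d1")
  r3p <- full("r3p"); d3p <- full("d3p")
  r3d <- full("r3d"); d3d <- full("d3d")
  mu1 <- full("mu1"); delta1 <- full("delta1")
  mu3 <- full("mu3"); delta3 <- full("delta3")
  out <- cbind(
    assoc_len_dnmt1 = 1 / d1,
    assoc_len_dnmt3_parent = 1 / d3p,
    assoc_len_dnmt3_daughter = 1 / d3d,
    nonassoc_len_dnmt1 = 1 / r1,
    assoc_freq_dnmt1 = r1 / (r1 + d1 * (1 - r1)),
    assoc_freq_dnmt3_parent = r3p / (r3p + d3p * (1 - r3p)),
    assoc_freq_dnmt3_daughter = r3d / (r3d + d3d * (1 - r3d)),
    hemi_ratio_dnmt1 = mu1 / delta1)
  if (samples$variant == "dnmt3_hemi")
    out <- cbind(out, hemi_ratio_dnmt3 = mu3 / delta3)
  out
}

#' Posterior summary: median and 80% credible interval
#'
#' Medians with 10- and 90-percentiles (type-7 quantiles) for every free
#' parameter and derived quantity. Hemi-preference ratios additionally
#' report the 20-percentile as a one-sided 80% lower bound, because the
#' data cannot exclude extremely large ratios.
#'
#' @param samples A `"methylhmm_samples"` or [methylhmm()] fit with at
#'   least 100 retained draws.
#' @return Data frame with columns `parameter`, `median`, `q10`, `q90`,
#'   `lower80` (20-percentile, ratios only, else NA).
#' @export
summarize_posterior <- function(samples) {
  if (inherits(samples, "methylhmm")) samples <- samples$samples
  if (is.null(samples$draws) || nrow(samples$draws) < 100)
    stop("need at least 100 retained draws to summarize")
  der <- derived_quantities(samples)
  all <- cbind(samples$draws, der)
  ratio_cols <- grep("^hemi_ratio", colnames(all))
  res <- data.frame(
    parameter = colnames(all),
    median = NA_real_, q10 = NA_real_, q90 = NA_real_,
    lower80 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(all))) {
    q <- .quantile_ext(all[, i], c(0.5, 0.1, 0.9))
    res$median[i] <- q[1]; res$q10[i] <- q[2]; res$q90[i] <- q[3]
    if (i %in% ratio_cols)
      res$lower80[i] <- .quantile_ext(all[, i], 0.2)
  }
  res
}

#' Convergence diagnostics
#'
#' Split-chain potential scale reduction (split-Rhat) and effective sample
#' size (initial positive sequence estimator on chain-averaged
#' autocorrelations) for each free parameter. Parameters with
#' Rhat > 1.1 or ESS < 100 are flagged.
#'
#' @param samples A `"methylhmm_samples"` or [methylhmm()] fit.
#' @return Data frame with columns `parameter`, `rhat`, `ess`, `flag`.
#'   With a single chain `rhat` is NA (with a warning).
#' @export
convergence_diagnostics <- function(samples) {
  if (inherits(samples, "methylhmm")) samples <- samples$samples
  d <- samples$draws; ch <- samples$chain
  chains <- split(seq_len(nrow(d)), ch)
  single <- length(chains) < 2
  if (single) warning("single chain: reporting effective size only")
  n <- min(lengths(chains))
  rhat1 <- function(x_by_chain) {
    # split each chain in half
    halves <- unlist(lapply(x_by_chain, function(x) {
      x <- x[seq_len(n)]
      h <- n %/% 2
      list(x[seq_len(h)], x[(h + 1):(2 * h)])
    }), recursive = FALSE)
    m <- length(halves); len <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars); B <- len * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((len - 1) / len * W + B / len) / W)
  }
  ess1 <- function(x_by_chain) {
    nm <- length(x_by_chain)
    len <- n
    rho_by_lag <- function(lag) {
      mean(vapply(x_by_chain, function(x) {
        x <- x[seq_len(len)]
        if (stats::sd(x) == 0) return(0)
        stats::cor(x[seq_len(len - lag)], x[(lag + 1):len])
      }, numeric(1)))
    }
    tau <- 1; lag <- 1
    while (lag < len - 2) {
      r1 <- rho_by_lag(lag); r2 <- rho_by_lag(lag + 1)
      if (is.na(r1) || is.na(r2) || r1 + r2 <= 0) break
      tau <- tau + 2 * (r1 + r2)
      lag <- lag + 2
    }
    nm * len / tau
  }
  res <- data.frame(parameter = colnames(d), rhat = NA_real_,
                    ess = NA_real_, flag = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(d))) {
    xs <- lapply(chains, function(idx) d[idx, j])
    if (!single) res$rhat[j] <- rhat1(xs)
    res$ess[j] <- ess1(xs)
  }
  res$flag <- (!is.na(res$rhat) & res$rhat > 1.1) | res$ess < 100
  res
}

#' Write posterior samples as TSV
#'
#' One row per retained draw; `#` header lines carry the seed, variant and
#' sampler configuration.
#'
#' @param samples A `"methylhmm_samples"` or [methylhmm()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  if (inherits(samples, "methylhmm")) samples <- samples$samples
  ctl <- samples$control
  hdr <- c(
    sprintf("# variant: %s", samples$variant),
    sprintf("# seed: %d", samples$seed),
    sprintf("# chains: %d, iterations: %d, burnin: %d, thin: %d",
            ctl$n_chains, ctl$n_iter, ctl$burnin, ctl$thin),
    sprintf("# errors_off: %s, fix_site_densities: %s",
            samples$errors_off, samples$fixed$fix_site_densities))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(chain = samples$chain, samples$draws,
                   loglik = samples$loglik, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
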