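# Forward-backward machinery over the 8 joint hidden states.
#
# Orientation convention: "A_is_parent" reads strand_a as the
# post-replication parent and strand_b as the daughter; "B_is_parent" swaps
# the roles. Parentage is unobserved, so pattern likelihoods mix the two
# orientations with prior weight 1/2 each.

# per-gap joint transition matrices for a locus
.gap_transitions <- function(locus, params) {
  gaps <- site_distances(locus)
  if (any(gaps < 1L)) stop("overlapping CpG sites (zero bp gap) not allowed")
  uniq <- unique(gaps)
  mats <- lapply(uniq, function(L) joint_transition(params, L))
  names(mats) <- as.character(uniq)
  mats[as.character(gaps)]
}

# S x 8 emission matrix for one oriented pattern
.emission_matrix <- function(obs_parent, obs_daughter, params) {
  S <- length(obs_parent)
  t(vapply(seq_len(S), function(i)
    .emission_vector(obs_parent[i], obs_daughter[i],
                     params$densities[i], params), numeric(8)))
}

# scaled forward pass; returns loglik and scaled alpha matrix
.forward <- function(emis, translist, init) {
  S <- nrow(emis)
  alpha <- init * emis[1, ]
  tot <- sum(alpha)
  if (tot <= 0) return(list(loglik = -Inf, alpha = NULL))
  loglik <- log(tot)
  alpha <- alpha / tot
  A <- matrix(0, S, 8)
  A[1, ] <- alpha
  if (S > 1) for (i in 2:S) {
    alpha <- as.vector(alpha %*% translist[[i - 1]]) * emis[i, ]
    tot <- sum(alpha)
    if (tot <= 0) return(list(loglik = -Inf, alpha = NULL))
    loglik <- loglik + log(tot)
    alpha <- alpha / tot
    A[i, ] <- alpha
  }
  list(loglik = loglik, alpha = A)
}

# scaled backward pass; returns matrix of (rescaled) beta values
.backward <- function(emis, translist) {
  S <- nrow(emis)
  B <- matrix(0, S, 8)
  beta <- rep(1, 8)
  B[S, ] <- beta
  if (S > 1) for (i in (S - 1):1) {
    beta <- as.vector(translist[[i]] %*% (emis[i + 1, ] * beta))
    if (sum(beta) > 0) beta <- beta / sum(beta)
    B[i, ] <- beta
  }
  B
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# both oriented log-likelihoods for every pattern: matrix n x 2
.orientation_logliks <- function(patterns, locus, params) {
  if (ncol(patterns$a) != n_sites(locus))
    stop("pattern width does not match the locus CpG count")
  if (length(params$densities) != n_sites(locus))
    stop("site density vector does not match the locus CpG count")
  translist <- .gap_transitions(locus, params)
  init <- .joint_initial(params)
  n <- length(patterns$id)
  out <- matrix(NA_real_, n, 2,
                dimnames = list(patterns$id, c("A_is_parent", "B_is_parent")))
  for (j in seq_len(n)) {
    a <- patterns$a[j, ]; b <- patterns$b[j, ]
    out[j, 1] <- .forward(.emission_matrix(a, b, params), translist, init)$loglik
    out[j, 2] <- .forward(.emission_matrix(b, a, params), translist, init)$loglik
  }
  out
}

#' Log-likelihood of observed patterns under the HMM
#'
#' For each pattern, runs the forward algorithm over the 8 joint hidden
#' states for both strand orientations (each chain starting from its
#' stationary law, inter-site transitions given by the bp gaps of the
#' locus) and returns `log(0.5 L(A is parent) + 0.5 L(B is parent))`.
#' Unread strand entries are marginalized in the emission.
#'
#' This is the plain-R reference implementation; [dataset_loglik()] is the
#' compiled equivalent used inside MCMC.
#'
#' @param patterns A [methyl_patterns()] container.
#' @param locus A [cpg_locus()].
#' @param params A [model_params()] with a density vector matching the
#'   locus.
#' @return Numeric vector of per-pattern log-likelihoods (one molecule
#'   each; multiplicities are not applied).
#' @export
pattern_loglik <- function(patterns, locus, params) {
  ll <- .orientation_logliks(patterns, locus, params)
  apply(ll, 1, .logsumexp) - log(2)
}

#' Total dataset log-likelihood (compiled core)
#'
#' Multiplicity-weighted sum of [pattern_loglik()] over all patterns,
#' computed by the compiled forward algorithm. This is the quantity the
#' MCMC sampler targets.
#'
#' @inheritParams pattern_loglik
#' @return A single number (may be `-Inf`).
#' @export
dataset_loglik <- function(patterns, locus, params) {
  if (ncol(patterns$a) != n_sites(locus))
    stop("pattern width does not match the locus CpG count")
  theta <- params_to_theta(params)
  if (any(!is.finite(theta)) || any(!is.finite(params$densities)))
    stop("non-finite parameter")
  dataset_loglik_cpp(patterns$a, patterns$b, patterns$mult,
                     site_distances(locus), theta, params$densities)
}

#' Posterior probability that strand A is the parent
#'
#' `L(A is parent) / (L(A is parent) + L(B is parent))` for each pattern.
#' Patterns symmetric under strand swap get probability 1/2.
#'
#' @inheritParams pattern_loglik
#' @return Numeric vector in `[0, 1]`, one entry per pattern.
#' @export
orientation_posterior <- function(patterns, locus, params) {
  ll <- .orientation_logliks(patterns, locus, params)
  out <- 1 / (1 + exp(ll[, 2] - ll[, 1]))
  # both orientations impossible: undefined, return NA
  out[!is.finite(ll[, 1]) & !is.finite(ll[, 2])] <- NA_real_
  unname(out)
}

#' Posterior hidden-state marginals of one pattern
#'
#' Forward-backward smoothing: for each CpG site, the posterior
#' distribution over the 8 joint association states, per orientation and
#' averaged over orientations (weighted by the orientation posterior).
#'
#' @inheritParams pattern_loglik
#' @param which Index of the pattern to decode.
#' @return List with `A_is_parent`, `B_is_parent`, `averaged` (each an
#'   S x 8 matrix of per-site state probabilities summing to 1 by row) and
#'   `p_A_parent` (the orientation posterior).
#' @export
posterior_state_marginals <- function(patterns, locus, params, which = 1L) {
  p1 <- patterns[which]
  translist <- .gap_transitions(locus, params)
  init <- .joint_initial(params)
  smooth <- function(op, od) {
    emis <- .emission_matrix(op, od, params)
    fw <- .forward(emis, translist, init)
    if (!is.finite(fw$loglik))
      return(list(loglik = -Inf,
                  marg = matrix(NA_real_, nrow(emis), 8)))
    bw <- .backward(emis, translist)
    g <- fw$alpha * bw
    list(loglik = fw$loglik, marg = g / rowSums(g))
  }
  a <- p1$a[1, ]; b <- p1$b[1, ]
  mA <- smooth(a, b); mB <- smooth(b, a)
  pA <- 1 / (1 + exp(mB$loglik - mA$loglik))
  if (!is.finite(mA$loglik) && !is.finite(mB$loglik)) pA <- NA_real_
  avg <- if (is.na(pA)) matrix(NA_real_, length(a), 8) else {
    wa <- if (is.finite(mA$loglik)) pA * mA$marg else 0
    wb <- if (is.finite(mB$loglik)) (1 - pA) * mB$marg else 0
    wa + wb
  }
  cn <- sprintf("s%d%d%d", state_bits(0:7)[, 1], state_bits(0:7)[, 2],
                state_bits(0:7)[, 3])
  lab <- function(m) { colnames(m) <- cn; m }
  list(A_is_parent = lab(mA$marg), B_is_parent = lab(mB$marg),
       averaged = lab(avg), p_A_parent = unname(pA))
}

#' Most likely enzymatic explanations of a pattern
#'
#' Finds the k (orientation, hidden path) configurations with the highest
#' posterior probability, by k-best dynamic programming run over both
#' orientations. Probabilities are normalized by the total pattern
#' likelihood, so all `2 * 8^S` configuration probabilities sum to 1. Ties
#' are broken by orientation (`A_is_parent` first) and then lexicographic
#' path order over state indices.
#'
#' @inheritParams posterior_state_marginals
#' @param k Number of explanations to return (>= 1); capped at the number
#'   of configurations.
#' @return Data frame with columns `rank`, `orientation`, `prob`, `path`
#'   (states 0..7, dash-separated); attribute `"paths"` holds the paths as
#'   an integer matrix.
#' @export
kbest_explanations <- function(patterns, locus, params, k = 2L, which = 1L) {
  stopifnot(k >= 1)
  p1 <- patterns[which]
  S <- ncol(p1$a)
  k <- min(as.integer(k), 2 * 8^S)
  translist <- .gap_transitions(locus, params)
  ltrans <- lapply(translist, function(m) log(m))
  linit <- log(.joint_initial(params))
  total_ll <- pattern_loglik(p1, locus, params)[1]

  kbest_one <- function(op, od) {
    lemis <- log(.emission_matrix(op, od, params))
    beam <- lapply(1:8, function(s)
      list(list(lp = linit[s] + lemis[1, s], path = s - 1L)))
    if (S > 1) for (i in 2:S) {
      beam <- lapply(1:8, function(sp) {
        cands <- unlist(lapply(1:8, function(s) {
          lapply(beam[[s]], function(e)
            list(lp = e$lp + ltrans[[i - 1]][s, sp] + lemis[i, sp],
                 path = c(e$path, sp - 1L)))
        }), recursive = FALSE)
        lp <- vapply(cands, `[[`, numeric(1), "lp")
        key <- vapply(cands, function(e)
          paste(sprintf("%d", e$path), collapse = ""), character(1))
        cands[order(-lp, key)[seq_len(min(k, length(cands)))]]
      })
    }
    unlist(beam, recursive = FALSE)
  }

  a <- p1$a[1, ]; b <- p1$b[1, ]
  ents <- c(lapply(kbest_one(a, b), function(e) c(e, orient = "A_is_parent")),
            lapply(kbest_one(b, a), function(e) c(e, orient = "B_is_parent")))
  lp <- vapply(ents, `[[`, numeric(1), "lp") + log(0.5)
  key <- vapply(ents, function(e)
    paste(sprintf("%d", e$path), collapse = ""), character(1))
  orient <- vapply(ents, `[[`, character(1), "orient")
  ord <- order(-lp, orient, key)[seq_len(min(k, length(ents)))]
  paths <- do.call(rbind, lapply(ents[ord], `[[`, "path"))
  out <- data.frame(
    rank = seq_along(ord),
    orientation = orient[ord],
    prob = exp(lp[ord] - total_ll),
    path = apply(paths, 1, paste, collapse = "-"),
    stringsAsFactors = FALSE)
  attr(out, "paths") <- paths
  out
}
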