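# Independent brute-force oracle: enumerate all 2 * 8^S (orientation,
# hidden path) configurations of a pattern and accumulate probabilities
# directly from first principles. Emissions are recomputed here from the
# generative law (not via the package's emission helpers) so the oracle is
# independent of the code paths it checks.

# P(observed pair | state, site) from scratch
oracle_emission <- function(state_idx, obs_p, obs_d, m, params) {
  s1 <- state_idx %/% 4L; s3p <- (state_idx %/% 2L) %% 2L; s3d <- state_idx %% 2L
  chan <- function(true, obs) {
    if (is.na(obs)) return(1)
    if (true == 0L) { if (obs == 1L) params$e_fail else 1 - params$e_fail }
    else            { if (obs == 0L) params$e_inap else 1 - params$e_inap }
  }
  tot <- 0
  for (z in 0:1) {
    pz <- if (z == 1L) m else 1 - m
    parent_true <- if (z == 1L) 1L else s3p
    q1 <- s1 * (if (z == 1L) params$mu1 else params$delta1)
    q3 <- s3d * (if (z == 1L) params$mu3 else params$delta3)
    pd <- 1 - (1 - q1) * (1 - q3)
    for (dtrue in 0:1) {
      pdt <- if (dtrue == 1L) pd else 1 - pd
      tot <- tot + pz * pdt * chan(parent_true, obs_p) * chan(dtrue, obs_d)
    }
  }
  tot
}

oracle_stationary <- function(p) {
  if (p$reassoc + p$dissoc <= 0) return(c(1, 0))
  f <- p$reassoc / (p$reassoc + p$dissoc * (1 - p$reassoc))
  c(1 - f, f)
}

# slow repeated multiplication (no squaring) for the L-bp chain matrix;
# assoc -> assoc = (1 - d) processive + d*r dissociation-reassociation
oracle_chain_matrix <- function(p, L) {
  r <- p$reassoc; d <- p$dissoc
  M1 <- matrix(c(1 - r, r, d * (1 - r), 1 - d + d * r), 2, 2, byrow = TRUE)
  out <- diag(2)
  for (i in seq_len(L)) out <- out %*% M1
  out
}

oracle_joint_matrix <- function(params, L) {
  T1 <- oracle_chain_matrix(params$dnmt1, L)
  T3p <- oracle_chain_matrix(params$dnmt3_parent, L)
  T3d <- oracle_chain_matrix(params$dnmt3_daughter, L)
  A <- matrix(0, 8, 8)
  for (s in 0:7) for (sp in 0:7) {
    A[s + 1, sp + 1] <-
      T1[s %/% 4 + 1, sp %/% 4 + 1] *
      T3p[(s %/% 2) %% 2 + 1, (sp %/% 2) %% 2 + 1] *
      T3d[s %% 2 + 1, sp %% 2 + 1]
  }
  A
}

# full enumeration: returns likelihood, per-site marginals, per-config
# table; vectorized over the 8^S paths (emissions still built from first
# principles above, independent of the package's emission code)
oracle_enumerate <- function(pat_a, pat_b, locus, params) {
  S <- length(pat_a)
  gaps <- site_distances(locus)
  trs <- lapply(gaps, function(L) oracle_joint_matrix(params, L))
  init <- kronecker(oracle_stationary(params$dnmt1),
                    kronecker(oracle_stationary(params$dnmt3_parent),
                              oracle_stationary(params$dnmt3_daughter)))
  paths <- as.matrix(expand.grid(rep(list(0:7), S)))[, seq_len(S),
                                                     drop = FALSE]
  colnames(paths) <- NULL
  emis_mat <- function(op, od) {
    out <- matrix(0, S, 8)
    for (i in seq_len(S)) for (s in 0:7)
      out[i, s + 1] <- oracle_emission(s, op[i], od[i],
                                       params$densities[i], params)
    out
  }
  marg <- list(matrix(0, S, 8), matrix(0, S, 8))
  probs <- matrix(0, nrow(paths), 2)
  for (orient in 1:2) {
    op <- if (orient == 1) pat_a else pat_b
    od <- if (orient == 1) pat_b else pat_a
    em <- emis_mat(op, od)
    pr <- 0.5 * init[paths[, 1] + 1] * em[cbind(1L, paths[, 1] + 1)]
    if (S > 1) for (i in 2:S) {
      pr <- pr * trs[[i - 1]][cbind(paths[, i - 1] + 1, paths[, i] + 1)] *
        em[cbind(i, paths[, i] + 1)]
    }
    probs[, orient] <- pr
    for (i in seq_len(S)) {
      agg <- rowsum(pr, group = paths[, i])
      marg[[orient]][i, as.integer(rownames(agg)) + 1] <- agg
    }
  }
  lik <- sum(probs)
  list(loglik = log(lik),
       marg_A = marg[[1]] / rowSums(marg[[1]]),
       marg_B = marg[[2]] / rowSums(marg[[2]]),
       marg_avg = (marg[[1]] + marg[[2]]) / lik,
       p_A_parent = sum(probs[, 1]) / lik,
       paths = paths, config_probs = probs / lik)
}

# random valid parameter set for property-style tests
random_params <- function(S, variant = "in_vivo_default") {
  model_params(
    dnmt1 = enzyme_process(runif(1), runif(1, 0.01, 1)),
    dnmt3_parent = enzyme_process(runif(1), runif(1, 0.01, 1)),
    dnmt3_daughter = enzyme_process(runif(1), runif(1, 0.01, 1)),
    mu1 = runif(1), delta1 = runif(1), mu3 = runif(1), delta3 = runif(1),
    e_fail = runif(1, 0, 0.2), e_inap = runif(1, 0, 0.2),
    densities = runif(S), variant = variant)
}

# random pattern with occasional missing entries
random_pattern <- function(S, p_missing = 0.15) {
  draw <- function() {
    v <- sample(c(0L, 1L, NA_integer_), S, replace = TRUE,
                prob = c((1 - p_missing) / 2, (1 - p_missing) / 2, p_missing))
    v
  }
  methyl_patterns("rp", rbind(draw()), rbind(draw()))
}

random_test_locus <- function(S) {
  cpg_locus("toy", "chrT",
            cumsum(c(50L, sample(1:12, S - 1, replace = TRUE))))
}
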