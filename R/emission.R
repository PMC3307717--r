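#' Error-free emission distribution of a hidden state
#'
#' Generative law at one CpG dyad, given the association triple
#' (s1, s3p, s3d) and the site's pre-replication methylation density m:
#'
#' 1. The pre-replication parent state is z ~ Bernoulli(m).
#' 2. Methyl groups are not actively removed, so the post-replication
#'    parent CpG is methylated (P = 1) whenever z = 1; when z = 0 it is
#'    methylated only by an associated parent-strand DNMT3, which
#'    methylates with probability 1 (P = s3p).
#' 3. The daughter CpG starts unmethylated. Associated DNMT1 methylates it
#'    with probability mu1 if z = 1 (maintenance) or delta1 if z = 0
#'    (de novo); associated daughter-strand DNMT3s likewise with mu3/delta3.
#'    The two enzymes act as independent attempts, so
#'    `P(D = 1) = 1 - (1 - q1)(1 - q3)` with `q1 = s1 * (z ? mu1 : delta1)`
#'    and `q3 = s3d * (z ? mu3 : delta3)`.
#'
#' The substrate (hemimethylated vs unmethylated) is judged by the
#' pre-replication state z, not by the concurrently modified parent strand.
#'
#' @param state Integer triple `c(s1, s3p, s3d)` of association indicators,
#'   or a single joint index 0..7 (bit order s1 most significant).
#' @param m Pre-replication methylation density of the site, in `[0, 1]`.
#' @param params A [model_params()] supplying mu1, delta1, mu3, delta3.
#' @return Named numeric 4-vector of probabilities over the true dyad
#'   (parent, daughter) in the order `00`, `01`, `10`, `11`; sums to 1.
#' @examples
#' p <- model_params(densities = rep(0.5, 2))
#' emission_true(c(1, 1, 0), m = 0.5, params = p)
#' @export
emission_true <- function(state, m, params) {
  if (length(state) == 1L) state <- drop(state_bits(as.integer(state)))
  stopifnot(length(state) == 3L, all(state %in% c(0L, 1L)),
            m >= 0, m <= 1)
  s1 <- state[[1]]; s3p <- state[[2]]; s3d <- state[[3]]
  # z = 1 branch: parent stays methylated
  pD_z1 <- 1 - (1 - s1 * params$mu1) * (1 - s3d * params$mu3)
  # z = 0 branch: parent methylated only by associated parent-strand DNMT3
  pD_z0 <- 1 - (1 - s1 * params$delta1) * (1 - s3d * params$delta3)
  out <- numeric(4)
  # (P, D) indexed 00, 01, 10, 11
  out[1] <- (1 - m) * (if (s3p == 1L) 0 else 1 - pD_z0)
  out[2] <- (1 - m) * (if (s3p == 1L) 0 else pD_z0)
  out[3] <- m * (1 - pD_z1) + (1 - m) * (if (s3p == 1L) 1 - pD_z0 else 0)
  out[4] <- m * pD_z1       + (1 - m) * (if (s3p == 1L) pD_z0 else 0)
  names(out) <- c("00", "01", "10", "11")
  out
}

# per-strand observation channel: P(observed | true)
# true 0 read as 1 with prob e_fail; true 1 read as 0 with prob e_inap
.obs_channel <- function(e_fail, e_inap) {
  matrix(c(1 - e_fail, e_inap, e_fail, 1 - e_inap), 2, 2,
         dimnames = list(truth = c("0", "1"), observed = c("0", "1")))
}

#' Emission distribution with bisulfite measurement errors
#'
#' Convolves [emission_true()] with the per-strand bisulfite error channel:
#' a truly unmethylated cytosine is read as methylated with probability
#' `e_fail` (failure of conversion) and a truly methylated cytosine is read
#' as unmethylated with probability `e_inap` (inappropriate conversion),
#' independently across the two strands.
#'
#' @inheritParams emission_true
#' @return Named numeric 4-vector over the observed dyad (parent, daughter)
#'   in the order `00`, `01`, `10`, `11`; sums to 1.
#' @export
emission_observed <- function(state, m, params) {
  tr <- emission_true(state, m, params)
  E <- .obs_channel(params$e_fail, params$e_inap)
  out <- numeric(4)
  for (op in 0:1) for (od in 0:1) {
    acc <- 0
    for (tp in 0:1) for (td in 0:1)
      acc <- acc + tr[[2 * tp + td + 1]] *
        E[tp + 1, op + 1] * E[td + 1, od + 1]
    out[2 * op + od + 1] <- acc
  }
  names(out) <- c("00", "01", "10", "11")
  out
}

# probability of an observed (parent, daughter) pair, each 0/1/NA, for all
# 8 hidden states at one site; missing strands are marginalized.
# Returns numeric(8). Used by the R reference likelihood.
.emission_vector <- function(obs_p, obs_d, m, params) {
  E <- .obs_channel(params$e_fail, params$e_inap)
  strand_lik <- function(obs) {
    # returns c(P(obs | true=0), P(obs | true=1)); 1,1 when missing
    if (is.na(obs)) c(1, 1) else E[, obs + 1]
  }
  lp <- strand_lik(obs_p); ld <- strand_lik(obs_d)
  vapply(0:7, function(s) {
    tr <- emission_true(s, m, params)
    sum(tr * c(lp[1] * ld[1], lp[1] * ld[2], lp[2] * ld[1], lp[2] * ld[2]))
  }, numeric(1))
}
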