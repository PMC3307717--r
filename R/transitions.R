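#' Per-bp transition matrix of an association chain
#'
#' Row/column order: state 0 = unassociated, state 1 = associated. Over one
#' bp, an unassociated molecule reassociates with probability r (row 0 =
#' `(1 - r, r)`). An associated molecule stays associated either by
#' processivity (never dissociating, probability `1 - d`) or by a
#' dissociation-reassociation event (falling off and re-binding at the next
#' position, probability `d * r`), so row 1 is `(d (1 - r), 1 - d + d r)`.
#' With `d = 1` the two rows are identical and the association state is
#' independent at each site (no processivity).
#'
#' @param p An [enzyme_process()].
#' @return A 2x2 row-stochastic matrix.
#' @export
per_bp_transition <- function(p) {
  r <- p$reassoc; d <- p$dissoc
  matrix(c(1 - r, d * (1 - r), r, 1 - d + d * r), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# matrix power by exponentiation-by-squaring
.matpow <- function(M, L) {
  out <- diag(nrow(M))
  P <- M
  while (L > 0) {
    if (L %% 2 == 1) out <- out %*% P
    L <- L %/% 2
    if (L > 0) P <- P %*% P
  }
  out
}

#' Transition matrix over an inter-site distance
#'
#' The per-bp matrix raised to the L-th power, giving the transition law of
#' the association chain between two CpG sites L bp apart.
#'
#' @param p An [enzyme_process()].
#' @param L Distance in bp (integer >= 1).
#' @return A 2x2 row-stochastic matrix.
#' @export
transition_over_distance <- function(p, L) {
  if (length(L) != 1 || is.na(L) || L < 1 || L != round(L))
    stop("L must be a positive integer number of bp")
  out <- .matpow(per_bp_transition(p), as.integer(L))
  dimnames(out) <- list(c("0", "1"), c("0", "1"))
  out
}

#' Stationary association frequency of a chain
#'
#' The long-run fraction of sites at which the enzyme is associated: the
#' stationary law of the per-bp matrix, `f = r / (r + d (1 - r))`. This is
#' the average association level reported for each process. With `d = 1`
#' (no processivity) it reduces to `f = r`.
#'
#' @param p An [enzyme_process()].
#' @return Probability in `[0, 1]`.
#' @export
stationary_association_frequency <- function(p) {
  r <- p$reassoc; d <- p$dissoc
  if (r + d <= 0) stop("stationary frequency undefined when r = d = 0")
  r / (r + d * (1 - r))
}

#' Mean association and non-association tract lengths
#'
#' Dwell times of the two-state chain are geometric: an association tract
#' has mean length `1/d` bp (the conventional processivity measure; it
#' excludes dissociation-reassociation events) and a non-association tract
#' (the gap between association tracts) has mean `1/r` bp. A zero
#' denominator yields an infinite mean.
#'
#' @param p An [enzyme_process()].
#' @return Named numeric: `association`, `non_association` (bp).
#' @export
mean_tract_lengths <- function(p) {
  c(association = if (p$dissoc > 0) 1 / p$dissoc else Inf,
    non_association = if (p$reassoc > 0) 1 / p$reassoc else Inf)
}

#' Joint transition matrix over the 8 hidden states
#'
#' The hidden state at a CpG site is the triple (s1, s3p, s3d) of
#' association indicators of the DNMT1-daughter, DNMT3-parent and
#' DNMT3-daughter chains. States are indexed 0..7 by bit packing with s1
#' most significant: `index = 4*s1 + 2*s3p + s3d`. Because the three chains
#' are independent, the joint L-bp transition matrix is the Kronecker
#' product of the three marginal L-bp matrices in that bit order.
#'
#' @param params A [model_params()].
#' @param L Distance in bp (>= 1).
#' @return An 8x8 row-stochastic matrix.
#' @export
joint_transition <- function(params, L) {
  T1 <- transition_over_distance(params$dnmt1, L)
  T3p <- transition_over_distance(params$dnmt3_parent, L)
  T3d <- transition_over_distance(params$dnmt3_daughter, L)
  kronecker(T1, kronecker(T3p, T3d))
}

# stationary initial distribution over the 8 joint states; chains with
# r = d = 0 are frozen in the unassociated state
.joint_initial <- function(params) {
  statio <- function(p) {
    if (p$reassoc + p$dissoc <= 0) return(c(1, 0))
    f <- p$reassoc / (p$reassoc + p$dissoc * (1 - p$reassoc))
    c(1 - f, f)
  }
  as.vector(kronecker(statio(params$dnmt1),
                      kronecker(statio(params$dnmt3_parent),
                                statio(params$dnmt3_daughter))))
}

# decode a joint state index 0..7 into c(s1, s3p, s3d)
state_bits <- function(idx) {
  cbind(s1 = idx %/% 4L, s3p = (idx %/% 2L) %% 2L, s3d = idx %% 2L)
}
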