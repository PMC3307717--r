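#' Simulate a hairpin-bisulfite dataset
#'
#' Generative dual of the HMM. For each molecule: the three association
#' chains are sampled along the locus (stationary start, L-bp transition
#' between consecutive CpG sites); pre-replication parent states are drawn
#' from the site densities; true dyads follow the emission law of
#' [emission_true()]; observed dyads pass through the per-strand bisulfite
#' error channel; finally the two strands are labelled A/B at random (when
#' `orientation_randomized`) to mimic unknown parentage. Optionally, a PCR
#' crossover artifact replaces a molecule by a single-breakpoint hybrid of
#' two simulated molecules.
#'
#' @param locus A [cpg_locus()].
#' @param params A [model_params()] whose density vector matches the locus.
#' @param n_patterns Number of molecules to simulate (>= 1).
#' @param seed Optional integer seed.
#' @param crossover_rate Per-molecule probability of a single-breakpoint
#'   PCR crossover hybrid (default 0).
#' @param orientation_randomized If `TRUE` (default) the parent strand is
#'   stored as strand A or B with probability 1/2 each; if `FALSE` the
#'   parent is always strand A.
#' @return An object of class `"methyl_sim"`: list with
#'   * `patterns`: a [methyl_patterns()] container (multiplicity 1 each);
#'   * `truth`: list with `orientation` (character, `A_is_parent` /
#'     `B_is_parent`), `hidden` (n x S x 3 array of association indicators
#'     for the DNMT1-daughter, DNMT3-parent, DNMT3-daughter chains),
#'     `pre_replication` (n x S matrix of z), `true_parent`,
#'     `true_daughter` (n x S true methylation before errors),
#'     `flip_parent`, `flip_daughter` (logical n x S error-flip masks),
#'     `crossover` (logical vector).
#' @export
simulate_patterns <- function(locus, params, n_patterns, seed = NULL,
                              crossover_rate = 0,
                              orientation_randomized = TRUE) {
  stopifnot(n_patterns >= 1, crossover_rate >= 0, crossover_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  S <- n_sites(locus)
  if (length(params$densities) != S)
    stop("site density vector does not match the locus CpG count")
  gaps <- site_distances(locus)

  sim_chain <- function(n, p) {
    # n molecules, one two-state chain over S sites
    f0 <- if (p$reassoc + p$dissoc <= 0) 0 else
      p$reassoc / (p$reassoc + p$dissoc * (1 - p$reassoc))
    x <- matrix(0L, n, S)
    x[, 1] <- stats::rbinom(n, 1L, f0)
    for (i in seq_len(S - 1)) {
      Tg <- transition_over_distance(p, gaps[i])
      pr <- ifelse(x[, i] == 1L, Tg[2, 2], Tg[1, 2])
      x[, i + 1] <- stats::rbinom(n, 1L, pr)
    }
    x
  }

  sim_block <- function(n) {
    s1 <- sim_chain(n, params$dnmt1)
    s3p <- sim_chain(n, params$dnmt3_parent)
    s3d <- sim_chain(n, params$dnmt3_daughter)
    z <- matrix(stats::rbinom(n * S, 1L, rep(params$densities, each = n)),
                n, S)
    # post-replication parent: kept if z=1, else set by associated 3p chain
    parent <- ifelse(z == 1L, 1L, s3p)
    pD <- ifelse(z == 1L,
                 1 - (1 - s1 * params$mu1) * (1 - s3d * params$mu3),
                 1 - (1 - s1 * params$delta1) * (1 - s3d * params$delta3))
    daughter <- matrix(stats::rbinom(n * S, 1L, pD), n, S)
    list(s1 = s1, s3p = s3p, s3d = s3d, z = z,
         parent = parent, daughter = daughter)
  }

  blk <- sim_block(n_patterns)
  crossover <- stats::runif(n_patterns) < crossover_rate
  if (any(crossover)) {
    # hybridize with an independent donor molecule at a uniform breakpoint
    donor <- sim_block(sum(crossover))
    bp <- sample(S - 1L, sum(crossover), replace = TRUE)
    rows <- which(crossover)
    for (k in seq_along(rows)) {
      j <- rows[k]; tail <- (bp[k] + 1L):S
      for (f in c("s1", "s3p", "s3d", "z", "parent", "daughter"))
        blk[[f]][j, tail] <- donor[[f]][k, tail]
    }
  }

  flip <- function(truth) {
    pr <- ifelse(truth == 1L, params$e_inap, params$e_fail)
    matrix(stats::rbinom(length(truth), 1L, pr), nrow(truth), ncol(truth)) == 1L
  }
  fp <- flip(blk$parent); fd <- flip(blk$daughter)
  obs_parent <- ifelse(fp, 1L - blk$parent, blk$parent)
  obs_daughter <- ifelse(fd, 1L - blk$daughter, blk$daughter)

  orient <- if (orientation_randomized)
    ifelse(stats::runif(n_patterns) < 0.5, "A_is_parent", "B_is_parent")
  else rep("A_is_parent", n_patterns)
  swap <- orient == "B_is_parent"
  a <- obs_parent; b <- obs_daughter
  a[swap, ] <- obs_daughter[swap, ]
  b[swap, ] <- obs_parent[swap, ]

  hidden <- array(c(blk$s1, blk$s3p, blk$s3d),
                  dim = c(n_patterns, S, 3),
                  dimnames = list(NULL, NULL,
                                  c("dnmt1", "dnmt3_parent", "dnmt3_daughter")))
  structure(list(
    patterns = methyl_patterns(sprintf("sim%04d", seq_len(n_patterns)), a, b),
    truth = list(orientation = orient, hidden = hidden,
                 pre_replication = blk$z,
                 true_parent = blk$parent, true_daughter = blk$daughter,
                 flip_parent = fp, flip_daughter = fd,
                 crossover = crossover),
    locus = locus, params = params, seed = seed),
    class = "methyl_sim")
}

#' @export
print.methyl_sim <- function(x, ...) {
  cat(sprintf("simulated hairpin-bisulfite dataset: %d molecules, %d CpG sites\n",
              length(x$patterns$id), ncol(x$patterns$a)))
  invisible(x)
}

#' Observed association frequency in simulated truth
#'
#' Fraction of (molecule, site) pairs at which each process was associated.
#' Converges to the stationary frequency `r / (r + d)` as the number of
#' molecules grows.
#'
#' @param sim A `"methyl_sim"` from [simulate_patterns()].
#' @return Named numeric vector for the three processes.
#' @export
empirical_association_frequency <- function(sim) {
  h <- sim$truth$hidden
  c(dnmt1 = mean(h[, , 1]), dnmt3_parent = mean(h[, , 2]),
    dnmt3_daughter = mean(h[, , 3]))
}

#' Write the truth sidecar of a simulation
#'
#' One TSV row per molecule: orientation, crossover flag, and the hidden
#' chains / pre-replication states as strings, so simulated pattern files
#' stay format-identical to real data.
#'
#' @param sim A `"methyl_sim"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  n <- length(sim$patterns$id)
  pack <- function(m) apply(matrix(m, nrow = n), 1, paste, collapse = "")
  h <- sim$truth$hidden
  out <- data.frame(
    pattern_id = sim$patterns$id,
    orientation = sim$truth$orientation,
    crossover = as.integer(sim$truth$crossover),
    dnmt1 = pack(h[, , 1, drop = TRUE]),
    dnmt3_parent = pack(h[, , 2, drop = TRUE]),
    dnmt3_daughter = pack(h[, , 3, drop = TRUE]),
    pre_replication = pack(sim$truth$pre_replication),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
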