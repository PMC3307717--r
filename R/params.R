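#' Per-bp association chain parameters for one methyltransferase process
#'
#' Each enzyme process (DNMT1 on the daughter strand, DNMT3s on the parent
#' strand, DNMT3s on the daughter strand) is a two-state Markov chain along
#' the DNA with a per-bp reassociating probability r (unassociated ->
#' associated over 1 bp) and a per-bp dissociating probability d
#' (associated -> unassociated over 1 bp). Small d means processive
#' behaviour; the mean association tract length is 1/d bp.
#'
#' @param reassoc Per-bp reassociating probability in `[0, 1]`.
#' @param dissoc Per-bp dissociating probability in `[0, 1]`.
#' @return An object of class `"enzyme_process"`.
#' @examples
#' enzyme_process(reassoc = 0.12, dissoc = 0.002)
#' @export
enzyme_process <- function(reassoc, dissoc) {
  stopifnot(is.numeric(reassoc), is.numeric(dissoc),
            reassoc >= 0, reassoc <= 1, dissoc >= 0, dissoc <= 1)
  structure(list(reassoc = reassoc, dissoc = dissoc),
            class = "enzyme_process")
}

#' @export
print.enzyme_process <- function(x, ...) {
  cat(sprintf("enzyme process: r = %g /bp, d = %g /bp\n", x$reassoc, x$dissoc))
  invisible(x)
}

#' Model variants
#'
#' * `in_vivo_default`: the parsimonious in vivo model in which the DNMT3s
#'   always methylate an associated daughter-strand CpG (mu3 = delta3 = 1);
#'   DNMT1's maintenance (mu1) and de novo (delta1) probabilities are free.
#' * `dnmt3_hemi`: a constraint set for estimating the DNMT3
#'   hemi-preference ratio; DNMT1 is purely a maintenance enzyme
#'   (mu1 = 1, delta1 = 0) and mu3, delta3 are free.
#' * `in_vitro_dnmt1`: in vitro experiments with purified DNMT1 only; both
#'   DNMT3 chains are disabled (reassoc = 0, dissoc = 1).
#'
#' @name model_variants
#' @keywords internal
NULL

.variants <- c("in_vivo_default", "dnmt3_hemi", "in_vitro_dnmt1")

#' Full parameter set of the methylation HMM
#'
#' Bundles the three association chains, the methylation-activity
#' probabilities, the bisulfite-error probabilities and the per-site
#' pre-replication methylation densities, and applies the constraints of
#' the chosen model variant.
#'
#' @param dnmt1,dnmt3_parent,dnmt3_daughter [enzyme_process()] objects for
#'   the daughter-strand DNMT1 chain and the parent/daughter DNMT3 chains.
#' @param mu1 Probability that associated DNMT1 methylates a daughter CpG
#'   whose pre-replication parent CpG was methylated (maintenance).
#' @param delta1 Same for an unmethylated pre-replication dyad (de novo).
#' @param mu3,delta3 Analogous probabilities for the daughter-strand DNMT3s.
#' @param e_fail Probability that an unmethylated cytosine is read as
#'   methylated (failure of bisulfite conversion), per CpG per strand.
#' @param e_inap Probability that a methylated cytosine is read as
#'   unmethylated (inappropriate bisulfite conversion), per CpG per strand.
#' @param densities Numeric vector of per-site probabilities that the
#'   pre-replication parent CpG is methylated (the site methylation
#'   density), one per CpG site.
#' @param variant One of `"in_vivo_default"`, `"dnmt3_hemi"`,
#'   `"in_vitro_dnmt1"`; see [model_variants].
#' @param errors_off If `TRUE`, both error probabilities are forced to 0.
#' @return An object of class `"dnmt_params"`.
#' @examples
#' model_params(densities = rep(0.85, 5))
#' @export
model_params <- function(dnmt1 = enzyme_process(0.12, 0.002),
                         dnmt3_parent = enzyme_process(0.01, 0.65),
                         dnmt3_daughter = enzyme_process(0.01, 0.28),
                         mu1 = 0.99, delta1 = 0.02,
                         mu3 = 1, delta3 = 1,
                         e_fail = 0.003, e_inap = 0.02,
                         densities = rep(0.88, 22),
                         variant = c("in_vivo_default", "dnmt3_hemi",
                                     "in_vitro_dnmt1"),
                         errors_off = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(dnmt1, "enzyme_process"),
            inherits(dnmt3_parent, "enzyme_process"),
            inherits(dnmt3_daughter, "enzyme_process"))
  probs <- c(mu1, delta1, mu3, delta3, e_fail, e_inap, densities)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("all probabilities must be finite and in [0, 1]")
  if (e_fail >= 1 || e_inap >= 1)
    stop("error probabilities must be < 1")
  if (variant == "in_vivo_default") {
    mu3 <- 1; delta3 <- 1
  } else if (variant == "dnmt3_hemi") {
    mu1 <- 1; delta1 <- 0
  } else if (variant == "in_vitro_dnmt1") {
    dnmt3_parent <- enzyme_process(0, 1)
    dnmt3_daughter <- enzyme_process(0, 1)
    mu3 <- 1; delta3 <- 1
  }
  if (errors_off) { e_fail <- 0; e_inap <- 0 }
  structure(list(
    dnmt1 = dnmt1, dnmt3_parent = dnmt3_parent,
    dnmt3_daughter = dnmt3_daughter,
    mu1 = mu1, delta1 = delta1, mu3 = mu3, delta3 = delta3,
    e_fail = e_fail, e_inap = e_inap,
    densities = as.numeric(densities),
    variant = variant, errors_off = errors_off),
    class = "dnmt_params")
}

#' @export
print.dnmt_params <- function(x, ...) {
  cat("HMM parameters (variant:", x$variant, ")\n")
  cat(sprintf("  DNMT1 daughter:  r = %g, d = %g\n",
              x$dnmt1$reassoc, x$dnmt1$dissoc))
  cat(sprintf("  DNMT3 parent:    r = %g, d = %g\n",
              x$dnmt3_parent$reassoc, x$dnmt3_parent$dissoc))
  cat(sprintf("  DNMT3 daughter:  r = %g, d = %g\n",
              x$dnmt3_daughter$reassoc, x$dnmt3_daughter$dissoc))
  cat(sprintf("  activities: mu1 = %g, delta1 = %g, mu3 = %g, delta3 = %g\n",
              x$mu1, x$delta1, x$mu3, x$delta3))
  cat(sprintf("  errors: fail = %g, inappropriate = %g\n", x$e_fail, x$e_inap))
  cat(sprintf("  site densities: %d sites, mean %.3f\n",
              length(x$densities), mean(x$densities)))
  invisible(x)
}

# flat parameter vector used by the likelihood core; fixed order
.theta_names <- c("r1", "d1", "r3p", "d3p", "r3d", "d3d",
                  "mu1", "delta1", "mu3", "delta3", "e_fail", "e_inap")

params_to_theta <- function(params) {
  c(r1 = params$dnmt1$reassoc, d1 = params$dnmt1$dissoc,
    r3p = params$dnmt3_parent$reassoc, d3p = params$dnmt3_parent$dissoc,
    r3d = params$dnmt3_daughter$reassoc, d3d = params$dnmt3_daughter$dissoc,
    mu1 = params$mu1, delta1 = params$delta1,
    mu3 = params$mu3, delta3 = params$delta3,
    e_fail = params$e_fail, e_inap = params$e_inap)
}

theta_to_params <- function(theta, densities, variant = "in_vivo_default",
                            errors_off = FALSE) {
  model_params(
    dnmt1 = enzyme_process(theta[["r1"]], theta[["d1"]]),
    dnmt3_parent = enzyme_process(theta[["r3p"]], theta[["d3p"]]),
    dnmt3_daughter = enzyme_process(theta[["r3d"]], theta[["d3d"]]),
    mu1 = theta[["mu1"]], delta1 = theta[["delta1"]],
    mu3 = theta[["mu3"]], delta3 = theta[["delta3"]],
    e_fail = theta[["e_fail"]], e_inap = theta[["e_inap"]],
    densities = densities, variant = variant, errors_off = errors_off)
}

#' Parameters of the densely methylated Xi-linked regime
#'
#' A ready-made parameter set matching the posterior medians inferred for a
#' densely methylated human inactive-X locus (FMR1-like): strongly
#' processive DNMT1 (d = 0.002, mean tract 500 bp), moderate reassociation
#' (r = 0.12), near-perfect maintenance (mu1 = 0.99), rare de novo activity
#' (delta1 = 0.02), nearly inactive DNMT3s, 2% inappropriate-conversion
#' error, and a site methylation density of 0.88 (chosen so the implied
#' stationary dyad-class fractions match densely methylated Xi-linked
#' data).
#'
#' @param n_sites Number of CpG sites for the density vector.
#' @return A [model_params()] object.
#' @export
fmr1_regime_params <- function(n_sites = 22L) {
  model_params(
    dnmt1 = enzyme_process(0.12, 0.002),
    dnmt3_parent = enzyme_process(0.01, 0.65),
    dnmt3_daughter = enzyme_process(0.01, 0.28),
    mu1 = 0.99, delta1 = 0.02, mu3 = 1, delta3 = 1,
    e_fail = 0.003, e_inap = 0.02,
    densities = rep(0.88, n_sites),
    variant = "in_vivo_default")
}
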