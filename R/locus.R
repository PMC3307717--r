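#' Define a CpG locus
#'
#' A locus is an ordered set of CpG sites on a reference region. Coordinates
#' are 1-based genomic bp positions of the C of each CpG on the top strand;
#' inter-site distances used by the transition model are differences of these
#' coordinates.
#'
#' @param name Text label for the locus (e.g. a gene name).
#' @param chromosome Chromosome label.
#' @param positions Integer vector of CpG positions, strictly increasing,
#'   at least two sites.
#' @param region_start,region_end Region boundaries in bp; default to the
#'   range of `positions`.
#' @return An object of class `"cpg_locus"`: a list with fields `name`,
#'   `chromosome`, `positions`, `region_start`, `region_end`.
#' @examples
#' loc <- cpg_locus("toy", "chrX", c(100, 107, 112))
#' site_distances(loc)
#' @export
cpg_locus <- function(name, chromosome, positions,
                      region_start = min(positions),
                      region_end = max(positions)) {
  positions <- as.integer(positions)
  if (length(positions) < 2L)
    stop("a locus needs at least 2 CpG positions")
  if (any(diff(positions) <= 0L))
    stop("CpG positions must be strictly increasing")
  if (any(positions < region_start) || any(positions > region_end))
    stop("all CpG positions must lie within [region_start, region_end]")
  structure(
    list(name = as.character(name), chromosome = as.character(chromosome),
         positions = positions,
         region_start = as.integer(region_start),
         region_end = as.integer(region_end)),
    class = "cpg_locus")
}

#' Number of CpG sites of a locus
#' @param locus A [cpg_locus()].
#' @return Integer site count.
#' @export
n_sites <- function(locus) length(locus$positions)

#' Inter-site distances of a locus
#' @param locus A [cpg_locus()].
#' @return Integer vector of bp gaps between consecutive CpG sites
#'   (length `n_sites(locus) - 1`).
#' @export
site_distances <- function(locus) diff(locus$positions)

#' @export
print.cpg_locus <- function(x, ...) {
  cat(sprintf("CpG locus '%s' (%s:%d-%d)\n", x$name, x$chromosome,
              x$region_start, x$region_end))
  cat(sprintf("  %d CpG sites, median inter-site distance %.1f bp\n",
              n_sites(x), stats::median(site_distances(x))))
  invisible(x)
}

#' Read / write a locus file
#'
#' Locus files are YAML key-value text with fields `name`, `chromosome`,
#' `region_start`, `region_end` and a list `cpg_positions`.
#'
#' @param path File path.
#' @return `read_locus()` returns a [cpg_locus()]; `write_locus()` returns
#'   `path` invisibly.
#' @export
read_locus <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("name", "chromosome", "cpg_positions")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop("locus file ", path, " lacks field(s): ", paste(miss, collapse = ", "))
  cpg_locus(y$name, y$chromosome, unlist(y$cpg_positions),
            region_start = if (is.null(y$region_start))
              min(unlist(y$cpg_positions)) else y$region_start,
            region_end = if (is.null(y$region_end))
              max(unlist(y$cpg_positions)) else y$region_end)
}

#' @rdname read_locus
#' @param locus A [cpg_locus()].
#' @export
write_locus <- function(locus, path) {
  yaml::write_yaml(
    list(name = locus$name, chromosome = locus$chromosome,
         region_start = locus$region_start, region_end = locus$region_end,
         cpg_positions = as.list(locus$positions)),
    path)
  invisible(path)
}

#' Generate a synthetic CpG locus
#'
#' Draws inter-site spacings uniformly from a set of candidate gaps. The
#' default gap set 4..10 bp gives a median spacing of about 7 bp, typical of
#' the dense CpG regions assayed by hairpin-bisulfite PCR.
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param n_sites Number of CpG sites (>= 2).
#' @param spacing Integer vector of candidate inter-site gaps in bp.
#' @param start Genomic position of the first CpG.
#' @param name,chromosome Labels.
#' @return A [cpg_locus()].
#' @export
random_locus <- function(n_sites, spacing = 4:10, start = 1000L,
                         name = "sim_locus", chromosome = "simN") {
  stopifnot(n_sites >= 2, all(spacing >= 1))
  gaps <- sample(spacing, n_sites - 1L, replace = TRUE)
  pos <- as.integer(start) + c(0L, cumsum(gaps))
  cpg_locus(name, chromosome, pos)
}
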