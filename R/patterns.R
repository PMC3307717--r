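#' Double-stranded methylation patterns
#'
#' A container for the molecules of one hairpin-bisulfite dataset. Each
#' molecule contributes two aligned strands of per-CpG methylation calls
#' (1 methylated, 0 unmethylated, NA unread); which strand is the parent and
#' which the daughter is unknown. Identical ascertained molecules may be
#' collapsed with a multiplicity count.
#'
#' @param ids Character vector of pattern identifiers.
#' @param strand_a,strand_b Integer matrices (patterns x sites) with entries
#'   0/1/NA, or character vectors of strings over `0`, `1`, `?`.
#' @param multiplicity Positive integer vector of molecule counts per
#'   pattern (default all 1).
#' @return An object of class `"methyl_patterns"`: list with `id`, `a`, `b`
#'   (integer matrices) and `mult`.
#' @examples
#' p <- methyl_patterns("p1", "101", "111")
#' classify_dyads(p)
#' @export
methyl_patterns <- function(ids, strand_a, strand_b, multiplicity = NULL) {
  if (is.character(strand_a)) strand_a <- .parse_strands(strand_a)
  if (is.character(strand_b)) strand_b <- .parse_strands(strand_b)
  strand_a <- rbind(strand_a); strand_b <- rbind(strand_b)
  storage.mode(strand_a) <- "integer"; storage.mode(strand_b) <- "integer"
  n <- nrow(strand_a)
  if (nrow(strand_b) != n || length(ids) != n)
    stop("ids, strand_a and strand_b must describe the same number of patterns")
  if (ncol(strand_a) != ncol(strand_b))
    stop("strand_a and strand_b must have the same number of CpG sites")
  if (is.null(multiplicity)) multiplicity <- rep(1L, n)
  multiplicity <- as.integer(multiplicity)
  if (length(multiplicity) != n || any(is.na(multiplicity)) || any(multiplicity < 1L))
    stop("multiplicity must be positive integers, one per pattern")
  ok <- function(m) all(is.na(m) | m == 0L | m == 1L)
  if (!ok(strand_a) || !ok(strand_b))
    stop("strand entries must be 0, 1 or NA")
  structure(list(id = as.character(ids), a = strand_a, b = strand_b,
                 mult = multiplicity),
            class = "methyl_patterns")
}

.parse_strands <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)
  len <- lengths(chars)
  if (length(unique(len)) > 1L)
    stop("strand strings have unequal lengths")
  bad <- vapply(chars, function(ch) any(!ch %in% c("0", "1", "?")), logical(1))
  if (any(bad))
    stop("illegal character in strand string (allowed: 0, 1, ?): pattern ",
         which(bad)[1])
  t(vapply(chars, function(ch) {
    v <- suppressWarnings(as.integer(ch)); v
  }, integer(len[1])))
}

#' @export
print.methyl_patterns <- function(x, ...) {
  cat(sprintf("methyl_patterns: %d distinct patterns (%d molecules), %d CpG sites\n",
              length(x$id), sum(x$mult), ncol(x$a)))
  invisible(x)
}

#' @export
length.methyl_patterns <- function(x) length(x$id)

#' Subset patterns
#' @param x A [methyl_patterns()] container.
#' @param i Index vector.
#' @param ... Unused.
#' @return A `methyl_patterns` container with the selected patterns.
#' @export
`[.methyl_patterns` <- function(x, i, ...) {
  methyl_patterns(x$id[i], x$a[i, , drop = FALSE], x$b[i, , drop = FALSE],
                  x$mult[i])
}

#' Read / write a pattern file
#'
#' The pattern file is a TSV with header
#' `pattern_id<TAB>strand_a<TAB>strand_b<TAB>count`; strand strings are over
#' `0` (unmethylated), `1` (methylated) and `?` (unread). Lines starting
#' with `#` are comments.
#'
#' @param path File path.
#' @param locus A [cpg_locus()]; strand lengths are validated against its
#'   site count.
#' @return `read_patterns()` returns a [methyl_patterns()] container;
#'   `write_patterns()` returns `path` invisibly.
#' @export
read_patterns <- function(path, locus) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no records in pattern file ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # header line required
  if (!identical(tolower(fields[[1]][1]), "pattern_id"))
    stop("pattern file ", path, " lacks the pattern_id header line")
  fields <- fields[-1]; lineno <- lineno[-1]
  if (!length(fields)) stop("no pattern records in ", path)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed record at line ", lineno[which(nf != 4L)[1]], " of ",
         path, " (expected 4 tab-separated fields)")
  rec <- do.call(rbind, fields)
  cnt <- suppressWarnings(as.integer(rec[, 4]))
  if (any(is.na(cnt) | cnt < 1L))
    stop("invalid count at line ", lineno[which(is.na(cnt) | cnt < 1L)[1]],
         " of ", path)
  S <- n_sites(locus)
  badlen <- nchar(rec[, 2]) != S | nchar(rec[, 3]) != S
  if (any(badlen))
    stop("strand length mismatch at line ", lineno[which(badlen)[1]], " of ",
         path, " (locus has ", S, " CpG sites)")
  pats <- tryCatch(
    methyl_patterns(rec[, 1], rec[, 2], rec[, 3], cnt),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  pats
}

#' @rdname read_patterns
#' @param patterns A [methyl_patterns()] container.
#' @param comments Optional character vector written as leading `#` lines.
#' @export
write_patterns <- function(patterns, path, comments = NULL) {
  enc <- function(m) apply(m, 1, function(r) {
    r <- as.character(r); r[is.na(r)] <- "?"; paste(r, collapse = "")
  })
  out <- c(if (length(comments)) paste0("# ", comments),
           "pattern_id\tstrand_a\tstrand_b\tcount",
           paste(patterns$id, enc(patterns$a), enc(patterns$b),
                 patterns$mult, sep = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' Classify CpG dyads
#'
#' Each CpG site of a pattern, read jointly on the two strands, is a dyad:
#' fully methylated (`M`), hemimethylated with the methyl on strand A
#' (`Ha`) or strand B (`Hb`), unmethylated (`U`), or `NA` if either strand
#' is unread at the site.
#'
#' @param patterns A [methyl_patterns()] container.
#' @return Character matrix (patterns x sites) over `M`, `Ha`, `Hb`, `U`, NA.
#' @export
classify_dyads <- function(patterns) {
  a <- patterns$a; b <- patterns$b
  out <- matrix(NA_character_, nrow(a), ncol(a))
  out[a == 1L & b == 1L] <- "M"
  out[a == 1L & b == 0L] <- "Ha"
  out[a == 0L & b == 1L] <- "Hb"
  out[a == 0L & b == 0L] <- "U"
  rownames(out) <- patterns$id
  out
}

# maximal runs (length >= 2) of same-orientation hemi dyads in one
# molecule's dyad sequence; returns integer vector of run lengths
.hemi_runs <- function(dyads) {
  r <- rle(ifelse(is.na(dyads), "na", dyads))
  r$lengths[r$values %in% c("Ha", "Hb") & r$lengths >= 2L]
}

#' Summarize a pattern dataset
#'
#' Computes the dyad-class percentages (fully methylated, hemimethylated,
#' unmethylated, over all scored dyads weighted by multiplicity) and the
#' tabulation of maximal runs of >= 2 consecutive hemimethylated dyads with
#' the methyl groups on the same strand. Runs are broken by a non-hemi dyad,
#' an unread dyad, or a hemi of the opposite orientation.
#'
#' @param patterns A [methyl_patterns()] container.
#' @param locus Optional [cpg_locus()] used only for labelling.
#' @return An object of class `"methyl_summary"`: list with `n_patterns`
#'   (molecule count), `n_sites`, `pct_M`, `pct_H`, `pct_U`,
#'   `hemi_run_counts` (named vector for run lengths 2,3,4,5,>=6) and
#'   `locus_name`.
#' @export
summarize_patterns <- function(patterns, locus = NULL) {
  if (!length(patterns$id)) stop("empty dataset")
  dy <- classify_dyads(patterns)
  w <- patterns$mult
  wm <- matrix(w, nrow(dy), ncol(dy))
  scored <- !is.na(dy)
  tot <- sum(wm[scored])
  if (tot == 0) stop("no scored dyads in dataset")
  cnt <- function(cls) sum(wm[scored & dy %in% cls])
  runs <- integer(0)
  for (i in seq_len(nrow(dy)))
    runs <- c(runs, rep(.hemi_runs(dy[i, ]), w[i]))
  run_counts <- c(`2` = sum(runs == 2L), `3` = sum(runs == 3L),
                  `4` = sum(runs == 4L), `5` = sum(runs == 5L),
                  `>=6` = sum(runs >= 6L))
  structure(list(
    n_patterns = sum(w), n_sites = ncol(dy),
    pct_M = 100 * cnt("M") / tot,
    pct_H = 100 * cnt(c("Ha", "Hb")) / tot,
    pct_U = 100 * cnt("U") / tot,
    hemi_run_counts = run_counts,
    locus_name = if (is.null(locus)) NA_character_ else locus$name),
    class = "methyl_summary")
}

#' @export
print.methyl_summary <- function(x, ...) {
  if (!is.na(x$locus_name)) cat("Locus:", x$locus_name, "\n")
  cat(sprintf("No. of ds patterns: %d (%d CpG sites)\n", x$n_patterns, x$n_sites))
  cat(sprintf("%% of M, H, U dyads: (%.0f, %.0f, %.0f)\n",
              x$pct_M, x$pct_H, x$pct_U))
  cat("Runs of same-orientation hemimethylated dyads:\n")
  for (k in names(x$hemi_run_counts))
    cat(sprintf("  runs of %s hemis: %d\n", k, x$hemi_run_counts[[k]]))
  invisible(x)
}

#' Write a dataset summary as TSV
#' @param x A `"methyl_summary"` from [summarize_patterns()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  rows <- c(
    sprintf("n_ds_patterns\t%d", x$n_patterns),
    sprintf("n_cpg_sites\t%d", x$n_sites),
    sprintf("pct_methylated\t%.2f", x$pct_M),
    sprintf("pct_hemimethylated\t%.2f", x$pct_H),
    sprintf("pct_unmethylated\t%.2f", x$pct_U),
    sprintf("runs_of_%s_hemis\t%d", names(x$hemi_run_counts),
            x$hemi_run_counts))
  writeLines(c("statistic\tvalue", rows), path)
  invisible(path)
}

#' Permutation test for clustering of hemimethylated dyads
#'
#' Runs of hemimethylated dyads with the methyl groups on the same strand
#' carry the signal of processive enzyme behaviour. The observed statistic
#' is the number of adjacent site pairs (within a molecule) where both
#' dyads are hemimethylated with the same orientation, summed over
#' molecules. The null distribution permutes each molecule's dyad sequence
#' across site order independently, preserving per-molecule dyad
#' composition while destroying spatial adjacency.
#'
#' This test is a reconstruction of the adjacent-site correlation
#' permutation test used with such data; the exact published permutation
#' scheme is not fully specified in the primary literature.
#'
#' @param patterns A [methyl_patterns()] container.
#' @param n_perm Number of permutation replicates (>= 100).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `statistic` (observed count), `p_value`
#'   (= (1 + #\{null >= observed\}) / (1 + n_perm)), and `n_perm`.
#' @export
adjacent_hemi_permutation_test <- function(patterns, n_perm = 1000L,
                                           seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  dy <- classify_dyads(patterns)
  # expand multiplicities: identical molecules are permuted independently
  dy <- dy[rep(seq_len(nrow(dy)), patterns$mult), , drop = FALSE]
  stat <- function(mat) {
    s1 <- mat[, -ncol(mat), drop = FALSE]
    s2 <- mat[, -1, drop = FALSE]
    sum(!is.na(s1) & !is.na(s2) & s1 == s2 & s1 %in% c("Ha", "Hb"))
  }
  obs <- stat(dy)
  S <- ncol(dy)
  null <- vapply(seq_len(n_perm), function(i) {
    perm <- t(apply(dy, 1, sample, size = S))
    stat(perm)
  }, numeric(1))
  list(statistic = obs,
       p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       n_perm = as.integer(n_perm))
}

#' Probability of PCR-crossover artifacts in a dataset
#'
#' PCR crossover produces chimeric molecules that hybridize two distinct
#' patterns. Under a binomial model with a per-molecule crossover rate, the
#' probability that at least one of the ascertained molecules arose from
#' `n_crossovers` crossover events is
#' `1 - (1 - rate^n_crossovers)^n_molecules`.
#'
#' @param n_molecules Number of ascertained molecules (>= 1).
#' @param per_molecule_rate Per-molecule crossover probability in `[0, 1]`.
#' @param n_crossovers Number of crossover events required (>= 1).
#' @return Probability in `[0, 1]`.
#' @examples
#' crossover_probability(169, 0.01, 1)  # ~0.82
#' crossover_probability(169, 0.01, 2)  # ~0.017
#' @export
crossover_probability <- function(n_molecules, per_molecule_rate,
                                  n_crossovers = 1L) {
  stopifnot(n_molecules >= 1, n_crossovers >= 1,
            per_molecule_rate >= 0, per_molecule_rate <= 1)
  1 - (1 - per_molecule_rate^n_crossovers)^n_molecules
}
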