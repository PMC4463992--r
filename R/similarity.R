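# The nine-parameter similarity of an ordered protein pair. The first
# argument is always the query protein: the per-shell and scalar similarity
# formulas divide by the query's value, so the score is deliberately
# asymmetric and may be negative (no clamping anywhere upstream of the
# network priors).

#' Radial layer scheme
#'
#' A layer scheme partitions radial distances into concentric shells using
#' half-open intervals `[lower, upper)`; the final shell is open-ended. The
#' default scheme has 10 shells with boundaries at 10, 20, 30, 40, 50, 60,
#' 70, 80 and 100 length units, the tenth shell collecting everything beyond
#' 100.
#'
#' @param breakpoints Strictly increasing positive numeric vector of shell
#'   upper boundaries; a scheme with `k` breakpoints has `k + 1` shells.
#' @return An object of class `layer_scheme`.
#' @export
layer_scheme <- function(breakpoints) {
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints) < 1L || any(!is.finite(breakpoints)) ||
      any(breakpoints <= 0) || any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be a strictly increasing vector of positive radii")
  }
  structure(list(breakpoints = breakpoints, n_shells = length(breakpoints) + 1L),
            class = "layer_scheme")
}

#' @rdname layer_scheme
#' @export
default_layer_scheme <- function() {
  layer_scheme(c(10, 20, 30, 40, 50, 60, 70, 80, 100))
}

#' @export
print.layer_scheme <- function(x, ...) {
  cat(sprintf("<layer_scheme> %d shells; boundaries: %s (last shell open-ended)\n",
              x$n_shells, paste(x$breakpoints, collapse = ", ")))
  invisible(x)
}

.same_scheme <- function(a, b) {
  length(a$breakpoints) == length(b$breakpoints) &&
    all(a$breakpoints == b$breakpoints)
}

#' Shell index of each radius
#'
#' Assigns every radius to exactly one shell under the half-open convention:
#' a radius equal to a boundary belongs to the outer shell (radius 10 under
#' the default scheme falls in shell 2).
#'
#' @param radii Non-negative numeric vector.
#' @param scheme A [layer_scheme].
#' @return Integer vector of shell indices in `1:n_shells`.
#' @export
shell_index <- function(radii, scheme = default_layer_scheme()) {
  stopifnot(inherits(scheme, "layer_scheme"))
  if (any(radii < 0)) stop("radii must be non-negative")
  findInterval(radii, scheme$breakpoints) + 1L
}

#' Per-shell atom counts of a structure or radius vector
#'
#' Counts the atoms falling in each shell of the scheme; the counts sum to
#' the total number of atoms.
#'
#' @param x A [protein_structure] or a non-negative numeric vector of radial
#'   distances.
#' @param scheme A [layer_scheme].
#' @return An object of class `layer_profile`: list with integer `counts`
#'   (one per shell), `total`, and the `scheme`.
#' @export
layer_profile <- function(x, scheme = default_layer_scheme()) {
  radii <- if (inherits(x, "protein_structure")) radial_distances(x) else as.numeric(x)
  idx <- shell_index(radii, scheme)
  counts <- tabulate(idx, nbins = scheme$n_shells)
  structure(list(counts = as.integer(counts), total = length(radii), scheme = scheme),
            class = "layer_profile")
}

#' @export
print.layer_profile <- function(x, ...) {
  cat(sprintf("<layer_profile> %d atoms in %d shells: [%s]\n",
              x$total, x$scheme$n_shells, paste(x$counts, collapse = ", ")))
  invisible(x)
}

.as_profile <- function(x, scheme) {
  if (inherits(x, "layer_profile")) {
    if (!.same_scheme(x$scheme, scheme)) {
      stop("layer profiles were built under different layer schemes")
    }
    x
  } else {
    layer_profile(x, scheme)
  }
}

#' Per-shell similarity of two layer profiles
#'
#' For shell i with query count `l1` and target count `l2`,
#' `sim_i = 1 - |l1 - l2| / l1`. The value can be negative when the target
#' holds more than twice the query's atoms. Shells empty in the query are
#' undefined under the formula; they score 1 when the target shell is also
#' empty and 0 otherwise, which preserves the self-similarity identity.
#'
#' @param p1 Query [layer_profile] (reference denominator).
#' @param p2 Target [layer_profile] under the same scheme.
#' @return Numeric vector with one similarity per shell.
#' @export
per_layer_similarity <- function(p1, p2) {
  stopifnot(inherits(p1, "layer_profile"), inherits(p2, "layer_profile"))
  if (!.same_scheme(p1$scheme, p2$scheme)) {
    stop("layer profiles were built under different layer schemes")
  }
  l1 <- p1$counts
  l2 <- p2$counts
  sim <- ifelse(l1 > 0, 1 - abs(l1 - l2) / l1, ifelse(l2 == 0, 1, 0))
  as.numeric(sim)
}

#' Shell weights for the density similarity
#'
#' Shell i is weighted by the average of the two proteins' atom-count
#' fractions in that shell: `w_i = (l1_i/n1 + l2_i/n2) / 2`. The weights sum
#' to 1 by construction.
#'
#' @inheritParams per_layer_similarity
#' @return Numeric vector of weights summing to 1.
#' @export
layer_weights <- function(p1, p2) {
  stopifnot(inherits(p1, "layer_profile"), inherits(p2, "layer_profile"))
  if (!.same_scheme(p1$scheme, p2$scheme)) {
    stop("layer profiles were built under different layer schemes")
  }
  if (p1$total == 0L || p2$total == 0L) stop("layer profiles must be non-empty")
  (p1$counts / p1$total + p2$counts / p2$total) / 2
}

#' Radial-shell density similarity
#'
#' The weighted sum of per-shell similarities under the shell weights:
#' `sum_i w_i * sim_i`. Equals exactly 1 when the two structures have
#' identical layer profiles.
#'
#' @param x1 Query [protein_structure] or [layer_profile].
#' @param x2 Target [protein_structure] or [layer_profile].
#' @param scheme A [layer_scheme]; ignored for inputs that already are
#'   profiles (their scheme must match).
#' @return Single numeric similarity (at most 1, possibly negative).
#' @export
density_similarity <- function(x1, x2, scheme = default_layer_scheme()) {
  p1 <- .as_profile(x1, scheme)
  p2 <- .as_profile(x2, scheme)
  sum(layer_weights(p1, p2) * per_layer_similarity(p1, p2))
}

#' Relative scalar similarity
#'
#' `1 - |n1 - n2| / n1`, with the query's value `n1` as the denominator.
#' Used for atom counts, residue counts, residue-type counts and elemental
#' proportions. The value is not clamped and goes negative once `n2`
#' exceeds `2 * n1`.
#'
#' @param n1 Query value, strictly positive.
#' @param n2 Target value, non-negative.
#' @return Single numeric similarity (at most 1).
#' @export
scalar_similarity <- function(n1, n2) {
  stopifnot(is.numeric(n1), is.numeric(n2), length(n1) == 1L, length(n2) == 1L)
  if (!is.finite(n1) || n1 <= 0) stop("the query value n1 must be positive")
  if (!is.finite(n2) || n2 < 0) stop("the target value n2 must be non-negative")
  1 - abs(n1 - n2) / n1
}

#' Atom, residue and residue-type counts
#'
#' `count_atoms` is the number of accepted atom records; `count_residues`
#' counts distinct (chain, residue number) pairs; `count_residue_types`
#' counts distinct residue names among the 20 standard amino acids.
#'
#' @param s A [protein_structure].
#' @return Single integer.
#' @export
count_atoms <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  nrow(s$atoms)
}

#' @rdname count_atoms
#' @export
count_residues <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  nrow(unique(s$atoms[, c("chain", "resno")]))
}

#' @rdname count_atoms
#' @export
count_residue_types <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  length(intersect(unique(s$atoms$resname), STANDARD_AA))
}

#' Fraction of atoms of one element
#'
#' @param s A [protein_structure].
#' @param element Element symbol (e.g. `"C"`).
#' @return Fraction in `[0, 1]`.
#' @export
element_fraction <- function(s, element) {
  stopifnot(inherits(s, "protein_structure"), is.character(element))
  mean(s$atoms$element == toupper(element))
}

#' Positional similarity of a sparse element (P or S)
#'
#' Phosphorus and sulfur are too scarce for count-based comparison, so their
#' radial position is compared instead: atoms of the element in the same
#' shell score 1.0, in adjacent shells 0.8, otherwise 0. When either protein
#' carries several such atoms the best-matching pair counts (the rule
#' reduces to the single-atom case). If both proteins lack the element the
#' score is 1.0 (full agreement in absence); if exactly one lacks it, 0.0.
#'
#' @param s1 Query [protein_structure].
#' @param s2 Target [protein_structure].
#' @param element `"P"` or `"S"`.
#' @param scheme A [layer_scheme].
#' @return One of 1.0, 0.8, 0.0.
#' @export
element_position_similarity <- function(s1, s2, element,
                                        scheme = default_layer_scheme()) {
  element <- toupper(element)
  if (!element %in% c("P", "S")) stop("positional similarity is defined for elements P and S")
  sh1 <- shell_index(radial_distances(s1), scheme)[s1$atoms$element == element]
  sh2 <- shell_index(radial_distances(s2), scheme)[s2$atoms$element == element]
  if (length(sh1) == 0L && length(sh2) == 0L) return(1.0)
  if (length(sh1) == 0L || length(sh2) == 0L) return(0.0)
  d <- min(abs(outer(sh1, sh2, "-")))
  if (d == 0L) 1.0 else if (d == 1L) 0.8 else 0.0
}

#' The nine-parameter similarity vector of an ordered pair
#'
#' Assembles, for query `s1` against target `s2`:
#' s1 shell-density similarity, s2 atom-count similarity, s3 residue-count
#' similarity, s4 residue-type-count similarity, s5/s6/s7 C/N/O proportion
#' similarities, s8 phosphorus positional similarity, s9 sulfur positional
#' similarity. Comparing a structure with itself gives all nine equal to 1.
#'
#' @inheritParams element_position_similarity
#' @return Named numeric vector `s1` ... `s9`.
#' @export
parameter_vector <- function(s1, s2, scheme = default_layer_scheme()) {
  stopifnot(inherits(s1, "protein_structure"), inherits(s2, "protein_structure"))
  c(
    s1 = density_similarity(s1, s2, scheme),
    s2 = scalar_similarity(count_atoms(s1), count_atoms(s2)),
    s3 = scalar_similarity(count_residues(s1), count_residues(s2)),
    s4 = scalar_similarity(count_residue_types(s1), count_residue_types(s2)),
    s5 = scalar_similarity(element_fraction(s1, "C"), element_fraction(s2, "C")),
    s6 = scalar_similarity(element_fraction(s1, "N"), element_fraction(s2, "N")),
    s7 = scalar_similarity(element_fraction(s1, "O"), element_fraction(s2, "O")),
    s8 = element_position_similarity(s1, s2, "P", scheme),
    s9 = element_position_similarity(s1, s2, "S", scheme)
  )
}

#' Overall weighted similarity
#'
#' Plain dot product of the nine parameter similarities with the nine
#' weights; no clamping or normalisation. With the packaged trained weights
#' an all-ones vector scores 1.0007 (the weights' sum), so self-similarity
#' slightly exceeds 1 by construction of the published weights.
#'
#' @param v Numeric vector of nine parameter similarities (s1..s9).
#' @param w Numeric vector of nine weights (defaults to [table1_weights()]).
#' @return Single numeric score.
#' @export
overall_similarity <- function(v, w = table1_weights()) {
  v <- as.numeric(v)
  w <- as.numeric(w)
  if (length(v) != 9L || length(w) != 9L) {
    stop("the parameter and weight vectors must both have nine components")
  }
  if (any(!is.finite(v)) || any(!is.finite(w))) stop("similarities and weights must be finite")
  sum(v * w)
}

#' Rank reference proteins by overall similarity
#'
#' Recomputes the overall weighted similarity for each named nine-parameter
#' row and orders the proteins by descending score, breaking ties by name so
#' the ranking is deterministic and independent of input order.
#'
#' @param rows `data.frame` with a `protein` column (or row names) and
#'   columns `s1` ... `s9`.
#' @param w Nine weights; defaults to [table1_weights()].
#' @return `data.frame` with columns `protein` and `score`, ordered by
#'   descending score.
#' @export
rank_reference_proteins <- function(rows, w = table1_weights()) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  cols <- paste0("s", 1:9)
  if (!all(cols %in% names(rows))) {
    stop("rows must contain the nine similarity columns s1..s9")
  }
  protein <- if ("protein" %in% names(rows)) as.character(rows$protein) else rownames(rows)
  score <- apply(as.matrix(rows[, cols]), 1L, overall_similarity, w = w)
  out <- data.frame(protein = protein, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}
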