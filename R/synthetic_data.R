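# Generators for every input the pipeline consumes: point-cloud structures
# with controlled radial density and element composition, training tables
# from a known weight vector, and signed DAGs with a planted dominant
# pathway. Each generator is deterministic under its seed and returns its
# ground truth alongside the data, so downstream tests never re-derive it.

#' Specification of a synthetic structure
#'
#' Describes a point-cloud "protein": how many atoms, how their radial
#' density distributes over the shells of a layer scheme, the element
#' composition, and a residue plan. The default shell profile mimics a
#' compact globular structure: the bulk of the atoms inside the first eight
#' shells, a small fraction in the ninth and very few beyond.
#'
#' @param n_atoms Total atom count (>= 1).
#' @param shell_fractions Target fraction of atoms per shell; length must
#'   equal the scheme's shell count and the fractions must sum to 1.
#' @param elements Named non-negative composition weights (e.g.
#'   `c(C = .62, N = .17, O = .20, S = .01)`); converted to planned integer
#'   counts by largest remainder.
#' @param n_residues Number of residues; atoms are split into contiguous
#'   runs. Default about one residue per eight atoms.
#' @param residue_types Optional character vector of residue names to draw
#'   from; default the 20 standard amino acids.
#' @param pin_elements Optional named integer vector mapping an element
#'   symbol to a shell index: all atoms of that element are placed in that
#'   shell (used to stage P/S positional comparisons).
#' @param seed Integer seed.
#' @param scheme A [layer_scheme].
#' @return List of class `structure_spec`.
#' @export
structure_spec <- function(n_atoms = 500L,
                           shell_fractions = c(0.05, 0.10, 0.15, 0.20, 0.20,
                                               0.12, 0.08, 0.05, 0.04, 0.01),
                           elements = c(C = 0.62, N = 0.17, O = 0.20, S = 0.01),
                           n_residues = NULL,
                           residue_types = NULL,
                           pin_elements = NULL,
                           seed = 1L,
                           scheme = default_layer_scheme()) {
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 1L) stop("a structure needs at least one atom")
  if (length(shell_fractions) != scheme$n_shells) {
    stop("shell_fractions must have one entry per shell of the scheme")
  }
  if (any(shell_fractions < 0) || abs(sum(shell_fractions) - 1) > 1e-8) {
    stop("shell_fractions must be non-negative and sum to 1")
  }
  if (is.null(names(elements)) || any(elements < 0) || sum(elements) <= 0) {
    stop("elements must be a named non-negative composition with positive total")
  }
  if (is.null(n_residues)) n_residues <- max(1L, round(n_atoms / 8))
  if (is.null(residue_types)) residue_types <- STANDARD_AA
  structure(list(n_atoms = n_atoms, shell_fractions = shell_fractions,
                 elements = elements / sum(elements),
                 n_residues = as.integer(n_residues),
                 residue_types = residue_types,
                 pin_elements = pin_elements,
                 seed = as.integer(seed), scheme = scheme),
            class = "structure_spec")
}

# Integer apportionment by largest remainder: counts sum exactly to n.
.largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(short)]] <- counts[o[seq_len(short)]] + 1L
  }
  as.integer(counts)
}

# Shell bounds [lo, hi) with a sampling margin so the planned shell
# assignment survives the tiny residual of the recentring step. The last
# (open-ended) shell is sampled within 15 units above its lower bound.
.shell_bounds <- function(scheme) {
  lo <- c(0, scheme$breakpoints)
  hi <- c(scheme$breakpoints, scheme$breakpoints[length(scheme$breakpoints)] + 15)
  cbind(lo = lo, hi = hi)
}

.sample_radius_in_shell <- function(shell, scheme, n) {
  b <- .shell_bounds(scheme)
  width <- b[shell, "hi"] - b[shell, "lo"]
  margin <- pmin(0.5, width / 4)
  stats::runif(n, b[shell, "lo"] + margin, b[shell, "hi"] - margin)
}

# Rebuild coordinates with prescribed radii and directions while driving the
# geometric center to ~0: alternately recenter and restore each atom's
# radius. The residual center offset after convergence is orders of
# magnitude below the 0.25-unit sampling margin, so shell membership of
# every atom is exactly as planned.
.center_with_fixed_radii <- function(P, radii, max_iter = 500L, tol = 1e-10) {
  for (it in seq_len(max_iter)) {
    m <- colMeans(P)
    if (max(abs(m)) < tol) return(P)
    P <- sweep(P, 2L, m)
    nr <- sqrt(rowSums(P^2))
    nr[nr == 0] <- 1
    P <- P * (radii / nr)
  }
  warning("recentring did not fully converge; residual center offset ",
          format(max(abs(colMeans(P))), digits = 3))
  P
}

#' Generate a synthetic structure with known ground truth
#'
#' Samples atoms shell by shell: radii uniform within each shell (with a
#' safety margin from the boundaries), directions uniform on the sphere,
#' then recentres the cloud so its geometric center coincides with the
#' sampling origin while every atom keeps its planned radius. Per-shell
#' counts and element counts are planned integers (largest remainder), not
#' sampled, so [layer_profile()] recovers them exactly. Elements and
#' residues are assigned per the spec; `pin_elements` forces all atoms of an
#' element into one shell.
#'
#' @param spec A [structure_spec()].
#' @param id Structure identifier.
#' @param path Optional path; when given the structure is also written as a
#'   PDB-format fixture via [write_structure()].
#' @return List with `structure` (a [protein_structure]) and `truth`:
#'   planned `shell_counts`, `element_counts`, `n_residues`,
#'   `n_residue_types`, per-atom `shells` and `radii`.
#' @export
make_structure <- function(spec, id = "synthetic", path = NULL) {
  stopifnot(inherits(spec, "structure_spec"))
  set.seed(spec$seed)
  n <- spec$n_atoms
  scheme <- spec$scheme

  shell_counts <- .largest_remainder(spec$shell_fractions, n)
  shells <- rep(seq_len(scheme$n_shells), shell_counts)
  if (n == 1L) {
    # A single atom is its own center: radius 0, shell 1 by convention.
    if (shells[1L] != 1L) stop("a 1-atom structure can only occupy shell 1")
    radii <- 0
    P <- matrix(0, 1L, 3L)
  } else {
    radii <- numeric(n)
    for (sh in which(shell_counts > 0L)) {
      radii[shells == sh] <- .sample_radius_in_shell(sh, scheme, shell_counts[sh])
    }
    dirs <- matrix(stats::rnorm(3L * n), n, 3L)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    P <- .center_with_fixed_radii(dirs * radii, radii)
  }

  element_counts <- .largest_remainder(spec$elements, n)
  names(element_counts) <- names(spec$elements)
  if (sum(element_counts) != n) stop("element apportionment failed")
  element <- character(n)
  assigned <- rep(FALSE, n)
  for (el in names(spec$pin_elements)) {
    k <- element_counts[[el]]
    if (is.null(k) || k == 0L) next
    target_shell <- spec$pin_elements[[el]]
    cand <- which(shells == target_shell & !assigned)
    if (length(cand) < k) {
      stop(sprintf("cannot pin %d %s atom(s) to shell %d: only %d atoms planned there",
                   k, el, target_shell, length(cand)))
    }
    pick <- if (length(cand) == 1L) cand else sample(cand, k)
    element[pick] <- el
    assigned[pick] <- TRUE
  }
  # remaining labels = full multiset minus the pinned ones
  full <- rep(names(element_counts), element_counts)
  for (el in names(spec$pin_elements)) {
    k <- element_counts[[el]]
    if (!is.null(k) && k > 0L) full <- full[-which(full == el)[seq_len(k)]]
  }
  open_idx <- which(!assigned)
  element[open_idx] <- sample(full, length(full))

  resno <- sort(rep_len(seq_len(spec$n_residues), n))
  types <- sample(spec$residue_types, spec$n_residues, replace = TRUE)
  resname <- types[resno]

  s <- protein_structure(id, data.frame(
    element = element,
    x = P[, 1L], y = P[, 2L], z = P[, 3L],
    resname = resname, resno = resno, chain = "A",
    stringsAsFactors = FALSE
  ))
  if (!is.null(path)) write_structure(s, path)
  list(
    structure = s,
    truth = list(
      shell_counts = shell_counts,
      element_counts = element_counts,
      n_residues = spec$n_residues,
      n_residue_types = length(intersect(unique(types), STANDARD_AA)),
      shells = shells,
      radii = radii
    )
  )
}

#' Relocate a fraction of atoms to different shells
#'
#' Moves `round(fraction * n)` atoms, chosen at random, each to a uniformly
#' chosen different shell (new radius uniform within that shell, direction
#' kept), then recentres with fixed radii so shell membership is exact.
#' Designed for generator output (radii sampled away from boundaries); used
#' to check that the density similarity degrades as structures diverge.
#'
#' @param s A [protein_structure] produced by [make_structure()].
#' @param fraction Fraction of atoms to relocate, in `[0, 1]`.
#' @param seed Integer seed.
#' @param scheme A [layer_scheme].
#' @return A [protein_structure] with the same atoms at new positions.
#' @export
perturb_structure <- function(s, fraction, seed = 1L,
                              scheme = default_layer_scheme()) {
  stopifnot(inherits(s, "protein_structure"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  set.seed(seed)
  n <- nrow(s$atoms)
  if (round(fraction * n) == 0L) return(s)
  ctr <- geometric_center(s)
  P <- cbind(s$atoms$x - ctr[[1]], s$atoms$y - ctr[[2]], s$atoms$z - ctr[[3]])
  radii <- sqrt(rowSums(P^2))
  shells <- shell_index(radii, scheme)
  k <- round(fraction * n)
  if (k > 0L) {
    move <- if (n == 1L) 1L else sample(n, k)
    for (i in move) {
      other <- setdiff(seq_len(scheme$n_shells), shells[i])
      new_shell <- other[sample.int(length(other), 1L)]
      radii[i] <- .sample_radius_in_shell(new_shell, scheme, 1L)
      shells[i] <- new_shell
    }
    dirs <- P / ifelse(sqrt(rowSums(P^2)) == 0, 1, sqrt(rowSums(P^2)))
    zero <- rowSums(dirs^2) == 0
    if (any(zero)) {
      d <- matrix(stats::rnorm(3L * sum(zero)), ncol = 3L)
      dirs[zero, ] <- d / sqrt(rowSums(d^2))
    }
    P <- .center_with_fixed_radii(dirs * radii, radii)
  }
  out <- s
  out$atoms$x <- P[, 1L]
  out$atoms$y <- P[, 2L]
  out$atoms$z <- P[, 3L]
  out
}

#' Generate a labelled training table from known weights
#'
#' Draws nine feature similarities uniformly in `[-0.5, 1]` — mirroring the
#' observed range of real parameter similarities, negatives included — and
#' labels each row with the dot product under `true_weights` plus Gaussian
#' noise. Stands in for homology-labelled protein pairs; `n = 100` matches
#' the size of the original training collection.
#'
#' @param true_weights Nine generating weights.
#' @param n Number of pairs.
#' @param noise_sd Label noise standard deviation (0 for noiseless).
#' @param seed Integer seed.
#' @return 10-column `data.frame` (`S1` ... `S9`, `S`) with the generating
#'   weights in `attr(, "true_weights")`.
#' @export
make_training_set <- function(true_weights = table1_weights(), n = 100L,
                              noise_sd = 0.05, seed = 1L) {
  true_weights <- as.numeric(true_weights)
  if (length(true_weights) != 9L) stop("true_weights must have nine components")
  if (n < 1L) stop("n must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)
  X <- matrix(stats::runif(9L * n, -0.5, 1), n, 9L)
  y <- drop(X %*% true_weights) + stats::rnorm(n, 0, noise_sd)
  tab <- as.data.frame(X)
  names(tab) <- paste0("S", 1:9)
  tab$S <- y
  attr(tab, "true_weights") <- stats::setNames(true_weights, paste0("q", 1:9))
  tab
}

#' Specification of a synthetic signed network
#'
#' A layered DAG of parallel source-to-sink chains with optional crossing
#' edges. One planted source receives a prior exceeding every other
#' source's by at least `margin` and an all-activating chain to the sink,
#' which guarantees (in union/path semantics) that its chain is the unique
#' maximum-probability pathway: a competing path's probability is either
#' its own source prior (<= planted - margin) or, after an odd number of
#' inhibiting edges, the complement of a prior, which stays below the
#' planted prior because competitor priors are kept above
#' `1 - planted_prior`.
#'
#' @param n_sources Number of source proteins (>= 1).
#' @param depth Number of edges in each chain (>= 1).
#' @param cross_p Probability of an extra crossing edge out of each
#'   non-planted internal node.
#' @param inhib_fraction Fraction of non-planted edges that inhibit.
#' @param margin Prior gap between the planted source and the best
#'   competitor, in `(0, planted_prior - 0.15]`.
#' @param planted_prior Prior of the planted source.
#' @param seed Integer seed.
#' @return List of class `network_spec`.
#' @export
network_spec <- function(n_sources = 5L, depth = 4L, cross_p = 0.25,
                         inhib_fraction = 0.25, margin = 0.4,
                         planted_prior = 0.9, seed = 1L) {
  if (n_sources < 1L) stop("n_sources must be >= 1")
  if (depth < 1L) stop("depth must be >= 1")
  if (cross_p < 0 || cross_p > 1 || inhib_fraction < 0 || inhib_fraction > 1) {
    stop("cross_p and inhib_fraction must be in [0, 1]")
  }
  if (planted_prior <= 0 || planted_prior > 1) stop("planted_prior must be in (0, 1]")
  lo <- 1 - planted_prior + 0.05
  if (margin <= 0 || planted_prior - margin < lo) {
    stop("margin must satisfy 0 < margin <= planted_prior - (1 - planted_prior) - 0.05")
  }
  structure(list(n_sources = as.integer(n_sources), depth = as.integer(depth),
                 cross_p = cross_p, inhib_fraction = inhib_fraction,
                 margin = margin, planted_prior = planted_prior,
                 seed = as.integer(seed)),
            class = "network_spec")
}

#' Generate a signed network with a planted dominant pathway
#'
#' Builds parallel chains `SRCj -> Nj_1 -> ... -> SINK`, one per source.
#' The planted chain (source `SRC1`) is all-activating and keeps the top
#' prior; competitor chain edges inhibit with probability `inhib_fraction`,
#' and non-planted internal nodes sprout crossing edges into strictly
#' deeper layers (possibly into the planted chain or the sink), so the
#' graph is acyclic by construction.
#'
#' @param spec A [network_spec()].
#' @return List with `network` (priors set), `priors`, and `top_path` (the
#'   planted chain as a character vector).
#' @export
make_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  set.seed(spec$seed)
  k <- spec$n_sources
  d <- spec$depth
  sink <- "SINK"
  src <- sprintf("SRC%d", seq_len(k))

  # layer l of chain j: l = 0 source, 1..d-1 internal, d sink
  node_at <- function(j, l) {
    if (l == 0L) src[j] else if (l == d) sink else sprintf("N%d_%d", j, l)
  }
  edges <- list()
  add_edge <- function(from, to, sgn) {
    edges[[length(edges) + 1L]] <<- data.frame(source = from, target = to,
                                               sign = sgn, stringsAsFactors = FALSE)
  }
  for (j in seq_len(k)) {
    for (l in seq_len(d)) {
      sgn <- if (j == 1L) "+" else {
        if (stats::runif(1) < spec$inhib_fraction) "-" else "+"
      }
      add_edge(node_at(j, l - 1L), node_at(j, l), sgn)
    }
  }
  if (k > 1L && d > 1L) {
    for (j in 2:k) {
      for (l in seq_len(d - 1L)) {
        if (stats::runif(1) < spec$cross_p) {
          deeper <- seq(l + 1L, d)
          l2 <- deeper[sample.int(length(deeper), 1L)]
          j2 <- sample.int(k, 1L)
          to <- node_at(j2, l2)
          from <- node_at(j, l)
          if (to != from) {
            sgn <- if (stats::runif(1) < spec$inhib_fraction) "-" else "+"
            add_edge(from, to, sgn)
          }
        }
      }
    }
  }
  edges <- do.call(rbind, edges)
  edges <- edges[!duplicated(edges[, c("source", "target")]), , drop = FALSE]

  lo <- 1 - spec$planted_prior + 0.05
  hi <- spec$planted_prior - spec$margin
  priors <- stats::setNames(c(spec$planted_prior,
                              if (k > 1L) stats::runif(k - 1L, lo, hi)),
                            src)
  net <- build_network(edges, sink = sink)
  net <- set_priors(net, priors)
  list(network = net, priors = priors,
       top_path = vapply(0:d, function(l) node_at(1L, l), character(1)))
}
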