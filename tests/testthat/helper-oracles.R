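# Independent brute-force recomputations used as oracles. These are written
# with plain loops and if-chains, deliberately sharing no code with the
# package implementation.

oracle_center <- function(s) {
  n <- nrow(s$atoms)
  cx <- cy <- cz <- 0
  for (i in seq_len(n)) {
    cx <- cx + s$atoms$x[i]
    cy <- cy + s$atoms$y[i]
    cz <- cz + s$atoms$z[i]
  }
  c(cx / n, cy / n, cz / n)
}

oracle_radii <- function(s) {
  ctr <- oracle_center(s)
  out <- numeric(nrow(s$atoms))
  for (i in seq_along(out)) {
    out[i] <- sqrt((s$atoms$x[i] - ctr[1])^2 +
                   (s$atoms$y[i] - ctr[2])^2 +
                   (s$atoms$z[i] - ctr[3])^2)
  }
  out
}

# Interval-membership count per shell: [lower, upper) with last shell open.
oracle_shell_counts <- function(radii, breakpoints) {
  bounds <- c(0, breakpoints, Inf)
  counts <- integer(length(breakpoints) + 1L)
  for (r in radii) {
    for (k in seq_along(counts)) {
      if (r >= bounds[k] && r < bounds[k + 1L]) {
        counts[k] <- counts[k] + 1L
        break
      }
    }
  }
  counts
}

oracle_layer_sim <- function(l1, l2) {
  out <- numeric(length(l1))
  for (i in seq_along(l1)) {
    if (l1[i] > 0) {
      out[i] <- 1 - abs(l1[i] - l2[i]) / l1[i]
    } else {
      out[i] <- if (l2[i] == 0) 1 else 0
    }
  }
  out
}

oracle_layer_weights <- function(l1, l2) {
  n1 <- sum(l1)
  n2 <- sum(l2)
  out <- numeric(length(l1))
  for (i in seq_along(l1)) out[i] <- (l1[i] / n1 + l2[i] / n2) / 2
  out
}

oracle_density <- function(l1, l2) {
  w <- oracle_layer_weights(l1, l2)
  s <- oracle_layer_sim(l1, l2)
  tot <- 0
  for (i in seq_along(w)) tot <- tot + w[i] * s[i]
  tot
}

# Least-squares weights via the normal equations.
oracle_ls_weights <- function(tab) {
  X <- as.matrix(tab[, paste0("S", 1:9)])
  y <- tab$S
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Exact activation probability of every node by enumerating the 2^k joint
# Bernoulli states of the sources, under the semantics: a non-source node is
# active iff at least one activating parent is active and no inhibiting
# parent is active.
oracle_enumerate <- function(edges, sources, priors, topo) {
  k <- length(sources)
  nodes <- topo
  prob <- setNames(rep(0, length(nodes)), nodes)
  for (state_id in 0:(2^k - 1)) {
    bits <- as.logical(bitwAnd(state_id, 2^(seq_len(k) - 1)))
    w <- 1
    for (j in seq_len(k)) w <- w * if (bits[j]) priors[[sources[j]]] else 1 - priors[[sources[j]]]
    active <- setNames(rep(FALSE, length(nodes)), nodes)
    for (v in nodes) {
      if (v %in% sources) {
        active[[v]] <- bits[match(v, sources)]
      } else {
        act_par <- edges$source[edges$target == v & edges$sign == "+"]
        inh_par <- edges$source[edges$target == v & edges$sign == "-"]
        any_act <- length(act_par) > 0 && any(active[act_par])
        any_inh <- length(inh_par) > 0 && any(active[inh_par])
        active[[v]] <- any_act && !any_inh
      }
    }
    prob[active] <- prob[active] + w
  }
  prob
}

# Recursive enumeration of all simple source-to-sink paths.
oracle_paths <- function(edges, sources, sink) {
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == sink) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (u in edges$target[edges$source == v]) {
      if (!u %in% path) walk(c(path, u))
    }
  }
  for (s in sources) walk(s)
  out
}

# Random in-tree over k sources: internal nodes merge disjoint subtrees, so
# every node's parents have independent ancestries and the union rule is
# exact. Returns edges, priors, and the sink name.
random_source_tree <- function(k, seed, inhib_p = 0.3) {
  set.seed(seed)
  sources <- sprintf("S%d", seq_len(k))
  priors <- setNames(runif(k), sources)
  frontier <- as.list(sources)
  edges <- NULL
  counter <- 0
  while (length(frontier) > 1L) {
    counter <- counter + 1
    take <- sample(length(frontier), 2L)
    child <- sprintf("M%d", counter)
    for (p in frontier[take]) {
      sgn <- if (runif(1) < inhib_p) "-" else "+"
      edges <- rbind(edges, data.frame(source = p, target = child, sign = sgn,
                                       stringsAsFactors = FALSE))
    }
    frontier <- c(frontier[-take], child)
  }
  root <- frontier[[1L]]
  if (k == 1L) {
    edges <- data.frame(source = root, target = "SINKNODE", sign = "+",
                        stringsAsFactors = FALSE)
    root <- "SINKNODE"
  }
  list(edges = edges, priors = priors, sink = root, sources = sources)
}
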