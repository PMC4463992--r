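# Signed regulatory network: a DAG whose edges activate ("+") or inhibit
# ("-") their target. Source nodes (in-degree 0) carry prior activation
# probabilities taken from similarity scores; probabilities are propagated
# in topological order and root-to-sink pathways are ranked. The published
# conditional-probability tables were never enumerated, so a sign-gated
# combination rule stands in for them: a node activates iff at least one
# activating parent fires and no inhibiting parent fires, with parents
# treated as independent (noisy-OR with inhibitor gating).

# Depth-first search for a cycle witness, used only to make rejection
# messages concrete.
.find_cycle <- function(edges, nodes) {
  adj <- split(edges$target, factor(edges$source, levels = nodes))
  state <- stats::setNames(rep(0L, length(nodes)), nodes)   # 0 new, 1 open, 2 done
  stack <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[[v]] <<- 1L
    stack <<- c(stack, v)
    for (u in adj[[v]]) {
      if (!is.null(found)) return()
      if (state[[u]] == 1L) {
        i <- match(u, stack)
        found <<- c(stack[i:length(stack)], u)
        return()
      }
      if (state[[u]] == 0L) visit(u)
    }
    state[[v]] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in nodes) if (state[[v]] == 0L) visit(v)
  found
}

#' Build and validate a signed regulatory network
#'
#' Validates that the signed edge list forms a DAG over the named nodes,
#' computes a topological order, and records the designated sink. Nodes with
#' no incoming edge are the sources (candidate pathway roots).
#'
#' @param edges `data.frame` with columns `source`, `target`, `sign`
#'   (`"+"` activating, `"-"` inhibiting).
#' @param sink Name of the terminal node (e.g. `"Cell proliferation"`).
#' @param nodes Optional character vector of node names; defaults to the
#'   union of edge endpoints plus the sink.
#' @return Object of class `regulatory_network`: list with `nodes`, `edges`,
#'   `sink`, `sources`, `topo_order`, and `priors` (unset until
#'   [set_priors()]).
#' @export
build_network <- function(edges, sink, nodes = NULL) {
  stopifnot(is.data.frame(edges))
  if (!all(c("source", "target", "sign") %in% names(edges))) {
    stop("edges must have columns source, target, sign")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$sign <- as.character(edges$sign)
  bad_sign <- which(!edges$sign %in% c("+", "-"))
  if (length(bad_sign) > 0L) {
    stop(sprintf("edge %s -> %s has sign '%s'; expected '+' or '-'",
                 edges$source[bad_sign[1L]], edges$target[bad_sign[1L]],
                 edges$sign[bad_sign[1L]]))
  }
  if (is.null(nodes)) nodes <- union(union(edges$source, edges$target), sink)
  nodes <- unique(as.character(nodes))
  unknown <- which(!(edges$source %in% nodes) | !(edges$target %in% nodes))
  if (length(unknown) > 0L) {
    stop(sprintf("edge %s -> %s refers to an unknown node",
                 edges$source[unknown[1L]], edges$target[unknown[1L]]))
  }
  if (!sink %in% nodes) stop("sink '", sink, "' is not among the nodes")
  if (anyDuplicated(edges[, c("source", "target")])) {
    stop("duplicated edge between the same source and target")
  }

  g <- igraph::graph_from_data_frame(edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    wit <- .find_cycle(edges, nodes)
    stop("the network contains a cycle: ", paste(wit, collapse = " -> "))
  }
  topo <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "out"))]
  indeg <- igraph::degree(g, mode = "in")
  sources <- sort(setdiff(names(indeg)[indeg == 0L], sink))
  reach_sink <- names(igraph::subcomponent(g, sink, mode = "in"))
  if (!any(sources %in% reach_sink)) {
    warning("the sink '", sink, "' is unreachable from every source")
  }
  structure(list(nodes = nodes, edges = edges, sink = sink, sources = sources,
                 topo_order = topo, priors = NULL, graph = g),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d nodes, %d edges (%d inhibiting), sink '%s'\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == "-"), x$sink))
  cat("  sources:", paste(x$sources, collapse = ", "), "\n")
  if (!is.null(x$priors)) {
    cat("  priors set on", length(x$priors), "source(s)\n")
  }
  invisible(x)
}

#' Set source priors from similarity scores
#'
#' Every source node receives the similarity score of its protein as prior
#' activation probability. Scores are clamped into `[0, 1]` — the similarity
#' scale is unbounded in principle — and each clamping event is reported via
#' `message()` and recorded in the returned network's `clamp_log`.
#'
#' @param net A [build_network()] result.
#' @param scores Named numeric vector mapping every source name to a score.
#' @return The network with `priors` set (named numeric over sources).
#' @export
set_priors <- function(net, scores) {
  stopifnot(inherits(net, "regulatory_network"))
  missing_src <- setdiff(net$sources, names(scores))
  if (length(missing_src) > 0L) {
    stop("no similarity score supplied for source node '", missing_src[1L], "'")
  }
  pri <- as.numeric(scores[net$sources])
  names(pri) <- net$sources
  clamp_log <- character(0)
  for (i in seq_along(pri)) {
    if (pri[i] > 1) {
      clamp_log <- c(clamp_log, sprintf("%s: %g clamped to 1", names(pri)[i], pri[i]))
      pri[i] <- 1
    } else if (pri[i] < 0) {
      clamp_log <- c(clamp_log, sprintf("%s: %g clamped to 0", names(pri)[i], pri[i]))
      pri[i] <- 0
    }
  }
  for (msg in clamp_log) message("prior ", msg)
  net$priors <- pri
  net$clamp_log <- clamp_log
  net
}

.parents_by_sign <- function(net) {
  act <- split(net$edges$source[net$edges$sign == "+"],
               factor(net$edges$target[net$edges$sign == "+"], levels = net$nodes))
  inh <- split(net$edges$source[net$edges$sign == "-"],
               factor(net$edges$target[net$edges$sign == "-"], levels = net$nodes))
  list(act = act, inh = inh)
}

#' Propagate activation probabilities through the network
#'
#' Processes nodes in topological order; sources keep their priors. In the
#' default `"union"` mode a node's probability is
#' `prod(1 - P(inhibiting parents)) * (1 - prod(1 - P(activating parents)))`
#' — the noisy-OR union of activators gated by the complement of every
#' inhibitor, which stays in `[0, 1]` for any priors. The `"literal"` mode
#' instead sums, under the same inhibitor gate, the individual activator
#' probabilities plus their full joint product (the published conditional
#' sum); this over-counts the union, so values above 1 are clamped with a
#' diagnostic message. A node with no activating parent (and no prior) gets
#' probability 0 in both modes.
#'
#' @param net A network with priors set.
#' @param mode `"union"` (default) or `"literal"`.
#' @return Named numeric vector of activation probabilities over all nodes.
#' @export
propagate <- function(net, mode = c("union", "literal")) {
  stopifnot(inherits(net, "regulatory_network"))
  mode <- match.arg(mode)
  if (is.null(net$priors)) stop("priors are unset; call set_priors() first")
  par <- .parents_by_sign(net)
  p <- stats::setNames(rep(NA_real_, length(net$nodes)), net$nodes)
  for (v in net$topo_order) {
    if (v %in% net$sources) {
      p[[v]] <- net$priors[[v]]
      next
    }
    pa <- p[par$act[[v]]]
    pi_ <- p[par$inh[[v]]]
    gate <- if (length(pi_) > 0L) prod(1 - pi_) else 1
    if (length(pa) == 0L) {
      p[[v]] <- 0
    } else if (mode == "union") {
      p[[v]] <- gate * (1 - prod(1 - pa))
    } else {
      raw <- if (length(pa) == 1L) gate * pa else gate * (sum(pa) + prod(pa))
      if (raw > 1) {
        message(sprintf("literal combination at node '%s' gave %.4f; clamped to 1", v, raw))
        raw <- 1
      }
      p[[v]] <- raw
    }
  }
  p
}

#' Enumerate all source-to-sink pathways
#'
#' All simple directed paths from any source to the sink, in a
#' deterministic lexicographic order (by the concatenated node names).
#'
#' @param net A [build_network()] result.
#' @return List of character vectors (node paths); empty if the sink is
#'   unreachable.
#' @export
enumerate_paths <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  paths <- list()
  for (src in net$sources) {
    ps <- igraph::all_simple_paths(net$graph, from = src, to = net$sink, mode = "out")
    paths <- c(paths, lapply(ps, function(p) igraph::V(net$graph)$name[as.integer(p)]))
  }
  if (length(paths) == 0L) return(list())
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(keys, method = "radix")]
}

.edge_sign <- function(net, from, to) {
  i <- which(net$edges$source == from & net$edges$target == to)
  if (length(i) != 1L) return(NA_character_)
  net$edges$sign[i]
}

#' Probability delivered along one pathway
#'
#' Propagation restricted to the pathway's own chain with only its root
#' prior active: an activating edge passes the running probability through
#' unchanged; an inhibiting edge replaces it by its complement
#' `1 - P(upstream)`. For an all-activating chain the pathway probability is
#' therefore exactly the root's prior.
#'
#' @param net A network with priors set.
#' @param path Character vector of node names from a source to the sink.
#' @return Probability in `[0, 1]`.
#' @export
path_probability <- function(net, path) {
  stopifnot(inherits(net, "regulatory_network"))
  if (is.null(net$priors)) stop("priors are unset; call set_priors() first")
  path <- as.character(path)
  if (length(path) < 1L || !path[1L] %in% net$sources) {
    stop("a pathway must start at a source node")
  }
  p <- net$priors[[path[1L]]]
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L)) {
      sgn <- .edge_sign(net, path[i], path[i + 1L])
      if (is.na(sgn)) {
        stop(sprintf("invalid pathway: no edge %s -> %s", path[i], path[i + 1L]))
      }
      p <- if (sgn == "+") p else 1 - p
    }
  }
  p
}

#' Rank all source-to-sink pathways by probability
#'
#' Computes [path_probability()] for every enumerated pathway and orders
#' them by descending probability, ties broken lexicographically. The top
#' entry is the maximum-probability regulatory pathway.
#'
#' @param net A network with priors set.
#' @return `data.frame` with columns `pathway` (nodes joined by `" -> "`)
#'   and `probability`, plus the node paths in `attr(, "paths")`. Empty,
#'   with a warning, when no pathway reaches the sink.
#' @export
rank_pathways <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  if (is.null(net$priors)) stop("priors are unset; call set_priors() first")
  paths <- enumerate_paths(net)
  if (length(paths) == 0L) {
    warning("no source-to-sink pathway exists in this network")
    return(structure(data.frame(pathway = character(0), probability = numeric(0)),
                     paths = list()))
  }
  prob <- vapply(paths, function(p) path_probability(net, p), numeric(1))
  lab <- vapply(paths, paste, character(1), collapse = " -> ")
  o <- order(-prob, lab, method = "radix")
  out <- data.frame(pathway = lab[o], probability = prob[o],
                    stringsAsFactors = FALSE)
  attr(out, "paths") <- paths[o]
  out
}

#' Attribute a node's activation to the source proteins
#'
#' Bayesian inversion of the propagation: for each source, the node's
#' union-mode activation probability is recomputed in the sub-network where
#' only that source keeps its prior (all other priors zeroed); the
#' contributions are normalised to a distribution over sources.
#'
#' @param net A network with priors set.
#' @param node Node name.
#' @return Named numeric distribution over sources summing to 1, or an
#'   empty vector with a warning when no source reaches the node.
#' @export
posterior_attribution <- function(net, node) {
  stopifnot(inherits(net, "regulatory_network"))
  if (is.null(net$priors)) stop("priors are unset; call set_priors() first")
  if (!node %in% net$nodes) stop("unknown node '", node, "'")
  contrib <- vapply(net$sources, function(s) {
    solo <- net$priors
    solo[] <- 0
    solo[[s]] <- net$priors[[s]]
    net2 <- net
    net2$priors <- solo
    propagate(net2, mode = "union")[[node]]
  }, numeric(1))
  total <- sum(contrib)
  if (total <= 0) {
    warning("node '", node, "' receives no probability from any source")
    return(stats::setNames(numeric(0), character(0)))
  }
  contrib / total
}

#' Read a signed edge list and a priors table from disk
#'
#' Edge lists are tab-delimited with columns `source`, `target`, `sign`;
#' priors tables with columns `node`, `score`.
#'
#' @param path File path.
#' @return `read_edge_list`: `data.frame(source, target, sign)`;
#'   `read_priors`: named numeric vector of scores.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("source", "target", "sign") %in% names(tab))) {
    stop("malformed edge list ", path, ": expected columns source, target, sign")
  }
  tab
}

#' @rdname read_edge_list
#' @export
read_priors <- function(path) {
  if (!file.exists(path)) stop("priors file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node", "score") %in% names(tab))) {
    stop("malformed priors file ", path, ": expected columns node, score")
  }
  stats::setNames(tab$score, tab$node)
}
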