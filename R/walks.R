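#' Build the directed fitness graph
#'
#' Nodes are all genotypes with a fitness value; a directed edge u -> v is
#' drawn when the adjacency allows the single substitution and
#' w(v) > w(u) strictly. The graph is acyclic by construction; fitness
#' peaks are the nodes with no outgoing edge.
#'
#' @param ls A `fitness_landscape` (complete, or with missing genotypes
#'   simply absent from the graph).
#' @param adjacency An [aa_adjacency()] matrix (default full).
#' @param measured_only Restrict nodes to measured entries.
#' @return Object of class `fitness_graph`: list with `genotypes`, `w`,
#'   `successors` (list of integer node indices with higher fitness),
#'   `adjacency`, landscape metadata.
#' @export
build_graph <- function(ls, adjacency = aa_adjacency("full",
                                                     alphabet = ls$alphabet),
                        measured_only = FALSE) {
  nodes <- if (measured_only) {
    names(ls$entries)[ls$origin == "measured"]
  } else {
    names(ls$entries)
  }
  if (length(nodes) == 0) stop("empty landscape")
  w <- unname(ls$entries[nodes])
  idx <- stats::setNames(seq_along(nodes), nodes)
  gm <- genotype_matrix(nodes)
  succ <- vector("list", length(nodes))
  for (v in seq_along(nodes)) {
    nb <- neighbors(nodes[v], adjacency)
    ni <- idx[nb]
    ni <- ni[!is.na(ni)]
    succ[[v]] <- unname(ni[w[ni] > w[v]])
  }
  structure(
    list(genotypes = nodes, w = w, successors = succ,
         adjacency = adjacency, wt = ls$wt, L = ls$L,
         alphabet = ls$alphabet),
    class = "fitness_graph"
  )
}

#' @export
print.fitness_graph <- function(x, ...) {
  cat("Fitness graph:", length(x$genotypes), "nodes,",
      sum(lengths(x$successors)), "edges (mode:",
      attr(x$adjacency, "mode"), ")\n")
  invisible(x)
}

#' Fitness peaks of the graph
#'
#' @param g A `fitness_graph`.
#' @return Data frame with `genotype`, `fitness`, and `basin_size` (greedy
#'   basin of attraction), sorted by decreasing fitness.
#' @export
find_peaks <- function(g) {
  peak <- lengths(g$successors) == 0
  basins <- greedy_basins(g)
  bs <- basins$sizes[g$genotypes[peak]]
  bs[is.na(bs)] <- 0
  out <- data.frame(genotype = g$genotypes[peak],
                    fitness = g$w[peak],
                    basin_size = unname(bs),
                    stringsAsFactors = FALSE)
  out[order(-out$fitness), ]
}

#' Per-step fixation probabilities
#'
#' Over the M fitter neighbors of a node: the greedy model puts probability
#' 1 on the largest fitness (deterministic; ties broken by lexicographic
#' genotype order), the correlated (SSWM) model weights by fitness gain
#' (w_k - w_i) / sum(w_n - w_i), the equal model uses 1/M. Deleterious and
#' neutral steps never fix.
#'
#' @param g A `fitness_graph`.
#' @param node Genotype string.
#' @param model `"greedy"`, `"correlated"` or `"equal"`.
#' @return Named numeric vector of probabilities over fitter neighbors
#'   (empty at a peak).
#' @export
fixation_probabilities <- function(g, node,
                                   model = c("greedy", "correlated",
                                             "equal")) {
  model <- match.arg(model)
  v <- match(node, g$genotypes)
  if (is.na(v)) stop("node not in graph: ", node)
  succ <- g$successors[[v]]
  if (length(succ) == 0) return(stats::setNames(numeric(0), character(0)))
  wk <- g$w[succ]
  p <- switch(model,
    greedy = {
      best <- succ[wk == max(wk)]
      pick <- best[order(g$genotypes[best])][1]
      as.numeric(succ == pick)
    },
    correlated = (wk - g$w[v]) / sum(wk - g$w[v]),
    equal = rep(1 / length(succ), length(succ))
  )
  stats::setNames(p, g$genotypes[succ])
}

# Internal: greedy successor index (0 at a peak), vectorized over all nodes.
greedy_next <- function(g) {
  vapply(seq_along(g$genotypes), function(v) {
    succ <- g$successors[[v]]
    if (length(succ) == 0) return(0L)
    wk <- g$w[succ]
    best <- succ[wk == max(wk)]
    as.integer(best[order(g$genotypes[best])][1])
  }, integer(1))
}

#' Greedy basins of attraction
#'
#' Deterministic greedy ascent (largest fitness gain, lexicographic
#' tie-break) from every node; the basin of a peak is the set of nodes whose
#' ascent terminates there. Basins partition the node set.
#'
#' @param g A `fitness_graph`.
#' @return List with `peak_of` (named character: node -> terminal peak) and
#'   `sizes` (named integer per peak).
#' @export
greedy_basins <- function(g) {
  nxt <- greedy_next(g)
  n <- length(nxt)
  term <- integer(n)
  for (v in seq_len(n)) {
    u <- v
    while (nxt[u] != 0L) u <- nxt[u]
    term[v] <- u
  }
  peak_of <- stats::setNames(g$genotypes[term], g$genotypes)
  sizes <- table(peak_of)
  list(peak_of = peak_of,
       sizes = stats::setNames(as.integer(sizes), names(sizes)))
}

#' Simulate adaptive walks
#'
#' From `start`, repeatedly fixes one beneficial substitution sampled by
#' the chosen fixation model until a peak is reached. Each step is then
#' classified against the walk's own endpoint by the change in Hamming
#' distance: towards (-1), conversion (0), detour (+1).
#'
#' @param g A `fitness_graph`.
#' @param start Genotype string (must be a node).
#' @param model Fixation model.
#' @param n Number of walks (default 1000).
#' @param seed Seed.
#' @return List of `adaptive_walk` objects: each has `path` (genotypes),
#'   `length`, `endpoint`, and step-class counts `n_towards`,
#'   `n_conversion`, `n_detour`.
#' @export
simulate_walks <- function(g, start, model = c("greedy", "correlated",
                                               "equal"),
                           n = 1000, seed = 1) {
  model <- match.arg(model)
  v0 <- match(start, g$genotypes)
  if (is.na(v0)) stop("start genotype not in graph")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    path <- integer(0)
    v <- v0
    repeat {
      path <- c(path, v)
      succ <- g$successors[[v]]
      if (length(succ) == 0) break
      wk <- g$w[succ]
      v <- switch(model,
        greedy = {
          best <- succ[wk == max(wk)]
          best[order(g$genotypes[best])][1]
        },
        correlated = succ[sample.int(length(succ), 1,
                                     prob = wk - g$w[path[length(path)]])],
        equal = succ[sample.int(length(succ), 1)]
      )
    }
    classify_walk(g$genotypes[path])
  })
}

# Build an adaptive_walk object from a genotype path, classifying each step
# by the change of Hamming distance to the realized endpoint.
classify_walk <- function(path) {
  endpoint <- path[length(path)]
  hd <- vapply(path, hamming_distance, numeric(1), b = endpoint)
  dh <- diff(hd)
  structure(
    list(path = path, length = length(path) - 1L, endpoint = endpoint,
         n_towards = sum(dh == -1), n_conversion = sum(dh == 0),
         n_detour = sum(dh == 1)),
    class = "adaptive_walk"
  )
}

#' Summarize step classes over a set of walks
#'
#' @param walks List of `adaptive_walk` objects.
#' @return Named vector: fraction of towards / conversion / detour steps,
#'   plus mean walk length.
#' @export
step_class_fractions <- function(walks) {
  tw <- sum(vapply(walks, `[[`, numeric(1), "n_towards"))
  cv <- sum(vapply(walks, `[[`, numeric(1), "n_conversion"))
  dt <- sum(vapply(walks, `[[`, numeric(1), "n_detour"))
  tot <- tw + cv + dt
  c(towards = tw / tot, conversion = cv / tot, detour = dt / tot,
    mean_length = mean(vapply(walks, `[[`, numeric(1), "length")))
}

#' Classify accessibility of targets from a start genotype
#'
#' Breadth-first shortest directed path length from `start` in the fitness
#' graph. A target is `inaccessible` when unreachable, `direct` when the
#' shortest monotone path equals the (Hamming or genetic) distance, and
#' `indirect_required` when every monotone path is longer than the
#' distance.
#'
#' @param g A `fitness_graph`.
#' @param start Genotype string.
#' @param targets Character vector of target genotypes.
#' @param distance `"hamming"` or `"genetic"` (per-site code-constrained
#'   shortest substitution distance).
#' @return Data frame: target, distance, path_length (NA if unreachable),
#'   class.
#' @export
accessibility <- function(g, start, targets,
                          distance = c("hamming", "genetic")) {
  distance <- match.arg(distance)
  v0 <- match(start, g$genotypes)
  if (is.na(v0)) stop("start genotype not in graph")
  # BFS over successor lists
  dist <- rep(NA_integer_, length(g$genotypes))
  dist[v0] <- 0L
  frontier <- v0
  while (length(frontier) > 0) {
    nxt <- unique(unlist(g$successors[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0) break
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  ti <- match(targets, g$genotypes)
  plen <- dist[ti]
  ref <- if (distance == "hamming") {
    vapply(targets, hamming_distance, numeric(1), b = start)
  } else {
    vapply(targets, genetic_distance, numeric(1), b = start,
           adjacency = g$adjacency)
  }
  cls <- ifelse(is.na(plen), "inaccessible",
                ifelse(plen == ref, "direct", "indirect_required"))
  data.frame(target = targets, distance = ref, path_length = plen,
             class = cls, stringsAsFactors = FALSE, row.names = NULL)
}

#' Entropy of evolutionary outcomes
#'
#' Simulates n walks from `start` and returns the Shannon entropy (natural
#' log) of the empirical distribution of endpoint peaks. 0 means full
#' commitment to a single peak.
#'
#' @inheritParams simulate_walks
#' @return Nonnegative entropy value.
#' @export
outcome_entropy <- function(g, start, model = c("correlated", "greedy",
                                                "equal"),
                            n = 1000, seed = 1) {
  model <- match.arg(model)
  walks <- simulate_walks(g, start, model = model, n = n, seed = seed)
  ends <- vapply(walks, `[[`, character(1), "endpoint")
  p <- table(ends) / length(ends)
  -sum(p * log(p))
}
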