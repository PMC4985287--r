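#' Extract a diallelic subgraph between two genotypes
#'
#' The 2^d sub-hypercube spanned by the source and a destination differing
#' at d sites: every combination of source/destination alleles at those
#' sites. Variants are ordered by the binary vector z (bit i = 1 when
#' differing site i carries the destination allele), with bit 1 the lowest
#' bit, so z = 0 is the source and z = 2^d - 1 the destination.
#'
#' @param ls A `fitness_landscape`.
#' @param source,destination Genotype strings.
#' @return Object of class `diallelic_subgraph`: list with `source`,
#'   `destination`, `sites` (differing site positions, 1-based), `d`,
#'   `genotypes`, `w` (fitness, `NA` for missing members), `complete`.
#' @export
extract_subgraph <- function(ls, source, destination) {
  cs <- strsplit(source, "")[[1]]
  cd <- strsplit(destination, "")[[1]]
  sites <- which(cs != cd)
  d <- length(sites)
  if (d == 0) stop("source and destination are identical")
  z <- as.matrix(expand.grid(rep(list(0:1), d)))
  gm <- matrix(cs, nrow(z), length(cs), byrow = TRUE)
  for (i in seq_len(d)) {
    gm[z[, i] == 1, sites[i]] <- cd[sites[i]]
  }
  genos <- matrix_genotype(gm)
  w <- unname(ls$entries[genos])
  structure(
    list(source = source, destination = destination, sites = sites, d = d,
         genotypes = genos, w = w, complete = !anyNA(w)),
    class = "diallelic_subgraph"
  )
}

# Build a subgraph directly from a fitness vector (z-ordered, length 2^d).
subgraph_from_fitness <- function(w, source = NULL, destination = NULL,
                                  sites = NULL) {
  d <- round(log2(length(w)))
  stopifnot(2^d == length(w))
  structure(
    list(source = source, destination = destination,
         sites = if (is.null(sites)) seq_len(d) else sites, d = d,
         genotypes = NULL, w = w, complete = !anyNA(w)),
    class = "diallelic_subgraph"
  )
}

# z index (0-based bit vector rows) helpers
z_bits <- function(d) as.matrix(expand.grid(rep(list(0:1), d)))

#' Find subgraphs with a unique fitness peak at one end
#'
#' For every genotype at Hamming distance `d` from the source (optionally
#' restricted to a fitness window), builds the diallelic subgraph and keeps
#' those that are complete and in which the designated endpoint (destination
#' for `from_source`, source for `to_source`) is the unique local fitness
#' maximum within the subgraph. This isolates the classical picture of
#' adaptation toward a single peak through 2^d intermediates.
#'
#' @param ls A `fitness_landscape`.
#' @param source Source genotype (e.g. the wild type).
#' @param direction `"from_source"` (adaptation from source to a fitter
#'   destination; default window: destination fitness > 1) or `"to_source"`
#'   (adaptation back to the source; default window: destination fitness in
#'   (0.01, 1)).
#' @param d Hamming distance of destinations (default `ls$L`).
#' @param fitness_window Length-2 numeric, destinations kept when strictly
#'   inside `(lo, hi)`.
#' @return List with `subgraphs` (list of `diallelic_subgraph`), and a
#'   summary data frame `table` (destination, n_accessible, reachable,
#'   unique_peak counts considered). Subgraphs are those passing the unique
#'   peak test; `table$reachable` records whether at least one direct path
#'   is accessible.
#' @export
enumerate_single_peak_subgraphs <- function(ls, source,
                                            direction = c("from_source",
                                                          "to_source"),
                                            d = ls$L,
                                            fitness_window = NULL) {
  direction <- match.arg(direction)
  if (is.null(fitness_window)) {
    fitness_window <- if (direction == "from_source") c(1, Inf)
                      else c(0.01, 1)
  }
  space <- all_genotypes(ls$alphabet, ls$L)
  cs <- strsplit(source, "")[[1]]
  sm <- genotype_matrix(space)
  hd <- rowSums(sm != matrix(cs, nrow(sm), ls$L, byrow = TRUE))
  cand <- space[hd == d]
  wc <- ls$entries[cand]
  keep <- !is.na(wc) & wc > fitness_window[1] & wc < fitness_window[2]
  cand <- cand[keep]
  subs <- list()
  tab <- list()
  for (g in cand) {
    sub <- extract_subgraph(ls, source, g)
    if (!sub$complete) next
    endpoint_idx <- if (direction == "from_source") 2^sub$d else 1
    if (direction == "to_source") {
      # orient the walk toward the source: swap roles
      sub_walk <- extract_subgraph(ls, g, source)
    } else {
      sub_walk <- sub
    }
    if (!is_unique_peak(sub, endpoint_idx)) next
    acc <- accessible_direct_paths(sub_walk)
    subs[[length(subs) + 1]] <- sub_walk
    tab[[length(tab) + 1]] <- data.frame(
      destination = g, n_accessible = acc, reachable = acc > 0,
      stringsAsFactors = FALSE)
  }
  list(subgraphs = subs,
       table = if (length(tab)) do.call(rbind, tab) else
         data.frame(destination = character(0), n_accessible = integer(0),
                    reachable = logical(0)))
}

# Is node `idx` (1-based position in z order) the unique local maximum of
# the subgraph under single-bit-flip adjacency?
is_unique_peak <- function(sub, idx) {
  d <- sub$d
  w <- sub$w
  n <- 2^d
  peak <- logical(n)
  for (v in seq_len(n)) {
    nb <- bit_neighbors(v, d)
    peak[v] <- all(w[nb] < w[v])
  }
  sum(peak) == 1 && peak[idx]
}

# 1-based indices of the d single-bit-flip neighbors of 1-based index v.
bit_neighbors <- function(v, d) {
  z <- v - 1
  vapply(seq_len(d) - 1, function(b) bitwXor(z, bitwShiftL(1, b)) + 1,
         numeric(1))
}

#' Count accessible direct paths through a subgraph
#'
#' A direct path orders the d substitutions from source to destination; it
#' is accessible when fitness strictly increases at every step. Counted by
#' dynamic programming over the subset lattice (number of strictly monotone
#' chains from z = 0 to z = 1...1 adding one site at a time).
#'
#' @param sub A complete `diallelic_subgraph`.
#' @return Integer in [0, d!].
#' @export
accessible_direct_paths <- function(sub) {
  stopifnot(inherits(sub, "diallelic_subgraph"))
  if (!sub$complete) stop("subgraph has missing variants")
  d <- sub$d
  w <- sub$w
  npaths <- numeric(2^d)
  npaths[1] <- 1
  codes <- 0:(2^d - 1)
  ord <- codes[order(vapply(codes, bitcount, numeric(1)))]  # by subset size
  for (v in ord) {
    if (v == 0) next
    total <- 0
    for (b in which(bitwAnd(v, bitwShiftL(1, seq_len(d) - 1)) != 0)) {
      prev <- bitwXor(v, bitwShiftL(1, b - 1))
      if (w[prev + 1] < w[v + 1]) total <- total + npaths[prev + 1]
    }
    npaths[v + 1] <- total
  }
  as.integer(npaths[2^d])
}

bitcount <- function(x) {
  n <- 0
  while (x > 0) { n <- n + bitwAnd(x, 1); x <- bitwShiftR(x, 1) }
  n
}

#' Realization probabilities of direct paths (fixation-model weighted)
#'
#' Each of the d! direct paths gets the product of its per-step fixation
#' probabilities (computed over all fitter neighbors within the subgraph
#' under the chosen model), then probabilities are normalized over the d!
#' direct paths. Inaccessible paths carry probability 0.
#'
#' @param sub A complete `diallelic_subgraph` whose destination is the
#'   unique peak.
#' @param model `"greedy"`, `"correlated"` or `"equal"`.
#' @return Object of class `path_distribution`: list with `paths` (matrix,
#'   one row per permutation of sites), `probabilities`,
#'   `accessible_count`, `all_zero` flag and `gini`.
#' @export
path_probabilities <- function(sub, model = c("correlated", "equal",
                                              "greedy")) {
  model <- match.arg(model)
  stopifnot(inherits(sub, "diallelic_subgraph"))
  if (!sub$complete) stop("subgraph has missing variants")
  d <- sub$d
  w <- sub$w
  perms <- permutations(d)
  probs <- numeric(nrow(perms))
  for (p in seq_len(nrow(perms))) {
    z <- 0
    pr <- 1
    for (b in perms[p, ]) {
      nxt <- bitwOr(z, bitwShiftL(1, b - 1))
      pr <- pr * step_probability(w, z, nxt, d, model)
      if (pr == 0) break
      z <- nxt
    }
    probs[p] <- pr
  }
  acc <- sum(probs > 0)
  all_zero <- acc == 0
  if (!all_zero) probs <- probs / sum(probs)
  dist <- structure(
    list(paths = perms, probabilities = probs, accessible_count = acc,
         all_zero = all_zero),
    class = "path_distribution"
  )
  dist$gini <- if (length(probs) >= 2) gini_index(probs) else NA_real_
  dist
}

# Fixation probability of the step z -> nxt (0-based subset codes) within
# the subgraph, per model, over all fitter single-flip neighbors of z.
step_probability <- function(w, z, nxt, d, model) {
  wi <- w[z + 1]
  nb <- bit_neighbors(z + 1, d)
  wn <- w[nb]
  fitter <- wn > wi
  if (w[nxt + 1] <= wi || !any(fitter)) return(0)
  target <- which(nb == nxt + 1)
  switch(model,
    greedy = {
      best <- which(wn == max(wn[fitter]) & fitter)
      # deterministic tie-break: lowest z index
      as.numeric(target == best[order(nb[best])][1])
    },
    correlated = (wn[target] - wi) / sum(wn[fitter] - wi),
    equal = as.numeric(fitter[target]) / sum(fitter)
  )
}

permutations <- function(d) {
  if (d == 1) return(matrix(1, 1, 1))
  sub <- permutations(d - 1)
  out <- matrix(0L, 0, d)
  for (i in seq_len(d)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Gini index of path realization probabilities
#'
#' Probabilities (inaccessible paths included as 0) are sorted descending;
#' with A the cumulative sums over t paths,
#' Gini = (2 * sum(A_1..A_{t-1}) + A_t - t) / (t - 1).
#' 0 for a uniform distribution, 1 when one path captures everything.
#'
#' @param p Numeric vector of path probabilities (will be sorted), t >= 2.
#' @return Gini index in [0, 1] (NA if all probabilities are 0).
#' @export
gini_index <- function(p) {
  t <- length(p)
  if (t < 2) stop("need at least two path probabilities")
  if (all(p == 0)) return(NA_real_)
  p <- sort(p, decreasing = TRUE) / sum(p)
  A <- cumsum(p)
  (2 * sum(A[seq_len(t - 1)]) + A[t] - t) / (t - 1)
}
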