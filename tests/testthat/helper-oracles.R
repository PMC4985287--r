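# Independent oracles used to cross-check the package implementations.
# Each is a direct, unoptimized transcription of the defining formula or an
# exhaustive enumeration; none shares code with the implementation path it
# checks.

# All permutations of 1..d (recursive, independent of the package's version).
oracle_permutations <- function(d) {
  if (d == 1) return(list(1L))
  out <- list()
  for (p in oracle_permutations(d - 1)) {
    for (pos in 0:(d - 1)) {
      out[[length(out) + 1]] <- append(p, d, after = pos)
    }
  }
  out
}

# Accessible direct paths by walking every ordering of the d substitutions
# and checking strict fitness increase step by step. w is z-ordered
# (bit i lowest for site i), length 2^d.
oracle_direct_paths <- function(w) {
  d <- round(log2(length(w)))
  count <- 0
  for (perm in oracle_permutations(d)) {
    z <- 0
    ok <- TRUE
    for (s in perm) {
      nxt <- z + 2^(s - 1)
      if (w[nxt + 1] <= w[z + 1]) { ok <- FALSE; break }
      z <- nxt
    }
    if (ok) count <- count + 1
  }
  count
}

# Peaks by exhaustive neighbor comparison over all genotypes with fitness.
oracle_peaks <- function(ls) {
  genos <- names(ls$entries)
  peaks <- character(0)
  for (g in genos) {
    nb <- neighbors(g, aa_adjacency("full", alphabet = ls$alphabet))
    wn <- ls$entries[intersect(nb, genos)]
    if (all(wn < ls$entries[g])) peaks <- c(peaks, g)
  }
  sort(peaks)
}

# Walsh-Fourier coefficients by direct double loop over z and k.
oracle_fourier <- function(f) {
  d <- round(log2(length(f)))
  n <- 2^d
  coef <- numeric(n)
  for (k in 0:(n - 1)) {
    s <- 0
    for (z in 0:(n - 1)) {
      par <- sum(as.integer(intToBits(bitwAnd(z, k))))
      s <- s + f[z + 1] * (-1)^par
    }
    coef[k + 1] <- s / n
  }
  coef
}

# Taylor coefficients of a 3-cube by the closed-form differences.
oracle_taylor <- function(f) {
  names(f) <- c("f000", "f001", "f010", "f011", "f100", "f101", "f110",
                "f111")
  c(a0 = unname(f["f000"]),
    a1 = unname(f["f001"] - f["f000"]),
    a2 = unname(f["f010"] - f["f000"]),
    a3 = unname(f["f100"] - f["f000"]),
    a12 = unname(f["f011"] - f["f001"] - f["f010"] + f["f000"]),
    a13 = unname(f["f101"] - f["f001"] - f["f100"] + f["f000"]),
    a23 = unname(f["f110"] - f["f010"] - f["f100"] + f["f000"]),
    a123 = unname(f["f111"] - f["f110"] - f["f101"] - f["f011"] +
                    f["f100"] + f["f010"] + f["f001"] - f["f000"]))
}

# Exact endpoint-peak distribution of an adaptive walk started at `start`:
# pushes probability mass through nodes in increasing fitness order (walks
# only ever move uphill, so this order is topological).
oracle_absorption <- function(g, start, model) {
  n <- length(g$genotypes)
  mass <- numeric(n)
  mass[match(start, g$genotypes)] <- 1
  for (v in order(g$w)) {
    if (mass[v] == 0) next
    p <- fixation_probabilities(g, g$genotypes[v], model)
    if (length(p) == 0) next
    ti <- match(names(p), g$genotypes)
    mass[ti] <- mass[ti] + mass[v] * p
    mass[v] <- 0
  }
  stats::setNames(mass[mass > 0], g$genotypes[mass > 0])
}

# Exhaustive conversion-bypass check: enumerate all length-3 strictly
# increasing paths bg -> x -> y -> ab where x and y differ from their
# predecessors at one of the two focal sites, and x carries a third allele.
oracle_conversion <- function(ls, background, sites, subs) {
  chars <- strsplit(background, "")[[1]]
  ab <- chars; ab[sites[1]] <- subs[1]; ab[sites[2]] <- subs[2]
  ab <- paste(ab, collapse = "")
  w <- ls$entries
  hits <- character(0)
  for (s in sites) {
    other <- setdiff(sites, s)
    for (cc in setdiff(ls$alphabet, c(chars[s], subs[match(s, sites)]))) {
      x <- chars; x[s] <- cc
      y <- x; y[other] <- subs[match(other, sites)]
      xs <- paste(x, collapse = ""); ys <- paste(y, collapse = "")
      if (!is.na(w[xs]) && !is.na(w[ys]) &&
          w[xs] > w[background] && w[ys] > w[xs] && w[ab] > w[ys]) {
        hits <- c(hits, paste0(s, cc))
      }
    }
  }
  hits
}

# Exhaustive detour-bypass check: all monotone routes
# 000 -> 100 -> {110|101} -> 111 -> 011 for each third site and allele.
oracle_detour <- function(ls, background, sites, subs) {
  chars <- strsplit(background, "")[[1]]
  ab <- chars; ab[sites[1]] <- subs[1]; ab[sites[2]] <- subs[2]
  abs_ <- paste(ab, collapse = "")
  w <- ls$entries
  hits <- character(0)
  for (s3 in setdiff(seq_len(ls$L), sites)) {
    for (cc in setdiff(ls$alphabet, chars[s3])) {
      g100 <- chars; g100[s3] <- cc
      g110 <- g100; g110[sites[1]] <- subs[1]
      g101 <- g100; g101[sites[2]] <- subs[2]
      g111 <- g110; g111[sites[2]] <- subs[2]
      f <- w[c(paste(g100, collapse = ""), paste(g110, collapse = ""),
               paste(g101, collapse = ""), paste(g111, collapse = ""))]
      if (anyNA(f)) next
      ok <- f[1] > w[background] &&
        ((f[2] > f[1] && f[4] > f[2]) || (f[3] > f[1] && f[4] > f[3])) &&
        w[abs_] > f[4]
      if (ok) hits <- c(hits, paste0(s3, cc))
    }
  }
  hits
}

# Gini by the mean-absolute-difference formula, normalized so that a
# one-path distribution scores exactly 1 (matching the cumulative-sum
# definition used by the package).
oracle_gini <- function(p) {
  p <- p / sum(p)
  n <- length(p)
  sum(outer(p, p, function(a, b) abs(a - b))) / (2 * (n - 1))
}

# Small handmade landscape constructors ------------------------------------

# Fully multiplicative landscape: log fitness additive across sites.
make_multiplicative <- function(alphabet = c("A", "C", "D"), L = 3,
                                seed = 1) {
  set.seed(seed)
  effects <- matrix(stats::rnorm(L * length(alphabet), 0, 0.4),
                    L, length(alphabet),
                    dimnames = list(NULL, alphabet))
  effects[, 1] <- 0
  genos <- all_genotypes(alphabet, L)
  gm <- do.call(rbind, strsplit(genos, ""))
  logw <- rowSums(sapply(seq_len(L), function(s) effects[s, gm[, s]]))
  wt <- paste(rep(alphabet[1], L), collapse = "")
  fitness_landscape(wt, stats::setNames(exp(logw), genos),
                    alphabet = alphabet)
}

# Seeded random rugged landscape over a small space.
make_rugged <- function(alphabet = c("A", "C", "D", "E"), L = 3, seed = 1,
                        lethal = 0) {
  set.seed(seed)
  genos <- all_genotypes(alphabet, L)
  w <- stats::setNames(exp(stats::rnorm(length(genos), 0, 0.7)), genos)
  wt <- paste(rep(alphabet[1], L), collapse = "")
  w[wt] <- 1
  if (lethal > 0) {
    kill <- sample(setdiff(genos, wt), round(lethal * length(genos)))
    w[kill] <- 0
  }
  fitness_landscape(wt, w, alphabet = alphabet)
}
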