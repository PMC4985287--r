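#' Relative pairwise epistasis
#'
#' Deviation of the double mutant's log fitness from additivity of the two
#' single mutants on a shared background:
#' epsilon = ln(w_ab/w_BG) - ln(w_a/w_BG) - ln(w_b/w_BG).
#'
#' @param w_ab,w_a,w_b,w_bg Fitness of the double mutant, the two single
#'   mutants and the background. All must be > 0 for a defined value.
#' @return Numeric epsilon; `NA` if any value is not strictly positive
#'   (route such quads through [epsilon_adjusted()]).
#' @export
#' @examples
#' epsilon(0.5, 0.5, 0.5, 1) # log(2)
epsilon <- function(w_ab, w_a, w_b, w_bg) {
  if (anyNA(c(w_ab, w_a, w_b, w_bg)) ||
      min(w_ab, w_a, w_b, w_bg) <= 0) {
    return(NA_real_)
  }
  log(w_ab / w_bg) - log(w_a / w_bg) - log(w_b / w_bg)
}

#' Detection-limit adjusted epistasis
#'
#' Fitness below the assay's detection limit (~0.01) cannot be resolved, so
#' raw epsilon from such quads is unreliable. Three rules temper it:
#' Rule 1 - if all of w_ab/w_BG, w_a/w_BG, w_b/w_BG are below the limit, the
#' whole quad is at the floor: epsilon = 0.
#' Rule 2 - if either single mutant (absolutely or relative to background) is
#' at the floor, positive epistasis may be overestimated only in appearance:
#' keep max(0, epsilon).
#' Rule 3 - if the double mutant is at the floor, negative epistasis is the
#' only trustworthy sign: keep min(0, epsilon).
#' Rules 2 and 3 together force 0. Each rule can only shrink |epsilon|.
#'
#' @inheritParams epsilon
#' @param detection_limit Fitness detection limit (default 0.01).
#' @return Adjusted epsilon (0 replaces undefined raw values when a rule
#'   fires on a zero-fitness member).
#' @export
epsilon_adjusted <- function(w_ab, w_a, w_b, w_bg, detection_limit = 0.01) {
  stopifnot(detection_limit > 0)
  if (anyNA(c(w_ab, w_a, w_b, w_bg)) || w_bg <= 0) return(NA_real_)
  eps <- epsilon(w_ab, w_a, w_b, w_bg)
  r_ab <- w_ab / w_bg; r_a <- w_a / w_bg; r_b <- w_b / w_bg
  rule1 <- max(r_ab, r_a, r_b) < detection_limit
  rule2 <- min(w_a, w_b, r_a, r_b) < detection_limit
  rule3 <- min(w_ab, r_ab) < detection_limit
  if (rule1) return(0)
  if (rule2 && rule3) return(0)
  if (rule2) return(max(0, eps, na.rm = TRUE))
  if (rule3) return(min(0, eps, na.rm = TRUE))
  eps
}

#' Classify one pairwise-epistasis quad
#'
#' The 2 x 2 face (BG, a, b, ab) is classified by whether each mutation's
#' fitness-effect sign flips across the partner's backgrounds:
#' both flip = reciprocal sign, exactly one = sign, neither = magnitude.
#' A zero effect (exact tie) counts as no flip.
#'
#' @inheritParams epsilon
#' @return One of `"magnitude"`, `"sign"`, `"reciprocal_sign"`, or `NA` if
#'   any fitness is missing.
#' @export
#' @examples
#' classify_quad(4, 0.5, 2, 1)   # "sign"
#' classify_quad(2, 0.5, 0.5, 1) # "reciprocal_sign"
classify_quad <- function(w_ab, w_a, w_b, w_bg) {
  if (anyNA(c(w_ab, w_a, w_b, w_bg))) return(NA_character_)
  flip_a <- sign(w_a - w_bg) * sign(w_ab - w_b) < 0
  flip_b <- sign(w_b - w_bg) * sign(w_ab - w_a) < 0
  n_flip <- flip_a + flip_b
  c("magnitude", "sign", "reciprocal_sign")[n_flip + 1]
}

# Build the quad fitness values for background bg, sites (s1, s2) and
# substitution alleles (a1, a2): returns c(w_bg, w_a, w_b, w_ab).
quad_fitness <- function(ls, bg, s1, s2, a1, a2) {
  chars <- strsplit(bg, "")[[1]]
  ga <- chars; ga[s1] <- a1
  gb <- chars; gb[s2] <- a2
  gab <- ga; gab[s2] <- a2
  g <- c(bg, matrix_genotype(rbind(ga, gb, gab)))
  stats::setNames(ls$entries[g], c("bg", "a", "b", "ab"))
}

#' Epistasis over a neighborhood or random sample of quads
#'
#' Either all quads on one background (`center`: every site pair and every
#' substitution-allele pair, 19^2 x choose(L,2) = 2166 quads for L = 4 with
#' the full alphabet) or a seeded uniform sample of (background, site pair,
#' allele pair) faces with replacement.
#'
#' @param ls A `fitness_landscape`.
#' @param center Background genotype; mutually exclusive with `sample_size`.
#' @param sample_size Number of faces to sample uniformly.
#' @param seed Seed for sampling.
#' @param detection_limit Passed to [epsilon_adjusted()].
#' @return List with `quads` (data frame: background, site_i, site_j, a, b,
#'   the four fitness values, eps_raw, eps_adj, type), `fractions` (named
#'   fractions of classified quads by type), `n_classified`, `n_skipped`
#'   (quads with a missing member).
#' @export
classify_neighborhood <- function(ls, center = NULL, sample_size = NULL,
                                  seed = 1, detection_limit = 0.01) {
  L <- ls$L
  pairs <- utils::combn(L, 2)
  rows <- list()
  if (!is.null(center)) {
    chars <- strsplit(center, "")[[1]]
    for (p in seq_len(ncol(pairs))) {
      s1 <- pairs[1, p]; s2 <- pairs[2, p]
      alt1 <- setdiff(ls$alphabet, chars[s1])
      alt2 <- setdiff(ls$alphabet, chars[s2])
      grid <- expand.grid(a = alt1, b = alt2, stringsAsFactors = FALSE)
      rows[[p]] <- data.frame(background = center, site_i = s1, site_j = s2,
                              a = grid$a, b = grid$b,
                              stringsAsFactors = FALSE)
    }
  } else if (!is.null(sample_size)) {
    set.seed(seed)
    space <- all_genotypes(ls$alphabet, ls$L)
    bg <- sample(space, sample_size, replace = TRUE)
    pr <- sample(ncol(pairs), sample_size, replace = TRUE)
    s1 <- pairs[1, pr]; s2 <- pairs[2, pr]
    bgm <- genotype_matrix(bg)
    pick_alt <- function(cur) {
      # uniform over the other alphabet letters
      alt <- sample(ls$alphabet, length(cur), replace = TRUE)
      clash <- alt == cur
      while (any(clash)) {
        alt[clash] <- sample(ls$alphabet, sum(clash), replace = TRUE)
        clash <- alt == cur
      }
      alt
    }
    a <- pick_alt(bgm[cbind(seq_len(sample_size), s1)])
    b <- pick_alt(bgm[cbind(seq_len(sample_size), s2)])
    rows[[1]] <- data.frame(background = bg, site_i = s1, site_j = s2,
                            a = a, b = b, stringsAsFactors = FALSE)
  } else {
    stop("give either center or sample_size")
  }
  df <- do.call(rbind, rows)

  # vectorized fitness lookup of the four corners
  bgm <- genotype_matrix(df$background)
  n <- nrow(df)
  ga <- bgm; ga[cbind(seq_len(n), df$site_i)] <- df$a
  gb <- bgm; gb[cbind(seq_len(n), df$site_j)] <- df$b
  gab <- ga; gab[cbind(seq_len(n), df$site_j)] <- df$b
  df$w_bg <- unname(ls$entries[df$background])
  df$w_a <- unname(ls$entries[matrix_genotype(ga)])
  df$w_b <- unname(ls$entries[matrix_genotype(gb)])
  df$w_ab <- unname(ls$entries[matrix_genotype(gab)])

  df$eps_raw <- mapply(epsilon, df$w_ab, df$w_a, df$w_b, df$w_bg)
  df$eps_adj <- mapply(epsilon_adjusted, df$w_ab, df$w_a, df$w_b, df$w_bg,
                       MoreArgs = list(detection_limit = detection_limit))
  df$type <- mapply(classify_quad, df$w_ab, df$w_a, df$w_b, df$w_bg)

  classified <- df$type[!is.na(df$type)]
  if (length(classified) == 0) stop("no classifiable quads")
  fractions <- c(magnitude = mean(classified == "magnitude"),
                 sign = mean(classified == "sign"),
                 reciprocal_sign = mean(classified == "reciprocal_sign"))
  list(quads = df, fractions = fractions,
       n_classified = length(classified),
       n_skipped = sum(is.na(df$type)))
}

#' Ruggedness score of a diallelic subgraph
#'
#' Classifies all choose(d,2) x 2^(d-2) pairwise-epistasis quads of a
#' complete subgraph (24 for d = 4) and scores ruggedness as
#' f_sign + 2 * f_reciprocal, weighting by how strongly each class blocks
#' direct adaptive paths. Ranges from 0 (all magnitude) to 2 (all
#' reciprocal sign).
#'
#' @param sub A complete `diallelic_subgraph` (see [extract_subgraph()]).
#' @return List with the class fractions, quad count and `score`.
#' @export
ruggedness <- function(sub) {
  stopifnot(inherits(sub, "diallelic_subgraph"))
  if (!sub$complete) stop("ruggedness requires a complete subgraph")
  d <- sub$d
  pairs <- utils::combn(d, 2)
  types <- character(0)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    others <- setdiff(seq_len(d), c(i, j))
    # all backgrounds over the remaining sites
    bg_bits <- as.matrix(expand.grid(rep(list(0:1), length(others))))
    if (length(others) == 0) bg_bits <- matrix(0, 1, 0)
    for (r in seq_len(nrow(bg_bits))) {
      z <- integer(d)
      z[others] <- bg_bits[r, ]
      idx <- function(zi, zj) {
        zz <- z; zz[i] <- zi; zz[j] <- zj
        sum(zz * 2^(seq_len(d) - 1)) + 1
      }
      types <- c(types, classify_quad(sub$w[idx(1, 1)], sub$w[idx(1, 0)],
                                      sub$w[idx(0, 1)], sub$w[idx(0, 0)]))
    }
  }
  f <- c(magnitude = mean(types == "magnitude"),
         sign = mean(types == "sign"),
         reciprocal_sign = mean(types == "reciprocal_sign"))
  list(fractions = f, n_quads = length(types),
       score = unname(f["sign"] + 2 * f["reciprocal_sign"]))
}
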