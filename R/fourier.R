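# Walsh-Hadamard design for dimension d: H[z, k] = (-1)^popcount(z & k),
# rows/cols in z order (bit 1 lowest). Symmetric, H %*% H = 2^d I.
walsh_matrix <- function(d) {
  n <- 2^d
  z <- 0:(n - 1)
  H <- outer(z, z, function(a, b) {
    v <- bitwAnd(a, b)
    p <- integer(length(v))
    for (b2 in 0:(d - 1)) p <- p + bitwAnd(bitwShiftR(v, b2), 1)
    (-1)^p
  })
  H
}

subset_order <- function(d) vapply(0:(2^d - 1), bitcount, numeric(1))

#' Walsh-Fourier decomposition of a diallelic subgraph
#'
#' Writes subgraph fitness as f(z) = sum_k fhat_k (-1)^(z.k) over site
#' subsets k; the coefficient of subset k is
#' fhat_k = 2^-d sum_z f(z) (-1)^(z.k). Coefficients of order |k| = 1 are
#' main effects, |k| = 2 pairwise epistasis, |k| >= 3 higher-order
#' epistasis. Parseval: sum_k fhat_k^2 = mean(f^2).
#'
#' @param sub A complete `diallelic_subgraph` (or a plain z-ordered fitness
#'   vector of length 2^d).
#' @return Object of class `fourier_spectrum`: list with `d`,
#'   `coefficients` (length 2^d, named by subset bitmask), `order` (|k| per
#'   coefficient), `variance_fraction` (share of non-constant Parseval
#'   variance per order 1..d), and the input fitness `f`.
#' @export
fourier_transform <- function(sub) {
  f <- if (inherits(sub, "diallelic_subgraph")) {
    if (!sub$complete) stop("subgraph has missing variants")
    sub$w
  } else {
    as.numeric(sub)
  }
  d <- round(log2(length(f)))
  stopifnot(2^d == length(f))
  H <- walsh_matrix(d)
  coef <- as.numeric(H %*% f) / 2^d
  names(coef) <- 0:(2^d - 1)
  ord <- subset_order(d)
  ss <- coef^2
  nonconst <- sum(ss[ord > 0])
  vf <- vapply(seq_len(d), function(o)
    if (nonconst > 0) sum(ss[ord == o]) / nonconst else NA_real_,
    numeric(1))
  structure(
    list(d = d, coefficients = coef, order = ord,
         variance_fraction = stats::setNames(vf, seq_len(d)), f = f),
    class = "fourier_spectrum"
  )
}

#' Reconstruct fitness from a truncated Fourier expansion
#'
#' Keeps only coefficients of subsets with |k| <= max_order. At
#' max_order = d the reconstruction reproduces the input exactly; the gap
#' at max_order = 2 measures higher-order epistasis.
#'
#' @param spectrum A `fourier_spectrum`.
#' @param max_order Truncation order in 0..d.
#' @return List with `fitness` (reconstructed vector), `r_squared`
#'   (squared Pearson correlation with the input; 0 when the reconstruction
#'   is constant), and `parseval_share` (truncated non-constant power over
#'   total non-constant power).
#' @export
truncated_reconstruction <- function(spectrum, max_order) {
  stopifnot(inherits(spectrum, "fourier_spectrum"),
            max_order >= 0, max_order <= spectrum$d)
  d <- spectrum$d
  H <- walsh_matrix(d)
  keep <- spectrum$order <= max_order
  rec <- as.numeric(H[, keep, drop = FALSE] %*% spectrum$coefficients[keep])
  r2 <- if (stats::sd(rec) == 0 || stats::sd(spectrum$f) == 0) 0
        else stats::cor(rec, spectrum$f)^2
  ss <- spectrum$coefficients^2
  nonconst <- sum(ss[spectrum$order > 0])
  pshare <- if (nonconst > 0)
    sum(ss[spectrum$order > 0 & keep]) / nonconst else NA_real_
  list(fitness = rec, r_squared = r2, parseval_share = pshare)
}

#' Zero out higher-order epistasis in a subgraph
#'
#' Returns the order-<=2 Fourier reconstruction as a new subgraph, so that
#' ruggedness and path accessibility can be re-analyzed with the
#' higher-order terms removed.
#'
#' @param sub A complete `diallelic_subgraph`.
#' @return A `diallelic_subgraph` with the truncated fitness values.
#' @export
remove_higher_order <- function(sub) {
  stopifnot(inherits(sub, "diallelic_subgraph"))
  spec <- fourier_transform(sub)
  rec <- truncated_reconstruction(spec, min(2, spec$d))
  out <- sub
  out$w <- rec$fitness
  out
}

#' Screen subgraphs for higher-order epistasis
#'
#' For every complete diallelic subgraph between `source` and a genotype at
#' Hamming distance d, computes the fraction of fitness variance explained
#' by the order-2 truncated reconstruction, ranks subgraphs ascending (least
#' explained = strongest higher-order epistasis first) and returns the
#' bottom `quantile` together with the position frequency matrix of their
#' destination genotypes. Ties in the ranking are broken by destination
#' lexicographic order, so the screen is deterministic.
#'
#' @param ls A `fitness_landscape`.
#' @param source Source genotype.
#' @param quantile Fraction of subgraphs to flag (default 0.001).
#' @param d Destination Hamming distance (default `ls$L`).
#' @param measure `"r_squared"` (squared Pearson correlation, default) or
#'   `"parseval"` for ranking.
#' @return List with `table` (destination, r_squared, parseval_share,
#'   sorted ascending by the ranking measure), `selected` (flagged
#'   destinations), `pfm` (L x alphabet position frequency matrix of the
#'   flagged destinations), `n_complete`.
#' @export
higher_order_screen <- function(ls, source, quantile = 0.001, d = ls$L,
                                measure = c("r_squared", "parseval")) {
  measure <- match.arg(measure)
  stopifnot(quantile > 0, quantile < 1)
  space <- all_genotypes(ls$alphabet, ls$L)
  cs <- strsplit(source, "")[[1]]
  sm <- genotype_matrix(space)
  hd <- rowSums(sm != matrix(cs, nrow(sm), ls$L, byrow = TRUE))
  dests <- space[hd == d]
  # fitness of all 2^d members for every destination, as a matrix
  zb <- z_bits(d)
  n <- length(dests)
  W <- matrix(NA_real_, n, 2^d)
  dm <- genotype_matrix(dests)
  for (r in seq_len(nrow(zb))) {
    gm <- matrix(cs, n, ls$L, byrow = TRUE)
    sites_masks <- which(zb[r, ] == 1)
    # which of the d differing sites carry the destination allele: note the
    # differing sites vary per destination (always all L here when d == L,
    # otherwise computed per destination below)
    if (d == ls$L) {
      for (i in sites_masks) gm[, i] <- dm[, i]
    } else {
      stop("higher_order_screen currently requires d == L")
    }
    W[, r] <- ls$entries[matrix_genotype(gm)]
  }
  complete <- !apply(W, 1, anyNA)
  if (!any(complete)) stop("no complete subgraphs")
  W <- W[complete, , drop = FALSE]
  dests <- dests[complete]

  H <- walsh_matrix(d)
  Coef <- W %*% H / 2^d
  ord <- subset_order(d)
  keep <- ord <= 2
  Rec <- Coef[, keep, drop = FALSE] %*% t(H[, keep, drop = FALSE])
  # rowwise squared Pearson correlation between Rec and W
  r2 <- vapply(seq_len(nrow(W)), function(i) {
    if (stats::sd(Rec[i, ]) == 0 || stats::sd(W[i, ]) == 0) 0
    else stats::cor(Rec[i, ], W[i, ])^2
  }, numeric(1))
  ss <- Coef^2
  nonconst <- rowSums(ss[, ord > 0, drop = FALSE])
  pshare <- ifelse(nonconst > 0,
                   rowSums(ss[, ord > 0 & keep, drop = FALSE]) / nonconst,
                   NA_real_)
  tab <- data.frame(destination = dests, r_squared = r2,
                    parseval_share = pshare, stringsAsFactors = FALSE)
  key <- if (measure == "r_squared") tab$r_squared else tab$parseval_share
  tab <- tab[order(key, tab$destination), ]
  n_sel <- max(1, floor(quantile * nrow(tab)))
  selected <- tab$destination[seq_len(n_sel)]
  list(table = tab, selected = selected,
       pfm = position_frequency_matrix(selected, ls$alphabet),
       n_complete = nrow(tab))
}

#' Position frequency matrix of a genotype set
#'
#' @param genotypes Character vector of equal-length genotypes.
#' @param alphabet Letters to tabulate (default [AA_ALPHABET]).
#' @return List with `counts` and `frequencies` (L x alphabet matrices;
#'   frequency rows sum to 1).
#' @export
position_frequency_matrix <- function(genotypes, alphabet = AA_ALPHABET) {
  gm <- genotype_matrix(genotypes)
  counts <- t(apply(gm, 2, function(col)
    table(factor(col, levels = alphabet))))
  rownames(counts) <- paste0("site", seq_len(nrow(counts)))
  freq <- counts / rowSums(counts)
  list(counts = counts, frequencies = freq)
}
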