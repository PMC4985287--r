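#' Specification for a synthetic fitness landscape
#'
#' The generator draws a sparse log-linear landscape: log fitness is an
#' intercept (0 for WT) plus single-site effects, plus a sparse set of
#' pairwise interaction terms, plus a sparse set of three-way interaction
#' terms confined to one site triple, plus Gaussian measurement noise. A
#' random fraction of non-WT genotypes is then overwritten as lethal (w = 0)
#' and another fraction moved to the missing set. Defaults emulate the
#' four-site GB1 study conditions: 20 letters at L = 4 sites, 6.6% missing,
#' 19.7% lethal, three-way interactions among sites 39/41/54.
#'
#' @param L Number of sites (>= 2).
#' @param alphabet_size Letters per site, 2..20.
#' @param additive_sd SD of single-site effects on log fitness.
#' @param pairwise_density,pairwise_sd Fraction of nonzero pairwise terms and
#'   their SD.
#' @param threeway_sites Site triple (1-based positions) carrying three-way
#'   terms, or `NULL` for none. Default: positions of sites 39, 41, 54
#'   (i.e. c(1, 3, 4)) when L >= 4.
#' @param threeway_density,threeway_sd Sparsity and spread of three-way terms.
#' @param lethal_fraction Fraction of non-WT genotypes overwritten with w = 0.
#' @param missing_fraction Fraction of non-WT genotypes moved to the missing
#'   set.
#' @param noise_sd SD of Gaussian noise added to log fitness.
#' @param seed Integer seed; fixes the landscape completely.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(L = 4, alphabet_size = 20,
                           additive_sd = 0.5,
                           pairwise_density = 0.05, pairwise_sd = 0.3,
                           threeway_sites = if (L >= 4) c(1, 3, 4) else NULL,
                           threeway_density = 0.02, threeway_sd = 0.4,
                           lethal_fraction = 0.197,
                           missing_fraction = 0.066,
                           noise_sd = 0.05, seed = 1) {
  stopifnot(L >= 2, alphabet_size >= 2, alphabet_size <= 20,
            pairwise_density >= 0, pairwise_density <= 1,
            threeway_density >= 0, threeway_density <= 1,
            lethal_fraction >= 0, lethal_fraction < 1,
            missing_fraction >= 0, missing_fraction < 1,
            noise_sd >= 0, additive_sd >= 0)
  if (!is.null(threeway_sites)) {
    if (L < 3) stop("threeway_sites given with L < 3")
    stopifnot(length(threeway_sites) == 3,
              all(threeway_sites %in% seq_len(L)))
  }
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a synthetic fitness landscape with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `landscape` (a `fitness_landscape`) and
#'   `truth` (ground-truth model coefficients: `intercept`, sparse named
#'   vectors `single`, `pairwise`, `threeway`, and the log-fitness before
#'   lethality/missingness). Coefficient names follow the imputation module's
#'   indicator naming, e.g. `"39V>W"`, `"39V>W|54V>A"`, `"39W|41L|54H"`.
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  alphabet <- AA_ALPHABET[seq_len(spec$alphabet_size)]
  L <- spec$L
  site_labels <- if (L == 4) c(39L, 40L, 41L, 54L) else seq_len(L)
  genos <- all_genotypes(alphabet, L)
  # wt carries alphabet[1] at every site; all coefficients are relative to it
  wt <- paste(rep(alphabet[1], L), collapse = "")
  gm <- genotype_matrix(genos)
  mut <- gm != alphabet[1]  # n x L: is site mutated

  a1 <- spec$alphabet_size - 1
  mut_alleles <- alphabet[-1]

  # single-site effects beta[site, allele]
  beta <- matrix(stats::rnorm(L * a1, 0, spec$additive_sd), L, a1,
                 dimnames = list(NULL, mut_alleles))
  logf <- numeric(length(genos))
  for (s in seq_len(L)) {
    idx <- match(gm[, s], mut_alleles)
    hit <- !is.na(idx)
    logf[hit] <- logf[hit] + beta[s, idx[hit]]
  }
  single <- stats::setNames(
    as.vector(t(beta)),
    as.vector(vapply(seq_len(L), function(s)
      paste0(site_labels[s], alphabet[1], ">", mut_alleles), character(a1)))
  )

  # pairwise terms gamma[(site pair), allele pair], sparse
  pair_sites <- utils::combn(L, 2)
  pairwise <- numeric(0)
  for (p in seq_len(ncol(pair_sites))) {
    s1 <- pair_sites[1, p]; s2 <- pair_sites[2, p]
    nz <- stats::runif(a1 * a1) < spec$pairwise_density
    if (!any(nz)) next
    gam <- matrix(0, a1, a1)
    gam[nz] <- stats::rnorm(sum(nz), 0, spec$pairwise_sd)
    i1 <- match(gm[, s1], mut_alleles)
    i2 <- match(gm[, s2], mut_alleles)
    hit <- !is.na(i1) & !is.na(i2)
    logf[hit] <- logf[hit] + gam[cbind(i1[hit], i2[hit])]
    nm <- outer(mut_alleles, mut_alleles, function(x, y)
      paste0(site_labels[s1], alphabet[1], ">", x, "|",
             site_labels[s2], alphabet[1], ">", y))
    pairwise <- c(pairwise, stats::setNames(gam[nz], nm[nz]))
  }

  # three-way terms on the designated triple
  threeway <- numeric(0)
  if (!is.null(spec$threeway_sites)) {
    ts <- sort(spec$threeway_sites)
    nz <- stats::runif(a1^3) < spec$threeway_density
    if (any(nz)) {
      del <- array(0, dim = rep(a1, 3))
      del[nz] <- stats::rnorm(sum(nz), 0, spec$threeway_sd)
      i1 <- match(gm[, ts[1]], mut_alleles)
      i2 <- match(gm[, ts[2]], mut_alleles)
      i3 <- match(gm[, ts[3]], mut_alleles)
      hit <- !is.na(i1) & !is.na(i2) & !is.na(i3)
      logf[hit] <- logf[hit] + del[cbind(i1[hit], i2[hit], i3[hit])]
      nm <- array(
        outer(outer(paste0(site_labels[ts[1]], mut_alleles),
                    paste0(site_labels[ts[2]], mut_alleles), paste, sep = "|"),
              paste0(site_labels[ts[3]], mut_alleles), paste, sep = "|"),
        dim = rep(a1, 3))
      threeway <- stats::setNames(del[nz], nm[nz])
    }
  }

  noise <- stats::rnorm(length(genos), 0, spec$noise_sd)
  noise[genos == wt] <- 0  # wt anchors the scale exactly
  logf_noisy <- logf + noise
  w <- exp(logf_noisy)
  w[genos == wt] <- 1
  names(w) <- genos

  non_wt <- setdiff(genos, wt)
  n_lethal <- round(spec$lethal_fraction * length(non_wt))
  lethal <- sample(non_wt, n_lethal)
  w[lethal] <- 0
  n_missing <- round(spec$missing_fraction * length(non_wt))
  missing <- sample(non_wt, n_missing)
  entries <- w[!(names(w) %in% missing)]

  ls <- fitness_landscape(wt = wt, entries = entries, alphabet = alphabet,
                          site_labels = site_labels, missing = missing)
  list(
    landscape = ls,
    truth = list(intercept = 0, single = single, pairwise = pairwise,
                 threeway = threeway,
                 log_fitness = stats::setNames(logf, genos),
                 lethal = lethal, missing = missing)
  )
}

#' Simulate sequencing count tables from a landscape
#'
#' Input-library counts are multinomial over genotypes with
#' Dirichlet-perturbed frequencies (library construction is never perfectly
#' uniform); selected-library counts are multinomial with probabilities
#' proportional to input frequency times fitness. Inverts the enrichment
#' definition of fitness, so [compute_fitness()] recovers the landscape as
#' depth grows.
#'
#' @param ls A `fitness_landscape` (missing genotypes draw no reads; WT must
#'   not be missing).
#' @param depth_input,depth_selected Total read counts for the two libraries.
#' @param seed Integer seed.
#' @param dirichlet_conc Concentration of the per-genotype Dirichlet
#'   frequency perturbation (larger = more uniform library).
#' @return Data frame with columns `genotype`, `count_input`,
#'   `count_selected`.
#' @export
generate_counts <- function(ls, depth_input, depth_selected, seed = 1,
                            dirichlet_conc = 20) {
  if (ls$wt %in% ls$missing) stop("WT must not be missing")
  if (depth_input <= 0 || depth_selected <= 0) stop("zero sequencing depth")
  set.seed(seed)
  genos <- names(ls$entries)
  # Dirichlet(conc) via gammas: perturbed input frequencies
  p_in <- stats::rgamma(length(genos), shape = dirichlet_conc, rate = 1)
  p_in <- p_in / sum(p_in)
  c_in <- stats::rmultinom(1, size = depth_input, prob = p_in)[, 1]
  p_sel <- p_in * ls$entries
  if (sum(p_sel) == 0) stop("all-lethal landscape: no selected reads possible")
  c_sel <- stats::rmultinom(1, size = depth_selected, prob = p_sel)[, 1]
  data.frame(genotype = genos, count_input = as.integer(c_in),
             count_selected = as.integer(c_sel), stringsAsFactors = FALSE)
}
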