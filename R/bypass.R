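#' Taylor expansion coefficients of a 3-site diallelic cube
#'
#' For fitness values f000..f111 (string digits ordered so that the LEFTMOST
#' digit is the third/detour site and the rightmost two digits the focal
#' interacting pair), solves the triangular Boolean-hypercube Taylor system:
#' f000 = a0, f001 = a0 + a1, ..., f111 = a0 + a1 + a2 + a3 + a12 + a13 +
#' a23 + a123. a123 is the unique three-way (higher-order) interaction term.
#'
#' @param f Named or ordered numeric vector of the 8 fitness values in order
#'   f000, f001, f010, f011, f100, f101, f110, f111.
#' @return Object of class `taylor_cube`: list with `f` and `alpha` (named
#'   a0, a1, a2, a3, a12, a13, a23, a123).
#' @export
taylor_coefficients <- function(f) {
  stopifnot(length(f) == 8, all(is.finite(f)))
  lbl <- c("f000", "f001", "f010", "f011", "f100", "f101", "f110", "f111")
  if (!is.null(names(f))) f <- f[lbl]
  names(f) <- lbl
  # design: row per corner (z1 = last digit, z3 = first digit), column per
  # coefficient; entry 1 when the coefficient's sites are all mutated
  z1 <- c(0, 1, 0, 1, 0, 1, 0, 1)
  z2 <- c(0, 0, 1, 1, 0, 0, 1, 1)
  z3 <- c(0, 0, 0, 0, 1, 1, 1, 1)
  M <- cbind(a0 = 1, a1 = z1, a2 = z2, a3 = z3,
             a12 = z1 * z2, a13 = z1 * z3, a23 = z2 * z3,
             a123 = z1 * z2 * z3)
  alpha <- solve(M, unname(f))
  names(alpha) <- colnames(M)
  structure(list(f = f, alpha = alpha), class = "taylor_cube")
}

#' Check whether a detour-bypass scenario forces higher-order epistasis
#'
#' A reciprocal-sign quad on the base face (third site unmutated) combined
#' with an adaptive detour (gain then loss of the third-site mutation)
#' admits three edge configurations on the lifted face. When the lifted
#' face shows magnitude epistasis (scenario B) or sign epistasis with the
#' 001 -> 101 edge open (scenario C), the inequality chain forces the
#' three-way Taylor term a123 < 0: higher-order epistasis is necessary.
#' When the 001 -> 101 edge is closed (scenario D) all inequalities can be
#' met with a123 = 0.
#'
#' @param cube A `taylor_cube` (or the 8 fitness values, see
#'   [taylor_coefficients()]).
#' @param scenario `"B"`, `"C"` or `"D"`.
#' @return `TRUE` if a123 != 0 is forced by the scenario (B, C), `FALSE`
#'   for D. Errors if the cube violates the scenario's defining edge
#'   inequalities.
#' @export
verify_necessity <- function(cube, scenario = c("B", "C", "D")) {
  scenario <- match.arg(scenario)
  if (!inherits(cube, "taylor_cube")) cube <- taylor_coefficients(cube)
  f <- cube$f
  common <- c(
    f["f001"] < f["f000"],          # a1 < 0
    f["f010"] < f["f000"],          # a2 < 0
    f["f011"] > f["f001"],          # a2 + a12 > 0
    f["f011"] > f["f010"],          # a1 + a12 > 0
    f["f100"] > f["f000"],          # detour gain: a3 > 0
    f["f011"] > f["f111"]           # loss step: a3 + a13 + a23 + a123 < 0
  )
  extra <- switch(scenario,
    B = c(f["f101"] > f["f100"],    # a1 + a13 > 0
          f["f110"] > f["f100"]),   # a2 + a23 > 0
    C = c(f["f101"] > f["f001"],    # a3 + a13 > 0
          f["f110"] > f["f100"]),   # a2 + a23 > 0
    D = c(f["f101"] < f["f001"])    # a3 + a13 < 0
  )
  if (!all(c(common, extra))) {
    stop("cube does not satisfy the scenario-", scenario,
         " edge inequalities")
  }
  scenario %in% c("B", "C")
}

#' Find conversion bypasses of a reciprocal-sign quad
#'
#' A reciprocal-sign interaction blocks both direct routes from the
#' background 00 to the fitter double mutant 11. A conversion bypass
#' substitutes one interacting site with a third amino acid c
#' (00 -> c0 -> c1 -> 11): the extra letter is gained and later lost. The
#' candidate succeeds when that four-step route increases fitness strictly
#' at every step. There are at most 19 * 2 - 2 = 36 candidates.
#'
#' @param ls A `fitness_landscape`.
#' @param background Background genotype (the "00" corner).
#' @param sites Length-2 integer: the interacting site positions (1-based).
#' @param subs Length-2 character: the substitution alleles at those sites.
#' @param check_type Verify the focal quad is reciprocal sign with
#'   w11 > w00 (default TRUE).
#' @return List with `candidates` (data frame: site, allele, success),
#'   `n_success`, `n_skipped_missing` (candidates with an unmeasured
#'   intermediate), `success` (any bypass found).
#' @export
find_conversion_bypasses <- function(ls, background, sites, subs,
                                     check_type = TRUE) {
  w <- focal_quad(ls, background, sites, subs)
  if (check_type) {
    if (!identical(classify_quad(w["ab"], w["a"], w["b"], w["bg"]),
                   "reciprocal_sign") || !(w["ab"] > w["bg"])) {
      stop("focal quad is not reciprocal sign with a fitter double mutant")
    }
  }
  chars <- strsplit(background, "")[[1]]
  cand <- list()
  for (k in 1:2) {
    s <- sites[k]
    other <- sites[3 - k]
    other_sub <- subs[3 - k]
    extra <- setdiff(ls$alphabet, c(chars[s], subs[k]))
    for (cc in extra) {
      g_c0 <- chars; g_c0[s] <- cc
      g_c1 <- g_c0; g_c1[other] <- other_sub
      w_c0 <- unname(ls$entries[matrix_genotype(g_c0)])
      w_c1 <- unname(ls$entries[matrix_genotype(g_c1)])
      missing <- is.na(w_c0) || is.na(w_c1)
      ok <- !missing &&
        w_c0 > w["bg"] && w_c1 > w_c0 && w["ab"] > w_c1
      cand[[length(cand) + 1]] <- data.frame(
        site = s, allele = cc, missing = missing, success = isTRUE(ok),
        stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(site = integer(0), allele = character(0),
               missing = logical(0), success = logical(0))
  list(candidates = cand, n_success = sum(cand$success),
       n_skipped_missing = sum(cand$missing),
       success = any(cand$success))
}

#' Find detour bypasses of a reciprocal-sign quad
#'
#' A detour bypass gains a mutation at a third site
#' (000 -> 100), crosses the lifted face to 111, and loses the third-site
#' mutation (111 -> 011). The candidate succeeds when some route
#' 000 -> 100 -> {110 or 101} -> 111 -> 011 increases fitness strictly at
#' every step. There are at most 19 * (L - 2) candidates. Successful
#' candidates are classified into the three lifted-face scenarios: B
#' (reciprocal sign changed to magnitude), C or D (changed to sign,
#' distinguished by whether the 001 -> 101 edge opens).
#'
#' @inheritParams find_conversion_bypasses
#' @return List with `candidates` (data frame: third_site, allele, missing,
#'   success, scenario), `n_success`, `n_skipped_missing`, `success`.
#' @export
find_detour_bypasses <- function(ls, background, sites, subs,
                                 check_type = TRUE) {
  if (ls$L < 3) stop("detour bypass requires L >= 3")
  w <- focal_quad(ls, background, sites, subs)
  if (check_type) {
    if (!identical(classify_quad(w["ab"], w["a"], w["b"], w["bg"]),
                   "reciprocal_sign") || !(w["ab"] > w["bg"])) {
      stop("focal quad is not reciprocal sign with a fitter double mutant")
    }
  }
  chars <- strsplit(background, "")[[1]]
  third_sites <- setdiff(seq_len(ls$L), sites)
  cand <- list()
  for (s3 in third_sites) {
    extra <- setdiff(ls$alphabet, chars[s3])
    for (cc in extra) {
      lift <- function(g) { g2 <- g; g2[s3] <- cc; g2 }
      g000 <- chars
      g001 <- chars; g001[sites[1]] <- subs[1]
      g010 <- chars; g010[sites[2]] <- subs[2]
      g011 <- g001; g011[sites[2]] <- subs[2]
      f100 <- unname(ls$entries[matrix_genotype(lift(g000))])
      f101 <- unname(ls$entries[matrix_genotype(lift(g001))])
      f110 <- unname(ls$entries[matrix_genotype(lift(g010))])
      f111 <- unname(ls$entries[matrix_genotype(lift(g011))])
      missing <- anyNA(c(f100, f101, f110, f111))
      success <- FALSE
      scenario <- NA_character_
      if (!missing) {
        up1 <- f100 > w["bg"]
        cross <- (f101 > f100 & f111 > f101) || (f110 > f100 & f111 > f110)
        down <- w["ab"] > f111
        success <- up1 && cross && down
        if (success) {
          scenario <- detour_scenario(
            f000 = w[["bg"]], f001 = w[["a"]], f010 = w[["b"]],
            f011 = w[["ab"]], f100 = f100, f101 = f101, f110 = f110,
            f111 = f111)
        }
      }
      cand[[length(cand) + 1]] <- data.frame(
        third_site = s3, allele = cc, missing = missing, success = success,
        scenario = scenario, stringsAsFactors = FALSE)
    }
  }
  cand <- if (length(cand)) do.call(rbind, cand) else
    data.frame(third_site = integer(0), allele = character(0),
               missing = logical(0), success = logical(0),
               scenario = character(0))
  list(candidates = cand, n_success = sum(cand$success),
       n_skipped_missing = sum(cand$missing),
       success = any(cand$success))
}

# Classify the lifted-face configuration of a successful detour bypass.
# Magnitude epistasis of the focal pair on the lifted background -> "B";
# sign epistasis -> "C" when, for some orientation of the focal pair
# (mut1, mut2), the 001->101 edge opens (f101 > f001) while 100->110 opens
# (f110 > f100); otherwise "D".
detour_scenario <- function(f000, f001, f010, f011, f100, f101, f110,
                            f111) {
  top <- classify_quad(f111, f101, f110, f100)
  if (identical(top, "magnitude")) return("B")
  # orientation 1: mut1 -> 001/101, mut2 -> 010/110
  c1 <- (f101 > f001) && (f110 > f100)
  # orientation 2: swap the focal pair roles
  c2 <- (f110 > f010) && (f101 > f100)
  if (c1 || c2) "C" else "D"
}

# Fitness of the four corners of the focal quad (bg, single a, single b,
# double ab) for background + (sites, subs).
focal_quad <- function(ls, background, sites, subs) {
  chars <- strsplit(background, "")[[1]]
  ga <- chars; ga[sites[1]] <- subs[1]
  gb <- chars; gb[sites[2]] <- subs[2]
  gab <- ga; gab[sites[2]] <- subs[2]
  w <- ls$entries[c(background, matrix_genotype(rbind(ga, gb, gab)))]
  stats::setNames(unname(w), c("bg", "a", "b", "ab"))
}

#' Survey bypass availability over sampled reciprocal-sign quads
#'
#' Samples 2 x 2 faces uniformly (background, site pair, allele pair),
#' keeps reciprocal-sign quads whose double mutant is fitter than the
#' background, and tests conversion and detour bypasses for each. Quads
#' with zero-fitness or missing members on the focal face are not testable
#' and are skipped.
#'
#' @param ls A `fitness_landscape`.
#' @param n_sample Number of faces to sample.
#' @param seed Sampling seed.
#' @return List with per-quad results (`quads` data frame) and a summary:
#'   counts, success fractions for conversion and detour (over all
#'   reciprocal-sign quads and over those with no missing candidate
#'   intermediates), and mean bypass counts.
#' @export
sample_bypass_survey <- function(ls, n_sample = 1000, seed = 1) {
  cls <- classify_neighborhood(ls, sample_size = n_sample, seed = seed)
  q <- cls$quads
  rs <- q[!is.na(q$type) & q$type == "reciprocal_sign" &
            !is.na(q$w_ab) & !is.na(q$w_bg) & q$w_ab > q$w_bg, ]
  res <- list()
  for (i in seq_len(nrow(rs))) {
    conv <- find_conversion_bypasses(ls, rs$background[i],
                                     c(rs$site_i[i], rs$site_j[i]),
                                     c(rs$a[i], rs$b[i]), check_type = FALSE)
    det <- if (ls$L >= 3) {
      find_detour_bypasses(ls, rs$background[i],
                           c(rs$site_i[i], rs$site_j[i]),
                           c(rs$a[i], rs$b[i]), check_type = FALSE)
    } else {
      list(n_success = NA_integer_, n_skipped_missing = NA_integer_,
           success = NA)
    }
    res[[i]] <- data.frame(
      background = rs$background[i], site_i = rs$site_i[i],
      site_j = rs$site_j[i], a = rs$a[i], b = rs$b[i],
      n_conversion = conv$n_success,
      conv_missing = conv$n_skipped_missing,
      conversion_success = conv$success,
      n_detour = det$n_success,
      det_missing = det$n_skipped_missing,
      detour_success = det$success,
      stringsAsFactors = FALSE)
  }
  quads <- if (length(res)) do.call(rbind, res) else NULL
  summary <- if (!is.null(quads)) {
    full_conv <- quads$conv_missing == 0
    full_det <- !is.na(quads$det_missing) & quads$det_missing == 0
    list(
      n_sampled = n_sample,
      n_reciprocal = nrow(quads),
      conversion_success_fraction = mean(quads$conversion_success),
      conversion_success_fraction_complete =
        if (any(full_conv)) mean(quads$conversion_success[full_conv])
        else NA_real_,
      mean_conversion_bypasses = mean(quads$n_conversion),
      detour_success_fraction = mean(quads$detour_success),
      detour_success_fraction_complete =
        if (any(full_det)) mean(quads$detour_success[full_det])
        else NA_real_,
      mean_detour_bypasses = mean(quads$n_detour)
    )
  } else {
    list(n_sampled = n_sample, n_reciprocal = 0)
  }
  list(quads = quads, summary = summary)
}
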