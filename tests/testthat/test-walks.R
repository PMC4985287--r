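test_that("graph edges point strictly uphill and peaks have no successors", {
  ls <- fitness_landscape("A", c(A = 1, C = 2), alphabet = c("A", "C"))
  g <- build_graph(ls)
  expect_identical(g$successors[[match("A", g$genotypes)]],
                   match("C", g$genotypes))
  expect_length(g$successors[[match("C", g$genotypes)]], 0)
  # equal fitness: no edge either way
  ls2 <- fitness_landscape("A", c(A = 1, C = 1), alphabet = c("A", "C"))
  g2 <- build_graph(ls2)
  expect_true(all(lengths(g2$successors) == 0))
})

test_that("peak finding matches the exhaustive local-maximum scan", {
  for (seed in 1:6) {
    ls <- make_rugged(alphabet = c("A", "C", "D", "E"), L = 3, seed = seed)
    g <- build_graph(ls)
    pk <- find_peaks(g)
    expect_identical(sort(pk$genotype), oracle_peaks(ls))
  }
  # additive landscape has exactly one peak
  lsa <- make_multiplicative(alphabet = c("A", "C", "D"), L = 3, seed = 3)
  expect_identical(nrow(find_peaks(build_graph(lsa))), 1L)
})

test_that("fixation probabilities implement the three models", {
  genos <- c("A", "C", "D", "E")
  ls <- fitness_landscape("A", c(A = 1, C = 1.1, D = 1.3, E = 0.9),
                          alphabet = genos)
  g <- build_graph(ls)
  # correlated: gains 0.1 and 0.3 -> 0.25 / 0.75
  pc <- fixation_probabilities(g, "A", "correlated")
  expect_equal(pc[c("C", "D")], c(C = 0.25, D = 0.75))
  # equal: 1/M each
  pe <- fixation_probabilities(g, "A", "equal")
  expect_equal(unname(pe), rep(0.5, 2))
  # greedy: all mass on the best neighbor
  pg <- fixation_probabilities(g, "A", "greedy")
  expect_equal(pg[["D"]], 1)
  expect_equal(sum(pg), 1)
  # peaks get the empty map
  expect_length(fixation_probabilities(g, "D", "equal"), 0)
})

test_that("walks increase fitness, end at peaks, and book-keep steps", {
  ls <- make_rugged(alphabet = c("A", "C", "D", "E"), L = 3, seed = 10,
                    lethal = 0.1)
  g <- build_graph(ls)
  peaks <- find_peaks(g)$genotype
  for (model in c("greedy", "correlated", "equal")) {
    walks <- simulate_walks(g, ls$wt, model, n = 40, seed = 3)
    for (wk in walks) {
      wpath <- ls$entries[wk$path]
      expect_true(all(diff(wpath) > 0))
      expect_true(wk$endpoint %in% peaks)
      expect_identical(wk$n_towards + wk$n_conversion + wk$n_detour,
                       wk$length)
      expect_identical(wk$n_towards - wk$n_detour,
                       as.integer(hamming_distance(wk$path[1],
                                                   wk$endpoint)))
      if (wk$length > 0) {
        steps <- vapply(seq_len(wk$length), function(i)
          hamming_distance(wk$path[i], wk$path[i + 1]), numeric(1))
        expect_true(all(steps == 1))
      }
    }
  }
  # greedy walks are all identical; starting at a peak gives length 0
  gw <- simulate_walks(g, ls$wt, "greedy", n = 5, seed = 1)
  expect_length(unique(vapply(gw, function(w)
    paste(w$path, collapse = "-"), character(1))), 1L)
  pw <- simulate_walks(g, peaks[1], "equal", n = 3, seed = 1)
  expect_true(all(vapply(pw, `[[`, numeric(1), "length") == 0))
})

test_that("endpoint frequencies match exact absorption probabilities", {
  ls <- make_rugged(alphabet = c("A", "C", "D", "E"), L = 3, seed = 17)
  g <- build_graph(ls)
  for (model in c("correlated", "equal")) {
    exact <- oracle_absorption(g, ls$wt, model)
    n <- 1000
    walks <- simulate_walks(g, ls$wt, model, n = n, seed = 29)
    ends <- vapply(walks, `[[`, character(1), "endpoint")
    for (pk in names(exact)) {
      p <- exact[pk]
      se <- sqrt(p * (1 - p) / n)
      expect_lt(abs(mean(ends == pk) - p), max(3 * se, 1e-9))
    }
    expect_true(all(ends %in% names(exact)))
  }
})

test_that("walk lengths order with selection strength", {
  for (seed in c(2, 12)) {
    spec <- synthetic_spec(L = 4, alphabet_size = 4, seed = seed,
                           pairwise_density = 0.2, threeway_density = 0.1,
                           lethal_fraction = 0.15, missing_fraction = 0)
    ls <- generate_landscape(spec)$landscape
    g <- build_graph(ls)
    ml <- vapply(c("greedy", "correlated", "equal"), function(m)
      step_class_fractions(
        simulate_walks(g, ls$wt, m, n = 300, seed = 7))["mean_length"],
      numeric(1))
    expect_lte(ml[1], ml[2] + 1e-9)
    expect_lte(ml[2], ml[3] + 1e-9)
  }
})

test_that("accessibility classes agree with shortest monotone paths", {
  # constructed reciprocal sign trap with a third-allele rescue
  genos <- all_genotypes(c("A", "C", "D"), 2)
  w <- stats::setNames(rep(0.01, 9), genos)
  w["AA"] <- 1; w["CA"] <- 0.5; w["AC"] <- 0.5; w["CC"] <- 2
  w["DA"] <- 1.5; w["DC"] <- 1.8
  ls <- fitness_landscape("AA", w, alphabet = c("A", "C", "D"))
  g <- build_graph(ls)
  acc <- accessibility(g, "AA", c("CC", "CA", "DA"))
  expect_identical(acc$class[acc$target == "CC"], "indirect_required")
  expect_identical(acc$path_length[acc$target == "CC"], 3L)
  expect_identical(acc$class[acc$target == "CA"], "inaccessible")
  expect_identical(acc$class[acc$target == "DA"], "direct")
  # multiplicative landscape: site effects have fixed signs, so a monotone
  # path can never pass through a deleterious substitution -- whatever is
  # accessible at all is accessible directly
  lsa <- make_multiplicative(alphabet = c("A", "C", "D"), L = 3, seed = 5)
  ga <- build_graph(lsa)
  fitter <- names(lsa$entries)[lsa$entries > lsa$entries[lsa$wt]]
  acca <- accessibility(ga, lsa$wt, fitter)
  expect_false(any(acca$class == "indirect_required"))
  # targets whose substitutions are all individually beneficial are direct
  singles <- neighbors(lsa$wt, aa_adjacency("full", alphabet = lsa$alphabet))
  up <- singles[lsa$entries[singles] > lsa$entries[lsa$wt]]
  acc1 <- accessibility(ga, lsa$wt, up)
  expect_true(all(acc1$class == "direct"))
})

test_that("accessibility matches brute-force monotone path enumeration", {
  ls <- make_rugged(alphabet = c("A", "C", "D"), L = 3, seed = 23)
  g <- build_graph(ls)
  start <- ls$wt
  targets <- setdiff(names(ls$entries)[ls$entries > ls$entries[start]],
                     start)
  acc <- accessibility(g, start, targets)
  # oracle: BFS-free recursive enumeration of monotone paths up to length 8
  reach_len <- function(from, target, depth) {
    if (from == target) return(0L)
    if (depth == 0) return(NA_integer_)
    best <- NA_integer_
    for (nb in g$genotypes[g$successors[[match(from, g$genotypes)]]]) {
      sub <- reach_len(nb, target, depth - 1)
      if (!is.na(sub) && (is.na(best) || sub + 1L < best)) best <- sub + 1L
    }
    best
  }
  for (i in seq_len(nrow(acc))) {
    len <- reach_len(start, acc$target[i], 8)
    expect_identical(acc$path_length[i], len)
  }
})

test_that("genetic-code constraints only remove accessibility", {
  spec <- synthetic_spec(L = 3, alphabet_size = 8, seed = 37,
                         threeway_sites = c(1, 2, 3),
                         lethal_fraction = 0.15, missing_fraction = 0)
  ls <- generate_landscape(spec)$landscape
  g_full <- build_graph(ls)
  g_code <- build_graph(ls, aa_adjacency("genetic_code",
                                         alphabet = ls$alphabet))
  targets <- names(ls$entries)[ls$entries > 1]
  acc_full <- accessibility(g_full, ls$wt, targets)
  acc_code <- accessibility(g_code, ls$wt, targets, distance = "genetic")
  reachable_full <- acc_full$target[acc_full$class != "inaccessible"]
  reachable_code <- acc_code$target[acc_code$class != "inaccessible"]
  expect_true(all(reachable_code %in% reachable_full))
})

test_that("greedy basins partition the graph and respect determinism", {
  ls <- make_rugged(alphabet = c("A", "C", "D", "E"), L = 3, seed = 41)
  g <- build_graph(ls)
  basins <- greedy_basins(g)
  expect_identical(sum(basins$sizes), length(g$genotypes))
  peaks <- find_peaks(g)
  expect_setequal(names(basins$sizes), peaks$genotype)
  # every node's greedy endpoint is its basin's peak
  walks <- simulate_walks(g, ls$wt, "greedy", n = 1, seed = 1)
  expect_identical(unname(basins$peak_of[ls$wt]), walks[[1]]$endpoint)
  # additive landscape: one basin holding everything
  lsa <- make_multiplicative(alphabet = c("A", "C"), L = 3, seed = 2)
  ba <- greedy_basins(build_graph(lsa))
  expect_length(ba$sizes, 1)
  expect_identical(unname(ba$sizes), 8L)
})

test_that("outcome entropy reflects endpoint diversity", {
  # single reachable peak: zero entropy
  lsa <- make_multiplicative(alphabet = c("A", "C", "D"), L = 3, seed = 7)
  ga <- build_graph(lsa)
  expect_equal(outcome_entropy(ga, lsa$wt, "equal", n = 100, seed = 1), 0)
  # entropy bounded by log of reachable peak count
  ls <- make_rugged(alphabet = c("A", "C", "D", "E"), L = 3, seed = 47)
  g <- build_graph(ls)
  ent <- outcome_entropy(g, ls$wt, "equal", n = 400, seed = 2)
  exact <- oracle_absorption(g, ls$wt, "equal")
  expect_lte(ent, log(length(exact)) + 1e-9)
  expect_gte(ent, 0)
})
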