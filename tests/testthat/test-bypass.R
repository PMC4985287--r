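test_that("taylor coefficients solve Eq-style cube expansion exactly", {
  # additive cube f(z) = 1 + z1 + z2 + z3
  f_add <- c(1, 2, 2, 3, 2, 3, 3, 4)
  tc <- taylor_coefficients(f_add)
  expect_equal(unname(tc$alpha[c("a12", "a13", "a23", "a123")]),
               rep(0, 4))
  # perturbing only f111 moves only a123
  f2 <- f_add; f2[8] <- f2[8] + 0.5
  expect_equal(unname(taylor_coefficients(f2)$alpha["a123"]), 0.5)
  # random cubes: match closed-form oracle and reconstruct exactly
  set.seed(41)
  for (i in 1:25) {
    f <- exp(rnorm(8, 0, 1))
    tc <- taylor_coefficients(f)
    expect_equal(tc$alpha, oracle_taylor(f), tolerance = 1e-12)
    a <- tc$alpha
    rec <- c(a["a0"],
             a["a0"] + a["a1"],
             a["a0"] + a["a2"],
             a["a0"] + a["a1"] + a["a2"] + a["a12"],
             a["a0"] + a["a3"],
             a["a0"] + a["a1"] + a["a3"] + a["a13"],
             a["a0"] + a["a2"] + a["a3"] + a["a23"],
             sum(a))
    expect_equal(unname(rec), f, tolerance = 1e-12)
  }
})

test_that("conversion bypass search equals exhaustive candidate testing", {
  set.seed(43)
  tested <- 0
  for (seed in 1:12) {
    ls <- make_rugged(alphabet = c("A", "C", "D", "E", "F"), L = 3,
                      seed = seed, lethal = 0.1)
    cls <- classify_neighborhood(ls, sample_size = 300, seed = seed)
    q <- cls$quads
    rs <- q[!is.na(q$type) & q$type == "reciprocal_sign" & q$w_ab > q$w_bg, ]
    if (nrow(rs) == 0) next
    for (i in seq_len(min(5, nrow(rs)))) {
      rep_ <- find_conversion_bypasses(
        ls, rs$background[i], c(rs$site_i[i], rs$site_j[i]),
        c(rs$a[i], rs$b[i]))
      oracle <- oracle_conversion(ls, rs$background[i],
                                  c(rs$site_i[i], rs$site_j[i]),
                                  c(rs$a[i], rs$b[i]))
      got <- with(rep_$candidates[rep_$candidates$success, ],
                  paste0(site, allele))
      expect_setequal(got, oracle)
      # candidate bound: (A-1)*2 - 2 per interacting pair
      expect_identical(nrow(rep_$candidates), as.integer(4 * 2 - 2))
      tested <- tested + 1
    }
  }
  expect_gt(tested, 5)
})

test_that("detour bypass search equals exhaustive candidate testing", {
  set.seed(47)
  tested <- 0
  for (seed in 1:12) {
    ls <- make_rugged(alphabet = c("A", "C", "D", "E"), L = 4,
                      seed = seed + 40, lethal = 0.1)
    cls <- classify_neighborhood(ls, sample_size = 300, seed = seed)
    q <- cls$quads
    rs <- q[!is.na(q$type) & q$type == "reciprocal_sign" & q$w_ab > q$w_bg, ]
    if (nrow(rs) == 0) next
    for (i in seq_len(min(4, nrow(rs)))) {
      rep_ <- find_detour_bypasses(
        ls, rs$background[i], c(rs$site_i[i], rs$site_j[i]),
        c(rs$a[i], rs$b[i]))
      oracle <- oracle_detour(ls, rs$background[i],
                              c(rs$site_i[i], rs$site_j[i]),
                              c(rs$a[i], rs$b[i]))
      got <- with(rep_$candidates[rep_$candidates$success, ],
                  paste0(third_site, allele))
      expect_setequal(got, oracle)
      # candidate bound: (A-1) * (L-2)
      expect_identical(nrow(rep_$candidates), as.integer(3 * 2))
      tested <- tested + 1
    }
  }
  expect_gt(tested, 5)
})

test_that("constructed bypasses are found with the expected routes", {
  # conversion: third allele D lifts the trap
  genos <- all_genotypes(c("A", "C", "D"), 2)
  w <- stats::setNames(rep(0.1, 9), genos)
  w["AA"] <- 1; w["CA"] <- 0.5; w["AC"] <- 0.5; w["CC"] <- 2
  w["DA"] <- 1.5; w["DC"] <- 1.8
  ls <- fitness_landscape("AA", w, alphabet = c("A", "C", "D"))
  bp <- find_conversion_bypasses(ls, "AA", c(1, 2), c("C", "C"))
  expect_identical(bp$n_success, 1L)
  expect_identical(bp$candidates$allele[bp$candidates$success], "D")
  # alphabet of two letters leaves no extra dimension
  ls2 <- fitness_landscape(
    "AA", stats::setNames(c(1, 0.5, 0.5, 2), all_genotypes(c("A", "C"), 2)),
    alphabet = c("A", "C"))
  bp2 <- find_conversion_bypasses(ls2, "AA", c(1, 2), c("C", "C"))
  expect_identical(nrow(bp2$candidates), 0L)
  expect_false(bp2$success)
  # detour via the third site (scenario B lifted face)
  genos3 <- all_genotypes(c("A", "C"), 3)
  w3 <- stats::setNames(numeric(8), genos3)
  w3[c("AAA", "CAA", "ACA", "CCA")] <- c(1, 0.5, 0.5, 2)
  w3[c("AAC", "CAC", "ACC", "CCC")] <- c(1.2, 1.4, 1.6, 1.9)
  ls3 <- fitness_landscape("AAA", w3, alphabet = c("A", "C"))
  bd <- find_detour_bypasses(ls3, "AAA", c(1, 2), c("C", "C"))
  expect_true(bd$success)
  expect_identical(bd$candidates$scenario[bd$candidates$success], "B")
  # non reciprocal-sign quads are rejected up front
  expect_error(find_conversion_bypasses(ls, "AA", c(1, 2), c("D", "C")),
               "reciprocal")
})

test_that("scenario B and C cubes always carry three-way epistasis", {
  # rejection-sample cubes satisfying the scenario inequalities
  set.seed(53)
  n <- 2e5
  f <- matrix(exp(rnorm(8 * n, 0, 0.8)), n, 8)
  colnames(f) <- c("f000", "f001", "f010", "f011",
                   "f100", "f101", "f110", "f111")
  common <- f[, "f001"] < f[, "f000"] & f[, "f010"] < f[, "f000"] &
    f[, "f011"] > f[, "f001"] & f[, "f011"] > f[, "f010"] &
    f[, "f100"] > f[, "f000"] & f[, "f011"] > f[, "f111"]
  scenB <- common & f[, "f101"] > f[, "f100"] & f[, "f110"] > f[, "f100"]
  scenC <- common & f[, "f101"] > f[, "f001"] & f[, "f110"] > f[, "f100"]
  a123 <- f[, "f111"] - f[, "f110"] - f[, "f101"] - f[, "f011"] +
    f[, "f100"] + f[, "f010"] + f[, "f001"] - f[, "f000"]
  expect_gt(sum(scenB), 50)
  expect_gt(sum(scenC), 50)
  expect_true(all(a123[scenB] < -1e-12))
  expect_true(all(a123[scenC] < -1e-12))
  # verify_necessity agrees on a sample of them
  for (i in utils::head(which(scenB), 10)) {
    expect_true(verify_necessity(taylor_coefficients(f[i, ]), "B"))
  }
  for (i in utils::head(which(scenC), 10)) {
    expect_true(verify_necessity(taylor_coefficients(f[i, ]), "C"))
  }
})

test_that("a scenario D witness exists with exactly zero a123", {
  # built from alpha: a0=2, a1=-1, a2=-0.1, a3=0.2, a12=2, a13=-0.5,
  # a23=0.2, a123=0
  f <- c(f000 = 2, f001 = 1, f010 = 1.9, f011 = 2.9,
         f100 = 2.2, f101 = 0.7, f110 = 2.3, f111 = 2.8)
  tc <- taylor_coefficients(f)
  expect_equal(unname(tc$alpha["a123"]), 0, tolerance = 1e-12)
  expect_false(verify_necessity(tc, "D"))
  # and the detour route is open despite a123 = 0:
  # 000 -> 100 -> 110 -> 111 -> 011 strictly increasing then decreasing loss
  expect_true(f["f100"] > f["f000"] && f["f110"] > f["f100"] &&
                f["f111"] > f["f110"] && f["f011"] > f["f111"])
  # wrong-scenario preconditions are rejected
  expect_error(verify_necessity(tc, "B"), "inequalit")
})
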