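#' Build the sparse log-linear model design matrix
#'
#' One row per genotype, one binary indicator column per term of the fitness
#' model: every single mutation relative to the wild type
#' (N_M = (A-1) * L; 76 for the 20-letter, 4-site space), every pairwise
#' mutation combination (N_P = (A-1)^2 * choose(L,2); 2166), and every
#' three-way mutation combination at the designated site triple
#' (N_T = (A-1)^3; 6859). With the intercept the 20-letter 4-site model has
#' 9102 coefficients. The wild-type row is all zeros.
#'
#' @param genotypes Character vector of genotypes.
#' @param wt Wild-type genotype string.
#' @param alphabet Alphabet of the space.
#' @param site_labels Site labels used in coefficient names.
#' @param threeway_sites Positions (1-based) of the three-way interaction
#'   triple, or `NULL` to omit three-way terms. Default c(1, 3, 4) for
#'   L = 4 (sites 39, 41, 54).
#' @return Sparse `dgCMatrix` with named columns ("39V>W",
#'   "39V>W|54V>A", "39W|41L|54H" style).
#' @export
build_design <- function(genotypes, wt, alphabet = AA_ALPHABET,
                         site_labels = NULL,
                         threeway_sites = if (nchar(wt) >= 4) c(1, 3, 4)
                                          else NULL) {
  L <- nchar(wt)
  if (is.null(site_labels)) {
    site_labels <- if (L == 4) c(39L, 40L, 41L, 54L) else seq_len(L)
  }
  wtc <- strsplit(wt, "")[[1]]
  gm <- genotype_matrix(genotypes)
  n <- nrow(gm)
  a1 <- length(alphabet) - 1

  # per-site mutant-allele index (NA when the site carries the wt allele)
  mut_levels <- lapply(seq_len(L), function(s) setdiff(alphabet, wtc[s]))
  midx <- sapply(seq_len(L), function(s) match(gm[, s], mut_levels[[s]]))
  if (n == 1) midx <- matrix(midx, nrow = 1)

  ii <- list(); jj <- list()
  col_names <- character(0)
  ncol_used <- 0

  single_name <- function(s, a) paste0(site_labels[s], wtc[s], ">", a)

  # single-mutation indicators, site-major then allele order
  for (s in seq_len(L)) {
    col_names <- c(col_names, single_name(s, mut_levels[[s]]))
    hit <- which(!is.na(midx[, s]))
    ii[[length(ii) + 1]] <- hit
    jj[[length(jj) + 1]] <- ncol_used + midx[hit, s]
    ncol_used <- ncol_used + a1
  }

  # pairwise indicators
  pair_sites <- utils::combn(L, 2)
  for (p in seq_len(ncol(pair_sites))) {
    s1 <- pair_sites[1, p]; s2 <- pair_sites[2, p]
    nm <- outer(mut_levels[[s1]], mut_levels[[s2]], function(x, y)
      paste0(single_name(s1, x), "|", single_name(s2, y)))
    col_names <- c(col_names, as.vector(nm))  # column-major: allele2 slow
    hit <- which(!is.na(midx[, s1]) & !is.na(midx[, s2]))
    jj[[length(jj) + 1]] <- ncol_used +
      (midx[hit, s2] - 1) * a1 + midx[hit, s1]
    ii[[length(ii) + 1]] <- hit
    ncol_used <- ncol_used + a1 * a1
  }

  # three-way indicators at the designated triple
  if (!is.null(threeway_sites)) {
    ts <- sort(threeway_sites)
    nm <- as.vector(outer(outer(
      paste0(site_labels[ts[1]], mut_levels[[ts[1]]]),
      paste0(site_labels[ts[2]], mut_levels[[ts[2]]]), paste, sep = "|"),
      paste0(site_labels[ts[3]], mut_levels[[ts[3]]]), paste, sep = "|"))
    col_names <- c(col_names, nm)
    hit <- which(!is.na(midx[, ts[1]]) & !is.na(midx[, ts[2]]) &
                   !is.na(midx[, ts[3]]))
    jj[[length(jj) + 1]] <- ncol_used +
      (midx[hit, ts[3]] - 1) * a1 * a1 +
      (midx[hit, ts[2]] - 1) * a1 + midx[hit, ts[1]]
    ii[[length(ii) + 1]] <- hit
    ncol_used <- ncol_used + a1^3
  }

  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = 1,
    dims = c(n, ncol_used),
    dimnames = list(genotypes, col_names)
  )
}

#' Fit the sparse log-linear fitness model by lasso
#'
#' Regresses natural-log fitness of the non-lethal measured variants on the
#' binary indicators of [build_design()] with an L1 penalty (coordinate
#' descent via glmnet; objective (1/2n) RSS + lambda * sum|coef|, intercept
#' unpenalized, indicators unstandardized). K-fold cross-validation MSE (on
#' log fitness) is reported per lambda; the model at `lambda_choice`
#' (default 1e-4) is returned.
#'
#' @param ls A `fitness_landscape`.
#' @param lambda_grid Descending vector of penalty values.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param lambda_choice Penalty at which coefficients are extracted: a
#'   number, or `"cv"` to take the CV-MSE-minimizing value on the grid.
#' @param threeway_sites Passed to [build_design()].
#' @return Object of class `fitness_model`: list with `intercept`,
#'   `coefficients` (named, sparse), `lambda`, `cv` (data frame lambda /
#'   cv_mse / cv_se / nonzero), `ols_cv_mse` (unpenalized reference), and
#'   the design metadata needed to predict.
#' @export
fit_l1 <- function(ls, lambda_grid = 10^seq(-1, -5, length.out = 9),
                   folds = 10, seed = 1, lambda_choice = 1e-4,
                   threeway_sites = if (ls$L >= 4) c(1, 3, 4) else NULL) {
  fit_set <- names(ls$entries)[ls$origin == "measured" & ls$entries > 0]
  if (length(fit_set) < folds) stop("fewer fit rows than CV folds")
  y <- log(ls$entries[fit_set])
  X <- build_design(fit_set, ls$wt, alphabet = ls$alphabet,
                    site_labels = ls$site_labels,
                    threeway_sites = threeway_sites)
  if (is.numeric(lambda_choice)) {
    lambda_grid <- sort(unique(c(lambda_grid, lambda_choice)),
                        decreasing = TRUE)
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  cvfit <- glmnet::cv.glmnet(X, y, family = "gaussian", alpha = 1,
                             lambda = lambda_grid, foldid = foldid,
                             standardize = FALSE, thresh = 1e-9)
  fit <- cvfit$glmnet.fit
  if (identical(lambda_choice, "cv")) lambda_choice <- cvfit$lambda.min
  i_choice <- which.min(abs(fit$lambda - lambda_choice))
  beta <- fit$beta[, i_choice]
  cv <- data.frame(lambda = cvfit$lambda, cv_mse = cvfit$cvm,
                   cv_se = cvfit$cvsd, nonzero = cvfit$nzero)
  structure(
    list(
      intercept = unname(fit$a0[i_choice]),
      coefficients = beta[beta != 0],
      lambda = fit$lambda[i_choice],
      cv = cv,
      response = "log fitness (natural log)",
      wt = ls$wt, alphabet = ls$alphabet, site_labels = ls$site_labels,
      threeway_sites = threeway_sites,
      n_terms = ncol(X) + 1
    ),
    class = "fitness_model"
  )
}

#' @export
print.fitness_model <- function(x, ...) {
  cat("Sparse log-linear fitness model:", x$n_terms, "terms,",
      length(x$coefficients), "nonzero at lambda =", x$lambda, "\n")
  invisible(x)
}

#' Predict fitness for genotypes from a fitted model
#'
#' @param object A `fitness_model`.
#' @param genotypes Character vector of genotypes.
#' @param ... Unused.
#' @return Numeric predicted fitness, exp(predicted log fitness).
#' @export
predict.fitness_model <- function(object, genotypes, ...) {
  X <- build_design(genotypes, object$wt, alphabet = object$alphabet,
                    site_labels = object$site_labels,
                    threeway_sites = object$threeway_sites)
  eta <- object$intercept +
    as.numeric(X[, names(object$coefficients), drop = FALSE] %*%
                 object$coefficients)
  exp(stats::setNames(eta, genotypes))
}

#' Impute missing-variant fitness
#'
#' Every genotype in the missing set receives the model-predicted fitness
#' (origin flag `"imputed"`); measured entries are untouched. Lethal
#' variants are never overwritten, and imputation never produces an exact 0.
#'
#' @param ls A `fitness_landscape`.
#' @param model A `fitness_model` from [fit_l1()].
#' @return The completed `fitness_landscape` (empty missing set).
#' @export
impute <- function(ls, model) {
  if (length(ls$missing) == 0) return(ls)
  pred <- predict(model, ls$missing)
  entries <- c(ls$entries, pred)
  origin <- c(ls$origin,
              stats::setNames(rep("imputed", length(pred)), names(pred)))
  fitness_landscape(wt = ls$wt, entries = entries, origin = origin,
                    alphabet = ls$alphabet, site_labels = ls$site_labels,
                    missing = character(0))
}

#' Export model coefficients as sparse JSON-ready list
#'
#' @param model A `fitness_model`.
#' @return List with `intercept`, `lambda`, `response` and `coefficients`
#'   (named list of nonzero values).
#' @export
model_coefficients <- function(model) {
  list(intercept = model$intercept, lambda = model$lambda,
       response = model$response,
       coefficients = as.list(model$coefficients))
}
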