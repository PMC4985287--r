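#' Construct a fitness landscape object
#'
#' A fitness landscape maps every genotype in `alphabet^L` either to a
#' nonnegative wild-type-relative fitness or to the missing set. Fitness is
#' unitless: the wild type is 1 by construction, 0 means no measurable
#' activity (lethal in the assay sense).
#'
#' @param wt Wild-type genotype string (fitness anchor).
#' @param entries Named numeric vector: genotype -> fitness (>= 0).
#' @param origin Named character vector parallel to `entries`, values
#'   `"measured"` or `"imputed"`. Defaults to all measured.
#' @param alphabet Amino-acid letters spanning the space (default: letters
#'   observed across entries, missing and wt).
#' @param site_labels Integer labels of the mutated sites
#'   (default `c(39, 40, 41, 54)` truncated/padded to L).
#' @param missing Character vector of genotypes with no fitness value. If
#'   `NULL`, computed as the complement of `entries` in `alphabet^L`.
#' @return Object of class `fitness_landscape`.
#' @export
fitness_landscape <- function(wt, entries, origin = NULL, alphabet = NULL,
                              site_labels = NULL, missing = NULL) {
  if (is.null(names(entries))) stop("entries must be named by genotype")
  L <- nchar(wt)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(strsplit(
      paste(c(names(entries), missing, wt), collapse = ""), "")[[1]]))
  }
  check_genotype(c(wt, names(entries), missing), L = L, alphabet = alphabet)
  if (is.null(origin)) {
    origin <- stats::setNames(rep("measured", length(entries)), names(entries))
  }
  if (!all(origin %in% c("measured", "imputed"))) {
    stop("origin flags must be 'measured' or 'imputed'")
  }
  if (any(entries < 0) || any(!is.finite(entries))) {
    stop("fitness values must be finite and >= 0")
  }
  if (anyDuplicated(names(entries))) stop("duplicate genotypes in entries")
  if (is.null(site_labels)) {
    site_labels <- if (L == 4) c(39L, 40L, 41L, 54L) else seq_len(L)
  }
  if (length(site_labels) != L || is.unsorted(site_labels, strictly = TRUE)) {
    stop("site_labels must be strictly increasing and of length L")
  }
  if (is.null(missing)) {
    missing <- setdiff(all_genotypes(alphabet, L), names(entries))
  }
  if (length(intersect(names(entries), missing)) > 0) {
    stop("genotype cannot be both present and missing")
  }
  n_space <- length(alphabet)^L
  if (length(entries) + length(missing) != n_space) {
    stop("entries + missing must cover alphabet^L exactly (",
         length(entries) + length(missing), " vs ", n_space, ")")
  }
  if (wt %in% names(entries) && origin[wt] == "measured" &&
      abs(entries[wt] - 1) > 1e-12) {
    stop("measured WT fitness must be 1")
  }
  structure(
    list(wt = wt, L = L, alphabet = alphabet, site_labels = site_labels,
         entries = entries, origin = origin, missing = missing),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat("Fitness landscape:", length(x$alphabet), "^", x$L, "genotype space\n")
  cat("  WT:", x$wt, " sites:", paste(x$site_labels, collapse = ","), "\n")
  cat("  entries:", length(x$entries),
      sprintf("(%d measured, %d imputed)", sum(x$origin == "measured"),
              sum(x$origin == "imputed")),
      " missing:", length(x$missing), "\n")
  invisible(x)
}

#' Fitness lookup
#'
#' @param ls A `fitness_landscape`.
#' @param g Character vector of genotypes.
#' @return Numeric fitness values; `NA` for missing genotypes.
#' @export
fitness_of <- function(ls, g) {
  unname(ls$entries[g])
}

#' Compute relative fitness from sequencing counts
#'
#' For each variant i, fitness is the enrichment ratio relative to wild type:
#' w_i = (selected_i / input_i) / (selected_WT / input_WT). Variants whose
#' input count falls below `min_input` are filtered into the missing set to
#' suppress counting noise.
#'
#' @param counts Data frame with columns `genotype`, `count_input`,
#'   `count_selected` (nonnegative integers).
#' @param wt Wild-type genotype string.
#' @param min_input Minimum input-library count to retain a variant
#'   (default 10).
#' @param alphabet Alphabet spanning the genotype space (default
#'   [AA_ALPHABET]).
#' @param site_labels Optional site labels, passed to [fitness_landscape()].
#' @param quiet Suppress the parse/filter log line on stderr.
#' @return A `fitness_landscape`; genotypes absent from `counts` or filtered
#'   out are in the missing set.
#' @export
compute_fitness <- function(counts, wt, min_input = 10,
                            alphabet = AA_ALPHABET, site_labels = NULL,
                            quiet = FALSE) {
  req <- c("genotype", "count_input", "count_selected")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(counts$genotype)) {
    stop("duplicate genotypes in count table")
  }
  if (any(counts$count_input < 0) || any(counts$count_selected < 0) ||
      any(counts$count_input != round(counts$count_input)) ||
      any(counts$count_selected != round(counts$count_selected))) {
    stop("counts must be nonnegative integers")
  }
  wt_row <- counts[counts$genotype == wt, ]
  if (nrow(wt_row) != 1 || wt_row$count_input < max(1, min_input) ||
      wt_row$count_selected <= 0) {
    stop("WT record absent or with insufficient counts; cannot anchor fitness")
  }
  keep <- counts$count_input >= min_input
  kept <- counts[keep, ]
  wt_ratio <- wt_row$count_selected / wt_row$count_input
  w <- (kept$count_selected / kept$count_input) / wt_ratio
  names(w) <- kept$genotype
  w[wt] <- 1  # exact by construction of the ratio
  if (!quiet) {
    message(sprintf("compute_fitness: parsed %d variants, filtered %d (input < %d), retained %d",
                    nrow(counts), sum(!keep), min_input, sum(keep)))
  }
  fitness_landscape(wt = wt, entries = w, alphabet = alphabet,
                    site_labels = site_labels)
}

#' Summarize a fitness landscape
#'
#' @param ls A `fitness_landscape`.
#' @return List with fractions of beneficial (w > 1), lethal (w == 0),
#'   measured and missing genotypes, and the WT fitness percentile among
#'   measured entries (fraction of measured entries with fitness >= WT's;
#'   small means WT is near the top).
#' @export
summarize_landscape <- function(ls) {
  if (length(ls$entries) == 0) stop("empty landscape")
  w <- ls$entries
  n_space <- length(w) + length(ls$missing)
  measured <- w[ls$origin == "measured"]
  wt_pct <- if (ls$wt %in% names(measured)) {
    mean(measured > measured[ls$wt]) + mean(measured == measured[ls$wt]) / 2
  } else {
    NA_real_
  }
  list(
    n_space = n_space,
    n_entries = length(w),
    fraction_beneficial = mean(w > 1),
    fraction_lethal = mean(w == 0),
    fraction_measured = sum(ls$origin == "measured") / n_space,
    fraction_missing = length(ls$missing) / n_space,
    wt_percentile = wt_pct
  )
}

#' Read / write landscape and count tables
#'
#' Plain UTF-8 tab-separated files. The landscape format has columns
#' `genotype`, `fitness`, `origin`; missing genotypes are listed with an
#' empty fitness field so that a round trip preserves the declared space.
#' The counts format has columns `genotype`, `count_input`, `count_selected`.
#'
#' @param ls A `fitness_landscape`.
#' @param path File path.
#' @param wt Wild-type genotype (stored in a `# wt:` header comment on write;
#'   required on read only if that comment is absent).
#' @return `read_landscape` returns a `fitness_landscape`;
#'   `write_landscape` returns `path` invisibly.
#' @name landscape_io
NULL

#' @rdname landscape_io
#' @export
write_landscape <- function(ls, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("# wt: ", ls$wt),
               paste0("# alphabet: ", paste(ls$alphabet, collapse = "")),
               paste0("# sites: ", paste(ls$site_labels, collapse = ","))),
             con)
  df <- data.frame(
    genotype = c(names(ls$entries), ls$missing),
    fitness = c(format(ls$entries, digits = 17, trim = TRUE, scientific = FALSE),
                rep("", length(ls$missing))),
    origin = c(unname(ls$origin), rep("", length(ls$missing))),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname landscape_io
#' @export
read_landscape <- function(path, wt = NULL) {
  header <- readLines(path, n = 10)
  meta <- grep("^# ", header, value = TRUE)
  get_meta <- function(key) {
    line <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (length(line) == 1) sub(paste0("^# ", key, ": "), "", line) else NULL
  }
  if (is.null(wt)) wt <- get_meta("wt")
  if (is.null(wt)) stop("wild type not given and no '# wt:' header in file")
  alphabet <- get_meta("alphabet")
  if (!is.null(alphabet)) alphabet <- strsplit(alphabet, "")[[1]]
  sites <- get_meta("sites")
  if (!is.null(sites)) sites <- as.integer(strsplit(sites, ",")[[1]])
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character",
                          stringsAsFactors = FALSE)
  is_missing <- df$fitness == "" | is.na(df$fitness)
  entries <- as.numeric(df$fitness[!is_missing])
  names(entries) <- df$genotype[!is_missing]
  origin <- df$origin[!is_missing]
  origin[origin == ""] <- "measured"
  names(origin) <- names(entries)
  fitness_landscape(wt = wt, entries = entries, origin = origin,
                    alphabet = alphabet, site_labels = sites,
                    missing = df$genotype[is_missing])
}

#' @rdname landscape_io
#' @param counts Data frame of count records (for `write_counts`).
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts[, c("genotype", "count_input", "count_selected")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname landscape_io
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "integer"))
  names(df) <- c("genotype", "count_input", "count_selected")
  df
}
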