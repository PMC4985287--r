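#' The 20 canonical amino acids
#'
#' Single-letter codes in alphabetical order. All genotype sequences in this
#' package are strings over (a subset of) this alphabet.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate a genotype string
#'
#' A genotype is a fixed-length amino-acid string, one letter per mutated
#' site (by default GB1 sites 39, 40, 41 and 54, so the wild type is "VDGV").
#'
#' @param g Character vector of genotype strings.
#' @param L Expected length (default: length of the first element).
#' @param alphabet Allowed letters.
#' @return Invisibly `g`; errors if any genotype is malformed.
#' @export
check_genotype <- function(g, L = nchar(g[1]), alphabet = AA_ALPHABET) {
  if (any(nchar(g) != L)) {
    stop("genotype length mismatch: expected ", L)
  }
  letters_used <- unique(strsplit(paste(g, collapse = ""), "")[[1]])
  bad <- setdiff(letters_used, alphabet)
  if (length(bad) > 0) {
    stop("invalid amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  invisible(g)
}

#' Hamming distance between two genotypes
#'
#' @param a,b Genotype strings of equal length.
#' @return Integer number of differing positions.
#' @export
#' @examples
#' hamming_distance("VDGV", "WLFA") # 4
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("genotype length mismatch")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Split genotypes into an n x L character matrix.
genotype_matrix <- function(g) {
  do.call(rbind, strsplit(g, ""))
}

# Paste an n x L character matrix back into genotype strings.
matrix_genotype <- function(m) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Enumerate the full genotype space
#'
#' All `length(alphabet)^L` genotypes, ordered so that the first site varies
#' fastest.
#'
#' @param alphabet Letters available at each site.
#' @param L Number of sites.
#' @return Character vector of genotypes.
#' @export
all_genotypes <- function(alphabet, L) {
  grid <- expand.grid(rep(list(alphabet), L), stringsAsFactors = FALSE)
  do.call(paste0, grid)
}

#' Amino-acid adjacency for single mutational steps
#'
#' In `full` mode any amino-acid exchange is a single step (protein-space
#' view, 19L neighbors per genotype). In `genetic_code` mode an exchange is
#' allowed only if some sense codon of one amino acid differs from some sense
#' codon of the other at exactly one nucleotide; stop codons are never used
#' as intermediates.
#'
#' @param mode `"full"` or `"genetic_code"`.
#' @param alphabet Amino-acid letters indexing the matrix.
#' @return Object of class `aa_adjacency`: a symmetric logical matrix with
#'   `FALSE` diagonal and a `mode` attribute.
#' @export
aa_adjacency <- function(mode = c("full", "genetic_code"),
                         alphabet = AA_ALPHABET) {
  mode <- match.arg(mode)
  if (mode == "full") {
    m <- matrix(TRUE, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
    diag(m) <- FALSE
  } else {
    m <- genetic_code_adjacency()[alphabet, alphabet, drop = FALSE]
  }
  structure(m, mode = mode, class = c("aa_adjacency", class(m)))
}

#' Single-nucleotide amino-acid substitution matrix
#'
#' Entry (a, b) is `TRUE` iff some sense codon of a and some sense codon of b
#' differ at exactly one nucleotide position under the standard genetic code.
#' This is the connectivity constraint the code imposes on protein space:
#' it thins the 19 substitutions per site down to roughly 6.
#'
#' @return Symmetric 20 x 20 logical matrix with `FALSE` diagonal, rows and
#'   columns named by [AA_ALPHABET].
#' @export
genetic_code_adjacency <- function() {
  code <- Biostrings::GENETIC_CODE
  sense <- code[code != "*"]
  codons <- names(sense)
  bases <- do.call(rbind, strsplit(codons, ""))
  m <- matrix(FALSE, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in seq_along(codons)) {
    # codons one substitution away from codon i
    diff1 <- rowSums(bases != matrix(bases[i, ], nrow(bases), 3,
                                     byrow = TRUE)) == 1
    aa_from <- sense[[i]]
    for (aa_to in unique(sense[diff1])) {
      if (aa_to != aa_from) {
        m[aa_from, aa_to] <- TRUE
        m[aa_to, aa_from] <- TRUE
      }
    }
  }
  m
}

#' Single-step mutational neighbors of a genotype
#'
#' @param g Genotype string.
#' @param adjacency An [aa_adjacency()] matrix (default: full protein space).
#' @return Character vector of all genotypes one allowed substitution away.
#' @export
#' @examples
#' length(neighbors("VD")) # 38 in full mode
neighbors <- function(g, adjacency = aa_adjacency("full")) {
  chars <- strsplit(g, "")[[1]]
  out <- character(0)
  for (i in seq_along(chars)) {
    repl <- rownames(adjacency)[adjacency[chars[i], ]]
    if (length(repl) == 0) next
    tmp <- matrix(chars, length(repl), length(chars), byrow = TRUE)
    tmp[, i] <- repl
    out <- c(out, matrix_genotype(tmp))
  }
  out
}

#' Genetic distance between genotypes under the standard code
#'
#' Per-site shortest-path distance in the amino-acid substitution graph of
#' [genetic_code_adjacency()], summed over sites. Under full adjacency this
#' reduces to the Hamming distance.
#'
#' @param a,b Genotype strings of equal length.
#' @param adjacency An [aa_adjacency()] matrix.
#' @return Numeric distance (Inf if some exchange is impossible).
#' @export
genetic_distance <- function(a, b, adjacency = aa_adjacency("genetic_code")) {
  if (nchar(a) != nchar(b)) stop("genotype length mismatch")
  dmat <- aa_distance_matrix(adjacency)
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(dmat[cbind(ca, cb)])
}

# Shortest-path distances between amino acids in an adjacency graph (cached
# per adjacency content within a session).
aa_distance_matrix <- local({
  cache <- NULL
  cache_key <- NULL
  function(adjacency) {
    key <- paste(c(rownames(adjacency), as.integer(adjacency)), collapse = "")
    if (!is.null(cache_key) && identical(key, cache_key)) return(cache)
    g <- igraph::graph_from_adjacency_matrix(
      (adjacency) * 1, mode = "undirected", diag = FALSE
    )
    d <- igraph::distances(g)
    dimnames(d) <- dimnames(adjacency)
    cache <<- d
    cache_key <<- key
    d
  }
})
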