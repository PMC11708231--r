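#' @useDynLib deltastats, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats qnorm setNames
#' @importFrom utils read.table write.table
NULL

#' Canonical allelic pattern codes
#'
#' The 15 polarized biallelic site classes over five ordered taxa. `A` is the
#' majority allele (at least three of five copies), `B` the minority allele,
#' so every pattern carries one or two `B`s: the 5 singletons first, then the
#' 10 doubletons, each in lexicographic order of the taxa carrying `B`.
#'
#' @return Character vector of length 15.
#' @export
#' @examples
#' pattern_codes()
pattern_codes <- function() {
  c("BAAAA", "ABAAA", "AABAA", "AAABA", "AAAAB",
    "BBAAA", "BABAA", "BAABA", "BAAAB", "ABBAA",
    "ABABA", "ABAAB", "AABBA", "AABAB", "AAABB")
}

# B-positions of each pattern as a 5-bit mask (bit i-1 set <=> taxon i is B)
.pattern_masks <- local({
  codes <- c("BAAAA", "ABAAA", "AABAA", "AAABA", "AAAAB",
             "BBAAA", "BABAA", "BAABA", "BAAAB", "ABBAA",
             "ABABA", "ABAAB", "AABBA", "AABAB", "AAABB")
  vapply(strsplit(codes, ""), function(s) sum(2L^(which(s == "B") - 1L)), 0)
})

#' Map a 5-bit minority mask to its pattern code
#'
#' Masks with three or four set bits are complemented first (the set leaves
#' would then carry the majority allele).
#'
#' @param mask Integer in 1..30; bit i-1 set means taxon i carries the focal
#'   allele.
#' @return A pattern code from [pattern_codes()].
#' @keywords internal
mask_to_pattern <- function(mask) {
  nb <- vapply(mask, function(m) sum(bitwAnd(m, 2L^(0:4)) > 0L), 0)
  m2 <- ifelse(nb > 2, bitwAnd(bitwNot(as.integer(mask)), 31L), as.integer(mask))
  pattern_codes()[match(m2, .pattern_masks)]
}

#' Polarize one site into an allelic pattern
#'
#' Applies the minority rule: the allele observed once or twice among the
#' five taxa becomes `B`, the majority allele `A`. No outgroup or ancestral
#' state is consulted; sites where taxon 5 carries the minority allele are
#' retained on purpose.
#'
#' @param alleles Character vector of 5 allele symbols (no missing values).
#' @return A pattern code, or `NULL` when the site is constant across the
#'   five taxa.
#' @export
#' @examples
#' polarize_site(c("C", "T", "C", "T", "C"))  # "ABABA"
#' polarize_site(c("T", "C", "C", "C", "C"))  # "BAAAA"
polarize_site <- function(alleles) {
  if (length(alleles) != 5L || anyNA(alleles)) {
    stop("polarize_site() needs exactly 5 non-missing allele symbols")
  }
  u <- unique(alleles)
  if (length(u) == 1L) return(NULL)
  if (length(u) > 2L) stop("site is not biallelic")
  n1 <- sum(alleles == u[1L])
  minor <- if (n1 <= 2L) u[1L] else u[2L]
  paste(ifelse(alleles == minor, "B", "A"), collapse = "")
}

#' Per-pattern weights from population allele frequencies
#'
#' Given the frequency of one of the two alleles in each of the five
#' populations, returns for every allelic pattern the probability that five
#' independently drawn haploid copies (one per population) display it. The
#' sum over both alleles of the product form merges each pattern with its
#' complement, so no explicit majority call is needed; the two constant
#' classes carry the remaining mass and are discarded.
#'
#' @param freqs Numeric vector of 5 frequencies of the same allele, in
#'   `[0, 1]`.
#' @return Named numeric vector of 15 weights (names are [pattern_codes()]).
#' @export
#' @examples
#' frequency_weights(c(0, 1, 0, 1, 0))["ABABA"]  # 1
frequency_weights <- function(freqs) {
  if (length(freqs) != 5L || anyNA(freqs)) {
    stop("frequency_weights() needs exactly 5 non-missing frequencies")
  }
  if (any(freqs < 0 | freqs > 1)) stop("allele frequencies must lie in [0, 1]")
  codes <- pattern_codes()
  w <- setNames(numeric(15L), codes)
  for (k in seq_along(codes)) {
    isB <- strsplit(codes[k], "")[[1L]] == "B"
    # focal allele plays the B role, then the other allele does
    w[k] <- prod(ifelse(isB, freqs, 1 - freqs)) +
      prod(ifelse(isB, 1 - freqs, freqs))
  }
  w
}

#' Construct a pattern-count container
#'
#' @param counts Named numeric vector; names must be a subset of
#'   [pattern_codes()]. Missing patterns are zero-filled.
#' @param n_retained,n_skipped Site bookkeeping totals.
#' @param skip_reasons Named integer vector (e.g. missing/multiallelic/constant).
#' @return A `pattern_counts` object: named numeric vector of length 15 with
#'   attributes `n_retained`, `n_skipped`, `skip_reasons`.
#' @export
pattern_counts <- function(counts = numeric(), n_retained = NULL,
                           n_skipped = 0L,
                           skip_reasons = c(missing = 0L, multiallelic = 0L,
                                            constant = 0L)) {
  full <- setNames(numeric(15L), pattern_codes())
  if (length(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% pattern_codes())) {
      stop("counts must be named by valid pattern codes")
    }
    if (any(counts < 0)) stop("pattern counts must be non-negative")
    full[names(counts)] <- full[names(counts)] + as.numeric(counts)
  }
  if (is.null(n_retained)) n_retained <- sum(full)
  structure(full, n_retained = n_retained, n_skipped = n_skipped,
            skip_reasons = skip_reasons, class = "pattern_counts")
}

#' @export
print.pattern_counts <- function(x, ...) {
  cat("Allelic pattern counts over 5 taxa\n")
  print(setNames(as.numeric(x), names(x)))
  cat(sprintf("sites retained: %s, skipped: %s\n",
              format(attr(x, "n_retained")), format(attr(x, "n_skipped"))))
  sr <- attr(x, "skip_reasons")
  if (!is.null(sr) && sum(sr) > 0) {
    cat("skip reasons:", paste(sprintf("%s=%d", names(sr), sr), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Accumulate pattern counts over a table of sites
#'
#' @param sites A data frame of site observations: columns `chrom`, `pos`,
#'   then five taxon columns in tree leaf order holding allele symbols
#'   (haploid mode; `NA` = missing) or allele frequencies (frequency mode).
#' @param mode `"haploid"` or `"frequency"`.
#' @return A [pattern_counts()] object. Skipped sites are tallied by reason:
#'   `missing` (any `NA` among the five taxa), `multiallelic` (more than two
#'   symbols), `constant` (no variation among the five taxa; in frequency
#'   mode this mass is subtracted per site rather than per pattern).
#' @export
count_patterns <- function(sites, mode = c("haploid", "frequency")) {
  mode <- match.arg(mode)
  acc <- setNames(numeric(15L), pattern_codes())
  skip <- c(missing = 0L, multiallelic = 0L, constant = 0L)
  retained <- 0
  if (nrow(sites) == 0L) {
    return(pattern_counts(acc, n_retained = 0, n_skipped = 0L,
                          skip_reasons = skip))
  }
  taxa <- as.matrix(sites[, 3:7])
  for (i in seq_len(nrow(taxa))) {
    obs <- taxa[i, ]
    if (anyNA(obs)) {
      skip["missing"] <- skip["missing"] + 1L
      next
    }
    if (mode == "haploid") {
      u <- unique(obs)
      if (length(u) > 2L) {
        skip["multiallelic"] <- skip["multiallelic"] + 1L
        next
      }
      p <- polarize_site(as.character(obs))
      if (is.null(p)) {
        skip["constant"] <- skip["constant"] + 1L
        next
      }
      acc[p] <- acc[p] + 1
      retained <- retained + 1
    } else {
      w <- frequency_weights(as.numeric(obs))
      if (sum(w) == 0) {
        skip["constant"] <- skip["constant"] + 1L
        next
      }
      acc <- acc + w
      retained <- retained + 1
    }
  }
  pattern_counts(acc, n_retained = retained, n_skipped = sum(skip),
                 skip_reasons = skip)
}

#' Read / write pattern counts as TSV
#'
#' Two-column table `pattern`, `count`; attributes are stored as comment
#' header lines so a written file round-trips exactly.
#'
#' @param x A `pattern_counts` object.
#' @param path File path.
#' @return `read_pattern_counts` returns a `pattern_counts` object.
#' @export
write_pattern_counts <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_retained=%.10g", attr(x, "n_retained")), con)
  writeLines(sprintf("# n_skipped=%d", as.integer(attr(x, "n_skipped"))), con)
  writeLines("pattern\tcount", con)
  writeLines(sprintf("%s\t%.10g", names(x), as.numeric(x)), con)
  invisible(path)
}

#' @rdname write_pattern_counts
#' @export
read_pattern_counts <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  nr <- sub("^# n_retained=", "", grep("n_retained", hdr, value = TRUE))
  ns <- sub("^# n_skipped=", "", grep("n_skipped", hdr, value = TRUE))
  pattern_counts(setNames(tab$count, tab$pattern),
                 n_retained = if (length(nr)) as.numeric(nr) else NULL,
                 n_skipped = if (length(ns)) as.integer(ns) else 0L)
}
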