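#' Binomial Delta-statistic definitions
#'
#' Each binomial statistic is the difference `n(left) - n(right)` of the
#' counts of two allelic patterns drawn from the same equal probability set
#' of its tree shape. Rows whose patterns are singletons additionally require
#' the synchronization assumption (mutation intensity depends only on time,
#' not population), which ancient samples violate.
#'
#' @param tree `"S"`, `"A"` or `"Q"`, or `NULL` for all three.
#' @return Data frame with columns `name`, `tree`, `left`, `right`,
#'   `requires_synchronization`.
#' @export
binomial_specs <- function(tree = NULL) {
  df <- data.frame(
    name  = c(paste0("S", 1:8), paste0("A", 1:4), paste0("Q", 1:8)),
    tree  = c(rep("S", 8), rep("A", 4), rep("Q", 8)),
    left  = c("BABAA", "ABBAA", "BABAA", "BAABA", "BAAAB", "AABAB", "BAAAA",
              "AABAA",
              "BABAA", "BAABA", "BAAAB", "BAAAA",
              "BAABA", "ABABA", "BAABA", "BAAAB", "BABAA", "AABBA", "BAAAA",
              "AAABA"),
    right = c("BAABA", "ABABA", "ABBAA", "ABABA", "ABAAB", "AAABB", "ABAAA",
              "AAABA",
              "ABBAA", "ABABA", "ABAAB", "ABAAA",
              "BAAAB", "ABAAB", "ABABA", "ABAAB", "ABBAA", "AABAB", "ABAAA",
              "AAAAB"),
    stringsAsFactors = FALSE
  )
  sing <- substr(df$left, 1, 5) %in% pattern_codes()[1:5] |
    df$right %in% pattern_codes()[1:5]
  df$requires_synchronization <- sing
  if (!is.null(tree)) df <- df[df$tree == tree, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Parse a composition name into binomial coefficients
#'
#' Composition names follow the subscript notation of the statistics
#' themselves: a tree letter followed by signed binomial indices, e.g.
#' `"S1-6"` (= S1 - S6), `"S3+4-5+7"`, `"S-3"` (sign-flipped S3),
#' `"Q1+2-6+8"`. Repeated indices accumulate, so coefficients beyond +-1 are
#' expressible.
#'
#' @param name Composition name.
#' @return Named integer vector of coefficients over binomial names, with
#'   attribute `tree`.
#' @export
parse_composition <- function(name) {
  m <- regmatches(name, regexec("^([SAQ])((?:[+-]?[0-9])+)$", name))[[1L]]
  if (length(m) == 0L) stop("cannot parse composition name: ", name)
  tree <- m[2L]
  toks <- regmatches(m[3L], gregexpr("[+-]?[0-9]", m[3L]))[[1L]]
  specs <- binomial_specs(tree)
  coef <- setNames(integer(nrow(specs)), specs$name)
  for (tk in toks) {
    s <- if (startsWith(tk, "-")) -1L else 1L
    idx <- paste0(tree, sub("^[+-]", "", tk))
    if (!idx %in% names(coef)) stop("no binomial statistic ", idx)
    coef[idx] <- coef[idx] + s
  }
  attr(coef, "tree") <- tree
  coef
}

#' Net per-pattern coefficients of a composition
#'
#' Expands the binomial coefficients onto the 15 allelic patterns and cancels
#' shared terms, so that the left and right pattern sets are disjoint (as the
#' scaling requires).
#'
#' @param composition Composition name or parsed coefficient vector.
#' @return Named numeric vector of net coefficients over [pattern_codes()].
#' @export
composition_coefficients <- function(composition) {
  coef <- if (is.character(composition)) parse_composition(composition)
  else composition
  specs <- binomial_specs(attr(coef, "tree"))
  net <- setNames(numeric(15L), pattern_codes())
  for (nm in names(coef)) {
    if (coef[nm] == 0L) next
    row <- specs[specs$name == nm, ]
    net[row$left] <- net[row$left] + coef[nm]
    net[row$right] <- net[row$right] - coef[nm]
  }
  net
}

#' Left/right weighted counts of a composition
#'
#' @param composition Composition name (e.g. `"S1+4"`) or parsed coefficients.
#' @param counts A [pattern_counts()] object or named count vector.
#' @return Numeric `c(nL, nR)`: summed weighted counts over the patterns
#'   with positive / negative net coefficient.
#' @export
#' @examples
#' cts <- pattern_counts(c(BABAA = 7, BAABA = 3, ABABA = 2))
#' compose("S1+4", cts)  # BAABA cancels: L = 7, R = 2
compose <- function(composition, counts) {
  net <- composition_coefficients(composition)
  v <- as.numeric(counts[pattern_codes()])
  if (anyNA(v)) stop("counts must cover all 15 patterns")
  if (any(v < 0)) stop("negative pattern counts")
  c(nL = sum((net * v)[net > 0]), nR = -sum((net * v)[net < 0]))
}

#' Critical value of the sign classification
#'
#' @param alpha Two-sided type-I error level; the default 0.01 gives 2.576.
#' @return `qnorm(1 - alpha / 2)`.
#' @export
z_critical <- function(alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  qnorm(1 - alpha / 2)
}

#' Evaluate one Delta-statistic on pattern counts
#'
#' Computes the unscaled difference `nL - nR`, the scaled statistic
#' `(nL - nR) / (nL + nR)`, the binomial Z-score `(nL - nR) / sqrt(nL + nR)`,
#' the Wald interval radius `z_crit * sqrt(4 nL nR / (nL + nR)^3)`, and the
#' sign class: `+` if `Z >= z_crit`, `-` if `Z <= -z_crit`, else `0`. The
#' degenerate case `nL = nR = 0` is classified `0` with scaled value 0.
#'
#' @inheritParams compose
#' @param alpha Per-statistic significance level (default 0.01).
#' @param name Optional display name; defaults to the composition string.
#' @return One-row data frame: `name, nL, nR, unscaled, scaled, Z,
#'   wald_radius, class`.
#' @export
evaluate_statistic <- function(composition, counts, alpha = 0.01,
                               name = NULL) {
  if (is.null(name)) {
    name <- if (is.character(composition)) composition else "composition"
  }
  lr <- compose(composition, counts)
  nL <- lr[["nL"]]
  nR <- lr[["nR"]]
  tot <- nL + nR
  zc <- z_critical(alpha)
  if (tot > 0) {
    scaled <- (nL - nR) / tot
    z <- (nL - nR) / sqrt(tot)
    wald <- zc * sqrt(4 * nL * nR / tot^3)
  } else {
    scaled <- 0
    z <- 0
    wald <- 0
  }
  cls <- if (tot == 0) "0" else if (z >= zc) "+" else if (z <= -zc) "-" else "0"
  data.frame(name = name, nL = nL, nR = nR, unscaled = nL - nR,
             scaled = scaled, Z = z, wald_radius = wald, class = cls,
             stringsAsFactors = FALSE)
}

#' Panel composition names of one tree shape
#'
#' The preferred scaled Delta-statistics in their fixed order; the entries
#' after the divider (positions 5-8 for trees S and Q, position 4 for tree A)
#' involve singleton patterns and require the synchronization assumption.
#'
#' @inheritParams compute_panel
#' @return Character vector of composition names.
#' @export
panel_compositions <- function(tree = c("S", "A", "Q"),
                               include_singletons = TRUE) {
  tree <- match.arg(tree)
  full <- switch(tree,
    S = c("S1-6", "S2-6", "S3-5", "S4-5",
          "S5+7", "S6+8", "S3+4-5+7", "S1+2-6+8"),
    A = c("A1-2", "A1-3", "A2-3", "A1+2-3+4"),
    Q = c("Q1-6", "Q2-6", "Q3-5", "Q4-5",
          "Q5+7", "Q6+8", "Q3+4-5+7", "Q1+2-6+8"))
  if (include_singletons) full else full[seq_len(if (tree == "A") 3L else 4L)]
}

#' Compute the Delta-statistic panel of one tree shape
#'
#' @param counts A [pattern_counts()] object (leaf order must match the tree
#'   labels 1..5).
#' @param tree Tree shape: `"S"` = (((1,2),(3,4)),5), `"A"` =
#'   ((((1,2),3),4),5), `"Q"` = (((1,2),3),(4,5)).
#' @param include_singletons Keep the statistics that rely on singleton
#'   patterns? Set `FALSE` for ancient samples (synchronization assumption
#'   violated).
#' @param alpha Per-statistic significance level.
#' @return A `delta_panel` data frame (one [evaluate_statistic()] row per
#'   panel statistic) with attributes `tree`, `include_singletons`, `alpha`.
#' @export
compute_panel <- function(counts, tree = c("S", "A", "Q"),
                          include_singletons = TRUE, alpha = 0.01) {
  tree <- match.arg(tree)
  comps <- panel_compositions(tree, include_singletons)
  res <- do.call(rbind, lapply(comps, evaluate_statistic, counts = counts,
                               alpha = alpha))
  structure(res, tree = tree, include_singletons = include_singletons,
            alpha = alpha, class = c("delta_panel", "data.frame"))
}

#' @export
print.delta_panel <- function(x, ...) {
  cat(sprintf("Delta-statistic panel, tree %s (singletons %s, alpha = %g)\n",
              attr(x, "tree"),
              if (attr(x, "include_singletons")) "included" else "excluded",
              attr(x, "alpha")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("signature:",
      format_signature(panel_signature(x), tree = attr(x, "tree")), "\n")
  invisible(x)
}

#' Signature of a computed panel
#'
#' @param panel A `delta_panel`.
#' @return Character vector of `+`/`-`/`0` classes in panel order.
#' @export
panel_signature <- function(panel) panel$class

#' DFOIL statistics as composed Delta-statistics
#'
#' `DFO = S1-2-6-8 = S3-4-6-8`, `DIL = S2-1-6-8 = S4-3-6-8`,
#' `DFI = S3-4-5-7 = S1-2-5-7`, `DOL = S4-3-5-7 = S2-1-5-7`; the two
#' compositions of each statistic coincide identically through the linear
#' relation S1 + S4 = S2 + S3.
#'
#' @inheritParams compute_panel
#' @param alternate Use the second printed composition of each statistic
#'   (identical result; exposed for verification).
#' @return A `delta_panel` with rows DFO, DIL, DFI, DOL.
#' @export
dfoil_panel <- function(counts, alpha = 0.01, alternate = FALSE) {
  comps <- if (!alternate) {
    c(DFO = "S1-2-6-8", DIL = "S2-1-6-8", DFI = "S3-4-5-7", DOL = "S4-3-5-7")
  } else {
    c(DFO = "S3-4-6-8", DIL = "S4-3-6-8", DFI = "S1-2-5-7", DOL = "S2-1-5-7")
  }
  res <- do.call(rbind, Map(function(comp, nm) {
    evaluate_statistic(comp, counts, alpha = alpha, name = nm)
  }, comps, names(comps)))
  rownames(res) <- NULL
  structure(res, tree = "S", include_singletons = TRUE, alpha = alpha,
            class = c("delta_panel", "data.frame"))
}

#' Partitioned D statistics as composed Delta-statistics
#'
#' `D12 = S5`, `D1 = -S3` (sign-flipped), `D2 = -S4`.
#'
#' @inheritParams compute_panel
#' @return A `delta_panel` with rows D12, D1, D2.
#' @export
partitioned_d <- function(counts, alpha = 0.01) {
  comps <- c(D12 = "S5", D1 = "S-3", D2 = "S-4")
  res <- do.call(rbind, Map(function(comp, nm) {
    evaluate_statistic(comp, counts, alpha = alpha, name = nm)
  }, comps, names(comps)))
  rownames(res) <- NULL
  structure(res, tree = "S", include_singletons = TRUE, alpha = alpha,
            class = c("delta_panel", "data.frame"))
}

#' Write a panel as TSV
#'
#' @param panel A `delta_panel`.
#' @param path Output file; `""` writes to stdout.
#' @export
write_panel <- function(panel, path = "") {
  write.table(as.data.frame(panel), file = path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(panel)
}
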