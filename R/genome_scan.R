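#' Windowed local-ancestry scan
#'
#' Buckets sites into fixed-width, nonoverlapping genomic windows anchored
#' at coordinate 1 of each chromosome, computes the pattern counts, panel,
#' signature and prediction-table match of every window. Small windows make
#' it reasonable to suppose each one carries traces of at most one
#' gene-flow event (the single-event assumption), so mixtures that blur a
#' genome-wide signature separate into their component rows.
#'
#' @param sites Site table as in [count_patterns()], sorted by
#'   `(chrom, pos)`; `pos` is 1-based.
#' @param window_size_bp Window width in base pairs.
#' @inheritParams compute_panel
#' @param mode Passed to [count_patterns()].
#' @return A `scan_result`: data frame with one row per window
#'   (`chrom`, `start`, `end` in 0-based half-open coordinates, `n_sites`,
#'   `signature`, `category`) plus attribute `panels` (list) and the
#'   prediction table used.
#' @export
scan_windows <- function(sites, window_size_bp, tree = c("S", "A", "Q"),
                         include_singletons = TRUE, alpha = 0.01,
                         mode = c("haploid", "frequency")) {
  tree <- match.arg(tree)
  mode <- match.arg(mode)
  stopifnot(window_size_bp > 0)
  if (nrow(sites) > 0) {
    o <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
    if (!identical(o, seq_len(nrow(sites)))) {
      stop("sites must be sorted by (chrom, pos)")
    }
  }
  tab <- prediction_table(tree, include_singletons)
  bin <- if (nrow(sites) > 0) (sites$pos - 1) %/% window_size_bp else integer()
  # every window from the start of each chromosome up to its last site, so
  # site-free windows are represented (and classified "Nothing") too
  keys <- unlist(lapply(unique(sites$chrom), function(ch) {
    paste(ch, 0:max(bin[sites$chrom == ch]), sep = "\r")
  }))
  key <- paste(sites$chrom, bin, sep = "\r")
  rows <- list()
  panels <- list()
  for (k in keys) {
    sel <- sites[key == k, , drop = FALSE]
    parts <- strsplit(k, "\r")[[1L]]
    w0 <- as.numeric(parts[2L]) * window_size_bp
    cts <- count_patterns(sel, mode = mode)
    panel <- compute_panel(cts, tree, include_singletons, alpha)
    sig <- panel_signature(panel)
    m <- match_signature(sig, tab)
    wid <- paste0(parts[1L], ":", w0, "-", w0 + window_size_bp)
    panels[[wid]] <- panel
    rows[[wid]] <- data.frame(
      chrom = parts[1L], start = w0, end = w0 + window_size_bp,
      n_sites = attr(cts, "n_retained"),
      signature = format_signature(sig, tree = tree),
      category = m$category, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               n_sites = numeric(), signature = character(),
               category = character())
  rownames(res) <- NULL
  structure(res, panels = panels, table = tab, tree = tree,
            class = c("scan_result", "data.frame"))
}

#' Aggregate window categories
#'
#' Counts scan windows per category: each ambiguity class of the prediction
#' table, `"Nothing"` (all-zero signature) and `"Unknown scenario"`
#' (nonzero but matching no row). Categories partition the windows, so the
#' counts sum to the number of windows.
#'
#' @param scan A `scan_result` from [scan_windows()].
#' @return Data frame `category`, `n_windows`, sorted by decreasing count.
#' @export
aggregate_scan <- function(scan) {
  tb <- table(scan$category)
  out <- data.frame(category = names(tb), n_windows = as.integer(tb),
                    stringsAsFactors = FALSE)
  out[order(-out$n_windows, out$category), , drop = FALSE]
}

#' Text bar summary of an aggregated scan
#'
#' @param agg Output of [aggregate_scan()].
#' @param width Maximum bar width in characters.
#' @return Invisibly, the printed lines.
#' @export
scan_barplot <- function(agg, width = 50L) {
  if (nrow(agg) == 0L) return(invisible(character()))
  mx <- max(agg$n_windows)
  lines <- sprintf("%-20s %6d %s", agg$category, agg$n_windows,
                   strrep("#", pmax(1L, round(agg$n_windows / mx * width))))
  cat(lines, sep = "\n")
  invisible(lines)
}
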