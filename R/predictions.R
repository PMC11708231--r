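#' Signature formatting
#'
#' Signatures are ordered tuples of `+`/`-`/`0` classes in panel order,
#' printed as e.g. `"(++-0|+-00)"` with the divider separating the entries
#' that require the synchronization assumption.
#'
#' @param signature Character vector of `+`/`-`/`0`.
#' @param tree Tree shape (determines divider position for full signatures).
#' @return `format_signature` returns a string; `parse_signature` a character
#'   vector.
#' @export
format_signature <- function(signature, tree = NULL) {
  n <- length(signature)
  div <- if (n == 8L) 4L else if (n == 4L && !is.null(tree) && tree == "A")
    3L else NA_integer_
  if (is.na(div) && n == 4L && is.null(tree)) div <- NA_integer_
  s <- paste(signature, collapse = "")
  if (!is.na(div) && div < n) {
    s <- paste0(substr(s, 1, div), "|", substr(s, div + 1L, n))
  }
  paste0("(", s, ")")
}

#' @rdname format_signature
#' @param x Signature string, with or without parentheses/divider.
#' @export
parse_signature <- function(x) {
  s <- gsub("[()|]", "", x)
  s <- gsub("−", "-", s)  # tolerate typeset minus
  out <- strsplit(s, "")[[1L]]
  if (!all(out %in% c("+", "-", "0"))) stop("invalid signature string: ", x)
  out
}

# Full prediction tables. One row per unidirectional gene-flow event with a
# nonzero full signature; events not listed have the all-zero signature.
# Signature order matches panel_compositions() of the tree. Events are
# written "src>tgt" over branch labels (terminals 1-5; internals by the
# leaves they subtend; "12345" is the root lineage).
.predictions_full <- list(
  S = c(
    "1>3"     = "+++0|--00",
    "3>1"     = "+0++|--00",
    "1>4"     = "--0+|-+00",
    "4>1"     = "-0++|-+00",
    "2>3"     = "++-0|+-00",
    "3>2"     = "0+--|+-00",
    "2>4"     = "--0-|++00",
    "4>2"     = "0---|++00",
    "12345>1" = "00--|+0+0",
    "34>2"    = "00--|+000",
    "2>34"    = "00--|+000",
    "1234>1"  = "00--|+000",
    "5>1"     = "00--|+0-0",
    "1>5"     = "00--|00-0",
    "12345>2" = "00++|-0-0",
    "34>1"    = "00++|-000",
    "1>34"    = "00++|-000",
    "1234>2"  = "00++|-000",
    "5>2"     = "00++|-0+0",
    "2>5"     = "00++|00+0",
    "12345>3" = "--00|0+0+",
    "12>4"    = "--00|0+00",
    "4>12"    = "--00|0+00",
    "1234>3"  = "--00|0+00",
    "5>3"     = "--00|0+0-",
    "3>5"     = "--00|000-",
    "12345>4" = "++00|0-0-",
    "12>3"    = "++00|0-00",
    "3>12"    = "++00|0-00",
    "1234>4"  = "++00|0-00",
    "5>4"     = "++00|0-0+",
    "4>5"     = "++00|000+"
  ),
  A = c(
    "1>3"     = "++0|0",
    "3>1"     = "++0|0",
    "123>2"   = "++0|0",
    "2>3"     = "--0|0",
    "3>2"     = "--0|0",
    "123>1"   = "--0|0",
    "1>4"     = "-0+|0",
    "4>1"     = "--+|0",
    "2>4"     = "+0-|0",
    "4>2"     = "++-|0",
    "1>5"     = "0--|-",
    "5>1"     = "---|-",
    "1234>1"  = "---|0",
    "12345>1" = "---|+",
    "2>5"     = "0++|+",
    "5>2"     = "+++|+",
    "1234>2"  = "+++|0",
    "12345>2" = "+++|-"
  ),
  Q = c(
    "1>4"     = "+++0|--0-",
    "4>1"     = "+0++|--+0",
    "1>5"     = "--0+|-+0+",
    "5>1"     = "-0++|-++0",
    "2>4"     = "++-0|+-0-",
    "4>2"     = "0+--|+--0",
    "2>5"     = "--0-|++0+",
    "5>2"     = "0---|++-0",
    "2>45"    = "00--|+000",
    "45>2"    = "00--|+0-0",
    "1>3"     = "00--|00-0",
    "3>1"     = "00--|00-0",
    "123>2"   = "00--|00-0",
    "12345>2" = "00--|-0-0",
    "1>45"    = "00++|-000",
    "45>1"    = "00++|-0+0",
    "2>3"     = "00++|00+0",
    "3>2"     = "00++|00+0",
    "123>1"   = "00++|00+0",
    "12345>1" = "00++|+0+0",
    "5>12"    = "--00|0+00",
    "12>5"    = "--00|0+0+",
    "4>3"     = "--00|000-",
    "3>4"     = "--00|0-0-",
    "4>12"    = "++00|0-00",
    "12>4"    = "++00|0-0-",
    "5>3"     = "++00|000+",
    "3>5"     = "++00|0+0+",
    "123>5"   = "0000|0+0+",
    "5>123"   = "0000|0+0+",
    "12345>4" = "0000|0+0+",
    "123>4"   = "0000|0-0-",
    "4>123"   = "0000|0-0-",
    "12345>5" = "0000|0-0-"
  )
)

#' Predicted signatures of unidirectional gene-flow events
#'
#' Returns the encoded prediction table of a tree shape: one row per
#' unidirectional gene-flow event whose expected signature is nonzero, with
#' the `+`/`-`/`0` expectation of every panel statistic. Events absent from
#' the table have the all-zero signature. The collapsed table
#' (`include_singletons = FALSE`) is the projection onto the entries left of
#' the divider, with events merged when their projections coincide and
#' events dropped when the projection is all-zero.
#'
#' @inheritParams compute_panel
#' @return A `prediction_table` data frame with columns `event`, `source`,
#'   `target`, `signature` (string), one column per panel statistic, and
#'   `class_label` naming the ambiguity class (asterisked representative
#'   when several events share a signature).
#' @export
prediction_table <- function(tree = c("S", "A", "Q"),
                             include_singletons = TRUE) {
  tree <- match.arg(tree)
  sigs <- .predictions_full[[tree]]
  events <- names(sigs)
  mat <- t(vapply(sigs, parse_signature,
                  character(if (tree == "A") 4L else 8L)))
  if (!include_singletons) {
    keep <- seq_len(if (tree == "A") 3L else 4L)
    mat <- mat[, keep, drop = FALSE]
    nz <- apply(mat, 1L, function(r) any(r != "0"))
    mat <- mat[nz, , drop = FALSE]
    events <- events[nz]
  }
  sig_str <- apply(mat, 1L, function(r) format_signature(r, tree = tree))
  src <- sub(">.*$", "", events)
  tgt <- sub("^.*>", "", events)
  stats <- panel_compositions(tree, include_singletons)
  df <- data.frame(event = events, source = src, target = tgt,
                   signature = sig_str, stringsAsFactors = FALSE)
  for (j in seq_along(stats)) df[[stats[j]]] <- mat[, j]
  df$class_label <- .ambiguity_labels(df)
  rownames(df) <- NULL
  structure(df, tree = tree, include_singletons = include_singletons,
            class = c("prediction_table", "data.frame"))
}

# Representative labels in the asterisk convention: events sharing a
# signature form one ambiguity class; if the class contains both directions
# of some pair the representative is "a<>b", otherwise the first event.
# A trailing "*" marks classes with more than one member.
.ambiguity_labels <- function(df) {
  labels <- character(nrow(df))
  for (sig in unique(df$signature)) {
    idx <- which(df$signature == sig)
    evs <- df$event[idx]
    rep_lab <- evs[1L]
    for (e in evs) {
      rev_e <- paste0(sub("^.*>", "", e), ">", sub(">.*$", "", e))
      if (rev_e %in% evs) {
        rep_lab <- paste0(sub(">.*$", "", e), "<>", sub("^.*>", "", e))
        break
      }
    }
    if (length(evs) > 1L) rep_lab <- paste0(rep_lab, "*")
    labels[idx] <- rep_lab
  }
  labels
}

#' Events with nonzero expected full signature
#'
#' @inheritParams compute_panel
#' @return Character vector of `"src>tgt"` event labels (32 for tree S,
#'   18 for A, 34 for Q).
#' @export
enumerate_nonzero_events <- function(tree = c("S", "A", "Q")) {
  tree <- match.arg(tree)
  names(.predictions_full[[tree]])
}

#' Match an observed signature against a prediction table
#'
#' Matching is exact equality on signs. An all-zero signature is category
#' `"Nothing"`; a nonzero signature equal to no table row is an
#' `"Unknown scenario"`.
#'
#' @param observed Signature as character vector or formatted string.
#' @param table A [prediction_table()].
#' @return List with `category` (class label, `"Nothing"`, or
#'   `"Unknown scenario"`) and `events` (character vector of consistent
#'   events, empty for the two special categories).
#' @export
match_signature <- function(observed, table) {
  if (is.character(observed) && length(observed) == 1L) {
    observed <- parse_signature(observed)
  }
  stats <- setdiff(colnames(table),
                   c("event", "source", "target", "signature", "class_label"))
  if (length(observed) != length(stats)) {
    stop(sprintf("signature has %d entries but the table expects %d",
                 length(observed), length(stats)))
  }
  if (all(observed == "0")) {
    return(list(category = "Nothing", events = character()))
  }
  obs_str <- format_signature(observed, tree = attr(table, "tree"))
  hit <- which(table$signature == obs_str)
  if (length(hit) == 0L) {
    return(list(category = "Unknown scenario", events = character()))
  }
  list(category = table$class_label[hit[1L]], events = table$event[hit])
}

# Expected DFOIL signatures (DFO, DIL, DFI, DOL) for every tree-S event in
# the prediction table; all other events (notably x>5) give "0000".
.dfoil_predictions <- c(
  "1>3" = "+++0", "3>1" = "+0++", "2>3" = "++-0", "3>2" = "0+--",
  "1>4" = "--0+", "4>1" = "-0++", "2>4" = "--0-", "4>2" = "0---",
  "5>1" = "00--", "34>2" = "00--", "2>34" = "00--", "1234>1" = "00--",
  "12345>1" = "00--",
  "5>2" = "00++", "34>1" = "00++", "1>34" = "00++", "1234>2" = "00++",
  "12345>2" = "00++",
  "5>3" = "--00", "12>4" = "--00", "4>12" = "--00", "1234>3" = "--00",
  "12345>3" = "--00",
  "5>4" = "++00", "12>3" = "++00", "3>12" = "++00", "1234>4" = "++00",
  "12345>4" = "++00",
  "1>5" = "0000", "2>5" = "0000", "3>5" = "0000", "4>5" = "0000"
)

#' Expected DFOIL signature of a gene-flow event on tree S
#'
#' Signature order is (DFO, DIL, DFI, DOL). Events DFOIL cannot see (gene
#' flow into population 5 from a terminal branch, and anything absent from
#' the tree-S prediction table) give `(0000)`.
#'
#' @param event Event label `"src>tgt"`.
#' @return Character vector of 4 signs.
#' @export
#' @examples
#' dfoil_prediction("1>3")  # "+" "+" "+" "0"
dfoil_prediction <- function(event) {
  event <- gsub("→", ">", event)
  if (event %in% names(.dfoil_predictions)) {
    parse_signature(.dfoil_predictions[[event]])
  } else {
    rep("0", 4L)
  }
}

#' Write a prediction table as TSV
#'
#' @param table A [prediction_table()].
#' @param path Output file; `""` writes to stdout.
#' @export
write_prediction_table <- function(table, path = "") {
  write.table(as.data.frame(table), file = path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(table)
}
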