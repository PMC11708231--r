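#' Default node times of the three tree shapes
#'
#' Root of the five populations at time 3 (time 0 = present, units of
#' roughly `2 lambda Ne` generations), remaining species-tree nodes placed
#' roughly evenly.
#'
#' @inheritParams compute_panel
#' @return Named numeric vector of node times.
#' @export
default_node_times <- function(tree = c("S", "A", "Q")) {
  tree <- match.arg(tree)
  switch(tree,
    S = c("12" = 1, "34" = 1, "1234" = 2, "12345" = 3),
    A = c("12" = 0.75, "123" = 1.5, "1234" = 2.25, "12345" = 3),
    Q = c("12" = 1, "123" = 2, "45" = 1, "12345" = 3))
}

# Branch topology of each shape: for every branch label, the parent label.
.shape_parents <- list(
  S = c("1" = "12", "2" = "12", "3" = "34", "4" = "34",
        "12" = "1234", "34" = "1234", "1234" = "12345", "5" = "12345"),
  A = c("1" = "12", "2" = "12", "12" = "123", "3" = "123",
        "123" = "1234", "4" = "1234", "1234" = "12345", "5" = "12345"),
  Q = c("1" = "12", "2" = "12", "12" = "123", "3" = "123",
        "123" = "12345", "4" = "45", "5" = "45", "45" = "12345")
)

#' Build a five-population species-tree model
#'
#' @inheritParams compute_panel
#' @param node_times Named numeric vector of internal-node times (defaults
#'   to [default_node_times()]); the root node `"12345"` must be present.
#' @param sampling_times Per-leaf sampling times (0 = modern; positive =
#'   ancient sample dead that long before the present, in coalescent units).
#' @param lambda Pairwise coalescence rate within every population.
#' @param mu Mutation intensity per unit time per lineage (used by
#'   [drop_mutations()]; the pattern sampler works in the vanishing-intensity
#'   limit where `mu` only sets the time-to-pattern exchange rate).
#' @return An `admixture_graph_model` with no gene-flow edges; add them with
#'   [add_gene_flow()].
#' @export
species_model <- function(tree = c("S", "A", "Q"), node_times = NULL,
                          sampling_times = rep(0, 5), lambda = 1,
                          mu = 1e-4) {
  tree <- match.arg(tree)
  if (is.null(node_times)) node_times <- default_node_times(tree)
  parents <- .shape_parents[[tree]]
  labels <- c(names(parents), "12345")
  starts <- setNames(numeric(length(labels)), labels)
  ends <- setNames(numeric(length(labels)), labels)
  for (b in labels) {
    starts[b] <- if (b %in% names(node_times)) node_times[[b]] else 0
    ends[b] <- if (b == "12345") Inf else node_times[[parents[[b]]]]
  }
  if (any(starts >= ends)) {
    stop("node times must strictly increase from tips to root")
  }
  if (length(sampling_times) != 5L || any(sampling_times < 0)) {
    stop("sampling_times must be 5 non-negative times")
  }
  term_end <- ends[as.character(1:5)]
  if (any(sampling_times >= term_end)) {
    stop("a sampling time lies beyond the leaf's terminal branch")
  }
  structure(list(tree = tree, node_times = node_times,
                 branch_start = starts, branch_end = ends,
                 branch_parent = c(parents, "12345" = NA_character_),
                 sampling_times = sampling_times, lambda = lambda, mu = mu,
                 edges = list()),
            class = "admixture_graph_model")
}

#' Lifetime interval of a branch
#'
#' @param model An `admixture_graph_model`.
#' @param branch Branch label.
#' @return `c(start, end)` in backward time.
#' @export
branch_interval <- function(model, branch) {
  if (!branch %in% names(model$branch_start)) {
    stop("no branch ", branch, " in tree ", model$tree)
  }
  start <- model$branch_start[[branch]]
  if (branch %in% as.character(1:5)) {
    start <- model$sampling_times[as.integer(branch)]
  }
  c(start, model$branch_end[[branch]])
}

#' Attach a unidirectional gene-flow edge
#'
#' Forward in time, a fraction `beta` of the target population at the
#' admixture time originates from the source branch. Backward in time, each
#' lineage in the target branch then switches to the source with probability
#' `beta`. When the two branches coexist the event is instantaneous at the
#' midpoint of their overlap; otherwise the flow is mediated by a ghost
#' branch that leaves the source at the source-interval midpoint and admixes
#' into the target at the target-interval midpoint.
#'
#' @param model An `admixture_graph_model`.
#' @param event Event label `"src>tgt"` (e.g. `"1>3"`, `"12345>1"`).
#' @param beta Admixture proportion in (0, 1).
#' @param t_admix,t_join Optional explicit times overriding the defaults.
#' @return The model with the edge appended.
#' @export
add_gene_flow <- function(model, event, beta = 0.1, t_admix = NULL,
                          t_join = NULL) {
  stopifnot(inherits(model, "admixture_graph_model"))
  if (!(beta >= 0 && beta < 1)) stop("beta must lie in [0, 1)")
  # beta = 0 is a no-op edge, useful for null comparisons
  event <- gsub("→", ">", event)
  src <- sub(">.*$", "", event)
  tgt <- sub("^.*>", "", event)
  if (src == tgt) stop("source and target must differ")
  is_root <- function(b) b == "12345"
  iv_s <- branch_interval(model, src)
  iv_t <- branch_interval(model, tgt)
  if (is_root(src)) iv_s[2] <- iv_s[1] + 1  # pseudo-end for placement only
  lo <- max(iv_s[1], iv_t[1])
  hi <- min(iv_s[2], iv_t[2])
  if (is.null(t_admix)) {
    if (lo < hi) {
      t_admix <- (lo + hi) / 2  # instantaneous
      t_join <- NULL
    } else if (iv_s[1] >= iv_t[2]) {
      # source branch older than the target: ghost-mediated flow
      t_admix <- mean(iv_t)
      if (is.null(t_join)) t_join <- mean(iv_s)
    } else {
      # source branch dies before the target is born: no time-consistent
      # edge exists under these node times
      stop("branches ", src, " and ", tgt, " never coexist under the ",
           "current node times; adjust them (see scenario_model())")
    }
  } else if (is.null(t_join) && !(t_admix > iv_s[1] && t_admix < iv_s[2])) {
    stop("explicit t_admix outside the source branch needs t_join")
  }
  if (!(t_admix > iv_t[1] && t_admix < iv_t[2])) {
    stop("admixture time must fall inside the target branch lifetime")
  }
  if (!is.null(t_join)) {
    if (!(t_join > iv_s[1] && (is_root(src) || t_join < iv_s[2]))) {
      stop("ghost join time must fall inside the source branch lifetime")
    }
    if (t_join <= t_admix) {
      stop("ghost join must be older than the admixture time")
    }
  }
  model$edges[[length(model$edges) + 1L]] <-
    list(event = event, source = src, target = tgt, beta = beta,
         t_admix = t_admix, t_join = t_join)
  model
}

# Flatten a model into the index vectors the compiled core consumes.
.model_lowlevel <- function(model) {
  labels <- names(model$branch_end)
  ends <- as.numeric(model$branch_end)
  parent_idx <- match(model$branch_parent[labels], labels) - 1L
  parent_idx[is.na(parent_idx)] <- -1L
  a_time <- numeric(0)
  a_target <- integer(0)
  a_dest <- integer(0)
  a_beta <- numeric(0)
  for (e in model$edges) {
    tgt_i <- match(e$target, labels) - 1L
    if (is.null(e$t_join)) {
      a_time <- c(a_time, e$t_admix)
      a_target <- c(a_target, tgt_i)
      a_dest <- c(a_dest, match(e$source, labels) - 1L)
      a_beta <- c(a_beta, e$beta)
    } else {
      ghost <- paste0("ghost:", e$event)
      labels <- c(labels, ghost)
      ends <- c(ends, e$t_join)
      parent_idx <- c(parent_idx, match(e$source, labels) - 1L)
      a_time <- c(a_time, e$t_admix)
      a_target <- c(a_target, tgt_i)
      a_dest <- c(a_dest, length(labels) - 1L)
      a_beta <- c(a_beta, e$beta)
    }
  }
  list(branch_end = ends, branch_parent = as.integer(parent_idx),
       leaf_branch = match(as.character(1:5), labels) - 1L,
       leaf_time = as.numeric(model$sampling_times),
       admix_time = a_time, admix_target = as.integer(a_target),
       admix_dest = as.integer(a_dest), admix_beta = a_beta,
       lambda = model$lambda)
}

# Total-length cap of the rejection sampler: generous bound on the
# observable tree length; the vanishing fraction of heavier trees is
# accepted outright.
.length_cap <- function(model) {
  root <- max(model$branch_start)
  5 * (root + max(model$sampling_times)) + 25 / model$lambda
}

#' Simulate one gene tree
#'
#' Runs the structured coalescent backward in time under the model and
#' returns the merge sequence together with the per-leaf-subset subtending
#' branch lengths below the sample MRCA.
#'
#' @param model An `admixture_graph_model` (or a low-level branch list with
#'   the same fields, for non-standard demographies).
#' @return A `gene_tree`: list with `merges` (data frame `time`, `clade1`,
#'   `clade2`; clades as concatenated taxon labels), `lengths` (named by
#'   clade), and `total_length`.
#' @export
simulate_gene_tree <- function(model) {
  ll <- if (inherits(model, "admixture_graph_model")) .model_lowlevel(model)
  else model
  res <- sim_gene_tree_cpp(ll$branch_end, ll$branch_parent, ll$leaf_branch,
                           ll$leaf_time, ll$admix_time, ll$admix_target,
                           ll$admix_dest, ll$admix_beta, ll$lambda)
  mask_label <- function(m) {
    paste(which(bitwAnd(as.integer(m), 2L^(0:4)) > 0L), collapse = "")
  }
  mg <- as.data.frame(res$merges)
  structure(list(
    merges = data.frame(time = mg$time,
                        clade1 = vapply(mg$mask1, mask_label, ""),
                        clade2 = vapply(mg$mask2, mask_label, "")),
    lengths = res$lengths,
    total_length = res$total_length), class = "gene_tree")
}

#' Construct a gene tree from explicit branch lengths
#'
#' Convenience constructor for tests and examples: specify the subtending
#' branch length of each clade directly.
#'
#' @param lengths Named numeric vector; names are concatenated taxon labels
#'   (e.g. `"1"`, `"12"`, `"134"`).
#' @return A `gene_tree`.
#' @export
gene_tree <- function(lengths) {
  structure(list(merges = NULL, lengths = lengths,
                 total_length = sum(lengths)), class = "gene_tree")
}

#' Drop Poisson mutations on a gene tree
#'
#' The number of mutations is `Poisson(mu * total_length)`; each mutation
#' falls uniformly along the tree (branch chosen proportional to length)
#' and, under infinite sites, defines one biallelic pattern, polarized by
#' the minority rule.
#'
#' @param genetree A `gene_tree`.
#' @param mu Mutation intensity per unit time per lineage.
#' @return Character vector of pattern codes (possibly empty).
#' @export
drop_mutations <- function(genetree, mu) {
  stopifnot(mu > 0)
  lens <- genetree$lengths
  tot <- sum(lens)
  k <- stats::rpois(1L, mu * tot)
  if (k == 0L || tot == 0) return(character())
  clades <- sample(names(lens), k, replace = TRUE, prob = lens)
  vapply(clades, function(cl) {
    taxa <- as.integer(strsplit(cl, "")[[1L]])
    mask <- sum(2L^(taxa - 1L))
    mask_to_pattern(mask)
  }, "", USE.NAMES = FALSE)
}

#' Simulate polarized pattern counts under a model
#'
#' Draws `n_patterns` independent allelic patterns from the model: each
#' pattern arises from its own gene tree, selected with probability
#' proportional to observable branch length, with the single mutation
#' placed uniformly — the exact distribution of Poisson mutation dropping
#' in the rare-mutation limit, conditioned on the number of patterns.
#'
#' @param model A five-leaf `admixture_graph_model`.
#' @param n_patterns Number of patterns to accumulate.
#' @param seed Optional integer seed (`set.seed` is applied when given).
#' @return A [pattern_counts()] object.
#' @export
simulate_pattern_counts <- function(model, n_patterns, seed = NULL) {
  stopifnot(inherits(model, "admixture_graph_model"), n_patterns >= 1)
  if (!is.null(seed)) set.seed(seed)
  ll <- .model_lowlevel(model)
  cts <- sim_pattern_counts_cpp(ll$branch_end, ll$branch_parent,
                                ll$leaf_branch, ll$leaf_time, ll$admix_time,
                                ll$admix_target, ll$admix_dest, ll$admix_beta,
                                ll$lambda, as.integer(n_patterns),
                                .length_cap(model))
  pattern_counts(setNames(cts, pattern_codes()))
}

#' Build the default model for one gene-flow scenario
#'
#' Starts from the default node times of the tree shape and attaches the
#' single gene-flow edge. When the source branch dies before the target
#' branch is born (e.g. `"3>12"`: a terminal branch donating into an
#' ancestral branch), no time-consistent edge exists under the default
#' times, so the node closing the source branch is raised to the midpoint
#' between the target's birth and the node above — the predictions hold for
#' any valid branch lengths, and tree shapes only require their within-pair
#' symmetries, which the shift preserves.
#'
#' @inheritParams compute_panel
#' @param event Event label `"src>tgt"`.
#' @param beta Admixture proportion.
#' @inheritParams species_model
#' @return An `admixture_graph_model` with the edge attached.
#' @export
scenario_model <- function(tree = c("S", "A", "Q"), event, beta = 0.1,
                           lambda = 1, mu = 1e-4) {
  tree <- match.arg(tree)
  event <- gsub("→", ">", event)
  src <- sub(">.*$", "", event)
  tgt <- sub("^.*>", "", event)
  nt <- default_node_times(tree)
  model <- species_model(tree, node_times = nt, lambda = lambda, mu = mu)
  iv_s <- branch_interval(model, src)
  iv_t <- branch_interval(model, tgt)
  if (iv_s[2] <= iv_t[1] && src != "12345") {
    parent <- model$branch_parent[[src]]
    upper <- model$branch_end[[parent]]
    if (!is.finite(upper)) upper <- nt[["12345"]] + 1
    if (iv_t[1] >= upper) {
      stop("cannot make branches ", src, " and ", tgt, " coexist")
    }
    nt[[parent]] <- (iv_t[1] + upper) / 2
    model <- species_model(tree, node_times = nt, lambda = lambda, mu = mu)
  }
  add_gene_flow(model, event, beta = beta)
}

#' Run every nonzero gene-flow scenario of a tree shape
#'
#' For each event in [enumerate_nonzero_events()], builds the default model
#' with that single gene-flow edge (admixture proportion `beta`), simulates
#' `n_patterns` patterns, computes the full panel, and compares the observed
#' signature with the encoded prediction.
#'
#' @inheritParams compute_panel
#' @param n_patterns Patterns per scenario.
#' @param seed Master seed; per-scenario substreams are derived from it.
#' @param beta Admixture proportion.
#' @return List with `results` (data frame: `event`, `predicted`,
#'   `observed`, `match_full`, `match_nonsingleton`) and `panels` (named
#'   list of `delta_panel`s).
#' @export
scenario_suite <- function(tree = c("S", "A", "Q"), n_patterns = 1e5,
                           seed = 1, alpha = 0.01, beta = 0.1) {
  tree <- match.arg(tree)
  events <- enumerate_nonzero_events(tree)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, length(events))
  tab <- prediction_table(tree, include_singletons = TRUE)
  n_core <- if (tree == "A") 3L else 4L
  panels <- vector("list", length(events))
  names(panels) <- events
  rows <- vector("list", length(events))
  for (i in seq_along(events)) {
    ev <- events[i]
    model <- scenario_model(tree, ev, beta = beta)
    cts <- simulate_pattern_counts(model, n_patterns, seed = subseeds[i])
    panel <- compute_panel(cts, tree, include_singletons = TRUE,
                           alpha = alpha)
    panels[[i]] <- panel
    obs <- panel_signature(panel)
    pred <- parse_signature(tab$signature[tab$event == ev])
    rows[[i]] <- data.frame(
      event = ev,
      predicted = format_signature(pred, tree = tree),
      observed = format_signature(obs, tree = tree),
      match_full = all(obs == pred),
      match_nonsingleton = all(obs[seq_len(n_core)] == pred[seq_len(n_core)]),
      stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, rows), panels = panels)
}
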