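# Posterior tree-sample post-processing: ancestor-descendant support by
# counting, and per-branch rate-multiplier summaries on a reference tree.
#
# A sampled ancestor is a tip with a (near-)zero pendant branch sitting on
# an internal lineage; "a is an ancestor of b" means a is flagged as a
# sampled ancestor and b descends from a's attachment node.  Descent is
# transitive: a counts as ancestral to everything below its attachment,
# not only to adjacent nodes.

.tip_index <- function(tree, taxon) {
  i <- match(taxon, tree$tip.label)
  if (is.na(i)) stop("taxon '", taxon, "' not found in tree")
  i
}

.descendant_tips <- function(tree, node) {
  # tips below an internal node (or the tip itself), by edge-list traversal
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    ch <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

#' Is taxon a a sampled ancestor of taxon b?
#'
#' TRUE iff `a` carries the sampled-ancestor flag and `b` descends from the
#' node `a` attaches to.  A tip that is not flagged is never an ancestor,
#' whatever the topology.
#'
#' @param tree A `phylo` with a `sampled_ancestor` component (as produced
#'   by [read_tree_sample()]).
#' @param a,b Tip labels.
#' @return Logical scalar.
#' @export
is_ancestor_of <- function(tree, a, b) {
  stopifnot(inherits(tree, "phylo"))
  ia <- .tip_index(tree, a)
  ib <- .tip_index(tree, b)
  sa <- tree$sampled_ancestor
  if (is.null(sa)) sa <- stats::setNames(rep(FALSE, length(tree$tip.label)),
                                         tree$tip.label)
  if (!isTRUE(unname(sa[a]))) return(FALSE)
  attach_node <- tree$edge[tree$edge[, 2L] == ia, 1L]
  ib %in% .descendant_tips(tree, attach_node)
}

#' Ancestor-descendant posterior probability by counting
#'
#' The posterior support for "a is an ancestor of b" is the fraction of
#' trees in the sample where [is_ancestor_of()] holds.  With
#' `b = "ANY"` (the default when `b` is `NULL`), a tree counts whenever
#' `a` is placed as a sampled ancestor of anything — both readings of
#' "placed as an ancestor" are legitimate, so both are exposed.
#'
#' @param sample A `"tree_sample"`.
#' @param a Ancestor tip label.
#' @param b Descendant tip label, or `NULL`/`"ANY"` for any descendant.
#' @return Posterior probability in `[0, 1]`.
#' @export
ad_posterior <- function(sample, a, b = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  any_b <- is.null(b) || identical(b, "ANY")
  hits <- vapply(sample$trees, function(tr) {
    if (any_b) {
      ia <- .tip_index(tr, a)
      isTRUE(unname(tr$sampled_ancestor[a]))
    } else {
      is_ancestor_of(tr, a, b)
    }
  }, logical(1))
  sum(hits) / sample$n_trees
}

# clade key: sorted tip labels below an edge's child node
.edge_keys <- function(tree) {
  vapply(seq_len(nrow(tree$edge)), function(k) {
    tips <- .descendant_tips(tree, tree$edge[k, 2L])
    paste(sort(tree$tip.label[tips]), collapse = "\r")
  }, character(1))
}

#' Summarize per-branch rate multipliers over a tree sample
#'
#' Each branch of the reference tree is identified by the set of tips it
#' subtends (the rooted-clade convention).  For every reference branch the
#' mean of the rate multipliers over the sample trees containing that clade
#' is reported, together with the number of supporting trees.  Pendant
#' branches of sampled-ancestor tips have zero duration and are excluded
#' from the mapping.
#'
#' @param sample A `"tree_sample"` whose trees carry `edge_rate`
#'   annotations.
#' @param reference A `phylo` sharing the sample's taxon namespace.
#' @return Object of class `"rate_summary"`: the reference tree with an
#'   `edge_rate_mean` component, and a data frame `table` with columns
#'   `branch` (semicolon-joined tip set), `n_tips`, `mean_rate`, `support`.
#' @export
summarize_branch_rates <- function(sample, reference) {
  stopifnot(inherits(sample, "tree_sample"), inherits(reference, "phylo"))
  acc <- new.env(parent = emptyenv())   # key -> c(sum, count)
  for (tr in sample$trees) {
    if (all(is.na(tr$edge_rate)))
      stop("a sample tree carries no rate annotations")
    keys <- .edge_keys(tr)
    sa_tips <- which(tr$sampled_ancestor[tr$tip.label])
    sa_edge <- tr$edge[, 2L] %in% sa_tips
    for (k in seq_along(keys)) {
      if (sa_edge[k] || is.na(tr$edge_rate[k])) next
      prev <- if (is.null(acc[[keys[k]]])) c(0, 0) else acc[[keys[k]]]
      acc[[keys[k]]] <- prev + c(tr$edge_rate[k], 1)
    }
  }
  ref_keys <- .edge_keys(reference)
  mean_rate <- rep(NA_real_, length(ref_keys))
  support <- rep(0L, length(ref_keys))
  for (k in seq_along(ref_keys)) {
    v <- acc[[ref_keys[k]]]
    if (!is.null(v)) {
      mean_rate[k] <- v[1L] / v[2L]
      support[k] <- as.integer(v[2L])
    }
  }
  if (any(is.na(mean_rate)))
    warning(sum(is.na(mean_rate)),
            " reference branch(es) found in no sample tree; set to NA")
  reference$edge_rate_mean <- mean_rate
  tab <- data.frame(
    branch = gsub("\r", ";", ref_keys, fixed = TRUE),
    n_tips = vapply(strsplit(ref_keys, "\r", fixed = TRUE), length,
                    integer(1)),
    mean_rate = mean_rate, support = support, stringsAsFactors = FALSE)
  structure(list(tree = reference, table = tab), class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("per-branch rate summary:", nrow(x$table), "branches,",
      sum(!is.na(x$table$mean_rate)), "annotated\n")
  invisible(x)
}

#' Branch with the highest mean rate multiplier
#'
#' Ties are broken by the smallest subtended tip set, then by lexicographic
#' tip labels; a tie triggers a message.
#'
#' @param summary A `"rate_summary"` from [summarize_branch_rates()], or
#'   its `table` data frame.
#' @return One-row data frame (branch, n_tips, mean_rate, support).
#' @export
max_rate_branch <- function(summary) {
  tab <- if (inherits(summary, "rate_summary")) summary$table else summary
  tab <- tab[!is.na(tab$mean_rate), , drop = FALSE]
  if (nrow(tab) == 0L) stop("no annotated branches")
  top <- tab[tab$mean_rate == max(tab$mean_rate), , drop = FALSE]
  if (nrow(top) > 1L) {
    message("rate tie among ", nrow(top), " branches; smallest clade wins")
    top <- top[order(top$n_tips, top$branch), , drop = FALSE]
  }
  top[1L, , drop = FALSE]
}
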