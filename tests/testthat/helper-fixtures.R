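# Shared fixture builders and independent oracles.  Everything is built in
# code; no binary fixtures.

# small five-locality series with a strong step decrease at ~428 Ma
toy_specs <- function() {
  data.frame(locality = c("Old1", "Old2", "Mid", "Young1", "Young2"),
             age_ma = c(433, 431, 429, 427, 425),
             n = c(30L, 40L, 50L, 40L, 30L),
             mean_area = c(0.60, 0.55, 0.50, 0.15, 0.14),
             sd_area = c(0.12, 0.12, 0.10, 0.04, 0.04))
}

toy_series <- function(seed = 42) gen_assemblages(toy_specs(), seed = seed)

toy_event <- function() event_window("MidDrop", "Mid", "Young1")

# summary-only series where all localities share one normal (global null)
null_series <- function(n_loc = 5L, n = 20L, mean = 0.5, sd = 0.1) {
  series_from_summary(data.frame(
    locality = paste0("L", seq_len(n_loc)),
    age_ma = seq(433, by = -2, length.out = n_loc),
    n = n, mean = mean, sd = sd))
}

# parse a set of newick strings into a tree_sample via a temp file
sample_from_newick <- function(strings, tol = 1e-8) {
  f <- withr::local_tempfile(fileext = ".nwk",
                             .local_envir = parent.frame())
  writeLines(strings, f)
  read_tree_sample(f, sa_branch_tolerance = tol)
}

# --- independent ancestor-descendant oracle ------------------------------
# Counts AD placements by climbing parents from the descendant to the root
# (a path-based algorithm, unlike the package's subtree traversal).
oracle_is_ad <- function(tree, a, b) {
  sa <- tree$sampled_ancestor
  if (!isTRUE(unname(sa[a]))) return(FALSE)
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  parent_of <- function(nd) {
    p <- tree$edge[tree$edge[, 2L] == nd, 1L]
    if (length(p)) p else NA_integer_
  }
  attach_a <- parent_of(ia)
  nd <- ib
  repeat {
    nd <- parent_of(nd)
    if (is.na(nd)) return(FALSE)
    if (nd == attach_a) return(TRUE)
  }
}

oracle_ad_posterior <- function(sample, a, b = NULL) {
  hits <- vapply(sample$trees, function(tr) {
    if (is.null(b)) {
      isTRUE(unname(tr$sampled_ancestor[a]))
    } else {
      oracle_is_ad(tr, a, b)
    }
  }, logical(1))
  mean(hits)
}

# --- independent three-timer oracle --------------------------------------
# Exhaustive per-taxon enumeration over the presence matrix.
oracle_three_timer <- function(P) {
  ni <- ncol(P)
  p <- rep(NA_real_, ni)
  for (i in 2:(ni - 1L)) {
    tt <- 0L; pt <- 0L
    for (tx in seq_len(nrow(P))) {
      if (P[tx, i - 1L] == 1L && P[tx, i + 1L] == 1L) {
        if (P[tx, i] == 1L) tt <- tt + 1L else pt <- pt + 1L
      }
    }
    if (tt + pt > 0L) p[i] <- tt / (tt + pt)
  }
  p
}

# stage table helper
toy_stages <- function(ni = 6L, width = 10) {
  data.frame(name = paste0("I", seq_len(ni)),
             start_ma = seq(ni * width, width, -width),
             end_ma = seq((ni - 1L) * width, 0, -width))
}
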