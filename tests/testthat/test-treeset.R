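test_that("is_ancestor_of follows flag + descent semantics", {
  chain <- sample_from_newick("((b:1,a:0):1,c:2);")$trees[[1]]
  expect_true(is_ancestor_of(chain, "a", "b"))
  expect_false(is_ancestor_of(chain, "a", "c"))
  expect_false(is_ancestor_of(chain, "b", "a"))   # b not flagged

  disjoint <- sample_from_newick("((a:0,d:1):1,(b:1,c:1):1);")$trees[[1]]
  expect_true(is_ancestor_of(disjoint, "a", "d"))
  expect_false(is_ancestor_of(disjoint, "a", "b"))

  # unflagged tip is never an ancestor, whatever the topology
  unflagged <- sample_from_newick("((b:1,a:0.4):1,c:2);")$trees[[1]]
  expect_false(is_ancestor_of(unflagged, "a", "b"))

  expect_error(is_ancestor_of(chain, "zz", "b"), "zz")
})

test_that("descent is transitive below the attachment node", {
  deep <- sample_from_newick("(((d:1,(e:1,f:1):1):1,a:0):1,c:2);")$trees[[1]]
  for (tip in c("d", "e", "f")) expect_true(is_ancestor_of(deep, "a", tip))
  expect_false(is_ancestor_of(deep, "a", "c"))
})

test_that("ad_posterior counts over trees; PP(a,b) <= PP(a,ANY)", {
  smp <- sample_from_newick(c(
    "((b:1,a:0):1,c:2);",
    "((b:1,a:0):1,c:2);",
    "((c:1,a:0):1,b:2);",     # a ancestral to c, not b
    "((a:1,b:1):1,c:2);"))    # a ordinary tip
  expect_equal(ad_posterior(smp, "a", "b"), 0.5)
  expect_equal(ad_posterior(smp, "a", "ANY"), 0.75)
  expect_equal(ad_posterior(smp, "b", "a"), 0)
  expect_gte(ad_posterior(smp, "a"), ad_posterior(smp, "a", "b"))
})

test_that("ad_posterior equals the independent path-climbing recount", {
  set.seed(123)
  for (rep in 1:8) {
    n_taxa <- sample(4:8, 1)
    smp <- gen_tree_sample(sample(3:10, 1), paste0("t", seq_len(n_taxa)),
                           ad_fraction = runif(1), seed = 500 + rep)
    a <- "t1"
    for (b in c("t2", "t3", NULL)) {
      expect_equal(ad_posterior(smp, a, b), oracle_ad_posterior(smp, a, b))
    }
    expect_equal(ad_posterior(smp, a), oracle_ad_posterior(smp, a))
  }
})

test_that("concatenating a sample with itself changes no PP", {
  smp <- gen_tree_sample(6, letters[1:5], 0.5, seed = 77)
  doubled <- tree_sample(c(smp$trees, smp$trees))
  expect_equal(ad_posterior(doubled, "a", "b"), ad_posterior(smp, "a", "b"))
  expect_equal(ad_posterior(doubled, "a"), ad_posterior(smp, "a"))
})

# two fixed 4-taxon topologies with rate annotations
rate_sample <- function(rates1 = c(ab = 2), rates2 = c(ab = 4)) {
  s1 <- sprintf("(((a:1[&rate=%g],b:1):1[&rate=%g],c:1):1,d:1);",
                1.0, rates1[["ab"]])
  s2 <- sprintf("(((a:1[&rate=%g],b:1):1[&rate=%g],c:1):1,d:1);",
                1.0, rates2[["ab"]])
  sample_from_newick(c(s1, s2))
}

test_that("summarize_branch_rates averages per bipartition", {
  smp <- rate_sample()
  ref <- smp$trees[[1]]
  expect_warning(rs <- summarize_branch_rates(smp, ref), "NA")
  tab <- rs$table
  ab <- tab[tab$branch == "a;b", ]
  expect_equal(ab$mean_rate, 3)         # mean of {2, 4}
  expect_equal(ab$support, 2L)
  a_tip <- tab[tab$branch == "a", ]
  expect_equal(a_tip$mean_rate, 1)      # constant rate -> that rate
  expect_true(is.na(tab$mean_rate[tab$branch == "c"]))  # never annotated

  # invariant to tree order within the sample
  rs2 <- suppressWarnings(summarize_branch_rates(tree_sample(rev(smp$trees)), ref))
  expect_equal(rs2$table, tab)

  # self-concatenation leaves branch means unchanged
  rs3 <- suppressWarnings(
    summarize_branch_rates(tree_sample(c(smp$trees, smp$trees)), ref))
  expect_equal(rs3$table$mean_rate, tab$mean_rate)
})

test_that("sampled-ancestor pendant branches are excluded from rate maps", {
  smp <- sample_from_newick(
    "(((a:0[&SA,rate=9],b:1[&rate=2]):1[&rate=3],c:1):1,d:1);")
  rs <- suppressWarnings(summarize_branch_rates(smp, smp$trees[[1]]))
  expect_true(is.na(rs$table$mean_rate[rs$table$branch == "a"]))
  expect_equal(rs$table$mean_rate[rs$table$branch == "b"], 2)
})

test_that("max_rate_branch picks the 24.76 fixture branch and breaks ties", {
  smp <- sample_from_newick(
    "(((a:1[&rate=0.1],b:1):1[&rate=24.76],c:1[&rate=1.0]):1,d:1);")
  rs <- suppressWarnings(summarize_branch_rates(smp, smp$trees[[1]]))
  top <- max_rate_branch(rs)
  expect_equal(top$branch, "a;b")
  expect_equal(top$mean_rate, 24.76)

  tied <- sample_from_newick(
    "(((a:1[&rate=2],b:1):1[&rate=2],c:1):1,d:1);")
  rs2 <- suppressWarnings(summarize_branch_rates(tied, tied$trees[[1]]))
  expect_message(top2 <- max_rate_branch(rs2), "tie")
  expect_equal(top2$branch, "a")       # smallest clade, then lexicographic

  empty <- rs2$table[0, ]
  expect_error(max_rate_branch(empty), "no annotated branches")
})
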