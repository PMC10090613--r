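mat_dm <- function(d) {
  structure(list(labels = rownames(d), values = d,
                 comparable_sites = matrix(1L, nrow(d), ncol(d)),
                 metric = "raw_differences"), class = "dist_matrix")
}

test_that("three taxa yield the closed-form star", {
  d <- matrix(c(0, 3, 7, 3, 0, 8, 7, 8, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(mat_dm(d))
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], (3 + 7 - 8) / 2)
  expect_equal(el[["B"]], (3 + 8 - 7) / 2)
  expect_equal(el[["C"]], (7 + 8 - 3) / 2)
})

test_that("a four-taxon additive matrix recovers its generating tree exactly", {
  gen <- ape::read.tree(text = "((A:2,B:3):1,(C:2,D:2):0);")
  d <- ape::cophenetic.phylo(gen)
  tr <- neighbor_joining(mat_dm(d))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
  # all pairwise path lengths reproduced
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d)
})

test_that("ties resolve deterministically and equidistant input still resolves", {
  d <- matrix(5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(mat_dm(d))
  t2 <- neighbor_joining(mat_dm(d))
  expect_equal(write_newick(t1), write_newick(t2))
  expect_true(ape::is.binary(t1) || t1$Nnode == 2L)
  # lexicographically smallest pair joined first
  expect_true(is_bipartition_clade(t1, c("A", "B")))
})

test_that("errors on undefined distances list the offending pairs", {
  d <- matrix(c(0, NA, 3, NA, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(neighbor_joining(mat_dm(d)), "A/B")
})

test_that("NJ recovers random additive topologies (spot sample)", {
  withr::local_seed(31)
  for (rep in 1:40) {
    cs <- random_additive_case(sample(4:12, 1))
    tr <- neighbor_joining(cs$dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(cs$tree), tr)), 0)
    # and agrees topologically with ape's independent NJ implementation
    ref <- ape::nj(stats::as.dist(cs$dm$values))
    expect_equal(as.numeric(ape::dist.topo(ref, tr)), 0)
  }
})

test_that("total branch length is invariant under label permutation", {
  withr::local_seed(17)
  cs <- random_additive_case(8)
  base <- sum(neighbor_joining(cs$dm)$edge.length)
  perm <- sample(length(cs$dm$labels))
  dmp <- mat_dm(cs$dm$values[perm, perm])
  expect_equal(sum(neighbor_joining(dmp)$edge.length), base)
})

test_that("bipartition-clade tests match worked examples and conventions", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_true(is_bipartition_clade(tr, c("A", "B")))
  expect_false(is_bipartition_clade(tr, c("A", "C")))
  expect_true(is_bipartition_clade(tr, "A"))
  expect_true(is_bipartition_clade(tr, c("A", "B", "C", "D")))
  expect_error(is_bipartition_clade(tr, "Z"), "unknown tip")
  expect_error(is_bipartition_clade(tr, character(0)), "non-empty")
})

test_that("bipartition-clade test equals exhaustive split enumeration", {
  withr::local_seed(23)
  for (rep in 1:30) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    labs <- tr$tip.label
    # every subset of tips of sizes 1..n
    for (k in seq_len(n)) {
      subs <- utils::combn(labs, k, simplify = FALSE)
      for (tips in subs) {
        expect_equal(is_bipartition_clade(tr, tips),
                     splits_oracle_is_clade(tr, tips),
                     info = paste(write_newick(tr), paste(tips, collapse = ",")))
      }
    }
  }
})

test_that("reciprocal monophyly uses restriction semantics", {
  tr <- parse_newick("((A1,A2),(B1,B2));")
  expect_true(reciprocal_monophyly(tr, c("A1", "A2"), c("B1", "B2")))
  tr2 <- parse_newick("((A1,B1),(A2,B2));")
  expect_false(reciprocal_monophyly(tr2, c("A1", "A2"), c("B1", "B2")))
  # an excluded outsider does not break restricted monophyly
  tr3 <- parse_newick("((A1,A2),X,(B1,B2));")
  expect_true(reciprocal_monophyly(tr3, c("A1", "A2"), c("B1", "B2")))
  # outsider interleaved inside one group's clade still fine after pruning
  tr4 <- parse_newick("(((A1,X),A2),(B1,B2));")
  expect_true(reciprocal_monophyly(tr4, c("A1", "A2"), c("B1", "B2")))
  expect_error(reciprocal_monophyly(tr, c("A1"), c("A1", "B1")), "overlap")
})

test_that("newick parsing round-trips and reports imbalance position", {
  t1 <- parse_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(sort(t1$tip.label), c("A", "B", "C"))
  expect_equal(parse_newick(write_newick(t1))$edge.length, t1$edge.length)

  t2 <- parse_newick("((A,B)95:0.5,(C,D)87:0.2);")
  expect_setequal(setdiff(t2$node.label, ""), c("95", "87"))
  expect_true(grepl("95", write_newick(t2)))

  expect_error(parse_newick("((A,B);"), "position")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
})

test_that("bootstrap supports behave at the extremes and under reseeding", {
  # two 4-taxon groups, identical within, differing at 40 of 80 columns
  g1 <- paste(c(rep("A", 40), rep("C", 40)), collapse = "")
  g2 <- paste(c(rep("A", 40), rep("G", 40)), collapse = "")
  aln <- seq_set(stats::setNames(rep(c(g1, g2), each = 4),
                                 c(paste0("a", 1:4), paste0("b", 1:4))))
  tr <- bootstrap_support(aln, replicates = 200, seed = 5)
  sup <- attr(tr, "bipartition_support")
  central <- paste(sort(paste0("b", 1:4)), collapse = "|")
  expect_gte(sup[[central]], 99)

  # single replicate: supports are 0 or 100
  tr1 <- bootstrap_support(aln, replicates = 1, seed = 9)
  expect_true(all(attr(tr1, "bipartition_support") %in% c(0, 100)))

  # determinism under a fixed seed
  s1 <- attr(bootstrap_support(aln, replicates = 50, seed = 3),
             "bipartition_support")
  s2 <- attr(bootstrap_support(aln, replicates = 50, seed = 3),
             "bipartition_support")
  expect_identical(s1, s2)
})
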