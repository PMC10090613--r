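# Independent oracles and generators used across the suite. These stay
# deliberately naive (column-by-column loops, exhaustive enumeration) so
# they check the vectorized implementations from the outside.

MISSING_CHARS <- c("-", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H",
                   "V", "?")

# brute-force raw differences with pairwise deletion, one column at a time
brute_differences <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  vals <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  comp <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { vals[i, j] <- 0; next }
      d <- 0L; nc <- 0L
      for (k in seq_len(ncol(m))) {
        a <- m[i, k]; b <- m[j, k]
        if (a %in% MISSING_CHARS || b %in% MISSING_CHARS) next
        nc <- nc + 1L
        if (a != b) d <- d + 1L
      }
      comp[i, j] <- nc
      vals[i, j] <- if (nc == 0L) NA_real_ else d
    }
  }
  list(values = vals, comparable = comp)
}

# random gapped alignment over ACGT plus occasional missing characters
random_alignment <- function(n_seq, n_col, p_missing = 0.1) {
  chars <- matrix(sample(c("A", "C", "G", "T"), n_seq * n_col, replace = TRUE),
                  n_seq, n_col)
  miss <- matrix(stats::runif(n_seq * n_col) < p_missing, n_seq, n_col)
  chars[miss] <- sample(c("-", "N", "R", "Y"), sum(miss), replace = TRUE)
  rownames(chars) <- sprintf("s%02d", seq_len(n_seq))
  aln_from_matrix(chars, marker = "cox1")
}

# random binary tree with positive branch lengths and its additive distance
# matrix, for NJ topology-recovery checks
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.5, 3))
  d <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(d))
  d <- d[ord, ord]
  dm <- structure(list(labels = ord, values = d,
                       comparable_sites = matrix(1L, n_taxa, n_taxa),
                       metric = "raw_differences"),
                  class = "dist_matrix")
  list(tree = tr, dm = dm)
}

# exhaustive bipartition enumeration via phangorn splits (independent of the
# package's prop.part-based path)
splits_oracle_is_clade <- function(tree, tips) {
  labs <- tree$tip.label
  tips <- unique(tips)
  if (length(tips) == 1L || length(tips) >= length(labs) - 1L) return(TRUE)
  sp <- phangorn::as.splits(tree)
  m <- as.matrix(sp)
  for (r in seq_len(nrow(m))) {
    side <- labs[m[r, ] == 1]
    if (setequal(side, tips) || setequal(setdiff(labs, side), tips))
      return(TRUE)
  }
  FALSE
}

# simulation design meeting the clustering-closure margins: within-species
# expected differences ~1 (well under threshold/2, so realized values stay
# below the threshold with overwhelming probability), between-species >= 40
# (> 2x threshold) on 474 columns, no population structure
closure_sim_spec <- function(k_species, seed) {
  L <- 474L
  h <- function(nd) jc_distance_for_differences(nd, L) / 2
  tip <- h(1); spd <- h(40)
  cherries <- sprintf("(%s1:%f,%s2:%f):%f",
                      letters[1:k_species], tip,
                      letters[1:k_species], tip, spd - tip)
  nwk <- paste0("(", paste(cherries, collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  plant <- stats::setNames(rep(LETTERS[1:k_species], each = 2L),
                           tree$tip.label[order(tree$tip.label)])
  plant <- stats::setNames(toupper(substr(tree$tip.label, 1, 1)),
                           tree$tip.label)
  sim_spec(tree, seq_length = L, seed = seed, planted_partition = plant)
}

partition_equal <- function(assignment, truth) {
  # same partition up to relabelling
  a <- split(names(assignment), assignment)
  b <- split(names(truth), truth)
  setequal(lapply(a, sort), lapply(b, sort))
}
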