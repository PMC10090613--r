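#' Neighbour-joining tree from a raw-difference matrix
#'
#' Standard Saitou-Nei agglomeration on the Q criterion, returning an
#' unrooted `phylo` tree (basal trifurcation). Two conventions are fixed for
#' determinism across platforms: when several pairs minimize Q, the pair
#' whose (lexicographically smallest member-label, largest member-label) is
#' smallest is joined, a cluster being keyed by its smallest leaf label; and
#' negative intermediate branch lengths are clamped to 0 with the deficit
#' transferred to the sister edge so the joined pair's path length is
#' preserved.
#'
#' @param dm a `dist_matrix` with at least 3 labels and no undefined entries
#' @return an unrooted [ape::read.tree()]-style `phylo` object
#' @examples
#' aln <- seq_set(c(A = "AAAA", B = "AAAT", C = "TTTA"), marker = "cox1")
#' neighbor_joining(pairwise_differences(aln))
#' @export
neighbor_joining <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  d <- dm$values
  storage.mode(d) <- "double"
  n <- length(dm$labels)
  if (n < 3L) stop("need at least 3 labels")
  und <- undefined_pairs(dm)
  if (nrow(und) > 0L)
    stop("undefined distances present for pairs: ",
         paste(apply(und, 1L, paste, collapse = "/"), collapse = ", "))
  frag <- dm$labels            # growing newick fragments
  key <- dm$labels             # smallest leaf label per cluster
  clamp_join <- function(la, lb) {
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    c(max(la, 0), max(lb, 0))
  }
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    eps <- 1e-9 * max(1, abs(qmin))
    cand <- which(q - qmin <= eps & upper.tri(q), arr.ind = TRUE)
    keys <- cbind(pmin(key[cand[, 1L]], key[cand[, 2L]]),
                  pmax(key[cand[, 1L]], key[cand[, 2L]]))
    ord <- order(keys[, 1L], keys[, 2L])[1L]
    i <- cand[ord, 1L]; j <- cand[ord, 2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    ll <- clamp_join(li, lj)
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(ll[1]),
                       frag[j], fmt(ll[2]))
    newkey <- min(key[i], key[j])
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
  }
  # final 3-cluster star: closed-form branch lengths
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  c3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  lens <- pmax(c(a, b, c3), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(lens[1]),
                 frag[2], fmt(lens[2]), frag[3], fmt(lens[3]))
  ape::read.tree(text = txt)
}

# Canonical string keys for the non-trivial bipartitions of a tree: for each
# internal edge, the tip set on the side not containing the alphabetically
# first leaf, sorted and collapsed.
bipartition_keys <- function(tree) {
  labs <- tree$tip.label
  ref <- min(labs)
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) == length(labs)) next       # root pseudo-clade
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Column bootstrap supports for the neighbour-joining tree
#'
#' Resamples alignment columns with replacement to the original length,
#' recomputes raw differences and the NJ tree per replicate, and annotates
#' each internal edge of the point-estimate tree with the percentage of
#' replicate trees containing its bipartition. Replicates in which
#' resampling leaves some pair with no comparable site are discarded and
#' counted; more than 10% discarded is an error.
#'
#' @param aln an alignment
#' @param replicates bootstrap replicates (>= 1). 1000 keeps desk-scale
#'   runtime; raise to 10000 for publication-grade supports.
#' @param seed integer seed
#' @return the point-estimate tree with `node.label` holding support
#'   percentages (internal edges) and attributes `bipartition_support`
#'   (named vector) and `n_discarded`
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L) {
  stopifnot(replicates >= 1L)
  m <- aln_matrix(aln)
  point_dm <- pairwise_differences(aln)
  point <- neighbor_joining(point_dm)
  target <- bipartition_keys(point)
  counts <- stats::setNames(numeric(length(target)), target)
  set.seed(seed)
  discarded <- 0L
  used <- 0L
  L <- ncol(m)
  for (b in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- aln_from_matrix(m[, cols, drop = FALSE], marker = aln$marker)
    dmb <- pairwise_differences(rep_aln)
    if (nrow(undefined_pairs(dmb)) > 0L) { discarded <- discarded + 1L; next }
    tb <- neighbor_joining(dmb)
    hits <- intersect(bipartition_keys(tb), target)
    counts[hits] <- counts[hits] + 1
    used <- used + 1L
  }
  if (discarded > 0.1 * replicates)
    stop(sprintf("%d of %d bootstrap replicates discarded (undefined distances)",
                 discarded, replicates))
  supports <- 100 * counts / used
  # map supports onto node labels of the point tree
  labs <- point$tip.label
  ref <- min(labs)
  pp <- ape::prop.part(point)
  node.label <- rep("", point$Nnode)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) == length(labs)) next
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    keyk <- paste(sort(side), collapse = "|")
    node.label[k] <- format(round(supports[[keyk]], 1))
  }
  point$node.label <- node.label
  attr(point, "bipartition_support") <- supports
  attr(point, "n_discarded") <- discarded
  point
}

#' Does a tip set form an edge-induced bipartition of the tree?
#'
#' On an unrooted tree, "clade" is formalized as an edge-induced
#' bipartition: `tips` is a bipartition-clade iff some edge splits the
#' leaves into (`tips` | rest). Singletons and the full leaf set are clades
#' by convention.
#'
#' @param tree a `phylo`
#' @param tips character vector of leaf labels
#' @return logical
#' @export
is_bipartition_clade <- function(tree, tips) {
  labs <- tree$tip.label
  if (length(tips) == 0L) stop("tips must be non-empty")
  unknown <- setdiff(tips, labs)
  if (length(unknown) > 0L)
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  tips <- unique(tips)
  if (length(tips) == 1L || length(tips) == length(labs)) return(TRUE)
  if (length(tips) == length(labs) - 1L) return(TRUE) # complement of a leaf edge
  key <- local({
    ref <- min(labs)
    side <- if (ref %in% tips) setdiff(labs, tips) else tips
    paste(sort(side), collapse = "|")
  })
  key %in% bipartition_keys(tree)
}

#' Reciprocal monophyly of two groups on a tree
#'
#' True iff, on the tree restricted to the union of the two groups, each
#' group is an edge-induced bipartition-clade. Restriction means other
#' leaves are pruned first, so an interleaving outsider does not break
#' reciprocal monophyly of the two groups with respect to *each other*.
#'
#' @param tree a `phylo`
#' @param group_a,group_b disjoint sets of leaf labels
#' @return logical
#' @export
reciprocal_monophyly <- function(tree, group_a, group_b) {
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups overlap: ",
         paste(intersect(group_a, group_b), collapse = ", "))
  labs <- tree$tip.label
  unknown <- setdiff(c(group_a, group_b), labs)
  if (length(unknown) > 0L)
    stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  if (length(group_a) <= 1L && length(group_b) <= 1L) return(TRUE)
  keep <- union(group_a, group_b)
  sub <- if (length(keep) < length(labs)) ape::keep.tip(tree, keep) else tree
  if (length(keep) <= 3L) return(TRUE) # any split of <=3 leaves is an edge
  is_bipartition_clade(sub, group_a) && is_bipartition_clade(sub, group_b)
}

#' Newick input and output
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] adding
#' position-reporting validation of parenthesis balance and a duplicate
#' label check. `write_newick(parse_newick(x))` preserves topology, branch
#' lengths (10 significant digits) and node supports.
#'
#' @param text newick string
#' @return `phylo`
#' @export
parse_newick <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (pos in seq_along(chars)) {
    if (chars[pos] == "(") depth <- depth + 1L
    if (chars[pos] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("newick parse error: unbalanced ')' at position ", pos)
    }
  }
  if (depth != 0L)
    stop("newick parse error: ", depth,
         " unclosed '(' by position ", length(chars))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree))
    stop("newick parse error: malformed tree text")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' @rdname parse_newick
#' @param tree a `phylo`
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}
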