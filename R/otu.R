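#' Threshold OTU delimitation by single-linkage clustering
#'
#' Implements the barcode criterion "differences at fewer than `threshold`
#' base positions are intraspecific variation": sequences are the vertices
#' of a graph with an edge wherever the raw difference count is below the
#' threshold, and OTUs are the connected components (strict single linkage,
#' so chains merge). Undefined (`NA`) distances are non-edges and are
#' reported; a sequence whose distances to all others are undefined becomes
#' a singleton OTU with a warning. OTU labels are integers 1..n_otus in
#' order of each OTU's first member in the matrix.
#'
#' @param dm a raw-differences `dist_matrix`
#' @param threshold integer difference threshold (default 10, the
#'   conventional cox1 criterion for this workflow)
#' @return object of class `otu_partition`: `assignment` (named integer
#'   vector), `threshold`, `n_otus`, `undefined_pairs`
#' @examples
#' aln <- seq_set(c(A = "AAAAAA", B = "AAAAAT", C = "TTTTTG"), marker = "cox1")
#' cluster_otus(pairwise_differences(aln), threshold = 3)
#' @export
cluster_otus <- function(dm, threshold = 10L) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (dm$metric != "raw_differences")
    stop("cluster_otus requires the raw_differences metric, got ", dm$metric)
  if (threshold < 1L) stop("threshold must be >= 1")
  n <- length(dm$labels)
  adj <- !is.na(dm$values) & dm$values < threshold
  diag(adj) <- TRUE
  comp <- integer(n)            # connected components, BFS in label order
  nxt <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    comp[s] <- nxt
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- nxt
      queue <- c(queue, nb)
    }
  }
  und <- undefined_pairs(dm)
  isolated <- dm$labels[vapply(seq_len(n), function(i)
    all(is.na(dm$values[i, -i])), logical(1))]
  if (length(isolated) > 0L)
    warning("sequences with no comparable sites to any other form singleton OTUs: ",
            paste(isolated, collapse = ", "))
  structure(list(
    assignment = stats::setNames(comp, dm$labels),
    threshold = as.integer(threshold),
    n_otus = nxt,
    undefined_pairs = und
  ), class = "otu_partition")
}

#' @export
print.otu_partition <- function(x, ...) {
  cat(sprintf("<otu_partition> %d OTUs at threshold %d\n",
              x$n_otus, x$threshold))
  print(split(names(x$assignment), x$assignment))
  invisible(x)
}

#' Per-OTU and between-OTU distance summary
#'
#' @param partition an `otu_partition`
#' @param dm the `dist_matrix` it was derived from
#' @return list of data frames: `otus` (size, max within-OTU difference;
#'   `NA` for singletons) and `between` (min between-OTU difference per OTU
#'   pair)
#' @export
partition_summary <- function(partition, dm) {
  stopifnot(inherits(partition, "otu_partition"),
            inherits(dm, "dist_matrix"))
  if (!setequal(names(partition$assignment), dm$labels))
    stop("partition labels do not match distance matrix labels")
  g <- stats::setNames(as.character(partition$assignment),
                       names(partition$assignment))
  s <- group_distance_summary(dm, g)
  otus <- data.frame(otu = as.integer(s$within$group), size = s$within$n,
                     max_within = s$within$max)
  otus <- otus[order(otus$otu), , drop = FALSE]
  rownames(otus) <- NULL
  between <- data.frame(otu_a = as.integer(s$between$group_a),
                        otu_b = as.integer(s$between$group_b),
                        min_between = s$between$min)
  list(otus = otus, between = between)
}

#' Export an OTU partition as two-column CSV
#' @param partition an `otu_partition`
#' @param path output path
#' @export
write_otu_csv <- function(partition, path) {
  utils::write.csv(
    data.frame(sequence_id = names(partition$assignment),
               otu = unname(partition$assignment)),
    path, row.names = FALSE)
  invisible(path)
}
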