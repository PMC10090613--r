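#' Raw pairwise base-position differences under pairwise deletion
#'
#' For each sequence pair, alignment columns where either member carries a
#' gap, `N`, `?` or any IUPAC ambiguity code are excluded (pairwise
#' deletion); the value is the count of mismatching columns among those
#' remaining. This is the model-free "number of differences" metric used to
#' delimit barcode OTUs. A pair with zero jointly comparable columns gets an
#' undefined (`NA`) value, never 0.
#'
#' @param aln an [seq_set()] alignment
#' @return a `dist_matrix`: list with `labels`, integer matrix `values`
#'   (`NA` = undefined), integer matrix `comparable_sites`, and
#'   `metric = "raw_differences"`
#' @examples
#' aln <- seq_set(c(A = "AC-T", B = "ACGT"), marker = "cox1")
#' pairwise_differences(aln)$values
#' @export
pairwise_differences <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("alignment must contain at least 2 sequences")
  code <- matrix(match(m, DNA_BASES, nomatch = 0L), nrow = n) # 0 = missing
  vals <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  comp <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- code[i, ] > 0L & code[j, ] > 0L
      nc <- sum(ok)
      comp[i, j] <- comp[j, i] <- nc
      d <- if (nc == 0L) NA_integer_ else sum(code[i, ok] != code[j, ok])
      vals[i, j] <- vals[j, i] <- d
    }
  }
  structure(list(labels = rownames(m), values = vals,
                 comparable_sites = comp, metric = "raw_differences"),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d labels, metric %s\n",
              length(x$labels), x$metric))
  if (any(is.na(x$values[upper.tri(x$values)])))
    cat("note: undefined (NA) entries present\n")
  print(x$values)
  invisible(x)
}

#' Undefined (non-overlapping) pairs of a distance matrix
#' @param dm a `dist_matrix`
#' @return two-column character matrix of label pairs with undefined values
#' @export
undefined_pairs <- function(dm) {
  idx <- which(is.na(dm$values) & upper.tri(dm$values), arr.ind = TRUE)
  cbind(a = dm$labels[idx[, 1L]], b = dm$labels[idx[, 2L]])
}

#' Convert raw differences to p-distances
#'
#' Divides each raw difference count by the pairwise count of comparable
#' sites, so `p_distance * comparable_sites == raw_differences` exactly.
#' @param dm a raw-differences `dist_matrix`
#' @export
as_p_distance <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  if (dm$metric != "raw_differences") stop("input metric must be raw_differences")
  vals <- dm$values / dm$comparable_sites
  diag(vals) <- 0
  dm$values <- vals
  dm$metric <- "p_distance"
  dm
}

#' Within- and between-group distance summary
#'
#' Per group the minimum and maximum within-group distance (singletons are
#' `NA`); per group pair the minimum and maximum between-group distance.
#' Undefined pairwise values are dropped from the summaries.
#'
#' @param dm a `dist_matrix`
#' @param groups named vector mapping every matrix label to a group label
#' @return list with data frames `within` and `between`
#' @export
group_distance_summary <- function(dm, groups) {
  stopifnot(inherits(dm, "dist_matrix"))
  missing_lab <- setdiff(dm$labels, names(groups))
  if (length(missing_lab) > 0L)
    stop("labels without group assignment: ",
         paste(missing_lab, collapse = ", "))
  unknown <- setdiff(names(groups), dm$labels)
  if (length(unknown) > 0L)
    stop("unknown labels in groups: ", paste(unknown, collapse = ", "))
  g <- groups[dm$labels]
  glev <- unique(unname(g))
  pick <- function(la, lb) {
    v <- dm$values[dm$labels %in% la, dm$labels %in% lb, drop = FALSE]
    v
  }
  rng <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) c(NA_real_, NA_real_) else range(v)
  }
  within <- do.call(rbind, lapply(glev, function(gl) {
    members <- dm$labels[g == gl]
    if (length(members) < 2L) {
      data.frame(group = gl, n = length(members),
                 min = NA_real_, max = NA_real_)
    } else {
      v <- pick(members, members)
      v <- v[upper.tri(v)]
      r <- rng(v)
      data.frame(group = gl, n = length(members), min = r[1], max = r[2])
    }
  }))
  between <- NULL
  if (length(glev) >= 2L) {
    pairs <- utils::combn(glev, 2L)
    between <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- pairs[1L, k]; b <- pairs[2L, k]
      r <- rng(pick(dm$labels[g == a], dm$labels[g == b]))
      data.frame(group_a = a, group_b = b, min = r[1], max = r[2])
    }))
  } else {
    between <- data.frame(group_a = character(0), group_b = character(0),
                          min = numeric(0), max = numeric(0))
  }
  list(within = within, between = between)
}

#' Export a distance matrix as square CSV
#' @param dm a `dist_matrix`
#' @param path output path
#' @export
write_distance_csv <- function(dm, path) {
  utils::write.csv(as.data.frame(dm$values), path, row.names = TRUE)
  invisible(path)
}

#' Export a distance matrix in PHYLIP square format
#'
#' Undefined entries are written as `-1`, the conventional sentinel for
#' missing distances in square PHYLIP files.
#' @param dm a `dist_matrix`
#' @param path output path
#' @export
write_distance_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(dm$labels)
  writeLines(sprintf("%5d", n), con)
  v <- dm$values
  v[is.na(v)] <- -1
  for (i in seq_len(n)) {
    writeLines(paste0(formatC(dm$labels[i], width = -10L), " ",
                      paste(format(v[i, ], trim = TRUE), collapse = " ")),
               con)
  }
  invisible(path)
}
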