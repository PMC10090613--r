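#' Base-composition stationarity chi-square test
#'
#' Classic R x C chi-square of per-taxon A/C/G/T counts against the pooled
#' expectation, the usual pre-analysis screen for compositional
#' non-stationarity before distance or tree estimation. Only unambiguous
#' bases are counted; gaps, `N` and ambiguity codes are ignored. Following
#' the convention of phylogenetic software, the degrees of freedom are
#' `(n_taxa - 1) * 3` regardless of empty base classes (base classes with
#' zero total count contribute nothing to the statistic).
#'
#' @param aln an alignment
#' @param sites `"all"` (default) or `"variable"` — which columns to count.
#'   Implementations of this test differ; variable-sites-only is offered for
#'   comparison.
#' @return object of class `composition_test`: `statistic`, `df`, `p_value`,
#'   `per_taxon_counts` (matrix taxa x ACGT)
#' @export
composition_chi2 <- function(aln, sites = c("all", "variable")) {
  sites <- match.arg(sites)
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  if (sites == "variable") {
    keep <- apply(m, 2L, function(col) {
      b <- col[col %in% DNA_BASES]
      length(unique(b)) > 1L
    })
    m <- m[, keep, drop = FALSE]
  }
  counts <- t(apply(m, 1L, function(row) {
    tabulate(match(row, DNA_BASES, nomatch = 0L), nbins = 4L)
  }))
  colnames(counts) <- DNA_BASES
  zero <- rowSums(counts) == 0L
  if (any(zero))
    stop("taxa with no countable bases: ",
         paste(rownames(m)[zero], collapse = ", "))
  use <- colSums(counts) > 0L
  cc <- counts[, use, drop = FALSE]
  expd <- outer(rowSums(cc), colSums(cc)) / sum(cc)
  stat <- sum((cc - expd)^2 / expd)
  df <- (nrow(counts) - 1L) * 3L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 per_taxon_counts = counts),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("base-composition chi-square: X2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# Mean per-column Shannon entropy scaled to [0, 1]. Missing characters are
# dropped per column; the maximum attainable entropy is log(min(4, n_taxa)).
.entropy_index <- function(code_matrix) {
  n_taxa <- nrow(code_matrix)
  hmax <- log(min(4L, n_taxa))
  h <- apply(code_matrix, 2L, function(col) {
    col <- col[col > 0L]
    if (length(col) == 0L) return(NA_real_)
    p <- tabulate(col, nbins = 4L)
    p <- p[p > 0L] / length(col)
    -sum(p * log(p))
  })
  mean(h, na.rm = TRUE) / hmax
}

#' Randomization-based substitution-saturation assessment
#'
#' Computes an entropy-based saturation index: the mean per-site Shannon
#' entropy of alignment columns scaled by its maximum `log(min(4, n_taxa))`,
#' so an invariant alignment scores 0 and a fully randomized one scores near
#' 1. The full-saturation null is obtained by redrawing each column's states
#' i.i.d. uniformly over A/C/G/T (taxon count preserved) `n_randomizations`
#' times under the given seed. The alignment is called saturated when the
#' observed index is not significantly below that null at level `alpha`
#' (one-sided).
#'
#' This is a seeded randomization analogue of published saturation tests
#' whose critical values come from external simulation studies; the decision
#' semantics (saturated / not saturated) are preserved while remaining fully
#' reproducible offline.
#'
#' @param aln an alignment (at least 4 sequences)
#' @param n_randomizations number of null draws; fewer than 100 records a
#'   warning in the report
#' @param seed integer seed
#' @param alpha one-sided significance level (default 0.05)
#' @return object of class `saturation_report`: `iss`, `iss_null` (mean and
#'   quantiles), `saturated`, `p_value` (fraction of null at or below the
#'   observed index), `n_randomizations`, `warnings`
#' @export
saturation_index <- function(aln, n_randomizations = 200L, seed = 1L,
                             alpha = 0.05) {
  m <- aln_matrix(aln)
  if (nrow(m) < 4L) stop("need at least 4 sequences")
  warnings <- character(0)
  if (n_randomizations < 100L)
    warnings <- c(warnings,
                  sprintf("only %d randomizations; null quantiles unstable",
                          n_randomizations))
  code <- matrix(match(m, DNA_BASES, nomatch = 0L), nrow = nrow(m))
  iss <- .entropy_index(code)
  n_taxa <- nrow(code); n_sites <- ncol(code)
  set.seed(seed)
  null <- vapply(seq_len(n_randomizations), function(i) {
    .entropy_index(matrix(sample.int(4L, n_taxa * n_sites, replace = TRUE),
                          nrow = n_taxa))
  }, numeric(1))
  crit <- stats::quantile(null, alpha, names = FALSE)
  structure(list(
    iss = iss,
    iss_null = list(mean = mean(null),
                    quantiles = stats::quantile(null, c(0.005, 0.025, 0.05,
                                                        0.5, 0.95, 0.995))),
    p_value = mean(null <= iss),
    saturated = !(iss < crit),
    alpha = alpha,
    n_randomizations = as.integer(n_randomizations),
    warnings = warnings
  ), class = "saturation_report")
}

#' @export
print.saturation_report <- function(x, ...) {
  cat(sprintf("saturation index %.4f; null mean %.4f; p = %.3f; %s\n",
              x$iss, x$iss_null$mean, x$p_value,
              if (x$saturated) "SATURATED" else "not saturated"))
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Run both sequence diagnostics for a marker alignment
#'
#' Diagnostics annotate the analysis, they never block it: they provide
#' go/no-go context for including all codon positions downstream.
#' @param aln alignment
#' @param seed seed for the saturation randomization
#' @param n_randomizations randomization count
#' @return list with `composition` and `saturation`
#' @export
run_diagnostics <- function(aln, seed = 1L, n_randomizations = 200L) {
  comp <- composition_chi2(aln)
  sat <- if (length(aln$ids) >= 4L)
    saturation_index(aln, n_randomizations = n_randomizations, seed = seed)
  else NULL
  list(composition = comp, saturation = sat)
}
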