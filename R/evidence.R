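#' Construct a host-record table
#'
#' One row per taxon/host/locality combination. `host_family` is free text
#' but the families central to this workflow (Holocentridae, Muraenidae,
#' Serranidae) are used verbatim in summaries. Counts `n_infected` of
#' `n_examined` are reporting-only (never used in delimitation decisions)
#' and may be `NA` when not recorded.
#'
#' @param otu_or_taxon,host_species,host_family,locality character vectors
#' @param n_infected,n_examined integer vectors (default `NA`)
#' @return data.frame of class `host_records`
#' @export
host_records <- function(otu_or_taxon, host_species, host_family,
                         locality = NA_character_,
                         n_infected = NA_integer_, n_examined = NA_integer_) {
  df <- data.frame(otu_or_taxon = otu_or_taxon, host_species = host_species,
                   host_family = host_family, locality = locality,
                   n_infected = as.integer(n_infected),
                   n_examined = as.integer(n_examined))
  bad <- !is.na(df$n_infected) & !is.na(df$n_examined) &
    (df$n_infected < 0L | df$n_infected > df$n_examined)
  if (any(bad))
    stop("n_infected must be between 0 and n_examined (rows ",
         paste(which(bad), collapse = ", "), ")")
  class(df) <- c("host_records", "data.frame")
  df
}

#' Biological distinction from host distributions
#'
#' Two taxa are biologically "overlapping" when they share at least one
#' host family (default rule) or host species (`rule = "shared_species"`),
#' and "distinct" otherwise. The family-level default reflects how regional
#' populations of one species are lumped even when their host species
#' differ, while disjunction at family level (e.g. apogonids vs a
#' pomacentrid) counts as biological distinction. Geography is never a
#' criterion. A label with no records yields `"unknown"` with a warning.
#'
#' @param records a `host_records` table
#' @param a,b taxon/OTU labels
#' @param rule `"shared_family"` (default) or `"shared_species"`
#' @return `"overlapping"`, `"distinct"` or `"unknown"`
#' @export
assess_host_distinction <- function(records, a, b,
                                    rule = c("shared_family", "shared_species")) {
  rule <- match.arg(rule)
  col <- if (rule == "shared_family") "host_family" else "host_species"
  ra <- unique(records[[col]][records$otu_or_taxon == a])
  rb <- unique(records[[col]][records$otu_or_taxon == b])
  if (length(ra) == 0L || length(rb) == 0L) {
    missing <- c(a, b)[c(length(ra) == 0L, length(rb) == 0L)]
    warning("no host records for: ", paste(missing, collapse = ", "))
    return("unknown")
  }
  if (length(intersect(ra, rb)) > 0L) "overlapping" else "distinct"
}

#' Host-association summary through a species map
#'
#' Maps record labels (OTUs or taxa) to species and summarizes host use:
#' per species the set of host families, host species and localities, and
#' global counts of species per host family and per named host species.
#' Counts are invariant to record order and to duplicated identical
#' records.
#'
#' @param records a `host_records` table
#' @param species_map named character vector mapping every record label to
#'   a species name
#' @return list with `per_species` (data.frame), `species_per_family`,
#'   `species_per_host` (named integer vectors)
#' @export
host_association_summary <- function(records, species_map) {
  unmapped <- setdiff(unique(records$otu_or_taxon), names(species_map))
  if (length(unmapped) > 0L)
    stop("labels not in species_map: ", paste(unmapped, collapse = ", "))
  if (nrow(records) == 0L)
    return(list(per_species = data.frame(species = character(0),
                                         host_families = character(0),
                                         host_species = character(0),
                                         localities = character(0)),
                species_per_family = integer(0),
                species_per_host = integer(0)))
  sp <- unname(species_map[records$otu_or_taxon])
  per_species <- do.call(rbind, lapply(unique(sp), function(s) {
    r <- records[sp == s, , drop = FALSE]
    data.frame(
      species = s,
      host_families = paste(sort(unique(r$host_family)), collapse = ";"),
      host_species = paste(sort(unique(r$host_species)), collapse = ";"),
      localities = paste(sort(unique(stats::na.omit(r$locality))),
                         collapse = ";"))
  }))
  tally <- function(col) {
    pairs <- unique(data.frame(sp = sp, v = records[[col]]))
    sort(table(pairs$v), decreasing = TRUE)
  }
  list(per_species = per_species,
       species_per_family = c(tally("host_family")),
       species_per_host = c(tally("host_species")))
}

#' Derived morphometrics for one specimen record
#'
#' From raw measurements in micrometres derives the standard descriptive
#' ratios and relative positions: body length/width (elongation), pharynx
#' length/width, each positional landmark both in micrometres and as
#' percent of body length under its stated reference end (anterior or
#' posterior extremity), and the vitelline field length and its percent of
#' body length. For any landmark, anterior% + posterior% = 100 exactly.
#'
#' @param rec a list or one-row data.frame with at least `body_length` and
#'   `body_width`; optional fields: `pharynx_length`, `pharynx_width`,
#'   `caeca_end_from_posterior`, `testis_from_anterior`,
#'   `cirrus_sac_from_anterior`, `ovary_from_posterior`,
#'   `vitelline_start_from_anterior`, `vitelline_end_from_posterior`,
#'   `excretory_arm_tip_from_anterior` (all micrometres)
#' @return named list of derived metrics; metrics whose raw fields are
#'   missing are omitted
#' @export
derive_morphometrics <- function(rec) {
  rec <- as.list(rec)
  if (is.null(rec$body_length) || is.na(rec$body_length))
    stop("body_length is required")
  bl <- rec$body_length
  out <- list()
  has <- function(f) !is.null(rec[[f]]) && !is.na(rec[[f]])
  if (has("body_width")) out$length_width_ratio <- bl / rec$body_width
  if (has("pharynx_length") && has("pharynx_width"))
    out$pharynx_ratio <- rec$pharynx_length / rec$pharynx_width
  pos <- function(field, reference) {
    if (!has(field)) return(NULL)
    v <- rec[[field]]
    if (v > bl) stop(field, " exceeds body_length")
    pct <- 100 * v / bl
    r <- list(um = v)
    r[[paste0("pct_from_", reference)]] <- pct
    r[[paste0("pct_from_", if (reference == "anterior") "posterior" else "anterior")]] <-
      100 - pct
    r
  }
  out$caeca_end <- pos("caeca_end_from_posterior", "posterior")
  out$testis <- pos("testis_from_anterior", "anterior")
  out$cirrus_sac <- pos("cirrus_sac_from_anterior", "anterior")
  out$ovary <- pos("ovary_from_posterior", "posterior")
  out$excretory_arm_tip <- pos("excretory_arm_tip_from_anterior", "anterior")
  if (has("vitelline_start_from_anterior") &&
      has("vitelline_end_from_posterior")) {
    len <- bl - rec$vitelline_start_from_anterior -
      rec$vitelline_end_from_posterior
    if (len < 0) stop("vitelline field has negative length")
    out$vitelline_field <- list(um = len, pct_body_length = 100 * len / bl)
  }
  out[!vapply(out, is.null, logical(1))]
}

#' Host-family shape comparison
#'
#' Compares a derived metric (default the body length/width elongation
#' ratio) between specimen groups, typically host families, in the style of
#' a body-shape scatter: per group n/min/median/max, cross-group exceedance
#' counts (how many members of group A exceed the maximum of group B), a
#' rank-based two-sided test (Wilcoxon; an analytic addition to the purely
#' graphical comparison this emulates), and the underlying length-width
#' scatter data. Groups with fewer than 2 records are reported but excluded
#' from the test.
#'
#' @param recs data.frame of specimen records with columns `body_length`,
#'   `body_width` and the grouping column
#' @param group_by name of the grouping column (default `"host_family"`)
#' @param metric derived metric: `"length_width_ratio"` (default) or the
#'   name of a numeric column of `recs`
#' @return object of class `shape_comparison`: `groups` (summary
#'   data.frame), `exceedance` (matrix), `p_value`, `test`, `scatter`
#' @export
shape_comparison <- function(recs, group_by = "host_family",
                             metric = "length_width_ratio") {
  if (!group_by %in% names(recs)) stop("missing grouping column: ", group_by)
  val <- if (metric == "length_width_ratio") {
    recs$body_length / recs$body_width
  } else if (metric %in% names(recs)) {
    recs[[metric]]
  } else stop("unknown metric: ", metric)
  g <- as.character(recs[[group_by]])
  lev <- unique(g)
  if (length(lev) < 2L) stop("need at least 2 groups")
  groups <- do.call(rbind, lapply(lev, function(l) {
    v <- val[g == l]
    data.frame(group = l, n = length(v), min = min(v),
               median = stats::median(v), max = max(v))
  }))
  exceed <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (a in lev) for (b in lev) if (a != b)
    exceed[a, b] <- sum(val[g == a] > max(val[g == b]))
  testable <- groups$group[groups$n >= 2L]
  p <- NA_real_
  test <- NULL
  if (length(testable) >= 2L) {
    keep <- g %in% testable
    if (length(unique(g[keep])) == 2L) {
      test <- suppressWarnings(
        stats::wilcox.test(val[keep] ~ factor(g[keep]), exact = FALSE))
    } else {
      test <- stats::kruskal.test(val[keep], factor(g[keep]))
    }
    p <- test$p.value
  }
  structure(list(
    metric = metric, groups = groups, exceedance = exceed,
    p_value = p, test = test,
    scatter = data.frame(group = g, body_length = recs$body_length,
                         body_width = recs$body_width, value = val)
  ), class = "shape_comparison")
}

#' @export
print.shape_comparison <- function(x, ...) {
  cat("shape comparison on", x$metric, "\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf("rank-based test p = %.4g\n", x$p_value))
  invisible(x)
}

#' Scatter plot of body length vs width by group
#'
#' Base-graphics rendering of the `scatter` component of a
#' [shape_comparison()], one symbol per group.
#' @param x a `shape_comparison`
#' @param ... passed to [plot()]
#' @export
plot_shape_comparison <- function(x, ...) {
  s <- x$scatter
  gf <- factor(s$group)
  graphics::plot(s$body_length, s$body_width, pch = c(1, 19, 2, 0)[gf],
                 xlab = "body length (µm)",
                 ylab = "body width (µm)", ...)
  graphics::legend("topleft", legend = levels(gf),
                   pch = c(1, 19, 2, 0)[seq_along(levels(gf))], bty = "n")
  invisible(x)
}
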