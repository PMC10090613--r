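#' Criteria configuration for species delimitation
#'
#' @param otu_threshold integer raw-difference OTU threshold (default 10)
#' @param marker_priority markers in decreasing order of informativeness;
#'   reciprocal monophyly is assessed on the first available one (default
#'   cox1 first, mitochondrial barcodes resolving where ribosomal markers
#'   do not)
#' @param biology_rule host-distinction rule, see
#'   [assess_host_distinction()]
#' @param merge_distance_ceiling optional integer: veto merging OTUs whose
#'   within-clade raw distance exceeds this value. `NULL` (default) applies
#'   no ceiling — distance alone is deliberately not a criterion, since
#'   conspecific geographic populations can sit well above the OTU
#'   threshold.
#' @return list of class `criteria_config`
#' @export
criteria_config <- function(otu_threshold = 10L,
                            marker_priority = c("cox1", "ITS2", "28S"),
                            biology_rule = c("shared_family", "shared_species"),
                            merge_distance_ceiling = NULL) {
  biology_rule <- match.arg(biology_rule)
  if (otu_threshold < 1L) stop("otu_threshold must be >= 1")
  if (length(marker_priority) == 0L) stop("marker_priority must be non-empty")
  structure(list(otu_threshold = as.integer(otu_threshold),
                 marker_priority = marker_priority,
                 biology_rule = biology_rule,
                 merge_distance_ceiling = merge_distance_ceiling),
            class = "criteria_config")
}

#' Pairwise distinction flags
#'
#' Symmetric matrices of expert flags per OTU/taxon pair. Morphological
#' distinction is an input judgement, not computed from measurements:
#' [shape_comparison()] supports such judgements but does not replace them.
#'
#' @param labels OTU/taxon labels
#' @param morphology,biology square character matrices over `labels` with
#'   values `distinct` / `indistinguishable` / `unknown` (morphology) and
#'   `distinct` / `overlapping` / `unknown` (biology)
#' @return list of class `distinction_matrix`
#' @export
distinction_matrix <- function(labels, morphology, biology) {
  chk <- function(m, vals, what) {
    m <- as.matrix(m)
    if (!identical(dim(m), c(length(labels), length(labels))))
      stop(what, " matrix dimensions must match labels")
    dimnames(m) <- list(labels, labels)
    if (!all(m %in% vals))
      stop(what, " flags must be in {", paste(vals, collapse = ", "), "}")
    if (!identical(m, t(m))) stop(what, " matrix must be symmetric")
    m
  }
  morphology <- chk(morphology,
                    c("distinct", "indistinguishable", "unknown"),
                    "morphology")
  biology <- chk(biology, c("distinct", "overlapping", "unknown"), "biology")
  diag(morphology) <- "indistinguishable"
  diag(biology) <- "overlapping"
  structure(list(labels = labels, morphology = morphology, biology = biology),
            class = "distinction_matrix")
}

#' Assemble an evidence table for the decision engine
#'
#' Bundles everything the recognition criteria consume: the OTU labels, the
#' guide tree over OTUs built from the most informative marker, pairwise
#' distinction flags, host records, optional additional marker trees
#' (reported, never vetoing), optional morphology-only taxa, optional
#' OTU-level distances (for the optional merge ceiling), and an optional
#' `comparative` flag marking reference OTUs carried for context (archival
#' comparative material) that are delimited but reported separately from
#' the focal hypothesis set.
#'
#' @param otus character vector of OTU labels
#' @param guide_tree `phylo` whose leaf set equals `otus`
#' @param distinctions a [distinction_matrix()] covering all OTUs and
#'   morphospecies
#' @param host_records a [host_records()] table
#' @param marker_trees optional named list of additional `phylo` trees
#' @param morphospecies optional character vector of morphology-only taxa
#' @param species_names optional named character vector OTU -> species name
#' @param otu_distances optional symmetric numeric matrix over `otus`
#' @param comparative optional character vector of OTUs flagged comparative
#' @return list of class `evidence_table`
#' @export
evidence_table <- function(otus, guide_tree, distinctions, host_records,
                           marker_trees = list(), morphospecies = character(0),
                           species_names = NULL, otu_distances = NULL,
                           comparative = character(0)) {
  if (!setequal(guide_tree$tip.label, otus))
    stop("guide tree leaf set must equal the OTU set")
  need <- c(otus, morphospecies)
  if (!setequal(distinctions$labels, need))
    stop("distinction matrix must cover all OTUs and morphospecies")
  if (!all(comparative %in% otus))
    stop("comparative labels must be OTUs")
  if (!is.null(otu_distances) &&
      !setequal(rownames(otu_distances), otus))
    stop("otu_distances must be labelled by the OTU set")
  structure(list(otus = otus, guide_tree = guide_tree,
                 distinctions = distinctions, host_records = host_records,
                 marker_trees = marker_trees, morphospecies = morphospecies,
                 species_names = species_names, otu_distances = otu_distances,
                 comparative = comparative),
            class = "evidence_table")
}

# All candidate bipartition-clades of an unrooted guide tree: every side of
# every edge, plus singletons and the full leaf set.
.candidate_clades <- function(tree) {
  labs <- tree$tip.label
  sides <- list()
  pp <- ape::prop.part(tree)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    if (length(side) == length(labs)) next
    sides <- c(sides, list(side), list(setdiff(labs, side)))
  }
  sides <- c(sides, as.list(labs), list(labs))
  sides <- sides[!duplicated(vapply(sides, function(s)
    paste(sort(s), collapse = "|"), character(1)))]
  sides
}

#' Delimit species from an evidence table
#'
#' Applies criterion-based integrative species recognition: reciprocal
#' monophyly on the most informative marker (every multi-OTU species must
#' be an edge-induced clade of the guide tree) plus either morphological or
#' biological distinction between species. Concretely:
#'
#' 1. a pair of OTUs is merge-compatible iff its morphology flag is
#'    `indistinguishable` AND its biology flag is `overlapping` (`unknown`
#'    blocks merging);
#' 2. the maximal bipartition-clades of the guide tree whose members are
#'    pairwise merge-compatible become species (singletons included); these
#'    maximal clades are non-overlapping (asserted);
#' 3. with `cfg$merge_distance_ceiling` set, clades whose within-clade
#'    distance exceeds the ceiling are vetoed before maximality is taken;
#' 4. an OTU whose morphology flags are all `unknown` (no morphological
#'    specimen) becomes a `provisional_sequence_only` species;
#' 5. each morphospecies distinct from all OTUs is appended as an
#'    `unsequenced_morphospecies`;
#' 6. every hypothesis carries a justification trace against every other
#'    hypothesis: the distinguishing flag where one exists, otherwise
#'    topological separation (cryptic non-sister pair separated by another
#'    clearly distinct species).
#'
#' OTUs flagged `comparative` in the evidence table are delimited under the
#' same rules but returned in `$comparative`, keeping the focal species
#' count in `$species` aligned with the collection under study.
#'
#' @param ev an [evidence_table()]
#' @param cfg a [criteria_config()]
#' @return object of class `species_hypotheses`: `species` (list of
#'   hypotheses: `members`, `name`, `status`, `justification`),
#'   `comparative` (same structure), `config`
#' @export
delimit_species <- function(ev, cfg = criteria_config()) {
  stopifnot(inherits(ev, "evidence_table"), inherits(cfg, "criteria_config"))
  otus <- ev$otus
  morph <- ev$distinctions$morphology
  biol <- ev$distinctions$biology
  compat <- morph[otus, otus, drop = FALSE] == "indistinguishable" &
    biol[otus, otus, drop = FALSE] == "overlapping"
  diag(compat) <- TRUE

  cands <- .candidate_clades(ev$guide_tree)
  ok <- vapply(cands, function(s) all(compat[s, s]), logical(1))
  if (!is.null(cfg$merge_distance_ceiling) && !is.null(ev$otu_distances)) {
    ok <- ok & vapply(cands, function(s) {
      if (length(s) < 2L) return(TRUE)
      v <- ev$otu_distances[s, s]
      max(v[upper.tri(v)], na.rm = TRUE) <= cfg$merge_distance_ceiling
    }, logical(1))
  }
  cands <- cands[ok]
  # maximal by inclusion
  maximal <- cands[vapply(seq_along(cands), function(i) {
    !any(vapply(cands, function(o)
      length(o) > length(cands[[i]]) && all(cands[[i]] %in% o), logical(1)))
  }, logical(1))]
  # laminarity check: maximal merge-compatible clades must not overlap
  cover <- unlist(maximal)
  if (anyDuplicated(cover))
    stop("internal error: maximal merge-compatible clades overlap")
  stopifnot(setequal(cover, otus))

  morph_unknown <- vapply(otus, function(o)
    all(morph[o, setdiff(c(otus, ev$morphospecies), o)] == "unknown"),
    logical(1))

  mk_hypothesis <- function(members) {
    nm <- NULL
    if (!is.null(ev$species_names)) {
      nms <- unique(stats::na.omit(ev$species_names[members]))
      if (length(nms) == 1L) nm <- unname(nms)
      if (length(nms) > 1L)
        stop("members of one species map to several names: ",
             paste(nms, collapse = ", "))
    }
    status <- if (length(members) >= 1L && all(morph_unknown[members]))
      "provisional_sequence_only" else "named"
    list(members = sort(members), name = nm, status = status,
         justification = list())
  }
  hyps <- lapply(maximal, mk_hypothesis)
  for (ms in ev$morphospecies) {
    others <- c(otus, setdiff(ev$morphospecies, ms))
    # appended when no OTU is morphologically indistinguishable from it; an
    # unknown flag (e.g. vs a sequence-only OTU) does not block the
    # morphospecies, it only blocks merging elsewhere
    if (any(morph[ms, others] == "indistinguishable")) {
      warning("morphospecies ", ms,
              " is indistinguishable from a sequenced OTU; not appended")
      next
    }
    hyps <- c(hyps, list(list(members = character(0), name = ms,
                              status = "unsequenced_morphospecies",
                              justification = list())))
  }
  label_of <- function(h) {
    if (!is.null(h$name)) h$name
    else if (length(h$members) > 0L) paste(h$members, collapse = "+")
    else "morphospecies"
  }
  names(hyps) <- vapply(hyps, label_of, character(1))

  # justification traces between every hypothesis pair
  flag_between <- function(ha, hb, mat) {
    la <- if (length(ha$members)) ha$members else ha$name
    lb <- if (length(hb$members)) hb$members else hb$name
    f <- mat[la, lb, drop = FALSE]
    # the pairwise flags between two recognized species should agree; report
    # the dominant one (distinct wins over unknown wins over compatible)
    if (any(f == "distinct")) "distinct"
    else if (any(f == "unknown")) "unknown"
    else f[1L]
  }
  n_h <- length(hyps)
  for (i in seq_len(n_h)) {
    for (j in seq_len(n_h)) {
      if (i == j) next
      ha <- hyps[[i]]; hb <- hyps[[j]]
      mf <- flag_between(ha, hb, morph)
      bf <- flag_between(ha, hb, biol)
      crit <- if (mf == "distinct" && bf == "distinct")
        "morphology and biology"
      else if (mf == "distinct") "morphology"
      else if (bf == "distinct") "biology"
      else if (mf == "unknown" || bf == "unknown") "insufficient evidence"
      else "topology"
      note <- switch(
        crit,
        "topology" = paste0(
          "morphologically indistinguishable with overlapping hosts, but no ",
          "guide-tree clade contains both without a clearly distinct species: ",
          "separated by topology (non-sister cryptic pair)"),
        "insufficient evidence" = paste0(
          "distinction flags unknown (e.g. no morphological specimen); ",
          "kept separate, not merged"),
        paste0("separated by ", crit, " (morphology: ", mf,
               "; biology: ", bf, ")"))
      hyps[[i]]$justification[[label_of(hb)]] <-
        list(against = label_of(hb), criterion = crit, note = note)
    }
  }

  is_comp <- vapply(hyps, function(h)
    length(h$members) > 0L && all(h$members %in% ev$comparative), logical(1))
  structure(list(species = hyps[!is_comp], comparative = hyps[is_comp],
                 config = cfg, guide_tree = ev$guide_tree),
            class = "species_hypotheses")
}

#' @export
print.species_hypotheses <- function(x, ...) {
  cat(sprintf("<species_hypotheses> %d species", length(x$species)))
  if (length(x$comparative) > 0L)
    cat(sprintf(" (+%d comparative)", length(x$comparative)))
  cat("\n")
  for (h in x$species) {
    cat(sprintf("- %s [%s]%s\n",
                if (!is.null(h$name)) h$name else paste(h$members, collapse = "+"),
                h$status,
                if (length(h$members)) paste0(" members: ",
                                              paste(h$members, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' Explain how two species hypotheses are separated
#'
#' Human-readable trace: the guide-tree relationship of the two hypotheses,
#' the flags consulted, and the criterion that separated them.
#'
#' @param result a `species_hypotheses`
#' @param a,b names (or member-label strings) of two distinct hypotheses
#' @return character trace (invisibly printed)
#' @export
explain_decision <- function(result, a, b) {
  all_h <- c(result$species, result$comparative)
  find <- function(lbl) {
    if (lbl %in% names(all_h)) return(all_h[[lbl]])
    hit <- which(vapply(all_h, function(h)
      identical(h$name, lbl) || lbl %in% h$members, logical(1)))
    if (length(hit) == 0L) stop("no hypothesis matching: ", lbl)
    all_h[[hit[[1L]]]]
  }
  ha <- find(a); hb <- find(b)
  if (identical(ha, hb)) stop("requested hypotheses are identical: ", a)
  key <- if (!is.null(hb$name)) hb$name else paste(hb$members, collapse = "+")
  j <- ha$justification[[key]]
  if (is.null(j)) {
    # fall back: match by hypothesis content
    idx <- which(vapply(ha$justification, function(x)
      identical(x$against, key), logical(1)))
    j <- if (length(idx)) ha$justification[[idx[[1L]]]] else NULL
  }
  rel <- if (length(ha$members) && length(hb$members)) {
    sis <- tryCatch(
      reciprocal_monophyly(result$guide_tree, ha$members, hb$members) &&
        is_bipartition_clade(result$guide_tree,
                             c(ha$members, hb$members)),
      error = function(e) NA)
    if (isTRUE(sis)) "sister clades on the guide tree"
    else "non-sister on the guide tree"
  } else "at least one hypothesis lacks sequence data (no tree placement)"
  txt <- paste0(
    "hypotheses: ",
    if (!is.null(ha$name)) ha$name else paste(ha$members, collapse = "+"),
    " vs ", key, "\n",
    "guide tree: ", rel, "\n",
    "criterion: ", if (!is.null(j)) j$criterion else "n/a", "\n",
    "trace: ", if (!is.null(j)) j$note else "no recorded trace")
  cat(txt, "\n")
  invisible(txt)
}
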