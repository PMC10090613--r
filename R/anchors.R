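#' Verify published raw-difference anchors against deposited sequences
#'
#' Recomputes, from locally stored aligned FASTA files of the deposited
#' GenBank sequences, the raw-difference values printed in the source
#' study and compares them with the anchors embedded in
#' [bivesicula_evidence()]:
#'
#' * cox1 *B. neglecta* (OM456635) vs *B. unexpecta* (OM456679): 35
#'   differences;
#' * ITS2 for the same pair (OM523336 vs OM523355): 1 difference;
#' * within-*B. sheni* cox1 maximum over OM456662-77: at most 4;
#' * single-linkage OTU count at threshold 10 over all deposited cox1
#'   accessions (sensitive to the deposited subset: not all analysed
#'   sequences were submitted).
#'
#' Sequence download and alignment happen outside this function (see the
#' repository's `scripts/fetch_genbank.R`); inputs must be pre-aligned,
#' with ids beginning with the accession.
#'
#' @param cox1_path aligned cox1 FASTA of deposited accessions
#' @param its2_path optional aligned ITS2 FASTA
#' @param threshold OTU threshold (default 10)
#' @return data.frame with columns `check`, `value`, `reference`, `pass`
#'   (`reference` `NA` where the study prints no single value)
#' @export
verify_published_anchors <- function(cox1_path, its2_path = NULL,
                                     threshold = 10L) {
  anchors <- bivesicula_evidence()$anchors
  out <- list()
  find_id <- function(aln, acc) {
    hit <- grep(paste0("^", acc), aln$ids, value = TRUE)
    if (length(hit) != 1L)
      stop("accession ", acc, " not found uniquely in alignment")
    hit
  }
  aln <- read_fasta(cox1_path, marker = "cox1")
  dm <- pairwise_differences(aln)
  a <- find_id(aln, "OM456635"); b <- find_id(aln, "OM456679")
  out$cox1_neglecta_unexpecta <- list(
    value = dm$values[a, b], reference = anchors$cox1_neglecta_unexpecta,
    cmp = "eq")
  sheni <- unlist(lapply(sprintf("OM4566%02d", 62:77), function(acc)
    grep(paste0("^", acc), aln$ids, value = TRUE)))
  if (length(sheni) >= 2L) {
    v <- dm$values[sheni, sheni]
    out$cox1_sheni_within_max <- list(
      value = max(v[upper.tri(v)], na.rm = TRUE),
      reference = anchors$cox1_sheni_within_max, cmp = "le")
  }
  out$cox1_otu_count <- list(
    value = cluster_otus(dm, threshold = threshold)$n_otus,
    reference = NA_real_, cmp = "none")
  if (!is.null(its2_path)) {
    it <- read_fasta(its2_path, marker = "ITS2")
    dmi <- pairwise_differences(it)
    ia <- find_id(it, "OM523336"); ib <- find_id(it, "OM523355")
    out$its2_neglecta_unexpecta <- list(
      value = dmi$values[ia, ib], reference = anchors$its2_neglecta_unexpecta,
      cmp = "eq")
  }
  data.frame(
    check = names(out),
    value = vapply(out, function(x) as.numeric(x$value), numeric(1)),
    reference = vapply(out, function(x) as.numeric(x$reference), numeric(1)),
    pass = vapply(out, function(x) switch(
      x$cmp,
      eq = as.numeric(x$value) == as.numeric(x$reference),
      le = as.numeric(x$value) <= as.numeric(x$reference),
      NA), logical(1)),
    row.names = NULL)
}
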