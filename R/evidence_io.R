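#' Read and write evidence tables as JSON
#'
#' The JSON schema mirrors [evidence_table()]: `otus` (array),
#' `guide_tree` (newick string), `morphology` / `biology` (square arrays of
#' flags, row-major, ordered like `labels = c(otus, morphospecies)`),
#' `host_records` (array of objects with the [host_records()] columns),
#' `morphospecies`, `species_names` (object, label -> name),
#' `comparative` (array), optional `otu_distances` (square array).
#'
#' @param ev an `evidence_table`
#' @param path file path
#' @return `read_evidence_json()` returns an `evidence_table`;
#'   `write_evidence_json()` returns `path` invisibly.
#' @export
write_evidence_json <- function(ev, path) {
  stopifnot(inherits(ev, "evidence_table"))
  hr <- ev$host_records
  obj <- list(
    otus = ev$otus,
    guide_tree = write_newick(ev$guide_tree),
    labels = ev$distinctions$labels,
    morphology = unname(ev$distinctions$morphology),
    biology = unname(ev$distinctions$biology),
    host_records = hr,
    morphospecies = ev$morphospecies,
    species_names = as.list(ev$species_names),
    comparative = ev$comparative,
    otu_distances = if (!is.null(ev$otu_distances))
      unname(ev$otu_distances))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_evidence_json
#' @export
read_evidence_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- obj$labels
  morph <- as.matrix(obj$morphology); dimnames(morph) <- list(labels, labels)
  biol <- as.matrix(obj$biology); dimnames(biol) <- list(labels, labels)
  hrdf <- obj$host_records
  hr <- host_records(hrdf$otu_or_taxon, hrdf$host_species, hrdf$host_family,
                     hrdf$locality, hrdf$n_infected, hrdf$n_examined)
  sn <- unlist(obj$species_names)
  morphosp <- if (length(obj$morphospecies)) obj$morphospecies else character(0)
  comp <- if (length(obj$comparative)) obj$comparative else character(0)
  od <- NULL
  if (!is.null(obj$otu_distances)) {
    od <- as.matrix(obj$otu_distances)
    dimnames(od) <- list(obj$otus, obj$otus)
  }
  evidence_table(
    otus = obj$otus,
    guide_tree = parse_newick(obj$guide_tree),
    distinctions = distinction_matrix(labels, morph, biol),
    host_records = hr,
    morphospecies = morphosp,
    species_names = sn,
    otu_distances = od,
    comparative = comp)
}
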