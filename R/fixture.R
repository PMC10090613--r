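#' Worked bivesiculid evidence fixture
#'
#' A fully encoded evidence set for species of *Bivesicula* (Trematoda:
#' Bivesiculidae) from Indo-Pacific holocentrid, muraenid and serranid
#' fishes: 15 cox1 OTUs in three deeply separated clades, the unrooted
#' cox1 guide-tree topology over OTUs, pairwise morphological-distinction
#' flags, host and locality records with prevalences, the morphology-only
#' species *B. nana*, and published raw-difference anchors for
#' cross-checking. Two Clade 3 OTUs (*B. neglecta*, *B. unexpecta*) derive
#' from archival comparative material and are flagged `comparative`; their
#' hosts (apogonids and a pomacentrid) fall outside the focal collection.
#'
#' OTU-to-species assignments follow the species accounts. Within the pairs
#' OTU08/OTU09 and OTU14/OTU15 the numeric labels are arbitrary (the source
#' does not print them): OTU08 = *B. cephalopholicola*, OTU09 = the Bali
#' form (sequence only, no morphological specimen), OTU14 = *B. neglecta*,
#' OTU15 = *B. unexpecta*.
#'
#' The construction is pure: repeated calls return identical objects.
#'
#' @return list of class `bivesicula_fixture`: `evidence` (an
#'   [evidence_table()]), `clades` (named OTU -> clade vector),
#'   `species_names`, `anchors` (published raw-difference values for
#'   verification)
#' @examples
#' fx <- bivesicula_evidence()
#' length(fx$evidence$otus)
#' @export
bivesicula_evidence <- function() {
  otus <- sprintf("OTU%02d", 1:15)
  nana <- "Bivesicula nana"
  species_names <- stats::setNames(c(
    "Bivesicula sheni",              # OTU01
    "Bivesicula obovata",            # OTU02
    "Bivesicula polynesiensis",      # OTU03
    rep("Bivesicula claviformis", 4),# OTU04-07 regional populations
    "Bivesicula cephalopholicola",   # OTU08
    NA,                              # OTU09 Bali form, sequence only
    "Bivesicula novaecaledoniensis", # OTU10
    "Bivesicula palauensis",         # OTU11
    rep("Bivesicula gymnothoracis", 2), # OTU12-13 regional populations
    "Bivesicula neglecta",           # OTU14 (comparative)
    "Bivesicula unexpecta"           # OTU15 (comparative)
  ), otus)
  clades <- stats::setNames(
    c(rep("Clade 1", 9), rep("Clade 2", 4), rep("Clade 3", 2)), otus)

  # cox1 guide tree over OTUs: cephalopholicola and the Bali form basal in
  # Clade 1; sheni sister to obovata; that pair sister to the claviformis
  # population clade; polynesiensis sister to the whole assemblage;
  # novaecaledoniensis sister to palauensis; the gymnothoracis populations
  # a clade; Clade 3 an isolated pair.
  guide_tree <- ape::read.tree(text = paste0(
    "((OTU09,(OTU08,(OTU03,((OTU01,OTU02),",
    "(OTU04,((OTU05,OTU06),OTU07)))))),",
    "((OTU10,OTU11),(OTU12,OTU13)),(OTU14,OTU15));"))

  labels <- c(otus, nana)
  n <- length(labels)
  morph <- matrix("distinct", n, n, dimnames = list(labels, labels))
  set_flag <- function(m, a, b, val) {
    m[a, b] <- val; m[b, a] <- val; m
  }
  # the claviformis-like cryptic complex: sheni, polynesiensis and the
  # claviformis populations are morphologically indistinguishable
  cryptic1 <- c("OTU01", "OTU03", "OTU04", "OTU05", "OTU06", "OTU07")
  morph[cryptic1, cryptic1] <- "indistinguishable"
  # novaecaledoniensis is cryptic relative to gymnothoracis; the two
  # gymnothoracis populations are one morphotype
  cryptic2 <- c("OTU10", "OTU12", "OTU13")
  morph[cryptic2, cryptic2] <- "indistinguishable"
  # the Bali form has no morphological specimen
  morph["OTU09", ] <- "unknown"
  morph[, "OTU09"] <- "unknown"
  diag(morph) <- "indistinguishable"

  H <- "Holocentridae"; S <- "Serranidae"; M <- "Muraenidae"
  rec <- function(otu, sp, fam, loc, inf = NA, exam = NA)
    data.frame(otu_or_taxon = otu, host_species = sp, host_family = fam,
               locality = loc, n_infected = as.integer(inf),
               n_examined = as.integer(exam))
  hr <- do.call(rbind, list(
    # B. sheni (OTU01), GBR; infected = sequenced + morphology-only
    rec("OTU01", "Sargocentron rubrum", H, "Heron Is.", 1, 27),
    rec("OTU01", "Sargocentron caudimaculatum", H, "Lizard Is.", 4, 6),
    rec("OTU01", "Sargocentron spiniferum", H, "Lizard Is.", 9, 21),
    rec("OTU01", "Epinephelus cyanopodus", S, "Heron Is.", 1, 9),
    rec("OTU01", "Epinephelus cyanopodus", S, "Lizard Is.", 3, 4),
    rec("OTU01", "Epinephelus fasciatus", S, "Heron Is.", 9, 63),
    rec("OTU01", "Epinephelus fasciatus", S, "Lizard Is.", 3, 4),
    rec("OTU01", "Epinephelus maculatus", S, "Lizard Is.", 4, 10),
    rec("OTU01", "Epinephelus merra", S, "Lizard Is.", 5, 20),
    rec("OTU01", "Epinephelus ongus", S, "Lizard Is.", 1, 3),
    rec("OTU01", "Epinephelus quoyanus", S, "Heron Is.", 3, 74),
    rec("OTU01", "Epinephelus quoyanus", S, "Lizard Is.", 6, 20),
    rec("OTU01", "Epinephelus undulatostriatus", S, "Heron Is.", 2, 4),
    # B. obovata (OTU02), Heron Is.
    rec("OTU02", "Sargocentron rubrum", H, "Heron Is.", 1, 27),
    rec("OTU02", "Epinephelus fasciatus", S, "Heron Is.", 1, 63),
    rec("OTU02", "Epinephelus quoyanus", S, "Heron Is.", 1, 74),
    rec("OTU02", "Epinephelus undulatostriatus", S, "Heron Is.", 1, 3),
    # B. polynesiensis (OTU03), French Polynesia
    rec("OTU03", "Neoniphon sammara", H, "Gambier Archipelago", 1, 1),
    rec("OTU03", "Sargocentron diadema", H, "Gambier Archipelago", 1, 1),
    rec("OTU03", "Sargocentron spiniferum", H, "Gambier Archipelago", 1, 2),
    rec("OTU03", "Sargocentron microstoma", H, "Society Archipelago", 1, 6),
    rec("OTU03", "Sargocentron caudimaculatum", H, "Society Archipelago", 1, 12),
    rec("OTU03", "Epinephelus fasciatus", S, "Australs Archipelago", 1, 1),
    rec("OTU03", "Cephalopholis urodeta", S, "Society Archipelago", 1, 4),
    # B. claviformis populations: OTU04 Okinawa, OTU05-06 Ningaloo,
    # OTU07 Lizard Is.
    rec("OTU04", "Cephalopholis argus", S, "Okinawa", 1, 1),
    rec("OTU04", "Epinephelus fasciatus", S, "Okinawa", 3, 5),
    rec("OTU04", "Epinephelus merra", S, "Okinawa", 1, 3),
    rec("OTU05", "Epinephelus fasciatus", S, "Ningaloo Reef", 5, 8),
    rec("OTU05", "Epinephelus tauvina", S, "Ningaloo Reef", 1, 3),
    rec("OTU06", "Epinephelus fasciatus", S, "Ningaloo Reef", 5, 8),
    rec("OTU07", "Epinephelus merra", S, "Lizard Is.", 1, 20),
    rec("OTU07", "Sargocentron caudimaculatum", H, "Lizard Is.", 1, 6),
    rec("OTU07", "Sargocentron spiniferum", H, "Lizard Is.", 1, 21),
    # B. cephalopholicola (OTU08), Cephalopholis only
    rec("OTU08", "Cephalopholis boenak", S, "Lizard Is.", 2, 12),
    rec("OTU08", "Cephalopholis boenak", S, "New Caledonia", 3, 18),
    rec("OTU08", "Cephalopholis cyanostigma", S, "Lizard Is.", 2, 54),
    rec("OTU08", "Cephalopholis microprion", S, "Lizard Is.", 8, 9),
    # Bali form (OTU09), single sequence
    rec("OTU09", "Epinephelus fasciatus", S, "Bali", 1, NA),
    # B. novaecaledoniensis (OTU10)
    rec("OTU10", "Epinephelus chlorostigma", S, "New Caledonia", 3, 3),
    rec("OTU10", "Epinephelus fasciatus", S, "New Caledonia", 3, 61),
    # B. palauensis (OTU11)
    rec("OTU11", "Epinephelus areolatus", S, "Okinawa", 1, 1),
    rec("OTU11", "Variola albimarginata", S, "Okinawa", 1, 2),
    rec("OTU11", "Epinephelus morrhua", S, "New Caledonia", 1, 4),
    # B. gymnothoracis populations: OTU12 Okinawa, OTU13 Minabe
    rec("OTU12", "Epinephelus fasciatus", S, "Okinawa", 3, 5),
    rec("OTU13", "Gymnothorax kidako", M, "Minabe", 2, 4),
    rec("OTU13", "Epinephelus fasciatus", S, "Minabe", 3, 3),
    # comparative Clade 3 species: non-overlapping host families
    rec("OTU14", "Apogonidae sp.", "Apogonidae", NA),
    rec("OTU15", "Pomacentridae sp.", "Pomacentridae", NA),
    # B. nana, morphology only
    rec(nana, "Epinephelus maculatus", S, "Lizard Is.", 1, 10)
  ))
  hr <- host_records(hr$otu_or_taxon, hr$host_species, hr$host_family,
                     hr$locality, hr$n_infected, hr$n_examined)

  # biology flags derived from the host records under the family rule
  biol <- matrix("overlapping", n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      f <- assess_host_distinction(hr, labels[i], labels[j],
                                   rule = "shared_family")
      biol[i, j] <- biol[j, i] <- if (f == "overlapping") "overlapping"
      else if (f == "distinct") "distinct" else "unknown"
    }
  }
  dist_flags <- distinction_matrix(labels, morph, biol)

  ev <- evidence_table(
    otus = otus, guide_tree = guide_tree, distinctions = dist_flags,
    host_records = hr, morphospecies = nana,
    species_names = species_names,
    comparative = c("OTU14", "OTU15"))

  # published raw-difference anchors (alignment: cox1 474, ITS2 453 columns)
  anchors <- list(
    cox1_neglecta_unexpecta = 35,
    its2_neglecta_unexpecta = 1,
    cox1_sheni_within_max = 4,
    cox1_claviformis_populations_range = c(17, 23),
    cox1_clade1_species_min = 21,
    cox1_gymnothoracis_novaecaledoniensis_range = c(81, 85),
    cox1_alignment_length = 474,
    its2_alignment_length = 453)

  structure(list(evidence = ev, clades = clades,
                 species_names = species_names, anchors = anchors),
            class = "bivesicula_fixture")
}

#' Species map from a delimitation result
#'
#' Maps every member OTU of every hypothesis (and every morphospecies,
#' mapped to itself) to the hypothesis label, for use with
#' [host_association_summary()].
#'
#' @param result a `species_hypotheses`
#' @param include_comparative also map comparative hypotheses' members
#' @return named character vector label -> species
#' @export
species_map_from_hypotheses <- function(result, include_comparative = TRUE) {
  hyps <- result$species
  if (include_comparative) hyps <- c(hyps, result$comparative)
  out <- character(0)
  for (i in seq_along(hyps)) {
    h <- hyps[[i]]
    lbl <- names(hyps)[i]
    if (length(h$members) > 0L)
      out[h$members] <- lbl
    else
      out[lbl] <- lbl
  }
  out
}
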