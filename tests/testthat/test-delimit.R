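# small helper: evidence table for toy OTU sets
toy_evidence <- function(newick, morph_pairs = list(), biol_records,
                         otus = NULL, ...) {
  tree <- parse_newick(newick)
  if (is.null(otus)) otus <- sort(tree$tip.label)
  n <- length(otus)
  morph <- matrix("indistinguishable", n, n, dimnames = list(otus, otus))
  for (p in morph_pairs) {
    morph[p[1], p[2]] <- morph[p[2], p[1]] <- p[3]
  }
  biol <- matrix("overlapping", n, n, dimnames = list(otus, otus))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    f <- assess_host_distinction(biol_records, otus[i], otus[j])
    biol[i, j] <- biol[j, i] <- f
  }
  dist_flags <- distinction_matrix(otus, morph, biol)
  evidence_table(otus = otus, guide_tree = tree, distinctions = dist_flags,
                 host_records = biol_records, ...)
}

serranid_records <- function(otus) {
  host_records(otus, rep("Epinephelus fasciatus", length(otus)),
               rep("Serranidae", length(otus)))
}

test_that("the bivesiculid fixture yields the published species hypothesis", {
  fx <- bivesicula_evidence()
  res <- delimit_species(fx$evidence)
  expect_length(res$species, 10L)
  # the four claviformis population OTUs merge into one species
  clav <- res$species[["Bivesicula claviformis"]]
  expect_equal(clav$members, sprintf("OTU%02d", 4:7))
  # the two gymnothoracis populations merge
  expect_equal(res$species[["Bivesicula gymnothoracis"]]$members,
               c("OTU12", "OTU13"))
  # the Bali form stays a provisional sequence-only species
  expect_equal(res$species[["OTU09"]]$status, "provisional_sequence_only")
  # one unsequenced morphospecies
  statuses <- vapply(res$species, `[[`, character(1), "status")
  expect_equal(sum(statuses == "unsequenced_morphospecies"), 1L)
  expect_equal(res$species[["Bivesicula nana"]]$status,
               "unsequenced_morphospecies")
  # every multi-OTU species is a clade of the guide tree
  for (h in res$species)
    if (length(h$members) > 1L)
      expect_true(is_bipartition_clade(fx$evidence$guide_tree, h$members))
  # the two comparative species are delimited but kept apart
  expect_length(res$comparative, 2L)
  expect_setequal(names(res$comparative),
                  c("Bivesicula neglecta", "Bivesicula unexpecta"))
})

test_that("cryptic non-sister species separated by a distinct species stay split", {
  # claviformis-lump, sheni and obovata: topology (clav,(sheni,obovata));
  # sheni/claviformis indistinguishable and host-overlapping, obovata
  # distinct from both
  recs <- serranid_records(c("clav", "sheni", "obov"))
  ev <- toy_evidence("(clav,(sheni,obov),out);",
                     morph_pairs = list(c("clav", "obov", "distinct"),
                                        c("sheni", "obov", "distinct"),
                                        c("out", "clav", "distinct"),
                                        c("out", "sheni", "distinct"),
                                        c("out", "obov", "distinct")),
                     biol_records = host_records(
                       c("clav", "sheni", "obov", "out"),
                       rep("Epinephelus fasciatus", 4),
                       rep("Serranidae", 4)))
  res <- delimit_species(ev)
  expect_length(res$species, 4L)
  members <- lapply(res$species, `[[`, "members")
  expect_true(list(c("clav")) %in% members || "clav" %in% unlist(members))
  expect_false(any(vapply(members, function(m)
    all(c("clav", "sheni") %in% m), logical(1))))
  tr <- explain_decision(res, "clav", "sheni")
  expect_match(tr, "topology")
})

test_that("sister OTUs merge or split according to the distinction flags", {
  # indistinguishable morphology + overlapping hosts: forced merge
  ev1 <- toy_evidence("((x,y),(z,w));",
                      morph_pairs = list(c("x", "z", "distinct"),
                                         c("x", "w", "distinct"),
                                         c("y", "z", "distinct"),
                                         c("y", "w", "distinct"),
                                         c("z", "w", "distinct")),
                      biol_records = serranid_records(c("x", "y", "z", "w")))
  res1 <- delimit_species(ev1)
  members1 <- lapply(res1$species, `[[`, "members")
  expect_true(any(vapply(members1, function(m)
    setequal(m, c("x", "y")), logical(1))))

  # same topology but disjoint host families: biology splits the sisters
  recs2 <- host_records(c("x", "y", "z", "w"),
                        c("Apogon sp.", "Pomacentrus sp.", "E1", "E2"),
                        c("Apogonidae", "Pomacentridae",
                          "Serranidae", "Serranidae"))
  ev2 <- toy_evidence("((x,y),(z,w));",
                      morph_pairs = list(c("x", "z", "distinct"),
                                         c("x", "w", "distinct"),
                                         c("y", "z", "distinct"),
                                         c("y", "w", "distinct"),
                                         c("z", "w", "distinct")),
                      biol_records = recs2)
  res2 <- delimit_species(ev2)
  members2 <- lapply(res2$species, `[[`, "members")
  expect_false(any(vapply(members2, function(m)
    setequal(m, c("x", "y")), logical(1))))
  tr <- explain_decision(res2, "x", "y")
  expect_match(tr, "biology")
})

test_that("unknown flags block merging", {
  ev <- toy_evidence("((x,y),z,o);",
                     morph_pairs = list(c("x", "y", "unknown"),
                                        c("x", "z", "distinct"),
                                        c("y", "z", "distinct"),
                                        c("o", "x", "distinct"),
                                        c("o", "y", "distinct"),
                                        c("o", "z", "distinct")),
                     biol_records = serranid_records(c("x", "y", "z", "o")))
  res <- delimit_species(ev)
  members <- lapply(res$species, `[[`, "members")
  expect_false(any(vapply(members, function(m)
    setequal(m, c("x", "y")), logical(1))))
})

test_that("the merge distance ceiling vetoes deep merges when enabled", {
  otus <- c("x", "y", "z")
  d <- matrix(c(0, 30, 60, 30, 0, 60, 60, 60, 0), 3, 3,
              dimnames = list(otus, otus))
  ev <- toy_evidence("((x,y),z,o);", otus = c("o", otus),
                     morph_pairs = list(c("x", "z", "distinct"),
                                        c("y", "z", "distinct"),
                                        c("o", "x", "distinct"),
                                        c("o", "y", "distinct"),
                                        c("o", "z", "distinct")),
                     biol_records = serranid_records(c("x", "y", "z", "o")))
  ev$otu_distances <- rbind(cbind(d, o = 90), o = c(90, 90, 90, 0))
  dimnames(ev$otu_distances) <- list(c(otus, "o"), c(otus, "o"))
  merged <- delimit_species(ev, criteria_config())
  expect_true(any(vapply(merged$species, function(h)
    setequal(h$members, c("x", "y")), logical(1))))
  vetoed <- delimit_species(ev, criteria_config(merge_distance_ceiling = 20))
  expect_false(any(vapply(vetoed$species, function(h)
    setequal(h$members, c("x", "y")), logical(1))))
})

test_that("the OTU partition is invariant to input order", {
  fx <- bivesicula_evidence()
  res <- delimit_species(fx$evidence)
  base <- sort(vapply(res$species, function(h)
    paste(sort(h$members), collapse = "+"), character(1)))
  withr::local_seed(10)
  for (rep in 1:5) {
    ev <- fx$evidence
    perm <- sample(ev$otus)
    ev$otus <- perm
    res2 <- delimit_species(ev)
    got <- sort(vapply(res2$species, function(h)
      paste(sort(h$members), collapse = "+"), character(1)))
    expect_equal(got, base)
  }
})

test_that("flipping a flag to distinct never decreases the species count", {
  fx <- bivesicula_evidence()
  base_n <- length(delimit_species(fx$evidence)$species)
  otus <- fx$evidence$otus
  withr::local_seed(2)
  pairs <- utils::combn(otus, 2)
  for (k in sample(ncol(pairs), 12)) {
    ev <- fx$evidence
    a <- pairs[1, k]; b <- pairs[2, k]
    if (ev$distinctions$morphology[a, b] != "indistinguishable") next
    ev$distinctions$morphology[a, b] <- "distinct"
    ev$distinctions$morphology[b, a] <- "distinct"
    expect_gte(length(delimit_species(ev)$species), base_n)
  }
})

test_that("decision traces name the separating criterion", {
  fx <- bivesicula_evidence()
  res <- delimit_species(fx$evidence)
  # cryptic pair distinguished only by sequence data and topology
  tr1 <- explain_decision(res, "Bivesicula sheni", "Bivesicula claviformis")
  expect_match(tr1, "topology")
  expect_match(tr1, "non-sister")
  # clearly distinct pair: morphology and host families both separate them
  tr2 <- explain_decision(res, "Bivesicula neglecta", "Bivesicula unexpecta")
  expect_match(tr2, "morphology and biology")
  expect_error(explain_decision(res, "Bivesicula sheni", "Bivesicula sheni"),
               "identical")
  expect_error(explain_decision(res, "Bivesicula sheni", "no such species"),
               "no hypothesis")
})

test_that("evidence tables round-trip through the JSON schema", {
  fx <- bivesicula_evidence()
  f <- withr::local_tempfile(fileext = ".json")
  write_evidence_json(fx$evidence, f)
  back <- read_evidence_json(f)
  expect_equal(back$otus, fx$evidence$otus)
  expect_equal(back$distinctions$morphology, fx$evidence$distinctions$morphology)
  expect_equal(back$distinctions$biology, fx$evidence$distinctions$biology)
  expect_equal(back$morphospecies, fx$evidence$morphospecies)
  expect_equal(back$comparative, fx$evidence$comparative)
  expect_equal(as.numeric(ape::dist.topo(back$guide_tree,
                                         fx$evidence$guide_tree)), 0)
  # and the reloaded evidence delimits identically
  r1 <- delimit_species(fx$evidence)
  r2 <- delimit_species(back)
  expect_equal(names(r1$species), names(r2$species))
  expect_equal(lapply(r1$species, `[[`, "members"),
               lapply(r2$species, `[[`, "members"))
})
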