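test_that("host distinction follows the family and species rules", {
  hr <- host_records(
    otu_or_taxon = c("A", "B", "B", "C", "D", "E", "F"),
    host_species = c("Epinephelus fasciatus", "Epinephelus merra",
                     "Sargocentron rubrum", "Apogonidae sp.",
                     "Pomacentridae sp.", "Epinephelus fasciatus",
                     "Epinephelus merra"),
    host_family = c("Serranidae", "Serranidae", "Holocentridae",
                    "Apogonidae", "Pomacentridae", "Serranidae",
                    "Serranidae"))
  expect_equal(assess_host_distinction(hr, "A", "B"), "overlapping")
  expect_equal(assess_host_distinction(hr, "C", "D"), "distinct")
  # same family, different host species: rules diverge
  expect_equal(assess_host_distinction(hr, "E", "F"), "overlapping")
  expect_equal(assess_host_distinction(hr, "E", "F", rule = "shared_species"),
               "distinct")
  expect_warning(f <- assess_host_distinction(hr, "A", "Z"), "no host records")
  expect_equal(f, "unknown")
})

test_that("host association summary reproduces the published counts", {
  fx <- bivesicula_evidence()
  res <- delimit_species(fx$evidence)
  smap <- species_map_from_hypotheses(res)
  s <- host_association_summary(fx$evidence$host_records, smap)
  # seven species have been found in Epinephelus fasciatus
  expect_equal(unname(s$species_per_host[["Epinephelus fasciatus"]]), 7L)
  # four species also infect holocentrids; all ten focal species infect
  # serranids; one also infects a muraenid
  expect_equal(unname(s$species_per_family[["Holocentridae"]]), 4L)
  expect_equal(unname(s$species_per_family[["Muraenidae"]]), 1L)
  focal <- names(res$species)
  per_sp <- s$per_species
  serranid <- vapply(focal, function(nm)
    grepl("Serranidae", per_sp$host_families[per_sp$species == nm]),
    logical(1))
  expect_true(all(serranid))
})

test_that("summary counts ignore record order and duplication", {
  hr <- host_records(c("A", "B"), c("h1", "h2"),
                     c("Serranidae", "Serranidae"), c("L1", "L2"))
  smap <- c(A = "sp1", B = "sp2")
  s1 <- host_association_summary(hr, smap)
  hr2 <- hr[c(2, 1, 1, 2, 1), ]
  s2 <- host_association_summary(hr2, smap)
  expect_equal(sort(s1$species_per_family), sort(s2$species_per_family))
  expect_equal(s2$species_per_family[["Serranidae"]], 2L)
  expect_error(host_association_summary(hr, c(A = "sp1")), "not in species_map")
  s0 <- host_association_summary(hr[0, ], smap)
  expect_equal(nrow(s0$per_species), 0L)
})

test_that("derived morphometrics compute ratios and dual-reference positions", {
  rec <- list(body_length = 1000, body_width = 400,
              testis_from_anterior = 700,
              caeca_end_from_posterior = 250,
              pharynx_length = 120, pharynx_width = 125,
              vitelline_start_from_anterior = 170,
              vitelline_end_from_posterior = 330)
  d <- derive_morphometrics(rec)
  expect_equal(d$length_width_ratio, 2.5)
  expect_equal(d$testis$pct_from_anterior, 70)
  expect_equal(d$testis$pct_from_posterior, 30)
  expect_equal(d$caeca_end$pct_from_posterior, 25)
  expect_equal(d$caeca_end$pct_from_anterior, 75)
  expect_equal(d$testis$pct_from_anterior + d$testis$pct_from_posterior, 100)
  expect_equal(d$vitelline_field$um, 500)
  expect_equal(d$vitelline_field$pct_body_length, 50)
  expect_equal(d$pharynx_ratio, 120 / 125)
  # omitted organs are simply absent; missing body length errors
  d2 <- derive_morphometrics(list(body_length = 1000, body_width = 500))
  expect_null(d2$testis)
  expect_error(derive_morphometrics(list(body_width = 400)), "body_length")
  expect_error(derive_morphometrics(list(body_length = 10,
                                         testis_from_anterior = 20)),
               "exceeds")
})

test_that("shape comparison counts exceedance and tests group shift", {
  recs <- data.frame(
    host_family = rep(c("Serranidae", "Holocentridae"), each = 2),
    body_length = c(1000, 1100, 800, 900),
    body_width = c(100, 100, 100, 100))
  sc <- shape_comparison(recs, metric = "body_length")
  expect_equal(sc$exceedance["Serranidae", "Holocentridae"], 2L)
  expect_equal(sc$exceedance["Holocentridae", "Serranidae"], 0L)

  # identical groups: exceedance 0, p near 1
  recs2 <- data.frame(host_family = rep(c("A", "B"), each = 3),
                      body_length = rep(c(10, 11, 12), 2),
                      body_width = rep(c(5, 5, 5), 2))
  sc2 <- shape_comparison(recs2)
  expect_equal(max(sc2$exceedance), 0L)
  expect_gt(sc2$p_value, 0.9)

  # exceedance equals brute-force enumeration on random inputs
  withr::local_seed(6)
  recs3 <- data.frame(host_family = sample(c("X", "Y", "Z"), 30, replace = TRUE),
                      body_length = stats::runif(30, 500, 1500),
                      body_width = stats::runif(30, 200, 700))
  sc3 <- shape_comparison(recs3)
  v <- recs3$body_length / recs3$body_width
  for (a in rownames(sc3$exceedance)) for (b in colnames(sc3$exceedance)) {
    if (a == b) next
    expect_equal(sc3$exceedance[a, b],
                 sum(v[recs3$host_family == a] >
                       max(v[recs3$host_family == b])))
  }
})

test_that("undersized groups are summarized but excluded from the test", {
  recs <- data.frame(host_family = c("A", "A", "A", "B"),
                     body_length = c(10, 11, 12, 9),
                     body_width = c(5, 5, 5, 5))
  sc <- shape_comparison(recs)
  expect_true("B" %in% sc$groups$group)
  expect_true(is.na(sc$p_value))
})
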