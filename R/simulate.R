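#' Inverse Jukes-Cantor branch-length calibration
#'
#' Maps a target expected raw difference count over `n_sites` comparable
#' positions to the JC69 path length (expected substitutions per site)
#' between two sequences: `d = -3/4 log(1 - 4p/3)` with `p = n_diff /
#' n_sites`.
#'
#' @param n_diff expected raw differences
#' @param n_sites alignment length
#' @return JC path length
#' @export
jc_distance_for_differences <- function(n_diff, n_sites) {
  p <- n_diff / n_sites
  if (any(p >= 0.75)) stop("target differences exceed the JC saturation bound")
  -0.75 * log(1 - 4 * p / 3)
}

#' Expected raw differences under Jukes-Cantor
#' @param d JC path length (substitutions/site)
#' @param n_sites alignment length
#' @return expected number of differing positions
#' @export
jc_expected_differences <- function(d, n_sites) {
  n_sites * 0.75 * (1 - exp(-4 * d / 3))
}

#' Specification for a sequence simulation
#'
#' @param tree `phylo` with branch lengths in expected substitutions/site
#' @param seq_length alignment columns (default 474, a typical partial cox1
#'   barcode fragment)
#' @param seed integer seed
#' @param planted_partition named vector leaf -> OTU label (the ground
#'   truth a clustering run should recover)
#' @param population_structure optional named vector OTU -> population
#' @return list of class `sim_spec`
#' @export
sim_spec <- function(tree, seq_length = 474L, seed = 1L,
                     planted_partition = NULL, population_structure = NULL) {
  stopifnot(inherits(tree, "phylo"), seq_length >= 1L)
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (is.null(planted_partition))
    planted_partition <- stats::setNames(tree$tip.label, tree$tip.label)
  structure(list(tree = tree, seq_length = as.integer(seq_length),
                 seed = as.integer(seed),
                 planted_partition = planted_partition,
                 population_structure = population_structure),
            class = "sim_spec")
}

#' Default study-shaped simulation design
#'
#' Builds a `sim_spec` emulating the structure of a multi-clade barcode
#' data set: three deeply separated clades; within species, individual
#' variation below 10 expected differences; within one widespread species,
#' regional populations at 10-23 expected differences; between species,
#' minima of at least 21 expected differences — on a 474-position cox1-like
#' alignment. Expectations are calibrated with the inverse JC formula.
#'
#' The design plants 6 species-level OTU groups across 3 clades with 2-4
#' individuals each; one species has two regional populations.
#'
#' @param seed integer seed
#' @return a `sim_spec`
#' @export
default_sim_spec <- function(seed = 1L) {
  L <- 474L
  h <- function(nd) jc_distance_for_differences(nd, L) / 2 # per-lineage depth
  tip <- h(2)        # individual depth: ~2 expected differences within tips
  popd <- h(16) - tip  # population split: ~16 differences between populations
  spd <- h(40)       # species split: >= ~40 differences between species
  cld <- h(80)       # clade split: ~80 differences between clades
  nwk <- sprintf(paste0(
    "(((a1:%1$f,a2:%1$f):%3$f,((b1:%1$f,b2:%1$f):%2$f,",
    "(b3:%1$f,b4:%1$f):%2$f):%4$f):%5$f,",
    "((c1:%1$f,c2:%1$f):%3$f,(d1:%1$f,d2:%1$f):%3$f):%5$f,",
    "((e1:%1$f,e2:%1$f):%3$f,(f1:%1$f,f2:%1$f):%3$f):%5$f);"),
    tip, popd, spd - tip, spd - tip - popd, cld - spd)
  tree <- ape::read.tree(text = nwk)
  plant <- stats::setNames(
    rep(c("A", "B", "C", "D", "E", "F"), times = c(2L, 4L, 2L, 2L, 2L, 2L)),
    c("a1", "a2", "b1", "b2", "b3", "b4", "c1", "c2", "d1", "d2",
      "e1", "e2", "f1", "f2"))
  pops <- stats::setNames(c("B1", "B1", "B2", "B2"),
                          c("b1", "b2", "b3", "b4"))
  sim_spec(tree, seq_length = L, seed = seed,
           planted_partition = plant, population_structure = pops)
}

#' Simulate sequences along a tree under Jukes-Cantor
#'
#' Site-independent JC69 evolution via [phangorn::simSeq()], deterministic
#' under the spec's seed. Returns the alignment together with the planted
#' truth record.
#'
#' @param spec a [sim_spec()]
#' @return list: `alignment` (a [seq_set()] alignment, marker `"cox1"`),
#'   `truth` (the spec's planted partition and population structure)
#' @export
simulate_tree_sequences <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  dat <- phangorn::simSeq(spec$tree, l = spec$seq_length, type = "DNA")
  m <- toupper(as.character(dat))
  aln <- aln_from_matrix(m, marker = "cox1")
  list(alignment = aln,
       truth = list(planted_partition = spec$planted_partition,
                    population_structure = spec$population_structure))
}

#' Specification for a morphometrics simulation
#'
#' @param n_per_group specimens per host family (default 40)
#' @param host_effect multiplicative shift in the body length/width
#'   (elongation) ratio of serranid-hosted over holocentrid-hosted
#'   specimens (default 1.5: specimens from holocentrids are broader)
#' @param base lognormal parameters: `meanlog_length`, `sdlog_length`,
#'   `meanlog_ratio`, `sdlog_ratio` (lengths in micrometres)
#' @param seed integer seed
#' @return list of class `morph_sim_spec`
#' @export
morph_sim_spec <- function(n_per_group = 40L, host_effect = 1.5,
                           base = list(meanlog_length = log(1100),
                                       sdlog_length = 0.15,
                                       meanlog_ratio = log(2.2),
                                       sdlog_ratio = 0.12),
                           seed = 1L) {
  stopifnot(n_per_group >= 1L, host_effect > 0)
  structure(list(n_per_group = as.integer(n_per_group),
                 host_effect = host_effect, base = base,
                 seed = as.integer(seed)),
            class = "morph_sim_spec")
}

#' Simulate specimen morphometrics with a host-family shape effect
#'
#' Generates lognormal body lengths and elongation ratios per specimen,
#' with the ratio of serranid-hosted specimens multiplied by
#' `host_effect` relative to holocentrid-hosted ones; widths are derived as
#' `length / ratio` so length and width are jointly consistent.
#'
#' @param spec a [morph_sim_spec()]
#' @return list: `records` (data.frame with `specimen_id`, `host_family`,
#'   `body_length`, `body_width`), `truth` (the spec)
#' @export
simulate_morphometrics <- function(spec) {
  stopifnot(inherits(spec, "morph_sim_spec"))
  set.seed(spec$seed)
  b <- spec$base
  fam <- rep(c("Holocentridae", "Serranidae"), each = spec$n_per_group)
  n <- length(fam)
  len <- stats::rlnorm(n, b$meanlog_length, b$sdlog_length)
  shift <- ifelse(fam == "Serranidae", log(spec$host_effect), 0)
  ratio <- stats::rlnorm(n, b$meanlog_ratio + shift, b$sdlog_ratio)
  records <- data.frame(
    specimen_id = sprintf("sp%03d", seq_len(n)),
    host_family = fam,
    body_length = len,
    body_width = len / ratio)
  list(records = records, truth = spec)
}
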