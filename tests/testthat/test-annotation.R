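toy_map <- function() {
  topology_map("AG", data.frame(
    start = c(1, 11, 21), end = c(10, 20, 30),
    label = c("intracellular", "transmembrane", "exofacial")))
}

test_that("topology maps must tile the sequence without gaps or overlaps", {
  expect_s3_class(toy_map(), "topology_map")
  expect_error(topology_map("AG", data.frame(
    start = c(1, 16), end = c(14, 30),
    label = c("intracellular", "exofacial"))), "gap or overlap")
  expect_error(topology_map("AG", data.frame(
    start = c(1, 10), end = c(12, 30),
    label = c("intracellular", "exofacial"))), "gap or overlap")
  expect_error(topology_map("AG", data.frame(
    start = c(2, 11), end = c(10, 30),
    label = c("intracellular", "exofacial"))), "start at residue 1")
  expect_error(topology_map("AG", data.frame(
    start = 1, end = 30, label = "outerspace")), "unknown region label")
})

test_that("start-residue rule labels cores by the interval holding their first residue", {
  m <- toy_map()
  expect_equal(classify_region(5, m), "intracellular")
  expect_equal(classify_region(11, m), "transmembrane")
  # start 20: only the first residue is transmembrane, 8 of 9 are exofacial
  expect_equal(classify_region(20, m), "transmembrane")
  expect_equal(classify_region(20, m, rule = "majority_overlap"), "exofacial")
  expect_error(classify_region(31, m), "outside topology map")
  # total over every valid window start
  expect_length(classify_region(1:22, m, k = 9), 22)
})

test_that("the packaged RhD map reproduces the published example labels", {
  map <- read_rh_topology("RHD01")
  expect_equal(map$length, 417)
  expect_equal(classify_region(38, map), "exofacial")
  # start 358 is the last exofacial residue of the 347-358 loop: still
  # exofacial under the start-residue rule
  expect_equal(classify_region(358, map), "exofacial")
  expect_equal(classify_region(31, map), "transmembrane")
})

test_that("the packaged maps agree with the published hotspot labels, up to the known 390 conflict", {
  t1 <- read_table1_hotspots()
  # RhCE: every label reproduced
  ce <- t1[t1$antigen == "RHCE01", ]
  pred_ce <- classify_region(ce$start, read_rh_topology("RHCE01"))
  expect_equal(mean(pred_ce == ce$region), 1.0)
  # RhD normal group: the source table carries contradictory labels for
  # start 390 (intracellular in DRB, transmembrane in DQA-DQB); the map
  # follows the majority, so exactly that one row mismatches
  g <- t1[t1$antigen == "RHD01", ]
  pred <- classify_region(g$start, read_rh_topology("RHD01"))
  mism <- g[pred != g$region, ]
  expect_equal(nrow(mism), 1)
  expect_equal(mism$start, 390)
  expect_equal(mism$locus_group, "DQA-DQB")
})

test_that("hotspot diffs partition the union of starts", {
  set.seed(31)
  for (i in 1:10) {
    mk <- function() {
      n <- sample(3:12, 1)
      starts <- sample(1:40, n)
      data.frame(start = starts,
                 core = vapply(seq_len(n), function(j) {
                   paste(sample(AA20, 9, replace = TRUE), collapse = "")
                 }, character(1)))
    }
    a <- mk(); b <- mk()
    # force some shared starts with identical cores
    shared_n <- min(3, nrow(a), nrow(b))
    b$start[seq_len(shared_n)] <- a$start[seq_len(shared_n)]
    b$core[seq_len(shared_n)] <- a$core[seq_len(shared_n)]
    b <- b[!duplicated(b$start), ]
    d <- diff_hotspots(a, b)
    parts <- c(d$shared, d$changed_core$start, d$lost, d$gained)
    expect_equal(sort(parts), sort(union(a$start, b$start)))
    expect_equal(anyDuplicated(parts), 0)
  }
  expect_error(diff_hotspots(data.frame(start = c(1, 1), core = "A"),
                             data.frame(start = 2, core = "B")),
               "deduplicated")
})

test_that("identical hotspot lists diff to all-shared", {
  a <- data.frame(start = c(5, 9), core = c("AAAAAAAAA", "CCCCCCCCC"))
  d <- diff_hotspots(a, a)
  expect_equal(d$shared, c(5L, 9L))
  expect_equal(nrow(d$changed_core), 0)
  expect_length(d$lost, 0)
  expect_length(d$gained, 0)
})

test_that("a substitution can only alter windows covering it", {
  s <- rhd_scaffold()
  v <- parse_hgvs_p("p.Val270Gly")
  starts <- variant_core_changes(s, v, k = 9)
  expect_equal(starts, 262:270)

  # clipped at both ends
  first <- substr(s$residues, 1, 1)
  alt1 <- setdiff(AA20, first)[1]
  three <- names(epihotspot:::AA_THREE_TO_ONE)
  one <- epihotspot:::AA_THREE_TO_ONE
  lab <- function(a, p, b) paste0("p.", three[match(a, one)], p,
                                  three[match(b, one)])
  expect_equal(variant_core_changes(s, parse_hgvs_p(lab(first, 1, alt1))),
               1L)
  last <- substr(s$residues, 417, 417)
  altL <- setdiff(AA20, last)[1]
  expect_equal(variant_core_changes(s, parse_hgvs_p(lab(last, 417, altL))),
               409L)
  expect_error(variant_core_changes(s, parse_hgvs_p("p.Ala500Gly")),
               "outside sequence")

  # oracle: windows whose sequence actually changes are a subset of the
  # predicted affected starts
  alt_seq <- apply_variants(s, v, id = s$id)
  w_ref <- enumerate_peptides(s)
  w_alt <- enumerate_peptides(alt_seq)
  changed <- w_ref$start[w_ref$sequence != w_alt$sequence]
  expect_true(all(changed %in% starts))
  expect_equal(changed, starts)  # nothing outside changes either
})

test_that("changed cores between variant hotspot lists sit on affected windows", {
  s <- rhd_scaffold()
  v <- parse_hgvs_p("p.Val270Gly")
  alt_seq <- apply_variants(s, v, id = s$id)
  w_ref <- enumerate_peptides(s)
  w_alt <- enumerate_peptides(alt_seq)
  pick <- c(100, 265, 269, 400)
  ref_calls <- data.frame(start = pick, core = w_ref$sequence[pick])
  cmp_calls <- data.frame(start = pick, core = w_alt$sequence[pick])
  d <- diff_hotspots(ref_calls, cmp_calls)
  expect_true(all(d$changed_core$start %in% variant_core_changes(s, v)))
  expect_equal(d$changed_core$diff_positions,
               rep("270", nrow(d$changed_core)))
})
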