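test_that("allele generation is seed-deterministic with distinct motifs across seeds", {
  a1 <- make_synthetic_allele(3)
  a2 <- make_synthetic_allele(3)
  expect_identical(a1$weights, a2$weights)
  expect_identical(a1$background_scores, a2$background_scores)
  expect_identical(a1$anchors, a2$anchors)

  anchor_sets <- lapply(1:20, function(s) make_synthetic_allele(s)$anchors)
  pairs <- utils::combn(20, 2)
  differing <- sum(apply(pairs, 2, function(p) {
    !identical(anchor_sets[[p[1]]], anchor_sets[[p[2]]])
  }))
  expect_gte(differing, 1)

  expect_error(make_synthetic_allele(1, n_anchors = 0), "n_anchors")
  expect_error(make_synthetic_allele(1, n_anchors = 10, k = 9), "n_anchors")
  expect_error(make_synthetic_allele(1, B = 50), "B must be")
})

test_that("allele generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_synthetic_allele(5))
  expect_equal(runif(1), before)
})

test_that("pseudo-rank matches its defining formula", {
  p <- make_synthetic_allele(8)
  # the consensus scores strictly above every background peptide
  best <- consensus_peptide(p)
  expect_equal(pseudo_rank(p, best), 100 / (p$B + 1))
  # the anti-consensus scores below every background peptide
  worst <- paste(epihotspot:::AA_ALPHABET[apply(p$weights, 1, which.min)],
                 collapse = "")
  expect_equal(pseudo_rank(p, worst), 100)
  # brute-force recomputation over the full background sample
  set.seed(4)
  for (i in 1:20) {
    pep <- paste(sample(AA20, 9, replace = TRUE), collapse = "")
    sc <- score_peptides(p, pep)
    expect_equal(pseudo_rank(p, pep),
                 100 * (1 + sum(p$background_scores >= sc)) / (p$B + 1))
  }
  expect_error(pseudo_rank(p, "SHORT"), "length")
  expect_error(score_peptides(p, "ACDEFGHIX"), "outside the 20-letter")
})

test_that("pseudo-rank of random peptides is approximately uniform", {
  # marginal uniformity: pool draws over many independently seeded
  # backgrounds (conditioning on a single realized background would
  # inflate deviations through its spacings)
  set.seed(1000)
  ranks <- unlist(lapply(1:40, function(s) {
    p <- make_synthetic_allele(5000 + s, B = 250)
    peps <- vapply(1:50, function(i) {
      paste(sample(AA20, 9, replace = TRUE), collapse = "")
    }, character(1))
    pseudo_rank(p, peps)
  }))
  expect_length(ranks, 2000)
  expect_true(all(ranks > 0 & ranks <= 100))
  counts <- table(cut(ranks, breaks = seq(0, 100, by = 10)))
  gof <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(gof$p.value, 0.001)
})

test_that("planted motifs are recovered exactly by the full pipeline", {
  panel <- pssm_panel(3, seed = 21)
  plants <- data.frame(start = 10, allele = names(panel)[1])
  pt <- plant_motifs(100, plants, panel, seed = 21)
  w <- enumerate_peptides(pt$antigen)
  rec <- predict_binding(w, names(panel), panel)
  for (a in names(panel)) {
    prof <- build_profile(rec[rec$allele == a, ], seq_length = 100)
    expect_equal(call_hotspots(prof)$start, pt$truth[[a]])
  }
  # determinism and empty-plant behavior
  pt2 <- plant_motifs(100, plants, panel, seed = 21)
  expect_identical(pt2$antigen$residues, pt$antigen$residues)
  pt0 <- plant_motifs(80, plants[0, ], panel, seed = 3)
  rec0 <- predict_binding(enumerate_peptides(pt0$antigen), names(panel),
                          panel)
  expect_true(all(classify_binder(rec0$percent_rank) == "NB"))
})

test_that("plant placement is validated", {
  panel <- pssm_panel(2, seed = 5)
  expect_error(plant_motifs(50, data.frame(start = c(10, 12),
                                           allele = names(panel)),
                            panel, seed = 1), "overlap")
  expect_error(plant_motifs(50, data.frame(start = 45, allele = names(panel)[1]),
                            panel, seed = 1), "outside 1\\.\\.42")
  expect_error(plant_motifs(50, data.frame(start = 1, allele = "DRB1*01:01"),
                            panel, seed = 1), "not in panel")
})

test_that("rank perturbation grows monotonically with the noise level", {
  panel <- pssm_panel(2, seed = 13)
  s <- random_protein("AG1", 60, 13)
  w <- enumerate_peptides(s)
  base <- predict_binding(w, names(panel), panel)
  # same seed at every noise level: the score perturbation is sigma * z
  # for a fixed z, so rank displacement is non-decreasing in sigma
  devs <- vapply(c(0.5, 1, 2, 4), function(sig) {
    r <- predict_binding(w, names(panel), panel, noise_sd = sig, seed = 77)
    sum(abs(r$percent_rank - base$percent_rank))
  }, numeric(1))
  expect_true(all(diff(devs) >= 0))
  expect_gt(devs[1], 0)
})

test_that("noise degrades planted-motif recovery gracefully", {
  panel <- pssm_panel(3, seed = 33)
  plants <- data.frame(start = c(20, 60), allele = names(panel)[c(1, 2)])
  pt <- plant_motifs(120, plants, panel, seed = 33)
  w <- enumerate_peptides(pt$antigen)
  recall_at <- function(sig, seed) {
    rec <- if (sig == 0) predict_binding(w, names(panel), panel)
           else predict_binding(w, names(panel), panel, noise_sd = sig,
                                seed = seed)
    hits <- 0
    for (a in names(panel)) {
      prof <- build_profile(rec[rec$allele == a, ], seq_length = 120)
      hits <- hits + sum(call_hotspots(prof)$start %in% pt$truth[[a]])
    }
    hits / nrow(plants)
  }
  expect_equal(recall_at(0, 1), 1.0)
  # strong noise wipes out the planted signal for at least some replicate
  noisy <- vapply(1:5, function(s) recall_at(25, s), numeric(1))
  expect_lt(mean(noisy), 1.0)
})

test_that("fixture files round-trip and mark themselves synthetic", {
  rec <- random_records(10, c("DRB1*15:01", "DRB1*04:01"), seed = 6)
  f <- tempfile()
  write_netmhc_fixture(rec, "netmhciipan41", f)
  expect_match(readLines(f, n = 1), "synthetic fixture")
  back <- parse_netmhc_output(f, "netmhciipan41")
  expect_equal(back$percent_rank, rec$percent_rank)
  # header-only file for an empty record list
  write_netmhc_fixture(rec[0, ], "netmhcpan41", f)
  expect_equal(nrow(parse_netmhc_output(f, "netmhcpan41")), 0)
})

test_that("simulation bundles write antigen, truth and parseable predictions", {
  panel <- pssm_panel(2, seed = 41)
  pt <- plant_motifs(80, data.frame(start = 30, allele = names(panel)[2]),
                     panel, seed = 41)
  out <- tempfile()
  paths <- write_simulation(pt, panel, out,
                            dialects = c("netmhciipan41", "netmhcpan41"))
  ag <- read_fasta(paths$fasta)
  expect_equal(ag[[1]]$residues, pt$antigen$residues)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_equal(truth$planted[[names(panel)[2]]], 30)
  for (d in c("netmhciipan41", "netmhcpan41")) {
    back <- parse_netmhc_output(paths[[d]], d)
    expect_equal(nrow(back), 2 * (80 - 9 + 1))
  }
})
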