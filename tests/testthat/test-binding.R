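test_that("strong/weak/non-binder classification uses strict bounds", {
  th <- binder_thresholds()
  expect_equal(classify_binder(0.3, th), "SB")
  expect_equal(classify_binder(0.5, th), "WB")   # boundary -> weaker class
  expect_equal(classify_binder(1.99, th), "WB")
  expect_equal(classify_binder(2.0, th), "NB")
  expect_equal(classify_binder(50, th), "NB")
  expect_error(classify_binder(0, th), "\\(0, 100\\]")
  expect_error(classify_binder(-1, th), "\\(0, 100\\]")
  expect_error(classify_binder(101, th), "\\(0, 100\\]")
  expect_error(binder_thresholds(2, 0.5), "sb_rank < wb_rank")
})

test_that("the SB set is monotone in the rank threshold", {
  set.seed(42)
  ranks <- runif(500, 0.01, 100)
  grid <- c(0.1, 0.5, 1, 2, 5, 10)
  sets <- lapply(grid, function(t) {
    which(classify_binder(ranks, binder_thresholds(t, t + 90)) == "SB")
  })
  for (i in seq_along(grid)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
})

test_that("HLA allele names normalize across engine spellings", {
  expect_equal(normalize_hla("DRB1_1501"), "DRB1*15:01")
  expect_equal(normalize_hla("HLA-DQA10101-DQB10301"),
               "DQA1*01:01-DQB1*03:01")
  expect_equal(normalize_hla("HLA-DPA10103-DPB110401"),
               "DPA1*01:03-DPB1*104:01")
  expect_equal(normalize_hla("HLA-A01:01"), "A*01:01")
  expect_equal(normalize_hla("DQA1*01:01-DQB1*03:01"),
               "DQA1*01:01-DQB1*03:01")  # canonical passthrough
  expect_equal(normalize_hla(c("DRB1_0301", "HLA-B07:02")),
               c("DRB1*03:01", "B*07:02"))
})

test_that("locus group and MHC class are inferred from the allele name", {
  a <- hla_allele("HLA-A02:01")
  expect_equal(a$locus_group, "A")
  expect_equal(a$mhc_class, "I")
  expect_equal(hla_allele("DRB3_0101")$locus_group, "DRB")
  expect_equal(hla_allele("HLA-DQA10101-DQB10402")$locus_group, "DQA-DQB")
  expect_equal(hla_allele("DPA1*02:01-DPB1*01:01")$locus_group, "DPA-DPB")
  expect_error(hla_allele("DQB1*03:01"), "paired")
})

test_that("engine output parses and round-trips through the fixture writer", {
  # class II dialect with DR and paired DQ/DP allele spellings
  rec <- random_records(20, c("DRB1*15:01", "DQA1*01:01-DQB1*03:01",
                              "DPA1*01:03-DPB1*04:01"), seed = 1)
  rec$locus_group <- vapply(rec$allele,
                            function(a) hla_allele(a)$locus_group,
                            character(1), USE.NAMES = FALSE)
  f <- tempfile()
  write_netmhc_fixture(rec, "netmhciipan41", f)
  back <- parse_netmhc_output(f, "netmhciipan41")
  expect_equal(back$allele, rec$allele)
  expect_equal(back$start, rec$start)
  expect_equal(back$core, rec$core)
  expect_equal(back$percent_rank, rec$percent_rank)
  expect_true(all(back$percent_rank > 0 & back$percent_rank <= 100))

  # class I dialect
  rec1 <- random_records(25, c("A*01:01", "B*07:02"), seed = 2)
  rec1$locus_group <- substr(rec1$allele, 1, 1)
  f1 <- tempfile()
  write_netmhc_fixture(rec1, "netmhcpan41", f1)
  back1 <- parse_netmhc_output(f1, "netmhcpan41")
  expect_equal(back1$allele, rec1$allele)
  expect_equal(back1$start, rec1$start)
  expect_equal(back1$percent_rank, rec1$percent_rank)
})

test_that("parser rejects the wrong dialect and malformed rows", {
  rec <- random_records(5, "DRB1*15:01", seed = 3)
  f <- tempfile()
  write_netmhc_fixture(rec, "netmhciipan41", f)
  expect_error(parse_netmhc_output(f, "netmhcpan41"), "dialect")

  # header-only file -> empty record list
  write_netmhc_fixture(rec[0, ], "netmhciipan41", f)
  expect_equal(nrow(parse_netmhc_output(f, "netmhciipan41")), 0)

  # truncated data row
  lines <- readLines(write_netmhc_fixture(rec, "netmhciipan41", f))
  data_line <- grep("DRB1", lines)[1]
  lines[data_line] <- substr(lines[data_line], 1, 20)
  writeLines(lines, f)
  expect_error(parse_netmhc_output(f, "netmhciipan41"),
               "truncated|unparseable")

  # not an engine file at all
  writeLines(c("just", "text"), f)
  expect_error(parse_netmhc_output(f, "netmhciipan41"), "not a recognized")
})

test_that("the predictor seam yields one record per (window, allele) pair", {
  panel <- pssm_panel(3, seed = 11)
  s <- random_protein("AG1", 12, 5)
  w <- enumerate_peptides(s)  # 4 windows
  rec <- predict_binding(w, names(panel), panel)
  expect_equal(nrow(rec), 12)
  expect_equal(sort(unique(rec$allele)), sort(names(panel)))
  expect_error(predict_binding(w, character(0), panel), "no alleles")
  expect_error(predict_binding(w[0, ], names(panel), panel), "no peptide")
  expect_error(predict_binding(w, "DRB1*01:01", panel), "not supported")
  # determinism: same inputs -> identical records
  expect_identical(rec, predict_binding(w, names(panel), panel))
  # with noise, same seed -> identical; different seed -> different
  r1 <- predict_binding(w, names(panel), panel, noise_sd = 1, seed = 4)
  r2 <- predict_binding(w, names(panel), panel, noise_sd = 1, seed = 4)
  r3 <- predict_binding(w, names(panel), panel, noise_sd = 1, seed = 5)
  expect_identical(r1, r2)
  expect_false(identical(r1$percent_rank, r3$percent_rank))
})

test_that("windows containing X are skipped audibly, not silently", {
  panel <- pssm_panel(2, seed = 11)
  s <- protein_sequence("AG1", "ACDXFGHIKLMNPQ")
  w <- enumerate_peptides(s)
  expect_message(rec <- predict_binding(w, names(panel), panel),
                 "skipping")
  expect_equal(nrow(rec), 2 * sum(!w$has_x))
  expect_false(any(grepl("X", rec$peptide)))
})
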