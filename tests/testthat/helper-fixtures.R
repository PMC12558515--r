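# In-code fixtures shared across test files. All sequences are synthetic
# scaffolds built at test time; none is a real Rh protein sequence.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(id, n, seed) {
  set.seed(seed)
  protein_sequence(id, paste(sample(AA20, n, replace = TRUE), collapse = ""))
}

# 417-residue synthetic scaffold carrying the published 9-mer core
# YVHSAVLAG at start 269 (so that p.Val270Gly turns it into YGHSAVLAG)
rhd_scaffold <- function() {
  set.seed(417)
  chars <- sample(AA20, 417, replace = TRUE)
  chars[269:277] <- strsplit("YVHSAVLAG", "")[[1]]
  protein_sequence("SYN_RHD_SCAFFOLD", paste(chars, collapse = ""))
}

write_temp_fasta <- function(records, path = tempfile(fileext = ".fa")) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# random binding-record frame over a synthetic panel (used by profile and
# round-trip tests)
random_records <- function(n_starts, alleles, seed, antigen_id = "AG1",
                           k = 9) {
  set.seed(seed)
  grid <- expand.grid(start = seq_len(n_starts), allele = alleles,
                      stringsAsFactors = FALSE)
  cores <- vapply(seq_len(n_starts), function(i) {
    paste(sample(AA20, k, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(
    antigen_id = antigen_id,
    start = grid$start,
    peptide = cores[grid$start],
    core = cores[grid$start],
    core_shifted = FALSE,
    allele = grid$allele,
    locus_group = "DRB",
    percent_rank = stats::runif(nrow(grid), 0.01, 100),
    score = stats::rnorm(nrow(grid)),
    stringsAsFactors = FALSE
  )
}
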