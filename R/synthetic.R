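# Seeded synthetic data: allele scoring matrices (PSSMs), empirical
# pseudo-%rank calibration against a background peptide sample, antigens
# with planted strong-binding motifs, and engine-dialect fixture files.
# Everything is deterministic under a fixed seed, so the whole pipeline is
# testable with no external prediction engine.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic allele scoring matrix
#'
#' Emulates motif-driven MHC class II binding with a position-specific
#' scoring matrix over the k-residue binding core: a few anchor positions
#' have one sharply preferred residue; the remaining positions are
#' near-flat. A background sample of `B` random peptides is drawn and
#' scored at construction time; [pseudo_rank()] is the empirical percentile
#' of a peptide's score in that sample. Deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @param k Core length (default 9).
#' @param n_anchors Number of anchor positions (1..k).
#' @param B Background sample size (>= 100; default 1000, giving a minimum
#'   achievable rank of 100/(B+1) ~ 0.0999).
#' @param name Allele name; defaults to a synthetic DRB1-style name derived
#'   from the seed.
#' @return A `synthetic_allele` object.
#' @export
make_synthetic_allele <- function(seed, k = 9L, n_anchors = 3L, B = 1000L,
                                  name = NULL) {
  k <- as.integer(k); n_anchors <- as.integer(n_anchors); B <- as.integer(B)
  if (n_anchors < 1L || n_anchors > k) {
    stop("n_anchors must be in 1..k (got ", n_anchors, ")", call. = FALSE)
  }
  if (B < 100L) stop("background size B must be >= 100", call. = FALSE)
  if (is.null(name)) {
    name <- sprintf("DRB1*9%d:%02d", seed %% 10L, (seed %/% 10L) %% 100L)
  }
  with_seed(seed, {
    anchors <- sort(sample.int(k, n_anchors))
    w <- matrix(stats::rnorm(k * 20L, mean = 0, sd = 0.15),
                nrow = k, ncol = 20L,
                dimnames = list(NULL, AA_ALPHABET))
    for (a in anchors) {
      preferred <- sample.int(20L, 1L)
      w[a, ] <- stats::rnorm(20L, mean = 0, sd = 0.3)
      w[a, preferred] <- 4
    }
    bg <- matrix(sample(AA_ALPHABET, B * k, replace = TRUE),
                 nrow = B, ncol = k)
    bg_peptides <- apply(bg, 1L, paste, collapse = "")
    pssm <- structure(
      list(name = normalize_hla(name), locus_group = hla_allele(name)$locus_group,
           k = k, weights = w, anchors = anchors, B = B, seed = seed,
           background_peptides = bg_peptides,
           background_scores = numeric(B)),
      class = "synthetic_allele")
    pssm$background_scores <- sort(score_peptides(pssm, bg_peptides))
    pssm
  })
}

#' @export
print.synthetic_allele <- function(x, ...) {
  cat("<synthetic_allele> ", x$name, " (k = ", x$k, ", anchors at ",
      paste(x$anchors, collapse = ","), ", B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Score peptides against a synthetic allele PSSM
#'
#' The score of a k-mer is the sum of its per-position weight-matrix
#' entries.
#'
#' @param pssm A [make_synthetic_allele()] object.
#' @param peptides Character vector of k-mers.
#' @return Numeric score vector.
#' @export
score_peptides <- function(pssm, peptides) {
  stopifnot(inherits(pssm, "synthetic_allele"))
  if (any(nchar(peptides) != pssm$k)) {
    stop("peptide length must equal k = ", pssm$k, call. = FALSE)
  }
  vapply(peptides, function(p) {
    chars <- strsplit(p, "", fixed = TRUE)[[1L]]
    idx <- match(chars, AA_ALPHABET)
    if (anyNA(idx)) {
      stop("peptide '", p, "' contains residues outside the 20-letter ",
           "alphabet", call. = FALSE)
    }
    sum(pssm$weights[cbind(seq_len(pssm$k), idx)])
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Empirical pseudo percentile rank of a peptide
#'
#' `rank = 100 * (1 + #{background peptides scoring >= peptide}) / (B + 1)`,
#' the add-one empirical upper-tail percentile of the peptide's score in
#' the allele's seeded background sample. Lower is stronger; the best
#' achievable rank is `100/(B+1)` and a peptide scoring below the whole
#' background gets rank 100. Deterministic per (pssm, peptide).
#'
#' @param pssm A [make_synthetic_allele()] object.
#' @param peptides Character vector of k-mers (vectorized).
#' @param scores Optional pre-computed scores (used internally to inject
#'   score noise before the rank lookup).
#' @return Numeric vector of %rank values in (0, 100].
#' @export
pseudo_rank <- function(pssm, peptides, scores = NULL) {
  if (is.null(scores)) scores <- score_peptides(pssm, peptides)
  bg <- pssm$background_scores  # sorted ascending
  n_below <- findInterval(scores, bg, left.open = TRUE)  # bg strictly < score
  n_ge <- pssm$B - n_below
  100 * (1 + n_ge) / (pssm$B + 1)
}

#' Consensus (highest-scoring) peptide of a synthetic allele
#' @param pssm A [make_synthetic_allele()] object.
#' @return The k-mer maximizing the PSSM score.
#' @export
consensus_peptide <- function(pssm) {
  paste(AA_ALPHABET[apply(pssm$weights, 1L, which.max)], collapse = "")
}

# a random strong binder: preferred residues at the anchors, uniform draws
# elsewhere. The anchors alone put the score far above the background, so
# any such peptide attains a strong-binder rank, while the random
# non-anchor residues vary between draws — this keeps windows that
# partially overlap a planted motif from inheriting anchor hits the way a
# fixed consensus (with its repeated residues) can. Uses the caller's RNG
# stream.
strong_peptide <- function(pssm) {
  chars <- sample(AA_ALPHABET, pssm$k, replace = TRUE)
  chars[pssm$anchors] <-
    AA_ALPHABET[apply(pssm$weights[pssm$anchors, , drop = FALSE], 1L,
                      which.max)]
  paste(chars, collapse = "")
}

#' Build a panel of synthetic alleles
#'
#' @param n_alleles Panel size.
#' @param seed Base seed; allele i uses `seed + i`.
#' @param ... Passed to [make_synthetic_allele()].
#' @return A `pssm_panel`: named list of `synthetic_allele` objects.
#' @export
pssm_panel <- function(n_alleles, seed, ...) {
  stopifnot(n_alleles >= 1L)
  alleles <- lapply(seq_len(n_alleles), function(i) {
    make_synthetic_allele(seed + i, name = sprintf("DRB1*90:%02d", i), ...)
  })
  names(alleles) <- vapply(alleles, `[[`, character(1L), "name")
  structure(alleles, class = c("pssm_panel", "list"))
}

#' @export
predict_binding.pssm_panel <- function(windows, alleles, engine,
                                       noise_sd = 0, seed = NULL) {
  unsupported <- setdiff(alleles, names(engine))
  if (length(unsupported) > 0L) {
    stop("allele(s) not supported by this panel: ",
         paste(unsupported, collapse = ", "), call. = FALSE)
  }
  skipped <- windows$has_x
  if (any(skipped)) {
    message("skipping ", sum(skipped),
            " window(s) containing 'X' at start(s): ",
            paste(windows$start[skipped], collapse = ", "))
    windows <- windows[!skipped, , drop = FALSE]
  }
  if (nrow(windows) == 0L) stop("all windows were skipped", call. = FALSE)
  if (noise_sd > 0 && is.null(seed)) {
    stop("a seed is required when noise_sd > 0", call. = FALSE)
  }
  noise <- function(n) stats::rnorm(n, 0, noise_sd)
  run <- function() {
    do.call(rbind, lapply(alleles, function(a) {
      pssm <- engine[[a]]
      scores <- score_peptides(pssm, windows$sequence)
      if (noise_sd > 0) scores <- scores + noise(length(scores))
      data.frame(
        antigen_id = windows$antigen_id,
        start = windows$start,
        peptide = windows$sequence,
        core = windows$sequence,
        core_shifted = FALSE,
        allele = pssm$name,
        locus_group = pssm$locus_group,
        percent_rank = pseudo_rank(pssm, windows$sequence, scores = scores),
        score = scores,
        stringsAsFactors = FALSE
      )
    }))
  }
  out <- if (noise_sd > 0) with_seed(seed, run()) else run()
  rownames(out) <- NULL
  out
}

#' Generate an antigen with planted strong-binding motifs
#'
#' Draws a random antigen sequence, embeds a strong-binding peptide of the
#' planted allele (preferred anchor residues, randomized elsewhere) at each
#' requested start, then verifies the construction: every
#' planted (start, allele) pair must classify as a strong binder and every
#' other (window, allele) pair as a non-binder. Windows that violate the
#' non-binder requirement have their free residues (those outside all
#' planted intervals) resampled, for up to `max_repair` rounds; if a
#' violation cannot be repaired the whole construction is retried with a
#' derived seed, up to `max_retries` times, after which generation fails
#' with advice to change parameters.
#'
#' @param length Antigen length in residues.
#' @param plants Data frame with columns `start` (1-based) and `allele`
#'   (names present in `panel`). Plants must not overlap at k-mer scale
#'   unless `allow_overlap = TRUE`.
#' @param panel A [pssm_panel()].
#' @param seed Integer seed.
#' @param thresholds A [binder_thresholds()] used for the construction-time
#'   verification.
#' @param antigen_id Identifier for the generated antigen.
#' @param allow_overlap Permit overlapping plants (skips the overlap check;
#'   verification still applies).
#' @param max_repair,max_retries Repair-round and retry bounds.
#' @return A `planted_truth` list: `antigen` (a [protein_sequence()]),
#'   `truth` (named list allele -> sorted planted starts), `plants`.
#' @export
plant_motifs <- function(length, plants, panel, seed,
                         thresholds = binder_thresholds(),
                         antigen_id = "SYNTHETIC_ANTIGEN",
                         allow_overlap = FALSE,
                         max_repair = 25L, max_retries = 20L) {
  stopifnot(inherits(panel, "pssm_panel"),
            all(c("start", "allele") %in% names(plants)))
  k <- panel[[1L]]$k
  if (nrow(plants) > 0L) {
    unknown <- setdiff(plants$allele, names(panel))
    if (length(unknown) > 0L) {
      stop("plant allele(s) not in panel: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (any(plants$start < 1L | plants$start > length - k + 1L)) {
      stop("plant start outside 1..", length - k + 1L, call. = FALSE)
    }
    if (!allow_overlap) {
      s <- sort(plants$start)
      if (any(diff(s) < k)) {
        stop("plants overlap at k-mer scale; set allow_overlap = TRUE to ",
             "permit this", call. = FALSE)
      }
    }
  }
  planted_res <- unique(unlist(lapply(plants$start, function(s) s:(s + k - 1L))))
  alleles <- names(panel)
  truth <- lapply(alleles, function(a)
    sort(as.integer(plants$start[plants$allele == a])))
  names(truth) <- alleles

  for (try in seq_len(max_retries)) {
    attempt_seed <- seed + (try - 1L) * 10007L
    res <- with_seed(attempt_seed, {
      chars <- sample(AA_ALPHABET, length, replace = TRUE)
      for (i in seq_len(nrow(plants))) {
        s <- plants$start[i]
        chars[s:(s + k - 1L)] <-
          strsplit(strong_peptide(panel[[plants$allele[i]]]), "",
                   fixed = TRUE)[[1L]]
      }
      ok <- FALSE
      for (round in seq_len(max_repair)) {
        seq_str <- paste(chars, collapse = "")
        starts <- seq_len(length - k + 1L)
        windows <- substring(seq_str, starts, starts + k - 1L)
        bad_windows <- integer(0)
        planted_fail <- FALSE
        for (a in alleles) {
          ranks <- pseudo_rank(panel[[a]], windows)
          cls <- classify_binder(ranks, thresholds)
          want_sb <- starts %in% truth[[a]]
          if (any(cls[want_sb] != "SB")) planted_fail <- TRUE
          bad_windows <- union(bad_windows, starts[!want_sb & cls != "NB"])
        }
        if (planted_fail) break        # consensus not SB: retry from scratch
        if (length(bad_windows) == 0L) { ok <- TRUE; break }
        free <- setdiff(unique(unlist(lapply(bad_windows,
                                             function(s) s:(s + k - 1L)))),
                        planted_res)
        if (length(free) == 0L) break  # violation inside planted residues
        chars[free] <- sample(AA_ALPHABET, length(free), replace = TRUE)
      }
      if (ok) paste(chars, collapse = "") else NULL
    })
    if (!is.null(res)) {
      return(structure(
        list(antigen = protein_sequence(antigen_id, res),
             truth = truth, plants = plants, k = k, seed = seed),
        class = "planted_truth"))
    }
  }
  stop("could not generate a verified planted antigen in ", max_retries,
       " attempts; try a different seed, fewer plants, a longer antigen, ",
       "or more anchors per allele", call. = FALSE)
}

# canonical allele name -> engine output spelling
engine_spelling <- function(allele, dialect) {
  vapply(allele, function(a) {
    if (grepl("-", a, fixed = TRUE)) {
      parts <- strsplit(a, "-", fixed = TRUE)[[1L]]
      return(paste0("HLA-", paste(gsub("[*:]", "", parts), collapse = "-")))
    }
    locus <- sub("\\*.*$", "", a)
    if (locus %in% c("A", "B", "C")) return(paste0("HLA-", sub("\\*", "", a)))
    if (grepl("^DRB", locus)) return(gsub(":", "", sub("\\*", "_", a)))
    a
  }, character(1L), USE.NAMES = FALSE)
}

#' Write binding records as a NetMHC-dialect fixture file
#'
#' Emits a plain-text result file in the named engine dialect's column
#' layout (marked synthetic in its header comment) such that
#' [parse_netmhc_output()] round-trips allele, position, core and %rank
#' exactly. Allele names are written in engine spelling (`DRB1_1501`,
#' `HLA-DQA10101-DQB10301`, `HLA-A01:01`) to exercise name normalization.
#'
#' @param records Binding-record data.frame.
#' @param dialect `"netmhcpan41"` or `"netmhciipan41"`.
#' @param path Output path.
#' @export
write_netmhc_fixture <- function(records, dialect = c("netmhcpan41",
                                                      "netmhciipan41"),
                                 path) {
  dialect <- match.arg(dialect)
  if (nrow(records) > 0L && any(grepl("[[:space:]]", records$antigen_id))) {
    stop("antigen_id must not contain whitespace in engine fixtures",
         call. = FALSE)
  }
  engine_name <- if (dialect == "netmhcpan41") "NetMHCpan version 4.1"
                 else "NetMHCIIpan version 4.1"
  rule <- strrep("-", 110L)
  lines <- c(
    paste0("# ", engine_name, " (synthetic fixture, not engine output)"),
    "# Threshold for Strong binding peptides (%Rank) 0.5",
    rule
  )
  if (dialect == "netmhcpan41") {
    lines <- c(lines,
      sprintf("%5s %18s %15s %11s %3s %11s %15s %10s %9s %s",
              "Pos", "MHC", "Peptide", "Core", "Of", "Icore", "Identity",
              "Score_EL", "%Rank_EL", "BindLevel"),
      rule)
  } else {
    lines <- c(lines,
      sprintf("%5s %28s %15s %3s %11s %9s %15s %10s %9s %s",
              "Pos", "MHC", "Peptide", "Of", "Core", "Core_Rel", "Identity",
              "Score_EL", "%Rank_EL", "BindLevel"),
      rule)
  }
  if (nrow(records) > 0L) {
    of <- vapply(seq_len(nrow(records)), function(i) {
      hit <- regexpr(records$core[i], records$peptide[i], fixed = TRUE)
      if (hit > 0L) as.integer(hit) - 1L else 0L
    }, integer(1L))
    core_start <- records$start
    bind_tag <- ifelse(records$percent_rank < 0.5, "<= SB",
                       ifelse(records$percent_rank < 2.0, "<= WB", ""))
    mhc <- engine_spelling(records$allele, dialect)
    score <- ifelse(is.na(records$score), 0, records$score)
    rows <- if (dialect == "netmhcpan41") {
      sprintf("%5d %18s %15s %11s %3d %11s %15s %10.6f %9s %s",
              core_start - 1L - of, mhc, records$peptide, records$core, of,
              records$core, records$antigen_id, score,
              sprintf("%.17g", records$percent_rank), bind_tag)
    } else {
      sprintf("%5d %28s %15s %3d %11s %9.3f %15s %10.6f %9s %s",
              core_start - of, mhc, records$peptide, of, records$core,
              1.0, records$antigen_id, score,
              sprintf("%.17g", records$percent_rank), bind_tag)
    }
    lines <- c(lines, sub("[[:space:]]+$", "", rows))
  }
  lines <- c(lines, rule)
  writeLines(lines, path)
  invisible(path)
}

#' Write a planted-truth bundle to disk
#'
#' Emits the antigen FASTA, the planted ground truth as JSON, and one
#' fixture file per requested engine dialect — a self-contained simulated
#' input set for an end-to-end pipeline run.
#'
#' @param truth A [plant_motifs()] result.
#' @param panel The [pssm_panel()] the truth was generated against.
#' @param out_dir Output directory (created if needed).
#' @param dialects Engine dialects to emit fixture files for.
#' @param thresholds A [binder_thresholds()] (recorded in the truth JSON).
#' @return Invisible named list of written paths.
#' @export
write_simulation <- function(truth, panel, out_dir,
                             dialects = "netmhciipan41",
                             thresholds = binder_thresholds()) {
  stopifnot(inherits(truth, "planted_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(out_dir, "antigen.fa")
  writeLines(c(paste0(">", truth$antigen$id), truth$antigen$residues), fasta)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(antigen_id = truth$antigen$id, k = truth$k, seed = truth$seed,
         sb_rank = thresholds$sb_rank, wb_rank = thresholds$wb_rank,
         planted = truth$truth),
    truth_path, auto_unbox = TRUE, digits = NA)
  windows <- enumerate_peptides(truth$antigen, k = truth$k)
  records <- predict_binding(windows, names(panel), panel)
  paths <- list(fasta = fasta, truth = truth_path)
  for (d in dialects) {
    p <- file.path(out_dir, paste0("predictions.", d, ".txt"))
    write_netmhc_fixture(records, d, p)
    paths[[d]] <- p
  }
  invisible(paths)
}
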