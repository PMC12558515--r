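# Peptide-MHC binding records: HLA allele naming, strong/weak-binder
# classification by %rank, NetMHC-family output parsing, and the pluggable
# predictor seam.

#' Normalize an HLA allele name
#'
#' Canonical forms are `A*01:01` (class I), `DRB1*15:01` (DR), and the
#' single-hyphen paired alpha-beta forms `DQA1*01:01-DQB1*03:01` /
#' `DPA1*01:03-DPB1*04:01`. Engine spelling variants are accepted:
#' a leading `HLA-` prefix, underscore-compact DR names (`DRB1_1501`),
#' compact paired names (`HLA-DQA10101-DQB10301`), and unstarred class I
#' names (`HLA-A01:01`). Compact numeric fields of 4 digits split 2+2 and of
#' 5 digits split 3+2 (e.g. `DPB110401` is `DPB1*104:01`).
#'
#' @param name Allele name string (vectorized).
#' @return Canonical allele name(s).
#' @export
normalize_hla <- function(name) {
  vapply(name, function(x) {
    x <- trimws(x)
    x <- sub("^HLA-", "", x)
    if (grepl("-", x, fixed = TRUE) || grepl("^(DQA|DPA)", x)) {
      parts <- strsplit(x, "-", fixed = TRUE)[[1L]]
      if (length(parts) != 2L) {
        stop("cannot normalize paired allele name '", name, "'", call. = FALSE)
      }
      return(paste(vapply(parts, normalize_hla_component, character(1L)),
                   collapse = "-"))
    }
    normalize_hla_component(x)
  }, character(1L), USE.NAMES = FALSE)
}

normalize_hla_component <- function(x) {
  x <- sub("^HLA-", "", trimws(x))
  if (grepl("^[A-Z0-9]+\\*[0-9]+:[0-9]+$", x)) return(x)
  # underscore-compact (DRB1_1501) and fully compact (DQA10101) forms
  m <- regmatches(x, regexec("^([A-Z]+[0-9]?)[_]?([0-9]{4,5})$", x))[[1L]]
  if (length(m) == 3L) {
    digits <- m[3L]
    split_at <- nchar(digits) - 2L
    return(paste0(m[2L], "*", substr(digits, 1L, split_at), ":",
                  substr(digits, split_at + 1L, nchar(digits))))
  }
  # unstarred colon form: A01:01
  m <- regmatches(x, regexec("^([A-Z]+[0-9]?)([0-9]{2,3}:[0-9]+)$", x))[[1L]]
  if (length(m) == 3L) return(paste0(m[2L], "*", m[3L]))
  stop("cannot normalize HLA allele name '", x, "'", call. = FALSE)
}

#' Construct an HLA allele descriptor
#'
#' Infers the locus group and MHC class from the (normalized) name. Paired
#' alpha-beta names are required for DQ and DP (class II heterodimers whose
#' binding groove is formed by both chains); a lone `DQB1`/`DPB1` chain is
#' rejected.
#'
#' @param name Allele name in any form accepted by [normalize_hla()].
#' @return An `hla_allele` list with `name`, `locus_group`
#'   (`A`, `B`, `C`, `DRB`, `DQA-DQB` or `DPA-DPB`) and `mhc_class`
#'   (`"I"` or `"II"`).
#' @export
hla_allele <- function(name) {
  canon <- normalize_hla(name)
  locus <- sub("\\*.*$", "", canon)
  if (grepl("-", canon, fixed = TRUE)) {
    loci <- sub("\\*.*$", "", strsplit(canon, "-", fixed = TRUE)[[1L]])
    group <- if (identical(loci, c("DQA1", "DQB1"))) "DQA-DQB"
             else if (identical(loci, c("DPA1", "DPB1"))) "DPA-DPB"
             else stop("unsupported paired loci in '", canon, "'", call. = FALSE)
    cls <- "II"
  } else if (locus %in% c("A", "B", "C")) {
    group <- locus
    cls <- "I"
  } else if (grepl("^DRB[1345]$", locus)) {
    group <- "DRB"
    cls <- "II"
  } else if (grepl("^(DQ|DP)", locus)) {
    stop("allele '", canon, "' is a single DQ/DP chain; paired ",
         "alpha-beta names are required (e.g. DQA1*01:01-DQB1*03:01)",
         call. = FALSE)
  } else {
    stop("cannot determine locus group for allele '", canon, "'",
         call. = FALSE)
  }
  structure(list(name = canon, locus_group = group, mhc_class = cls),
            class = "hla_allele")
}

#' Strong/weak-binder %rank thresholds
#'
#' Strong binders (SB) are predictions with percentile rank strictly below
#' `sb_rank`; weak binders (WB) fall in `[sb_rank, wb_rank)`; everything else
#' is a non-binder (NB). The default SB bound is 0.5% rank for both class I
#' and class II predictions.
#'
#' @param sb_rank Strong-binder %rank bound (default 0.5).
#' @param wb_rank Weak-binder %rank bound (default 2.0).
#' @return A `binder_thresholds` list.
#' @export
binder_thresholds <- function(sb_rank = 0.5, wb_rank = 2.0) {
  stopifnot(is.numeric(sb_rank), is.numeric(wb_rank))
  if (!(sb_rank > 0 && sb_rank < wb_rank)) {
    stop("need 0 < sb_rank < wb_rank (got sb_rank = ", sb_rank,
         ", wb_rank = ", wb_rank, ")", call. = FALSE)
  }
  structure(list(sb_rank = sb_rank, wb_rank = wb_rank),
            class = "binder_thresholds")
}

#' Classify predictions as strong, weak or non-binders
#'
#' Both comparisons are strict: a %rank exactly at a bound falls into the
#' weaker class (rank 0.5 with the default thresholds is WB, not SB).
#'
#' @param percent_rank Numeric vector of %rank values in (0, 100].
#' @param thresholds A [binder_thresholds()].
#' @return Character vector of `"SB"`, `"WB"`, `"NB"`.
#' @export
classify_binder <- function(percent_rank, thresholds = binder_thresholds()) {
  stopifnot(inherits(thresholds, "binder_thresholds"))
  if (any(!is.finite(percent_rank)) || any(percent_rank <= 0) ||
      any(percent_rank > 100)) {
    stop("percent_rank values must lie in (0, 100]", call. = FALSE)
  }
  ifelse(percent_rank < thresholds$sb_rank, "SB",
         ifelse(percent_rank < thresholds$wb_rank, "WB", "NB"))
}

# column layouts of the supported engine output dialects
NETMHC_DIALECTS <- list(
  netmhcpan41 = list(
    columns = c("Pos", "MHC", "Peptide", "Core", "Of", "Icore", "Identity",
                "Score_EL", "%Rank_EL"),
    pos_offset = 1L   # engine Pos is 0-based; +1 gives 1-based peptide start
  ),
  netmhciipan41 = list(
    columns = c("Pos", "MHC", "Peptide", "Of", "Core", "Core_Rel", "Identity",
                "Score_EL", "%Rank_EL"),
    pos_offset = 0L   # engine Pos is already the 1-based peptide start
  )
)

#' Parse NetMHCpan-4.1 / NetMHCIIpan-4.1 tabular output
#'
#' Reads the engines' plain-text result layout (comment lines, a dashed
#' separator, a column-header line, whitespace-separated data rows, optional
#' trailing `<=SB`/`<=WB` bind-level tags) into a normalized record frame.
#' The class I dialect's `Pos` column is taken as 0-based and shifted to
#' 1-based; the class II dialect's as 1-based. The record's `start` is the
#' 1-based start of the reported binding core (`Pos` + frame offset `Of`),
#' so that cores align with this package's peptide-window coordinates even
#' when the engine peptide is longer than the core; such records are flagged
#' `core_shifted`.
#'
#' @param path Path to the result file.
#' @param dialect `"netmhcpan41"` or `"netmhciipan41"`.
#' @return A data.frame of binding records with columns `antigen_id`, `start`
#'   (1-based core start), `peptide`, `core`, `core_shifted`, `allele`
#'   (canonical name), `locus_group`, `percent_rank`, `score`.
#' @export
parse_netmhc_output <- function(path, dialect = c("netmhcpan41",
                                                  "netmhciipan41")) {
  dialect <- match.arg(dialect)
  layout <- NETMHC_DIALECTS[[dialect]]
  lines <- readLines(path)
  is_rule <- grepl("^-{5,}", trimws(lines))
  header_idx <- which(grepl("\\bPos\\b", lines) & grepl("\\bMHC\\b", lines))
  if (length(header_idx) == 0L) {
    stop("no column-header line (Pos/MHC) found in '", path,
         "'; not a recognized NetMHC result file", call. = FALSE)
  }
  header_idx <- header_idx[1L]
  header_cols <- strsplit(trimws(lines[header_idx]), "[[:space:]]+")[[1L]]
  missing_cols <- setdiff(layout$columns, header_cols)
  if (length(missing_cols) > 0L) {
    stop("line ", header_idx, " of '", path, "' does not match the ",
         dialect, " dialect: missing column(s) ",
         paste(missing_cols, collapse = ", "),
         " in header '", trimws(lines[header_idx]), "'", call. = FALSE)
  }
  data_idx <- setdiff(seq(header_idx + 1L, length(lines)),
                      which(is_rule | grepl("^#", lines) |
                            !nzchar(trimws(lines))))
  data_idx <- data_idx[data_idx > header_idx]
  records <- lapply(data_idx, function(i) {
    row <- sub("<=\\s*[SW]B\\s*$", "", trimws(lines[i]))
    fields <- strsplit(row, "[[:space:]]+")[[1L]]
    if (length(fields) < length(header_cols) - 1L) {
      stop("truncated data row at line ", i, " of '", path, "': '",
           trimws(lines[i]), "'", call. = FALSE)
    }
    names(fields) <- header_cols[seq_along(fields)]
    pos <- suppressWarnings(as.integer(fields[["Pos"]]))
    rank <- suppressWarnings(as.numeric(fields[["%Rank_EL"]]))
    if (is.na(pos) || is.na(rank)) {
      stop("unparseable numeric field at line ", i, " of '", path, "'",
           call. = FALSE)
    }
    of <- suppressWarnings(as.integer(fields[["Of"]]))
    allele <- hla_allele(fields[["MHC"]])
    data.frame(
      antigen_id = fields[["Identity"]],
      start = pos + layout$pos_offset + (if (is.na(of)) 0L else of),
      peptide = fields[["Peptide"]],
      core = fields[["Core"]],
      core_shifted = nchar(fields[["Peptide"]]) != nchar(fields[["Core"]]),
      allele = allele$name,
      locus_group = allele$locus_group,
      percent_rank = rank,
      score = suppressWarnings(as.numeric(fields[["Score_EL"]])),
      stringsAsFactors = FALSE
    )
  })
  if (length(records) == 0L) {
    return(data.frame(antigen_id = character(), start = integer(),
                      peptide = character(), core = character(),
                      core_shifted = logical(), allele = character(),
                      locus_group = character(), percent_rank = numeric(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(records, list(make.row.names = FALSE)))
  if (nrow(out) > 0L && (any(out$percent_rank <= 0) ||
                         any(out$percent_rank > 100))) {
    stop("parsed %rank values outside (0, 100] in '", path, "'",
         call. = FALSE)
  }
  out
}

#' Predict binding of peptide windows against an allele panel
#'
#' The pluggable predictor seam: `engine` supplies per-(allele, peptide)
#' %rank values; this package ships a seeded PSSM simulator
#' ([pssm_panel()]) as its built-in engine, and real NetMHC output enters
#' through [parse_netmhc_output()] instead. Produces exactly one record per
#' (window, allele) pair; windows containing `X` are skipped with a message
#' (never silently).
#'
#' @param windows Data frame from [enumerate_peptides()].
#' @param alleles Character vector of allele names to predict for; each must
#'   be supported by the engine.
#' @param engine Prediction engine, e.g. a [pssm_panel()].
#' @param noise_sd Standard deviation of seeded Gaussian score noise
#'   (simulator engines only); 0 gives noise-free deterministic output.
#' @param seed Integer seed for the noise draw; required when `noise_sd > 0`.
#' @return A binding-record data.frame as from [parse_netmhc_output()].
#' @export
predict_binding <- function(windows, alleles, engine, noise_sd = 0,
                            seed = NULL) {
  if (nrow(windows) == 0L) stop("no peptide windows supplied", call. = FALSE)
  if (length(alleles) == 0L) stop("no alleles supplied", call. = FALSE)
  UseMethod("predict_binding", engine)
}

#' @export
predict_binding.default <- function(windows, alleles, engine, noise_sd = 0,
                                    seed = NULL) {
  stop("no predict_binding method for engine of class '",
       paste(class(engine), collapse = "/"), "'", call. = FALSE)
}

#' Write normalized binding records as TSV
#'
#' @param records Binding-record data.frame.
#' @param path Output path.
#' @param thresholds Optional [binder_thresholds()]; when given, a
#'   `binder_class` column is appended.
#' @export
write_records_tsv <- function(records, path,
                              thresholds = binder_thresholds()) {
  out <- records
  if (!is.null(thresholds)) {
    out$binder_class <- classify_binder(out$percent_rank, thresholds)
  }
  writeLines("# binding records; start is the 1-based core start position",
             path)
  suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  invisible(path)
}
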