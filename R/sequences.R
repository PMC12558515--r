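# Antigen protein sequences, substitution variants, peptide window enumeration.
# Coordinates are 1-based inclusive throughout the package, matching the
# residue numbering used for blood-group antigen variants (e.g. p.Val270Gly
# means residue 270 of the mature-protein numbering in the input FASTA).

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter amino-acid code lookup
AA_THREE_TO_ONE <- c(
  Ala = "A", Cys = "C", Asp = "D", Glu = "E", Phe = "F", Gly = "G",
  His = "H", Ile = "I", Lys = "K", Leu = "L", Met = "M", Asn = "N",
  Pro = "P", Gln = "Q", Arg = "R", Ser = "S", Thr = "T", Val = "V",
  Trp = "W", Tyr = "Y"
)

#' Construct a protein sequence record
#'
#' @param id Character identifier for the antigen (e.g. an allele name).
#' @param residues One-letter amino-acid string. Lowercase input is
#'   uppercased. `X` (unknown residue) is tolerated and flagged; gap
#'   characters and anything outside the 20-letter alphabet are rejected.
#'
#' @return An object of class `protein_sequence` with elements `id`,
#'   `residues`, `length` and `has_x`.
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L) {
    stop("protein sequence '", id, "' is empty", call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop("protein sequence '", id, "' contains invalid residue characters: ",
         paste(bad, collapse = " "), call. = FALSE)
  }
  structure(
    list(id = id, residues = residues, length = nchar(residues),
         has_x = any(chars == "X")),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", x$length, " aa",
      if (x$has_x) ", contains X" else "", ")\n", sep = "")
  invisible(x)
}

#' Read antigen protein sequences from a FASTA file
#'
#' Each FASTA record becomes one [protein_sequence()]; identifiers are the
#' full header lines and record order is preserved. Sequences are uppercased;
#' residues outside the amino-acid alphabet (plus `X`) are a format error.
#'
#' @param path Path to a (possibly multi-record) protein FASTA file.
#' @return A named list of `protein_sequence` objects.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  seqs <- lapply(seq_along(set), function(i) {
    protein_sequence(names(set)[i], as.character(set[[i]]))
  })
  names(seqs) <- vapply(seqs, `[[`, character(1L), "id")
  seqs
}

#' Parse an HGVS protein substitution label
#'
#' Accepts the `p.<Aaa><N><Bbb>` form with three-letter amino-acid codes,
#' e.g. `"p.Val270Gly"` for a valine-to-glycine substitution at residue 270.
#'
#' @param label HGVS p. string.
#' @return A `protein_variant` list with `ref`, `position`, `alt` (one-letter
#'   codes and a 1-based residue index) and the original `label`.
#' @export
parse_hgvs_p <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  m <- regmatches(label,
                  regexec("^p\\.([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", label))[[1L]]
  if (length(m) != 4L) {
    stop("cannot parse HGVS p. label: '", label,
         "' (expected form p.Val270Gly)", call. = FALSE)
  }
  ref3 <- m[2L]; pos <- as.integer(m[3L]); alt3 <- m[4L]
  for (code in c(ref3, alt3)) {
    if (!code %in% names(AA_THREE_TO_ONE)) {
      stop("unknown amino-acid code '", code, "' in '", label, "'",
           call. = FALSE)
    }
  }
  if (pos < 1L) {
    stop("non-positive residue position in '", label, "'", call. = FALSE)
  }
  ref <- unname(AA_THREE_TO_ONE[ref3])
  alt <- unname(AA_THREE_TO_ONE[alt3])
  if (ref == alt) {
    stop("reference and alternate residues are identical in '", label, "'",
         call. = FALSE)
  }
  structure(list(ref = ref, position = pos, alt = alt, label = label),
            class = "protein_variant")
}

#' Apply protein substitution variants to a sequence
#'
#' Each variant's reference residue is checked against the sequence before
#' substitution; a mismatch is an error naming the position and both residues.
#' The input object is not modified.
#'
#' @param seq A [protein_sequence()].
#' @param variants A list of variants from [parse_hgvs_p()] (or a single one).
#' @param id Identifier for the derived sequence; default appends the variant
#'   labels to the input id.
#' @return A new `protein_sequence` differing from `seq` exactly at the
#'   variant positions.
#' @export
apply_variants <- function(seq, variants, id = NULL) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (inherits(variants, "protein_variant")) variants <- list(variants)
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  for (v in variants) {
    stopifnot(inherits(v, "protein_variant"))
    if (v$position > seq$length) {
      stop("variant ", v$label, " position ", v$position,
           " exceeds sequence length ", seq$length, call. = FALSE)
    }
    observed <- chars[v$position]
    if (observed != v$ref) {
      stop("reference mismatch for ", v$label, " on '", seq$id,
           "': expected '", v$ref, "' at position ", v$position,
           " but found '", observed, "'", call. = FALSE)
    }
    chars[v$position] <- v$alt
  }
  if (is.null(id)) {
    labels <- vapply(variants, `[[`, character(1L), "label")
    id <- if (length(labels) == 0L) seq$id else
      paste0(seq$id, ":", paste(labels, collapse = ","))
  }
  protein_sequence(id, paste(chars, collapse = ""))
}

#' Enumerate k-mer peptide windows of a protein sequence
#'
#' Produces every window of length `k`, at 1-based start positions
#' `1..length-k+1`, in order. Windows containing `X` are enumerated but
#' flagged so that downstream binding predictors can skip them.
#'
#' @param seq A [protein_sequence()].
#' @param k Window (binding-core) length; default 9, the canonical MHC class
#'   II binding-core length.
#' @param on_short `"warn"` (default) returns an empty frame with a warning
#'   when the sequence is shorter than `k`; `"error"` stops instead.
#' @return A data.frame of peptide windows with columns `antigen_id`, `start`,
#'   `k`, `sequence`, `has_x`.
#' @export
enumerate_peptides <- function(seq, k = 9L, on_short = c("warn", "error")) {
  stopifnot(inherits(seq, "protein_sequence"))
  on_short <- match.arg(on_short)
  k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- seq$length - k + 1L
  if (n < 1L) {
    msg <- paste0("sequence '", seq$id, "' (", seq$length,
                  " aa) is shorter than k = ", k, "; no windows")
    if (on_short == "error") stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    return(data.frame(antigen_id = character(), start = integer(),
                      k = integer(), sequence = character(),
                      has_x = logical(), stringsAsFactors = FALSE))
  }
  starts <- seq_len(n)
  windows <- substring(seq$residues, starts, starts + k - 1L)
  data.frame(
    antigen_id = seq$id,
    start = starts,
    k = k,
    sequence = windows,
    has_x = grepl("X", windows, fixed = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Write peptide windows as TSV
#'
#' Columns: `antigen_id`, `start` (1-based inclusive), `k`, `sequence`.
#'
#' @param windows Data frame from [enumerate_peptides()].
#' @param path Output file path.
#' @export
write_peptides_tsv <- function(windows, path) {
  header <- c("# peptide windows; start is the 1-based inclusive residue index")
  writeLines(header, path)
  suppressWarnings(utils::write.table(
    windows[, c("antigen_id", "start", "k", "sequence")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}
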