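# Per-position strong-binder profiles, hotspot calling, heatmap matrices,
# and per-locus hotspot summaries.

#' Build a per-position strong-binder profile
#'
#' Aggregates one antigen's binding records over an allele panel into a
#' count vector. In `per_start` mode `counts[s]` is the number of distinct
#' panel alleles whose prediction at window start `s` is a strong binder;
#' in `per_residue` mode every strong-binder record increments all `k`
#' residue positions its core covers (useful for topology-coverage
#' analyses).
#'
#' @param records Binding-record data.frame for a single antigen (mixed
#'   antigens are an error). Duplicate (allele, start) rows are an error.
#' @param thresholds A [binder_thresholds()].
#' @param mode `"per_start"` (default) or `"per_residue"`.
#' @param seq_length Antigen length in residues; when `NULL` it is inferred
#'   as `max(start) + k - 1` from the records.
#' @param panel_id Label for the allele panel (e.g. a locus group).
#' @return A `binding_profile` object: `antigen_id`, `panel_id`, `mode`,
#'   `k`, `counts` (1-based integer vector), plus the start-to-core map
#'   used by [call_hotspots()].
#' @export
build_profile <- function(records, thresholds = binder_thresholds(),
                          mode = c("per_start", "per_residue"),
                          seq_length = NULL, panel_id = "panel") {
  mode <- match.arg(mode)
  antigens <- unique(records$antigen_id)
  if (length(antigens) > 1L) {
    stop("records span multiple antigens: ",
         paste(antigens, collapse = ", "),
         "; build one profile per antigen", call. = FALSE)
  }
  key <- paste(records$allele, records$start, sep = "@")
  if (anyDuplicated(key)) {
    stop("duplicate (allele, start) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  k <- if (nrow(records) > 0L) nchar(records$core[1L]) else 9L
  if (is.null(seq_length)) {
    seq_length <- if (nrow(records) > 0L) max(records$start) + k - 1L else k
  }
  n_starts <- seq_length - k + 1L
  sb <- records[classify_binder(records$percent_rank, thresholds) == "SB", ,
                drop = FALSE]
  if (any(sb$start > n_starts)) {
    stop("record start beyond the last window (seq_length too small?)",
         call. = FALSE)
  }
  counts <- integer(if (mode == "per_start") n_starts else seq_length)
  if (nrow(sb) > 0L) {
    if (mode == "per_start") {
      tab <- table(sb$start)
      counts[as.integer(names(tab))] <- as.integer(tab)
    } else {
      for (s in sb$start) {
        idx <- s:(s + k - 1L)
        counts[idx] <- counts[idx] + 1L
      }
    }
  }
  cores <- character(0)
  if (nrow(records) > 0L) {
    first <- !duplicated(records$start)
    cores <- stats::setNames(records$core[first],
                             as.character(records$start[first]))
  }
  structure(
    list(antigen_id = if (length(antigens)) antigens else NA_character_,
         panel_id = panel_id, mode = mode, k = k, counts = counts,
         n_alleles = length(unique(records$allele)), cores = cores),
    class = "binding_profile"
  )
}

#' @export
print.binding_profile <- function(x, ...) {
  cat("<binding_profile> ", x$antigen_id, " / ", x$panel_id,
      " (", x$mode, ", ", length(x$counts), " positions, ",
      sum(x$counts > 0L), " nonzero)\n", sep = "")
  invisible(x)
}

#' Call hotspots from a per-start profile
#'
#' A hotspot is a binding core that is a strong binder for at least
#' `min_alleles` panel alleles. The default `min_alleles = 1` follows the
#' per-peptide hotspot definition (any strong-binding core of the antigen);
#' raise it for stricter panel-level calling.
#'
#' @param profile A `per_start` [build_profile()] result.
#' @param min_alleles Minimum number of strong-binding panel alleles.
#' @return A data.frame of calls (`antigen_id`, `panel_id`, `start`, `core`,
#'   `n_alleles_sb`), ascending by start.
#' @export
call_hotspots <- function(profile, min_alleles = 1L) {
  stopifnot(inherits(profile, "binding_profile"))
  if (profile$mode != "per_start") {
    stop("hotspot calling requires a per_start profile (got ",
         profile$mode, ")", call. = FALSE)
  }
  stopifnot(min_alleles >= 1L)
  starts <- which(profile$counts >= min_alleles)
  data.frame(
    antigen_id = rep(profile$antigen_id, length(starts)),
    panel_id = rep(profile$panel_id, length(starts)),
    start = as.integer(starts),
    core = unname(profile$cores[as.character(starts)]),
    n_alleles_sb = profile$counts[starts],
    stringsAsFactors = FALSE
  )
}

#' Merge adjacent hotspot starts into regions
#'
#' Optional region-level view: consecutive hotspot starts separated by at
#' most `gap` residues are merged into `[start, end]` intervals. Individual
#' cores remain the primary unit of reporting.
#'
#' @param calls Data frame from [call_hotspots()].
#' @param gap Maximum start-to-start gap to bridge (default 0: only directly
#'   adjacent starts merge).
#' @return A data.frame with `start`, `end`, `n_cores`.
#' @export
merge_hotspot_regions <- function(calls, gap = 0L) {
  if (nrow(calls) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      n_cores = integer()))
  }
  s <- sort(unique(calls$start))
  grp <- cumsum(c(1L, diff(s) > gap + 1L))
  do.call(rbind, lapply(split(s, grp), function(x) {
    data.frame(start = min(x), end = max(x), n_cores = length(x))
  }))
}

#' Allele-by-position strong-binder matrix
#'
#' Rows are panel alleles (lexicographic), columns are window start
#' positions (ascending over the starts present in the records). Cells are
#' either a 0/1 strong-binder indicator (`value = "binary"`) or the %rank
#' itself (`value = "rank"`).
#'
#' @param records Single-antigen binding-record data.frame.
#' @param thresholds A [binder_thresholds()].
#' @param value `"binary"` or `"rank"`.
#' @return A numeric matrix with allele row names and start column names.
#' @export
heatmap_matrix <- function(records, thresholds = binder_thresholds(),
                           value = c("binary", "rank")) {
  value <- match.arg(value)
  if (length(unique(records$antigen_id)) > 1L) {
    stop("heatmap_matrix requires records for a single antigen",
         call. = FALSE)
  }
  if (nrow(records) == 0L) {
    warning("no binding records; returning an empty matrix", call. = FALSE)
    return(matrix(numeric(0), nrow = 0L, ncol = 0L))
  }
  alleles <- sort(unique(records$allele))
  starts <- sort(unique(records$start))
  m <- matrix(if (value == "binary") 0 else NA_real_,
              nrow = length(alleles), ncol = length(starts),
              dimnames = list(alleles, as.character(starts)))
  cls <- classify_binder(records$percent_rank, thresholds)
  for (i in seq_len(nrow(records))) {
    r <- records$allele[i]
    s <- as.character(records$start[i])
    m[r, s] <- if (value == "binary") as.numeric(cls[i] == "SB")
               else records$percent_rank[i]
  }
  m
}

#' Count distinct hotspots per antigen and locus group
#'
#' @param calls A data.frame of hotspot calls with columns `antigen`,
#'   `locus_group` and `start` (e.g. a hotspot table read from TSV).
#'   Duplicate starts within an (antigen, locus_group) cell count once.
#' @return A data.frame `antigen`, `locus_group`, `n_hotspots`.
#' @export
summarize_by_locus <- function(calls) {
  required <- c("antigen", "locus_group", "start")
  if (!all(required %in% names(calls))) {
    stop("calls must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(calls) == 0L) {
    return(data.frame(antigen = character(), locus_group = character(),
                      n_hotspots = integer(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(start ~ antigen + locus_group, data = calls,
                          FUN = function(x) length(unique(x)))
  names(agg)[names(agg) == "start"] <- "n_hotspots"
  agg[order(agg$antigen, agg$locus_group), , drop = FALSE]
}

#' Write a profile as two-column TSV (position, count)
#' @param profile A [build_profile()] result.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  writeLines(sprintf("# strong-binder profile: %s / %s (%s mode)",
                     profile$antigen_id, profile$panel_id, profile$mode),
             path)
  suppressWarnings(utils::write.table(
    data.frame(position = seq_along(profile$counts), count = profile$counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}
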