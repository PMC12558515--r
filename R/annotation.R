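# Membrane-topology annotation of hotspot cores and differential hotspot
# analysis between antigen variants.

REGION_LABELS <- c("exofacial", "transmembrane", "intracellular")

#' Construct and validate a membrane-topology map
#'
#' A topology map partitions an antigen's residues 1..length into ordered,
#' non-overlapping exofacial / transmembrane / intracellular intervals
#' (1-based inclusive) with no gaps. Gaps or overlaps are a validation error
#' listing the offending intervals.
#'
#' @param antigen_id Antigen identifier.
#' @param intervals Data frame with columns `start`, `end`, `label`.
#' @return A `topology_map` object.
#' @export
topology_map <- function(antigen_id, intervals) {
  stopifnot(all(c("start", "end", "label") %in% names(intervals)))
  intervals <- intervals[order(intervals$start),
                         c("start", "end", "label"), drop = FALSE]
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  bad_label <- setdiff(unique(intervals$label), REGION_LABELS)
  if (length(bad_label) > 0L) {
    stop("unknown region label(s): ", paste(bad_label, collapse = ", "),
         "; allowed: ", paste(REGION_LABELS, collapse = ", "), call. = FALSE)
  }
  if (any(intervals$end < intervals$start)) {
    stop("interval with end < start in topology map for '", antigen_id, "'",
         call. = FALSE)
  }
  if (nrow(intervals) == 0L || intervals$start[1L] != 1L) {
    stop("topology map for '", antigen_id, "' must start at residue 1",
         call. = FALSE)
  }
  if (nrow(intervals) > 1L) {
    gaps <- which(intervals$start[-1L] != intervals$end[-nrow(intervals)] + 1L)
    if (length(gaps) > 0L) {
      offending <- vapply(gaps, function(i) {
        sprintf("[%d-%d %s] then [%d-%d %s]",
                intervals$start[i], intervals$end[i], intervals$label[i],
                intervals$start[i + 1L], intervals$end[i + 1L],
                intervals$label[i + 1L])
      }, character(1L))
      stop("gap or overlap in topology map for '", antigen_id, "': ",
           paste(offending, collapse = "; "), call. = FALSE)
    }
  }
  rownames(intervals) <- NULL
  structure(list(antigen_id = antigen_id, intervals = intervals,
                 length = intervals$end[nrow(intervals)]),
            class = "topology_map")
}

#' @export
print.topology_map <- function(x, ...) {
  cat("<topology_map> ", x$antigen_id, " (", x$length, " aa, ",
      nrow(x$intervals), " intervals)\n", sep = "")
  invisible(x)
}

#' Read a topology map from a tab-separated interval file
#'
#' Expected columns: `antigen_id`, `start`, `end`, `label`, with 1-based
#' inclusive coordinates (unlike BED's 0-based half-open convention; the
#' packaged fixtures document this in their header comments). Comment lines
#' start with `#`.
#'
#' @param path TSV path.
#' @param antigen_id Optional: select one antigen from a multi-antigen file.
#' @return A `topology_map` (or named list of maps if the file holds several
#'   antigens and `antigen_id` is `NULL`).
#' @export
read_topology_map <- function(path, antigen_id = NULL) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("antigen_id", "start", "end", "label") %in% names(df)))
  if (!is.null(antigen_id)) {
    df <- df[df$antigen_id == antigen_id, , drop = FALSE]
    if (nrow(df) == 0L) {
      stop("no intervals for antigen '", antigen_id, "' in ", path,
           call. = FALSE)
    }
    return(topology_map(antigen_id, df))
  }
  maps <- lapply(split(df, df$antigen_id),
                 function(d) topology_map(d$antigen_id[1L], d))
  if (length(maps) == 1L) maps[[1L]] else maps
}

#' Classify a binding core into a topology region
#'
#' The default `start_residue` rule assigns the label of the interval
#' containing the window's first residue. This is the rule consistent with
#' published hotspot-region tables, where e.g. a core starting at the last
#' residue of an exofacial loop is labelled exofacial even though 8 of its
#' 9 residues lie in the adjacent transmembrane segment. The alternative
#' `majority_overlap` rule labels by the region covering most of the k
#' residues, breaking ties toward exofacial then transmembrane.
#'
#' @param start 1-based window start position(s) (vectorized).
#' @param map A [topology_map()].
#' @param k Window length (used by `majority_overlap` only).
#' @param rule `"start_residue"` (default) or `"majority_overlap"`.
#' @return Character vector of region labels.
#' @export
classify_region <- function(start, map, k = 9L,
                            rule = c("start_residue", "majority_overlap")) {
  rule <- match.arg(rule)
  stopifnot(inherits(map, "topology_map"))
  label_at <- function(pos) {
    hit <- which(map$intervals$start <= pos & map$intervals$end >= pos)
    if (length(hit) == 0L) {
      stop("position ", pos, " outside topology map for '",
           map$antigen_id, "' (1..", map$length, ")", call. = FALSE)
    }
    map$intervals$label[hit[1L]]
  }
  vapply(start, function(s) {
    if (rule == "start_residue") return(label_at(s))
    labels <- vapply(s:(s + k - 1L), label_at, character(1L))
    tab <- table(factor(labels, levels = REGION_LABELS))
    REGION_LABELS[which.max(tab)]   # which.max ties -> first level: exofacial
  }, character(1L))
}

#' Differential hotspot analysis between two antigen variants
#'
#' Partitions the union of hotspot start positions into four sets, keyed on
#' start: `shared` (both lists, identical cores), `changed_core` (both
#' lists, differing core sequences — the same hotspot carrying a
#' substitution), `lost` (reference only) and `gained` (comparator only).
#' For changed cores the absolute protein position of every differing
#' residue (`start + offset - 1`) is reported.
#'
#' @param reference,comparator Hotspot-call data.frames with columns `start`
#'   and `core`, each deduplicated by start.
#' @return A `hotspot_diff` list with elements `shared` (integer starts),
#'   `changed_core` (data.frame `start`, `core_ref`, `core_cmp`,
#'   `diff_positions` as comma-joined absolute positions), `lost`, `gained`.
#' @export
diff_hotspots <- function(reference, comparator) {
  for (nm in list(reference = reference, comparator = comparator)) {
    stopifnot(all(c("start", "core") %in% names(nm)))
  }
  if (anyDuplicated(reference$start) || anyDuplicated(comparator$start)) {
    stop("hotspot lists must be deduplicated by start", call. = FALSE)
  }
  ref_core <- stats::setNames(reference$core, reference$start)
  cmp_core <- stats::setNames(comparator$core, comparator$start)
  both <- sort(as.integer(intersect(reference$start, comparator$start)))
  lost <- sort(as.integer(setdiff(reference$start, comparator$start)))
  gained <- sort(as.integer(setdiff(comparator$start, reference$start)))
  same <- both[ref_core[as.character(both)] == cmp_core[as.character(both)]]
  changed <- setdiff(both, same)
  changed_df <- do.call(rbind, lapply(changed, function(s) {
    a <- strsplit(ref_core[[as.character(s)]], "", fixed = TRUE)[[1L]]
    b <- strsplit(cmp_core[[as.character(s)]], "", fixed = TRUE)[[1L]]
    if (length(a) != length(b)) {
      diffs <- NA_character_
    } else {
      diffs <- paste(s + which(a != b) - 1L, collapse = ",")
    }
    data.frame(start = s,
               core_ref = ref_core[[as.character(s)]],
               core_cmp = cmp_core[[as.character(s)]],
               diff_positions = diffs,
               stringsAsFactors = FALSE)
  }))
  if (is.null(changed_df)) {
    changed_df <- data.frame(start = integer(), core_ref = character(),
                             core_cmp = character(),
                             diff_positions = character(),
                             stringsAsFactors = FALSE)
  }
  structure(list(shared = same, changed_core = changed_df,
                 lost = lost, gained = gained),
            class = "hotspot_diff")
}

#' @export
print.hotspot_diff <- function(x, ...) {
  cat("<hotspot_diff> shared:", length(x$shared),
      " changed_core:", nrow(x$changed_core),
      " lost:", length(x$lost),
      " gained:", length(x$gained), "\n")
  invisible(x)
}

#' Window starts whose core a substitution can alter
#'
#' A substitution at residue `p` changes every k-mer window covering `p`,
#' i.e. starts `max(1, p-k+1) .. min(p, length-k+1)`.
#'
#' @param seq A [protein_sequence()].
#' @param variant A variant from [parse_hgvs_p()].
#' @param k Window length.
#' @return Integer vector of affected 1-based window starts.
#' @export
variant_core_changes <- function(seq, variant, k = 9L) {
  stopifnot(inherits(seq, "protein_sequence"),
            inherits(variant, "protein_variant"))
  p <- variant$position
  if (p > seq$length) {
    stop("variant position ", p, " outside sequence '", seq$id, "' (1..",
         seq$length, ")", call. = FALSE)
  }
  lo <- max(1L, p - k + 1L)
  hi <- min(p, seq$length - k + 1L)
  if (hi < lo) return(integer(0))
  lo:hi
}
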