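# Population HLA allele frequencies: reading AFND-style tables, frequency
# filtering, and frequency-weighted hotspot burden.

#' Read an allele-frequency table (AFND-style CSV)
#'
#' First column `allele`; one column per population holding allele
#' frequencies in decimal form on the 2n-alleles basis; optional
#' `n_<population>` columns carry sample sizes. Blank cells are recorded as
#' `NA` ("not typed in this population"), which is deliberately distinct
#' from an observed frequency of 0.
#'
#' @param path CSV path.
#' @return An `allele_frequency_table`: `frequencies` (data.frame, allele
#'   rows x population columns), `populations`, `sample_sizes`.
#' @export
read_frequency_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  if (!"allele" %in% names(df)) {
    stop("frequency CSV must have an 'allele' first column", call. = FALSE)
  }
  size_cols <- grep("^n_", names(df), value = TRUE)
  pops <- setdiff(names(df), c("allele", size_cols))
  if (length(pops) == 0L) stop("no population columns found", call. = FALSE)
  if (anyDuplicated(pops)) stop("duplicate population columns", call. = FALSE)
  if (anyDuplicated(df$allele)) {
    stop("duplicate allele rows: ",
         paste(unique(df$allele[duplicated(df$allele)]), collapse = ", "),
         call. = FALSE)
  }
  freq <- df[, pops, drop = FALSE]
  for (p in pops) {
    v <- freq[[p]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0L) {
      stop("frequency outside [0, 1] at allele '", df$allele[bad[1L]],
           "', population '", p, "': ", v[bad[1L]], call. = FALSE)
    }
    freq[[p]] <- v
  }
  rownames(freq) <- df$allele
  sizes <- NULL
  if (length(size_cols) > 0L) {
    sizes <- stats::setNames(
      vapply(size_cols, function(cn) as.numeric(df[[cn]][1L]), numeric(1L)),
      sub("^n_", "", size_cols))
  }
  all_absent <- pops[vapply(pops, function(p) all(is.na(freq[[p]])), logical(1L))]
  structure(list(frequencies = freq, populations = pops,
                 sample_sizes = sizes, all_absent = all_absent),
            class = "allele_frequency_table")
}

#' @export
print.allele_frequency_table <- function(x, ...) {
  cat("<allele_frequency_table> ", nrow(x$frequencies), " alleles x ",
      length(x$populations), " populations\n", sep = "")
  invisible(x)
}

#' Look up one population's frequencies
#'
#' @param table An [read_frequency_table()] result.
#' @param population Population column name.
#' @return Named numeric vector (allele -> frequency, `NA` = not typed).
#' @export
population_frequencies <- function(table, population) {
  stopifnot(inherits(table, "allele_frequency_table"))
  if (!population %in% table$populations) {
    stop("unknown population '", population, "'; available: ",
         paste(table$populations, collapse = ", "), call. = FALSE)
  }
  stats::setNames(table$frequencies[[population]],
                  rownames(table$frequencies))
}

#' Filter alleles by population frequency
#'
#' Returns alleles whose frequency in the population exceeds `min_freq`
#' (strict `>` by default, matching the common ">10%" phrasing; set
#' `strict = FALSE` for `>=`), sorted by descending frequency. `NA`
#' (not-typed) frequencies never pass.
#'
#' @param table An [read_frequency_table()] result.
#' @param population Population name.
#' @param min_freq Frequency bound in [0, 1].
#' @param strict Use strict `>` (default) rather than `>=`.
#' @return Character vector of allele names, descending by frequency.
#' @export
filter_by_frequency <- function(table, population, min_freq,
                                strict = TRUE) {
  f <- population_frequencies(table, population)
  keep <- if (strict) which(!is.na(f) & f > min_freq)
          else which(!is.na(f) & f >= min_freq)
  names(sort(f[keep], decreasing = TRUE))
}

#' Frequency-weighted hotspot burden per position
#'
#' For each window start `p`, sums the population frequencies of the panel
#' alleles that have a strong-binder call at `p`:
#' `burden[p] = sum_a f_a * 1[p in SB starts of allele a]`. Alleles absent
#' from the table, or not typed in the chosen population, are skipped with
#' a warning (never silently treated as frequency 0).
#'
#' @param sb_starts Named list: allele name -> integer vector of SB window
#'   starts for that allele.
#' @param table An [read_frequency_table()] result.
#' @param population Population name.
#' @return A `population_burden` list: `population`, `burden` (named numeric
#'   vector over the union of starts, ascending), `skipped` alleles.
#' @export
weighted_hotspot_burden <- function(sb_starts, table, population) {
  f <- population_frequencies(table, population)
  alleles <- names(sb_starts)
  missing <- setdiff(alleles, names(f))
  untyped <- intersect(alleles, names(f)[is.na(f)])
  skipped <- union(missing, untyped)
  if (length(skipped) > 0L) {
    warning("skipping ", length(skipped),
            " allele(s) with no frequency in '", population, "': ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  used <- setdiff(alleles, skipped)
  all_starts <- sort(unique(unlist(sb_starts[used], use.names = FALSE)))
  burden <- stats::setNames(numeric(length(all_starts)),
                            as.character(all_starts))
  for (a in used) {
    hits <- as.character(sb_starts[[a]])
    burden[hits] <- burden[hits] + f[[a]]
  }
  structure(list(population = population, burden = burden,
                 skipped = skipped),
            class = "population_burden")
}

#' @export
print.population_burden <- function(x, ...) {
  cat("<population_burden> ", x$population, ": ", length(x$burden),
      " positions (", length(x$skipped), " alleles skipped)\n", sep = "")
  invisible(x)
}
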