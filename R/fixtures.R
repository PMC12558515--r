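# Accessors for the packaged desk-scale fixtures: the published hotspot
# tables and the reconstructed Rh topology maps.

#' Path to a packaged fixture file
#' @param file File name under the package's `extdata/` directory.
#' @return Absolute path.
#' @export
epihotspot_extdata <- function(file) {
  path <- system.file("extdata", file, package = "epihotspot",
                      mustWork = FALSE)
  if (!nzchar(path)) stop("no packaged fixture '", file, "'", call. = FALSE)
  path
}

#' Packaged hotspot table of the Rh antigens against HLA class II loci
#'
#' The published per-locus hotspot lists (antigen, locus group, 1-based
#' core start, 9-mer core, topology region label), transcribed verbatim
#' including the source table's internal inconsistencies (documented in the
#' file's header comments). Antigen `RHD01` stands for the RhD
#' normal-allele group, `RHD01W1` for weak D type 1 (p.Val270Gly), `RHCE01`
#' for the RhCE reference allele.
#'
#' @return A data.frame with columns `antigen`, `locus_group`, `start`,
#'   `core`, `region`.
#' @export
read_table1_hotspots <- function() {
  utils::read.delim(epihotspot_extdata("table1_hotspots.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged HLA-DRB1 allele-frequency table for four US ethnic groups
#' @return An `allele_frequency_table` (see [read_frequency_table()]).
#' @export
read_table2_frequencies <- function() {
  read_frequency_table(epihotspot_extdata("table2_drb1_frequencies.csv"))
}

#' Packaged per-allele HLA-DRB1 hotspot start positions on the Rh antigens
#'
#' @param antigen Optional filter (`"RHD_normal"`, `"RHD01W1"`, `"RHCE01"`).
#' @return A data.frame `allele`, `antigen`, `starts`, `cores` (semicolon
#'   lists; `NA` = no hotspot for that allele/antigen).
#' @export
read_table2_hotspots <- function(antigen = NULL) {
  df <- utils::read.delim(epihotspot_extdata("table2_drb1_hotspots.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE,
                          fill = TRUE)
  if (!is.null(antigen)) df <- df[df$antigen == antigen, , drop = FALSE]
  df
}

#' Per-allele strong-binder start sets for one antigen
#'
#' Reshapes [read_table2_hotspots()] into the named-list form consumed by
#' [weighted_hotspot_burden()]: allele name -> integer vector of hotspot
#' starts (alleles with no hotspot map to an empty vector).
#'
#' @param antigen One of `"RHD_normal"`, `"RHD01W1"`, `"RHCE01"`.
#' @return Named list of integer vectors.
#' @export
table2_sb_start_sets <- function(antigen) {
  df <- read_table2_hotspots(antigen)
  sets <- lapply(seq_len(nrow(df)), function(i) {
    s <- df$starts[i]
    if (is.na(s) || !nzchar(s)) integer(0)
    else as.integer(strsplit(s, ";", fixed = TRUE)[[1L]])
  })
  stats::setNames(sets, df$allele)
}

#' Packaged (reconstructed) Rh membrane-topology maps
#'
#' Exofacial loops follow the published Rh topology; the transmembrane and
#' intracellular boundaries between them are a one-time constraint fit
#' against the published hotspot Region labels and are marked as
#' reconstructed estimates in the fixture file.
#'
#' @param antigen_id `"RHD01"` or `"RHCE01"`.
#' @return A [topology_map()].
#' @export
read_rh_topology <- function(antigen_id = "RHD01") {
  read_topology_map(epihotspot_extdata("rh_topology.tsv"), antigen_id)
}
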