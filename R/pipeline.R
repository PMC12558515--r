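# End-to-end orchestration: antigens -> predictions -> profiles -> hotspot
# calls -> topology annotation -> variant diffs -> population burden, with a
# reproducibility manifest. Every intermediate is written as a TSV another
# function can consume; rerunning with an identical config and seed
# reproduces byte-identical tables.

#' Build a pipeline run configuration
#'
#' Either supply `fasta` (paths to antigen FASTA files) plus per-antigen
#' `variants`, with predictions from parsed engine `prediction_files`, or
#' set `synthetic` to simulate everything from a seed. Precedence of
#' settings is caller arguments over defaults; the resolved configuration
#' is echoed into the run manifest.
#'
#' @param fasta Character vector of antigen FASTA paths (optional when
#'   `synthetic` is given).
#' @param variants Named list: antigen id -> character vector of HGVS p.
#'   labels to apply (each derived antigen is analyzed alongside its
#'   reference).
#' @param prediction_files Named list: locus group -> list(path, dialect)
#'   of engine result files to parse.
#' @param synthetic `NULL`, or a list with `length`, `n_alleles`, `plants`
#'   (data.frame start/allele index) for a simulated run.
#' @param sb_rank,wb_rank Binder thresholds (%rank).
#' @param min_alleles Hotspot calling threshold.
#' @param topology Path to a topology interval TSV (optional).
#' @param frequencies Path to an allele-frequency CSV (optional).
#' @param populations Populations to compute burden for (default: all in
#'   the frequency table).
#' @param reference_antigen Antigen id used as the reference for
#'   differential hotspot analysis (optional).
#' @param out_dir Output directory.
#' @param seed Integer seed controlling every stochastic step.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(fasta = NULL, variants = list(),
                            prediction_files = list(), synthetic = NULL,
                            sb_rank = 0.5, wb_rank = 2.0, min_alleles = 1L,
                            topology = NULL, frequencies = NULL,
                            populations = NULL, reference_antigen = NULL,
                            out_dir, seed = 1L) {
  for (p in c(fasta, topology, frequencies,
              unlist(lapply(prediction_files, `[[`, "path")))) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configured input does not exist: ", p, call. = FALSE)
    }
  }
  if (is.null(fasta) && is.null(synthetic)) {
    stop("either 'fasta' or 'synthetic' must be configured", call. = FALSE)
  }
  structure(
    list(fasta = fasta, variants = variants,
         prediction_files = prediction_files, synthetic = synthetic,
         thresholds = binder_thresholds(sb_rank, wb_rank),
         min_alleles = as.integer(min_alleles), topology = topology,
         frequencies = frequencies, populations = populations,
         reference_antigen = reference_antigen,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Field names mirror the arguments of [pipeline_config()]; relative paths
#' are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  y$fasta <- resolve(y$fasta)
  y$topology <- resolve(y$topology)
  y$frequencies <- resolve(y$frequencies)
  if (!is.null(y$prediction_files)) {
    y$prediction_files <- lapply(y$prediction_files, function(x) {
      x$path <- resolve(x$path); x
    })
  }
  if (!is.null(y$synthetic) && !is.null(y$synthetic$plants)) {
    y$synthetic$plants <- as.data.frame(y$synthetic$plants)
  }
  do.call(pipeline_config, y)
}

write_tsv_with_header <- function(df, path, comment_lines) {
  writeLines(paste0("# ", comment_lines), path)
  suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, append = TRUE))
  path
}

#' Run the full hotspot pipeline
#'
#' Stages: load (or simulate) antigens, apply variants, enumerate 9-mer
#' windows, obtain binding records (parsed engine files or the seeded
#' simulator), build per-start strong-binder profiles, call hotspots,
#' annotate regions against a topology map, diff every antigen against the
#' reference antigen, and compute population frequency-weighted burden.
#' All outputs are TSV/JSON under `config$out_dir`; the manifest records
#' the resolved configuration, its hash, the seed, the package version and
#' input checksums.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`antigens`,
#'   `records`, `profiles`, `hotspots`, `diffs`, `burdens`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  thresholds <- config$thresholds
  outputs <- character(0)
  provenance <- sprintf("epihotspot %s; seed %d",
                        as.character(utils::packageVersion("epihotspot")),
                        config$seed)

  # --- stage: antigens -------------------------------------------------
  panel <- NULL
  truth <- NULL
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    panel <- pssm_panel(syn$n_alleles, config$seed)
    plants <- as.data.frame(syn$plants)
    if (!"allele" %in% names(plants) && "allele_index" %in% names(plants)) {
      plants$allele <- names(panel)[plants$allele_index]
    }
    truth <- plant_motifs(syn$length, plants, panel, config$seed,
                          thresholds = thresholds)
    antigens <- list(truth$antigen)
    names(antigens) <- truth$antigen$id
  } else {
    antigens <- list()
    for (f in config$fasta) antigens <- c(antigens, read_fasta(f))
  }
  for (aid in names(config$variants)) {
    if (!aid %in% names(antigens)) {
      stop("variants configured for unknown antigen '", aid, "'",
           call. = FALSE)
    }
    vars <- lapply(config$variants[[aid]], parse_hgvs_p)
    derived <- apply_variants(antigens[[aid]], vars)
    antigens[[derived$id]] <- derived
  }

  # --- stage: binding records ------------------------------------------
  if (!is.null(panel)) {
    records_by_locus <- list()
    for (ag in antigens) {
      windows <- enumerate_peptides(ag, k = truth$k)
      rec <- predict_binding(windows, names(panel), panel)
      records_by_locus[["DRB"]] <- rbind(records_by_locus[["DRB"]], rec)
    }
  } else {
    if (length(config$prediction_files) == 0L) {
      stop("no prediction source configured (prediction_files or synthetic)",
           call. = FALSE)
    }
    records_by_locus <- lapply(config$prediction_files, function(x) {
      parse_netmhc_output(x$path, x$dialect)
    })
  }

  # --- stage: profiles, hotspot calls, annotation ----------------------
  topo_maps <- if (!is.null(config$topology)) {
    maps <- read_topology_map(config$topology)
    if (inherits(maps, "topology_map")) {
      stats::setNames(list(maps), maps$antigen_id)
    } else maps
  } else NULL

  profiles <- list()
  hotspot_rows <- list()
  for (locus in names(records_by_locus)) {
    recs <- records_by_locus[[locus]]
    for (aid in unique(recs$antigen_id)) {
      sub <- recs[recs$antigen_id == aid, , drop = FALSE]
      seq_len_a <- if (aid %in% names(antigens)) antigens[[aid]]$length
                   else NULL
      prof <- build_profile(sub, thresholds, mode = "per_start",
                            seq_length = seq_len_a, panel_id = locus)
      key <- paste(aid, locus, sep = "/")
      profiles[[key]] <- prof
      ppath <- file.path(config$out_dir,
                         sprintf("profile_%s_%s.tsv", aid, locus))
      write_tsv_with_header(
        data.frame(position = seq_along(prof$counts), count = prof$counts),
        ppath, c(provenance,
                 sprintf("per-start strong-binder profile: %s / %s",
                         aid, locus)))
      outputs <- c(outputs, ppath)
      m <- heatmap_matrix(sub, thresholds)
      hpath <- file.path(config$out_dir,
                         sprintf("heatmap_%s_%s.tsv", aid, locus))
      write_tsv_with_header(
        data.frame(allele = rownames(m), m, check.names = FALSE),
        hpath, c(provenance,
                 sprintf("binary SB matrix (alleles x starts): %s / %s",
                         aid, locus)))
      outputs <- c(outputs, hpath)
      calls <- call_hotspots(prof, config$min_alleles)
      if (nrow(calls) > 0L && !is.null(topo_maps) &&
          aid %in% names(topo_maps)) {
        calls$region <- classify_region(calls$start, topo_maps[[aid]],
                                        k = prof$k)
      } else {
        calls$region <- rep(NA_character_, nrow(calls))
      }
      calls$locus_group <- rep(locus, nrow(calls))
      hotspot_rows[[key]] <- calls
    }
  }
  hotspots <- do.call(rbind, c(hotspot_rows, list(make.row.names = FALSE)))
  if (is.null(hotspots)) {
    hotspots <- data.frame(antigen_id = character(), panel_id = character(),
                           start = integer(), core = character(),
                           n_alleles_sb = integer(), region = character(),
                           locus_group = character())
  }
  hs_path <- file.path(config$out_dir, "hotspots.tsv")
  write_tsv_with_header(
    hotspots[, c("antigen_id", "locus_group", "start", "core",
                 "n_alleles_sb", "region")],
    hs_path, c(provenance,
               "hotspot calls; start is the 1-based core start position"))
  outputs <- c(outputs, hs_path)

  # --- stage: differential analysis ------------------------------------
  diffs <- list()
  if (!is.null(config$reference_antigen)) {
    ref_id <- config$reference_antigen
    for (locus in unique(hotspots$locus_group)) {
      ref <- hotspots[hotspots$antigen_id == ref_id &
                      hotspots$locus_group == locus, , drop = FALSE]
      for (aid in setdiff(unique(hotspots$antigen_id), ref_id)) {
        cmp <- hotspots[hotspots$antigen_id == aid &
                        hotspots$locus_group == locus, , drop = FALSE]
        d <- diff_hotspots(ref, cmp)
        diffs[[paste(ref_id, aid, locus, sep = "/")]] <- d
        cat_rows <- function(category, start, detail = NULL) {
          data.frame(category = rep(category, length(start)), start = start,
                     detail = if (is.null(detail)) character(length(start))
                              else detail,
                     stringsAsFactors = FALSE)
        }
        rows <- rbind(
          cat_rows("shared", d$shared),
          cat_rows("changed_core", d$changed_core$start,
                   sprintf("%s>%s@%s", d$changed_core$core_ref,
                           d$changed_core$core_cmp,
                           d$changed_core$diff_positions)),
          cat_rows("lost", d$lost),
          cat_rows("gained", d$gained))
        dpath <- file.path(config$out_dir,
                           sprintf("diff_%s_vs_%s_%s.tsv", ref_id, aid,
                                   locus))
        write_tsv_with_header(rows, dpath,
                              c(provenance,
                                sprintf("hotspot diff %s vs %s (%s)",
                                        ref_id, aid, locus)))
        outputs <- c(outputs, dpath)
      }
    }
  }

  # --- stage: population burden ----------------------------------------
  burdens <- list()
  if (!is.null(config$frequencies)) {
    ftab <- read_frequency_table(config$frequencies)
    pops <- if (is.null(config$populations)) ftab$populations
            else config$populations
    for (locus in names(records_by_locus)) {
      recs <- records_by_locus[[locus]]
      cls <- classify_binder(recs$percent_rank, thresholds)
      sb_recs <- recs[cls == "SB", , drop = FALSE]
      sets <- lapply(split(sb_recs$start, sb_recs$allele), unique)
      sets <- sets[intersect(names(sets), rownames(ftab$frequencies))]
      if (length(sets) == 0L) next
      for (pop in pops) {
        b <- suppressWarnings(weighted_hotspot_burden(sets, ftab, pop))
        burdens[[paste(locus, pop, sep = "/")]] <- b
        bpath <- file.path(config$out_dir,
                           sprintf("burden_%s_%s.tsv", locus, pop))
        write_tsv_with_header(
          data.frame(position = as.integer(names(b$burden)),
                     burden = unname(b$burden)),
          bpath, c(provenance,
                   sprintf("frequency-weighted SB burden: %s / %s",
                           locus, pop)))
        outputs <- c(outputs, bpath)
      }
    }
  }

  # --- manifest ---------------------------------------------------------
  input_files <- c(config$fasta, config$topology, config$frequencies,
                   unlist(lapply(config$prediction_files, `[[`, "path")))
  cfg_plain <- unclass(config)
  cfg_plain$thresholds <- unclass(cfg_plain$thresholds)
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file), add = TRUE)
  saveRDS(cfg_plain, cfg_file)
  manifest <- list(
    tool = "epihotspot",
    version = as.character(utils::packageVersion("epihotspot")),
    seed = config$seed,
    config = cfg_plain,
    config_hash = unname(tools::md5sum(cfg_file)),
    input_checksums = if (length(input_files) > 0L)
      as.list(tools::md5sum(input_files)) else list(),
    outputs = basename(outputs)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(antigens = antigens, records = records_by_locus,
                 profiles = profiles, hotspots = hotspots, diffs = diffs,
                 burdens = burdens, truth = truth, manifest = manifest))
}
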