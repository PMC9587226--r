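# End-to-end orchestration: catalog -> regions -> patches -> differential ->
# occupancy, with per-stage logging, written stage tables, a summary, and a
# machine-readable run manifest. The pipeline itself draws no random numbers,
# so identical inputs give byte-identical outputs.

#' Pipeline configuration
#'
#' @param proteome_fasta,features_tsv,psm_tsv Paths to the proteome FASTA,
#'   feature table and PSM table (required).
#' @param protein_tsv Optional path to the non-enriched protein
#'   quantification table (enables the abundance filter).
#' @param peak_tsv Optional path to the MS1 peak table (enables the
#'   occupancy stage).
#' @param out_dir Output directory.
#' @param wt_label Wild-type condition label (default "WT").
#' @param params Named list of per-stage parameter overrides
#'   (`prob_cutoff`, `stem_window`, `linker_max`, `terminus_window`,
#'   `patch_window`, `patch_min_sites`, `alpha`, `down_fc`, `up_fc`,
#'   `ppm_window`, `idotp_min`, `rt_window_min`, `min_id_score`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(proteome_fasta, features_tsv, psm_tsv,
                            protein_tsv = NULL, peak_tsv = NULL,
                            out_dir = tempfile("oglyco_run_"),
                            wt_label = "WT", params = list()) {
  defaults <- list(prob_cutoff = 95, stem_window = 50, linker_max = 100,
                   terminus_window = 10, patch_window = 25,
                   patch_min_sites = 5, alpha = 0.05, down_fc = 0.5,
                   up_fc = 2, ppm_window = 1.5, idotp_min = 0.85,
                   rt_window_min = 5, min_id_score = 200)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stopf("unknown parameter(s): %s",
                             paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  cfg <- list(proteome_fasta = proteome_fasta, features_tsv = features_tsv,
              psm_tsv = psm_tsv, protein_tsv = protein_tsv,
              peak_tsv = peak_tsv, out_dir = out_dir, wt_label = wt_label,
              params = defaults)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Reads all inputs, runs catalog, region, patch, differential and (when a
#' peak table is configured) occupancy stages in order, writes each stage
#' table plus a summary TSV and a JSON run manifest to the output directory,
#' and audits the summary against a recount from the written tables.
#'
#' @param config A [pipeline_config()], or a path to a `key = value` config
#'   file with entries named as the [pipeline_config()] arguments.
#' @param dry_run Validate inputs only; run no stage.
#' @return Invisibly, a list with the stage results and `summary`.
#' @export
run_pipeline <- function(config, dry_run = FALSE) {
  if (is.character(config)) {
    kv <- read_config(config)
    config <- pipeline_config(
      proteome_fasta = kv$proteome_fasta, features_tsv = kv$features_tsv,
      psm_tsv = kv$psm_tsv, protein_tsv = kv$protein_tsv,
      peak_tsv = kv$peak_tsv,
      out_dir = if (!is.null(kv$out_dir)) kv$out_dir else tempfile("oglyco_run_"),
      wt_label = if (!is.null(kv$wt_label)) kv$wt_label else "WT")
  }
  stopifnot(inherits(config, "pipeline_config"))
  p <- config$params
  for (f in c(config$proteome_fasta, config$features_tsv, config$psm_tsv,
              config$protein_tsv, config$peak_tsv))
    if (!is.null(f) && !file.exists(f)) stopf("input not found: %s", f)
  if (dry_run) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logmsg <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  proteome <- stage("io", read_fasta(config$proteome_fasta))
  features <- stage("io", read_features(config$features_tsv))
  psms <- stage("io", read_psm_table(config$psm_tsv))
  logmsg("input: %d proteins, %d features, %d PSMs", nrow(proteome),
         nrow(features), nrow(psms))

  catalog <- stage("catalog", build_catalog(psms, proteome,
                                            prob_cutoff = p$prob_cutoff))
  write_site_catalog(catalog, file.path(config$out_dir, "site_catalog.tsv"))
  logmsg("catalog: %d sites (%d unambiguous) on %d proteins (prob_cutoff=%g)",
         nrow(catalog), sum(catalog$status == "unambiguous"),
         length(unique(catalog$accession)), p$prob_cutoff)

  assignments <- stage("regions", classify_sites(
    catalog, proteome, features, stem_window = p$stem_window,
    linker_max = p$linker_max, terminus_window = p$terminus_window))
  region_sum <- summarize_regions(assignments, total = nrow(catalog))
  write_tsv(assignments, file.path(config$out_dir, "region_assignments.tsv"),
            "region_assignments")
  dstats <- stage("regions", domain_statistics(catalog, proteome, features))
  write_tsv(dstats, file.path(config$out_dir, "domain_stats.tsv"),
            "domain_stats")

  patches <- stage("patches", rank_patches(find_patches(
    catalog, window = p$patch_window, min_sites = p$patch_min_sites)))
  write_patches(patches, file.path(config$out_dir, "patches.tsv"))
  logmsg("patches: %d found (window=%g, min_sites=%g)", nrow(patches),
         p$patch_window, p$patch_min_sites)

  site_tab <- stage("differential", {
    st <- site_quant_table(psms, prob_cutoff = p$prob_cutoff)
    normalize_total(st)
  })
  protein_tab <- NULL
  if (!is.null(config$protein_tsv)) {
    protein_tab <- stage("io", normalize_total(read_tsv(config$protein_tsv)))
  }
  channels <- channel_columns(site_tab)
  kos <- setdiff(unique(channel_condition(channels)), config$wt_label)
  diff <- stage("differential", differential_panel(
    site_tab, config$wt_label, kos, protein_table = protein_tab,
    alpha = p$alpha, down_fc = p$down_fc, up_fc = p$up_fc))
  write_regulation(diff$calls, file.path(config$out_dir, "regulation.tsv"))
  dsum <- summary(diff)
  logmsg("differential: %d contrasts, %d sites down, %d isoform-specific",
         length(kos), attr(dsum, "n_down_any"),
         attr(dsum, "n_isoform_specific"))

  occ <- NULL
  occ_classes <- NULL
  if (!is.null(config$peak_tsv)) {
    peaks <- stage("io", read_peak_table(config$peak_tsv))
    flt <- stage("occupancy", filter_peaks(
      peaks, ppm_window = p$ppm_window, idotp_min = p$idotp_min,
      rt_window_min = p$rt_window_min, min_id_score = p$min_id_score))
    logmsg("peak filter: %d accepted, %d rejected", nrow(flt$accepted),
           nrow(flt$rejected))
    occ <- stage("occupancy", occupancy_table(flt$accepted))
    occ_classes <- classify_occupancy(occ)
    write_occupancy(occ, file.path(config$out_dir, "occupancy.tsv"))
  } else {
    logmsg("occupancy: skipped (no peak table configured)")
  }

  summary_df <- data.frame(
    metric = c("total_sites", "unambiguous_sites", "glycoproteins",
               paste0("pct_", region_sum$category),
               "patch_count", "max_patch_size",
               "sites_down_any", "isoform_specific_sites",
               "occupancy_regions", "occupancy_pct_high"),
    value = c(nrow(catalog), sum(catalog$status == "unambiguous"),
              length(unique(catalog$accession)), region_sum$pct,
              nrow(patches), if (nrow(patches)) max(patches$n_sites) else 0,
              attr(dsum, "n_down_any"), attr(dsum, "n_isoform_specific"),
              if (is.null(occ)) NA else nrow(occ),
              if (is.null(occ_classes)) NA else
                round(100 * occ_classes$fraction[occ_classes$class == "high"], 1)),
    stringsAsFactors = FALSE)
  write_tsv(summary_df, file.path(config$out_dir, "summary.tsv"), "summary")

  # audit: summary counts must equal a recount from the written tables
  cat_rt <- read_site_catalog(file.path(config$out_dir, "site_catalog.tsv"))
  pat_rt <- read_patches(file.path(config$out_dir, "patches.tsv"))
  reg_rt <- read_regulation(file.path(config$out_dir, "regulation.tsv"))
  stopifnot(nrow(cat_rt) == nrow(catalog),
            nrow(pat_rt) == nrow(patches),
            length(unique(reg_rt$site_key[reg_rt$call == "down"])) ==
              attr(dsum, "n_down_any"))

  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "out_dir")],
                               auto_unbox = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(package = "oglyco",
                   version = as.character(utils::packageVersion("oglyco")),
                   parameters = p, wt_label = config$wt_label,
                   config_hash = unname(tools::md5sum(tmp)),
                   log = log_lines)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  invisible(list(catalog = catalog, assignments = assignments,
                 region_summary = region_sum, domain_stats = dstats,
                 patches = patches, differential = diff, occupancy = occ,
                 occupancy_classes = occ_classes, summary = summary_df,
                 out_dir = config$out_dir))
}
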