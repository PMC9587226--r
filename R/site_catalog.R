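# Glycosite catalog construction.
#
# Site localization rests on ETD spectra only: a peptide-relative position
# whose ptmRS-style probability exceeds the cutoff (default 95%) maps to an
# unambiguous protein-coordinate site; glycans that cannot be placed above
# the cutoff are retained as ambiguous sites spanning the peptide's S/T/Y
# range rather than dropped. Reporter quantification uses the HCD spectrum of
# the same precursor as the highest-scoring ETD PSM per glycopeptide.

glycopeptide_key <- function(psms) {
  paste(psms$accession, psms$pep_start, psms$pep_end, psms$peptide, sep = "|")
}

#' Build a non-redundant glycosite catalog from PSMs
#'
#' Only ETD PSMs contribute localization. For each ETD PSM, positions with
#' probability strictly above `prob_cutoff` become unambiguous sites at
#' protein coordinate `pep_start + pos - 1`; unplaced glycans (hexnac_count
#' minus localized positions) each yield one ambiguous site whose range is
#' the peptide's S/T/Y span. Duplicate (accession, position) entries are
#' merged, PSM support summed, and the best-scoring supporting PSM retained.
#'
#' @param psms PSM data frame ([read_psm_table()] or the simulator).
#' @param proteome Proteome data frame (`accession`, `sequence`).
#' @param prob_cutoff Localization probability cutoff, percent (default 95;
#'   sites require probability > cutoff).
#' @return A `glyco_catalog` data frame: `accession`, `position` (NA for
#'   ambiguous sites), `residue`, `status` (unambiguous/ambiguous),
#'   `amb_start`/`amb_end` (NA for unambiguous), `n_psms`, `best_psm`
#'   (psm_id), `best_score`.
#' @export
build_catalog <- function(psms, proteome, prob_cutoff = 95) {
  etd <- psms[psms$frag_type == "ETD", , drop = FALSE]
  seqs <- proteome$sequence
  names(seqs) <- proteome$accession
  unamb <- new.env(parent = emptyenv())
  amb <- new.env(parent = emptyenv())
  upsert <- function(env, key, entry) {
    if (exists(key, envir = env)) {
      cur <- get(key, envir = env)
      cur$n_psms <- cur$n_psms + 1L
      if (entry$best_score > cur$best_score) {
        cur$best_psm <- entry$best_psm
        cur$best_score <- entry$best_score
      }
      assign(key, cur, envir = env)
    } else assign(key, entry, envir = env)
  }
  for (i in seq_len(nrow(etd))) {
    acc <- etd$accession[i]
    if (!acc %in% names(seqs))
      stopf("PSM %s references unknown accession '%s'", etd$psm_id[i], acc)
    pep <- etd$peptide[i]
    ref <- substr(seqs[[acc]], etd$pep_start[i], etd$pep_end[i])
    if (!identical(ref, pep))
      stopf("PSM %s: peptide does not match protein %s at %d..%d",
            etd$psm_id[i], acc, etd$pep_start[i], etd$pep_end[i])
    pos <- split_num(etd$site_positions[i])
    prob <- split_num(etd$site_probabilities[i])
    loc <- pos[prob > prob_cutoff]
    for (p in loc) {
      prot_pos <- etd$pep_start[i] + p - 1L
      res <- substr(seqs[[acc]], prot_pos, prot_pos)
      if (!res %in% c("S", "T", "Y"))
        stopf("PSM %s: localized residue at %s:%d is '%s', not S/T/Y",
              etd$psm_id[i], acc, prot_pos, res)
      upsert(unamb, paste(acc, prot_pos),
             list(accession = acc, position = as.integer(prot_pos),
                  residue = res, n_psms = 1L,
                  best_psm = etd$psm_id[i], best_score = etd$psm_score[i]))
    }
    n_unplaced <- etd$hexnac_count[i] - length(loc)
    if (n_unplaced > 0) {
      pep_chr <- strsplit(pep, "")[[1]]
      sty <- which(pep_chr %in% c("S", "T", "Y"))
      if (length(sty) == 0)
        stopf("PSM %s: glycan on peptide without S/T/Y", etd$psm_id[i])
      a_start <- etd$pep_start[i] + min(sty) - 1L
      a_end <- etd$pep_start[i] + max(sty) - 1L
      for (k in seq_len(n_unplaced))
        upsert(amb, paste(acc, a_start, a_end, k),
               list(accession = acc, amb_start = as.integer(a_start),
                    amb_end = as.integer(a_end), n_psms = 1L,
                    best_psm = etd$psm_id[i], best_score = etd$psm_score[i]))
    }
  }
  to_df <- function(env, ambiguous) {
    entries <- mget(ls(envir = env), envir = env)
    if (length(entries) == 0) return(NULL)
    if (ambiguous) {
      data.frame(accession = vapply(entries, `[[`, character(1), "accession"),
                 position = NA_integer_, residue = NA_character_,
                 status = "ambiguous",
                 amb_start = vapply(entries, `[[`, integer(1), "amb_start"),
                 amb_end = vapply(entries, `[[`, integer(1), "amb_end"),
                 n_psms = vapply(entries, `[[`, integer(1), "n_psms"),
                 best_psm = vapply(entries, `[[`, numeric(1), "best_psm"),
                 best_score = vapply(entries, `[[`, numeric(1), "best_score"),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(accession = vapply(entries, `[[`, character(1), "accession"),
                 position = vapply(entries, `[[`, integer(1), "position"),
                 residue = vapply(entries, `[[`, character(1), "residue"),
                 status = "unambiguous", amb_start = NA_integer_,
                 amb_end = NA_integer_,
                 n_psms = vapply(entries, `[[`, integer(1), "n_psms"),
                 best_psm = vapply(entries, `[[`, numeric(1), "best_psm"),
                 best_score = vapply(entries, `[[`, numeric(1), "best_score"),
                 stringsAsFactors = FALSE)
    }
  }
  out <- rbind(to_df(unamb, FALSE), to_df(amb, TRUE))
  if (is.null(out))
    out <- data.frame(accession = character(0), position = integer(0),
                      residue = character(0), status = character(0),
                      amb_start = integer(0), amb_end = integer(0),
                      n_psms = integer(0), best_psm = numeric(0),
                      best_score = numeric(0))
  out <- out[order(out$accession, out$position, out$amb_start), ]
  rownames(out) <- NULL
  class(out) <- c("glyco_catalog", "data.frame")
  out
}

#' @export
print.glyco_catalog <- function(x, ...) {
  n_un <- sum(x$status == "unambiguous")
  n_am <- sum(x$status == "ambiguous")
  cat(sprintf("O-glycosite catalog: %d sites (%d unambiguous, %d ambiguous) on %d proteins\n",
              nrow(x), n_un, n_am, length(unique(x$accession))))
  if (n_un + n_am > 0)
    cat(sprintf("  unambiguous fraction: %.1f%%\n", 100 * n_un / nrow(x)))
  NextMethod()
}

#' Select the quantification PSM for one glycopeptide
#'
#' Reporter quantification uses the HCD spectrum of the same precursor as the
#' highest-scoring ETD PSM of the glycopeptide; ties break by input order. If
#' the chosen precursor has no HCD partner, the ETD record's intensities are
#' used.
#'
#' @param psms PSM rows (ETD and HCD) of a single glycopeptide.
#' @return One PSM row, or `NULL` (with a message attribute) when the
#'   glycopeptide has no ETD PSM and is therefore excluded from
#'   quantification.
#' @export
select_quant_psm <- function(psms) {
  etd <- psms[psms$frag_type == "ETD", , drop = FALSE]
  if (nrow(etd) == 0) return(NULL)
  best <- etd[which.max(etd$psm_score), , drop = FALSE]
  hcd <- psms[psms$frag_type == "HCD" &
                psms$precursor_id == best$precursor_id, , drop = FALSE]
  if (nrow(hcd) >= 1) hcd[1, , drop = FALSE] else best
}

#' Split glycopeptides into single-site and multi-site sets
#'
#' Site-level quantification is restricted to glycopeptides carrying a single
#' glycan in every supporting PSM. Peptides with mixed or multi-glycan
#' evidence can only be quantified at the peptide level and are routed to a
#' separate table.
#'
#' @param psms PSM data frame.
#' @return List with `single_site` and `multi_site` PSM data frames.
#' @export
single_site_filter <- function(psms) {
  key <- glycopeptide_key(psms)
  max_glycans <- tapply(psms$hexnac_count, key, max)
  single_keys <- names(max_glycans)[max_glycans == 1]
  sel <- key %in% single_keys
  list(single_site = psms[sel, , drop = FALSE],
       multi_site = psms[!sel, , drop = FALSE])
}

#' Build the site-level quantification table
#'
#' For every single-site glycopeptide, picks the quantification PSM via
#' [select_quant_psm()] and keys its reporter intensities by the site it
#' supports: the localized protein coordinate when the localization
#' probability clears the cutoff, otherwise the ambiguous S/T/Y range.
#' Glycopeptides supporting the same site are merged by keeping the
#' best-scoring quantification PSM.
#'
#' @param psms PSM data frame.
#' @param prob_cutoff Localization cutoff (percent), as in [build_catalog()].
#' @return Data frame with `site_key`, `accession`, `position` (NA when
#'   ambiguous) and one column per channel.
#' @export
site_quant_table <- function(psms, prob_cutoff = 95) {
  ss <- single_site_filter(psms)$single_site
  channels <- channel_columns(ss)
  key <- glycopeptide_key(ss)
  rows <- list()
  for (k in unique(key)) {
    grp <- ss[key == k, , drop = FALSE]
    q <- select_quant_psm(grp)
    if (is.null(q)) next
    etd <- grp[grp$frag_type == "ETD", , drop = FALSE]
    best <- etd[which.max(etd$psm_score), ]
    pos <- split_num(best$site_positions)
    prob <- split_num(best$site_probabilities)
    loc <- pos[prob > prob_cutoff]
    if (length(loc) >= 1) {
      position <- best$pep_start + loc[1] - 1L
      site_key <- paste0(best$accession, ":", position)
    } else {
      position <- NA_integer_
      site_key <- paste0(best$accession, ":", best$pep_start, "-",
                         best$pep_end)
    }
    row <- data.frame(site_key = site_key, accession = best$accession,
                      position = position, quant_score = best$psm_score,
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (ch in channels) row[[ch]] <- q[[ch]]
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  # merge glycopeptides supporting the same site: keep best-scoring record
  out <- out[order(out$site_key, -out$quant_score), ]
  out <- out[!duplicated(out$site_key), ]
  out$quant_score <- NULL
  rownames(out) <- NULL
  out
}

#' Compare two glycosite catalogs
#'
#' Reports protein- and site-level intersections as percentages of catalog
#' `b` (site level uses unambiguous sites), plus counts unique to each.
#'
#' @param a,b `glyco_catalog` data frames over the same proteome.
#' @return List of class `catalog_overlap`.
#' @export
compare_catalogs <- function(a, b) {
  prot_a <- unique(a$accession)
  prot_b <- unique(b$accession)
  sa <- a[a$status == "unambiguous", ]
  sb <- b[b$status == "unambiguous", ]
  site_a <- paste(sa$accession, sa$position)
  site_b <- paste(sb$accession, sb$position)
  out <- list(protein_overlap_pct = pct1(length(intersect(prot_a, prot_b)),
                                         length(prot_b)),
              site_overlap_pct = pct1(length(intersect(site_a, site_b)),
                                      length(site_b)),
              n_proteins_a = length(prot_a), n_proteins_b = length(prot_b),
              n_sites_a = length(site_a), n_sites_b = length(site_b),
              proteins_only_a = length(setdiff(prot_a, prot_b)),
              proteins_only_b = length(setdiff(prot_b, prot_a)),
              sites_only_a = length(setdiff(site_a, site_b)),
              sites_only_b = length(setdiff(site_b, site_a)))
  class(out) <- "catalog_overlap"
  out
}

#' @export
print.catalog_overlap <- function(x, ...) {
  cat(sprintf("Catalog overlap relative to b: proteins %.1f%%, sites %.1f%%\n",
              x$protein_overlap_pct, x$site_overlap_pct))
  cat(sprintf("  a: %d proteins / %d sites (%d / %d unique)\n",
              x$n_proteins_a, x$n_sites_a, x$proteins_only_a, x$sites_only_a))
  cat(sprintf("  b: %d proteins / %d sites (%d / %d unique)\n",
              x$n_proteins_b, x$n_sites_b, x$proteins_only_b, x$sites_only_b))
  invisible(x)
}
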