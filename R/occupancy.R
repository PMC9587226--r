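# MS1-based O-glycosylation site-occupancy estimation.
#
# Occupancy of a peptide region is the total-area ratio
#   [sum of glycoform areas] / [sum of glycoform areas + non-glycosylated area]
# computed per replicate after charge states are summed within glycoform.
# When the non-glycosylated form is not detected in any replicate the ratio
# is reported as the High flag instead of a number. xTn percentages are each
# glycoform's share of the glycoform-only total.

#' Filter MS1 glycoform peaks on acceptance criteria
#'
#' Keeps peaks with mass error strictly inside (-ppm_window, +ppm_window),
#' isotopic dot product strictly above `idotp_min`, retention-time offset
#' strictly within `rt_window_min` minutes, and identification score at
#' least `min_id_score`. When an `iso_rel_abund` column is present (peaks
#' resolved to isotopologue level), relative abundance must exceed
#' `iso_rel_abund_min`. Rejected peaks are returned with reason codes.
#'
#' @param peaks Peak data frame ([read_peak_table()] or the simulator).
#' @param ppm_window Mass-error half-window in ppm (default 1.5, exclusive).
#' @param idotp_min Minimum isotopic dot product (default 0.85, exclusive).
#' @param rt_window_min Retention-time half-window in minutes (default 5,
#'   exclusive).
#' @param iso_rel_abund_min Minimum isotopologue relative abundance
#'   (default 20, exclusive; only applied when the column exists).
#' @param min_id_score Minimum identification score (default 200, inclusive).
#' @return List with `accepted` and `rejected` (with a `reason` column of
#'   semicolon-joined codes).
#' @export
filter_peaks <- function(peaks, ppm_window = 1.5, idotp_min = 0.85,
                         rt_window_min = 5, iso_rel_abund_min = 20,
                         min_id_score = 200) {
  n <- nrow(peaks)
  fail <- matrix(FALSE, n, 5,
                 dimnames = list(NULL, c("ppm", "idotp", "rt", "id_score",
                                         "iso_rel_abund")))
  fail[, "ppm"] <- !(abs(peaks$mass_error_ppm) < ppm_window)
  fail[, "idotp"] <- !(peaks$idotp > idotp_min)
  fail[, "rt"] <- !(abs(peaks$rt_delta_min) < rt_window_min)
  fail[, "id_score"] <- !(peaks$id_score >= min_id_score)
  if ("iso_rel_abund" %in% names(peaks))
    fail[, "iso_rel_abund"] <- !is.na(peaks$iso_rel_abund) &
      !(peaks$iso_rel_abund > iso_rel_abund_min)
  bad <- rowSums(fail) > 0
  reason <- apply(fail, 1, function(f)
    paste(colnames(fail)[f], collapse = ";"))
  rejected <- peaks[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[bad]
  list(accepted = peaks[!bad, , drop = FALSE], rejected = rejected)
}

# Per-replicate areas of one region: charge states (and duplicate rows)
# summed within glycoform.
replicate_areas <- function(peaks) {
  lapply(split(peaks, peaks$replicate), function(p)
    tapply(p$area, p$glycoform, sum))
}

#' Compute the occupancy record for one peptide region
#'
#' @param peaks Accepted peaks of a single peptide region (all replicates).
#' @return List of class `occupancy_record`: `glyco_ratio` (mean over
#'   replicates, NA when `high_flag`), `sd`, `high_flag` (non-glycosylated
#'   form detected in no replicate), `partial_flag` (detected in some but
#'   not all replicates; ratio uses detected replicates only), `tn_max`,
#'   `xtn_percent` (integer-rounded, per glycan count 1..tn_max),
#'   `xtn_percent_raw`, `n_replicates`, plus the region identity columns.
#'   Returns `NULL` with a warning when the region has no glycoform peaks.
#' @export
compute_occupancy <- function(peaks) {
  if (nrow(peaks[peaks$glycoform > 0, , drop = FALSE]) == 0) {
    warning("region has no glycoform peaks; skipped")
    return(NULL)
  }
  by_rep <- replicate_areas(peaks)
  tn_max <- max(peaks$glycoform)
  has_ng <- vapply(by_rep, function(a) "0" %in% names(a), logical(1))
  high_flag <- !any(has_ng)
  ratios <- numeric(0)
  if (!high_flag) {
    ratios <- vapply(by_rep[has_ng], function(a) {
      g <- sum(a[names(a) != "0"])
      g / (g + a[["0"]])
    }, numeric(1))
  }
  # xTn shares over the glycoform-only total, averaged across replicates
  xtn_mat <- do.call(rbind, lapply(by_rep, function(a) {
    g <- a[names(a) != "0"]
    out <- stats::setNames(rep(0, tn_max), as.character(seq_len(tn_max)))
    if (length(g) && sum(g) > 0) out[names(g)] <- g / sum(g)
    out
  }))
  xtn_raw <- 100 * colMeans(xtn_mat)
  out <- list(accession = peaks$accession[1],
              region_id = if ("region_id" %in% names(peaks))
                peaks$region_id[1] else NA_character_,
              pep_start = peaks$pep_start[1], pep_end = peaks$pep_end[1],
              peptide = peaks$peptide[1], tn_max = tn_max,
              glyco_ratio = if (high_flag) NA_real_ else mean(ratios),
              sd = if (length(ratios) >= 2) stats::sd(ratios) else NA_real_,
              high_flag = high_flag,
              partial_flag = !high_flag && !all(has_ng),
              n_replicates = length(by_rep),
              xtn_percent = round(xtn_raw),
              xtn_percent_raw = xtn_raw)
  class(out) <- "occupancy_record"
  out
}

#' @export
print.occupancy_record <- function(x, ...) {
  ratio <- if (x$high_flag) "High" else
    sprintf("%.2f +/- %s", x$glyco_ratio,
            if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd))
  cat(sprintf("[%d]%s[%d] (%s): glyco ratio %s; xTn%%: %s\n",
              x$pep_start, x$peptide, x$pep_end, x$accession, ratio,
              paste(x$xtn_percent, collapse = "/")))
  invisible(x)
}

#' Occupancy table over all regions of a peak set
#'
#' Applies [compute_occupancy()] per region (regions keyed by `region_id`
#' when present, else by accession/coordinates) and assembles a table in
#' bracket-coordinate peptide notation.
#'
#' @param peaks Accepted peaks (after [filter_peaks()]).
#' @return Data frame of class `occupancy_table`: one row per region with
#'   `glyco_ratio` (NA when High), `sd`, `high_flag`, `partial_flag`,
#'   `tn_max`, `xtn_percent` (semicolon list, integer-rounded) and
#'   `xtn_percent_raw` (full precision).
#' @export
occupancy_table <- function(peaks) {
  key <- if ("region_id" %in% names(peaks)) peaks$region_id
         else paste(peaks$accession, peaks$pep_start, peaks$pep_end)
  rows <- list()
  for (k in unique(key)) {
    rec <- compute_occupancy(peaks[key == k, , drop = FALSE])
    if (is.null(rec)) next
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = rec$region_id, accession = rec$accession,
      pep_start = rec$pep_start, pep_end = rec$pep_end,
      peptide = rec$peptide, tn_max = rec$tn_max,
      glyco_ratio = rec$glyco_ratio, sd = rec$sd,
      high_flag = rec$high_flag, partial_flag = rec$partial_flag,
      n_replicates = rec$n_replicates,
      xtn_percent = join_num(rec$xtn_percent),
      xtn_percent_raw = join_num(signif(rec$xtn_percent_raw, 10)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(0), accession = character(0),
               pep_start = integer(0), pep_end = integer(0),
               peptide = character(0), tn_max = integer(0),
               glyco_ratio = numeric(0), sd = numeric(0),
               high_flag = logical(0), partial_flag = logical(0),
               n_replicates = integer(0), xtn_percent = character(0),
               xtn_percent_raw = character(0))
  rownames(out) <- NULL
  class(out) <- c("occupancy_table", "data.frame")
  out
}

#' Classify occupancy records into abundance classes
#'
#' Classes follow the reporting convention: high (> 0.75, High-flagged
#' records included), medium (0.25 to 0.75), low (0.001 to 0.1), with the
#' 0.1 to 0.25 interval reported separately (`gap`) and ratios below 0.001
#' as `below_floor`.
#'
#' @param records An `occupancy_table`.
#' @param bounds Named numeric: `high`, `medium`, `low_hi`, `floor`
#'   thresholds.
#' @return Data frame `class`/`count`/`fraction`.
#' @export
classify_occupancy <- function(records,
                               bounds = c(high = 0.75, medium = 0.25,
                                          low_hi = 0.1, floor = 0.001)) {
  r <- records$glyco_ratio
  high <- records$high_flag | (!is.na(r) & r > bounds[["high"]])
  medium <- !high & !is.na(r) & r > bounds[["medium"]] & r <= bounds[["high"]]
  gap <- !is.na(r) & r > bounds[["low_hi"]] & r <= bounds[["medium"]]
  low <- !is.na(r) & r >= bounds[["floor"]] & r <= bounds[["low_hi"]]
  below <- !is.na(r) & r < bounds[["floor"]]
  counts <- c(high = sum(high), medium = sum(medium), gap = sum(gap),
              low = sum(low), below_floor = sum(below))
  total <- nrow(records)
  data.frame(class = names(counts), count = as.integer(counts),
             fraction = if (total == 0) rep(0, 5) else
               as.numeric(counts) / total,
             stringsAsFactors = FALSE)
}

#' Compare occupancy between two conditions
#'
#' Least-squares regression of matched ratios (records matched by identical
#' peptide sequence; High-flagged records excluded).
#'
#' @param records_a,records_b `occupancy_table`s of the two conditions.
#' @return List of class `occupancy_comparison`: `r_squared`, `slope`,
#'   `intercept`, `n_matched`, `insufficient` (fewer than 3 matched pairs).
#' @export
compare_conditions <- function(records_a, records_b) {
  a <- records_a[!records_a$high_flag & !is.na(records_a$glyco_ratio), ]
  b <- records_b[!records_b$high_flag & !is.na(records_b$glyco_ratio), ]
  m <- merge(a[c("peptide", "glyco_ratio")], b[c("peptide", "glyco_ratio")],
             by = "peptide", suffixes = c("_a", "_b"))
  out <- list(r_squared = NA_real_, slope = NA_real_, intercept = NA_real_,
              n_matched = nrow(m), insufficient = nrow(m) < 3)
  if (!out$insufficient) {
    fit <- stats::lm(glyco_ratio_a ~ glyco_ratio_b, data = m)
    out$r_squared <- summary(fit)$r.squared
    out$slope <- unname(stats::coef(fit)[2])
    out$intercept <- unname(stats::coef(fit)[1])
  }
  class(out) <- "occupancy_comparison"
  out
}

#' @export
print.occupancy_comparison <- function(x, ...) {
  if (x$insufficient)
    cat(sprintf("Occupancy comparison: insufficient matched pairs (n = %d)\n",
                x$n_matched))
  else
    cat(sprintf("Occupancy comparison: R^2 = %.3f, slope = %.3f, intercept = %.3f (n = %d)\n",
                x$r_squared, x$slope, x$intercept, x$n_matched))
  invisible(x)
}
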