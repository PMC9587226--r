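# Differential site-level glycosylation between wild type and knockouts.
#
# Fold change is the ratio of replicate medians (KO / WT); statistical
# confidence is a two-sided equal-variance t-test on log2 intensities,
# adjusted across all sites of a contrast with Benjamini-Hochberg. The
# default call rule follows the main-text thresholds (fold change < 0.5 AND
# FDR-adjusted p < 0.05 for down; > 2 for up); a raw-p variant matching the
# rank-plot convention is available via `use_raw_p`. Missing intensities are
# never imputed.

condition_channels <- function(df, label) {
  chans <- channel_columns(df)
  chans[channel_condition(chans) == label]
}

#' Total-intensity channel normalization
#'
#' Scales each channel by a single factor so all channel totals equal the
#' grand mean of the input channel totals, preserving within-channel
#' structure. Totals are computed over non-missing values.
#'
#' @param table Data frame with `condition:replicate` channel columns.
#' @return The table with scaled channels; scale factors in attribute
#'   `"norm_factors"`.
#' @export
normalize_total <- function(table) {
  chans <- channel_columns(table)
  if (length(chans) == 0) stopf("no channel columns to normalize")
  totals <- vapply(chans, function(ch) sum(table[[ch]], na.rm = TRUE),
                   numeric(1))
  if (any(totals == 0)) stopf("channel '%s' has zero total intensity",
                              chans[totals == 0][1])
  factors <- mean(totals) / totals
  for (i in seq_along(chans))
    table[[chans[i]]] <- table[[chans[i]]] * factors[i]
  attr(table, "norm_factors") <- stats::setNames(factors, chans)
  table
}

# Two-sided equal-variance t-test on log2 values, robust to zero variance:
# constant equal groups give p = 1, constant distinct groups p = 0.
log2_ttest <- function(a, b) {
  la <- log2(a); lb <- log2(b)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0)
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
  tryCatch(stats::t.test(la, lb, var.equal = TRUE)$p.value,
           error = function(e) NA_real_)
}

#' Test sites for differential glycosylation in one contrast
#'
#' @param site_table Quantification table ([site_quant_table()] output or
#'   similar) with a `site_key` column and channel columns; intensities are
#'   assumed normalized ([normalize_total()]).
#' @param wt_label,ko_label Condition labels of the contrast.
#' @param alpha Significance level on the adjusted (or raw, see `use_raw_p`)
#'   p-value (default 0.05).
#' @param down_fc,up_fc Fold-change thresholds for down/up calls (defaults
#'   0.5 and 2).
#' @param use_raw_p Call on the raw p-value instead of the FDR-adjusted one.
#' @return Data frame of class `regulation_calls`: one row per site with
#'   `fold_change` (KO median / WT median), `log2_fc`, `p_raw`, `p_adj`
#'   (Benjamini-Hochberg across tested sites), `call`
#'   (down/up/unchanged/untested), `n_wt`, `n_ko`.
#' @export
test_sites <- function(site_table, wt_label, ko_label, alpha = 0.05,
                       down_fc = 0.5, up_fc = 2, use_raw_p = FALSE) {
  wt_ch <- condition_channels(site_table, wt_label)
  ko_ch <- condition_channels(site_table, ko_label)
  if (length(wt_ch) < 2 || length(ko_ch) < 2)
    stopf("need >= 2 replicate channels per condition (%s: %d, %s: %d)",
          wt_label, length(wt_ch), ko_label, length(ko_ch))
  n <- nrow(site_table)
  fc <- p_raw <- rep(NA_real_, n)
  n_wt <- n_ko <- integer(n)
  for (i in seq_len(n)) {
    wv <- as.numeric(site_table[i, wt_ch])
    kv <- as.numeric(site_table[i, ko_ch])
    wv <- wv[!is.na(wv)]; kv <- kv[!is.na(kv)]
    n_wt[i] <- length(wv); n_ko[i] <- length(kv)
    if (length(wv) < 2 || length(kv) < 2) next
    fc[i] <- stats::median(kv) / stats::median(wv)
    p_raw[i] <- log2_ttest(kv, wv)
  }
  tested <- !is.na(p_raw)
  p_adj <- rep(NA_real_, n)
  p_adj[tested] <- stats::p.adjust(p_raw[tested], method = "BH")
  p_use <- if (use_raw_p) p_raw else p_adj
  call <- rep("untested", n)
  call[tested] <- "unchanged"
  call[tested & fc < down_fc & p_use < alpha] <- "down"
  call[tested & fc > up_fc & p_use < alpha] <- "up"
  out <- data.frame(site_key = site_table$site_key,
                    accession = site_table$accession,
                    position = site_table$position,
                    knockout = ko_label, fold_change = fc,
                    log2_fc = log2(fc), p_raw = p_raw, p_adj = p_adj,
                    call = call, n_wt = n_wt, n_ko = n_ko,
                    stringsAsFactors = FALSE)
  class(out) <- c("regulation_calls", "data.frame")
  out
}

#' Remove sites on abundance-changed proteins
#'
#' Sites are interpretable as glycosylation changes only when their parent
#' protein's overall abundance is stable between knockout and wild type.
#' Proteins whose KO/WT median fold change in the (non-enriched) proteome
#' falls outside `fc_bounds` with FDR-adjusted p below `alpha` have all
#' their sites removed. Sites whose protein is absent from the protein table
#' are retained and flagged.
#'
#' @param site_table Site quantification table (`accession` column required).
#' @param protein_table Protein quantification table (`accession` + channel
#'   columns), from the non-enriched proteome channels.
#' @param wt_label,ko_label Contrast condition labels.
#' @param fc_bounds Protein fold-change stability bounds (default 0.5..2).
#' @param alpha Significance level on the protein adjusted p (default 0.05).
#' @return Filtered site table with logical column `protein_unquantified`;
#'   removed site keys in attribute `"removed_sites"`, the protein test in
#'   attribute `"protein_calls"`.
#' @export
protein_abundance_filter <- function(site_table, protein_table, wt_label,
                                     ko_label, fc_bounds = c(0.5, 2),
                                     alpha = 0.05) {
  pt <- protein_table
  pt$site_key <- pt$accession
  pt$position <- NA_integer_
  pcalls <- test_sites(pt, wt_label, ko_label, alpha = alpha)
  changed <- !is.na(pcalls$fold_change) &
    (pcalls$fold_change < fc_bounds[1] | pcalls$fold_change > fc_bounds[2]) &
    !is.na(pcalls$p_adj) & pcalls$p_adj < alpha
  changed_acc <- pcalls$accession[changed]
  keep <- !(site_table$accession %in% changed_acc)
  out <- site_table[keep, , drop = FALSE]
  out$protein_unquantified <- !(out$accession %in% protein_table$accession)
  attr(out, "removed_sites") <- site_table$site_key[!keep]
  attr(out, "protein_calls") <- pcalls
  out
}

#' Flag isoform-specific regulation across a knockout panel
#'
#' A site is isoform-specific for a knockout when it is called down in that
#' knockout and in no other; sites down in two or more knockouts are flagged
#' shared.
#'
#' @param calls Long-format `regulation_calls` covering every knockout
#'   contrast over the same site universe (e.g. rbind of [test_sites()]
#'   outputs).
#' @return The calls with logical columns `isoform_specific` and `shared`,
#'   and integer `n_knockouts_down`.
#' @export
assign_isoform_specificity <- function(calls) {
  down_counts <- tapply(calls$call == "down", calls$site_key, sum)
  nd <- as.integer(down_counts[calls$site_key])
  calls$n_knockouts_down <- nd
  calls$isoform_specific <- calls$call == "down" & nd == 1L
  calls$shared <- nd >= 2L
  calls
}

#' Run the full differential panel
#'
#' For each knockout: optional protein-abundance filtering, site testing,
#' then panel-wide isoform-specificity assignment.
#'
#' @param site_table Normalized site quantification table.
#' @param wt_label Wild-type condition label.
#' @param ko_labels Knockout condition labels.
#' @param protein_table Optional protein quantification table enabling the
#'   abundance filter.
#' @inheritParams test_sites
#' @inheritParams protein_abundance_filter
#' @return Object of class `glyco_differential`: list with `calls` (long
#'   format with specificity flags), `ko_labels`, and `site_universe`.
#' @export
differential_panel <- function(site_table, wt_label, ko_labels,
                               protein_table = NULL, alpha = 0.05,
                               down_fc = 0.5, up_fc = 2,
                               fc_bounds = c(0.5, 2), use_raw_p = FALSE) {
  all_calls <- list()
  for (ko in ko_labels) {
    st <- site_table
    if (!is.null(protein_table))
      st <- protein_abundance_filter(st, protein_table, wt_label, ko,
                                     fc_bounds = fc_bounds, alpha = alpha)
    all_calls[[ko]] <- test_sites(st, wt_label, ko, alpha = alpha,
                                  down_fc = down_fc, up_fc = up_fc,
                                  use_raw_p = use_raw_p)
  }
  calls <- do.call(rbind, all_calls)
  rownames(calls) <- NULL
  calls <- assign_isoform_specificity(calls)
  out <- list(calls = calls, wt_label = wt_label, ko_labels = ko_labels,
              site_universe = unique(site_table$site_key))
  class(out) <- "glyco_differential"
  out
}

#' Summarize a differential panel
#'
#' @param object A `glyco_differential`.
#' @param total_sites Denominator for the headline percentages; defaults to
#'   the tested site universe.
#' @param ... Unused.
#' @return Data frame of per-knockout down/up counts plus attributes
#'   `n_down_any`, `pct_down_any`, `n_isoform_specific`,
#'   `pct_isoform_specific`.
#' @method summary glyco_differential
#' @export
summary.glyco_differential <- function(object,
                                       total_sites =
                                         length(object$site_universe), ...) {
  calls <- object$calls
  per_ko <- data.frame(knockout = object$ko_labels, stringsAsFactors = FALSE)
  per_ko$n_down <- vapply(per_ko$knockout, function(k)
    sum(calls$call == "down" & calls$knockout == k), integer(1))
  per_ko$n_up <- vapply(per_ko$knockout, function(k)
    sum(calls$call == "up" & calls$knockout == k), integer(1))
  per_ko$n_specific <- vapply(per_ko$knockout, function(k)
    sum(calls$isoform_specific & calls$knockout == k), integer(1))
  down_sites <- unique(calls$site_key[calls$call == "down"])
  spec_sites <- unique(calls$site_key[calls$isoform_specific])
  up_sites <- unique(calls$site_key[calls$call == "up"])
  structure(per_ko,
            n_down_any = length(down_sites),
            pct_down_any = pct1(length(down_sites), total_sites),
            n_up_any = length(up_sites),
            n_isoform_specific = length(spec_sites),
            pct_isoform_specific = pct1(length(spec_sites), total_sites),
            total_sites = total_sites,
            class = c("glyco_differential_summary", "data.frame"))
}

#' @export
print.glyco_differential <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("Differential glycosylation panel: %s vs %d knockout(s), %d sites\n",
              x$wt_label, length(x$ko_labels), length(x$site_universe)))
  cat(sprintf("  down in >= 1 knockout: %d (%.1f%%); isoform-specific: %d (%.1f%%)\n",
              attr(s, "n_down_any"), attr(s, "pct_down_any"),
              attr(s, "n_isoform_specific"), attr(s, "pct_isoform_specific")))
  print.data.frame(s)
  invisible(x)
}

#' @export
print.glyco_differential_summary <- function(x, ...) {
  cat(sprintf("Down in >= 1 knockout: %d of %d (%.1f%%); isoform-specific: %d (%.1f%%)\n",
              attr(x, "n_down_any"), attr(x, "total_sites"),
              attr(x, "pct_down_any"), attr(x, "n_isoform_specific"),
              attr(x, "pct_isoform_specific")))
  print.data.frame(x)
  invisible(x)
}
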