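# Glycan-patch (mucin-like region) detection.
#
# A patch is a maximal cluster of sites satisfying the density rule: some
# window of `window` consecutive residues (default 25) contains at least
# `min_sites` (default 5) sites. Qualifying windows that share a member site
# are merged into one maximal patch, so a dense cluster is reported once
# rather than as many shifted windows. Patch extent is reported as the
# first-to-last member site, not window bounds.

# Patches for one protein's sorted site positions: returns a list of integer
# index ranges into `pos`. Every qualifying interval can be anchored at its
# leftmost contained site, so only site-anchored windows need checking;
# merging by shared membership is equivalent to merging overlapping index
# ranges.
patch_ranges <- function(pos, window, min_sites) {
  n <- length(pos)
  if (n < min_sites) return(list())
  qual <- list()
  for (i in seq_len(n)) {
    j <- findInterval(pos[i] + window - 1L, pos)
    if (j - i + 1L >= min_sites) qual[[length(qual) + 1L]] <- c(i, j)
  }
  if (length(qual) == 0) return(list())
  merged <- list()
  cur <- qual[[1]]
  for (q in qual[-1]) {
    if (q[1] <= cur[2]) cur[2] <- max(cur[2], q[2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- q }
  }
  merged[[length(merged) + 1L]] <- cur
  merged
}

#' Detect high-density O-glycan patches
#'
#' Slides a `window`-residue window over each protein's unambiguous sites;
#' windows containing at least `min_sites` sites are flagged, and flagged
#' windows sharing a member site are merged into maximal patches. Patches on
#' one protein are disjoint in membership.
#'
#' @param catalog A `glyco_catalog`, or a data frame with `accession` and
#'   `position` columns.
#' @param window Window width in residues (default 25).
#' @param min_sites Minimum sites per window (default 5).
#' @return Data frame of class `glyco_patches`: `accession`, `start`, `end`
#'   (first/last member site, 1-based inclusive), `n_sites`, `member_sites`
#'   (semicolon list) and `density` (sites per `window` residues of span).
#' @export
find_patches <- function(catalog, window = 25, min_sites = 5) {
  if (window < 1) stopf("window must be >= 1")
  if (min_sites < 1) stopf("min_sites must be >= 1")
  df <- as.data.frame(catalog)
  if ("status" %in% names(df))
    df <- df[df$status == "unambiguous", , drop = FALSE]
  df <- df[!is.na(df$position), , drop = FALSE]
  rows <- list()
  for (acc in unique(df$accession)) {
    pos <- sort(unique(df$position[df$accession == acc]))
    for (rg in patch_ranges(pos, as.integer(window), min_sites)) {
      members <- pos[rg[1]:rg[2]]
      span <- members[length(members)] - members[1] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        accession = acc, start = members[1],
        end = members[length(members)], n_sites = length(members),
        member_sites = join_num(members),
        density = length(members) / span * window,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), start = integer(0),
               end = integer(0), n_sites = integer(0),
               member_sites = character(0), density = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("glyco_patches", "data.frame")
  out
}

#' Rank patches by size
#'
#' Orders by site count descending, ties by span ascending (denser first),
#' then accession; optionally filters to patches of at least `min_size`
#' sites.
#'
#' @param patches Output of [find_patches()].
#' @param min_size Optional minimum patch size for the report.
#' @return Reordered (and possibly filtered) patch data frame.
#' @export
rank_patches <- function(patches, min_size = NULL) {
  df <- as.data.frame(patches)
  if (!is.null(min_size)) df <- df[df$n_sites >= min_size, , drop = FALSE]
  if (nrow(df) == 0) { class(df) <- class(patches); return(df) }
  span <- df$end - df$start + 1L
  df <- df[order(-df$n_sites, span, df$accession), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- class(patches)
  df
}

#' @export
print.glyco_patches <- function(x, ...) {
  cat(sprintf("%d O-glycan patch(es)", nrow(x)))
  if (nrow(x))
    cat(sprintf("; largest has %d sites", max(x$n_sites)))
  cat("\n")
  NextMethod()
}
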