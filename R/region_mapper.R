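# Region classification of glycosites.
#
# Each unambiguous site is assigned to exactly one of five protein-region
# categories, evaluated in a fixed precedence order (domain membership being
# the most specific structural claim wins):
#   domain > stem > functional_region > terminus > linker, else unassigned.
#
# Stems are juxtamembrane extracellular segments of single-pass membrane
# proteins: for type-I topology the extracellular side is N-terminal of the
# transmembrane span, for type-II it is C-terminal; the stem distance is
# measured to the nearest transmembrane boundary residue. Termini count
# residues from the mature N-terminus (first residue after the signal
# peptide, else residue 1) or from the C-terminus. Linkers are gaps between
# consecutive domains narrower than `linker_max`.

REGION_CATEGORIES <- c("domain", "stem", "functional_region", "terminus",
                       "linker", "unassigned")

#' Classify one glycosite into a protein-region category
#'
#' @param position 1-based protein coordinate of an unambiguous site.
#' @param protein One-row proteome data frame (`accession`, `sequence`,
#'   `topology`).
#' @param features Feature annotations of this protein.
#' @param stem_window Maximum distance (aa) from the transmembrane span for a
#'   stem assignment (default 50).
#' @param linker_max Maximum inter-domain gap (aa) that still counts as a
#'   linker (default 100; the gap must be strictly smaller).
#' @param terminus_window Terminal window (aa) counted from the mature
#'   N-terminus or the C-terminus (default 10).
#' @param precedence Category evaluation order.
#' @return List with `category`, `feature_label`, `feature_start`,
#'   `feature_end` (anchoring feature, NA if none) and `distance` (aa to the
#'   transmembrane boundary, stems only).
#' @export
classify_site <- function(position, protein, features,
                          stem_window = 50, linker_max = 100,
                          terminus_window = 10,
                          precedence = c("domain", "stem", "functional_region",
                                         "terminus", "linker")) {
  L <- nchar(protein$sequence)
  if (nrow(features)) {
    bad <- features$end > L | features$start < 1
    if (any(bad))
      stopf("feature interval %d..%d outside protein %s (length %d)",
            features$start[bad][1], features$end[bad][1],
            protein$accession, L)
  }
  doms <- features[features$kind == "domain", , drop = FALSE]
  doms <- doms[order(doms$start), , drop = FALSE]
  tm <- features[features$kind == "transmembrane", , drop = FALSE]
  sig <- features[features$kind == "signal_peptide", , drop = FALSE]
  fun <- features[features$kind == "functional_region", , drop = FALSE]
  mature_n <- if (nrow(sig)) max(sig$end) + 1L else 1L
  res <- list(category = "unassigned", feature_label = NA_character_,
              feature_start = NA_integer_, feature_end = NA_integer_,
              distance = NA_integer_)
  try_category <- function(cat) {
    switch(cat,
      domain = {
        hit <- which(doms$start <= position & position <= doms$end)
        if (length(hit)) {
          h <- hit[1]
          list(category = "domain", feature_label = doms$label[h],
               feature_start = doms$start[h], feature_end = doms$end[h],
               distance = NA_integer_)
        }
      },
      stem = {
        if (protein$topology %in% c("type_I", "type_II") && nrow(tm)) {
          t1 <- tm[1, ]
          d <- if (protein$topology == "type_I" && position < t1$start)
            t1$start - position
          else if (protein$topology == "type_II" && position > t1$end)
            position - t1$end
          else NA_integer_
          if (!is.na(d) && d <= stem_window)
            list(category = "stem", feature_label = NA_character_,
                 feature_start = t1$start, feature_end = t1$end,
                 distance = as.integer(d))
        }
      },
      functional_region = {
        hit <- which(fun$start <= position & position <= fun$end)
        if (length(hit)) {
          h <- hit[1]
          list(category = "functional_region", feature_label = fun$label[h],
               feature_start = fun$start[h], feature_end = fun$end[h],
               distance = NA_integer_)
        }
      },
      terminus = {
        off_n <- position - mature_n + 1L
        off_c <- L - position + 1L
        if ((off_n >= 1 && off_n <= terminus_window) ||
            (off_c >= 1 && off_c <= terminus_window))
          list(category = "terminus", feature_label = NA_character_,
               feature_start = NA_integer_, feature_end = NA_integer_,
               distance = NA_integer_)
      },
      linker = {
        if (nrow(doms) >= 2) {
          for (d in seq_len(nrow(doms) - 1L)) {
            gap <- doms$start[d + 1L] - doms$end[d] - 1L
            if (position > doms$end[d] && position < doms$start[d + 1L] &&
                gap < linker_max)
              return(list(category = "linker", feature_label = NA_character_,
                          feature_start = doms$end[d] + 1L,
                          feature_end = doms$start[d + 1L] - 1L,
                          distance = NA_integer_))
          }
        }
        NULL
      })
  }
  for (cat in precedence) {
    hit <- try_category(cat)
    if (!is.null(hit)) return(hit)
  }
  res
}

#' Classify every unambiguous catalog site
#'
#' @param catalog A `glyco_catalog` data frame.
#' @param proteome Proteome data frame.
#' @param features Feature annotation data frame.
#' @inheritParams classify_site
#' @return Data frame with one row per unambiguous site: `accession`,
#'   `position`, `category`, `feature_label`, `feature_start`, `feature_end`,
#'   `distance`.
#' @export
classify_sites <- function(catalog, proteome, features, stem_window = 50,
                           linker_max = 100, terminus_window = 10,
                           precedence = c("domain", "stem",
                                          "functional_region", "terminus",
                                          "linker")) {
  un <- catalog[catalog$status == "unambiguous", , drop = FALSE]
  rows <- vector("list", nrow(un))
  for (i in seq_len(nrow(un))) {
    prot <- proteome[proteome$accession == un$accession[i], , drop = FALSE]
    if (nrow(prot) == 0)
      stopf("site references unknown accession '%s'", un$accession[i])
    fi <- features[features$accession == un$accession[i], , drop = FALSE]
    cl <- classify_site(un$position[i], prot, fi, stem_window, linker_max,
                        terminus_window, precedence)
    rows[[i]] <- data.frame(accession = un$accession[i],
                            position = un$position[i],
                            category = cl$category,
                            feature_label = cl$feature_label,
                            feature_start = cl$feature_start,
                            feature_end = cl$feature_end,
                            distance = cl$distance, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), position = integer(0),
               category = character(0), feature_label = character(0),
               feature_start = integer(0), feature_end = integer(0),
               distance = integer(0))
  out
}

#' Summarize region assignments
#'
#' Per-category counts and one-decimal percentages of the total site count,
#' plus an `assigned` row aggregating the five named categories.
#'
#' @param assignments Output of [classify_sites()].
#' @param total Denominator for percentages; defaults to the number of
#'   assignments, but can be set to the full catalog size when ambiguous
#'   sites should count in the denominator.
#' @return Data frame `category`/`count`/`pct`, class `region_summary`.
#' @export
summarize_regions <- function(assignments, total = nrow(assignments)) {
  counts <- vapply(REGION_CATEGORIES,
                   function(cat) sum(assignments$category == cat), integer(1))
  assigned <- sum(counts[setdiff(REGION_CATEGORIES, "unassigned")])
  out <- data.frame(category = c(REGION_CATEGORIES, "assigned"),
                    count = c(counts, assigned),
                    pct = c(pct1(counts, total), pct1(assigned, total)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Per-domain-type glycosylation statistics
#'
#' Counts domain instances over catalog glycoproteins only, the glycosylation
#' rate (instances with >= 1 unambiguous site / total instances), per-instance
#' site counts, and the distribution of within-domain relative site
#' positions over 10 equal bins. The relative position of a site uses the
#' midpoint offset `(position - start + 0.5) / width`, so the first and last
#' residues fall into bins 1 and 10 symmetrically.
#'
#' @param catalog A `glyco_catalog`.
#' @param proteome Proteome data frame.
#' @param features Feature annotations (must include domains).
#' @return Data frame with one row per domain label: `domain_label`,
#'   `n_domains_total`, `n_domains_glycosylated`, `rate`, `n_sites`,
#'   `bin1`..`bin10`; per-instance site counts in attribute
#'   `"sites_per_domain"`.
#' @export
domain_statistics <- function(catalog, proteome, features) {
  un <- catalog[catalog$status == "unambiguous", , drop = FALSE]
  glycoprots <- unique(catalog$accession)
  doms <- features[features$kind == "domain" &
                     features$accession %in% glycoprots, , drop = FALSE]
  if (nrow(doms) == 0)
    return(data.frame(domain_label = character(0),
                      n_domains_total = integer(0),
                      n_domains_glycosylated = integer(0), rate = numeric(0),
                      n_sites = integer(0)))
  if (any(doms$end < doms$start)) stopf("zero-length domain interval")
  doms$width <- doms$end - doms$start + 1L
  doms$n_sites <- 0L
  bins <- matrix(0L, nrow(doms), 10)
  for (i in seq_len(nrow(doms))) {
    sel <- un$accession == doms$accession[i] &
      un$position >= doms$start[i] & un$position <= doms$end[i]
    doms$n_sites[i] <- sum(sel)
    if (any(sel)) {
      rel <- (un$position[sel] - doms$start[i] + 0.5) / doms$width[i]
      b <- pmin(10L, floor(rel * 10) + 1L)
      for (bb in b) bins[i, bb] <- bins[i, bb] + 1L
    }
  }
  labs <- sort(unique(doms$label))
  out <- data.frame(domain_label = labs, stringsAsFactors = FALSE)
  out$n_domains_total <- vapply(labs, function(l) sum(doms$label == l),
                                integer(1))
  out$n_domains_glycosylated <- vapply(labs, function(l)
    sum(doms$label == l & doms$n_sites > 0), integer(1))
  out$rate <- out$n_domains_glycosylated / out$n_domains_total
  out$n_sites <- vapply(labs, function(l) sum(doms$n_sites[doms$label == l]),
                        integer(1))
  binagg <- t(vapply(labs, function(l)
    colSums(bins[doms$label == l, , drop = FALSE]), numeric(10)))
  colnames(binagg) <- paste0("bin", 1:10)
  out <- cbind(out, binagg)
  rownames(out) <- NULL
  attr(out, "sites_per_domain") <-
    lapply(stats::setNames(labs, labs),
           function(l) doms$n_sites[doms$label == l])
  out
}
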