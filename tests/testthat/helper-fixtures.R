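# Fixture builders and independent brute-force oracles used across tests.

# --- builders -------------------------------------------------------------

make_protein <- function(accession = "P1", sequence = "MKTAYSTLLV",
                         topology = "other") {
  data.frame(accession = accession, sequence = sequence, topology = topology,
             stringsAsFactors = FALSE)
}

make_feature <- function(accession = "P1", kind = "domain", start = 1,
                         end = 10, label = if (kind == "domain") "Dom" else "") {
  data.frame(accession = accession, kind = kind, start = as.integer(start),
             end = as.integer(end), label = label, stringsAsFactors = FALSE)
}

# One PSM row with optional intensity channels.
make_psm <- function(psm_id = 1, precursor_id = psm_id, peptide, accession,
                     pep_start, frag_type = "ETD", hexnac_count = 1,
                     positions = numeric(0), probabilities = numeric(0),
                     psm_score = 100, intensities = NULL) {
  row <- data.frame(psm_id = psm_id, precursor_id = precursor_id,
                    peptide = peptide, accession = accession,
                    pep_start = as.integer(pep_start),
                    pep_end = as.integer(pep_start + nchar(peptide) - 1),
                    hexnac_count = as.integer(hexnac_count), hex_count = 0L,
                    site_positions = paste(positions, collapse = ";"),
                    site_probabilities = paste(probabilities, collapse = ";"),
                    frag_type = frag_type, psm_score = psm_score,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(intensities))
    for (ch in names(intensities)) row[[ch]] <- intensities[[ch]]
  row
}

# Quant table with WT:1..n and KO:1..n channels from two value matrices.
make_quant_table <- function(wt, ko, wt_label = "WT", ko_label = "KO",
                             site_keys = paste0("s", seq_len(nrow(wt)))) {
  df <- data.frame(site_key = site_keys,
                   accession = sub(":.*", "", site_keys),
                   position = seq_len(nrow(wt)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(wt))) df[[paste0(wt_label, ":", j)]] <- wt[, j]
  for (j in seq_len(ncol(ko))) df[[paste0(ko_label, ":", j)]] <- ko[, j]
  df
}

make_peak <- function(peak_id = 1, accession = "P1", region_id = "R1",
                      pep_start = 10, pep_end = 20, peptide = "SSTTASSTYPK",
                      glycoform = 1, charge = 2, area = 100,
                      mass_error_ppm = 0, idotp = 0.95, rt_delta_min = 0,
                      replicate = "rep1", id_score = 300) {
  data.frame(peak_id = peak_id, accession = accession, region_id = region_id,
             pep_start = pep_start, pep_end = pep_end, peptide = peptide,
             glycoform = glycoform, charge = charge, area = area,
             mass_error_ppm = mass_error_ppm, idotp = idotp,
             rt_delta_min = rt_delta_min, replicate = replicate,
             id_score = id_score, stringsAsFactors = FALSE)
}

# --- oracles --------------------------------------------------------------

# Patch oracle: enumerate EVERY window of `window` consecutive residues over
# the protein, collect qualifying member-site sets, and merge sets into
# connected components by shared membership (fixed-point iteration).
patch_oracle <- function(pos, protein_length, window = 25, min_sites = 5) {
  pos <- sort(unique(pos))
  sets <- list()
  for (s in seq_len(max(1L, protein_length))) {
    members <- pos[pos >= s & pos <= s + window - 1L]
    if (length(members) >= min_sites) sets[[length(sets) + 1L]] <- members
  }
  if (length(sets) == 0) return(list())
  repeat {
    merged_any <- FALSE
    out <- list()
    for (s in sets) {
      hit <- FALSE
      for (i in seq_along(out)) {
        if (length(intersect(out[[i]], s))) {
          out[[i]] <- sort(union(out[[i]], s))
          hit <- TRUE
          merged_any <- TRUE
          break
        }
      }
      if (!hit) out[[length(out) + 1L]] <- s
    }
    sets <- out
    if (!merged_any) break
  }
  sets[order(vapply(sets, min, numeric(1)))]
}

# Region oracle: build explicit residue sets for every category from first
# principles, then apply the precedence order by set membership.
region_oracle <- function(position, protein, features, stem_window = 50,
                          linker_max = 100, terminus_window = 10) {
  L <- nchar(protein$sequence)
  doms <- features[features$kind == "domain", , drop = FALSE]
  doms <- doms[order(doms$start), , drop = FALSE]
  tm <- features[features$kind == "transmembrane", , drop = FALSE]
  sig <- features[features$kind == "signal_peptide", , drop = FALSE]
  fun <- features[features$kind == "functional_region", , drop = FALSE]
  domain_set <- unlist(lapply(seq_len(nrow(doms)),
                              function(i) doms$start[i]:doms$end[i]))
  stem_set <- integer(0)
  if (protein$topology == "type_I" && nrow(tm))
    stem_set <- intersect(seq_len(L), (tm$start[1] - stem_window):(tm$start[1] - 1))
  if (protein$topology == "type_II" && nrow(tm))
    stem_set <- intersect(seq_len(L), (tm$end[1] + 1):(tm$end[1] + stem_window))
  fun_set <- unlist(lapply(seq_len(nrow(fun)),
                           function(i) fun$start[i]:fun$end[i]))
  mature_n <- if (nrow(sig)) max(sig$end) + 1L else 1L
  term_set <- union(intersect(seq_len(L), mature_n:(mature_n + terminus_window - 1L)),
                    (L - terminus_window + 1L):L)
  linker_set <- integer(0)
  if (nrow(doms) >= 2)
    for (d in seq_len(nrow(doms) - 1L)) {
      gap <- doms$start[d + 1L] - doms$end[d] - 1L
      if (gap >= 1 && gap < linker_max)
        linker_set <- union(linker_set, (doms$end[d] + 1L):(doms$start[d + 1L] - 1L))
    }
  if (position %in% domain_set) return("domain")
  if (position %in% stem_set) return("stem")
  if (position %in% fun_set) return("functional_region")
  if (position %in% term_set) return("terminus")
  if (position %in% linker_set) return("linker")
  "unassigned"
}

# Benjamini-Hochberg oracle: adj_i = min(1, min_{j >= rank(i)} p_(j) * m / j).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m))
    adj_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Catalog oracle: enumerate all (ETD PSM, position) pairs above the cutoff.
catalog_oracle <- function(psms, prob_cutoff = 95) {
  etd <- psms[psms$frag_type == "ETD", , drop = FALSE]
  out <- character(0)
  for (i in seq_len(nrow(etd))) {
    pos <- as.numeric(strsplit(etd$site_positions[i], ";")[[1]])
    prob <- as.numeric(strsplit(etd$site_probabilities[i], ";")[[1]])
    keep <- which(prob > prob_cutoff)
    for (k in keep)
      out <- c(out, paste(etd$accession[i], etd$pep_start[i] + pos[k] - 1))
  }
  sort(unique(out))
}
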