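# Synthetic ground-truth generator.
#
# Emulates the statistical structure the downstream analysis assumes:
# proteomes with membrane topologies and UniProt-style feature architectures;
# true O-glycosites placed on Ser/Thr (rarely Tyr), partly in dense clusters;
# ETD/HCD PSM pairs with ptmRS-like localization probabilities; multi-channel
# TMT reporter intensities with multiplicative knockout effects and lognormal
# measurement noise; and MS1 glycoform peak areas drawn from known
# occupancies and xTn mixing proportions, with labeled out-of-spec decoys.
#
# One pseudo-random stream per run: each stage seeds from config$seed plus a
# fixed stage offset, so adding draws to one stage never perturbs another's.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","T","V","W","Y","S")

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults mirror the
#' study design the analysis targets: a TMT panel of wild type plus nine
#' GalNAc-T knockouts with three replicates each, a strong knockout effect
#' (targeted site intensity reduced to 10%), 20% lognormal coefficient of
#' variation on intensities, and an occupancy mixture with 60% of regions
#' highly occupied (>0.75), 11% intermediate (0.25-0.75) and 29% low
#' (0.001-0.1).
#'
#' @param seed Integer seed; the run is bit-identical for identical configs.
#' @param n_proteins Number of proteins to simulate.
#' @param length_range Min/max protein length (residues).
#' @param n_sites Number of true glycosites.
#' @param patch_fraction Fraction of sites placed in dense clusters
#'   (>= 5 sites within 25 residues).
#' @param conditions Condition labels; the first is the wild-type reference,
#'   the rest are knockouts.
#' @param replicates Replicates per condition (>= 2).
#' @param effect_size Multiplicative intensity reduction on a targeted site in
#'   its knockout, in (0, 1]; 1 gives a null simulation.
#' @param cv_noise Lognormal coefficient of variation of intensities/areas.
#' @param frac_isoform_specific Fraction of sites assigned to exactly one
#'   knockout's target set.
#' @param frac_low_loc Fraction of ETD PSMs drawn with localization
#'   probability below 95 (exercises the ambiguity filter).
#' @param frac_multisite Fraction of clustered sites additionally covered by
#'   multi-glycan PSMs (exercises single-site filtering).
#' @param n_abundance_changed Number of proteins given a whole-protein
#'   abundance change in one knockout.
#' @param abundance_effect Multiplicative factor for abundance-changed
#'   proteins.
#' @param occupancy_weights Mixture weights over the high/medium/low
#'   occupancy classes (must sum to 1).
#' @param max_tn Maximum HexNAc residues per simulated peptide region.
#' @param n_regions Number of peptide regions in the MS1 peak table.
#' @param frac_signal_peptide Fraction of type-I/secreted proteins given a
#'   signal peptide.
#' @param decoy_fraction Fraction of extra out-of-spec peak rows appended
#'   (labeled in the ground truth, for exact filter tests).
#' @param rt_jitter In-spec retention-time jitter half-width (minutes).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 40L,
                       length_range = c(300L, 800L),
                       n_sites = 300L,
                       patch_fraction = 0.2,
                       conditions = c("WT", "T1", "T2", "T3", "T6", "T7",
                                      "T10", "T11", "T14", "T18"),
                       replicates = 3L,
                       effect_size = 0.1,
                       cv_noise = 0.2,
                       frac_isoform_specific = 0.1,
                       frac_low_loc = 0.08,
                       frac_multisite = 0.15,
                       n_abundance_changed = 3L,
                       abundance_effect = 0.3,
                       occupancy_weights = c(high = 0.6, medium = 0.11, low = 0.29),
                       max_tn = 5L,
                       n_regions = 70L,
                       frac_signal_peptide = 0.6,
                       decoy_fraction = 0.1,
                       rt_jitter = 3) {
  cfg <- list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              n_sites = as.integer(n_sites), patch_fraction = patch_fraction,
              conditions = conditions, replicates = as.integer(replicates),
              effect_size = effect_size, cv_noise = cv_noise,
              frac_isoform_specific = frac_isoform_specific,
              frac_low_loc = frac_low_loc, frac_multisite = frac_multisite,
              n_abundance_changed = as.integer(n_abundance_changed),
              abundance_effect = abundance_effect,
              occupancy_weights = occupancy_weights,
              max_tn = as.integer(max_tn), n_regions = as.integer(n_regions),
              frac_signal_peptide = frac_signal_peptide,
              decoy_fraction = decoy_fraction, rt_jitter = rt_jitter)
  fracs <- c(patch_fraction, frac_isoform_specific, frac_low_loc,
             frac_multisite, frac_signal_peptide, decoy_fraction)
  if (any(fracs < 0 | fracs > 1)) stopf("all fractions must lie in [0,1]")
  if (cfg$replicates < 2) stopf("replicates must be >= 2")
  if (effect_size <= 0 || effect_size > 1)
    stopf("effect_size must lie in (0, 1]")
  if (abs(sum(occupancy_weights) - 1) > 1e-8)
    stopf("occupancy_weights must sum to 1")
  if (length(length_range) != 2 || length_range[1] > length_range[2])
    stopf("length_range must be c(min, max)")
  if (length_range[1] < 150)
    stopf("length_range too small to host the feature architecture (need >= 150)")
  class(cfg) <- "sim_config"
  cfg
}

stage_seed <- function(config, offset) {
  set.seed(config$seed * 101L + offset, kind = "Mersenne-Twister")
}

# Lognormal multiplicative noise with a given coefficient of variation and
# unit mean. cv = 0 degenerates to exactly 1.
lnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a proteome with feature architectures
#'
#' Generates proteins of each membrane topology with signal peptides,
#' transmembrane spans, 1-4 annotated domains and functional regions, and a
#' Ser/Thr-enriched segment per protein where clustered glycosites can later
#' be placed.
#'
#' @param config A [sim_config()].
#' @return List with `proteome` (accession/sequence/topology data frame) and
#'   `features` (feature annotation data frame).
#' @export
simulate_proteome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, 0L)
  n <- config$n_proteins
  empty <- list(proteome = data.frame(accession = character(0),
                                      sequence = character(0),
                                      topology = character(0)),
                features = data.frame(accession = character(0),
                                      kind = character(0),
                                      start = integer(0), end = integer(0),
                                      label = character(0)))
  if (n == 0) return(empty)
  topo_pool <- c("type_I", "type_II", "secreted", "multipass", "other")
  topo <- sample(topo_pool, n, replace = TRUE,
                 prob = c(0.25, 0.15, 0.3, 0.1, 0.2))
  domain_labels <- c("Fibronectin type-III", "Ig-like C2-type", "Thioredoxin",
                     "LDL-receptor class A", "Cadherin", "EGF-like")
  # Base residue frequencies: mildly realistic, S/T jointly ~15%.
  base_prob <- rep(0.85 / 18, 20)
  names(base_prob) <- AA20
  base_prob["S"] <- 0.08
  base_prob["T"] <- 0.07
  prot <- vector("list", n)
  feats <- list()
  for (i in seq_len(n)) {
    L <- sample(seq(config$length_range[1], config$length_range[2]), 1)
    seq_chr <- sample(AA20, L, replace = TRUE, prob = base_prob)
    acc <- sprintf("SYN%04d", i)
    fi <- list()
    sig_end <- 0L
    if (topo[i] %in% c("type_I", "secreted") &&
        stats::runif(1) < config$frac_signal_peptide) {
      sig_end <- sample(15:30, 1)
      fi[[length(fi) + 1]] <- list(kind = "signal_peptide", start = 1L,
                                   end = sig_end, label = "")
    }
    tm <- NULL
    if (topo[i] == "type_I") {
      tm_start <- L - sample(40:90, 1)
      tm <- c(tm_start, tm_start + 20L)
    } else if (topo[i] == "type_II") {
      tm_start <- sig_end + sample(10:40, 1)
      tm <- c(tm_start, tm_start + 20L)
    }
    if (!is.null(tm))
      fi[[length(fi) + 1]] <- list(kind = "transmembrane", start = tm[1],
                                   end = tm[2], label = "")
    # Extracellular span available for domains / ST-rich segment.
    ecto <- if (topo[i] == "type_I") c(sig_end + 1L, tm[1] - 1L)
            else if (topo[i] == "type_II") c(tm[2] + 1L, L)
            else c(sig_end + 1L, L)
    # ST-rich segment (length 40, ~50% S/T) for later patch placement.
    st_len <- 40L
    lo <- ecto[1]; hi <- ecto[2] - st_len
    if (hi > lo) {
      st_start <- sample(seq(lo, hi), 1)
      idx <- st_start:(st_start + st_len - 1L)
      st_mask <- stats::runif(st_len) < 0.5
      seq_chr[idx[st_mask]] <- sample(c("S", "T"), sum(st_mask), replace = TRUE)
    }
    # 1-4 non-overlapping domains in the ectodomain.
    n_dom <- sample(1:4, 1)
    cursor <- ecto[1] + 5L
    for (d in seq_len(n_dom)) {
      dlen <- sample(40:90, 1)
      gap <- sample(5:60, 1)
      dstart <- cursor + gap
      dend <- dstart + dlen - 1L
      if (dend > ecto[2] - 5L) break
      fi[[length(fi) + 1]] <- list(kind = "domain", start = dstart, end = dend,
                                   label = sample(domain_labels, 1))
      cursor <- dend
    }
    # 0-2 short functional regions.
    for (f in seq_len(sample(0:2, 1))) {
      flen <- sample(6:15, 1)
      if (ecto[2] - flen <= ecto[1]) break
      fstart <- sample(seq(ecto[1], ecto[2] - flen), 1)
      fi[[length(fi) + 1]] <- list(kind = "functional_region", start = fstart,
                                   end = fstart + flen - 1L,
                                   label = sample(c("proteolytic cleavage",
                                                    "heparin binding",
                                                    "sorting signal"), 1))
    }
    prot[[i]] <- data.frame(accession = acc,
                            sequence = paste(seq_chr, collapse = ""),
                            topology = topo[i], stringsAsFactors = FALSE)
    if (length(fi))
      feats[[length(feats) + 1]] <- data.frame(
        accession = acc,
        kind = vapply(fi, `[[`, character(1), "kind"),
        start = vapply(fi, function(x) as.integer(x$start), integer(1)),
        end = vapply(fi, function(x) as.integer(x$end), integer(1)),
        label = vapply(fi, `[[`, character(1), "label"),
        stringsAsFactors = FALSE)
  }
  list(proteome = do.call(rbind, prot),
       features = if (length(feats)) do.call(rbind, feats) else empty$features)
}

sty_positions <- function(seq_chr) which(seq_chr %in% c("S", "T", "Y"))
st_positions <- function(seq_chr) which(seq_chr %in% c("S", "T"))

#' Simulate true glycosites, PSMs and quantification tables
#'
#' Places `n_sites` true sites on Ser/Thr (rarely Tyr), a `patch_fraction` of
#' them in clusters of >= 5 within 25 residues; emits >= 1 ETD PSM per site,
#' each paired with an HCD PSM of the same precursor carrying the TMT
#' reporter intensities; assigns a fraction of sites to a single knockout's
#' target set and reduces their intensity by `effect_size` in that knockout's
#' channels, under lognormal noise. Also generates a flat protein-level
#' (non-enriched proteome) quantification table, with a configurable set of
#' abundance-changed proteins, and draws per-region true occupancies and xTn
#' mixing proportions for the MS1 stage.
#'
#' @param config A [sim_config()].
#' @param proteome,features Output of [simulate_proteome()].
#' @return List with `truth` (ground-truth list), `psms` (PSM data frame) and
#'   `protein_table` (accession x channel data frame).
#' @export
simulate_sites_and_psms <- function(config, proteome, features) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, 1L)
  channels <- as.vector(t(outer(config$conditions, seq_len(config$replicates),
                                paste, sep = ":")))
  cond_of_channel <- channel_condition(channels)
  kos <- setdiff(config$conditions, config$conditions[1])

  seqs <- strsplit(proteome$sequence, "")
  names(seqs) <- proteome$accession

  # --- site placement ---
  n_patch <- round(config$patch_fraction * config$n_sites)
  sites <- list()
  used <- new.env(parent = emptyenv())
  mark <- function(acc, pos) assign(paste(acc, pos), TRUE, envir = used)
  taken <- function(acc, pos) exists(paste(acc, pos), envir = used)

  # clustered sites: pick the densest 25-aa S/T window of a random protein,
  # take 5-8 of its S/T positions
  placed <- 0L
  guard <- 0L
  while (placed < n_patch && guard < 1000L) {
    guard <- guard + 1L
    pi <- sample(nrow(proteome), 1)
    sc <- seqs[[pi]]
    st <- st_positions(sc)
    if (length(st) < 5) next
    # densest window via counts of st within [p, p+24]
    cnt <- vapply(st, function(p) sum(st >= p & st <= p + 24L), integer(1))
    best <- st[which.max(cnt)]
    members <- st[st >= best & st <= best + 24L]
    if (length(members) < 5) next
    k <- min(length(members), sample(5:8, 1), n_patch - placed + 5L)
    members <- sort(sample(members, k))
    if (length(members) < 5) next
    new <- members[!vapply(members, function(p) taken(proteome$accession[pi], p),
                           logical(1))]
    if (length(new) == 0) next
    for (p in new) {
      mark(proteome$accession[pi], p)
      sites[[length(sites) + 1]] <- data.frame(
        accession = proteome$accession[pi], position = as.integer(p),
        residue = sc[p], clustered = TRUE, stringsAsFactors = FALSE)
      placed <- placed + 1L
    }
  }
  # isolated sites on S/T/Y (Y with low probability)
  n_iso <- max(0L, config$n_sites - placed)
  avail <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(i) {
    sc <- seqs[[i]]
    pos <- sty_positions(sc)
    data.frame(accession = proteome$accession[i], position = pos,
               residue = sc[pos], stringsAsFactors = FALSE)
  }))
  avail <- avail[!mapply(taken, avail$accession, avail$position), ]
  if (nrow(avail) < n_iso)
    stopf("n_sites (%d) exceeds available S/T/Y residues (%d)",
          config$n_sites, nrow(avail) + placed)
  w <- ifelse(avail$residue == "Y", 0.02, 1)
  pick <- sample(nrow(avail), n_iso, prob = w)
  iso <- avail[pick, ]
  iso$clustered <- FALSE
  sites <- rbind(do.call(rbind, sites), iso)
  sites <- sites[order(sites$accession, sites$position), ]
  rownames(sites) <- NULL

  # --- isoform targets ---
  n_spec <- round(config$frac_isoform_specific * nrow(sites))
  target <- rep(NA_character_, nrow(sites))
  if (n_spec > 0 && length(kos) > 0)
    target[sample(nrow(sites), n_spec)] <- sample(kos, n_spec, replace = TRUE)
  sites$target <- target

  # --- PSMs ---
  psm_rows <- list()
  psm_id <- 0L
  prec_id <- 0L
  add_psm <- function(acc, pep_start, pep_end, pep, positions, probs, hexnac,
                      frag, score, prec, intens) {
    psm_id <<- psm_id + 1L
    row <- data.frame(psm_id = psm_id, precursor_id = prec, peptide = pep,
                      accession = acc, pep_start = pep_start,
                      pep_end = pep_end, hexnac_count = hexnac, hex_count = 0L,
                      site_positions = join_num(positions),
                      site_probabilities = join_num(probs),
                      frag_type = frag, psm_score = score,
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (ch in channels) row[[ch]] <- intens[ch]
    psm_rows[[length(psm_rows) + 1L]] <<- row
  }
  site_intensities <- function(baseline, site_targets) {
    # one value per channel; effect applied where the channel's condition
    # targets any of the covered sites
    eff <- ifelse(cond_of_channel %in% site_targets, config$effect_size, 1)
    v <- baseline * eff * lnoise(length(channels), config$cv_noise)
    names(v) <- channels
    v
  }
  make_peptide <- function(acc, pos_set) {
    L <- nchar(proteome$sequence[proteome$accession == acc])
    ps <- max(1L, min(pos_set) - sample(3:10, 1))
    pe <- min(L, max(pos_set) + sample(3:10, 1))
    list(start = as.integer(ps), end = as.integer(pe),
         seq = substr(proteome$sequence[proteome$accession == acc], ps, pe))
  }
  for (s in seq_len(nrow(sites))) {
    acc <- sites$accession[s]
    pos <- sites$position[s]
    pep <- make_peptide(acc, pos)
    baseline <- stats::rlnorm(1, log(1e6), 0.5)
    n_psm <- sample(1:3, 1)
    tgt <- sites$target[s]
    tgt <- if (is.na(tgt)) character(0) else tgt
    for (k in seq_len(n_psm)) {
      prec_id <- prec_id + 1L
      rel <- pos - pep$start + 1L
      prob <- if (stats::runif(1) < config$frac_low_loc)
        stats::runif(1, 50, 94) else stats::runif(1, 95.5, 100)
      score <- stats::runif(1, 50, 400)
      intens <- site_intensities(baseline, tgt)
      add_psm(acc, pep$start, pep$end, pep$seq, rel, round(prob, 1), 1L,
              "ETD", round(score, 1), prec_id, intens)
      add_psm(acc, pep$start, pep$end, pep$seq, numeric(0), numeric(0), 1L,
              "HCD", round(stats::runif(1, 50, 400), 1), prec_id,
              site_intensities(baseline, tgt))
    }
  }
  # multi-glycan PSMs over clustered sites (peptide-level evidence)
  clust <- sites[sites$clustered, ]
  if (nrow(clust) >= 2 && config$frac_multisite > 0) {
    by_acc <- split(clust, clust$accession)
    n_multi <- max(0L, round(config$frac_multisite * nrow(clust) / 2))
    for (m in seq_len(n_multi)) {
      g <- by_acc[[sample(length(by_acc), 1)]]
      if (nrow(g) < 2) next
      i0 <- sample(seq_len(max(1L, nrow(g) - 2L)), 1)
      cover <- g[i0:min(nrow(g), i0 + sample(1:2, 1)), ]
      pep <- make_peptide(cover$accession[1], cover$position)
      prec_id <- prec_id + 1L
      rel <- cover$position - pep$start + 1L
      probs <- round(stats::runif(length(rel), 95.5, 100), 1)
      tgts <- stats::na.omit(cover$target)
      baseline <- stats::rlnorm(1, log(1e6), 0.5)
      add_psm(cover$accession[1], pep$start, pep$end, pep$seq, rel, probs,
              nrow(cover), "ETD", round(stats::runif(1, 50, 400), 1), prec_id,
              site_intensities(baseline, tgts))
      add_psm(cover$accession[1], pep$start, pep$end, pep$seq, numeric(0),
              numeric(0), nrow(cover), "HCD",
              round(stats::runif(1, 50, 400), 1), prec_id,
              site_intensities(baseline, tgts))
    }
  }
  psms <- do.call(rbind, psm_rows)
  attr(psms, "channels") <- channels

  # --- protein-level (non-enriched) table ---
  ab_changed <- data.frame(accession = character(0), condition = character(0),
                           factor = numeric(0))
  hosts <- unique(sites$accession)
  n_ab <- min(config$n_abundance_changed, length(hosts))
  if (n_ab > 0 && length(kos) > 0) {
    ab_acc <- sample(hosts, n_ab)
    ab_changed <- data.frame(accession = ab_acc,
                             condition = sample(kos, n_ab, replace = TRUE),
                             factor = config$abundance_effect,
                             stringsAsFactors = FALSE)
  }
  prot_tab <- data.frame(accession = proteome$accession,
                         stringsAsFactors = FALSE, check.names = FALSE)
  for (ch in channels) {
    cond <- channel_condition(ch)
    f <- rep(1, nrow(proteome))
    hit <- match(prot_tab$accession, ab_changed$accession)
    sel <- !is.na(hit) & ab_changed$condition[hit] == cond
    f[sel] <- ab_changed$factor[hit[sel]]
    prot_tab[[ch]] <- 1e7 * f * lnoise(nrow(proteome), config$cv_noise)
  }

  # --- occupancy ground truth for the MS1 stage ---
  draw_occ <- function(n) {
    cls <- sample(c("high", "medium", "low"), n, replace = TRUE,
                  prob = config$occupancy_weights)
    occ <- numeric(n)
    occ[cls == "high"] <- stats::runif(sum(cls == "high"), 0.7501, 1)
    # within the high class, some regions are fully occupied (non-glyco form
    # never detectable -> exercises the High flag)
    full <- cls == "high" & stats::runif(n) < 0.3
    occ[full] <- 1
    occ[cls == "medium"] <- stats::runif(sum(cls == "medium"), 0.2501, 0.75)
    occ[cls == "low"] <- stats::runif(sum(cls == "low"), 0.001, 0.1)
    list(occ = occ, class = cls)
  }
  n_reg <- config$n_regions
  reg_rows <- list()
  if (n_reg > 0) {
    d <- draw_occ(n_reg)
    seen_span <- character(0)
    for (r in seq_len(n_reg)) {
      # distinct peptide regions carry distinct spans; retry collisions
      for (try in 1:100) {
        srow <- sites[sample(nrow(sites), 1), ]
        pep <- make_peptide(srow$accession, srow$position)
        span_key <- paste(srow$accession, pep$start, pep$end)
        if (!span_key %in% seen_span) break
      }
      seen_span <- c(seen_span, span_key)
      tn_max <- sample(seq_len(config$max_tn), 1)
      xtn <- stats::rgamma(tn_max, shape = 2)
      xtn <- xtn / sum(xtn)
      reg_rows[[r]] <- data.frame(region_id = sprintf("R%03d", r),
                                  accession = srow$accession,
                                  pep_start = pep$start, pep_end = pep$end,
                                  peptide = pep$seq, tn_max = tn_max,
                                  occupancy = d$occ[r], occ_class = d$class[r],
                                  xtn = join_num(signif(xtn, 10)),
                                  stringsAsFactors = FALSE)
    }
  }
  regions <- if (n_reg > 0) do.call(rbind, reg_rows) else NULL

  truth <- list(true_sites = sites[c("accession", "position", "residue",
                                     "clustered")],
                site_targets = sites[!is.na(sites$target),
                                     c("accession", "position", "target")],
                abundance_changed = ab_changed,
                regions = regions)
  list(truth = truth, psms = psms, protein_table = prot_tab)
}

#' Simulate an MS1 glycoform peak table
#'
#' For each ground-truth region and replicate, the non-glycosylated area is
#' `total * (1 - occupancy)` and glycoform `x` gets
#' `total * occupancy * xtn[x]`, each perturbed by lognormal noise; regions
#' with occupancy 1 emit no non-glycosylated row (detection absence). A
#' fraction of glycoforms is split over two charge states. Out-of-spec decoy
#' rows (mass error, idotp, retention time, or identification score outside
#' the acceptance windows) are appended and labeled so filter tests can
#' assert exact accept/reject sets.
#'
#' @param config A [sim_config()].
#' @param truth Ground-truth list from [simulate_sites_and_psms()].
#' @return List with `peaks` (peak data frame) and `decoys`
#'   (peak_id/reason labels for the appended out-of-spec rows).
#' @export
simulate_peak_table <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  stage_seed(config, 2L)
  regions <- truth$regions
  empty <- list(peaks = data.frame(), decoys = data.frame(
    peak_id = integer(0), reason = character(0)))
  if (is.null(regions) || nrow(regions) == 0) return(empty)
  rows <- list()
  peak_id <- 0L
  add_peak <- function(reg, glycoform, charge, area, ppm, idotp, rt, rep_lab,
                       score) {
    peak_id <<- peak_id + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      peak_id = peak_id, accession = reg$accession, region_id = reg$region_id,
      pep_start = reg$pep_start, pep_end = reg$pep_end, peptide = reg$peptide,
      glycoform = glycoform, charge = charge, area = area,
      mass_error_ppm = ppm, idotp = idotp, rt_delta_min = rt,
      replicate = rep_lab, id_score = score, stringsAsFactors = FALSE)
    peak_id
  }
  in_spec <- function() list(ppm = round(stats::runif(1, -1.2, 1.2), 2),
                             idotp = round(stats::runif(1, 0.88, 1), 3),
                             rt = round(stats::runif(1, -config$rt_jitter,
                                                     config$rt_jitter), 2),
                             score = round(stats::runif(1, 250, 600), 1))
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    xtn <- split_num(reg$xtn)
    for (rep_i in seq_len(config$replicates)) {
      rep_lab <- paste0("rep", rep_i)
      total <- stats::rlnorm(1, log(1e6), 0.3)
      if (reg$occupancy < 1) {
        q <- in_spec()
        add_peak(reg, 0L, sample(2:3, 1),
                 total * (1 - reg$occupancy) * lnoise(1, config$cv_noise),
                 q$ppm, q$idotp, q$rt, rep_lab, q$score)
      }
      for (x in seq_len(reg$tn_max)) {
        area <- total * reg$occupancy * xtn[x] * lnoise(1, config$cv_noise)
        q <- in_spec()
        if (stats::runif(1) < 0.2) {
          # split over two charge states to exercise charge summing
          fr <- stats::runif(1, 0.3, 0.7)
          add_peak(reg, x, 2L, area * fr, q$ppm, q$idotp, q$rt, rep_lab,
                   q$score)
          q2 <- in_spec()
          add_peak(reg, x, 3L, area * (1 - fr), q2$ppm, q2$idotp, q2$rt,
                   rep_lab, q2$score)
        } else {
          add_peak(reg, x, sample(2:3, 1), area, q$ppm, q$idotp, q$rt,
                   rep_lab, q$score)
        }
      }
    }
  }
  # labeled out-of-spec decoys
  decoys <- list()
  n_decoy <- round(config$decoy_fraction * length(rows))
  if (n_decoy > 0) {
    reasons <- sample(c("ppm", "idotp", "rt", "id_score"), n_decoy,
                      replace = TRUE)
    for (d in seq_len(n_decoy)) {
      reg <- regions[sample(nrow(regions), 1), ]
      q <- in_spec()
      ppm <- q$ppm; idotp <- q$idotp; rt <- q$rt; score <- q$score
      switch(reasons[d],
             ppm = { ppm <- round(sample(c(-1, 1), 1) * stats::runif(1, 1.5, 5), 2) },
             idotp = { idotp <- round(stats::runif(1, 0.5, 0.849), 3) },
             rt = { rt <- round(sample(c(-1, 1), 1) * stats::runif(1, 5, 15), 2) },
             id_score = { score <- round(stats::runif(1, 50, 199), 1) })
      id <- add_peak(reg, sample(0:reg$tn_max, 1), sample(2:3, 1),
                     stats::rlnorm(1, log(1e5), 0.5), ppm, idotp, rt,
                     paste0("rep", sample(config$replicates, 1)), score)
      decoys[[d]] <- data.frame(peak_id = id, reason = reasons[d],
                                stringsAsFactors = FALSE)
    }
  }
  list(peaks = do.call(rbind, rows),
       decoys = if (length(decoys)) do.call(rbind, decoys) else empty$decoys)
}

#' Run the full generator and optionally write all tables
#'
#' Convenience wrapper chaining [simulate_proteome()],
#' [simulate_sites_and_psms()] and [simulate_peak_table()].
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes the proteome
#'   FASTA, feature, PSM, protein, peak and ground-truth tables.
#' @return List with `proteome`, `features`, `truth`, `psms`,
#'   `protein_table`, `peaks`, `decoys`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  pr <- simulate_proteome(config)
  sp <- simulate_sites_and_psms(config, pr$proteome, pr$features)
  pk <- simulate_peak_table(config, sp$truth)
  out <- list(proteome = pr$proteome, features = pr$features,
              truth = sp$truth, psms = sp$psms,
              protein_table = sp$protein_table,
              peaks = pk$peaks, decoys = pk$decoys)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(out$proteome, file.path(dir, "proteome.fasta"))
    write_features(out$features, file.path(dir, "features.tsv"))
    write_psm_table(out$psms, file.path(dir, "psms.tsv"))
    write_tsv(out$protein_table, file.path(dir, "protein_table.tsv"),
              "protein_table")
    write_peak_table(out$peaks, file.path(dir, "peaks.tsv"))
    write_tsv(out$truth$true_sites, file.path(dir, "truth_sites.tsv"),
              "truth_sites")
  }
  out
}
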