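# Protein with S/T/Y at known places: positions 100..110 spell "AASTYAAAST?"
# within a 200-residue background of A with planted residues.
catalog_protein <- function() {
  s <- rep("A", 200)
  s[102] <- "S"; s[103] <- "T"; s[104] <- "Y"
  s[108] <- "S"; s[109] <- "T"
  make_protein("P1", paste(s, collapse = ""))
}

test_that("localized positions map to protein coordinates via pep_start + pos - 1", {
  prot <- catalog_protein()
  pep <- substr(prot$sequence, 100, 110)
  psm <- make_psm(1, peptide = pep, accession = "P1", pep_start = 100,
                  positions = 3, probabilities = 99.2)
  cat1 <- build_catalog(psm, prot)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$position, 102L)
  expect_equal(cat1$residue, "S")
  expect_equal(cat1$status, "unambiguous")
  expect_true(is.na(cat1$amb_start))
})

test_that("sub-cutoff localization yields an ambiguous site spanning the peptide S/T/Y range", {
  prot <- catalog_protein()
  pep <- substr(prot$sequence, 100, 110)
  psm <- make_psm(1, peptide = pep, accession = "P1", pep_start = 100,
                  positions = 3, probabilities = 80)
  cat1 <- build_catalog(psm, prot)
  expect_equal(cat1$status, "ambiguous")
  expect_true(is.na(cat1$position))
  # S/T/Y span of the peptide: first S at 102, last T at 109
  expect_equal(cat1$amb_start, 102L)
  expect_equal(cat1$amb_end, 109L)
  # a probability exactly at the cutoff is not sufficient (strict >)
  psm2 <- make_psm(1, peptide = pep, accession = "P1", pep_start = 100,
                   positions = 3, probabilities = 95)
  expect_equal(build_catalog(psm2, prot)$status, "ambiguous")
})

test_that("duplicate sites merge with summed PSM support and best-scoring PSM kept", {
  prot <- catalog_protein()
  pep <- substr(prot$sequence, 100, 110)
  psms <- rbind(
    make_psm(1, peptide = pep, accession = "P1", pep_start = 100,
             positions = 3, probabilities = 99, psm_score = 50),
    make_psm(2, peptide = pep, accession = "P1", pep_start = 100,
             positions = 3, probabilities = 98, psm_score = 90),
    make_psm(3, peptide = pep, accession = "P1", pep_start = 100,
             positions = 3, probabilities = 97, psm_score = 70))
  cat1 <- build_catalog(psms, prot)
  expect_equal(nrow(cat1), 1)
  expect_equal(cat1$n_psms, 3L)
  expect_equal(cat1$best_psm, 2)
})

test_that("HCD spectra never contribute localization and bad references error", {
  prot <- catalog_protein()
  pep <- substr(prot$sequence, 100, 110)
  hcd <- make_psm(1, peptide = pep, accession = "P1", pep_start = 100,
                  positions = 3, probabilities = 99, frag_type = "HCD")
  expect_equal(nrow(build_catalog(hcd, prot)), 0)
  expect_error(build_catalog(
    make_psm(1, peptide = pep, accession = "NOPE", pep_start = 100,
             positions = 3, probabilities = 99), prot), "unknown accession")
  expect_error(build_catalog(
    make_psm(1, peptide = pep, accession = "P1", pep_start = 100,
             positions = 1, probabilities = 99), prot), "not S/T/Y")
})

test_that("quantification uses the HCD partner of the best-scoring ETD PSM", {
  pep <- "AASTYAAAK"
  mk <- function(id, frag, score, prec, wt1) {
    make_psm(id, precursor_id = prec, peptide = pep, accession = "P1",
             pep_start = 100, positions = if (frag == "ETD") 3 else numeric(0),
             probabilities = if (frag == "ETD") 99 else numeric(0),
             frag_type = frag, psm_score = score,
             intensities = list("WT:1" = wt1))
  }
  psms <- rbind(mk(1, "ETD", 50, 1, 10), mk(2, "HCD", 10, 1, 111),
                mk(3, "ETD", 90, 2, 20), mk(4, "HCD", 11, 2, 222),
                mk(5, "ETD", 70, 3, 30), mk(6, "HCD", 12, 3, 333))
  q <- select_quant_psm(psms)
  expect_equal(q$psm_id, 4)
  expect_equal(q[["WT:1"]], 222)
  # single PSM: itself
  expect_equal(select_quant_psm(psms[1, ])$psm_id, 1)
  # tie on top score: first in input order wins
  tie <- rbind(mk(1, "ETD", 90, 1, 10), mk(2, "HCD", 10, 1, 111),
               mk(3, "ETD", 90, 2, 20), mk(4, "HCD", 11, 2, 222))
  expect_equal(select_quant_psm(tie)$psm_id, 2)
  # no ETD evidence: excluded (NULL)
  expect_null(select_quant_psm(psms[psms$frag_type == "HCD", ]))
})

test_that("single-site filtering routes multi-glycan and mixed-evidence peptides away", {
  pep <- "AASTYAAAK"
  single <- make_psm(1, peptide = pep, accession = "P1", pep_start = 100,
                     hexnac_count = 1, positions = 3, probabilities = 99)
  multi <- make_psm(2, peptide = pep, accession = "P2", pep_start = 100,
                    hexnac_count = 3, positions = c(3, 4, 5),
                    probabilities = c(99, 99, 99))
  mixed1 <- make_psm(3, peptide = pep, accession = "P3", pep_start = 100,
                     hexnac_count = 1, positions = 3, probabilities = 99)
  mixed2 <- make_psm(4, peptide = pep, accession = "P3", pep_start = 100,
                     hexnac_count = 2, positions = c(3, 4),
                     probabilities = c(99, 99))
  out <- single_site_filter(rbind(single, multi, mixed1, mixed2))
  expect_equal(out$single_site$psm_id, 1)
  expect_setequal(out$multi_site$psm_id, c(2, 3, 4))
})

test_that("catalog construction matches the brute-force (PSM, position) oracle", {
  set.seed(42)
  for (rep in 1:25) {
    s <- sample(c("A", "G", "S", "T", "Y", "P"), 120, replace = TRUE)
    prot <- make_protein("PX", paste(s, collapse = ""))
    n_psm <- sample(3:20, 1)
    psms <- do.call(rbind, lapply(seq_len(n_psm), function(i) {
      ps <- sample(1:100, 1)
      pep <- substr(prot$sequence, ps, ps + 14)
      sty <- which(strsplit(pep, "")[[1]] %in% c("S", "T", "Y"))
      if (length(sty) == 0) return(NULL)
      k <- sample(seq_len(min(3, length(sty))), 1)
      pos <- sort(sample(sty, k))
      make_psm(i, peptide = pep, accession = "PX", pep_start = ps,
               hexnac_count = k, positions = pos,
               probabilities = round(runif(k, 60, 100), 1),
               psm_score = round(runif(1, 10, 100), 1))
    }))
    if (is.null(psms)) next
    got <- build_catalog(psms, prot)
    un <- got[got$status == "unambiguous", ]
    expect_identical(sort(paste(un$accession, un$position)),
                     catalog_oracle(psms))
  }
})

test_that("with confident localization everywhere the catalog equals the ground truth", {
  cfg <- sim_config(seed = 5, n_proteins = 15, n_sites = 120,
                    conditions = c("WT", "T2"), frac_low_loc = 0,
                    n_regions = 0)
  d <- simulate_dataset(cfg)
  catal <- build_catalog(d$psms, d$proteome)
  expect_true(all(catal$status == "unambiguous"))
  got <- sort(paste(catal$accession, catal$position))
  want <- sort(paste(d$truth$true_sites$accession,
                     d$truth$true_sites$position))
  expect_identical(got, want)
})

test_that("catalog overlap reports intersections relative to the reference", {
  mk_cat <- function(pos) {
    structure(data.frame(accession = "P1", position = pos, residue = "S",
                         status = "unambiguous", stringsAsFactors = FALSE),
              class = c("glyco_catalog", "data.frame"))
  }
  a <- mk_cat(1:100)
  expect_equal(compare_catalogs(a, a)$site_overlap_pct, 100)
  expect_equal(compare_catalogs(a, a)$protein_overlap_pct, 100)
  b <- mk_cat(101:200)
  expect_equal(compare_catalogs(a, b)$site_overlap_pct, 0)
  expect_equal(compare_catalogs(mk_cat(1:77), mk_cat(1:100))$site_overlap_pct,
               77)
})
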