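test_that("peak acceptance windows use the documented boundary semantics", {
  ok <- make_peak(1, mass_error_ppm = 1.2, idotp = 0.90, rt_delta_min = 3)
  expect_equal(nrow(filter_peaks(ok)$rejected), 0)

  low_idotp <- make_peak(2, idotp = 0.80)
  r <- filter_peaks(low_idotp)
  expect_equal(nrow(r$accepted), 0)
  expect_equal(r$rejected$reason, "idotp")
  # boundaries are strict: -1.5 ppm, idotp 0.85 and rt 5 min are all rejected
  expect_equal(filter_peaks(make_peak(3, mass_error_ppm = -1.5))$rejected$reason,
               "ppm")
  expect_equal(filter_peaks(make_peak(4, idotp = 0.85))$rejected$reason,
               "idotp")
  expect_equal(filter_peaks(make_peak(5, rt_delta_min = 5))$rejected$reason,
               "rt")
  # identification score 200 is inclusive
  expect_equal(nrow(filter_peaks(make_peak(6, id_score = 200))$rejected), 0)
  expect_equal(filter_peaks(make_peak(7, id_score = 199))$rejected$reason,
               "id_score")
  # several violations join reason codes
  multi <- filter_peaks(make_peak(8, mass_error_ppm = 3, idotp = 0.5))
  expect_equal(multi$rejected$reason, "ppm;idotp")
})

test_that("isotopologue relative-abundance filtering applies when supplied", {
  pk <- rbind(make_peak(1), make_peak(2))
  pk$iso_rel_abund <- c(50, 15)
  r <- filter_peaks(pk)
  expect_equal(r$accepted$peak_id, 1)
  expect_equal(r$rejected$reason, "iso_rel_abund")
})

test_that("filtering simulated decoys recovers the ground-truth accept/reject sets exactly", {
  d <- simulate_dataset(sim_config(seed = 23, n_proteins = 10, n_sites = 40,
                                   conditions = c("WT", "T2"), n_regions = 30,
                                   decoy_fraction = 0.25))
  r <- filter_peaks(d$peaks)
  expect_setequal(r$rejected$peak_id, d$decoys$peak_id)
  # idempotence: filtering an accepted set changes nothing
  r2 <- filter_peaks(r$accepted)
  expect_identical(r2$accepted, r$accepted)
  expect_equal(nrow(r2$rejected), 0)
})

test_that("the occupancy ratio and xTn shares follow the total-area formula", {
  pk <- rbind(make_peak(1, glycoform = 1, area = 80),
              make_peak(2, glycoform = 2, area = 15),
              make_peak(3, glycoform = 0, area = 5))
  rec <- compute_occupancy(pk)
  expect_equal(rec$glyco_ratio, 0.95)
  expect_false(rec$high_flag)
  expect_equal(rec$xtn_percent, c("1" = 84, "2" = 16))
  expect_equal(rec$xtn_percent_raw, c("1" = 8000 / 95, "2" = 1500 / 95))
})

test_that("charge states are summed within glycoform before the ratio", {
  pk <- rbind(make_peak(1, glycoform = 1, charge = 2, area = 30),
              make_peak(2, glycoform = 1, charge = 3, area = 50),
              make_peak(3, glycoform = 0, charge = 2, area = 20))
  expect_equal(compute_occupancy(pk)$glyco_ratio, 0.8)
})

test_that("replicate summaries give mean, SD and the High flag on total absence", {
  mk_rep <- function(rep, g, ng) rbind(
    make_peak(rep * 10, glycoform = 1, area = g, replicate = paste0("rep", rep)),
    make_peak(rep * 10 + 1, glycoform = 0, area = ng,
              replicate = paste0("rep", rep)))
  pk <- rbind(mk_rep(1, 92, 8), mk_rep(2, 93, 7), mk_rep(3, 94, 6))
  rec <- compute_occupancy(pk)
  expect_equal(rec$glyco_ratio, 0.93)
  expect_equal(rec$sd, sd(c(0.92, 0.93, 0.94)))
  expect_equal(rec$n_replicates, 3)

  # non-glycosylated form absent everywhere -> High, xTn still reported
  glyc_only <- rbind(make_peak(1, glycoform = 1, area = 60),
                     make_peak(2, glycoform = 2, area = 40))
  rec2 <- compute_occupancy(glyc_only)
  expect_true(rec2$high_flag)
  expect_true(is.na(rec2$glyco_ratio))
  expect_equal(rec2$xtn_percent, c("1" = 60, "2" = 40))

  # partial detection: ratio over detected replicates only, flagged
  pk3 <- rbind(mk_rep(1, 90, 10),
               make_peak(99, glycoform = 1, area = 50, replicate = "rep2"))
  rec3 <- compute_occupancy(pk3)
  expect_true(rec3$partial_flag)
  expect_equal(rec3$glyco_ratio, 0.9)

  expect_warning(rec4 <- compute_occupancy(make_peak(1, glycoform = 0)),
                 "no glycoform")
  expect_null(rec4)
})

test_that("occupancy is invariant to rescaling all areas of a region", {
  pk <- rbind(make_peak(1, glycoform = 1, area = 37),
              make_peak(2, glycoform = 2, area = 11),
              make_peak(3, glycoform = 0, area = 29))
  a <- compute_occupancy(pk)
  pk$area <- pk$area * 1234.5
  b <- compute_occupancy(pk)
  expect_equal(a$glyco_ratio, b$glyco_ratio)
  expect_equal(a$xtn_percent_raw, b$xtn_percent_raw)
})

test_that("noise-free simulated regions are recovered to machine precision", {
  cfg <- sim_config(seed = 29, n_proteins = 10, n_sites = 40,
                    conditions = c("WT", "T2"), n_regions = 40, cv_noise = 0,
                    decoy_fraction = 0)
  d <- simulate_dataset(cfg)
  occ <- occupancy_table(d$peaks)
  m <- merge(occ, d$truth$regions, by = "region_id")
  not_high <- !m$high_flag
  expect_equal(m$glyco_ratio[not_high], m$occupancy[not_high],
               tolerance = 1e-9)
  expect_true(all(m$occupancy[m$high_flag] == 1))
  # xTn percentages sum to 100 within integer rounding
  sums <- vapply(strsplit(occ$xtn_percent, ";"),
                 function(x) sum(as.numeric(x)), numeric(1))
  expect_true(all(abs(sums - 100) <= 1 + 1e-9))
})

test_that("occupancy classes split at the documented ratio boundaries", {
  mk_rec <- function(ratio, high = FALSE)
    data.frame(glyco_ratio = ifelse(high, NA, ratio), high_flag = high)
  recs <- rbind(mk_rec(0.9), mk_rec(NA, TRUE), mk_rec(0.5), mk_rec(0.05),
                mk_rec(0.15), mk_rec(0.0005))
  cls <- classify_occupancy(recs)
  got <- setNames(cls$count, cls$class)
  expect_equal(got[["high"]], 2)
  expect_equal(got[["medium"]], 1)
  expect_equal(got[["low"]], 1)
  expect_equal(got[["gap"]], 1)
  expect_equal(got[["below_floor"]], 1)
  empty <- classify_occupancy(recs[0, ])
  expect_true(all(empty$count == 0))
})

test_that("condition comparison regresses matched peptides and flags small overlaps", {
  mk_tab <- function(ratios, peptides = paste0("PEP", seq_along(ratios)))
    data.frame(peptide = peptides, glyco_ratio = ratios,
               high_flag = FALSE, stringsAsFactors = FALSE)
  a <- mk_tab(c(0.1, 0.4, 0.6, 0.9))
  # exact collinearity triggers R's perfect-fit warning; the fit itself is
  # what is under test
  cmp <- suppressWarnings(compare_conditions(a, a))
  expect_equal(cmp$r_squared, 1)
  expect_equal(cmp$slope, 1)
  anti <- mk_tab(1 - c(0.1, 0.4, 0.6, 0.9))
  expect_equal(suppressWarnings(compare_conditions(anti, a))$slope, -1)
  small <- compare_conditions(mk_tab(c(0.1, 0.2)), mk_tab(c(0.1, 0.2)))
  expect_true(small$insufficient)

  # two noisy peak sets from the same truth correlate strongly
  base <- sim_config(seed = 31, n_proteins = 10, n_sites = 40,
                     conditions = c("WT", "T2"), n_regions = 60,
                     cv_noise = 0.1, decoy_fraction = 0)
  d <- simulate_dataset(base)
  other <- base
  other$seed <- 32L
  pk2 <- simulate_peak_table(other, d$truth)
  occ_a <- occupancy_table(d$peaks)
  occ_b <- occupancy_table(pk2$peaks)
  cmp2 <- compare_conditions(occ_a, occ_b)
  expect_gte(cmp2$n_matched, 10)
  expect_gte(cmp2$r_squared, 0.9)
})
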