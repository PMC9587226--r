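seq_of <- function(n) paste(rep("A", n), collapse = "")

test_that("stem, terminus, linker and unassigned follow the window rules", {
  # type-I protein, TM 401-421: site 370 is 31 aa N-terminal of the TM
  prot <- make_protein("P1", seq_of(500), topology = "type_I")
  tm <- make_feature("P1", "transmembrane", 401, 421)
  cl <- classify_site(370, prot, tm)
  expect_equal(cl$category, "stem")
  expect_equal(cl$distance, 31L)
  # just past the stem window
  expect_equal(classify_site(350, prot, tm)$category, "unassigned")
  # cytosolic side of a type-I protein is never stem
  expect_equal(classify_site(430, prot, tm)$category, "unassigned")

  # signal peptide 1-20: mature N-terminus is 21, site 25 is its 5th residue
  prot2 <- make_protein("P2", seq_of(500), topology = "secreted")
  sig <- make_feature("P2", "signal_peptide", 1, 20)
  expect_equal(classify_site(25, prot2, sig)$category, "terminus")
  expect_equal(classify_site(30, prot2, sig)$category, "terminus")
  expect_equal(classify_site(31, prot2, sig)$category, "unassigned")
  # C-terminal window
  expect_equal(classify_site(495, prot2, sig)$category, "terminus")

  # linker requires an inter-domain gap strictly below 100 aa
  doms_wide <- rbind(make_feature("P2", "domain", 100, 200, "D1"),
                     make_feature("P2", "domain", 320, 400, "D2"))
  expect_equal(classify_site(260, prot2, doms_wide)$category, "unassigned")
  doms_close <- rbind(make_feature("P2", "domain", 100, 200, "D1"),
                      make_feature("P2", "domain", 250, 320, "D2"))
  cl <- classify_site(225, prot2, doms_close)
  expect_equal(cl$category, "linker")
  expect_equal(c(cl$feature_start, cl$feature_end), c(201L, 249L))
})

test_that("type-II stems lie C-terminal of the transmembrane span", {
  prot <- make_protein("P1", seq_of(500), topology = "type_II")
  tm <- make_feature("P1", "transmembrane", 30, 50)
  cl <- classify_site(80, prot, tm)
  expect_equal(cl$category, "stem")
  expect_equal(cl$distance, 30L)
  expect_equal(classify_site(5, prot, tm)$category, "terminus")
  expect_equal(classify_site(101, prot, tm)$category, "unassigned")
})

test_that("domain membership beats stem in the precedence order", {
  prot <- make_protein("P1", seq_of(500), topology = "type_I")
  feats <- rbind(make_feature("P1", "transmembrane", 401, 421),
                 make_feature("P1", "domain", 350, 390, "Cadherin"))
  cl <- classify_site(371, prot, feats)  # in the domain AND 30 aa from TM
  expect_equal(cl$category, "domain")
  expect_equal(cl$feature_label, "Cadherin")
})

test_that("the classifier agrees with the explicit residue-set oracle on random architectures", {
  set.seed(99)
  topo_pool <- c("type_I", "type_II", "secreted", "other")
  for (rep in 1:40) {
    L <- sample(200:500, 1)
    topo <- sample(topo_pool, 1)
    prot <- make_protein("PR", seq_of(L), topology = topo)
    feats <- make_feature("PR", "domain", 1, 1, "zz")[0, ]
    if (topo == "type_I") {
      ts <- sample(150:(L - 30), 1)
      feats <- rbind(feats, make_feature("PR", "transmembrane", ts, ts + 20))
    } else if (topo == "type_II") {
      ts <- sample(25:60, 1)
      feats <- rbind(feats, make_feature("PR", "transmembrane", ts, ts + 20))
    }
    if (runif(1) < 0.5)
      feats <- rbind(feats, make_feature("PR", "signal_peptide", 1,
                                         sample(15:25, 1)))
    cursor <- 40
    for (d in seq_len(sample(0:3, 1))) {
      st <- cursor + sample(5:80, 1)
      en <- st + sample(20:60, 1)
      if (en > L - 10) break
      feats <- rbind(feats, make_feature("PR", "domain", st, en,
                                         paste0("D", d)))
      cursor <- en
    }
    if (runif(1) < 0.5) {
      fs <- sample(1:(L - 12), 1)
      feats <- rbind(feats, make_feature("PR", "functional_region", fs,
                                         fs + 10, "site"))
    }
    for (pos in sample(L, 40)) {
      got <- classify_site(pos, prot, feats)$category
      expect_equal(got, region_oracle(pos, prot, feats),
                   info = sprintf("rep %d topo %s pos %d", rep, topo, pos))
    }
  }
})

test_that("stem and linker counts respond monotonically to their windows", {
  set.seed(7)
  d <- simulate_dataset(sim_config(seed = 21, n_proteins = 25, n_sites = 150,
                                   conditions = c("WT", "T2"), n_regions = 0))
  catal <- build_catalog(d$psms, d$proteome)
  count_cat <- function(stem_window = 50, linker_max = 100) {
    a <- classify_sites(catal, d$proteome, d$features,
                        stem_window = stem_window, linker_max = linker_max)
    table(factor(a$category, levels = c("domain", "stem", "functional_region",
                                        "terminus", "linker", "unassigned")))
  }
  base <- count_cat()
  wider <- count_cat(stem_window = 80)
  expect_gte(wider[["stem"]], base[["stem"]])
  narrower <- count_cat(linker_max = 40)
  expect_lte(narrower[["linker"]], base[["linker"]])
})

test_that("region summaries report one-decimal percentages that cover every site", {
  mk_assign <- function(counts) {
    data.frame(category = rep(names(counts), counts),
               stringsAsFactors = FALSE)
  }
  a <- mk_assign(c(stem = 330, linker = 155, terminus = 192,
                   functional_region = 142, domain = 353, unassigned = 1718))
  s <- summarize_regions(a)
  expect_equal(sum(s$count[s$category %in% c("domain", "stem",
                                             "functional_region", "terminus",
                                             "linker", "unassigned")]),
               nrow(a))
  expect_equal(s$pct[s$category == "stem"], 11.4)
  # all-unassigned: every named category at 0%
  s0 <- summarize_regions(mk_assign(c(unassigned = 50)))
  expect_true(all(s0$pct[s0$category != "unassigned"] == 0))
})

test_that("domain statistics count instances, rates and boundary bins correctly", {
  prot <- make_protein("P1", seq_of(400))
  feats <- do.call(rbind, lapply(0:3, function(i)
    make_feature("P1", "domain", 50 + i * 80, 50 + i * 80 + 39, "Cadherin")))
  catal <- structure(
    data.frame(accession = "P1", position = c(50L, 89L, 150L),
               residue = "S", status = "unambiguous",
               stringsAsFactors = FALSE),
    class = c("glyco_catalog", "data.frame"))
  ds <- domain_statistics(catal, prot, feats)
  expect_equal(ds$n_domains_total, 4L)
  expect_equal(ds$n_domains_glycosylated, 2L)
  expect_equal(ds$rate, 0.5)
  # site at domain start falls in bin 1, at domain end in bin 10
  expect_equal(ds$bin1, 1)
  expect_equal(ds$bin10, 1)
  expect_equal(sum(ds[paste0("bin", 1:10)]), ds$n_sites)
})
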