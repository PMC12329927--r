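# Adjudication fixtures built directly from classification-result stubs.
stub_result <- function(otu_id, group, method = "tophit", db = "db",
                        marker = "ITS1") {
  species <- if (length(group) == 1) group else NA_character_
  genus <- {
    g <- unique(genus_of(group))
    if (length(g) == 1) g else NA_character_
  }
  dmcbench:::new_classification_result(otu_id, method, db, marker,
                                       species = species, genus = genus,
                                       group = sort(group))
}

stub_community <- function(members, dmc_id = "DMC01") {
  out <- data.frame(dmc_id = dmc_id, replicate_of = NA_character_,
                    stringsAsFactors = FALSE)
  out$members <- list(members)
  out
}

MEMBERS <- c("Genus01 fictum1", "Genus02 fictum1", "Genus03 fictum1",
             "Genus04 fictum1", "Genus05 fictum1")

test_that("synonym canonicalisation matches either name and follows chains", {
  map <- c("Alias tassiana" = "Genus01 fictum1")
  expect_equal(apply_synonyms("Alias tassiana", map), "Genus01 fictum1")
  expect_equal(apply_synonyms("Unmapped name", map), "Unmapped name")
  chain <- c(A = "B", B = "C")
  expect_equal(apply_synonyms(c("A", "B", "C"), chain), rep("C", 3))
  # a call naming the synonym of a member adjudicates as TP
  com <- stub_community(MEMBERS)
  res <- stub_result("o1", "Alias tassiana")
  call <- adjudicate(res, com, "species", "strict", synonym_map = map)
  expect_equal(call$verdict, "TP")
})

test_that("strict and loose settings implement the three-way verdicts", {
  com <- stub_community(MEMBERS)
  # single hit = member -> TP in both settings
  for (s in c("strict", "loose")) {
    call <- adjudicate(stub_result("o", MEMBERS[1]), com, "species", s)
    expect_equal(call$verdict, "TP")
    expect_equal(call$matched_taxon, MEMBERS[1])
  }
  # equivalence group of 2 containing a member: strict FN, loose TP
  grp <- c(MEMBERS[1], "Genus01 fictum9")
  expect_equal(adjudicate(stub_result("o", grp), com, "species", "strict")$verdict,
               "FN_unclassified")
  expect_equal(adjudicate(stub_result("o", grp), com, "species", "loose")$verdict,
               "TP")
  # single non-member -> FP in both
  for (s in c("strict", "loose")) {
    expect_equal(adjudicate(stub_result("o", "Genus09 fictum1"), com,
                            "species", s)$verdict, "FP")
  }
  # loose FP from a member-free group reports a seeded random representative
  grp2 <- c("Genus08 fictum1", "Genus09 fictum1")
  c1 <- adjudicate(stub_result("oX", grp2), com, "species", "loose", seed = 5)
  c2 <- adjudicate(stub_result("oX", grp2), com, "species", "loose", seed = 5)
  expect_equal(c1$verdict, "FP")
  expect_true(c1$matched_taxon %in% grp2)
  expect_identical(c1$matched_taxon, c2$matched_taxon)
  # unclassified results are FN regardless of setting
  unc <- dmcbench:::new_classification_result("o", "tophit", "db", "ITS1",
                                              reason = "no_hit")
  expect_equal(adjudicate(unc, com, "species", "loose")$verdict,
               "FN_unclassified")
})

test_that("genus-level adjudication rescues congeners and collapses groups", {
  com <- stub_community(MEMBERS)
  # wrong species, right genus: species FP, genus TP
  res <- stub_result("o", "Genus03 fictum9")
  expect_equal(adjudicate(res, com, "species", "strict")$verdict, "FP")
  expect_equal(adjudicate(res, com, "genus", "strict")$verdict, "TP")
  # a within-genus equivalence group is unique at genus level
  grp <- c("Genus03 fictum1", "Genus03 fictum9")
  expect_equal(adjudicate(stub_result("o", grp), com, "genus", "strict")$verdict,
               "TP")
  # species TP implies genus TP over randomized scenarios (hierarchy)
  set.seed(7)
  for (i in 1:50) {
    grp <- sample(c(MEMBERS, "Genus08 fictum1", "Genus09 fictum1"),
                  sample(1:3, 1))
    res <- stub_result("o", grp)
    for (s in c("strict", "loose")) {
      sp <- adjudicate(res, com, "species", s)
      ge <- adjudicate(res, com, "genus", s)
      if (sp$verdict == "TP") expect_equal(ge$verdict, "TP")
      if (s == "strict" && sp$verdict == "TP") {
        expect_equal(adjudicate(res, com, "species", "loose")$verdict, "TP")
      }
    }
  }
})

test_that("subgeneric mapping rescues single-section groups only", {
  com <- stub_community(MEMBERS)
  submap <- data.frame(
    species = c("Genus01 fictum1", "Genus01 fictum2", "Genus01 fictum3",
                "Genus01 fictum4"),
    subgeneric_kind = "section",
    subgeneric_name = c("S1", "S1", "S1", "S2"),
    stringsAsFactors = FALSE)
  # all three congeners in section S1, truth member in S1: rescued
  grp <- c("Genus01 fictum1", "Genus01 fictum2", "Genus01 fictum3")
  res <- stub_result("o", grp)
  call <- adjudicate(res, com, "species", "strict")
  expect_equal(call$verdict, "FN_unclassified")
  up <- map_subgeneric(call, res, com, submap)
  expect_equal(up$verdict, "TP")
  expect_equal(up$level, "subgeneric")
  expect_equal(up$matched_taxon, "S1")
  # group spanning two sections: unchanged
  grp2 <- c("Genus01 fictum2", "Genus01 fictum4")
  res2 <- stub_result("o", grp2)
  call2 <- adjudicate(res2, com, "species", "strict")
  expect_equal(map_subgeneric(call2, res2, com, submap)$verdict,
               "FN_unclassified")
  # species-level TP is a no-op
  res3 <- stub_result("o", MEMBERS[1])
  call3 <- adjudicate(res3, com, "species", "strict")
  expect_equal(map_subgeneric(call3, res3, com, submap)$verdict, "TP")
  # missing map entries leave the call unchanged but logged
  res4 <- stub_result("o", c("Genus02 fictum1", "Genus02 fictum9"))
  call4 <- adjudicate(res4, com, "species", "strict")
  up4 <- map_subgeneric(call4, res4, com, submap)
  expect_equal(up4$verdict, "FN_unclassified")
  expect_equal(up4$notes, "subgeneric_map_missing")
})

test_that("consensus requires agreement in both markers", {
  com <- stub_community(MEMBERS)
  adj <- function(group, marker, otu) {
    adjudicate(stub_result(otu, group, marker = marker), com, "species",
               "loose")
  }
  c1 <- do.call(rbind, list(adj(MEMBERS[1], "ITS1", "a"),
                            adj(MEMBERS[2], "ITS1", "b"),
                            adj("Genus09 fictum1", "ITS1", "c")))
  c2 <- do.call(rbind, list(adj(MEMBERS[1], "ITS2", "d"),
                            adj("Genus08 fictum1", "ITS2", "e"),
                            adj("Genus09 fictum1", "ITS2", "f")))
  cc <- consensus_combine(c1, c2, com, "species")
  # member1 TP in both -> consensus TP; member2 TP only in ITS1 -> FN
  expect_equal(cc$tp_taxa, MEMBERS[1])
  expect_true(MEMBERS[2] %in% cc$fn_taxa)
  # FP taxon called in both markers -> consensus FP; Genus08 called once -> FP
  expect_setequal(cc$fp_taxa, c("Genus08 fictum1", "Genus09 fictum1"))
  expect_equal(cc$counts$TP, 1)
  expect_equal(cc$counts$FN, 4)
})

test_that("confusion tallies equal a brute-force recount and metrics match Table-style formulas", {
  set.seed(11)
  com <- stub_community(MEMBERS)
  calls <- do.call(rbind, lapply(1:40, function(i) {
    grp <- sample(c(MEMBERS, "Genus08 fictum1", "Genus09 fictum1"),
                  sample(1:3, 1))
    adjudicate(stub_result(paste0("o", i), grp), com,
               sample(c("species", "genus"), 1),
               sample(c("strict", "loose"), 1), seed = i)
  }))
  cc <- confusion_counts(calls)
  for (r in seq_len(nrow(cc))) {
    sub <- calls[calls$level == cc$level[r] & calls$setting == cc$setting[r], ]
    expect_equal(cc$TP[r], sum(sub$verdict == "TP"))
    expect_equal(cc$FP[r], sum(sub$verdict == "FP"))
    expect_equal(cc$FN[r], sum(sub$verdict == "FN_unclassified"))
  }
  # direct formula checks
  m <- metrics(data.frame(TP = c(5, 3, 0), FP = c(0, 1, 0), FN = c(0, 2, 2)))
  expect_equal(m$precision, c(100, 75, NA))
  expect_equal(m$recall, c(100, 60, 0))
  expect_equal(m$f1, c(1, 6 / 9, 0))
  # undefined entries are excluded from aggregates
  m$level <- "species"; m$db <- "d"; m$method <- "t"; m$setting <- "s"
  m$marker <- "ITS1"
  s <- metrics_summary(m)
  expect_equal(s$precision_mean, 87.5)
  expect_equal(s$n_dmcs, 2)
  expect_equal(s$recall_mean, mean(c(100, 60, 0)))
})

test_that("abundance profiles renormalise over classified reads and bound L1", {
  com <- stub_community(MEMBERS)
  tab <- data.frame(otu_id = paste0("o", 1:5),
                    total_count = rep(200L, 5), stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(1:5, function(i) {
    adjudicate(stub_result(paste0("o", i), MEMBERS[i]), com, "species",
               "strict")
  }))
  p <- abundance_profile(tab, calls, com)
  expect_equal(p$l1, 0)
  # all classified mass on non-members: L1 = 2
  wrong <- do.call(rbind, lapply(1:5, function(i) {
    adjudicate(stub_result(paste0("o", i), sprintf("Genus%02d fictum9", i + 10)),
               com, "species", "strict")
  }))
  expect_equal(abundance_profile(tab, wrong, com)$l1, 2)
  # one member doubled, one missing: L1 = 0.4 (brute-force over the taxa)
  tab2 <- data.frame(otu_id = paste0("o", 1:4),
                     total_count = c(400L, 200L, 200L, 200L))
  calls2 <- do.call(rbind, lapply(1:4, function(i) {
    adjudicate(stub_result(paste0("o", i), MEMBERS[i]), com, "species",
               "strict")
  }))
  p2 <- abundance_profile(tab2, calls2, com)
  expect_equal(p2$l1, abs(0.4 - 0.2) + 0.2, tolerance = 1e-12)
  # no classified OTUs: NULL (excluded)
  unc <- calls; unc$verdict <- "FN_unclassified"
  expect_null(abundance_profile(tab, unc, com))
})

test_that("threshold sweeps are monotone with 21 grid points", {
  set.seed(13)
  com <- stub_community(MEMBERS)
  tab <- data.frame(otu_id = paste0("o", 1:8),
                    total_count = c(500L, 300L, 100L, 40L, 20L, 10L, 4L, 1L),
                    stringsAsFactors = FALSE)
  calls <- do.call(rbind, lapply(1:8, function(i) {
    grp <- if (i <= 5) MEMBERS[i] else sprintf("Genus%02d fictum9", i + 10)
    adjudicate(stub_result(paste0("o", i), grp), com, "species", "strict")
  }))
  sw <- threshold_sweep(list(DMC01 = tab), calls)
  expect_equal(length(unique(sw$threshold)), 21)
  expect_true(all(diff(sw$n_otus) <= 0))
  # threshold 0 keeps a superset of the default threshold's survivors
  s0 <- filter_rare(tab, threshold_override = 0)$otu_id
  sdef <- filter_rare(tab)$otu_id
  expect_true(all(sdef %in% s0))
})
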