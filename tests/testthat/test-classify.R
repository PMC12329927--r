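make_db_fixture <- function(seed = 23, n_genera = 8, spg = NULL,
                            confusable = NULL, d_conf = 0.03, ...) {
  tax <- generate_taxonomy(n_genera, spg, seed = seed)
  tax <- generate_marker_sequences(tax, markers = "ITS1",
                                   confusable_groups = confusable %||% list(),
                                   d_conf = d_conf, seed = seed)
  db <- build_reference_db(tax, "ITS1", name = "db", seed = seed, ...)
  list(tax = tax, db = db)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("top-hit search finds unique references and applies retention floors", {
  fx <- make_db_fixture()
  q <- fx$tax$ITS1[4]
  res <- tophit_search(q, fx$db, "otu1")
  expect_equal(res$species, fx$tax$species[4])
  expect_equal(res$identity, 1.0)
  expect_equal(length(res$group), 1)
  # a query unlike everything: unclassified with reason no_hit
  set.seed(1)
  res2 <- tophit_search(rand_seq(280), fx$db, "otu2")
  expect_true(is.na(res2$species))
  expect_equal(res2$reason, "no_hit")
  # identity floor: a query at ~94% identity to its best reference is rejected
  q3 <- q
  n_mut <- ceiling(0.06 * nchar(q3))
  set.seed(2)
  for (p in sample(nchar(q3), n_mut)) {
    substr(q3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(q3, p, p))[1]
  }
  res3 <- tophit_search(q3, fx$db, "otu3")
  if (!is.na(res3$species)) {
    expect_gte(res3$identity, 0.95) # only retained if still above the floor
  } else {
    expect_equal(res3$reason, "no_hit")
  }
})

test_that("identical references produce an equivalence group (tie verified by oracle)", {
  tax <- generate_taxonomy(4, c(3, 1, 1, 1), seed = 29)
  trio <- tax$species[1:3]
  tax <- generate_marker_sequences(tax, markers = "ITS1",
                                   confusable_groups = list(trio),
                                   d_conf = 0, seed = 29)
  db <- build_reference_db(tax, "ITS1", name = "db", seed = 29)
  res <- tophit_search(tax$ITS1[1], db, "otu1")
  expect_setequal(res$group, trio)
  expect_true(is.na(res$species)) # no unique top hit
  expect_equal(res$genus, "Genus01") # but a unique genus
  # oracle: scores of the three refs against the query are exactly tied
  sc <- vapply(tax$ITS1[1:3], function(r) {
    r_align(tax$ITS1[1], r, match = 2, mismatch = -3, gap_open = -5,
            gap_ext = -2, free_ends = TRUE)$score
  }, numeric(1))
  expect_true(all(sc == sc[1]))
})

test_that("naive-Bayes bootstrap assigns distinctive species and truncates confusables", {
  fx <- make_db_fixture(seed = 31)
  model <- nb_fit(fx$db)
  res <- nb_classify(fx$tax$ITS1[2], model, "otu1", seed = 31)
  expect_equal(res$species, fx$tax$species[2])
  expect_gte(res$confidence[["species"]], 0.8)
  # confidence is monotone non-decreasing toward higher ranks
  expect_true(all(diff(res$confidence) <= 1e-12))
  # independent recount: rerun the bootstrap votes with the same stream
  # and check the species confidence
  km <- dmcbench:::kmer_set(fx$tax$ITS1[2], model$k)
  idx <- match(km, model$vocab); idx <- idx[!is.na(idx)]
  set.seed(derive_seed(31, "nb_classify", paste(model$db_name, "otu1")))
  sc <- model$logp[, idx, drop = FALSE]
  full <- which.max(rowSums(sc))
  nsub <- max(1L, floor(length(idx) / model$k))
  agree <- vapply(1:100, function(b) {
    take <- sample.int(length(idx), nsub, replace = TRUE)
    model$species[which.max(rowSums(sc[, take, drop = FALSE]))] ==
      model$species[full]
  }, TRUE)
  expect_equal(unname(res$confidence[["species"]]), mean(agree))

  # a three-species indistinguishable group: genus retained, species
  # truncated (bootstrap votes split over the tied congeners)
  tax <- generate_taxonomy(5, c(3, 1, 1, 1, 1), seed = 37)
  trio <- tax$species[1:3]
  tax <- generate_marker_sequences(tax, markers = "ITS1",
                                   confusable_groups = list(trio),
                                   d_conf = 0, seed = 37)
  db <- build_reference_db(tax, "ITS1", name = "db", seed = 37)
  model2 <- nb_fit(db)
  res2 <- nb_classify(tax$ITS1[1], model2, "otu_conf", seed = 37)
  expect_equal(res2$genus, "Genus01")
  expect_lt(res2$confidence[["species"]], 0.8)
  expect_true(is.na(res2$species))
  # degenerate input: no shared k-mers
  res3 <- nb_classify(strrep("A", 50), model, "otu_bad", seed = 1)
  expect_true(is.na(res3$species))
  expect_equal(res3$reason, "no_kmers")
})

test_that("knn assigns the nearest lineage and never abstains on annotated dbs", {
  fx <- make_db_fixture(seed = 41)
  res <- knn_classify(fx$tax$ITS1[3], fx$db, "otu1")
  expect_equal(res$species, fx$tax$species[3])
  # mutated query still lands on the nearest species
  q <- fx$tax$ITS1[3]
  set.seed(3)
  for (p in sample(nchar(q), 8)) {
    substr(q, p, p) <- sample(c("A", "C", "G", "T"), 1)
  }
  res2 <- knn_classify(q, fx$db, "otu2")
  expect_equal(res2$species, fx$tax$species[3])
  # equidistant references: first by accession order, tie logged
  tax <- generate_taxonomy(3, c(2, 1, 1), seed = 43)
  tax <- generate_marker_sequences(tax, markers = "ITS1",
                                   confusable_groups = list(tax$species[1:2]),
                                   d_conf = 0, seed = 43)
  db <- build_reference_db(tax, "ITS1", name = "db", seed = 43)
  res3 <- knn_classify(tax$ITS1[1], db, "otu3")
  expect_equal(res3$species, db$entries$species[1])
  expect_match(res3$tie_note, "tied")
})

test_that("placeholder names are truncated to unclassified at their rank", {
  r <- dmcbench:::new_classification_result("o", "tophit", "db", "ITS1",
                                            species = "Genus07 sp",
                                            genus = "Genus07",
                                            group = "Genus07 sp")
  t <- truncate_unannotated(r)
  expect_true(is.na(t$species))
  expect_equal(t$genus, "Genus07")
  # fully annotated lineage unchanged
  r2 <- dmcbench:::new_classification_result("o", "knn", "db", "ITS1",
                                             species = "Genus01 fictum1",
                                             genus = "Genus01",
                                             group = "Genus01 fictum1")
  expect_identical(truncate_unannotated(r2), r2)
  # genus placeholder propagates downward
  r3 <- dmcbench:::new_classification_result("o", "knn", "db", "ITS1",
                                             species = "unclassified unclassified",
                                             genus = "unclassified",
                                             group = "unclassified unclassified")
  t3 <- truncate_unannotated(r3)
  expect_true(is.na(t3$genus))
  expect_true(is.na(t3$species))
})

test_that("all methods recover the truth on complete dbs; incompleteness only hurts", {
  fx <- make_db_fixture(seed = 47, n_genera = 6, spg = 1)
  reps <- data.frame(otu_id = paste0("o", 1:6), seq = fx$tax$ITS1,
                     stringsAsFactors = FALSE)
  results <- classify_otus(reps, fx$db, seed = 47)
  for (res in results) {
    expect_equal(res$species,
                 fx$tax$species[match(res$otu_id, reps$otu_id)],
                 label = paste(res$method, res$otu_id))
  }
  # remove one species from the db: its queries can only get worse
  tax_missing <- fx$tax[-2, ]
  db2 <- build_reference_db(tax_missing, "ITS1", name = "db2", seed = 47)
  res2 <- classify_otus(reps[2, , drop = FALSE], db2, seed = 47)
  for (r in res2) {
    expect_false(isTRUE(r$species == fx$tax$species[2]))
  }
})
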