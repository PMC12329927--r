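test_that("dereplication counts and conserves reads", {
  seqs <- data.frame(id = paste0("r", 1:4),
                     seq = c("ACGT", "ACGT", "ACGT", "TTTT"),
                     stringsAsFactors = FALSE)
  d <- dereplicate(seqs)
  expect_equal(nrow(d), 2)
  expect_equal(sort(d$weight), c(1, 3))
  expect_equal(sum(d$weight), 4)
  expect_equal(d$id[d$seq == "ACGT"], "r1") # first-seen id
  # all distinct: identity
  u <- data.frame(id = paste0("u", 1:3), seq = c("AA", "CC", "GG"))
  expect_equal(sort(dereplicate(u)$seq), sort(u$seq))
})

test_that("pre-clustering absorbs children within two mismatches", {
  set.seed(41)
  parent <- rand_seq(100)
  child1 <- parent; substr(child1, 10, 10) <- "N" # treat as mismatch
  child1 <- gsub("N", setdiff(c("A","C","G","T"), substr(parent, 10, 10))[1],
                 child1)
  child3 <- parent
  for (p in c(5, 50, 95)) {
    substr(child3, p, p) <- setdiff(c("A", "C", "G", "T"), substr(parent, p, p))[1]
  }
  d <- data.frame(id = c("p", "c1", "c3"), seq = c(parent, child1, child3),
                  weight = c(100L, 1L, 1L), stringsAsFactors = FALSE)
  pc <- precluster(d)
  expect_equal(nrow(pc$seqs), 2) # child at 3 mismatches retained
  expect_equal(pc$seqs$weight[pc$seqs$id == "p"], 101L)
  expect_equal(pc$log$parent_id, "p")
  expect_equal(sum(pc$seqs$weight), 102L)
  # equal weights: lexicographically smaller sequence absorbs the other
  a <- "AAAA"; b <- "AAAT"
  eq <- precluster(data.frame(id = c("x", "y"), seq = c(b, a),
                              weight = c(5L, 5L)))
  expect_equal(eq$seqs$seq, a)
  expect_equal(eq$seqs$weight, 10L)
  # planted error children within <= 2 mismatches are all absorbed
  set.seed(42)
  base <- rand_seq(150)
  kids <- vapply(1:10, function(i) {
    s <- base
    for (p in sample(150, sample(1:2, 1))) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }, character(1))
  dd <- dereplicate(data.frame(id = c("b", paste0("k", 1:10)),
                               seq = c(base, kids),
                               weight = c(500L, rep(1L, 10))))
  pc2 <- precluster(dd)
  expect_equal(nrow(pc2$seqs), 1)
  expect_equal(pc2$seqs$weight, 500L + sum(dd$weight[dd$seq != base]))
})

test_that("chimera detection flags constructed positives only", {
  set.seed(43)
  pa <- rand_seq(200); pb <- rand_seq(200)
  chim <- paste0(substr(pa, 1, 100), substr(pb, 101, 200))
  clean <- rand_seq(200)
  d <- data.frame(id = c("pa", "pb", "chim", "clean"),
                  seq = c(pa, pb, chim, clean),
                  weight = c(100L, 80L, 5L, 5L), stringsAsFactors = FALSE)
  det <- detect_chimeras(d)
  expect_setequal(det$flagged$id, "chim")
  # seeded sensitivity/specificity set: 100 chimeras, 100 clean queries
  set.seed(44)
  parents <- vapply(1:6, function(i) rand_seq(250), character(1))
  chims <- vapply(1:100, function(i) {
    ab <- sample(6, 2)
    bp <- sample(40:210, 1)
    paste0(substr(parents[ab[1]], 1, bp), substr(parents[ab[2]], bp + 1, 250))
  }, character(1))
  cleans <- vapply(1:100, function(i) rand_seq(250), character(1))
  d2 <- data.frame(id = c(paste0("p", 1:6), paste0("ch", 1:100),
                          paste0("cl", 1:100)),
                   seq = c(parents, chims, cleans),
                   weight = c(rep(500L, 6), rep(2L, 200)),
                   stringsAsFactors = FALSE)
  det2 <- detect_chimeras(d2)
  flagged <- det2$log$chimeric
  sens <- mean(flagged[7:106])
  false_flags <- sum(flagged[107:206]) + sum(flagged[1:6])
  expect_gte(sens, 0.9)
  expect_equal(false_flags, 0)
})

test_that("pairwise distances match the independent DP oracle", {
  expect_equal(pairwise_distances(c("ACGTACGTAC", "ACGTACGTAC"))[1, 2], 0)
  expect_equal(pairwise_distances(c("ACGTACGTAC", "ACGTTCGTAC"))[1, 2], 0.1)
  set.seed(45)
  for (i in 1:20) {
    a <- rand_seq(sample(30:60, 1))
    b <- if (i %% 2 == 0) rand_seq(sample(30:60, 1)) else {
      s <- a
      for (p in sample(nchar(a), sample(1:4, 1))) {
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      s
    }
    expect_equal(pairwise_distances(c(a, b))[1, 2], r_distance(a, b),
                 tolerance = 1e-12)
  }
})

test_that("clustering separates above-cutoff pairs and opticlust beats greedy", {
  # two sequences at distance 0.01 -> one OTU; at 0.10 -> two
  D <- matrix(c(0, 0.01, 0.01, 0), 2)
  expect_equal(length(unique(cluster_otus(D))), 1)
  D <- matrix(c(0, 0.1, 0.1, 0), 2)
  expect_equal(length(unique(cluster_otus(D))), 2)
  # seeded 30-sequence sets: opticlust MCC >= greedy baseline MCC
  for (seed in 1:3) {
    set.seed(seed)
    centers <- vapply(1:5, function(i) rand_seq(120), character(1))
    seqs <- unlist(lapply(centers, function(cn) {
      vapply(1:6, function(i) {
        s <- cn
        for (p in sample(120, sample(0:3, 1))) {
          substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
        }
        s
      }, character(1))
    }))
    seqs <- unique(seqs)
    D <- pairwise_distances(seqs)
    w <- rep(1, length(seqs))
    opti <- cluster_otus(D, w, method = "opticlust")
    greedy <- cluster_otus(D, w, method = "greedy_baseline")
    expect_gte(r_mcc(D, opti), r_mcc(D, greedy) - 1e-12)
  }
})

test_that("rare-OTU filtering applies the inclusive threshold and singleton rule", {
  tab <- data.frame(otu_id = c("a", "b", "c", "d"),
                    total_count = c(9794L, 100L, 5L, 1L),
                    stringsAsFactors = FALSE)
  total <- sum(tab$total_count) # 9900
  # c sits at exactly 0.05%: removed under the inclusive rule
  tab$total_count[3] <- as.integer(round(total * 5e-04))
  tab$total_count[1] <- 10000L - tab$total_count[2] - tab$total_count[3] - 1L
  expect_equal(sum(tab$total_count), 10000L)
  kept <- filter_rare(tab)
  expect_setequal(kept$otu_id, c("a", "b"))
  # threshold 0: only singletons removed
  kept0 <- filter_rare(tab, threshold_override = 0)
  expect_setequal(kept0$otu_id, c("a", "b", "c"))
  # singleton removed even in large samples
  expect_false("d" %in% filter_rare(tab)$otu_id)
})

test_that("representatives are the heaviest members with lexicographic ties", {
  seqs <- data.frame(id = c("A", "B", "C"),
                     seq = c("CCC", "AAA", "TTT"),
                     weight = c(5L, 2L, 7L), stringsAsFactors = FALSE)
  rep1 <- pick_representatives(seqs, c(1L, 1L, 2L))
  expect_equal(rep1$id, c("A", "C"))
  ties <- data.frame(id = c("A", "B"), seq = c("TTT", "AAA"),
                     weight = c(3L, 3L), stringsAsFactors = FALSE)
  expect_equal(pick_representatives(ties, c(1L, 1L))$seq, "AAA")
  expect_error(pick_representatives(seqs[0, ], integer()), "empty|length")
})

test_that("error-free well-separated species yield exactly k true-marker OTUs", {
  tax <- generate_marker_sequences(generate_taxonomy(7, 1, seed = 17), seed = 17)
  reg <- build_mock_communities(tax, n_communities = 1, size = 5,
                                n_genus_violations = 0,
                                include_replicate_pair = FALSE, seed = 17)
  cfg <- benchmark_config(seed = 17, reads_per_community = 400, markers = "ITS1")
  run <- run_dmc_pipeline(reg[1, ], tax, "ITS1", cfg)
  expect_equal(nrow(run$otus$table), 5)
  truth_markers <- tax$ITS1[match(reg$members[[1]], tax$species)]
  expect_setequal(run$otus$table$rep_seq, truth_markers)
})

test_that("confusable congeners within the cutoff co-cluster into one OTU", {
  tax <- generate_taxonomy(6, c(3, 1, 1, 1, 1, 1), seed = 19)
  trio <- tax$species[1:3]
  tax <- generate_marker_sequences(tax, confusable_groups = list(trio),
                                   d_conf = 0.03, seed = 19)
  seqs <- tax$ITS1[c(1:3, 4, 5)]
  D <- pairwise_distances(seqs)
  cl <- cluster_otus(D, weights = c(10, 8, 6, 10, 10))
  expect_equal(cl[1], cl[2])
  expect_equal(cl[1], cl[3])
  expect_equal(length(unique(cl)), 3)
})
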