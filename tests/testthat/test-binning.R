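test_that("canonical TNF pools reverse complements and skips N windows", {
  v <- tnf("AAAA")
  expect_length(v, 136L)
  expect_equal(sum(v), 1)
  expect_equal(unname(v["AAAA"]), 1)
  # N splits the window run: AAAANAAAA has 2 valid 4-mers
  v2 <- tnf("AAAANAAAA")
  expect_equal(unname(v2["AAAA"]), 1)
  expect_error(tnf("ACG"), "4-mer")
  expect_error(tnf("AANNA"), "4-mer")
  # reverse-complement invariance, many random draws
  set.seed(61)
  for (i in 1:100) {
    s <- rand_dna(200, gc = runif(1, 0.3, 0.7))
    expect_equal(tnf(s), tnf(revcomp(s)))
  }
})

test_that("contig taxonomy needs 10 kb and a strict gene majority", {
  expect_equal(contig_taxonomy(c(rep("A", 6), rep("B", 4)), 12000), "A")
  expect_equal(contig_taxonomy(c(rep("A", 5), rep("B", 5)), 12000),
               "unclassified")
  expect_equal(contig_taxonomy(rep("A", 10), 9000), "unclassified")
  expect_equal(contig_taxonomy(character(), 12000), "unclassified")
})

test_that("feature projection is deterministic and separates compositions", {
  set.seed(62)
  gens <- lapply(1:2, function(i) {
    set.seed(620 + i)
    generate_genome(200000, composition_model(c(38, 52)[i]),
                    seed = 620 + i, id = c("lo", "hi")[i])
  })
  wins <- unlist(lapply(gens, cut_windows), recursive = FALSE)
  feats <- contig_features(wins)
  coords <- project_features(feats)
  truth <- sub("_w.*", "", feats$ids)
  sil <- cluster::silhouette(as.integer(factor(truth)), dist(coords))
  expect_gte(mean(sil[, 3]), 0.5)
  # duplicated rows land on identical coordinates
  feats2 <- contig_features(c(wins, wins[1]))
  coords2 <- project_features(feats2)
  expect_equal(unname(coords2[1, ]), unname(coords2[nrow(coords2), ]))
  expect_error(project_features(feats, n_components = 1000), "rank")
})

test_that("single-genome windows form one bin", {
  set.seed(63)
  g <- generate_genome(200000, composition_model(45), seed = 631,
                       id = "solo")
  feats <- contig_features(cut_windows(g))
  coords <- project_features(feats)
  bins <- bin_contigs(coords, feats$taxon)
  found <- unique(na.omit(bins$bin))
  expect_length(found, 1L)
  expect_gte(sum(!is.na(bins$bin)), 0.8 * nrow(bins))
})

test_that("indistinguishable genomes may merge but contamination flags it", {
  # same composition model and coverage: windows of two genomes fall in
  # one cluster; duplicated single-copy markers then show up as
  # contamination > 0
  set.seed(64)
  cm <- composition_model(45)
  g1 <- generate_genome(100000, cm, seed = 641, id = "t1")
  g2 <- generate_genome(100000, cm, seed = 641, id = "t2") # same seed
  wins <- c(cut_windows(g1), cut_windows(g2))
  feats <- contig_features(wins)
  coords <- project_features(feats)
  bins <- bin_contigs(coords, feats$taxon)
  big <- names(which.max(table(bins$bin)))
  members <- bins$contig_id[!is.na(bins$bin) & bins$bin == big]
  expect_true(any(grepl("^t1_", members)) && any(grepl("^t2_", members)))
  # each genome contributes one full marker set spread over its windows
  markers <- setNames(vector("list", length(feats$ids)), feats$ids)
  cat35 <- usc_catalog(35)
  for (gid in c("t1", "t2")) {
    w <- grep(paste0("^", gid, "_"), feats$ids, value = TRUE)
    markers[w] <- unname(split(cat35, rep_len(seq_along(w), 35)))
  }
  summ <- bin_summary(bins, feats, markers, usc_catalog(35))
  expect_gt(summ$contamination[summ$bin == big], 0)
})

test_that("completeness and contamination follow the marker formulas", {
  cat35 <- usc_catalog(35)
  expect_equal(completeness_contamination(cat35, cat35),
               c(completeness = 100, contamination = 0))
  expect_equal(completeness_contamination(cat35[1:7], cat35),
               c(completeness = 20, contamination = 0))
  expect_equal(completeness_contamination(c(cat35, cat35[1:7]), cat35),
               c(completeness = 100, contamination = 20))
  expect_error(completeness_contamination("USC001", character()),
               "empty")
})

test_that("adding contigs never decreases completeness", {
  set.seed(65)
  cat35 <- usc_catalog(35)
  pool <- sample(cat35, 60, replace = TRUE)
  comp <- vapply(seq(5, 60, by = 5), function(k)
    completeness_contamination(pool[1:k], cat35)[["completeness"]],
    numeric(1))
  expect_true(all(diff(comp) >= 0))
})
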