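test_that("greedy reference clustering honours the identity radius", {
  set.seed(41)
  s <- rand_dna(300)
  # identical pair -> one centroid
  ref <- build_reference(c(a = s, b = s), c("Bacteria;P1", "Bacteria;P1"))
  expect_equal(nrow(ref), 1L)
  expect_equal(ref$n_members, 2L)
  # ~80% identity pair at radius 0.90 -> two centroids
  set.seed(42)
  s2 <- sub_at(s, sample(300, 60))
  ref2 <- build_reference(c(a = s, b = s2),
                          c("Bacteria;P1", "Bacteria;P2"))
  expect_equal(nrow(ref2), 2L)
  expect_error(build_reference(c(a = s), ""), "taxonomy")
})

test_that("cluster count is order-invariant for well-separated inputs", {
  # brute-force oracle: all pairwise identities far below the radius,
  # so every permutation must give one centroid per sequence
  set.seed(43)
  seqs <- setNames(replicate(5, rand_dna(250)), paste0("q", 1:5))
  ids <- combn(5, 2, function(ij)
    seq_identity(seqs[[ij[1]]], seqs[[ij[2]]]))
  expect_true(all(ids < 80))
  tax <- paste0("Bacteria;P", 1:5)
  n1 <- nrow(build_reference(seqs, tax))
  perm <- c(3, 5, 1, 4, 2)
  n2 <- nrow(build_reference(seqs[perm], tax[perm]))
  expect_equal(n1, 5L)
  expect_equal(n1, n2)
})

test_that("the detection screen is recall-oriented yet specific", {
  ref <- bundled_16s_reference()
  tmpl <- marker_templates()
  # reads cut from a reference taxon are detected
  s16 <- tmpl$s16[["tax_bacter"]]
  reads16 <- vapply(seq(1, 1300, by = 97), function(i)
    substring(s16, i, i + 149), "")
  expect_equal(detect_candidates(reads16, ref), seq_along(reads16))
  # empirical null: random 150-mers at GC 40% are not candidates
  set.seed(44)
  null_reads <- replicate(1000, rand_dna(150, gc = 0.40))
  expect_equal(length(detect_candidates(null_reads, ref)), 0L)
})

test_that("profile verification separates 16S reads from shuffles", {
  ref <- bundled_16s_reference()
  prof <- build_domain_profiles(ref)
  expect_named(prof, c("Bacteria", "Archaea"), ignore.order = TRUE)
  tmpl <- marker_templates()
  reads <- c(vapply(seq(1, 1300, by = 150), function(i)
    substring(tmpl$s16[["tax_alpha"]], i, i + 149), ""),
    vapply(seq(1, 1300, by = 150), function(i)
      substring(tmpl$s16[["tax_thaum1"]], i, i + 149), ""))
  ver <- verify_candidates(reads, prof, seed = 7)
  expect_gte(nrow(ver), 0.9 * length(reads))
  expect_true(all(ver$domain[ver$read <= 9] == "Bacteria"))
  expect_true(all(ver$domain[ver$read > 9] == "Archaea"))
  # mononucleotide shuffles of the same reads fail at the same cutoff
  set.seed(45)
  shuf <- vapply(reads, function(r)
    paste(sample(strsplit(r, "")[[1]]), collapse = ""), "",
    USE.NAMES = FALSE)
  cut <- calibrate_profile_cutoff(reads, prof, seed = 7)
  ver_shuf <- verify_candidates(shuf, prof, cutoff = cut)
  expect_lte(nrow(ver_shuf), 1L)
  # candidates shorter than the minimum window are rejected
  expect_equal(nrow(verify_candidates(substring(reads[1], 1, 30), prof,
                                      cutoff = cut)), 0L)
})

test_that("fragment classification applies the 80% / 90 bp thresholds", {
  ref <- bundled_16s_reference()
  base <- substring(ref$sequence[1], 201, 300) # 100 bp own-centroid read
  # 15 substitutions (over the first 80 bp, leaving a clean anchor
  # region as real error clumping does) -> 85% identity: classified
  r85 <- sub_at(base, seq(4, 80, length.out = 15))
  # 21 substitutions -> 79%: discarded
  r79 <- sub_at(base, seq(3, 99, length.out = 21))
  # 95% identity but only 80 bp: discarded on length
  r80bp <- sub_at(substring(ref$sequence[1], 201, 280), seq(10, 70, 15))
  cls <- classify_fragment(c(r85, r79, r80bp), ref)
  expect_equal(cls$read, 1L)
  expect_equal(cls$taxonomy, ref$taxonomy[1])
})

test_that("abundance tables are percentages with the 1% display rule", {
  cl <- list(
    s1 = c(rep("Bacteria;Bacteroidetes", 60),
           rep("Bacteria;Cyanobacteria", 39),
           "Bacteria;Planctomycetes"),
    s2 = c(rep("Bacteria;Bacteroidetes", 50),
           rep("Bacteria;Proteobacteria;Alphaproteobacteria", 50)))
  tab <- abundance_table(cl, rank = "phylum")
  expect_equal(unname(colSums(tab$percent)), c(100, 100))
  expect_equal(tab$percent["Bacteroidetes", "s1"], 60)
  # Proteobacteria reported at class level
  expect_true("Alphaproteobacteria" %in% rownames(tab$percent))
  expect_false("Proteobacteria" %in% rownames(tab$percent))
  # 0.5%-everywhere taxon folds into "other"
  cl2 <- list(s1 = c(rep("Bacteria;A", 199), "Bacteria;B"),
              s2 = c(rep("Bacteria;A", 199), "Bacteria;B"))
  tab2 <- abundance_table(cl2, rank = "phylum")
  expect_false("B" %in% rownames(tab2$display))
  expect_equal(unname(tab2$display["other", ]), c(0.5, 0.5))
  # duplication of every read leaves percentages unchanged
  tab3 <- abundance_table(lapply(cl, rep, 2), rank = "phylum")
  expect_equal(tab3$percent, tab$percent)
})

test_that("the full cascade composes and honours the subsample knob", {
  ref <- bundled_16s_reference()
  tmpl <- marker_templates()
  reads16 <- vapply(seq(1, 1300, by = 130), function(i)
    substring(tmpl$s16[["tax_verruco"]], i, i + 149), "")
  set.seed(47)
  noise <- replicate(20, rand_dna(150, gc = 0.45))
  reads <- c(reads16, noise)
  full <- profile_16s(reads, ref, seed = 2)
  expect_setequal(full$read, seq_along(reads16))
  expect_true(all(grepl("Verrucomicrobia", full$taxonomy)))
  # seeded subsample: indices still refer to the full input
  sub <- profile_16s(reads, ref, seed = 2, subsample = 15)
  expect_true(all(sub$read %in% full$read))
})

test_that("Gini-Simpson diversity matches closed forms and vegan", {
  expect_equal(simpson_diversity(1), 0)
  expect_equal(simpson_diversity(rep(0.25, 4)), 0.75)
  expect_equal(simpson_diversity(c(0.5, 0.5)), 0.5)
  expect_error(simpson_diversity(c(-0.1, 1.1)), "negative")
  # monotone in richness for uniform communities
  d <- vapply(2:10, function(k) simpson_diversity(rep(1 / k, k)),
              numeric(1))
  expect_true(all(diff(d) > 0))
  # independent cross-check on random compositions
  set.seed(46)
  for (i in 1:5) {
    x <- rmultinom(1, 500, runif(6))[, 1]
    expect_equal(simpson_diversity(x / sum(x)),
                 vegan::diversity(x, index = "simpson"))
  }
})
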