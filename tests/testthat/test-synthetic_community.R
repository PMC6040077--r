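test_that("genome generation is deterministic and hits its GC target", {
  set.seed(1)
  cm <- composition_model(38.6)
  g1 <- generate_genome(200000, cm, seed = 5)
  g2 <- generate_genome(200000, cm, seed = 5)
  expect_identical(g1$sequence, g2$sequence)
  expect_gte(gc_content(g1), 36.6)
  expect_lte(gc_content(g1), 40.6)
  expect_error(composition_model(0), "between 0 and 100")
  expect_error(composition_model(100), "between 0 and 100")
  expect_error(generate_genome(5000, cm, seed = 1), ">= 10 kb")
})

test_that("order-0 1 Mb draw matches the binomial GC expectation", {
  # binomial oracle: sd of GC% = 100 * sqrt(p(1-p)/n) ~ 0.05 at n = 1e6
  set.seed(2)
  cm0 <- composition_model(50, markov_order = 0, jitter = 0)
  g <- generate_genome(1e6, cm0, seed = 9)
  expect_lt(abs(gc_content(g) - 50), 0.5) # 10 binomial sd
})

test_that("depth profiles follow the Gaussian niche model", {
  depths <- seq(15, 90, by = 15)
  d0 <- depth_profile(niche_spec("g", 45, 0, 0.8), depths)
  expect_equal(which(d0 > 0), 3L)
  fl <- depth_profile(niche_spec("g", flat = TRUE,
                                 peak_relative_abundance = 0.3), depths)
  expect_true(all(fl == 0.3))
  sym <- depth_profile(niche_spec("g", 45, 10, 1), c(30, 45, 60))
  expect_equal(sym[1], sym[3])
  expect_equal(sym[2], 1)
  expect_error(depth_profile(niche_spec("g", 45, -1, 1), depths),
               "width")
})

test_that("read simulation respects abundances and the error model", {
  set.seed(3)
  gA <- generate_genome(20000, composition_model(40), seed = 31, id = "a")
  gB <- generate_genome(20000, composition_model(60), seed = 32, id = "b")

  # error 0: every read is an exact substring of its source
  sim <- simulate_metagenome(list(gA, gB), c(0.5, 0.5), 50, 100,
                             error_rate = 0, seed = 7)
  src <- list(a = gA$sequence, b = gB$sequence)
  for (i in seq_len(50)) {
    tr <- sim$truth[i, ]
    r <- sim$readset$reads[i]
    if (tr$strand == "-") r <- revcomp(r)
    expect_equal(r, substring(src[[tr$genome_id]], tr$start + 1,
                              tr$start + 100))
  }

  # degenerate abundance: all reads from genome 1
  sim1 <- simulate_metagenome(list(gA, gB), c(1, 0), 200, 100, 0, seed = 8)
  expect_true(all(sim1$truth$genome_id == "a"))

  # binomial oracle: equal lengths, 50/50 -> counts within 3 sd of 5000
  simB <- simulate_metagenome(list(gA, gB), c(0.5, 0.5), 10000, 100,
                              0, seed = 9)
  nA <- sum(simB$truth$genome_id == "a")
  expect_lt(abs(nA - 5000), 3 * sqrt(10000 * 0.25))

  expect_error(simulate_metagenome(list(gA), 1, 0, 100, 0, 1), "n_reads")
  expect_error(simulate_metagenome(list(gA), 1, 10, 100, 0.5, 1),
               "error_rate")
  expect_error(simulate_metagenome(list(gA, gB), c(0.9, 0.3), 10, 100,
                                   0, 1), "sum to 1")
})

test_that("per-read identity under errors matches the binomial tail", {
  # fraction of 150 bp reads with >= 99% full-length identity at error
  # rate e is P(X <= 1), X ~ Bin(150, e)
  set.seed(5)
  g <- generate_genome(50000, composition_model(45), seed = 51)
  e <- 0.01
  sim <- simulate_metagenome(list(g), 1, 4000, 150, e, seed = 12)
  nerr <- vapply(seq_len(4000), function(i) {
    tr <- sim$truth[i, ]
    r <- sim$readset$reads[i]
    if (tr$strand == "-") r <- revcomp(r)
    orig <- substring(g$sequence, tr$start + 1, tr$start + 150)
    sum(strsplit(r, "")[[1]] != strsplit(orig, "")[[1]])
  }, numeric(1))
  p_obs <- mean(nerr <= 1)
  p_exp <- pbinom(1, 150, e)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 4000))
})

test_that("marker implantation records genes, taxonomy and copy numbers", {
  set.seed(6)
  tmpl <- marker_templates()
  g <- generate_genome(30000, composition_model(45), seed = 61)
  g <- implant_markers(g, list(
    marker_spec("recA"), marker_spec("radA"),
    marker_spec("rhodopsin", "green"),
    marker_spec("rrna16S", "tax_alpha", divergence = 0.015)), tmpl)
  expect_equal(sum(g$genes$role == "recA"), 1L)
  expect_equal(sum(g$genes$role == "radA"), 1L)
  expect_equal(sum(g$genes$role == "rhodopsin"), 1L)
  expect_equal(g$taxonomy[1], "Bacteria")
  expect_equal(g$taxonomy[2], "Proteobacteria")
  # intervals do not overlap
  gg <- g$genes[order(g$genes$start), ]
  expect_true(all(head(gg$end, -1) <= tail(gg$start, -1)))

  g2 <- implant_markers(g, marker_spec("rhodopsin", "blue", copies = 2),
                        tmpl)
  expect_equal(sum(g2$genes$role == "rhodopsin"), 3L)
})

test_that("distinct composition models separate in TNF space", {
  # |dGC| >= 10% -> between-genome TNF distance exceeds within-genome
  # window distances
  set.seed(7)
  g1 <- generate_genome(60000, composition_model(38), seed = 71, id = "l")
  set.seed(8)
  g2 <- generate_genome(60000, composition_model(52), seed = 72, id = "h")
  w1 <- vapply(cut_windows(g1, 15000), `[[`, "", "sequence")
  w2 <- vapply(cut_windows(g2, 15000), `[[`, "", "sequence")
  t1 <- tnf(w1); t2 <- tnf(w2)
  within <- c(dist(t1), dist(t2))
  between <- as.numeric(sqrt(rowSums((t1 - t2[rep(1, nrow(t1)), ])^2)))
  expect_gt(min(between), max(within))
})

test_that("the default study matches the sampling design and truth layout", {
  st <- get_study(1)
  expect_length(st$samples, 8L)
  expect_equal(vapply(st$samples, `[[`, numeric(1), "depth_m"),
               c(strat_15m = 15, strat_30m = 30, strat_45m = 45,
                 strat_60m = 60, strat_75m = 75, strat_90m = 90,
                 mixed_20m = 20, mixed_80m = 80))
  tab <- table(st$truth$classification$depth_range_class)
  expect_equal(as.integer(tab[c("stenobathic", "eurybathic", "absent")]),
               c(8L, 2L, 2L))
  occ <- st$truth$classification$seasonal_occupancy
  expect_equal(sum(occ == "winter_only"), 2L)
  expect_equal(sum(occ == "stratified_only"), 4L)
  expect_equal(sum(occ == "always"), 6L)
  # abundance columns normalised
  expect_equal(unname(colSums(st$truth$abundance)), rep(1, 8))
})
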