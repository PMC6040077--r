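test_that("identity thresholds are inclusive and correctly computed", {
  set.seed(31)
  gen <- genome_record("g1", rand_dna(20000))
  read0 <- substring(gen$sequence, 501, 600)     # exact 100-mer
  read1 <- sub_at(read0, 50)                     # 1 mid substitution
  read2 <- sub_at(read0, c(33, 66))              # 2 spread substitutions
  r <- recruit(c(read0, read1, read2), list(gen))
  expect_equal(unname(r$counts["g1"]), 2L)
  h <- r$hits
  expect_equal(h$identity[h$read == 1], 100)
  expect_equal(h$identity[h$read == 2], 99)      # boundary kept
  expect_false(3 %in% h$read)                    # 98% rejected

  # reverse-complement reads recruit too
  rrc <- recruit(revcomp(read0), list(gen))
  expect_equal(unname(rrc$counts["g1"]), 1L)

  # empty read set: all-zero counts, not an error
  r0 <- recruit(character(), list(gen))
  expect_equal(unname(r0$counts), 0L)
})

test_that("minimum alignment length gates short matches", {
  set.seed(32)
  gen <- genome_record("g1", rand_dna(20000))
  frag40 <- substring(gen$sequence, 1001, 1040)
  frag60 <- substring(gen$sequence, 2001, 2060)
  r <- recruit(c(frag40, frag60), list(gen), min_aln_len = 50)
  expect_equal(unname(r$counts["g1"]), 1L)
  expect_equal(r$hits$read, 2L)
})

test_that("best-hit ties break lexicographically by genome id", {
  set.seed(33)
  s <- rand_dna(20000)
  twins <- list(genome_record("gB", s), genome_record("gA", s))
  read <- substring(s, 101, 250)
  r <- recruit(read, twins)
  expect_equal(r$hits$genome_id, "gA")
  expect_equal(unname(r$counts), c(gA = 1L, gB = 0L), ignore_attr = TRUE)
})

test_that("rpkg implements its formula with linearity and guards", {
  expect_equal(rpkg(6000, 2e6, 10e9), 0.3)
  expect_equal(rpkg(3, 1000, 1e9), 3)
  expect_equal(rpkg(0, 1e6, 1e9), 0)
  expect_equal(rpkg(200, 5e5, 2e9), 2 * rpkg(100, 5e5, 2e9))
  expect_equal(rpkg(100, 5e5, 4e9), rpkg(100, 5e5, 2e9) / 2)
  expect_error(rpkg(1, 0, 1e9), "genome_length")
  expect_error(rpkg(1, 1e6, 0), "metagenome_bp")
})

test_that("presence threshold is inclusive at 3 RPKG", {
  rp <- rbind(g1 = c(2.99, 1.0), g2 = c(3.0, 0), g3 = c(0, 0))
  pf <- presence_filter(rp)
  expect_equal(unname(pf$retained), c(FALSE, TRUE, FALSE))
  expect_equal(sum(presence_filter(rp * 0)$retained), 0L)
})

test_that("depth-range classes follow the occupancy definition", {
  d <- seq(15, 90, by = 15)
  occ <- function(x) d %in% x
  expect_equal(classify_depth_range(occ(c(45, 60)), d), "stenobathic")
  expect_equal(classify_depth_range(occ(45), d), "stenobathic")
  expect_equal(classify_depth_range(occ(d), d), "eurybathic")
  expect_equal(classify_depth_range(occ(c(15, 60)), d), "intermediate")
  expect_equal(classify_depth_range(occ(c(15, 30, 45)), d), "intermediate")
  expect_equal(classify_depth_range(occ(numeric()), d), "absent")
  expect_error(classify_depth_range(rep(TRUE, 5), d), "length")
})

test_that("seasonal occupancy distinguishes the four categories", {
  expect_equal(classify_seasonal_occupancy(c(F, F, T), c(T, F)), "always")
  expect_equal(classify_seasonal_occupancy(c(T, F, F), c(F, F)),
               "stratified_only")
  expect_equal(classify_seasonal_occupancy(rep(F, 6), c(T, T)),
               "winter_only")
  expect_equal(classify_seasonal_occupancy(rep(F, 6), c(F, F)), "absent")
  expect_error(classify_seasonal_occupancy(logical(), c(TRUE)),
               "non-empty")
})

test_that("raising min_identity never increases counts", {
  set.seed(34)
  g <- generate_genome(30000, composition_model(45), seed = 341)
  sim <- simulate_metagenome(list(g), 1, 2000, 150, 0.01, seed = 35)
  cuts <- c(90, 95, 97, 99, 100)
  counts <- vapply(cuts, function(ci)
    sum(recruit(sim$readset, list(g), min_identity = ci)$counts),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("RPKG is consistent under 50% read subsampling", {
  set.seed(36)
  g <- generate_genome(40000, composition_model(42), seed = 361)
  sim <- simulate_metagenome(list(g), 1, 8000, 150, 0.002, seed = 37)
  full <- recruit(sim$readset, list(g))
  half_reads <- sim$readset$reads[seq(1, 8000, by = 2)]
  half <- recruit(half_reads, list(g))
  rp_full <- rpkg(sum(full$counts), 40000, sim$readset$total_bp)
  rp_half <- rpkg(sum(half$counts), 40000, sum(nchar(half_reads)))
  # Poisson error on the subsample count, propagated to RPKG
  sigma <- rp_half / sqrt(sum(half$counts))
  expect_lt(abs(rp_full - rp_half), 3 * sigma)
})
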