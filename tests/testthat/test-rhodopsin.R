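test_that("spectral classification reads the tuning residue", {
  ex <- rhodopsin_exemplars()
  expect_equal(spectral_class(ex[["green"]])$class, "green")
  expect_equal(spectral_class(ex[["blue"]])$class, "blue")
  # a residue other than L/Q at the tuning position -> unknown
  pos <- rhodopsin_tuning_position()
  odd <- ex[["green"]]
  substr(odd, pos, pos) <- "A"
  expect_equal(spectral_class(odd)$class, "unknown")
  expect_equal(spectral_class(odd)$residue, "A")
  # too-short fragment fails the coverage gate
  expect_equal(spectral_class(substring(ex[["green"]], 1, 40))$class,
               "unknown")
})

test_that("spectral class is invariant to synonymous nucleotide changes", {
  tmpl <- marker_templates()
  nt <- tmpl$rhodopsin[["green"]]
  expect_equal(spectral_class(nt)$class, "green")
  # recode leucines CTG -> CTC (synonymous), glutamines CAG -> CAA
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  codons[codons == "CTG"] <- "CTC"
  codons[codons == "CAG"] <- "CAA"
  syn <- paste(codons, collapse = "")
  expect_equal(translate_dna(syn), translate_dna(nt))
  expect_equal(spectral_class(syn)$class, "green")
})

test_that("rhodopsin detection respects the 5 kb contig gate", {
  set.seed(71)
  comm <- make_marker_community(2, 2, 71, genome_length = 10000)
  hits <- find_rhodopsins(comm[1])
  truth <- comm[[1]]$genes[comm[[1]]$genes$role == "rhodopsin", ]
  expect_equal(nrow(hits), 1L)
  # coordinates recover the implanted interval (ends may trim slightly)
  ov <- min(hits$end, truth$end) - max(hits$start, truth$start)
  expect_gte(ov / (truth$end - truth$start), 0.9)

  # same gene on a 4 kb contig is skipped
  short <- genome_record("short",
                         substring(comm[[1]]$sequence,
                                   max(1, truth$start - 1000),
                                   max(1, truth$start - 1000) + 4000))
  expect_equal(nrow(find_rhodopsins(list(short))), 0L)

  # rhodopsin-free contig yields nothing
  expect_equal(nrow(find_rhodopsins(comm[2])), 1L) # has one
  set.seed(72)
  bare <- generate_genome(10000, composition_model(45), seed = 721)
  expect_equal(nrow(find_rhodopsins(list(bare))), 0L)
})

test_that("the recA/radA-normalised estimator recovers copy number", {
  comm <- make_marker_community(6, 6, 73)
  sim <- simulate_metagenome(comm, rep(1 / 6, 6), 20000, 150, 0.002,
                             seed = 74)
  est <- rhodopsins_per_genome(sim$readset, gene_seqs(comm, "rhodopsin"),
                               gene_seqs(comm, "recA"),
                               gene_seqs(comm, "radA"))
  expect_lt(abs(est$rhodopsins_per_genome - 1), 0.1)
  # no rhodopsin-bearing genomes -> 0
  comm0 <- make_marker_community(3, 0, 75)
  sim0 <- simulate_metagenome(comm0, rep(1 / 3, 3), 5000, 150, 0.002,
                              seed = 76)
  est0 <- rhodopsins_per_genome(sim0$readset, character(),
                                gene_seqs(comm0, "recA"),
                                gene_seqs(comm0, "radA"))
  expect_equal(est0$rhodopsins_per_genome, 0)
  expect_error(rhodopsins_per_genome(sim0$readset, character(),
                                     character(), character()),
               "non-empty")
})

test_that("per-gene recruitment keeps genes at or above 1 RPKG", {
  set.seed(77)
  comm <- make_marker_community(3, 3, 78)
  sim <- simulate_metagenome(comm, c(0.98, 0.02, 0), 20000, 150, 0.002,
                             seed = 79, sample_id = "s1")
  genes <- gene_seqs(comm, "rhodopsin")
  m_all <- rhodopsin_recruit(list(sim$readset), genes, keep_rpkg = 0)
  # the absent genome's gene recruits nothing
  expect_equal(unname(m_all["m03_rhodopsin1", ]), 0)
  m <- rhodopsin_recruit(list(sim$readset), genes, keep_rpkg = 1)
  expect_false("m03_rhodopsin1" %in% rownames(m))
  expect_true("m01_rhodopsin1" %in% rownames(m))
})

test_that("a host's rhodopsin RPKG tracks the host genome RPKG", {
  # slope test over depth profiles: simulate one stenobathic host at
  # several abundances and regress gene RPKG on genome RPKG
  set.seed(80)
  comm <- make_marker_community(2, 1, 81)
  gene <- gene_seqs(comm[1], "rhodopsin")
  host_rp <- c(); gene_rp <- c()
  for (a in c(0.1, 0.3, 0.6, 0.9)) {
    sim <- simulate_metagenome(comm, c(a, 1 - a), 20000, 150, 0.002,
                               seed = 100 * a + 7)
    rr <- recruit(sim$readset, comm[1])
    host_rp <- c(host_rp, rpkg(sum(rr$counts), 12000,
                               sim$readset$total_bp))
    gr <- recruit(sim$readset, gene)
    gene_rp <- c(gene_rp, rpkg(sum(gr$counts), nchar(gene),
                               sim$readset$total_bp))
  }
  fit <- lm(gene_rp ~ host_rp)
  expect_gte(summary(fit)$r.squared, 0.95)
})
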