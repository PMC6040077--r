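# Shared fixtures, built in code at test time.

# random DNA string, uses the RNG in effect
rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute exactly the given 1-based positions with a different base
sub_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# small community of genomes each carrying recA + radA, the first
# `n_rho` also one rhodopsin (alternating green/blue)
make_marker_community <- function(n, n_rho, seed,
                                  genome_length = 12000) {
  tmpl <- marker_templates()
  lapply(seq_len(n), function(i) {
    set.seed(seed * 1000 + i)
    g <- generate_genome(genome_length,
                         composition_model(40 + i %% 10),
                         seed = seed * 1000 + i,
                         id = sprintf("m%02d", i))
    specs <- list(marker_spec("recA"), marker_spec("radA"))
    if (i <= n_rho)
      specs <- c(specs, list(marker_spec(
        "rhodopsin", if (i %% 2) "green" else "blue")))
    implant_markers(g, specs, tmpl)
  })
}

# extract implanted gene sequences of a role from a genome list
gene_seqs <- function(genomes, role) {
  out <- character()
  for (g in genomes) {
    gg <- g$genes[g$genes$role == role, , drop = FALSE]
    if (nrow(gg)) for (r in seq_len(nrow(gg)))
      out[paste0(g$id, "_", role, r)] <-
        substring(g$sequence, gg$start[r] + 1, gg$end[r])
  }
  out
}

# run the default study and its recruitment once per session; reused by
# the acceptance checks for depth classes, specificity, similarity and
# the 16S cascade
study_cache <- new.env(parent = emptyenv())
get_study <- function(seed) {
  key <- paste0("s", seed)
  if (is.null(study_cache[[key]])) {
    st <- make_study(seed = seed)
    st$rm <- recruitment_matrix(st$samples, st$genomes, keep_hits = TRUE)
    study_cache[[key]] <- st
  }
  study_cache[[key]]
}
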