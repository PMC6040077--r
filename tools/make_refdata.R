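# Generates the synthetic sequence reference bundle under inst/extdata.
# All sequences are synthetic stand-ins with realistic family structure:
# - a 16S-like reference: two domain cores (archaeal core ~30% diverged
#   from the bacterial core), taxa derived from their core by ~9.5%
#   i.i.d. substitution, all equal length (gap-free alignment);
# - recA / radA nucleotide templates;
# - green and blue rhodopsin coding templates, reverse-translated from
#   a synthetic 240-aa protein whose residue 105 is the spectral-tuning
#   position (L = green, Q = blue).
# Run from the repository root: Rscript tools/make_refdata.R

set.seed(20151015)

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  idx <- which(runif(length(ch)) < rate)
  ch[idx] <- vapply(ch[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  paste(ch, collapse = "")
}

write_fa <- function(x, path) {
  con <- file(path, "w")
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    writeLines(gsub("(.{70})", "\\1\n", x[[i]]), con)
  }
  close(con)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## 16S-like reference -------------------------------------------------
core_b <- rand_dna(1500, gc = 0.54)
core_a <- mutate(core_b, 0.30)

taxa <- list(
  tax_alpha   = c(core = "b", lin = "Bacteria;Proteobacteria;Alphaproteobacteria;Pelagibacter;Pelagibacter_synthA"),
  tax_gamma   = c(core = "b", lin = "Bacteria;Proteobacteria;Gammaproteobacteria;SAR86;SAR86_synthA"),
  tax_bacter  = c(core = "b", lin = "Bacteria;Bacteroidetes;Flavobacteriia;Flavobacterium;Flavobacterium_synthA"),
  tax_cyano   = c(core = "b", lin = "Bacteria;Cyanobacteria;Cyanophyceae;Synechococcus;Synechococcus_synthA"),
  tax_actino  = c(core = "b", lin = "Bacteria;Actinobacteria;Acidimicrobiia;Actinomarina;Actinomarina_synthA"),
  tax_verruco = c(core = "b", lin = "Bacteria;Verrucomicrobia;Verrucomicrobiae;Puniceicoccus;Puniceicoccus_synthA"),
  tax_marini  = c(core = "b", lin = "Bacteria;Marinimicrobia;Marinimicrobia_cls;Marinimicrobia_gen;Marinimicrobia_synthA"),
  tax_acido   = c(core = "b", lin = "Bacteria;Acidobacteria;Acidobacteriia;Acidobacterium;Acidobacterium_synthA"),
  tax_plancto = c(core = "b", lin = "Bacteria;Planctomycetes;Planctomycetia;Planctomyces;Planctomyces_synthA"),
  tax_chloro  = c(core = "b", lin = "Bacteria;Chloroflexi;Anaerolineae;Anaerolinea;Anaerolinea_synthA"),
  tax_eury1   = c(core = "a", lin = "Archaea;Euryarchaeota;MGII;MGII_gen;MGII_synthA"),
  tax_eury2   = c(core = "a", lin = "Archaea;Euryarchaeota;MGIII;MGIII_gen;MGIII_synthA"),
  tax_thaum1  = c(core = "a", lin = "Archaea;Thaumarchaeota;MGI;Nitrosopelagicus;Nitrosopelagicus_synthA"),
  tax_thaum2  = c(core = "a", lin = "Archaea;Thaumarchaeota;MGI;Nitrosopumilus;Nitrosopumilus_synthA"))

s16 <- lapply(taxa, function(t)
  mutate(if (t[["core"]] == "b") core_b else core_a, 0.095))
write_fa(s16, "inst/extdata/synthetic_16s_reference.fasta")
tax_df <- data.frame(genome_id = names(taxa),
                     taxonomy = vapply(taxa, `[[`, "", "lin"))
write.table(tax_df, "inst/extdata/synthetic_16s_taxonomy.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

## recA / radA templates ----------------------------------------------
write_fa(list(recA_synth = rand_dna(900, 0.45)),
         "inst/extdata/synthetic_reca.fasta")
write_fa(list(radA_synth = rand_dna(900, 0.45)),
         "inst/extdata/synthetic_rada.fasta")

## rhodopsin templates ------------------------------------------------
aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
codon_of <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
              G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
              M = "ATG", N = "AAT", P = "CCT", Q = "CAG", R = "CGT",
              S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
prot_green <- sample(aas, 240, replace = TRUE)
prot_green[105] <- "L"
prot_blue <- prot_green
idx <- sample(setdiff(seq_along(prot_blue), 105), 14) # ~6% divergence
prot_blue[idx] <- vapply(prot_blue[idx], function(a)
  sample(setdiff(aas, a), 1L), "")
prot_blue[105] <- "Q"
to_nt <- function(p) paste(codon_of[p], collapse = "")
write_fa(list(green = to_nt(prot_green), blue = to_nt(prot_blue)),
         "inst/extdata/synthetic_rhodopsin.fasta")

cat("reference bundle written to inst/extdata\n")
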