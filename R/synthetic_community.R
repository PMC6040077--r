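# Synthetic stratified/mixed water-column communities with known truth.
#
# Genomes are order-k Markov sequences whose per-context transition rows
# all emit G+C with the exact target probability, so the realised GC of
# a draw concentrates tightly on the target while the within-GC /
# within-AT splits differ between genomes and give each one a distinct
# tetranucleotide signature.  Depth niches are Gaussian in depth;
# sequencing is length-weighted read sampling with i.i.d. substitution
# errors (no indels, so identity arithmetic on recruited reads is
# exact).

#' Genome composition model
#'
#' @param gc_target Target GC percentage, in (0, 100).
#' @param markov_order Markov chain order, 0..3.
#' @param jitter Relative spread of the within-GC and within-AT splits
#'   across contexts (0 = i.i.d. rows, larger = stronger k-mer
#'   signature).  Rows are drawn with the RNG in effect, so seed before
#'   calling for reproducibility.
#' @return An object of class `composition_model`.
#' @export
composition_model <- function(gc_target, markov_order = 3, jitter = 0.6) {
  if (!is.numeric(gc_target) || gc_target <= 0 || gc_target >= 100)
    stop("gc_target must lie strictly between 0 and 100")
  stopifnot(markov_order %in% 0:3, jitter >= 0, jitter < 1)
  g <- gc_target / 100
  nctx <- 4L^markov_order
  split_gc <- pmin(pmax(0.5 + jitter * (runif(nctx) - 0.5), 0.02), 0.98)
  split_at <- pmin(pmax(0.5 + jitter * (runif(nctx) - 0.5), 0.02), 0.98)
  trans <- cbind(A = (1 - g) * split_at,
                 C = g * split_gc,
                 G = g * (1 - split_gc),
                 `T` = (1 - g) * (1 - split_at))
  structure(list(gc_target = gc_target, markov_order = markov_order,
                 trans = trans),
            class = "composition_model")
}

#' Generate a genome from a composition model
#'
#' Deterministic given the seed.  Every transition row emits G or C
#' with probability `gc_target/100`, so realised GC is within about
#' +/- 0.5% for 1 Mb draws and well within +/- 2% for 100 kb draws.
#'
#' @param length Genome length in bp (>= 10 kb).
#' @param composition A [composition_model()].
#' @param seed Integer seed.
#' @param id Genome id.
#' @return A [genome_record()].
#' @export
generate_genome <- function(length, composition, seed, id = "genome1") {
  stopifnot(inherits(composition, "composition_model"))
  if (length < 10000) stop("genome length must be >= 10 kb")
  set.seed(seed)
  seqs <- cpp_markov_seq(as.integer(length), composition$markov_order,
                         composition$trans)
  genome_record(id, seqs)
}

#' Bundled marker templates
#'
#' Loads the synthetic marker reference shipped with the package: a
#' taxonomically labelled 16S-like reference set, recA and radA
#' nucleotide templates, and green/blue rhodopsin coding templates
#' whose spectral-tuning codon is pinned (see
#' [rhodopsin_tuning_position()]).
#'
#' @return List with elements `s16` (named sequences), `s16_taxonomy`
#'   (data frame `genome_id`, `taxonomy`), `recA`, `radA`, `rhodopsin`
#'   (named `green`/`blue`).
#' @export
marker_templates <- function() {
  ext <- function(f) system.file("extdata", f, package = "stratiprof",
                                 mustWork = TRUE)
  s16 <- Biostrings::readDNAStringSet(ext("synthetic_16s_reference.fasta"))
  tax <- read.delim(ext("synthetic_16s_taxonomy.tsv"),
                    stringsAsFactors = FALSE)
  rec <- Biostrings::readDNAStringSet(ext("synthetic_reca.fasta"))
  rad <- Biostrings::readDNAStringSet(ext("synthetic_rada.fasta"))
  rho <- Biostrings::readDNAStringSet(ext("synthetic_rhodopsin.fasta"))
  list(s16 = setNames(as.character(s16), names(s16)),
       s16_taxonomy = tax,
       recA = as.character(rec[[1]]),
       radA = as.character(rad[[1]]),
       rhodopsin = setNames(as.character(rho), names(rho)))
}

#' Spectral-tuning position of the bundled rhodopsin reference
#'
#' Residue index (1-based, in the reference protein) whose amino acid
#' determines the absorption class: leucine (L) absorbs green,
#' glutamine (Q) absorbs blue.
#'
#' @return Integer position.
#' @export
rhodopsin_tuning_position <- function() 105L

# Substitute `round(rate * n)`-ish positions i.i.d.; positions in
# `protect` (1-based) are never touched.
mutate_seq <- function(seq, rate, protect = integer()) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  idx <- which(runif(length(ch)) < rate & ch %in% c("A", "C", "G", "T"))
  idx <- setdiff(idx, protect)
  if (length(idx)) {
    alt <- vapply(ch[idx], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
    ch[idx] <- alt
  }
  paste(ch, collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Mutate third codon positions of a CDS without creating stop codons
# and without touching the codon `protect_codon`.
mutate_cds <- function(seq, rate, protect_codon = NA_integer_) {
  ch <- strsplit(seq, "")[[1]]
  ncod <- length(ch) %/% 3L
  for (cod in seq_len(ncod)) {
    if (!is.na(protect_codon) && cod == protect_codon) next
    if (runif(1) >= rate) next
    i <- 3L * cod
    old <- ch[i]
    for (b in sample(setdiff(c("A", "C", "G", "T"), old))) {
      ch[i] <- b
      if (!(paste(ch[(i - 2):i], collapse = "") %in% STOP_CODONS)) break
      ch[i] <- old
    }
  }
  paste(ch, collapse = "")
}

#' Marker implantation spec
#'
#' @param role One of `rrna16S`, `recA`, `radA`, `rhodopsin`, `GH`,
#'   `other`.
#' @param family For `rrna16S`, the reference taxon id; for
#'   `rhodopsin`, `"green"` or `"blue"`; otherwise a free label.
#' @param copies Number of copies to implant.
#' @param divergence Per-base substitution rate applied to the template
#'   before implantation (third-codon-position mutation for rhodopsin,
#'   preserving the tuning codon and avoiding stops).
#' @return A `marker_spec` list.
#' @export
marker_spec <- function(role, family = NA_character_, copies = 1L,
                        divergence = 0.08) {
  role <- match.arg(role, GENE_ROLES)
  structure(list(role = role, family = family, copies = as.integer(copies),
                 divergence = divergence),
            class = "marker_spec")
}

#' Implant marker genes into a genome
#'
#' Each marker copy replaces a randomly placed, non-overlapping segment
#' of the genome (length preserved); the gene table is updated with the
#' implanted intervals.  Rhodopsin copies carry their declared tuning
#' class in the `family` column; 16S copies carry the reference taxon
#' id and set the genome's taxonomy to that taxon's lineage.
#'
#' @param genome A [genome_record()].
#' @param specs List of [marker_spec()]s.
#' @param templates Marker templates, see [marker_templates()].
#' @return The updated `genome_record`.  Uses the RNG in effect.
#' @export
implant_markers <- function(genome, specs, templates = marker_templates()) {
  stopifnot(inherits(genome, "genome_record"))
  if (inherits(specs, "marker_spec")) specs <- list(specs)
  n <- nchar(genome$sequence)
  occupied <- genome$genes[genome$genes$role != "other",
                           c("start", "end"), drop = FALSE]
  seqs <- genome$sequence
  genes <- genome$genes
  taxonomy <- genome$taxonomy
  for (sp in specs) {
    tmpl <- switch(sp$role,
      rrna16S = {
        if (is.na(sp$family) || !sp$family %in% names(templates$s16))
          stop("rrna16S implant needs a `family` naming a reference taxon")
        templates$s16[[sp$family]]
      },
      recA = templates$recA,
      radA = templates$radA,
      rhodopsin = {
        tun <- if (is.na(sp$family)) "green" else sp$family
        if (!tun %in% names(templates$rhodopsin))
          stop("rhodopsin family must be 'green' or 'blue'")
        templates$rhodopsin[[tun]]
      },
      stop("cannot implant role '", sp$role, "'"))
    L <- nchar(tmpl)
    if (L >= n) stop("marker longer than genome")
    for (cp in seq_len(sp$copies)) {
      variant <- if (sp$role == "rhodopsin") {
        mutate_cds(tmpl, sp$divergence * 3,
                   protect_codon = rhodopsin_tuning_position())
      } else {
        mutate_seq(tmpl, sp$divergence)
      }
      placed <- FALSE
      for (try in 1:2000) {
        s <- sample.int(n - L, 1L) - 1L # 0-based start
        e <- s + L
        ok <- !nrow(occupied) ||
          all(e <= occupied$start | s >= occupied$end)
        if (ok) { placed <- TRUE; break }
      }
      if (!placed) stop("cannot place marker '", sp$role,
                        "' without overlap in genome '", genome$id, "'")
      substr(seqs, s + 1L, e) <- variant
      occupied <- rbind(occupied, data.frame(start = s, end = e))
      genes <- rbind(genes, data.frame(
        start = s, end = e, strand = "+", role = sp$role,
        family = sp$family, stringsAsFactors = FALSE))
      if (sp$role == "rrna16S") {
        hit <- templates$s16_taxonomy$taxonomy[
          templates$s16_taxonomy$genome_id == sp$family]
        if (length(hit))
          taxonomy <- strsplit(hit[1], ";", fixed = TRUE)[[1]]
      }
    }
  }
  genome_record(genome$id, seqs, taxonomy = taxonomy, genes = genes)
}

#' Depth niche specification
#'
#' @param genome_id Genome id.
#' @param center_depth_m Niche centre (ignored when `flat`).
#' @param width_m Gaussian sigma in metres (>= 0; 0 collapses to an
#'   indicator at the nearest sampled depth).
#' @param peak_relative_abundance Unnormalised weight at the niche
#'   centre, in [0, 1]; 0 means absent from the stratified series.
#' @param mixed_abundance Unnormalised weight in mixed (winter)
#'   samples; 0 means absent in winter.
#' @param flat If `TRUE`, equal weight at every stratified depth
#'   (eurybathic profile).
#' @return A `niche_spec` list.
#' @export
niche_spec <- function(genome_id, center_depth_m = NA, width_m = NA,
                       peak_relative_abundance = 1, mixed_abundance = 0,
                       flat = FALSE) {
  if (!flat && peak_relative_abundance > 0) {
    if (!is.numeric(width_m) || is.na(width_m) || width_m < 0)
      stop("width_m must be a number >= 0")
  }
  structure(list(genome_id = genome_id, center_depth_m = center_depth_m,
                 width_m = width_m,
                 peak_relative_abundance = peak_relative_abundance,
                 mixed_abundance = mixed_abundance, flat = flat),
            class = "niche_spec")
}

#' Unnormalised abundance of one niche over sampled depths
#'
#' Gaussian profile `peak * exp(-(d - center)^2 / (2 width^2))`; width 0
#' yields an indicator at the nearest sampled depth; a flat niche gives
#' `peak` everywhere.
#'
#' @param niche A [niche_spec()].
#' @param depths Numeric vector of sampled depths (non-empty).
#' @return Numeric vector over `depths`.
#' @export
depth_profile <- function(niche, depths) {
  stopifnot(inherits(niche, "niche_spec"), length(depths) > 0)
  peak <- niche$peak_relative_abundance
  if (niche$flat) return(rep(peak, length(depths)))
  if (peak == 0) return(rep(0, length(depths)))
  if (niche$width_m < 0) stop("negative width")
  if (niche$width_m == 0) {
    out <- rep(0, length(depths))
    out[which.min(abs(depths - niche$center_depth_m))] <- peak
    return(out)
  }
  peak * exp(-(depths - niche$center_depth_m)^2 / (2 * niche$width_m^2))
}

#' Per-sample normalised community abundances
#'
#' @param niches List of [niche_spec()]s.
#' @param depths Stratified sampled depths.
#' @param mixed_depths Mixed (winter) sampled depths.
#' @return Matrix genomes x samples of relative abundances, each column
#'   summing to 1; column names `strat_<d>m` / `mixed_<d>m`.
#' @export
community_abundances <- function(niches, depths, mixed_depths = numeric()) {
  strat <- vapply(niches, depth_profile, numeric(length(depths)),
                  depths = depths)
  strat <- matrix(strat, nrow = length(depths))
  mix <- vapply(niches, function(n) rep(n$mixed_abundance,
                                        length(mixed_depths)),
                numeric(length(mixed_depths)))
  mix <- matrix(mix, nrow = length(mixed_depths))
  ab <- cbind(t(strat), t(mix)) # genomes x samples
  colnames(ab) <- c(sprintf("strat_%gm", depths),
                    sprintf("mixed_%gm", mixed_depths))
  rownames(ab) <- vapply(niches, `[[`, "", "genome_id")
  cs <- colSums(ab)
  if (any(cs == 0)) stop("sample(s) with zero total abundance: ",
                         paste(colnames(ab)[cs == 0], collapse = ", "))
  sweep(ab, 2, cs, "/")
}

#' Simulate one metagenome sample
#'
#' Reads are drawn from genomes with probability proportional to
#' relative abundance times genome length (length-weighted sampling, so
#' RPKG recovers relative cell abundance up to a constant), positions
#' uniform, strands equiprobable, with i.i.d. substitution errors.
#'
#' @param genomes List of [genome_record()]s.
#' @param abundances Relative abundances over `genomes`, summing to 1.
#' @param n_reads Number of reads (> 0).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution rate, in [0, 0.1].
#' @param seed Integer seed.
#' @param sample_id,depth_m,season Metadata for the returned read set.
#' @return List with `readset` (a [sample_readset()]) and `truth`, a
#'   data frame (`read`, `genome_id`, `start`, `strand`) giving each
#'   read's source (0-based start on the source genome, forward
#'   coordinates).
#' @export
simulate_metagenome <- function(genomes, abundances, n_reads,
                                read_length = 150, error_rate = 0.002,
                                seed = 1, sample_id = "sample1",
                                depth_m = 0, season = "stratified") {
  if (n_reads <= 0) stop("n_reads must be > 0")
  if (error_rate < 0 || error_rate > 0.1)
    stop("error_rate must be in [0, 0.1]")
  if (abs(sum(abundances) - 1) > 1e-6)
    stop("abundances must sum to 1")
  stopifnot(length(abundances) == length(genomes))
  set.seed(seed)
  lens <- vapply(genomes, genome_length, numeric(1))
  if (any(lens < read_length)) stop("genome shorter than read length")
  w <- abundances * lens
  w <- w / sum(w)
  gidx <- sample.int(length(genomes), n_reads, replace = TRUE, prob = w)
  starts <- integer(n_reads)
  reads <- character(n_reads)
  for (g in unique(gidx)) {
    sel <- which(gidx == g)
    s <- sample.int(lens[g] - read_length + 1L, length(sel),
                    replace = TRUE) - 1L
    starts[sel] <- s
    reads[sel] <- substring(genomes[[g]]$sequence, s + 1L, s + read_length)
  }
  strand <- ifelse(runif(n_reads) < 0.5, "+", "-")
  neg <- strand == "-"
  if (any(neg)) reads[neg] <- revcomp(reads[neg])
  reads <- cpp_add_errors(reads, error_rate)
  ids <- vapply(genomes, `[[`, "", "id")
  list(readset = sample_readset(sample_id, reads, depth_m, season),
       truth = data.frame(read = seq_len(n_reads), genome_id = ids[gidx],
                          start = starts, strand = strand,
                          stringsAsFactors = FALSE))
}

#' Default study configuration
#'
#' A desk-scale emulation of a single-day stratified photic-zone depth
#' series (15-90 m every 15 m) plus a winter mixed pair (20 and 80 m):
#' 12 genomes covering 8 stenobathic niches (4 centred on sampled
#' depths, 4 straddling two consecutive depths), 2 eurybathic flat
#' profiles present year-round, and 2 winter-only opportunists.  Each
#' genome carries one 16S copy of a distinct reference taxon, one recA
#' and one radA, 0-1 rhodopsins with a declared tuning class, and tiled
#' gene annotations with taxon-specific glycoside-hydrolase rates.
#'
#' @param n_reads Reads per sample.
#' @param read_length Read length (bp).
#' @param error_rate Per-base substitution rate.
#' @param genome_length Genome length (bp).
#' @return A `study_config` list.
#' @export
study_config <- function(n_reads = 50000, read_length = 150,
                         error_rate = 0.002, genome_length = 60000) {
  spec <- data.frame(
    genome_id = sprintf("g%02d", 1:12),
    taxon = c("tax_cyano", "tax_alpha", "tax_gamma", "tax_bacter",
              "tax_actino", "tax_verruco", "tax_eury2", "tax_thaum1",
              "tax_marini", "tax_acido", "tax_plancto", "tax_chloro"),
    gc = c(36, 38, 40, 42, 52, 54, 46, 44, 39, 50, 48, 56),
    center = c(15, 30, 45, 60, 37.5, 52.5, 67.5, 82.5, NA, NA, NA, NA),
    width = c(2.5, 2.5, 2.5, 2.5, 4, 4, 4, 4, NA, NA, NA, NA),
    flat = c(rep(FALSE, 8), TRUE, TRUE, FALSE, FALSE),
    peak = c(0.5, 0.45, 0.4, 0.4, 1, 1, 1, 1, 0.06, 0.06, 0, 0),
    mixed = c(0.1, 0.1, 0.1, 0.1, 0, 0, 0, 0, 0.06, 0.06, 0.35, 0.35),
    n_rhodopsin = c(1, 1, 1, 1, 1, 1, 0, 0, 1, 1, 0, 0),
    tuning = c("green", "green", "blue", "blue", "green", "blue",
               NA, NA, "green", "blue", NA, NA),
    gh_per_1000 = c(30, 14, 16, 74, 20, 54, 10, 0, 10, 10, 24, 24),
    n_genes = 500,
    stringsAsFactors = FALSE)
  structure(list(depths = seq(15, 90, by = 15), mixed_depths = c(20, 80),
                 n_reads = n_reads, read_length = read_length,
                 error_rate = error_rate, genome_length = genome_length,
                 genomes = spec, rpkg_threshold = 3),
            class = "study_config")
}

GH_FAMILIES <- c("GH5", "GH13", "GH16", "GH17", "GH29", "GH30",
                 "GH57", "GH77", "GH109")

# Tiled gene annotations (labels only; no sequence implant) for the
# functional profiler: `n_genes` intervals, `n_gh` of them labelled
# with GH families drawn round-robin.
annotate_genes <- function(genome, n_genes, n_gh) {
  n <- nchar(genome$sequence)
  glen <- max(30L, n %/% (n_genes + 1L))
  starts <- floor(seq(0, n - glen, length.out = n_genes))
  role <- rep("other", n_genes)
  family <- rep(NA_character_, n_genes)
  if (n_gh > 0) {
    pick <- round(seq(1, n_genes, length.out = n_gh))
    role[pick] <- "GH"
    family[pick] <- GH_FAMILIES[(seq_len(n_gh) - 1L) %% length(GH_FAMILIES) + 1L]
  }
  ann <- data.frame(start = as.integer(starts),
                    end = as.integer(starts + glen), strand = "+",
                    role = role, family = family, stringsAsFactors = FALSE)
  genome$genes <- rbind(genome$genes, ann)
  genome
}

#' Generate a full synthetic study
#'
#' Builds the community genomes, simulates every stratified and mixed
#' sample, and emits ground-truth tables: the normalised abundance
#' matrix, expected-profile depth-range class and seasonal occupancy
#' per genome (the niche profile converted to expected RPKG and
#' thresholded exactly as the profiler does), rhodopsin copy numbers
#' and tuning classes, GH counts per taxon, and per-read source
#' positions.
#'
#' @param config A [study_config()].
#' @param seed Integer master seed.
#' @param outdir Optional directory; when given, genome FASTA, per-
#'   sample FASTQ, a manifest and the truth tables are written there.
#' @return List with `genomes`, `samples` (list of [sample_readset()]),
#'   `read_truth` (per sample), and `truth` (list of tables).
#' @export
make_study <- function(config = study_config(), seed = 1, outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  spec <- config$genomes
  need <- c("genome_id", "taxon", "gc", "center", "width", "flat",
            "peak", "mixed", "n_rhodopsin", "tuning", "gh_per_1000",
            "n_genes")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("study config misses genome field(s): ",
                         paste(miss, collapse = ", "))
  templates <- marker_templates()
  set.seed(seed)
  gseeds <- sample.int(.Machine$integer.max %/% 2L, nrow(spec))
  genomes <- vector("list", nrow(spec))
  for (i in seq_len(nrow(spec))) {
    set.seed(gseeds[i])
    cm <- composition_model(spec$gc[i])
    g <- generate_genome(config$genome_length, cm, seed = gseeds[i],
                         id = spec$genome_id[i])
    set.seed(gseeds[i] + 1L)
    specs <- list(marker_spec("rrna16S", spec$taxon[i], divergence = 0.015),
                  marker_spec("recA"), marker_spec("radA"))
    if (spec$n_rhodopsin[i] > 0)
      specs <- c(specs, list(marker_spec("rhodopsin", spec$tuning[i],
                                         copies = spec$n_rhodopsin[i])))
    g <- implant_markers(g, specs, templates)
    g <- annotate_genes(g, spec$n_genes[i],
                        round(spec$gh_per_1000[i] * spec$n_genes[i] / 1000))
    genomes[[i]] <- g
  }
  names(genomes) <- spec$genome_id

  niches <- lapply(seq_len(nrow(spec)), function(i)
    niche_spec(spec$genome_id[i], spec$center[i], spec$width[i],
               spec$peak[i], spec$mixed[i], spec$flat[i]))
  ab <- community_abundances(niches, config$depths, config$mixed_depths)

  all_depths <- c(config$depths, config$mixed_depths)
  seasons <- rep(c("stratified", "mixed"),
                 c(length(config$depths), length(config$mixed_depths)))
  set.seed(seed)
  sseeds <- sample.int(.Machine$integer.max %/% 2L,
                       ncol(ab)) # per-sample seeds
  samples <- vector("list", ncol(ab))
  read_truth <- vector("list", ncol(ab))
  for (j in seq_len(ncol(ab))) {
    sim <- simulate_metagenome(genomes, ab[, j], config$n_reads,
                               config$read_length, config$error_rate,
                               seed = sseeds[j],
                               sample_id = colnames(ab)[j],
                               depth_m = all_depths[j],
                               season = seasons[j])
    samples[[j]] <- sim$readset
    read_truth[[j]] <- sim$truth
  }
  names(samples) <- names(read_truth) <- colnames(ab)

  # expected-profile truth: expected counts under length-weighted
  # sampling, converted to RPKG and thresholded like the profiler
  lens <- vapply(genomes, genome_length, numeric(1))
  w <- sweep(ab * lens, 2, colSums(ab * lens), "/")
  exp_counts <- w * config$n_reads
  total_bp <- config$n_reads * config$read_length
  exp_rpkg <- exp_counts / (lens / 1000) / (total_bp / 1e9)
  exp_presence <- exp_rpkg >= config$rpkg_threshold
  is_strat <- seasons == "stratified"
  depth_class <- apply(exp_presence[, is_strat, drop = FALSE], 1,
                       classify_depth_range, sampled_depths = config$depths)
  occupancy <- vapply(seq_len(nrow(spec)), function(i)
    classify_seasonal_occupancy(exp_presence[i, is_strat],
                                exp_presence[i, !is_strat]), "")
  truth <- list(
    abundance = ab,
    expected_rpkg = exp_rpkg,
    classification = data.frame(
      genome_id = spec$genome_id, taxon = spec$taxon,
      depth_range_class = unname(depth_class),
      seasonal_occupancy = unname(occupancy), stringsAsFactors = FALSE),
    rhodopsin = data.frame(
      genome_id = spec$genome_id,
      rhodopsin_per_genome = spec$n_rhodopsin,
      tuning = spec$tuning, stringsAsFactors = FALSE),
    gh = data.frame(genome_id = spec$genome_id, taxon = spec$taxon,
                    n_genes = spec$n_genes,
                    gh_count = round(spec$gh_per_1000 * spec$n_genes / 1000),
                    stringsAsFactors = FALSE))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genomes, file.path(outdir, "genomes.fasta"))
    gene_rows <- do.call(rbind, lapply(genomes, function(g)
      cbind(genome_id = g$id, g$genes)))
    write.table(gene_rows, file.path(outdir, "genes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    man <- data.frame(sample_id = names(samples), depth_m = all_depths,
                      season = seasons,
                      path = file.path(outdir,
                                       paste0(names(samples), ".fastq")))
    for (j in seq_along(samples))
      write_fastq(samples[[j]], man$path[j])
    write.table(man, file.path(outdir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth$classification,
                file.path(outdir, "truth_classification.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(cbind(genome_id = rownames(ab), as.data.frame(ab)),
                file.path(outdir, "truth_abundance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(genomes = genomes, samples = samples, read_truth = read_truth,
       truth = truth, config = config)
}
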