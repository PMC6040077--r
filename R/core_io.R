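#' @useDynLib stratiprof, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp sd quantile setNames aggregate dist hclust runif
#'   rbinom cutree
#' @importFrom utils read.delim write.table head
NULL

# Closed vocabulary for gene roles carried on genome records.
GENE_ROLES <- c("rrna16S", "recA", "radA", "rhodopsin", "GH", "other")

empty_genes <- function() {
  data.frame(start = integer(), end = integer(), strand = character(),
             role = character(), family = character(),
             stringsAsFactors = FALSE)
}

#' Construct a genome record
#'
#' A genome record holds one reference genome or assembled contig: its
#' sequence, an ordered taxonomy lineage (domain downwards, possibly
#' partial) and annotated gene intervals.  Gene coordinates are 0-based,
#' half-open, and must lie within the sequence; roles come from the
#' closed vocabulary `rrna16S`, `recA`, `radA`, `rhodopsin`, `GH`,
#' `other`.
#'
#' @param id Unique genome/contig identifier.
#' @param sequence DNA string over A, C, G, T, N (lowercase accepted,
#'   stored uppercase).
#' @param taxonomy Character vector of lineage labels, highest rank
#'   first; may be empty or partial.
#' @param genes Data frame with columns `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `role` and `family` (free-text family or marker
#'   label, `NA` allowed).
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, taxonomy = character(),
                          genes = empty_genes()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad))
    stop("genome '", id, "' contains non-ACGTN characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  genes <- as.data.frame(genes)
  if (nrow(genes)) {
    need <- c("start", "end", "strand", "role", "family")
    miss <- setdiff(need, names(genes))
    if (length(miss)) stop("gene table misses columns: ",
                           paste(miss, collapse = ", "))
    genes <- genes[, need]
    n <- nchar(sequence)
    if (any(genes$start < 0L) || any(genes$end > n) ||
        any(genes$start >= genes$end))
      stop("gene intervals of '", id,
           "' must satisfy 0 <= start < end <= sequence length (",
           n, "); coordinates are 0-based half-open")
    bad_role <- setdiff(unique(genes$role), GENE_ROLES)
    if (length(bad_role))
      stop("unknown gene role(s): ", paste(bad_role, collapse = ", "),
           "; allowed: ", paste(GENE_ROLES, collapse = ", "))
  } else {
    genes <- empty_genes()
  }
  structure(list(id = id, sequence = sequence,
                 taxonomy = as.character(taxonomy), genes = genes),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$id, ": ", nchar(x$sequence), " bp, ",
      nrow(x$genes), " genes",
      if (length(x$taxonomy)) paste0(" [", paste(x$taxonomy, collapse = ";"), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Genome length in bp
#' @param x A `genome_record`.
#' @return Integer sequence length.
#' @export
genome_length <- function(x) nchar(x$sequence)

#' Construct a sample read set
#'
#' One metagenome sample: its reads (single-end; qualities are not
#' modelled), collection depth, season regime and total sequenced bases.
#'
#' @param sample_id Sample identifier.
#' @param reads Character vector of DNA reads.
#' @param depth_m Collection depth in metres (>= 0).
#' @param season `"stratified"` or `"mixed"`.
#' @return An object of class `sample_readset` with `total_bp` equal to
#'   the summed read lengths.
#' @export
sample_readset <- function(sample_id, reads, depth_m, season) {
  season <- match.arg(season, c("stratified", "mixed"))
  stopifnot(is.numeric(depth_m), length(depth_m) == 1L, depth_m >= 0)
  reads <- toupper(as.character(reads))
  structure(list(sample_id = sample_id, reads = reads,
                 depth_m = as.numeric(depth_m), season = season,
                 total_bp = sum(nchar(reads))),
            class = "sample_readset")
}

#' @export
print.sample_readset <- function(x, ...) {
  cat("<sample_readset> ", x$sample_id, ": ", length(x$reads), " reads, ",
      x$total_bp, " bp, ", x$depth_m, " m (", x$season, ")\n", sep = "")
  invisible(x)
}

#' Read a FASTA file of genomes or contigs
#'
#' Sequences are uppercased; ids must be unique; characters outside
#' A, C, G, T, N are rejected.  Taxonomy and gene annotations can be
#' attached from sidecar tables.
#'
#' @param path FASTA file.
#' @param genes Optional gene sidecar: data frame or TSV path with
#'   columns `genome_id`, `start`, `end`, `strand`, `role`, `family`
#'   (0-based half-open coordinates).
#' @param taxonomy Optional named list/vector mapping genome id to a
#'   `;`-separated lineage string, or a data frame/TSV with columns
#'   `genome_id`, `taxonomy`.
#' @return List of [genome_record()] objects, named by id.
#' @export
read_fasta <- function(path, genes = NULL, taxonomy = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ",
                        paste(unique(dup), collapse = ", "))
  gtab <- if (is.character(genes)) read_gene_sidecar(genes) else genes
  ttab <- taxonomy
  if (is.character(ttab) && length(ttab) == 1L && file.exists(ttab))
    ttab <- read.delim(ttab, stringsAsFactors = FALSE)
  out <- lapply(seq_along(ss), function(i) {
    id <- ids[i]
    g <- if (!is.null(gtab)) {
      gi <- gtab[gtab$genome_id == id, , drop = FALSE]
      gi$genome_id <- NULL
      if (nrow(gi)) gi else empty_genes()
    } else empty_genes()
    tx <- character()
    if (!is.null(ttab)) {
      if (is.data.frame(ttab)) {
        hit <- ttab$taxonomy[ttab$genome_id == id]
        if (length(hit)) tx <- strsplit(hit[1], ";", fixed = TRUE)[[1]]
      } else if (!is.null(ttab[[id]])) {
        tx <- strsplit(ttab[[id]], ";", fixed = TRUE)[[1]]
      }
    }
    genome_record(id, as.character(ss[[i]]), taxonomy = tx, genes = g)
  })
  names(out) <- ids
  out
}

#' Write genome records (or named sequences) to FASTA
#' @param x List of `genome_record`s, or a named character vector.
#' @param path Output file.
#' @param width Line width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.list(x) && length(x) && inherits(x[[1]], "genome_record"))
    x <- setNames(vapply(x, `[[`, "", "sequence"),
                  vapply(x, `[[`, "", "id"))
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

parse_fastq <- function(path) {
  lines <- readLines(path)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  n <- length(lines)
  if (n == 0L) return(list(ids = character(), reads = character()))
  if (n %% 4L != 0L)
    stop("truncated FASTQ: record ", n %/% 4L + 1L, " is incomplete")
  heads <- lines[seq(1L, n, 4L)]
  seqs  <- lines[seq(2L, n, 4L)]
  plus  <- lines[seq(3L, n, 4L)]
  quals <- lines[seq(4L, n, 4L)]
  bad <- which(!startsWith(heads, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1],
         ": expected '@' header and '+' separator")
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism))
    stop("FASTQ record ", mism[1],
         ": sequence and quality lengths differ")
  list(ids = sub("\\s.*$", "", sub("^@", "", heads)), reads = toupper(seqs))
}

#' Read a FASTQ or FASTA read file into a sample read set
#'
#' Qualities are parsed for format validation but otherwise ignored:
#' all downstream filters are identity-based.
#'
#' @param path Read file.
#' @param format `"fastq"` or `"fasta"`.
#' @param sample_id Sample id (default: file base name).
#' @param depth_m Collection depth in metres.
#' @param season `"stratified"` or `"mixed"`.
#' @return A [sample_readset()]; read order is preserved and `total_bp`
#'   is the summed read length.
#' @export
read_reads <- function(path, format = c("fastq", "fasta"),
                       sample_id = NULL, depth_m = 0,
                       season = "stratified") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(fastq|fq|fasta|fa|fna)$", "", basename(path))
  reads <- if (format == "fastq") {
    parse_fastq(path)$reads
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    as.character(ss)
  }
  sample_readset(sample_id, unname(reads), depth_m, season)
}

#' Write a read set to FASTQ (constant dummy qualities)
#' @param readset A `sample_readset`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(readset, path) {
  n <- length(readset$reads)
  ids <- sprintf("%s_read%06d", readset$sample_id, seq_len(n))
  con <- file(path, "w")
  on.exit(close(con))
  if (n) {
    qual <- vapply(nchar(readset$reads),
                   function(l) strrep("I", l), "")
    writeLines(paste0("@", ids, "\n", readset$reads, "\n+\n", qual), con)
  }
  invisible(path)
}

#' Read a sample manifest
#'
#' TSV with columns `sample_id`, `depth_m`, `season`, `path`.  Seasons
#' must be `stratified` or `mixed`; stratified rows are returned sorted
#' by ascending depth, followed by the mixed rows.
#'
#' @param path Manifest TSV.
#' @return Data frame with the four columns, validated and ordered.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "depth_m", "season", "path")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest misses column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(m$season), c("stratified", "mixed"))
  if (length(bad))
    stop("unknown season label(s): ", paste(bad, collapse = ", "),
         "; expected 'stratified' or 'mixed'")
  dup <- m$sample_id[duplicated(m$sample_id)]
  if (length(dup))
    stop("duplicate sample_id(s): ", paste(unique(dup), collapse = ", "))
  for (ssn in unique(m$season)) {
    d <- m$depth_m[m$season == ssn]
    if (anyDuplicated(d))
      stop("depth_m must be unique within the '", ssn, "' series")
  }
  strat <- m[m$season == "stratified", , drop = FALSE]
  strat <- strat[order(strat$depth_m), , drop = FALSE]
  mix <- m[m$season == "mixed", , drop = FALSE]
  mix <- mix[order(mix$depth_m), , drop = FALSE]
  out <- rbind(strat, mix)
  rownames(out) <- NULL
  out
}

#' Read a gene sidecar table
#' @param path TSV with columns `genome_id`, `start`, `end`, `strand`,
#'   `role`, `family` (0-based half-open coordinates).
#' @return Data frame.
#' @export
read_gene_sidecar <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "start", "end", "strand", "role", "family")
  miss <- setdiff(need, names(g))
  if (length(miss))
    stop("gene sidecar misses column(s): ", paste(miss, collapse = ", "))
  g
}

#' Read a nutrient table
#'
#' TSV mirroring a standard water-column nutrient summary: one row per
#' sample with at least `sample_id`, `total_n_uM` and `total_p_uM`;
#' further columns (NOx, NH4, PO4, TOC, chlorophyll_a, temperature)
#' pass through untouched.
#'
#' @param path Nutrient TSV.
#' @return Data frame.
#' @export
read_nutrients <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "total_n_uM", "total_p_uM")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("nutrient table misses column(s): ", paste(miss, collapse = ", "))
  x
}

#' GC content in percent
#'
#' `100 * (G + C) / (A + C + G + T)`; N bases are excluded from both
#' numerator and denominator.
#'
#' @param x A DNA string, character vector of sequences, a
#'   `genome_record`, or a `sample_readset` (pooled over all reads).
#' @return GC percentage.
#' @export
gc_content <- function(x) {
  if (inherits(x, "genome_record")) x <- x$sequence
  if (inherits(x, "sample_readset")) x <- x$reads
  x <- toupper(paste(as.character(x), collapse = ""))
  n <- nchar(x)
  if (n == 0L) stop("empty sequence")
  cnt <- vapply(c("A", "C", "G", "T"), function(b) {
    lengths(regmatches(x, gregexpr(b, x, fixed = TRUE)))
  }, numeric(1))
  tot <- sum(cnt)
  if (tot == 0) stop("no A/C/G/T bases (all-N input?)")
  100 * (cnt[["C"]] + cnt[["G"]]) / tot
}

#' Reverse complement
#' @param x Character vector of DNA sequences.
#' @return Reverse-complemented sequences (N preserved).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
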