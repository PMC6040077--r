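# Rhodopsin detection on contigs, spectral (blue/green) tuning
# classification, and read-based rhodopsin abundance normalised by the
# single-copy housekeeping genes recA and radA.

#' Translate DNA to protein
#'
#' @param x DNA string; length is trimmed to a codon multiple; fuzzy
#'   codons (N) translate to X.
#' @return Amino-acid string (stops as `*`).
#' @export
translate_dna <- function(x) {
  x <- substr(x, 1L, (nchar(x) %/% 3L) * 3L)
  as.character(Biostrings::translate(Biostrings::DNAString(x),
                                     if.fuzzy.codon = "X"))
}

#' Bundled rhodopsin exemplar proteins
#'
#' Translations of the shipped green and blue rhodopsin templates;
#' the green exemplar is also the spectral-tuning reference whose
#' position [rhodopsin_tuning_position()] defines the tuning residue.
#'
#' @return Named character vector (`green`, `blue`).
#' @export
rhodopsin_exemplars <- function() {
  t <- marker_templates()
  vapply(t$rhodopsin, translate_dna, "")
}

aa_align <- function(pattern, subject, type = "global") {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = type)
}

#' Detect rhodopsin genes on contigs
#'
#' Six-frame translation of every contig of at least `min_contig_len`
#' (default 5 kb, shorter contigs skipped); a gene is called where a
#' translated frame aligns locally to a bundled exemplar protein with
#' at least `min_identity` percent identity over at least
#' `min_coverage` of the exemplar.  Per frame the best hit is masked
#' and the frame rescanned, so multiple copies are found.
#'
#' @param contigs List of [genome_record()]s.
#' @param exemplars Named protein exemplars, default
#'   [rhodopsin_exemplars()].
#' @param min_contig_len Contig length gate in bp.
#' @param min_identity Percent identity cutoff on the aligned region.
#' @param min_coverage Fraction of the exemplar that must align.
#' @param max_per_frame Rescan passes per frame.
#' @return Data frame: `id`, `contig`, `start`, `end` (0-based
#'   half-open, forward strand), `strand`, `sequence` (oriented nt),
#'   `protein`, `identity`.
#' @export
find_rhodopsins <- function(contigs, exemplars = rhodopsin_exemplars(),
                            min_contig_len = 5000, min_identity = 40,
                            min_coverage = 0.7, max_per_frame = 3) {
  out <- list()
  for (ctg in contigs) {
    n <- nchar(ctg$sequence)
    if (n < min_contig_len) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") ctg$sequence else revcomp(ctg$sequence)
      for (f in 0:2) {
        frame_aa <- translate_dna(substring(s, f + 1L, n))
        for (pass in seq_len(max_per_frame)) {
          best <- NULL
          for (ex in names(exemplars)) {
            aln <- aa_align(frame_aa, exemplars[[ex]], type = "local")
            cov <- Biostrings::nchar(Biostrings::subject(aln)) /
              nchar(exemplars[[ex]])
            pid <- Biostrings::pid(aln, type = "PID1")
            if (cov >= min_coverage && pid >= min_identity &&
                (is.null(best) || Biostrings::score(aln) > best$score)) {
              best <- list(aln = aln, score = Biostrings::score(aln),
                           pid = pid)
            }
          }
          if (is.null(best)) break
          aa_s <- Biostrings::start(Biostrings::pattern(best$aln))
          aa_e <- Biostrings::end(Biostrings::pattern(best$aln))
          nt_s <- f + 3L * (aa_s - 1L) # 0-based on strand s
          nt_e <- f + 3L * aa_e
          fwd <- if (strand == "+") c(nt_s, nt_e) else c(n - nt_e, n - nt_s)
          gene_nt <- substring(s, nt_s + 1L, nt_e)
          out[[length(out) + 1L]] <- data.frame(
            id = sprintf("%s_rho%d", ctg$id, length(out) + 1L),
            contig = ctg$id, start = fwd[1], end = fwd[2],
            strand = strand, sequence = gene_nt,
            protein = translate_dna(gene_nt), identity = best$pid,
            stringsAsFactors = FALSE)
          # mask and rescan this frame
          masked <- strsplit(frame_aa, "")[[1]]
          masked[aa_s:aa_e] <- "X"
          frame_aa <- paste(masked, collapse = "")
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), sequence = character(),
                      protein = character(), identity = numeric()))
  do.call(rbind, out)
}

#' Spectral tuning class of a rhodopsin
#'
#' The query protein (or coding sequence, translated) is aligned
#' globally to the bundled tuning reference; the residue in the column
#' of the reference tuning position decides the class: L = green,
#' Q = blue, anything else (or an unalignable query) = unknown.
#' Deterministic, and invariant to synonymous nucleotide changes.
#'
#' @param x Protein or DNA string.
#' @param reference Tuning reference protein (default: bundled green
#'   exemplar).
#' @param tuning_pos 1-based residue index in the reference.
#' @param min_coverage Minimum fraction of the reference that must be
#'   spanned by the aligned query, default 0.5.
#' @return List with `class` (`green`/`blue`/`unknown`) and `residue`.
#' @export
spectral_class <- function(x, reference = NULL,
                           tuning_pos = rhodopsin_tuning_position(),
                           min_coverage = 0.5) {
  if (is.null(reference)) reference <- rhodopsin_exemplars()[["green"]]
  if (grepl("^[ACGTNacgtn]+$", x)) x <- translate_dna(x)
  aln <- aa_align(x, reference, type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  spos <- cumsum(sub != "-")
  aligned_ref <- sum(sub != "-" & pat != "-")
  if (aligned_ref < min_coverage * nchar(reference))
    return(list(class = "unknown", residue = NA_character_))
  col <- which(spos == tuning_pos & sub != "-")
  if (!length(col)) return(list(class = "unknown",
                                residue = NA_character_))
  res <- pat[col[1]]
  cls <- if (res == "L") "green" else if (res == "Q") "blue" else "unknown"
  list(class = cls, residue = res)
}

#' Rhodopsin genes per genome, recA/radA-normalised
#'
#' Length-normalised rhodopsin read counts divided by length-
#' normalised recA+radA read counts:
#' `(rho_reads / rho_len) / ((recA_reads + radA_reads) / (recA_len +
#' radA_len))`.  Since recA and radA are universal single-copy genes,
#' the ratio estimates the community-weighted rhodopsin copy number
#' per genome.  Reads are assigned by the recruitment contract (best
#' hit over all reference sets jointly); reads whose best hit falls in
#' `exclude_refs` (e.g. viral or eukaryotic sequences) are not
#' counted.
#'
#' @param readset A [sample_readset()] or character vector.
#' @param rhodopsin_refs,recA_refs,radA_refs Named character vectors
#'   of nucleotide reference sequences (non-empty).
#' @param exclude_refs Optional named exclusion references.
#' @param min_identity,min_aln_len Recruitment filters (default 99 /
#'   50).
#' @return List with `rhodopsins_per_genome`, `rhodopsin_read_count`,
#'   `recA_read_count`, `radA_read_count`.
#' @export
rhodopsins_per_genome <- function(readset, rhodopsin_refs, recA_refs,
                                  radA_refs, exclude_refs = NULL,
                                  min_identity = 99, min_aln_len = 50L) {
  if (!length(recA_refs) || !length(radA_refs))
    stop("recA/radA reference sets must be non-empty")
  lab <- function(x, tag) {
    if (!length(x)) return(character())
    setNames(unname(x), paste0(tag, "::", seq_along(x)))
  }
  refs <- c(lab(rhodopsin_refs, "rho"), lab(recA_refs, "recA"),
            lab(radA_refs, "radA"))
  if (length(exclude_refs)) refs <- c(refs, lab(exclude_refs, "excl"))
  r <- recruit(readset, refs, min_identity, min_aln_len)
  cat_of <- sub("::.*$", "", names(r$counts))
  n_rho <- sum(r$counts[cat_of == "rho"])
  n_recA <- sum(r$counts[cat_of == "recA"])
  n_radA <- sum(r$counts[cat_of == "radA"])
  if (n_recA + n_radA == 0)
    stop("no recA/radA reads recruited; sample too shallow to normalise")
  # Length normalisation is per gene copy: reads over the typical
  # rhodopsin gene length, against recA+radA reads over the combined
  # per-genome housekeeping length (one recA and one radA per genome),
  # so the ratio estimates rhodopsin copies per genome.
  est <- if (length(rhodopsin_refs) == 0 || n_rho == 0) 0 else {
    (n_rho / mean(nchar(rhodopsin_refs))) /
      ((n_recA + n_radA) / (mean(nchar(recA_refs)) + mean(nchar(radA_refs))))
  }
  list(rhodopsins_per_genome = est, rhodopsin_read_count = n_rho,
       recA_read_count = n_recA, radA_read_count = n_radA)
}

#' Recruit reads to rhodopsin genes across samples
#'
#' Per-gene, per-sample RPKG (gene length as the kilobase
#' denominator); genes that never reach `keep_rpkg` (inclusive) are
#' dropped.
#'
#' @param readsets List of [sample_readset()]s.
#' @param genes Named character vector of rhodopsin gene sequences.
#' @param min_identity,min_aln_len Recruitment filters (99 / 50).
#' @param keep_rpkg Keep threshold in RPKG, default 1.
#' @return Genes x samples RPKG matrix (kept genes only).
#' @export
rhodopsin_recruit <- function(readsets, genes, min_identity = 99,
                              min_aln_len = 50L, keep_rpkg = 1.0) {
  stopifnot(length(genes) > 0)
  sid <- vapply(readsets, `[[`, "", "sample_id")
  m <- matrix(0, length(genes), length(readsets),
              dimnames = list(names(genes), sid))
  for (j in seq_along(readsets)) {
    r <- recruit(readsets[[j]], genes, min_identity, min_aln_len)
    m[names(r$counts), j] <- rpkg(r$counts, nchar(genes)[names(r$counts)],
                                  readsets[[j]]$total_bp)
  }
  m[apply(m, 1, function(x) any(x >= keep_rpkg)), , drop = FALSE]
}
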