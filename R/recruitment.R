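# Read recruitment, the RPKG abundance statistic, and the derived
# depth-range / seasonal-occupancy classifications.
#
# A read recruits to the genome holding its maximal-scoring local
# alignment (both strands searched, ungapped seed-and-extend; the
# simulator's error model is substitution-only so gaps carry no
# signal), and counts iff identity >= `min_identity` over
# >= `min_aln_len` aligned columns.  Identity is matches divided by
# alignment columns.  All thresholds are inclusive.  Score ties break
# lexicographically by genome id so reruns are deterministic.

#' Recruit reads to a set of genomes
#'
#' @param readset A [sample_readset()] (or character vector of reads).
#' @param genomes List of [genome_record()]s (or named character vector
#'   of sequences).
#' @param min_identity Minimum percent identity (inclusive; matches /
#'   alignment columns).
#' @param min_aln_len Minimum alignment length in columns (inclusive).
#' @param k Seed k-mer length of the aligner (exact-match seeds).
#' @param seed_stride Spacing of seeds along the read.
#' @return List with `counts` (named integer vector per genome) and
#'   `hits` (data frame `read`, `genome_id`, `identity`, `aln_len`,
#'   `strand`, `subject_start`), one best hit per recruited read.
#' @export
recruit <- function(readset, genomes, min_identity = 99.0,
                    min_aln_len = 50L, k = 16L, seed_stride = 4L) {
  if (length(genomes) == 0L) stop("no genomes supplied")
  stopifnot(min_identity >= 0, min_identity <= 100, min_aln_len >= 1)
  reads <- if (inherits(readset, "sample_readset")) readset$reads
           else as.character(readset)
  seqs <- if (is.list(genomes)) {
    setNames(vapply(genomes, `[[`, "", "sequence"),
             vapply(genomes, `[[`, "", "id"))
  } else genomes
  if (is.null(names(seqs))) names(seqs) <- sprintf("g%03d", seq_along(seqs))
  ord <- order(names(seqs)) # lexicographic tie-break = lowest index
  seqs <- seqs[ord]
  counts <- setNames(integer(length(seqs)), names(seqs))
  if (length(reads) == 0L) {
    return(list(counts = counts[order(names(counts))],
                hits = data.frame(read = integer(), genome_id = character(),
                                  identity = numeric(), aln_len = integer(),
                                  strand = integer(),
                                  subject_start = numeric())))
  }
  h <- cpp_recruit(reads, unname(seqs), min_identity,
                   as.integer(min_aln_len), as.integer(k),
                   as.integer(seed_stride))
  gid <- names(seqs)[h$subject]
  tab <- table(factor(gid, levels = names(seqs)))
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       hits = data.frame(read = h$read, genome_id = gid,
                         identity = h$identity, aln_len = h$aln_len,
                         strand = h$strand,
                         subject_start = h$subject_start,
                         stringsAsFactors = FALSE))
}

#' RPKG: reads per kilobase of genome per gigabase of metagenome
#'
#' `count / (genome_length_bp / 1e3) / (metagenome_bp / 1e9)`.  The
#' metagenome size is the total sequenced bases of the sample, not its
#' read count.
#'
#' @param count Recruited read count (vectorised).
#' @param genome_length_bp Genome length in bp (> 0).
#' @param metagenome_bp Total sample bases (> 0).
#' @return RPKG value(s).
#' @export
rpkg <- function(count, genome_length_bp, metagenome_bp) {
  if (any(genome_length_bp <= 0)) stop("genome_length_bp must be > 0")
  if (any(metagenome_bp <= 0)) stop("metagenome_bp must be > 0")
  count / (genome_length_bp / 1e3) / (metagenome_bp / 1e9)
}

#' Build a recruitment matrix over samples
#'
#' Runs [recruit()] per sample and assembles counts, RPKG and presence
#' (RPKG at or above the threshold in the sample).
#'
#' @param samples List of [sample_readset()]s.
#' @param genomes List of [genome_record()]s.
#' @param min_identity,min_aln_len Recruitment filters, see [recruit()].
#' @param rpkg_threshold Presence threshold in RPKG units (inclusive).
#' @param keep_hits Keep per-read hit tables (needed for coverage or
#'   specificity analyses).
#' @return An object of class `recruitment_matrix`: list with `counts`,
#'   `rpkg`, `presence` (genomes x samples matrices), `depths`,
#'   `seasons`, `genome_length`, and optionally `hits`.
#' @export
recruitment_matrix <- function(samples, genomes, min_identity = 99.0,
                               min_aln_len = 50L, rpkg_threshold = 3.0,
                               keep_hits = FALSE) {
  stopifnot(length(samples) > 0, rpkg_threshold > 0)
  ids <- vapply(genomes, `[[`, "", "id")
  lens <- vapply(genomes, genome_length, numeric(1))
  names(lens) <- ids
  sid <- vapply(samples, `[[`, "", "sample_id")
  counts <- matrix(0L, length(ids), length(samples),
                   dimnames = list(ids, sid))
  rp <- counts * 0
  hits <- if (keep_hits) vector("list", length(samples)) else NULL
  for (j in seq_along(samples)) {
    r <- recruit(samples[[j]], genomes, min_identity, min_aln_len)
    counts[names(r$counts), j] <- r$counts
    rp[, j] <- rpkg(counts[, j], lens, samples[[j]]$total_bp)
    if (keep_hits) hits[[j]] <- r$hits
  }
  if (keep_hits) names(hits) <- sid
  structure(list(counts = counts, rpkg = rp,
                 presence = rp >= rpkg_threshold,
                 rpkg_threshold = rpkg_threshold,
                 depths = vapply(samples, `[[`, numeric(1), "depth_m"),
                 seasons = vapply(samples, `[[`, "", "season"),
                 genome_length = lens, hits = hits),
            class = "recruitment_matrix")
}

#' @export
print.recruitment_matrix <- function(x, ...) {
  cat("<recruitment_matrix> ", nrow(x$counts), " genomes x ",
      ncol(x$counts), " samples; ", sum(presence_filter(x)$retained),
      " genomes above ", x$rpkg_threshold, " RPKG\n", sep = "")
  invisible(x)
}

#' Apply the RPKG presence threshold
#'
#' A genome is retained iff its RPKG reaches the threshold (inclusive)
#' in at least one sample.
#'
#' @param x A `recruitment_matrix`, or a genomes x samples RPKG matrix.
#' @param threshold Presence threshold (> 0), default 3 RPKG.
#' @return List with `presence` (boolean matrix) and `retained`
#'   (named logical over genomes).
#' @export
presence_filter <- function(x, threshold = 3.0) {
  stopifnot(threshold > 0)
  rp <- if (inherits(x, "recruitment_matrix")) x$rpkg else as.matrix(x)
  pres <- rp >= threshold
  list(presence = pres, retained = apply(pres, 1, any))
}

#' Classify the depth range of one genome
#'
#' Over the stratified depth series: `absent` when no depth is
#' occupied; `stenobathic` when one depth, or two adjacent depths in
#' the sampled series, are occupied; `eurybathic` when every sampled
#' depth is occupied; `intermediate` otherwise (including occupied
#' depths separated by a gap).
#'
#' @param presence_row Logical vector over the stratified samples.
#' @param sampled_depths The sampled depths, ascending, equally spaced.
#' @return One of `"absent"`, `"stenobathic"`, `"intermediate"`,
#'   `"eurybathic"`.
#' @export
classify_depth_range <- function(presence_row, sampled_depths) {
  if (length(presence_row) != length(sampled_depths))
    stop("presence row length (", length(presence_row),
         ") != number of sampled depths (", length(sampled_depths), ")")
  if (is.unsorted(sampled_depths, strictly = TRUE))
    stop("sampled_depths must be sorted ascending")
  occ <- which(as.logical(presence_row))
  n <- length(sampled_depths)
  if (length(occ) == 0L) return("absent")
  if (length(occ) == n) return("eurybathic")
  if (length(occ) == 1L ||
      (length(occ) == 2L && diff(occ) == 1L)) return("stenobathic")
  "intermediate"
}

#' Classify seasonal occupancy of one genome
#'
#' `always` when present in at least one stratified and one mixed
#' sample; `stratified_only` / `winter_only` when present in exactly
#' one of the two groups; `absent` otherwise.
#'
#' @param strat_presence Logical vector over stratified samples.
#' @param mixed_presence Logical vector over mixed (winter) samples.
#' @return One of `"always"`, `"stratified_only"`, `"winter_only"`,
#'   `"absent"`.
#' @export
classify_seasonal_occupancy <- function(strat_presence, mixed_presence) {
  if (!length(strat_presence) || !length(mixed_presence))
    stop("both sample groups must be non-empty")
  s <- any(as.logical(strat_presence))
  m <- any(as.logical(mixed_presence))
  if (s && m) "always"
  else if (s) "stratified_only"
  else if (m) "winter_only"
  else "absent"
}

#' Depth-range and occupancy classification for every genome
#'
#' @param rm A `recruitment_matrix` covering stratified and mixed
#'   samples.
#' @return Data frame `genome_id`, `depth_range_class`,
#'   `seasonal_occupancy`, `occupied_depths` (comma-joined).
#' @export
classify_genomes <- function(rm) {
  stopifnot(inherits(rm, "recruitment_matrix"))
  is_strat <- rm$seasons == "stratified"
  strat_depths <- rm$depths[is_strat]
  ord <- order(strat_depths)
  pres_s <- rm$presence[, which(is_strat)[ord], drop = FALSE]
  pres_m <- rm$presence[, !is_strat, drop = FALSE]
  data.frame(
    genome_id = rownames(rm$presence),
    depth_range_class = apply(pres_s, 1, classify_depth_range,
                              sampled_depths = strat_depths[ord]),
    seasonal_occupancy = vapply(seq_len(nrow(pres_s)), function(i)
      classify_seasonal_occupancy(pres_s[i, ], pres_m[i, ]), ""),
    occupied_depths = apply(pres_s, 1, function(p)
      paste(strat_depths[ord][p], collapse = ",")),
    stringsAsFactors = FALSE)
}

#' Mean per-base coverage of each genome from recruitment hits
#'
#' @param rm A `recruitment_matrix` built with `keep_hits = TRUE`.
#' @return Genomes x samples matrix of mean depth (aligned bases /
#'   genome length).
#' @export
coverage_from_hits <- function(rm) {
  stopifnot(inherits(rm, "recruitment_matrix"), !is.null(rm$hits))
  out <- rm$counts * 0
  for (j in seq_along(rm$hits)) {
    h <- rm$hits[[j]]
    if (nrow(h)) {
      ag <- tapply(h$aln_len, h$genome_id, sum)
      out[names(ag), j] <- unname(ag) / rm$genome_length[names(ag)]
    }
  }
  out
}
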