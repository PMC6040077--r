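# 16S rRNA fragment profiling: greedy reference clustering, a
# permissive identity screen over raw reads, positional log-odds
# profile verification with a shuffle-calibrated cutoff, final
# identity/length classification, abundance tables and Simpson
# diversity.

RANKS <- c("domain", "phylum", "class", "genus", "species")

#' Build a 16S reference by greedy identity clustering
#'
#' Inputs are processed in order; each sequence joins the first
#' existing centroid with global identity at or above the radius,
#' otherwise it founds a new centroid.  Every sequence must carry a
#' taxonomy label.
#'
#' @param sequences Named character vector of 16S sequences.
#' @param taxonomy Character vector of `;`-separated lineages
#'   (domain;phylum;class;genus;species), parallel to `sequences`.
#' @param radius Identity radius in [0, 1], default 0.90.
#' @return An object of class `reference_16s`: data frame with `id`,
#'   `sequence`, `taxonomy`, `n_members`.
#' @export
build_reference <- function(sequences, taxonomy, radius = 0.90) {
  if (length(sequences) < 1) stop("need at least one labelled sequence")
  if (length(taxonomy) != length(sequences) || any(!nzchar(taxonomy)) ||
      any(is.na(taxonomy)))
    stop("every sequence needs a taxonomy label")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%04d", seq_along(sequences))
  cent <- integer(0)
  assign <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    placed <- FALSE
    for (ci in cent) {
      if (seq_identity(sequences[[i]], sequences[[ci]]) >= radius * 100) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) { cent <- c(cent, i); assign[i] <- i }
  }
  out <- data.frame(id = names(sequences)[cent],
                    sequence = unname(sequences[cent]),
                    taxonomy = taxonomy[cent],
                    n_members = as.integer(table(factor(assign,
                                                        levels = cent))),
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_16s", "data.frame")
  out
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch alignment; identity is matches over alignment
#' columns (gaps included).
#'
#' @param a,b DNA strings.
#' @return Percent identity.
#' @export
seq_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(aln, type = "PID1")
}

#' The bundled synthetic 16S reference
#'
#' A small taxonomically labelled 16S-like set (10 bacterial and 4
#' archaeal taxa derived from two domain cores); sequences are equal
#' length and substitution-diverged, so the set doubles as a gap-free
#' reference alignment for the domain profiles.
#'
#' @return A `reference_16s` object.
#' @export
bundled_16s_reference <- function() {
  t <- marker_templates()
  build_reference(t$s16,
                  t$s16_taxonomy$taxonomy[match(names(t$s16),
                                                t$s16_taxonomy$genome_id)],
                  radius = 0.90)
}

#' Screen raw reads for candidate 16S fragments
#'
#' A permissive, recall-oriented identity screen against the reference
#' centroids (looser than the final classification, standing in for a
#' database E-value screen, which would depend on database size).
#'
#' @param readset A [sample_readset()] or character vector of reads.
#' @param reference A `reference_16s`.
#' @param screen_min_identity Minimum percent identity, default 70.
#' @param screen_min_len Minimum alignment length, default 40.
#' @return Integer indices of candidate reads.
#' @export
detect_candidates <- function(readset, reference,
                              screen_min_identity = 70,
                              screen_min_len = 40) {
  if (!nrow(reference)) stop("empty reference")
  reads <- if (inherits(readset, "sample_readset")) readset$reads
           else as.character(readset)
  if (!length(reads)) return(integer())
  h <- cpp_recruit(reads, reference$sequence, screen_min_identity,
                   as.integer(screen_min_len), 10L, 1L)
  sort(unique(h$read))
}

#' Positional log-odds profiles per domain
#'
#' Per-domain 4 x W matrices of `log2(freq / 0.25)` with a 0.5
#' pseudocount, built from the (gap-free, equal-length) reference
#' sequences of each domain.
#'
#' @param reference A `reference_16s`.
#' @return Named list of matrices (rows A, C, G, T).
#' @export
build_domain_profiles <- function(reference) {
  dom <- vapply(strsplit(reference$taxonomy, ";", fixed = TRUE),
                `[`, "", 1L)
  out <- list()
  for (d in unique(dom)) {
    seqs <- reference$sequence[dom == d]
    W <- unique(nchar(seqs))
    if (length(W) != 1L)
      stop("domain '", d, "' sequences are not equal length; ",
           "profiles need a gap-free alignment")
    m <- do.call(rbind, strsplit(seqs, ""))
    pwm <- vapply(seq_len(W), function(j) {
      cnt <- c(A = sum(m[, j] == "A"), C = sum(m[, j] == "C"),
               G = sum(m[, j] == "G"), `T` = sum(m[, j] == "T"))
      p <- (cnt + 0.5) / (sum(cnt) + 2)
      log2(p / 0.25)
    }, numeric(4))
    rownames(pwm) <- c("A", "C", "G", "T")
    out[[d]] <- pwm
  }
  out
}

#' Calibrate the profile-verification cutoff
#'
#' Scores mononucleotide shuffles of the candidate reads against every
#' domain profile and returns the 99.5th percentile of the null best
#' scores, so that about 0.5% of composition-matched non-16S reads
#' would pass verification.
#'
#' @param reads Candidate reads (character).
#' @param profiles Output of [build_domain_profiles()].
#' @param seed Seed for the shuffles.
#' @param n_null Number of shuffled reads scored (recycled over the
#'   candidates).
#' @return Numeric cutoff (mean per-base log-odds).
#' @export
calibrate_profile_cutoff <- function(reads, profiles, seed = 1,
                                     n_null = 1000) {
  set.seed(seed)
  idx <- rep_len(seq_along(reads), n_null)
  shuf <- vapply(reads[idx], function(r) {
    paste(sample(strsplit(r, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
  null_best <- do.call(pmax, c(lapply(profiles, function(p)
    cpp_pwm_best(shuf, p)), list(na.rm = TRUE)))
  unname(quantile(null_best, 0.995, na.rm = TRUE, names = FALSE))
}

#' Verify candidate 16S fragments against domain profiles
#'
#' A candidate is kept iff its best ungapped placement along some
#' domain profile reaches the cutoff; the domain is the argmax.  Reads
#' shorter than `min_len` or longer than the profile are rejected.
#'
#' @param reads Character vector of candidate reads.
#' @param profiles Output of [build_domain_profiles()].
#' @param cutoff Score cutoff; when `NULL`, calibrated from shuffles of
#'   the candidates via [calibrate_profile_cutoff()].
#' @param min_len Minimal candidate length, default 40.
#' @param seed Seed for the calibration shuffles.
#' @return Data frame `read` (index into `reads`), `domain`, `score`
#'   for the verified reads.
#' @export
verify_candidates <- function(reads, profiles, cutoff = NULL,
                              min_len = 40, seed = 1) {
  if (!length(reads))
    return(data.frame(read = integer(), domain = character(),
                      score = numeric()))
  if (is.null(cutoff))
    cutoff <- calibrate_profile_cutoff(reads, profiles, seed = seed)
  scores <- vapply(profiles, function(p) cpp_pwm_best(reads, p),
                   numeric(length(reads)))
  scores <- matrix(scores, nrow = length(reads),
                   dimnames = list(NULL, names(profiles)))
  best <- apply(scores, 1, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  keep <- !is.na(best) & best >= cutoff & nchar(reads) >= min_len
  dom <- apply(scores, 1, function(x) {
    if (all(is.na(x))) NA_character_
    else colnames(scores)[which.max(x)]
  })
  data.frame(read = which(keep), domain = dom[keep],
             score = best[keep], stringsAsFactors = FALSE)
}

#' Classify verified 16S fragments
#'
#' Best-identity centroid assignment: a fragment takes the full lineage
#' of its best centroid iff identity >= `min_identity` and alignment
#' length >= `min_len`; fragments failing either threshold are
#' discarded.
#'
#' @param reads Character vector of verified fragments.
#' @param reference A `reference_16s`.
#' @param min_identity Default 80 (percent, inclusive).
#' @param min_len Default 90 bp (inclusive).
#' @return Data frame `read` (index), `taxonomy`, `identity`,
#'   `aln_len`; unclassified reads are absent.
#' @export
classify_fragment <- function(reads, reference, min_identity = 80,
                              min_len = 90) {
  if (!length(reads))
    return(data.frame(read = integer(), taxonomy = character(),
                      identity = numeric(), aln_len = integer()))
  h <- cpp_recruit(reads, reference$sequence, min_identity,
                   as.integer(min_len), 10L, 1L)
  data.frame(read = h$read, taxonomy = reference$taxonomy[h$subject],
             identity = h$identity, aln_len = h$aln_len,
             stringsAsFactors = FALSE)
}

#' Run the full 16S cascade on one read set
#'
#' Detection screen, profile verification, final classification.
#'
#' @param readset A [sample_readset()] or character vector.
#' @param reference A `reference_16s`.
#' @param profiles Domain profiles; built from the reference when
#'   omitted.
#' @param cutoff Verification cutoff; `NULL` = shuffle-calibrated.
#' @param seed Seed for the calibration shuffles (and the subsample).
#' @param subsample Screen only a seeded random subset of this many
#'   reads (`Inf` = all; reported read indices always refer to the
#'   full input).
#' @return Data frame `read` (index into the read set), `domain`,
#'   `taxonomy` for every classified fragment.
#' @export
profile_16s <- function(readset, reference = bundled_16s_reference(),
                        profiles = NULL, cutoff = NULL, seed = 1,
                        subsample = Inf) {
  reads <- if (inherits(readset, "sample_readset")) readset$reads
           else as.character(readset)
  keep <- seq_along(reads)
  if (is.finite(subsample) && subsample < length(reads)) {
    set.seed(seed)
    keep <- sort(sample.int(length(reads), subsample))
    reads <- reads[keep]
  }
  if (is.null(profiles)) profiles <- build_domain_profiles(reference)
  cand <- detect_candidates(reads, reference)
  ver <- verify_candidates(reads[cand], profiles, cutoff = cutoff,
                           seed = seed)
  ver$read <- cand[ver$read]
  cls <- classify_fragment(reads[ver$read], reference)
  data.frame(read = keep[ver$read[cls$read]],
             domain = ver$domain[cls$read],
             taxonomy = cls$taxonomy, stringsAsFactors = FALSE)
}

cut_rank <- function(lineages, rank, split_proteobacteria = TRUE) {
  ri <- match(rank, RANKS)
  if (is.na(ri)) stop("unknown rank '", rank, "'")
  parts <- strsplit(lineages, ";", fixed = TRUE)
  vapply(parts, function(p) {
    lab <- if (length(p) >= ri) p[ri] else p[length(p)]
    if (split_proteobacteria && rank == "phylum" &&
        !is.na(lab) && lab == "Proteobacteria" && length(p) >= 3)
      lab <- p[3]
    lab
  }, "")
}

#' Taxon relative-abundance table across samples
#'
#' Percentages of classified 16S fragments per sample, cut at the
#' requested rank (Proteobacteria reported at class level when
#' `rank = "phylum"`, mirroring the usual convention).  Columns sum to
#' 100 over the full table; the display table keeps taxa reaching
#' `min_percent` in at least one sample and folds the rest into
#' `"other"`.
#'
#' @param classified Named list (one element per sample) of lineage
#'   strings as returned by [profile_16s()]`$taxonomy`.
#' @param rank One of domain, phylum, class, genus, species.
#' @param min_percent Display threshold, default 1.
#' @param split_proteobacteria Report Proteobacteria at class rank.
#' @return List with `percent` (full taxa x samples matrix) and
#'   `display` (filtered, with an `other` row).
#' @export
abundance_table <- function(classified, rank = "phylum",
                            min_percent = 1,
                            split_proteobacteria = TRUE) {
  if (!length(classified)) stop("no samples")
  labs <- lapply(classified, cut_rank, rank = rank,
                 split_proteobacteria = split_proteobacteria)
  taxa <- sort(unique(unlist(labs)))
  pct <- vapply(labs, function(x) {
    if (!length(x)) return(rep(NA_real_, length(taxa)))
    100 * as.vector(table(factor(x, levels = taxa))) / length(x)
  }, numeric(length(taxa)))
  pct <- matrix(pct, nrow = length(taxa),
                dimnames = list(taxa, names(classified)))
  if (anyNA(pct[1, ]))
    warning("sample(s) without classified fragments: ",
            paste(colnames(pct)[is.na(pct[1, ])], collapse = ", "))
  keep <- apply(pct, 1, function(x) any(x >= min_percent, na.rm = TRUE))
  disp <- pct[keep, , drop = FALSE]
  if (any(!keep))
    disp <- rbind(disp, other = colSums(pct[!keep, , drop = FALSE]))
  list(percent = pct, display = disp)
}

#' Gini-Simpson diversity
#'
#' `D = 1 - sum(p_i^2)`: the probability that two randomly drawn
#' individuals belong to different taxa; bounded in [0, 1).
#'
#' @param p Vector of proportions summing to 1 (or counts, normalised
#'   when `counts = TRUE`).
#' @param counts Treat `p` as counts.
#' @return Diversity value.
#' @export
simpson_diversity <- function(p, counts = FALSE) {
  if (any(p < 0)) stop("negative proportion")
  if (counts) p <- p / sum(p)
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  1 - sum(p^2)
}
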