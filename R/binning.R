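# Composition-based contig binning: taxonomy majority rule,
# canonical tetranucleotide frequencies, PCA projection with GC and
# coverage axes, taxonomy-stratified density clustering, and
# single-copy-marker completeness/contamination.

#' Canonical tetranucleotide frequencies
#'
#' Sliding 4-mers (step 1); windows containing N are skipped; each
#' 4-mer is pooled with its reverse complement into one of 136
#' canonical keys; frequencies are normalised to sum to 1.
#'
#' @param sequence DNA string (or character vector; one row each).
#' @return Named 136-vector (or matrix) of frequencies.
#' @export
tnf <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  m <- cpp_tnf(sequence)
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("no valid 4-mer in sequence(s) ",
         paste(which(tot == 0), collapse = ", "))
  if (length(sequence) == 1L) m[1, ] else m
}

#' Majority-rule contig taxonomy
#'
#' A contig of at least `min_len` (default 10 kb) takes the taxon
#' shared by strictly more than half of its annotated genes; anything
#' else (short contigs, no genes, no strict majority) is
#' `"unclassified"`.
#'
#' @param gene_taxa Character vector of per-gene taxon labels (`NA`
#'   allowed, counted as non-agreeing).
#' @param contig_length Contig length in bp.
#' @param min_len Length gate, default 10000.
#' @return Taxon label or `"unclassified"`.
#' @export
contig_taxonomy <- function(gene_taxa, contig_length, min_len = 10000) {
  if (contig_length < min_len || !length(gene_taxa)) return("unclassified")
  tab <- table(gene_taxa[!is.na(gene_taxa)])
  if (!length(tab)) return("unclassified")
  top <- which.max(tab)
  if (tab[top] > length(gene_taxa) / 2) names(tab)[top] else "unclassified"
}

#' Assemble the per-contig feature table
#'
#' @param contigs List of [genome_record()]s (contigs), length >= 1 kb
#'   each to be featurised; shorter contigs are dropped with a warning.
#' @param gene_taxa Optional named list mapping contig id to per-gene
#'   taxon labels (for the majority rule).
#' @param coverage Optional contigs x samples matrix of mean per-base
#'   depth.
#' @return List with `ids`, `length`, `gc`, `tnf` (matrix), `taxon`,
#'   `coverage`.
#' @export
contig_features <- function(contigs, gene_taxa = NULL, coverage = NULL) {
  lens <- vapply(contigs, genome_length, numeric(1))
  keep <- lens >= 1000
  if (any(!keep)) {
    warning(sum(!keep), " contig(s) < 1 kb dropped")
    contigs <- contigs[keep]
    lens <- lens[keep]
  }
  ids <- vapply(contigs, `[[`, "", "id")
  seqs <- vapply(contigs, `[[`, "", "sequence")
  tn <- cpp_tnf(seqs)
  rownames(tn) <- ids
  gc <- vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE)
  taxon <- vapply(seq_along(ids), function(i) {
    gt <- if (!is.null(gene_taxa)) gene_taxa[[ids[i]]] else character()
    contig_taxonomy(gt, lens[i])
  }, "")
  if (!is.null(coverage)) {
    coverage <- as.matrix(coverage)[ids, , drop = FALSE]
  }
  list(ids = ids, length = unname(lens), gc = gc, tnf = tn,
       taxon = taxon, coverage = coverage)
}

#' Project contig features for binning
#'
#' The TNF matrix is centred and scaled per dimension (constant
#' dimensions dropped with a warning) and projected onto the top
#' principal components; GC and `log10(coverage + 0.1)` are appended
#' as extra standardised axes.  Component signs are fixed so the
#' largest-magnitude loading is positive.
#'
#' @param features Output of [contig_features()].
#' @param n_components Number of TNF principal components, default 2.
#' @return Matrix contigs x (components + extra axes).
#' @export
project_features <- function(features, n_components = 2) {
  x <- features$tnf
  if (nrow(x) < 3) stop("need at least 3 contigs")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant TNF dimension(s) dropped")
    x <- x[, sds > 0, drop = FALSE]
  }
  if (n_components > min(dim(x)) - 1)
    stop("n_components exceeds the rank of the feature matrix")
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  coords <- sweep(p$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  colnames(coords) <- paste0("PC", seq_len(n_components))
  std <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
  coords <- cbind(coords, GC = std(features$gc))
  if (!is.null(features$coverage)) {
    cv <- log10(features$coverage + 0.1)
    cv <- apply(cv, 2, std)
    colnames(cv) <- paste0("cov_", seq_len(ncol(cv)))
    coords <- cbind(coords, cv)
  }
  rownames(coords) <- features$ids
  coords
}

# Plain O(n^2) DBSCAN; labels 0 = noise.
dbscan_simple <- function(x, eps, min_pts) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  labels <- rep(0L, n)
  visited <- rep(FALSE, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    nb <- which(d[i, ] <= eps)
    if (length(nb) < min_pts) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (!visited[j]) {
        visited[j] <- TRUE
        nb2 <- which(d[j, ] <= eps)
        if (length(nb2) >= min_pts) queue <- c(queue, setdiff(nb2, j))
      }
      if (labels[j] == 0L) labels[j] <- cl
    }
  }
  labels
}

#' Bin contigs by density clustering within taxon groups
#'
#' Within each taxon group (the unclassified group is treated as its
#' own), contigs are clustered by DBSCAN in the projected feature
#' space; noise points stay unbinned.  When `eps` is `NULL` it is set
#' per group to twice the median distance to the `min_pts`-th nearest
#' neighbour (a standard k-distance heuristic).
#'
#' @param coords Projection from [project_features()].
#' @param taxon_labels Per-contig taxon labels (same order).
#' @param eps DBSCAN radius; `NULL` = per-group heuristic.
#' @param min_pts DBSCAN core-point threshold, default 4.
#' @return Data frame `contig_id`, `taxon`, `bin` (`NA` = unbinned);
#'   bin ids are `<taxon>_bin<k>`.
#' @export
bin_contigs <- function(coords, taxon_labels, eps = NULL, min_pts = 4) {
  stopifnot(nrow(coords) == length(taxon_labels))
  out <- data.frame(contig_id = rownames(coords), taxon = taxon_labels,
                    bin = NA_character_, stringsAsFactors = FALSE)
  for (tx in unique(taxon_labels)) {
    sel <- which(taxon_labels == tx)
    if (length(sel) < min_pts) next
    x <- coords[sel, , drop = FALSE]
    e <- eps
    if (is.null(e)) {
      d <- as.matrix(dist(x))
      kd <- apply(d, 1, function(r) sort(r)[min(min_pts + 1L, length(r))])
      e <- 2 * stats::median(kd)
      if (e == 0) e <- 1e-9
    }
    lab <- dbscan_simple(x, e, min_pts)
    ok <- lab > 0L
    out$bin[sel[ok]] <- sprintf("%s_bin%d", tx, lab[ok])
  }
  out
}

#' Universal single-copy marker catalogue
#'
#' Role labels for the two marker sets used for completeness
#' estimation (35 or 111 markers); the simulator emits the same
#' labels.
#'
#' @param n 35 or 111.
#' @return Character vector of marker names.
#' @export
usc_catalog <- function(n = 35) {
  if (!n %in% c(35L, 111L)) stop("marker catalogue size must be 35 or 111")
  sprintf("USC%03d", seq_len(n))
}

#' Completeness and contamination of a bin
#'
#' Completeness is the percentage of catalogue markers present at
#' least once; contamination is extra copies beyond the first, summed,
#' as a percentage of the catalogue size (a simplified duplicated-
#' marker estimator).
#'
#' @param marker_labels Character vector of marker genes observed in
#'   the bin (one entry per gene copy; labels outside the catalogue
#'   are ignored).
#' @param catalog Marker catalogue, see [usc_catalog()].
#' @return Named vector `c(completeness, contamination)` in percent.
#' @export
completeness_contamination <- function(marker_labels, catalog) {
  if (!length(catalog)) stop("empty marker catalogue")
  m <- marker_labels[marker_labels %in% catalog]
  tab <- table(m)
  comp <- 100 * length(tab) / length(catalog)
  cont <- 100 * sum(pmax(tab - 1L, 0L)) / length(catalog)
  c(completeness = comp, contamination = cont)
}

#' Per-bin summary with completeness/contamination
#'
#' @param assignment Output of [bin_contigs()].
#' @param features Output of [contig_features()].
#' @param marker_genes Named list mapping contig id to the marker
#'   labels on it.
#' @param catalog Marker catalogue.
#' @return Data frame, one row per bin: `bin`, `n_contigs`,
#'   `total_bp`, `mean_gc`, `completeness`, `contamination`.
#' @export
bin_summary <- function(assignment, features, marker_genes = list(),
                        catalog = usc_catalog(35)) {
  bins <- unique(assignment$bin[!is.na(assignment$bin)])
  rows <- lapply(bins, function(b) {
    cs <- assignment$contig_id[!is.na(assignment$bin) & assignment$bin == b]
    idx <- match(cs, features$ids)
    mk <- unlist(marker_genes[cs], use.names = FALSE)
    cc <- completeness_contamination(mk %||% character(), catalog)
    data.frame(bin = b, n_contigs = length(cs),
               total_bp = sum(features$length[idx]),
               mean_gc = mean(features$gc[idx]),
               completeness = cc[["completeness"]],
               contamination = cc[["contamination"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cut a genome into fixed-width windows (synthetic contigs)
#'
#' @param genome A [genome_record()].
#' @param width Window width in bp, default 20 kb (trailing remainder
#'   dropped when shorter than `min_tail`).
#' @param min_tail Smallest trailing window kept, default `width / 2`.
#' @return List of contig `genome_record`s, ids `<genome>_w<k>`.
#' @export
cut_windows <- function(genome, width = 20000, min_tail = width / 2) {
  n <- nchar(genome$sequence)
  starts <- seq(1L, n, by = width)
  out <- list()
  for (i in seq_along(starts)) {
    e <- min(starts[i] + width - 1L, n)
    if (e - starts[i] + 1L < min_tail) break
    out[[length(out) + 1L]] <- genome_record(
      sprintf("%s_w%02d", genome$id, i),
      substring(genome$sequence, starts[i], e),
      taxonomy = genome$taxonomy)
  }
  out
}
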