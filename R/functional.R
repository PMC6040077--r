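# Glycoside-hydrolase rate statistics per taxon and sample group, and
# z-scored functional-category matrices for heatmaps.

#' Default depth grouping of samples
#'
#' Upper photic (UP) = 15 and 30 m, deep chlorophyll maximum (DCM) =
#' 45 and 60 m, lower photic (LP) = 75 and 90 m for stratified
#' samples; all mixed samples = MIX.
#'
#' @param depth_m Numeric vector of depths.
#' @param season Character vector (`stratified`/`mixed`).
#' @return Character vector of group labels.
#' @export
depth_group <- function(depth_m, season) {
  ifelse(season == "mixed", "MIX",
         ifelse(depth_m <= 30, "UP",
                ifelse(depth_m <= 60, "DCM", "LP")))
}

#' GH rate per 1000 genes (EQ)
#'
#' @param gh_gene_count Number of glycoside-hydrolase genes.
#' @param n_genes Total genes analysed (> 0).
#' @return `1000 * gh_gene_count / n_genes`.
#' @export
gh_rate <- function(gh_gene_count, n_genes) {
  if (any(n_genes <= 0)) stop("n_genes must be > 0")
  1000 * gh_gene_count / n_genes
}

#' Community-weighted GH rate (NORM)
#'
#' The EQ rate weighted by the taxon's share of the community as
#' measured by its 16S fragment percentage:
#' `NORM = EQ * taxon_16s_percent / 100`.  Multiplication (community
#' weighting) is used so that NORM reads as the taxon's contribution
#' to community-level GH capacity; see the methods vignette for the
#' discussion, and use `mode = "divide"` for the per-capita variant.
#'
#' @param eq EQ value(s).
#' @param taxon_16s_percent Percentage in [0, 100].
#' @param mode `"multiply"` (default) or `"divide"`.
#' @return NORM value(s).
#' @export
gh_norm <- function(eq, taxon_16s_percent, mode = c("multiply", "divide")) {
  mode <- match.arg(mode)
  if (any(taxon_16s_percent < 0 | taxon_16s_percent > 100))
    stop("taxon_16s_percent must be in [0, 100]")
  if (mode == "multiply") eq * taxon_16s_percent / 100
  else eq / (taxon_16s_percent / 100)
}

#' Cross-tabulate GH family counts by taxon and sample group
#'
#' Counts GH-annotated genes on taxonomically classified contigs of at
#' least `min_contig_len` (default 5 kb); shorter contigs are
#' excluded.  Taxa outside `taxa` (when given) are bucketed as
#' `"other"` with a warning.
#'
#' @param genes Data frame with columns `contig_id`, `contig_length`,
#'   `taxon`, `sample_group`, `role`, `family`.
#' @param taxa Optional vector of recognised taxa.
#' @param min_contig_len Contig length gate.
#' @return 3-d array taxon x group x family of counts, plus the gene
#'   totals per taxon/group as `attr(, "n_genes")`.
#' @export
gh_family_matrix <- function(genes, taxa = NULL, min_contig_len = 5000) {
  need <- c("contig_id", "contig_length", "taxon", "sample_group",
            "role", "family")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table misses column(s): ",
                         paste(miss, collapse = ", "))
  g <- genes[genes$contig_length >= min_contig_len, , drop = FALSE]
  if (!is.null(taxa)) {
    unknown <- !(g$taxon %in% taxa)
    if (any(unknown)) {
      warning(sum(unknown), " gene(s) with unknown taxon bucketed as 'other'")
      g$taxon[unknown] <- "other"
    }
  }
  gh <- g[g$role == "GH" & !is.na(g$family), , drop = FALSE]
  taxa_lv <- sort(unique(g$taxon))
  grp_lv <- sort(unique(g$sample_group))
  fam_lv <- sort(unique(gh$family))
  arr <- array(0L, dim = c(length(taxa_lv), length(grp_lv),
                           length(fam_lv)),
               dimnames = list(taxa_lv, grp_lv, fam_lv))
  if (nrow(gh)) {
    tab <- table(factor(gh$taxon, taxa_lv), factor(gh$sample_group, grp_lv),
                 factor(gh$family, fam_lv))
    arr[] <- as.integer(tab)
  }
  ntab <- table(factor(g$taxon, taxa_lv), factor(g$sample_group, grp_lv))
  attr(arr, "n_genes") <- unclass(ntab)
  arr
}

#' EQ and NORM per taxon and sample group
#'
#' @param fam Output of [gh_family_matrix()].
#' @param taxon_16s_percent Optional taxon x group matrix of 16S
#'   percentages for NORM.
#' @param mode Passed to [gh_norm()].
#' @return Data frame `taxon`, `sample_group`, `gh_count`, `n_genes`,
#'   `eq`, and `norm` when percentages are given.
#' @export
gh_profile <- function(fam, taxon_16s_percent = NULL,
                       mode = "multiply") {
  n <- attr(fam, "n_genes")
  gh <- apply(fam, c(1, 2), sum)
  out <- expand.grid(taxon = rownames(gh), sample_group = colnames(gh),
                     stringsAsFactors = FALSE)
  out$gh_count <- gh[cbind(out$taxon, out$sample_group)]
  out$n_genes <- n[cbind(out$taxon, out$sample_group)]
  keep <- out$n_genes > 0
  out <- out[keep, , drop = FALSE]
  out$eq <- gh_rate(out$gh_count, out$n_genes)
  if (!is.null(taxon_16s_percent)) {
    p <- taxon_16s_percent[cbind(out$taxon, out$sample_group)]
    out$norm <- gh_norm(out$eq, p, mode = mode)
  }
  rownames(out) <- NULL
  out
}

#' Row-wise z-scores of a category matrix
#'
#' Per row: `(x - mean) / sd` with the n-1 sd; rows with zero variance
#' become `NA` and are flagged.
#'
#' @param m Numeric matrix with at least two columns.
#' @return List with `z` (matrix) and `flat_rows` (names/indices of
#'   zero-variance rows).
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least two columns to z-score")
  sds <- apply(m, 1, sd)
  z <- (m - rowMeans(m)) / sds
  z[sds == 0, ] <- NA_real_
  flat <- if (is.null(rownames(m))) which(sds == 0) else
    rownames(m)[sds == 0]
  list(z = z, flat_rows = flat)
}
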