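# Whole-metagenome similarity by reciprocal read matching and
# hierarchical clustering of the resulting similarity matrix.

#' Reciprocal read similarity between two samples
#'
#' Fraction of (subsampled) reads of A with an end-to-end match of at
#' least `min_identity` percent to some read of B, and vice versa.
#' Identity is matches over the full alignment span including end
#' gaps, maximised over candidate partners and strands.  Reads shorter
#' than `min_len` are excluded before subsampling; subsampling is
#' seeded.
#'
#' @param readset_a,readset_b [sample_readset()]s or character vectors.
#' @param subset_size Reads drawn per sample (all available, with a
#'   warning, when fewer exist).
#' @param min_len Minimum read length, default 50.
#' @param min_identity Percent identity threshold, default 95.
#' @param seed Subsampling seed.
#' @return List with `s_ab`, `s_ba` and `mean`.
#' @export
reciprocal_similarity <- function(readset_a, readset_b,
                                  subset_size = 2e6, min_len = 50,
                                  min_identity = 95.0, seed = 1) {
  get_reads <- function(x) {
    r <- if (inherits(x, "sample_readset")) x$reads else as.character(x)
    r[nchar(r) >= min_len]
  }
  a <- get_reads(readset_a)
  b <- get_reads(readset_b)
  if (!length(a) || !length(b)) stop("empty read set after length filter")
  set.seed(seed)
  pick <- function(r) {
    if (length(r) > subset_size) r[sample.int(length(r), subset_size)]
    else {
      if (length(r) < subset_size)
        warning("subset larger than available reads; using all ",
                length(r), call. = FALSE)
      r
    }
  }
  a <- pick(a); b <- pick(b)
  s_ab <- mean(cpp_read_best_global(a, b, 16L, 4L, min_identity) >=
                 min_identity)
  s_ba <- mean(cpp_read_best_global(b, a, 16L, 4L, min_identity) >=
                 min_identity)
  list(s_ab = s_ab, s_ba = s_ba, mean = (s_ab + s_ba) / 2)
}

#' Pairwise similarity matrix over samples
#'
#' @param samples List of [sample_readset()]s.
#' @param ... Passed to [reciprocal_similarity()].
#' @return Symmetric samples x samples matrix of mean reciprocal
#'   similarities (diagonal from self-comparison).
#' @export
similarity_matrix <- function(samples, ...) {
  n <- length(samples)
  ids <- vapply(samples, `[[`, "", "sample_id")
  s <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      m <- reciprocal_similarity(samples[[i]], samples[[j]], ...)$mean
      s[i, j] <- s[j, i] <- m
    }
  }
  s
}

#' Cluster samples from a similarity matrix
#'
#' Agglomerative clustering (complete linkage by default) on euclidean
#' distances between the rows of the similarity matrix; deterministic;
#' the tree is returned as a newick string with branch lengths.
#'
#' @param s Square symmetric similarity matrix with dimnames.
#' @param method `hclust` linkage, default `"complete"`.
#' @return List with `hclust` (the tree) and `newick`.
#' @export
cluster_samples <- function(s, method = "complete") {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) stop("similarity matrix must be square")
  if (max(abs(s - t(s))) > 1e-8) stop("similarity matrix must be symmetric")
  hc <- hclust(dist(s), method = method)
  phy <- ape::as.phylo(hc)
  list(hclust = hc, newick = ape::write.tree(phy))
}
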