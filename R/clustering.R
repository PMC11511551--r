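#' Binary band matrix from co-dominant genotypes
#'
#' Converts fragment-size genotypes into the presence/absence band matrix of
#' a fingerprint gel: one column per distinct (locus, allele size) band,
#' entry 1 iff the sample carries that allele (a heterozygote lights two
#' bands at the locus, a homozygote one). A missing call leaves that
#' sample's entries for the locus `NA`.
#'
#' @param g A [genotype_matrix()].
#' @return A matrix of class `band_matrix` (samples x bands, values 0/1/NA);
#'   column names `locus:size`, attribute `locus` giving each column's
#'   locus.
#' @export
bands_from_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  cols <- list()
  for (l in g$loci$name) {
    sizes <- sort(unique(stats::na.omit(c(g$a1[, l], g$a2[, l]))))
    for (sz in sizes) {
      v <- as.integer(g$a1[, l] == sz | g$a2[, l] == sz)
      cols[[paste0(l, ":", sz)]] <- v
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- g$samples
  attr(m, "locus") <- sub(":[^:]*$", "", colnames(m))
  class(m) <- c("band_matrix", class(m))
  m
}

#' Simple-matching similarity of two binary band vectors
#'
#' `(a + d) / (a + b + c + d)`: the fraction of positions where the two
#' vectors agree, counting shared absences as matches (the property that
#' distinguishes the simple-matching coefficient from Jaccard, and that
#' materially changes clustering results). Positions where either vector is
#' `NA` are excluded from both numerator and denominator.
#'
#' @param x,y Binary vectors of equal length (>= 1 comparable position).
#' @return Similarity in `[0, 1]`.
#' @examples
#' sm_coefficient(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 0.5
#' @export
sm_coefficient <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no comparable positions")
  mean(x[ok] == y[ok])
}

#' Pairwise simple-matching similarity matrix
#'
#' @param bands A [bands_from_genotypes()] matrix (or any 0/1 matrix with
#'   row names).
#' @return A symmetric matrix of class `sm_similarity` with unit diagonal.
#' @export
similarity_matrix <- function(bands) {
  n <- nrow(bands)
  s <- diag(1, n)
  dimnames(s) <- list(rownames(bands), rownames(bands))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        s[i, j] <- s[j, i] <- sm_coefficient(bands[i, ], bands[j, ])
      }
    }
  }
  class(s) <- c("sm_similarity", class(s))
  s
}

.check_similarity <- function(s) {
  s <- unclass(as.matrix(s))
  if (nrow(s) != ncol(s) || !isTRUE(all.equal(s, t(s), tolerance = 1e-8)))
    stop("similarity matrix must be square and symmetric")
  if (any(s < -1e-9 | s > 1 + 1e-9)) stop("similarities must lie in [0, 1]")
  if (is.null(rownames(s))) rownames(s) <- colnames(s) <-
      paste0("S", seq_len(nrow(s)))
  s
}

#' UPGMA clustering of a similarity matrix
#'
#' Agglomerative unweighted pair-group average clustering: internally the
#' similarity `S` is converted to distance `1 - S`, the closest pair of
#' clusters is fused, and the distance from the new cluster to the others
#' is the member-count-weighted arithmetic mean. Fusion levels are recorded
#' both as distances and on the similarity scale. Exact ties in minimal
#' distance are broken toward the pair with the smallest (row, column)
#' index after sorting labels lexicographically, making the tree
#' deterministic across platforms.
#'
#' @param similarity A symmetric similarity matrix in `[0, 1]` with unit
#'   diagonal (e.g. from [similarity_matrix()]); at least 2 samples.
#' @return An object of class `c("ssr_upgma", "hclust")` with the usual
#'   `merge`, `height` (distance scale), `order`, `labels` components plus
#'   `similarity` (fusion levels as `1 - height`). Works with
#'   `plot()`, `ape::as.phylo()` and other `hclust` consumers.
#' @export
upgma <- function(similarity) {
  s <- .check_similarity(similarity)
  n <- nrow(s)
  if (n < 2L) stop("need at least 2 samples")
  ord0 <- order(rownames(s))
  s <- s[ord0, ord0, drop = FALSE]
  labels <- rownames(s)
  d <- 1 - s

  id <- -seq_len(n)               # hclust convention: negative = leaf
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- nrow(d)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        if (d[i, j] < bestd - 1e-12) { bestd <- d[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bestd
    if (m == 2L) break
    # weighted average distance to the fused cluster
    wi <- size[i]; wj <- size[j]
    newd <- (wi * d[i, -c(i, j), drop = TRUE] +
             wj * d[j, -c(i, j), drop = TRUE]) / (wi + wj)
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd),
               c(newd, 0))
    size <- c(size[keep], wi + wj)
    id <- c(id[keep], step)
  }
  res <- structure(list(merge = merge, height = height,
                        order = .hclust_order(merge),
                        labels = labels, method = "upgma",
                        similarity = 1 - height,
                        call = match.call(),
                        dist.method = "1 - simple matching"),
                   class = c("ssr_upgma", "hclust"))
  res
}

# leaf ordering for plotting, by recursive left-to-right traversal
.hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' @export
print.ssr_upgma <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram of %d samples (simple-matching similarity)\n",
              length(x$labels)))
  cat(sprintf("fusion similarities: %s\n",
              paste(sprintf("%.4f", rev(x$similarity)), collapse = ", ")))
  invisible(x)
}

#' Cophenetic similarity matrix of a UPGMA tree
#'
#' The cophenetic similarity of two samples is the similarity level at
#' which they first join one cluster (1 minus the fusion distance).
#'
#' @param tree An [upgma()] result.
#' @return A symmetric matrix of cophenetic similarities, unit diagonal.
#' @export
cophenetic_similarity <- function(tree) {
  stopifnot(inherits(tree, "ssr_upgma"))
  n <- length(tree$labels)
  cm <- diag(1, n)
  dimnames(cm) <- list(tree$labels, tree$labels)
  members <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    grab <- function(node) if (node < 0) -node else members[[node]]
    a <- grab(tree$merge[step, 1]); b <- grab(tree$merge[step, 2])
    for (x in a) for (y in b)
      cm[x, y] <- cm[y, x] <- 1 - tree$height[step]
    members[[step]] <- c(a, b)
  }
  cm
}

#' Cophenetic correlation between a tree and its source matrix
#'
#' Pearson correlation between the upper-triangle entries of the tree's
#' cophenetic similarity matrix and the original similarity matrix: the
#' standard goodness-of-fit check for a UPGMA dendrogram (r = 1 for exactly
#' ultrametric input).
#'
#' @param tree An [upgma()] result.
#' @param similarity The similarity matrix the tree was built from.
#' @return Pearson r in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(tree, similarity) {
  s <- .check_similarity(similarity)
  if (length(tree$labels) < 3L)
    stop("cophenetic correlation undefined for < 3 leaves")
  if (!setequal(tree$labels, rownames(s)))
    stop("tree leaves and matrix labels differ")
  s <- s[tree$labels, tree$labels]
  cm <- cophenetic_similarity(tree)
  ut <- upper.tri(s)
  stats::cor(cm[ut], s[ut])
}

#' Write a dendrogram as Newick
#'
#' Converts the tree to `ape::phylo` (branch lengths derived from fusion
#' distances in the usual ultrametric way) and writes Newick text.
#'
#' @param tree An [upgma()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ph <- ape::as.phylo(tree)
  ape::write.tree(ph, file = path)
  invisible(path)
}
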