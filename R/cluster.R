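#' Band presence/absence matrix from genotypes
#'
#' Converts co-dominant allele-size calls to the dominant band scoring used
#' for genetic-similarity clustering: one column per (locus, allele) combination
#' observed anywhere in the panel, cell 1 iff the individual carries that
#' allele. Columns belonging to a locus where an individual has a missing
#' call are flagged in a mask so they can be excluded pairwise.
#'
#' @param gm A [genotype_matrix()].
#' @return A list of class `band_matrix`: `bands` (0/1 matrix, individuals x
#'   bands), `observed` (logical mask, `TRUE` where the underlying call is
#'   non-missing) and `columns` (`data.frame` of `locus`, `allele`).
#' @export
band_matrix <- function(gm) {
  cols <- do.call(rbind, lapply(seq_along(gm$loci), function(j) {
    alleles <- sort(unique(c(gm$allele1[, j], gm$allele2[, j])))
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) return(NULL)
    data.frame(locus = gm$loci[j], allele = alleles, j = j)
  }))
  n <- length(gm$individuals)
  if (is.null(cols)) {
    return(structure(list(bands = matrix(0L, n, 0,
                                         dimnames = list(gm$individuals, NULL)),
                          observed = matrix(TRUE, n, 0),
                          columns = data.frame(locus = character(0),
                                               allele = integer(0))),
                     class = "band_matrix"))
  }
  bands <- matrix(0L, n, nrow(cols),
                  dimnames = list(gm$individuals,
                                  paste(cols$locus, cols$allele, sep = ":")))
  observed <- matrix(TRUE, n, nrow(cols), dimnames = dimnames(bands))
  for (c_i in seq_len(nrow(cols))) {
    j <- cols$j[c_i]
    a <- cols$allele[c_i]
    miss <- is.na(gm$allele1[, j])
    bands[, c_i] <- as.integer(!miss & (gm$allele1[, j] == a | gm$allele2[, j] == a))
    observed[miss, c_i] <- FALSE
  }
  structure(list(bands = bands, observed = observed,
                 columns = cols[, c("locus", "allele")]),
            class = "band_matrix")
}

similarity_methods <- c("simple_matching", "dice", "jaccard")

similarity_pair <- function(a, b, mask_a, mask_b, method) {
  use <- mask_a & mask_b
  if (!any(use)) stopf("no mutually observed bands between the two individuals")
  a <- a[use]; b <- b[use]
  m11 <- sum(a == 1L & b == 1L)
  m00 <- sum(a == 0L & b == 0L)
  m10 <- sum(a == 1L & b == 0L)
  m01 <- sum(a == 0L & b == 1L)
  switch(method,
         simple_matching = (m11 + m00) / (m11 + m00 + m10 + m01),
         dice = if (2 * m11 + m10 + m01 == 0) 1 else 2 * m11 / (2 * m11 + m10 + m01),
         jaccard = if (m11 + m10 + m01 == 0) 1 else m11 / (m11 + m10 + m01))
}

#' Genetic similarity coefficients between individuals
#'
#' Pairwise genetic similarity coefficients (GSC) over the mutually observed
#' band columns of a [band_matrix()] (missing loci are deleted pairwise).
#' `simple_matching` (the default, the common choice for dominant band data)
#' counts shared presences and shared absences; `dice` and `jaccard` ignore
#' shared absences.
#'
#' @param x A [band_matrix()] or a [genotype_matrix()] (converted
#'   internally).
#' @param method One of `"simple_matching"`, `"dice"`, `"jaccard"`.
#' @return A symmetric matrix of class `similarity_matrix`, unit diagonal,
#'   entries in `[0, 1]`, dimnames = individual ids.
#' @export
similarity_matrix <- function(x, method = similarity_methods) {
  method <- match.arg(method)
  if (inherits(x, "genotype_matrix")) x <- band_matrix(x)
  stopifnot(inherits(x, "band_matrix"))
  ids <- rownames(x$bands)
  n <- length(ids)
  s <- diag(1, n)
  dimnames(s) <- list(ids, ids)
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    s[i, j] <- s[j, i] <- similarity_pair(x$bands[i, ], x$bands[j, ],
                                          x$observed[i, ], x$observed[j, ],
                                          method)
  }
  structure(s, class = c("similarity_matrix", "matrix"))
}

#' UPGMA dendrogram from a similarity matrix
#'
#' Converts similarities to distances `d = 1 - GSC` and agglomerates with
#' unweighted pair-group average linkage: at each step the closest pair of
#' clusters is merged at height `d/2`, and the distance from the merged
#' cluster to any other is the size-weighted average of its members'
#' distances. Ties are broken deterministically by the lexicographically
#' smallest (smallest-member-id, smallest-member-id) pair, so identical
#' inputs always produce the identical tree. The result is ultrametric:
#' merge heights never decrease.
#'
#' @param sim A [similarity_matrix()] (or any symmetric similarity matrix
#'   with dimnames), entries in `[0, 1]`.
#' @return A list of class `upgma_dendrogram` with hclust-compatible fields
#'   `merge`, `height`, `order`, `labels` (heights are on the `d/2` scale).
#' @export
upgma <- function(sim) {
  s <- unclass(sim)
  if (!is.matrix(s) || nrow(s) != ncol(s) || !isTRUE(all.equal(s, t(s), tolerance = 1e-10)))
    stopf("similarity matrix must be square and symmetric")
  n <- nrow(s)
  if (n < 2L) stopf("need at least 2 individuals")
  labels <- rownames(s) %||% as.character(seq_len(n))
  d <- 1 - s
  # active cluster bookkeeping
  active <- seq_len(n)
  sizes <- rep(1L, n)
  members <- as.list(seq_len(n))          # leaf indices per cluster
  ids <- lapply(seq_len(n), function(i) labels[i])  # smallest member label
  node_of <- -seq_len(n)                  # hclust merge coding
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  dd <- d
  min_label <- labels
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (ii in 1:(k - 1L)) for (jj in (ii + 1L):k) {
      a <- active[ii]; b <- active[jj]
      dist_ab <- dd[a, b]
      la <- min_label[a]; lb <- min_label[b]
      key <- if (la <= lb) c(la, lb) else c(lb, la)
      if (is.null(best) || dist_ab < best$d - 1e-12 ||
          (abs(dist_ab - best$d) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(d = dist_ab, i = a, j = b, key = key)
      }
    }
    a <- best$i; b <- best$j
    # child with the lexicographically smaller member id first
    merge[step, ] <- if (min_label[a] <= min_label[b])
      c(node_of[a], node_of[b]) else c(node_of[b], node_of[a])
    height[step] <- best$d / 2
    # size-weighted average distance to every other active cluster
    for (c_ in setdiff(active, c(a, b))) {
      dac <- (sizes[a] * dd[a, c_] + sizes[b] * dd[b, c_]) / (sizes[a] + sizes[b])
      dd[a, c_] <- dd[c_, a] <- dac
    }
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- c(members[[a]], members[[b]])
    min_label[a] <- min(min_label[a], min_label[b])
    node_of[a] <- step
    active <- setdiff(active, b)
  }
  structure(list(merge = merge, height = height,
                 order = members[[active]], labels = labels,
                 method = "upgma"),
            class = "upgma_dendrogram")
}

#' @export
print.upgma_dendrogram <- function(x, ...) {
  cat(sprintf("<upgma_dendrogram: %d leaves, root height %.4f>\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Coerce a UPGMA dendrogram to an hclust object
#'
#' @param x A [upgma()] dendrogram.
#' @param ... Unused.
#' @return A `stats::hclust` object (heights on the `d/2` scale).
#' @export
as.hclust.upgma_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = "average",
                 call = match.call(), dist.method = "1 - GSC"),
            class = "hclust")
}

#' Cophenetic distance matrix of a dendrogram
#'
#' The height-scale distance (`2 * merge height = 1 - GSC` scale) at which
#' each pair of leaves first joins.
#'
#' @param tree A [upgma()] dendrogram.
#' @return Symmetric numeric matrix with dimnames = leaf labels.
#' @export
cophenetic_matrix <- function(tree) {
  2 * as.matrix(stats::cophenetic(as.hclust.upgma_dendrogram(tree)))
}

#' Newick serialisation of a dendrogram
#'
#' Branch lengths are height differences on the merge-height scale; the
#' string is terminated by `";"` and parseable by standard tree readers.
#'
#' @param tree A [upgma()] dendrogram.
#' @return A single Newick string.
#' @export
newick <- function(tree) {
  n <- length(tree$labels)
  node_str <- function(node, parent_h) {
    if (node < 0) {
      sprintf("%s:%s", tree$labels[-node], format_bl(parent_h))
    } else {
      h <- tree$height[node]
      kids <- vapply(tree$merge[node, ], node_str, character(1), parent_h = h)
      body <- sprintf("(%s)", paste(kids, collapse = ","))
      if (is.na(parent_h)) body else
        sprintf("%s:%s", body, format_bl(parent_h - h))
    }
  }
  format_bl <- function(x) {
    out <- format(x, trim = TRUE, scientific = FALSE, digits = 10)
    ifelse(grepl("\\.", out), out, paste0(out, ".0"))
  }
  paste0(node_str(nrow(tree$merge), NA_real_), ";")
}

#' Write a dendrogram (or phylo tree) to a Newick file
#'
#' @param tree A [upgma()] dendrogram or an `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "upgma_dendrogram")) {
    writeLines(newick(tree), path)
  } else {
    ape::write.tree(tree, file = path)
  }
  invisible(path)
}

#' Cut a dendrogram at a similarity threshold
#'
#' Cuts the ultrametric tree at height `(1 - threshold) / 2` (the height at
#' which pairs of GSC exactly `threshold` merge) and returns the resulting
#' groups.
#'
#' @param tree A [upgma()] dendrogram.
#' @param similarity_threshold GSC value in `[0, 1]`.
#' @return Named integer vector of group memberships (names = individuals).
#' @export
cut_clusters <- function(tree, similarity_threshold) {
  stopifnot(similarity_threshold >= 0, similarity_threshold <= 1)
  h <- (1 - similarity_threshold) / 2
  stats::cutree(as.hclust.upgma_dendrogram(tree), h = h)
}
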