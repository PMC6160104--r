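# Population-structure summaries on a CNV matrix: PCA, pairwise
# distances, UPGMA clustering with ordinary bootstrap support.

#' Principal component analysis of a CNV matrix
#'
#' Columns (regions) are centered but not scaled; components come from
#' the singular value decomposition of the centered matrix, so the
#' integer coding (presence or copy number) enters only through its
#' deviations from the column means.
#'
#' @param mat A `cnv_matrix` or a plain samples x regions numeric
#'   matrix.
#' @return A list of class `cnv_pca`: `coordinates` (samples x
#'   components), `variance_explained` (fraction per component,
#'   non-increasing), `sdev`.
#' @export
cnv_pca <- function(mat) {
  x <- if (inherits(mat, "cnv_matrix")) mat$values else as.matrix(mat)
  if (nrow(x) < 2L || ncol(x) < 1L)
    stop("PCA needs >= 2 samples and >= 1 region")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) stop("constant matrix: total variance is zero")
  structure(list(coordinates = pc$x,
                 variance_explained = pc$sdev^2 / tot,
                 sdev = pc$sdev),
            class = "cnv_pca")
}

#' Principal coordinates analysis of pairwise sample distances
#'
#' The distance-based companion to [cnv_pca()]: classical
#' multidimensional scaling of the [cnv_distances()] matrix. With
#' Euclidean distances it reproduces the PCA sample coordinates up to
#' axis sign.
#'
#' @param mat A `cnv_matrix` or numeric matrix (samples in rows).
#' @param method Distance method, see [cnv_distances()].
#' @param k Number of coordinate axes to return.
#' @return A list of class `cnv_pcoa`: `coordinates`,
#'   `variance_explained` (positive-eigenvalue fractions).
#' @export
cnv_pcoa <- function(mat, method = "euclidean", k = 2L) {
  d <- cnv_distances(mat, method)
  mds <- stats::cmdscale(d, k = k, eig = TRUE)
  pos <- mds$eig[mds$eig > 1e-12]
  structure(list(coordinates = mds$points,
                 variance_explained = pos / sum(pos)),
            class = "cnv_pcoa")
}

#' Pairwise sample distances on a CNV matrix
#'
#' Euclidean distance on the integer codes by default; `"jaccard"`
#' (1 - |intersection| / |union| of carried regions) is available for
#' presence matrices.
#'
#' @param mat A `cnv_matrix` or numeric matrix (samples in rows).
#' @param method `"euclidean"` or `"jaccard"`.
#' @return A `dist` object.
#' @export
cnv_distances <- function(mat, method = c("euclidean", "jaccard")) {
  method <- match.arg(method)
  x <- if (inherits(mat, "cnv_matrix")) mat$values else as.matrix(mat)
  if (method == "euclidean") return(stats::dist(x))
  stats::dist(x, method = "binary")
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted pair-group agglomeration: at each step the pair
#' of clusters with the smallest average inter-cluster distance is
#' merged at ultrametric height equal to half that distance. Ties are
#' broken deterministically by the lexicographically smallest pair of
#' cluster representatives (a cluster is represented by its smallest
#' member label).
#'
#' @param d A `dist` or symmetric matrix with zero diagonal and sample
#'   labels.
#' @return A list of class `cnv_dendrogram`: `phylo` (rooted
#'   ultrametric `ape` tree), `merge`/`height`/`labels` (hclust-style,
#'   heights are the full average distances), `node_heights`
#'   (ultrametric heights, i.e. distance / 2, one per internal node in
#'   `phylo` node order), `support` (`NULL` until
#'   [bootstrap_support()]).
#' @export
upgma_tree <- function(d) {
  dm <- as.matrix(d)
  if (any(is.na(dm))) stop("distance matrix contains NA")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(nrow(dm)))
  n <- nrow(dm)
  if (n < 2L) stop("need >= 2 samples")
  labels <- rownames(dm)
  diag(dm) <- Inf
  size <- rep(1L, n)
  id <- -seq_len(n)               # hclust convention: negatives = leaves
  rep_lab <- labels               # cluster representative label
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    act <- which(active)
    sub <- dm[act, act, drop = FALSE]
    dmin <- min(sub)
    hits <- which(sub == dmin, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    # lexicographic tie-break on sorted representative labels
    keys <- apply(hits, 1L, function(h) {
      paste(sort(c(rep_lab[act[h[1L]]], rep_lab[act[h[2L]]])),
            collapse = "\r")
    })
    pick <- hits[order(keys)[1L], ]
    i <- act[pick[1L]]; j <- act[pick[2L]]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- dmin
    # UPGMA update: size-weighted average of member distances
    new_d <- (size[i] * dm[i, ] + size[j] * dm[j, ]) / (size[i] + size[j])
    dm[i, ] <- new_d; dm[, i] <- new_d
    dm[i, i] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    id[i] <- step
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
  }
  hc <- structure(list(merge = merge, height = height, order = hclust_order(merge),
                       labels = labels, method = "upgma",
                       call = match.call(), dist.method = "euclidean"),
                  class = "hclust")
  phylo <- ape::as.phylo(hc)   # divides heights by 2 -> ultrametric tree
  structure(list(phylo = phylo, merge = merge, height = height,
                 labels = labels, node_heights = height / 2,
                 support = NULL),
            class = "cnv_dendrogram")
}

# leaf ordering consistent with the merge matrix (for plotting only)
hclust_order <- function(merge) {
  walk <- function(i) {
    if (i < 0L) return(-i)
    c(walk(merge[i, 1L]), walk(merge[i, 2L]))
  }
  walk(nrow(merge))
}

#' @export
print.cnv_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram over %d samples", length(x$labels)))
  if (!is.null(x$support))
    cat(sprintf("; bootstrap support on %d internal nodes",
                length(x$support)))
  cat("\n")
  invisible(x)
}

# canonical key for a clade: sorted member labels
clade_keys <- function(dend) {
  members <- vector("list", nrow(dend$merge))
  for (i in seq_len(nrow(dend$merge))) {
    grab <- function(v) if (v < 0L) dend$labels[-v] else members[[v]]
    members[[i]] <- sort(c(grab(dend$merge[i, 1L]),
                           grab(dend$merge[i, 2L])))
  }
  vapply(members, paste, character(1), collapse = "\r")
}

#' Ordinary bootstrap support for a UPGMA tree
#'
#' Regions (matrix columns) are resampled with replacement `n_boot`
#' times; the bootstrap proportion (BP) of an internal node is the
#' fraction of replicate UPGMA trees containing the same sample clade.
#' Columns are put in region-id order before resampling, so BP is
#' invariant to the column order of the input and reproducible from
#' the seed.
#'
#' @param mat A `cnv_matrix` or numeric matrix (samples in rows).
#' @param n_boot Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param method Distance method passed to [cnv_distances()].
#' @return The reference `cnv_dendrogram` with `support` filled:
#'   a numeric BP in \[0, 1\] per internal node (in merge order), also
#'   attached as `phylo$node.label`.
#' @export
bootstrap_support <- function(mat, n_boot = 200L, seed = 1L,
                              method = "euclidean") {
  stopifnot(n_boot >= 1L)
  x <- if (inherits(mat, "cnv_matrix")) mat$values else as.matrix(mat)
  x <- x[, order(colnames(x) %||% seq_len(ncol(x))), drop = FALSE]
  ref <- upgma_tree(cnv_distances(x, method))
  ref_keys <- clade_keys(ref)
  counts <- stats::setNames(numeric(length(ref_keys)), ref_keys)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(x), ncol(x), replace = TRUE)
    bt <- upgma_tree(cnv_distances(x[, cols, drop = FALSE], method))
    hit <- ref_keys %in% clade_keys(bt)
    counts[hit] <- counts[hit] + 1
  }
  ref$support <- unname(counts) / n_boot
  # node.label order: internal nodes of as.phylo(hclust) correspond to
  # merge rows; map merge-row clades onto phylo internal node numbers
  ref$phylo$node.label <- support_in_phylo_order(ref)
  ref
}

support_in_phylo_order <- function(dend) {
  ph <- dend$phylo
  ntip <- length(ph$tip.label)
  kids <- split(ph$edge[, 2L], factor(ph$edge[, 1L],
                                      levels = seq_len(ntip + ph$Nnode)))
  members <- vector("list", ntip + ph$Nnode)
  tips_under <- function(v) {
    if (!is.null(members[[v]])) return(members[[v]])
    out <- if (v <= ntip) ph$tip.label[v]
           else unlist(lapply(kids[[v]], tips_under))
    members[[v]] <<- out
    out
  }
  key_by_node <- vapply(seq_len(ph$Nnode), function(nd) {
    paste(sort(tips_under(ntip + nd)), collapse = "\r")
  }, character(1))
  merge_keys <- clade_keys(dend)
  dend$support[match(key_by_node, merge_keys)]
}

#' Write a dendrogram as Newick with BP node labels
#'
#' @param dend A `cnv_dendrogram` (support optional).
#' @param path Output path.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(dend$phylo, file = path)
  invisible(path)
}
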