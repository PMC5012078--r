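# Expression-character clustering: discrete call matrices -> mean
# character difference distances (pairwise deletion) -> neighbor joining
# (Saitou & Nei 1987) -> character bootstrap support.

#' Encode RNA-seq differential-expression results as discrete calls
#'
#' Significant genes with positive log fold change become state 2
#' (over-expressed), significant negative ones state 0 (under-expressed),
#' non-significant ones state 1; missing entries stay `NA`.
#'
#' @param logfc Numeric vector of log2 fold changes.
#' @param significant Logical vector of the same length.
#' @return Integer vector of states in \{0, 1, 2, NA\}.
#' @export
encode_rnaseq_calls <- function(logfc, significant) {
  if (length(logfc) != length(significant))
    stop("logfc and significant must have equal length")
  if (any(significant & !is.na(logfc) & logfc == 0, na.rm = TRUE))
    stop("contradictory input: logFC of 0 flagged significant")
  out <- rep(NA_integer_, length(logfc))
  known <- !is.na(logfc) & !is.na(significant)
  out[known] <- 1L
  out[known & significant & logfc > 0] <- 2L
  out[known & significant & logfc < 0] <- 0L
  out
}

#' Mean character difference distances with pairwise deletion
#'
#' For each species pair, characters (genes) where either cell is `NA` are
#' excluded for that pair only; the distance is the proportion of the
#' jointly scored characters at which the two species' states differ.
#'
#' @param m Matrix of discrete states (genes x species) over
#'   \{0, 1, 2, NA\} (any discrete coding works; only equality matters).
#' @return Object of class `char_dist`: list of species x species matrices
#'   `distance`, `n_comparable`, `n_differing`, plus `labels` and
#'   `undefined_pairs` (TRUE where no character was jointly scored).
#' @export
mean_character_distance <- function(m) {
  m <- as.matrix(m)
  ns <- ncol(m)
  if (ns < 2L) stop("need at least two species")
  labels <- colnames(m)
  if (is.null(labels)) labels <- sprintf("sp_%d", seq_len(ns))
  d <- matrix(0, ns, ns, dimnames = list(labels, labels))
  ncmp <- matrix(nrow(m), ns, ns, dimnames = dimnames(d))
  ndif <- matrix(0L, ns, ns, dimnames = dimnames(d))
  und <- matrix(FALSE, ns, ns, dimnames = dimnames(d))
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      comp <- !is.na(m[, i]) & !is.na(m[, j])
      nc <- sum(comp)
      nd <- sum(m[comp, i] != m[comp, j])
      ncmp[i, j] <- ncmp[j, i] <- nc
      ndif[i, j] <- ndif[j, i] <- nd
      if (nc == 0L) {
        d[i, j] <- d[j, i] <- NA_real_
        und[i, j] <- und[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- nd / nc
      }
    }
  }
  diag(ncmp) <- colSums(!is.na(m))
  structure(list(distance = d, n_comparable = ncmp, n_differing = ndif,
                 labels = labels, undefined_pairs = und),
            class = "char_dist")
}

#' @export
print.char_dist <- function(x, ...) {
  cat("Mean character difference distances (pairwise deletion)\n")
  print(round(x$distance, 6))
  invisible(x)
}

as_dist_matrix <- function(d) {
  if (inherits(d, "char_dist")) d$distance
  else if (inherits(d, "dist")) as.matrix(d)
  else as.matrix(d)
}

#' Neighbor-joining tree construction
#'
#' Saitou-Nei agglomeration: iteratively joins the pair minimizing
#' `Q(i, j) = (r - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`, with
#' branch lengths by the standard NJ formulas. Ties are broken by the
#' lowest (row, column) index pair; negative branch lengths are clamped to
#' zero (attribute `negative_branches_clamped` reports how many).
#'
#' @param d A `char_dist` object, `dist`, or square symmetric matrix with
#'   >= 3 taxa and no undefined entries.
#' @return Unrooted `phylo` tree (from \pkg{ape}'s representation, built
#'   by this package's own agglomeration).
#' @export
neighbor_joining <- function(d) {
  D <- as_dist_matrix(d)
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (any(is.na(D))) stop("undefined distances present")
  labels <- rownames(D)
  if (is.null(labels)) labels <- sprintf("t%d", seq_len(n))
  frag <- labels          # growing newick fragment per active cluster
  n_clamped <- 0L
  clamp <- function(b) {
    if (b < 0) { n_clamped <<- n_clamped + 1L; 0 } else b
  }
  fmt <- function(b) sprintf("%.17g", b)
  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    # lowest (row, column) tie-break over the upper triangle
    best <- c(NA_integer_, NA_integer_); qbest <- Inf
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        if (Q[i, j] < qbest) { qbest <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- clamp(D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2)))
    bj <- clamp(D[i, j] - (D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))))
    new_frag <- paste0("(", frag[i], ":", fmt(bi), ",",
                       frag[j], ":", fmt(bj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    rn <- c(rownames(D)[keep], "internal")
    dimnames(D2) <- list(rn, rn)
    D <- D2
    frag <- c(frag[keep], new_frag)
  }
  # final trifurcation by the three-point formulas
  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  newick <- paste0("(", frag[1], ":", fmt(b1), ",", frag[2], ":", fmt(b2),
                   ",", frag[3], ":", fmt(b3), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "negative_branches_clamped") <- n_clamped
  tree
}

# descendant tip labels per node (tips + internals) of an unrooted phylo
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  sets <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  # postorder: children resolved before parents
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

# canonical bipartition keys for the internal edges of an unrooted tree
tree_splits <- function(tree) {
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1]
  n_tip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  root <- n_tip + 1L
  internal_children <- tree$edge[tree$edge[, 2] > n_tip, 2]
  keys <- vapply(internal_children, function(nd) {
    side <- sort(sets[[nd]])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    if (length(side) < 2L || length(side) > n_tip - 2L) return(NA_character_)
    paste(side, collapse = "|")
  }, character(1))
  stats::setNames(keys, internal_children)
}

#' Character-bootstrap support for the neighbor-joining tree
#'
#' Builds the NJ tree on the full call matrix, then resamples gene rows
#' with replacement `n_reps` times (missing cells travel with their gene),
#' recomputes distances and the NJ tree per replicate, and scores each
#' internal edge of the full-data tree by the percentage of replicate
#' trees containing the same species bipartition. Replicates with an
#' undefined pairwise distance are redrawn and counted.
#'
#' @param m Call matrix (genes x species).
#' @param n_reps Number of bootstrap pseudoreplicates (default 100, the
#'   study's setting).
#' @param seed Integer seed for the resampling.
#' @return The full-data `phylo` tree with integer percentage support as
#'   `node.label` (empty at the basal trifurcation) and attributes
#'   `support` (named by bipartition key) and `n_redrawn`.
#' @export
bootstrap_support <- function(m, n_reps = 100, seed = 1) {
  if (n_reps < 1) stop("n_reps must be at least 1")
  m <- as.matrix(m)
  full <- neighbor_joining(mean_character_distance(m))
  keys <- tree_splits(full)
  counts <- stats::setNames(rep(0L, length(keys)), keys)
  set.seed(seed)
  n_redrawn <- 0L
  for (b in seq_len(n_reps)) {
    repeat {
      idx <- sample.int(nrow(m), replace = TRUE)
      dd <- mean_character_distance(m[idx, , drop = FALSE])
      if (!any(is.na(dd$distance))) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_reps)
        stop("bootstrap: too many replicates with undefined distances")
    }
    rep_keys <- tree_splits(neighbor_joining(dd))
    hit <- names(counts) %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }
  support <- round(100 * counts / n_reps)
  # node.label in internal-node-number order; basal node left blank
  n_tip <- length(full$tip.label)
  labels <- character(full$Nnode)
  node_ids <- as.integer(names(keys))
  for (k in seq_along(node_ids)) {
    if (!is.na(keys[k]))
      labels[node_ids[k] - n_tip] <- as.character(support[[k]])
  }
  full$node.label <- labels
  attr(full, "support") <- support
  attr(full, "n_redrawn") <- n_redrawn
  full
}

#' Serialize a tree to Newick
#'
#' Branch lengths and any internal-node support labels are written;
#' reserved characters in labels are handled by the serializer. The output
#' round-trips losslessly through [read_newick()].
#'
#' @param tree A `phylo` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse a Newick tree
#'
#' @param x A file path or a Newick string.
#' @return A `phylo` object.
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}
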