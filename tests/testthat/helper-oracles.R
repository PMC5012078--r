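# Independent brute-force oracles used to check the NG86 counting and the
# neighbor-joining implementation. These deliberately re-derive everything
# from first principles through different code paths than the package.

# translate a codon via Biostrings' translation machinery (computed once
# for all 64 codons, then looked up)
oracle_aa <- local({
  tab <- NULL
  function(codon) {
    if (is.null(tab)) {
      all64 <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 c("A", "C", "G", "T")), 1, function(x)
        paste(x[c(1, 2, 3)], collapse = ""))
      aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(all64),
                                               no.init.codon = TRUE))
      tab <<- stats::setNames(aa, all64)
    }
    tab[[codon]]
  }
})

oracle_count_sites <- function(codon) {
  aa0 <- oracle_aa(codon)
  syn <- 0L; nonstop <- 0L
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      aa <- oracle_aa(mut)
      if (aa == "*") next
      nonstop <- nonstop + 1L
      if (aa == aa0) syn <- syn + 1L
    }
  }
  s <- 3 * syn / nonstop
  c(s = s, n = 3 - s)
}

# enumerate every ordering of single-base steps recursively
oracle_count_differences <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, blocked) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      step_aa <- oracle_aa(nxt)
      recurse(nxt, setdiff(remaining, p),
              sd + (step_aa == oracle_aa(cur)),
              nd + (step_aa != oracle_aa(cur)),
              blocked || step_aa == "*")
    }
  }
  recurse(a, pos, 0, 0, FALSE)
  mat <- do.call(rbind, paths)
  open <- mat[mat[, 3] == 0, , drop = FALSE]
  use <- if (nrow(open) > 0) open else mat
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

# per-codon oracle totals for a pair of gap-free in-frame sequences
oracle_pair_counts <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  Sd <- 0; Nd <- 0; Sa <- 0; Sb <- 0; n_cmp <- 0L
  for (k in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[k]) || grepl("[^ACGT]", cb[k])) next
    if (oracle_aa(ca[k]) == "*" || oracle_aa(cb[k]) == "*") next
    n_cmp <- n_cmp + 1L
    d <- oracle_count_differences(ca[k], cb[k])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
    Sa <- Sa + oracle_count_sites(ca[k])[["s"]]
    Sb <- Sb + oracle_count_sites(cb[k])[["s"]]
  }
  S <- (Sa + Sb) / 2
  list(S = S, N = 3 * n_cmp - S, Sd = Sd, Nd = Nd, n_cmp = n_cmp)
}

# ---- neighbor-joining oracle -------------------------------------------

# random additive distance matrix from a random 5-taxon topology
random_additive_matrix <- function(seed, n_taxa = 5) {
  set.seed(seed)
  labels <- paste0("t", seq_len(n_taxa))
  trees <- phangorn::allTrees(n_taxa, rooted = FALSE, tip.label = labels)
  tree <- trees[[sample.int(length(trees), 1)]]
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.1, 1)
  D <- ape::cophenetic.phylo(tree)
  D <- D[labels, labels]
  list(D = D, tree = tree)
}

# indicator matrix: which edges lie on the path between each tip pair
path_design_matrix <- function(tree) {
  n <- length(tree$tip.label)
  prs <- utils::combn(n, 2)
  A <- matrix(0, ncol(prs), nrow(tree$edge))
  edge_key <- paste(pmin(tree$edge[, 1], tree$edge[, 2]),
                    pmax(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(ncol(prs))) {
    np <- ape::nodepath(tree, prs[1, k], prs[2, k])
    steps <- paste(pmin(np[-length(np)], np[-1]),
                   pmax(np[-length(np)], np[-1]))
    A[k, match(steps, edge_key)] <- 1
  }
  A
}

# brute-force least-squares fit over all unrooted topologies; returns the
# best topology (with fitted branch lengths) and its residual sum of squares
ls_tree_oracle <- function(D) {
  labels <- rownames(D)
  n <- length(labels)
  prs <- utils::combn(n, 2)
  dvec <- D[t(prs)]
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labels)
  best <- NULL; best_rss <- Inf
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]   # [[ restores the compressed multiPhylo tip labels
    A <- path_design_matrix(tr)
    # rows of A follow combn over tr's tip numbering; re-map to `labels`
    key_tr <- apply(utils::combn(n, 2), 2, function(ij)
      paste(sort(tr$tip.label[ij]), collapse = "|"))
    key_d <- apply(prs, 2, function(ij)
      paste(sort(labels[ij]), collapse = "|"))
    A <- A[match(key_d, key_tr), , drop = FALSE]
    fit <- stats::lm.fit(A, dvec)
    rss <- sum(fit$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      tr$edge.length <- fit$coefficients
      best <- tr
    }
  }
  list(tree = best, rss = best_rss)
}
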