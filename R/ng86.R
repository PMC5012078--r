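# Nei-Gojobori (1986) pairwise dN/dS: fractional site counting,
# pathway-averaged difference counting, Jukes-Cantor correction.

.eggspot_cache <- new.env(parent = emptyenv())

#' The standard genetic code
#'
#' Named character vector mapping the 64 codons to one-letter amino acids,
#' with `"*"` for stop codons (from \pkg{Biostrings}).
#'
#' @return Named character vector of length 64.
#' @export
genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons.
#' @export
sense_codons <- function() {
  code <- genetic_code()
  names(code)[code != "*"]
}

.bases <- c("A", "C", "G", "T")

# all nine single-base mutants of a codon, in position-major order
codon_neighbors <- function(codon) {
  out <- character(9)
  k <- 0L
  for (pos in 1:3) {
    cur <- substr(codon, pos, pos)
    for (b in .bases[.bases != cur]) {
      mut <- codon
      substr(mut, pos, pos) <- b
      k <- k + 1L
      out[k] <- mut
    }
  }
  out
}

#' Synonymous and nonsynonymous site counts for one codon
#'
#' Fractional site counting: over the nine single-base mutations of the
#' codon, mutations that create a stop codon are excluded and the codon's
#' three sites renormalized over the remainder, so `s + n = 3` always.
#'
#' @param codon A 3-character string over A/C/G/T; must be a sense codon.
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @export
count_sites <- function(codon) {
  codon <- toupper(codon)
  code <- genetic_code()
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("codon must be a 3-mer over A/C/G/T, got '", codon, "'")
  if (code[[codon]] == "*")
    stop("stop codon '", codon, "' has no site counts")
  nb <- codon_neighbors(codon)
  aa <- unname(code[nb])
  keep <- aa != "*"
  syn <- keep & aa == code[[codon]]
  s <- 3 * sum(syn) / sum(keep)
  c(s = s, n = 3 - s)
}

# permutations of 1..k for k <= 3
.perms <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' Enumerates all orderings of the single-base steps between the codons,
#' discards orderings passing through a stop codon, classifies each step as
#' synonymous or nonsynonymous, and averages over the retained orderings.
#' If every ordering is stop-blocked, all orderings are used and
#' `all_paths_blocked` is set.
#'
#' @param codon_a,codon_b Sense codons (3-mers over A/C/G/T).
#' @return List with `sd`, `nd` (means over retained orderings; `sd + nd`
#'   equals the number of differing positions) and `all_paths_blocked`.
#' @export
count_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  code <- genetic_code()
  for (cd in c(codon_a, codon_b)) {
    if (nchar(cd) != 3L || grepl("[^ACGT]", cd))
      stop("codon must be a 3-mer over A/C/G/T, got '", cd, "'")
    if (code[[cd]] == "*")
      stop("stop codon '", cd, "' not allowed")
  }
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  k <- length(diff_pos)
  if (k == 0L)
    return(list(sd = 0, nd = 0, all_paths_blocked = FALSE))
  perms <- .perms[[k]]
  walk <- function(order_idx, allow_stops) {
    cur <- codon_a
    sd <- 0; nd <- 0
    for (pos in diff_pos[order_idx]) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (!allow_stops && code[[nxt]] == "*") return(NULL)
      if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(seq_len(nrow(perms)), function(i) walk(perms[i, ], FALSE))
  blocked <- vapply(res, is.null, logical(1))
  if (all(blocked)) {
    res <- lapply(seq_len(nrow(perms)), function(i) walk(perms[i, ], TRUE))
    blocked_flag <- TRUE
  } else {
    res <- res[!blocked]
    blocked_flag <- FALSE
  }
  mat <- do.call(rbind, res)
  list(sd = mean(mat[, 1]), nd = mean(mat[, 2]),
       all_paths_blocked = blocked_flag)
}

# precomputed lookup tables over the 61 sense codons (built once per session)
ng86_tables <- function() {
  if (!is.null(.eggspot_cache$ng86)) return(.eggspot_cache$ng86)
  sense <- sense_codons()
  n <- length(sense)
  sites <- t(vapply(sense, count_sites, numeric(2)))
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- sd
  blocked <- matrix(FALSE, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in i:n) {
      d <- count_differences(sense[i], sense[j])
      sd[i, j] <- sd[j, i] <- d$sd
      nd[i, j] <- nd[j, i] <- d$nd
      blocked[i, j] <- blocked[j, i] <- d$all_paths_blocked
    }
  }
  .eggspot_cache$ng86 <- list(sites = sites, sd = sd, nd = nd,
                              blocked = blocked)
  .eggspot_cache$ng86
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`; proportions at or beyond the saturation
#' point `p >= 3/4` return `NA` (the caller flags saturation).
#'
#' @param p Proportion(s) of differing sites, `>= 0`.
#' @return Corrected distance(s); `NA` where saturated.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0, na.rm = TRUE)) stop("p must be non-negative")
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log1p(-4 * p / 3))
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Pairwise dN/dS by the Nei-Gojobori method
#'
#' Codons containing a gap, `N`, any other ambiguity, or a stop codon in
#' either sequence are skipped pairwise. `S` and `N` are the means of the
#' two sequences' site totals over the compared codons; `Sd`, `Nd` are
#' pathway-averaged difference counts summed over codons; `dS`, `dN` are
#' Jukes-Cantor corrected; `omega = dN/dS` when `dS > 0`.
#'
#' @param seq_a,seq_b Equal-length in-frame nucleotide strings.
#' @return Object of class `pairwise_rate`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `codons_compared`, `codons_skipped`
#'   and a `flags` list (`saturated_s`, `saturated_n`, `zero_ds`,
#'   `path_blocked`).
#' @export
pairwise_dnds <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences must have equal length")
  if (nchar(seq_a) %% 3L != 0L)
    stop("sequence length must be divisible by 3")
  tab <- ng86_tables()
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  sense <- rownames(tab$sites)
  ok <- ca %in% sense & cb %in% sense
  n_cmp <- sum(ok)
  if (n_cmp == 0L)
    stop("no comparable codons (all skipped for gaps/ambiguity/stops)")
  ca <- ca[ok]; cb <- cb[ok]
  S_a <- sum(tab$sites[ca, "s"]); S_b <- sum(tab$sites[cb, "s"])
  S <- (S_a + S_b) / 2
  N <- 3 * n_cmp - S
  idx <- cbind(match(ca, sense), match(cb, sense))
  Sd <- sum(tab$sd[idx])
  Nd <- sum(tab$nd[idx])
  path_blocked <- any(tab$blocked[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  dS <- jukes_cantor(pS)
  dN <- jukes_cantor(pN)
  flags <- list(
    saturated_s = !is.na(pS) && pS >= 0.75,
    saturated_n = !is.na(pN) && pN >= 0.75,
    zero_ds = !is.na(dS) && dS == 0,
    path_blocked = path_blocked
  )
  omega <- if (is.na(dS) || is.na(dN)) {
    NA_real_
  } else if (dS > 0) {
    dN / dS
  } else if (dN > 0) {
    Inf
  } else {
    NA_real_
  }
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 codons_compared = n_cmp,
                 codons_skipped = length(ok) - n_cmp,
                 flags = flags),
            class = "pairwise_rate")
}

#' @export
print.pairwise_rate <- function(x, ...) {
  cat("Nei-Gojobori pairwise rate (", x$codons_compared, " codons compared, ",
      x$codons_skipped, " skipped)\n", sep = "")
  cat(sprintf("  S = %.3f  N = %.3f  Sd = %.3f  Nd = %.3f\n",
              x$S, x$N, x$Sd, x$Nd))
  cat(sprintf("  dS = %s  dN = %s  dN/dS = %s\n",
              format(x$dS, digits = 5), format(x$dN, digits = 5),
              format(x$omega, digits = 5)))
  invisible(x)
}

#' Per-gene dN/dS as the mean over species pairs
#'
#' Averages `omega` over all unordered sequence pairs of a codon alignment,
#' excluding pairs whose `omega` is undefined or infinite.
#'
#' @param seqs Named character vector of >= 2 equal-length in-frame
#'   aligned sequences.
#' @param gene_id Gene identifier carried into the result.
#' @return List with `gene_id`, `omega_mean` (`NA` when no pair is usable),
#'   `n_pairs_used`, `n_pairs_total`.
#' @export
gene_dnds <- function(seqs, gene_id = "gene") {
  if (length(seqs) < 2L) stop("need at least two sequences")
  prs <- utils::combn(length(seqs), 2)
  omegas <- numeric(0)
  for (k in seq_len(ncol(prs))) {
    r <- tryCatch(pairwise_dnds(seqs[[prs[1, k]]], seqs[[prs[2, k]]]),
                  error = function(e) NULL)
    if (!is.null(r) && is.finite(r$omega)) omegas <- c(omegas, r$omega)
  }
  list(gene_id = gene_id,
       omega_mean = if (length(omegas)) mean(omegas) else NA_real_,
       n_pairs_used = length(omegas),
       n_pairs_total = ncol(prs))
}

as_omega_vector <- function(x) {
  if (is.numeric(x)) return(x[is.finite(x)])
  v <- vapply(x, function(g) g$omega_mean, numeric(1))
  v[is.finite(v)]
}

#' Compare mean evolutionary rates between gene sets
#'
#' Reports per-set mean and standard error of the per-gene dN/dS and Welch
#' two-sample t-tests of each expression set against the background, plus
#' the over- vs under-expressed contrast.
#'
#' @param over,under,background Numeric vectors of per-gene `omega_mean`
#'   values, or lists of [gene_dnds()] results.
#' @return Object of class `rate_set_comparison`: list with `summary`
#'   (data frame: set, n, mean, se) and `tests` (data frame: comparison,
#'   statistic, df, p_value).
#' @export
compare_rate_sets <- function(over, under, background) {
  sets <- list(over = as_omega_vector(over),
               under = as_omega_vector(under),
               background = as_omega_vector(background))
  ns <- vapply(sets, length, integer(1))
  if (any(ns < 2L))
    stop("each set needs at least 2 genes with defined omega; got ",
         paste(names(ns)[ns < 2], collapse = ", "))
  summary_df <- data.frame(
    set = names(sets),
    n = ns,
    mean = vapply(sets, mean, numeric(1)),
    se = vapply(sets, function(v) stats::sd(v) / sqrt(length(v)), numeric(1)),
    row.names = NULL
  )
  welch <- function(a, b) stats::t.test(sets[[a]], sets[[b]])
  tt <- list(over_vs_background = welch("over", "background"),
             under_vs_background = welch("under", "background"),
             over_vs_under = welch("over", "under"))
  tests_df <- data.frame(
    comparison = names(tt),
    statistic = vapply(tt, function(t) unname(t$statistic), numeric(1)),
    df = vapply(tt, function(t) unname(t$parameter), numeric(1)),
    p_value = vapply(tt, function(t) t$p.value, numeric(1)),
    row.names = NULL
  )
  structure(list(summary = summary_df, tests = tests_df),
            class = "rate_set_comparison")
}

#' @export
print.rate_set_comparison <- function(x, ...) {
  cat("Gene-set dN/dS comparison (Welch t-tests)\n")
  print(x$summary, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}
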