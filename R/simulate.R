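# Seeded generators for every input the pipeline consumes: codon pairs
# diverged under a target dN/dS, qPCR CT tables, discrete call matrices,
# and BLAST-style hit tables with a constructed pass fraction.

#' Simulate a pair of coding sequences diverged under a target dN/dS
#'
#' An ancestral sequence is drawn uniformly over sense codons and evolved
#' independently along two branches. Mutations are proposed site-wise
#' (Poisson number of events, uniform positions, uniform alternative base)
#' and accepted by rejection sampling: for `omega <= 1` synonymous changes
#' are always accepted and nonsynonymous ones with probability `omega`;
#' for `omega > 1` nonsynonymous changes are always accepted and synonymous
#' ones with probability `1/omega`. Proposals creating stop codons are
#' rejected, so no output sequence contains an in-frame stop.
#'
#' `subs_per_site` is the expected number of proposed substitutions per
#' nucleotide site summed over the two branches (i.e. the pair's proposal
#' divergence); rejection of nonsynonymous proposals makes the realized
#' divergence lower when `omega < 1`.
#'
#' @param n_codons Number of codons (>= 1).
#' @param omega Target dN/dS ratio (>= 0).
#' @param subs_per_site Expected proposed substitutions per site across the
#'   pair (>= 0).
#' @param seed Integer seed; identical arguments reproduce identical output.
#' @param gene_id Identifier carried into the result.
#' @return List with `sequences` (named character vector of the two
#'   descendants, equal length, gap-free), `ancestor`, and the simulation
#'   parameters.
#' @export
simulate_codon_pair <- function(n_codons, omega = 1, subs_per_site = 0.2,
                                seed = 1, gene_id = "sim_gene") {
  if (length(n_codons) != 1L || is.na(n_codons) || n_codons < 1)
    stop("n_codons must be a positive integer")
  if (length(omega) != 1L || is.na(omega) || omega < 0)
    stop("omega must be a non-negative number")
  if (subs_per_site < 0) stop("subs_per_site must be non-negative")
  n_codons <- as.integer(n_codons)
  set.seed(seed)
  code <- genetic_code()
  sense <- sense_codons()
  anc <- sample(sense, n_codons, replace = TRUE)
  L <- 3L * n_codons
  evolve <- function(cod) {
    n_ev <- stats::rpois(1, subs_per_site / 2 * L)
    if (n_ev == 0L) return(cod)
    pos <- sample.int(L, n_ev, replace = TRUE)
    for (p in pos) {
      ci <- (p - 1L) %/% 3L + 1L
      off <- (p - 1L) %% 3L + 1L
      cur <- cod[ci]
      curb <- substr(cur, off, off)
      newb <- sample(.bases[.bases != curb], 1)
      new <- cur
      substr(new, off, off) <- newb
      if (code[[new]] == "*") next
      syn <- code[[new]] == code[[cur]]
      p_acc <- if (omega <= 1) {
        if (syn) 1 else omega
      } else {
        if (syn) 1 / omega else 1
      }
      if (p_acc >= 1 || stats::runif(1) < p_acc) cod[ci] <- new
    }
    cod
  }
  s1 <- paste(evolve(anc), collapse = "")
  s2 <- paste(evolve(anc), collapse = "")
  list(sequences = c(seq_1 = s1, seq_2 = s2),
       ancestor = paste(anc, collapse = ""),
       gene_id = gene_id, n_codons = n_codons, omega = omega,
       subs_per_site = subs_per_site, seed = seed)
}

#' Simulate a paired-tissue qPCR CT table
#'
#' Emulates the paired ornament/plain-fin design: for each individual,
#' gene and tissue an endogenous-control CT is drawn from
#' `Normal(base_ct_control, sigma_ct)`; the focal-tissue target CT is the
#' control CT minus the gene's true log2 fold change plus noise, and the
#' reference-tissue target CT is the control CT plus noise, so the
#' downstream delta-delta-CT estimate converges to `-log2fc` and RQ to
#' `2^log2fc`. Cells are masked `NA` independently with probability
#' `na_rate`.
#'
#' @param n_genes Number of genes.
#' @param n_individuals Number of individuals (paired across tissues).
#' @param log2fc True log2 fold change (focal vs reference), scalar or one
#'   value per gene.
#' @param sigma_ct CT noise standard deviation in cycles (> 0 allowed to be
#'   0 for exact identities).
#' @param base_ct_control Mean control CT in cycles.
#' @param na_rate Probability a CT cell is missing, in \[0, 1\].
#' @param seed Integer seed.
#' @return Data frame with columns `individual`, `tissue`
#'   (`"focal"`/`"reference"`), `gene`, `ct_target`, `ct_control` and
#'   attribute `log2fc_true`.
#' @export
simulate_ct_table <- function(n_genes = 1, n_individuals = 6, log2fc = 0,
                              sigma_ct = 0.3, base_ct_control = 20,
                              na_rate = 0, seed = 1) {
  if (sigma_ct < 0) stop("sigma_ct must be non-negative")
  if (na_rate < 0 || na_rate > 1) stop("na_rate must be in [0, 1]")
  if (n_genes < 1 || n_individuals < 1)
    stop("n_genes and n_individuals must be positive")
  log2fc <- rep_len(log2fc, n_genes)
  set.seed(seed)
  grid <- expand.grid(
    individual = sprintf("ind_%02d", seq_len(n_individuals)),
    gene = sprintf("gene_%03d", seq_len(n_genes)),
    tissue = c("focal", "reference"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  n <- nrow(grid)
  fc <- log2fc[match(grid$gene, sprintf("gene_%03d", seq_len(n_genes)))]
  ct_control <- stats::rnorm(n, base_ct_control, sigma_ct)
  shift <- ifelse(grid$tissue == "focal", -fc, 0)
  ct_target <- ct_control + shift + stats::rnorm(n, 0, sigma_ct)
  if (na_rate > 0) {
    ct_target[stats::runif(n) < na_rate] <- NA_real_
    ct_control[stats::runif(n) < na_rate] <- NA_real_
  }
  out <- data.frame(grid[c("individual", "tissue", "gene")],
                    ct_target = ct_target, ct_control = ct_control,
                    stringsAsFactors = FALSE)
  attr(out, "log2fc_true") <- stats::setNames(
    log2fc, sprintf("gene_%03d", seq_len(n_genes)))
  out
}

#' Simulate a discrete expression-call matrix
#'
#' Per gene, a latent state in \{0, 1, 2\} is drawn uniformly for a
#' reference species (the first); every other species copies the reference
#' state with probability `agreement[1, j]` and otherwise redraws
#' uniformly. `NA` masks are applied independently.
#'
#' @param n_genes,n_species Matrix dimensions.
#' @param agreement Symmetric matrix of pairwise copy probabilities with
#'   unit diagonal, or a scalar used for all off-diagonal entries.
#' @param na_rate Probability a cell is missing.
#' @param seed Integer seed.
#' @param species Optional species names (default `sp_1`, ...).
#' @return Integer matrix genes x species with entries in \{0, 1, 2, NA\}.
#' @export
simulate_call_matrix <- function(n_genes = 46, n_species = 4,
                                 agreement = 0.5, na_rate = 0, seed = 1,
                                 species = NULL) {
  if (is.null(species)) species <- sprintf("sp_%d", seq_len(n_species))
  if (length(species) != n_species) stop("species names must match n_species")
  if (length(agreement) == 1L) {
    a <- matrix(agreement, n_species, n_species)
    diag(a) <- 1
    agreement <- a
  }
  if (!isTRUE(all.equal(agreement, t(agreement))))
    stop("agreement matrix must be symmetric")
  if (any(agreement < 0 | agreement > 1))
    stop("agreement entries must be in [0, 1]")
  if (any(diag(agreement) != 1)) stop("agreement diagonal must be 1")
  if (na_rate < 0 || na_rate > 1) stop("na_rate must be in [0, 1]")
  set.seed(seed)
  m <- matrix(NA_integer_, n_genes, n_species,
              dimnames = list(sprintf("gene_%03d", seq_len(n_genes)),
                              species))
  ref <- sample(0:2, n_genes, replace = TRUE)
  m[, 1] <- ref
  for (j in seq_len(n_species)[-1]) {
    copy <- stats::runif(n_genes) < agreement[1, j]
    m[, j] <- ifelse(copy, ref, sample(0:2, n_genes, replace = TRUE))
  }
  if (na_rate > 0)
    m[matrix(stats::runif(length(m)) < na_rate, nrow(m))] <- NA_integer_
  m
}

#' Simulate a BLAST tabular hit collection with a constructed pass count
#'
#' Exactly `round(n_hits * fraction_passing)` rows satisfy
#' identity > 90, alignment length > 200 and bit score > 200
#' simultaneously; every other row violates at least one criterion
#' (some exactly at a threshold, which the strict filter must discard).
#'
#' @param n_hits Total number of hits.
#' @param fraction_passing Fraction in \[0, 1\] that pass all three filters.
#' @param seed Integer seed.
#' @param species Optional vector of species labels assigned cyclically.
#' @return Data frame in BLAST outfmt-6 column order (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`) plus a `species` column, with attribute
#'   `n_passing`.
#' @export
simulate_hit_table <- function(n_hits = 100, fraction_passing = 0.5,
                               seed = 1, species = "sp_1") {
  if (fraction_passing < 0 || fraction_passing > 1)
    stop("fraction_passing must be in [0, 1]")
  if (n_hits < 0) stop("n_hits must be non-negative")
  set.seed(seed)
  n_pass <- round(n_hits * fraction_passing)
  pass <- sample(c(rep(TRUE, n_pass), rep(FALSE, n_hits - n_pass)))
  pident <- numeric(n_hits); len <- integer(n_hits); bits <- numeric(n_hits)
  # passing rows strictly exceed every threshold
  pident[pass] <- stats::runif(n_pass, 91, 100)
  len[pass] <- sample(210:2000, n_pass, replace = TRUE)
  bits[pass] <- stats::runif(n_pass, 210, 1200)
  n_fail <- n_hits - n_pass
  if (n_fail > 0) {
    # each failing row violates >= 1 criterion; non-violated fields pass
    viol <- matrix(stats::runif(3 * n_fail) < 0.5, n_fail, 3)
    none <- rowSums(viol) == 0L
    viol[cbind(which(none), sample.int(3, sum(none), replace = TRUE))] <- TRUE
    at_bound <- stats::runif(n_fail) < 0.25  # sit exactly on the threshold
    pident[!pass] <- ifelse(viol[, 1],
                            ifelse(at_bound, 90,
                                   stats::runif(n_fail, 50, 89.9)),
                            stats::runif(n_fail, 91, 100))
    len[!pass] <- ifelse(viol[, 2],
                         ifelse(at_bound, 200L,
                                sample(30:200, n_fail, replace = TRUE)),
                         sample(210:2000, n_fail, replace = TRUE))
    bits[!pass] <- ifelse(viol[, 3],
                          ifelse(at_bound, 200,
                                 stats::runif(n_fail, 40, 199.9)),
                          stats::runif(n_fail, 210, 1200))
  }
  qstart <- sample.int(500, n_hits, replace = TRUE)
  out <- data.frame(
    qseqid = sprintf("contig_%04d", sample.int(max(1, n_hits), n_hits)),
    sseqid = sprintf("ref_%04d", sample.int(max(1, n_hits), n_hits)),
    pident = round(pident, 3),
    length = len,
    mismatch = pmax(0L, as.integer(round(len * (100 - pident) / 100))),
    gapopen = sample(0:3, n_hits, replace = TRUE),
    qstart = qstart,
    qend = qstart + len - 1L,
    sstart = qstart,
    send = qstart + len - 1L,
    evalue = 10^-stats::runif(n_hits, 20, 180),
    bitscore = round(bits, 1),
    species = rep_len(species, n_hits),
    stringsAsFactors = FALSE
  )
  attr(out, "n_passing") <- n_pass
  out
}
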