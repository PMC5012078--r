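# Nei-Gojobori counting, Jukes-Cantor correction, pairwise and per-gene
# dN/dS, and the gene-set rate comparison.

test_that("site counting matches hand-derived codon cases", {
  expect_equal(count_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(count_sites("ATG"), c(s = 0, n = 3))
  # TGG: two stop-creating mutants excluded, remaining 7 all nonsynonymous
  expect_equal(count_sites("TGG"), c(s = 0, n = 3))
  expect_error(count_sites("TAA"), "stop")
  expect_error(count_sites("TT-"), "A/C/G/T")
})

test_that("pathway-averaged difference counting matches hand cases", {
  expect_equal(count_differences("GAG", "GAG")[c("sd", "nd")],
               list(sd = 0, nd = 0))
  expect_equal(count_differences("GAA", "GAG")[c("sd", "nd")],
               list(sd = 1, nd = 0))
  # two orderings: via GTT (1 syn + 1 nonsyn) and via TTA (2 nonsyn)
  expect_equal(count_differences("TTT", "GTA")[c("sd", "nd")],
               list(sd = 0.5, nd = 1.5))
})

test_that("site and difference counting agree with brute-force enumeration", {
  sense <- sense_codons()
  for (cd in sense) {
    expect_equal(count_sites(cd), oracle_count_sites(cd), tolerance = 1e-12)
  }
  # all sense-codon pairs
  tab <- eggspot:::ng86_tables()
  for (i in seq_along(sense)) {
    for (j in i:length(sense)) {
      o <- oracle_count_differences(sense[i], sense[j])
      expect_equal(unname(tab$sd[i, j]), unname(o[["sd"]]),
                   tolerance = 1e-12)
      expect_equal(unname(tab$nd[i, j]), unname(o[["nd"]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("per-codon sites sum to three and differences sum to k", {
  for (cd in sense_codons()) {
    cs <- count_sites(cd)
    expect_equal(unname(cs["s"] + cs["n"]), 3)
  }
  set.seed(42)
  sense <- sense_codons()
  for (rep in 1:50) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    d <- count_differences(a, b)
    expect_equal(d$sd + d$nd, k)
  }
})

test_that("Jukes-Cantor correction behaves across its domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.3), 0.383119, tolerance = 1e-6)
  expect_true(is.na(jukes_cantor(0.75)))
  expect_true(is.na(jukes_cantor(0.9)))
  expect_error(jukes_cantor(-0.1), "non-negative")
  # small-divergence limit: d(p) ~ p
  p <- seq(0.0005, 0.01, by = 0.0005)
  expect_true(all(abs(jukes_cantor(p) - p) <= 1e-4))
})

test_that("pairwise dN/dS is symmetric and handles edge cases", {
  sim <- simulate_codon_pair(300, omega = 0.8, subs_per_site = 0.3, seed = 4)
  a <- sim$sequences[[1]]; b <- sim$sequences[[2]]
  r_ab <- pairwise_dnds(a, b)
  r_ba <- pairwise_dnds(b, a)
  expect_equal(unclass(r_ab), unclass(r_ba))
  # identical sequences: zero distances, omega undefined with zero_ds flag
  r_id <- pairwise_dnds(a, a)
  expect_equal(r_id$dS, 0)
  expect_equal(r_id$dN, 0)
  expect_true(is.na(r_id$omega))
  expect_true(r_id$flags$zero_ds)
  # all codons skipped
  expect_error(pairwise_dnds("NNN---", "ATG---"), "no comparable codons")
})

test_that("pairwise counts equal the brute-force per-codon oracle", {
  set.seed(99)
  for (seed in sample.int(10000, 12)) {
    sim <- simulate_codon_pair(40, omega = runif(1, 0, 1.5),
                               subs_per_site = runif(1, 0, 0.6),
                               seed = seed)
    a <- sim$sequences[[1]]; b <- sim$sequences[[2]]
    r <- pairwise_dnds(a, b)
    o <- oracle_pair_counts(a, b)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$N, o$N, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
  }
})

test_that("gaps and ambiguities are skipped pairwise", {
  a <- "ATGGAA---TTT"
  b <- "ATGGAGNNNTTC"
  r <- pairwise_dnds(a, b)
  expect_equal(r$codons_compared, 3L)
  expect_equal(r$codons_skipped, 1L)
  # GAA->GAG synonymous, TTT->TTC synonymous
  expect_equal(r$Sd, 2)
  expect_equal(r$Nd, 0)
})

test_that("gene-level omega averages defined finite pairs only", {
  sim <- simulate_codon_pair(200, omega = 0.5, subs_per_site = 0.3, seed = 8)
  a <- sim$sequences[[1]]; b <- sim$sequences[[2]]
  # two-sequence alignment equals the single pairwise omega
  g2 <- gene_dnds(c(x = a, y = b))
  expect_equal(g2$omega_mean, pairwise_dnds(a, b)$omega)
  expect_equal(g2$n_pairs_used, 1L)
  # a third identical sequence creates dS = 0 pairs that must be excluded
  g3 <- gene_dnds(c(x = a, y = b, z = a))
  expect_equal(g3$n_pairs_used, 2L)
  expect_equal(g3$n_pairs_total, 3L)
  expect_equal(g3$omega_mean, pairwise_dnds(a, b)$omega)
  # no defined pair at all
  g0 <- gene_dnds(c(x = a, y = a))
  expect_true(is.na(g0$omega_mean))
  expect_equal(g0$n_pairs_used, 0L)
})

test_that("rate-set comparison reports means, SEs and Welch tests", {
  set.seed(5)
  over <- rlnorm(30, log(0.4), 0.4)
  under <- rlnorm(30, log(0.4), 0.4)
  bg <- rlnorm(60, log(0.15), 0.4)
  cmp <- compare_rate_sets(over, under, bg)
  expect_setequal(cmp$summary$set, c("over", "under", "background"))
  expect_true(all(cmp$summary$se >= 0))
  p_over <- cmp$tests$p_value[cmp$tests$comparison == "over_vs_background"]
  expect_lt(p_over, 0.01)
  # identical sets give p = 1
  same <- compare_rate_sets(over, over, over)
  expect_equal(same$tests$p_value, rep(1, 3), tolerance = 1e-12)
  expect_error(compare_rate_sets(over[1], under, bg), "at least 2")
})
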