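# Discrete-character distances, neighbor joining against brute-force
# oracles, character bootstrap and Newick round trips.

test_that("RNA-seq encoding maps direction and significance to states", {
  expect_equal(encode_rnaseq_calls(c(3.14, -5.02, 0.4, NA),
                                   c(TRUE, TRUE, FALSE, NA)),
               c(2L, 0L, 1L, NA))
  expect_error(encode_rnaseq_calls(0, TRUE), "contradictory")
})

test_that("mean character distance uses pairwise deletion", {
  m <- cbind(a = c(2, 0, 1, NA), b = c(2, 1, 1, 0))
  d <- mean_character_distance(m)
  expect_equal(d$n_comparable["a", "b"], 3)
  expect_equal(d$n_differing["a", "b"], 1L)
  expect_equal(d$distance["a", "b"], 1 / 3)
  expect_equal(d$distance, t(d$distance))
  expect_equal(unname(diag(d$distance)), c(0, 0))
  # identical columns
  m2 <- cbind(a = c(0, 1, 2), b = c(0, 1, 2))
  expect_equal(mean_character_distance(m2)$distance["a", "b"], 0)
  # relabeling states leaves distances unchanged (only equality matters)
  m3 <- m; m3[m3 == 2] <- 9
  expect_equal(mean_character_distance(m3)$distance,
               mean_character_distance(m)$distance)
  expect_error(mean_character_distance(m[, 1, drop = FALSE]), "two species")
  # no jointly scored characters: undefined with flag
  m4 <- cbind(a = c(1, NA), b = c(NA, 2))
  d4 <- mean_character_distance(m4)
  expect_true(is.na(d4$distance["a", "b"]))
  expect_true(d4$undefined_pairs["a", "b"])
})

test_that("pairwise counts reproduce the published distance arithmetic", {
  # five self-consistent (differing, comparable) pairs from the study's
  # distance table; constructed matrices must reproduce the printed values
  cases <- list(c(41, 45, 0.91111112), c(31, 44, 0.70454544),
                c(34, 43, 0.79069769), c(29, 42, 0.69047618),
                c(19, 40, 0.47499999))
  for (cs in cases) {
    nd <- cs[1]; nc <- cs[2]
    a <- rep(0L, 46)
    b <- a
    b[seq_len(nd)] <- 1L                    # differing characters
    a[nc + seq_len(46 - nc)] <- NA          # jointly unscored
    d <- mean_character_distance(cbind(a = a, b = b))
    expect_equal(d$n_comparable["a", "b"], nc)
    expect_equal(d$n_differing["a", "b"], as.integer(nd))
    expect_equal(d$distance["a", "b"], cs[3], tolerance = 1e-6)
  }
})

test_that("three-taxon NJ solves the three-point formulas", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
  # all-zero matrix: star tree with zero branch lengths
  z <- matrix(0, 3, 3, dimnames = dimnames(d))
  expect_true(all(neighbor_joining(z)$edge.length == 0))
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  dna <- d; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(neighbor_joining(dna), "undefined")
})

test_that("NJ recovers random additive five-taxon matrices exactly", {
  for (seed in c(101, 202, 303, 404, 505)) {
    gen <- random_additive_matrix(seed)
    tr <- neighbor_joining(gen$D)
    # branch lengths: path distances on the NJ tree equal the input matrix
    coph <- ape::cophenetic.phylo(tr)[rownames(gen$D), colnames(gen$D)]
    expect_equal(coph, gen$D, tolerance = 1e-10)
    # topology: matches the brute-force least-squares oracle over all 15
    oracle <- ls_tree_oracle(gen$D)
    expect_lt(oracle$rss, 1e-16)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                            ape::unroot(oracle$tree))), 0)
  }
})

test_that("NJ topology is invariant under uniform distance scaling", {
  gen <- random_additive_matrix(808)
  t1 <- neighbor_joining(gen$D)
  t2 <- neighbor_joining(gen$D * 7)
  expect_equal(as.numeric(ape::dist.topo(t1, t2)), 0)
  expect_equal(sort(t2$edge.length), sort(t1$edge.length * 7),
               tolerance = 1e-10)
})

test_that("high-agreement species pair together under the bootstrap", {
  agree <- matrix(1 / 3, 4, 4)
  agree[1, 2] <- agree[2, 1] <- 1
  diag(agree) <- 1
  sib <- 0L
  n_rep <- 40L
  for (seed in seq_len(n_rep)) {
    m <- simulate_call_matrix(46, 4, agreement = agree, seed = seed)
    tr <- neighbor_joining(mean_character_distance(m))
    key <- paste(sort(c("sp_3", "sp_4")), collapse = "|")
    sib <- sib + (key %in% eggspot:::tree_splits(tr))
  }
  # sibling split {sp_1, sp_2} is equivalent to {sp_3, sp_4} on 4 taxa
  expect_gte(sib / n_rep, 0.95)
})

test_that("bootstrap support is complete on a degenerate one-row matrix", {
  m <- matrix(rep(c(0L, 1L, 2L, 0L), each = 10), 10, 4,
              dimnames = list(NULL, c("w", "x", "y", "z")))
  tr <- bootstrap_support(m, n_reps = 20, seed = 5)
  sup <- attr(tr, "support")
  expect_true(all(sup == 100))
  expect_error(bootstrap_support(m, n_reps = 0), "at least 1")
})

test_that("bootstrap is seeded and reproducible", {
  m <- simulate_call_matrix(30, 4, agreement = 0.6, seed = 44)
  t1 <- bootstrap_support(m, n_reps = 50, seed = 7)
  t2 <- bootstrap_support(m, n_reps = 50, seed = 7)
  expect_identical(attr(t1, "support"), attr(t2, "support"))
  expect_identical(write_newick(t1), write_newick(t2))
})

test_that("Newick serialization round-trips through the reader", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  txt <- write_newick(tr)
  back <- read_newick(txt)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(sort(back$edge.length), sort(tr$edge.length))
  # via file, with support labels
  m <- simulate_call_matrix(30, 4, agreement = 0.7, seed = 3)
  tb <- bootstrap_support(m, n_reps = 25, seed = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tb, path)
  back2 <- read_newick(path)
  expect_setequal(back2$tip.label, tb$tip.label)
  expect_equal(as.numeric(ape::dist.topo(back2, tb)), 0)
  expect_identical(sort(back2$node.label), sort(tb$node.label))
})
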