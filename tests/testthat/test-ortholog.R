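# Hit filtering, all-species presence selection, plurality consensus,
# reference trimming and reading-frame validation.

make_hit <- function(pident, length, bitscore, qseqid = "g1",
                     species = "sp1") {
  data.frame(qseqid = qseqid, sseqid = "s", pident = pident,
             length = length, mismatch = 0L, gapopen = 0L, qstart = 1L,
             qend = length, sstart = 1L, send = length, evalue = 1e-60,
             bitscore = bitscore, species = species,
             stringsAsFactors = FALSE)
}

test_that("hit filtering uses strict inequalities and preserves order", {
  hits <- rbind(make_hit(95, 250, 300),    # retained
                make_hit(90, 250, 300),    # identity exactly at threshold
                make_hit(95, 200, 300),    # length exactly at threshold
                make_hit(95, 250, 200),    # bit score exactly at threshold
                make_hit(91, 201, 201))    # barely retained
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$pident, c(95, 91))
  expect_equal(nrow(filter_hits(hits[0, ])), 0L)
})

test_that("filtering is idempotent and monotone in thresholds", {
  hits <- simulate_hit_table(200, 0.5, seed = 17)
  kept <- filter_hits(hits)
  expect_identical(filter_hits(kept), kept)
  for (args in list(list(min_identity = 95), list(min_length = 400),
                    list(min_bitscore = 500))) {
    stricter <- do.call(filter_hits, c(list(hits), args))
    expect_lte(nrow(stricter), nrow(kept))
    expect_true(all(stricter$qseqid %in% kept$qseqid))
  }
})

test_that("genes are retained only with hits in all required species", {
  hits <- rbind(
    make_hit(95, 300, 300, "geneA", "sp1"),
    make_hit(95, 300, 300, "geneA", "sp2"),
    make_hit(95, 300, 300, "geneA", "sp3"),
    make_hit(95, 300, 300, "geneB", "sp1"),
    make_hit(95, 300, 300, "geneB", "sp2"),
    make_hit(95, 300, 300, "geneC", "sp2")
  )
  sel <- select_genes_present_in_all(hits, c("sp1", "sp2", "sp3"))
  expect_identical(sel, "geneA")
  sel2 <- select_genes_present_in_all(hits, c("sp1", "sp2"))
  expect_identical(sel2, c("geneA", "geneB"))
  expect_error(select_genes_present_in_all(hits, character(0)), "non-empty")
})

test_that("blast tabular round trip skips malformed rows with a tally", {
  hits <- simulate_hit_table(20, 0.5, seed = 23)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blast_hits(hits, path)
  lines <- readLines(path)
  lines <- append(lines, c("truncated\trow", "not\tnumeric\tX\tY\tZ\ta\tb\tc\td\te\tf\tg"), after = 3)
  writeLines(lines, path)
  expect_warning(back <- read_blast_hits(path), "2 malformed")
  expect_equal(nrow(back), 20L)
  expect_equal(attr(back, "n_skipped"), 2L)
  expect_equal(back$pident, hits$pident)
  expect_equal(back$bitscore, hits$bitscore)
})

test_that("plurality consensus matches hand-counted examples", {
  expect_equal(build_consensus(c("ACGT", "ACGA")), "ACGn")
  expect_equal(build_consensus(c("ACGT", "ACGT", "ACCT")), "ACGT")
  # a single unit-weight row never reaches the 1.5 cut-off
  expect_equal(build_consensus("ACGT"), "nnnn")
  # with plurality at or below the weight, a single row is returned as-is
  expect_equal(build_consensus("ACGT", plurality = 1), "ACGT")
  # ties at the maximum weight yield the unknown symbol
  expect_equal(build_consensus(c("AAAA", "CCCC"), plurality = 1), "nnnn")
  # gaps carry no weight; gap-only columns yield the unknown symbol
  expect_equal(build_consensus(c("A-G", "A-G")), "AnG")
  # sequence weights are honored
  expect_equal(build_consensus(c("AAAA", "CCCC"), weights = c(2, 1)), "AAAA")
  expect_equal(nchar(build_consensus(c("ACGTACGT", "ACGAACGA"))), 8L)
  expect_error(build_consensus(c("AC", "ACG")), "equal length")
})

test_that("reference trimming drops exactly the reference gap columns", {
  aln <- c(ref = "AT-G", other = "ATCG")
  out <- trim_to_reference(aln, "ref")
  expect_equal(out[["ref"]], "ATG")
  expect_equal(out[["other"]], "ATG")
  expect_equal(nchar(out[["ref"]]),
               nchar(gsub("-", "", aln[["ref"]])))
  # ungapped reference leaves the alignment unchanged
  aln2 <- c(ref = "ATGC", other = "AT-C")
  expect_identical(trim_to_reference(aln2, "ref"), aln2)
  expect_error(trim_to_reference(aln, "missing"), "not present")
})

test_that("frame validation fails only on internal stops", {
  aln <- c(good = "ATGGAATTT", bad = "ATGTAATTT", gappy = "ATG---TTT",
           terminal = "ATGGAATAA")
  rep <- validate_frame(aln)
  expect_true(rep$pass[rep$id == "good"])
  expect_false(rep$pass[rep$id == "bad"])
  expect_true(rep$pass[rep$id == "gappy"])       # gap codon skipped
  expect_true(rep$pass[rep$id == "terminal"])    # terminal stop allowed
  expect_false(attr(rep, "alignment_pass"))
  expect_error(validate_frame(c(a = "ATGA")), "divisible by 3")
})

test_that("paralog heuristic flags multi-transcript species without discarding", {
  hits <- rbind(make_hit(95, 300, 300, "geneA", "sp1"),
                make_hit(95, 300, 300, "geneA", "sp1"),
                make_hit(95, 300, 300, "geneB", "sp1"))
  hits$sseqid <- c("t1", "t2", "t3")
  fl <- flag_paralogs(hits)
  expect_equal(nrow(fl), 1L)
  expect_equal(fl$gene, "geneA")
  expect_equal(fl$n_transcripts, 2L)
})
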