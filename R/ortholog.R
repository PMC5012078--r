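# Ortholog-set preparation: BLAST-hit filtering, all-species presence
# selection, plurality consensus, reference trimming, frame validation.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

.blast6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a BLAST outfmt-6-style tabular hit file
#'
#' Expects the standard 12 columns, optionally followed by a 13th species
#' column. Malformed rows (wrong field count or non-numeric numeric fields)
#' are skipped with a warning carrying their line numbers; the skip tally
#' is attached as attribute `n_skipped`.
#'
#' @param path TSV path.
#' @param species Species label to assign when the file has no 13th column.
#' @return Data frame of hits with a `species` column.
#' @export
read_blast_hits <- function(path, species = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf %in% c(12L, 13L)
  rows <- lapply(which(ok), function(i) {
    f <- fields[[i]]
    num <- suppressWarnings(as.numeric(f[c(3:10, 11, 12)]))
    if (anyNA(num)) return(NULL)
    data.frame(qseqid = f[1], sseqid = f[2], pident = num[1],
               length = as.integer(num[2]), mismatch = as.integer(num[3]),
               gapopen = as.integer(num[4]), qstart = as.integer(num[5]),
               qend = as.integer(num[6]), sstart = as.integer(num[7]),
               send = as.integer(num[8]), evalue = num[9], bitscore = num[10],
               species = if (length(f) == 13L) f[13] else species,
               stringsAsFactors = FALSE)
  })
  bad <- which(!ok)
  bad <- c(bad, which(ok)[vapply(rows, is.null, logical(1))])
  if (length(bad))
    warning(length(bad), " malformed hit row(s) skipped (lines ",
            paste(sort(bad), collapse = ", "), ")")
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- stats::setNames(
    data.frame(matrix(nrow = 0, ncol = 13)), c(.blast6_cols, "species"))
  attr(out, "n_skipped") <- length(bad)
  out
}

#' Write hits as BLAST outfmt-6-style TSV
#'
#' @param hits Data frame of hits.
#' @param path Output path.
#' @param keep_species Whether to emit the species column as a 13th field.
#' @export
write_blast_hits <- function(hits, path, keep_species = TRUE) {
  cols <- .blast6_cols
  if (keep_species && "species" %in% names(hits)) cols <- c(cols, "species")
  utils::write.table(hits[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter BLAST hits on identity, alignment length and bit score
#'
#' A hit is retained iff it strictly exceeds every threshold
#' (identity > 90, length > 200 bp, bit score > 200 by default); input
#' order is preserved. Filtering is idempotent and monotone in the
#' thresholds.
#'
#' @param hits Data frame with `pident`, `length`, `bitscore` columns.
#' @param min_identity,min_length,min_bitscore Exclusive lower bounds.
#' @return The retained rows of `hits`.
#' @export
filter_hits <- function(hits, min_identity = 90, min_length = 200,
                        min_bitscore = 200) {
  if (any(c(min_identity, min_length, min_bitscore) < 0))
    stop("thresholds must be non-negative")
  keep <- hits$pident > min_identity &
    hits$length > min_length &
    hits$bitscore > min_bitscore
  hits[which(keep), , drop = FALSE]
}

#' Select genes with at least one retained hit in every required species
#'
#' @param hits Data frame of (already filtered) hits.
#' @param required_species Character vector of species that must all be hit.
#' @param gene_col,species_col Column names holding the gene identifier and
#'   the species label.
#' @return Sorted character vector of gene identifiers present in all
#'   required species.
#' @export
select_genes_present_in_all <- function(hits, required_species,
                                        gene_col = "qseqid",
                                        species_col = "species") {
  if (length(required_species) == 0L)
    stop("required_species must be non-empty")
  if (nrow(hits) == 0L) return(character(0))
  tab <- unique(hits[c(gene_col, species_col)])
  counts <- tapply(tab[[species_col]], tab[[gene_col]],
                   function(s) all(required_species %in% s))
  sort(names(counts)[counts])
}

#' Build a plurality consensus across aligned sequences
#'
#' Per column, sequence weights are summed per residue symbol (gaps carry
#' no weight); the maximum-weight residue is emitted iff its weight meets
#' the plurality cut-off and is uniquely maximal, otherwise the unknown
#' symbol is emitted. This mirrors the `cons` utility's plurality rule
#' (default cut-off 1.5 with unit sequence weights).
#'
#' @param seqs Character vector of equal-length aligned sequences.
#' @param plurality Minimum summed weight for a consensus residue (> 0).
#' @param weights Per-sequence weights (recycled; default 1).
#' @param unknown_symbol Symbol emitted where there is no consensus.
#' @return Single consensus string of the alignment length.
#' @export
build_consensus <- function(seqs, plurality = 1.5, weights = 1,
                            unknown_symbol = "n") {
  if (length(seqs) < 1L) stop("need at least one sequence")
  if (plurality <= 0) stop("plurality must be positive")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal length")
  weights <- rep_len(weights, length(seqs))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  out <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    keep <- col != "-" & col != "."
    if (!any(keep)) return(unknown_symbol)
    w <- tapply(weights[keep], col[keep], sum)
    mx <- max(w)
    if (mx < plurality || sum(w == mx) > 1L) unknown_symbol
    else names(w)[which.max(w)]
  }, character(1))
  paste(out, collapse = "")
}

#' Trim alignment columns to an ungapped reference
#'
#' Removes every column where the reference sequence has a gap; the output
#' length equals the reference's ungapped length.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param reference_id Name of the reference sequence.
#' @return Named character vector of trimmed sequences (reference included).
#' @export
trim_to_reference <- function(seqs, reference_id) {
  if (!reference_id %in% names(seqs))
    stop("reference '", reference_id, "' not present in alignment")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length")
  ref <- strsplit(seqs[[reference_id]], "")[[1]]
  keep <- ref != "-" & ref != "."
  vapply(seqs, function(s)
    paste(strsplit(s, "")[[1]][keep], collapse = ""), character(1))
}

#' Validate reading frame: no internal stop codons
#'
#' Translates each sequence in frame 0, skipping codons that contain a gap
#' or ambiguity symbol; a sequence fails iff an internal (non-terminal)
#' codon is a stop. The alignment passes iff all sequences pass.
#'
#' @param seqs Named character vector of equal-length sequences whose
#'   length is divisible by 3.
#' @return Data frame (`id`, `n_codons`, `n_skipped`, `n_internal_stops`,
#'   `pass`) with attribute `alignment_pass`.
#' @export
validate_frame <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences must have equal length")
  if (nchar(seqs[[1]]) %% 3L != 0L)
    stop("alignment length must be divisible by 3")
  code <- genetic_code()
  rows <- lapply(seq_along(seqs), function(i) {
    cods <- split_codons(seqs[[i]])
    plain <- !grepl("[^ACGT]", cods)
    is_stop <- plain & unname(code[cods] == "*")
    is_stop[is.na(is_stop)] <- FALSE
    internal <- is_stop & seq_along(cods) < length(cods)
    data.frame(id = names(seqs)[i] %||% paste0("seq_", i),
               n_codons = length(cods), n_skipped = sum(!plain),
               n_internal_stops = sum(internal), pass = !any(internal),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alignment_pass") <- all(out$pass)
  out
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || is.na(a[1])) b else a
}

#' Flag possible recent paralogs in a consensus grouping
#'
#' The study discarded alignments with paralogous sequences by visual
#' inspection; no algorithmic criterion exists, so this heuristic only
#' flags (never discards) genes where more than one transcript of a single
#' species survives consensus grouping.
#'
#' @param hits Data frame of retained hits with gene, species and subject
#'   columns.
#' @param gene_col,species_col,transcript_col Column names.
#' @return Data frame (`gene`, `species`, `n_transcripts`,
#'   `flag_paralog_review`) for flagged combinations (0 rows when none).
#' @export
flag_paralogs <- function(hits, gene_col = "qseqid",
                          species_col = "species",
                          transcript_col = "sseqid") {
  if (nrow(hits) == 0L)
    return(data.frame(gene = character(0), species = character(0),
                      n_transcripts = integer(0),
                      flag_paralog_review = logical(0)))
  key <- paste(hits[[gene_col]], hits[[species_col]], sep = "\r")
  n_tr <- tapply(hits[[transcript_col]], key,
                 function(x) length(unique(x)))
  flagged <- n_tr[n_tr > 1L]
  parts <- strsplit(names(flagged), "\r", fixed = TRUE)
  data.frame(
    gene = vapply(parts, `[`, character(1), 1),
    species = vapply(parts, `[`, character(1), 2),
    n_transcripts = as.integer(flagged),
    flag_paralog_review = TRUE,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
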