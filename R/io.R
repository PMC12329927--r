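# File-format plumbing. Sequence containers on disk are standard FASTA /
# 4-line FASTQ (Sanger Phred+33) handled through Biostrings; in memory the
# pipeline passes plain data frames (id, seq, qual) for speed.

#' Read and write FASTA
#'
#' @param path file path.
#' @return `read_fasta` gives a data.frame with columns `id` and `seq`
#'   (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(x), seq = toupper(as.character(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fasta
#' @param seqs data.frame with columns `id`, `seq`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write 4-line FASTQ (Phred+33)
#'
#' @param path file path.
#' @return `read_fastq` gives a data.frame with columns `id`, `seq`, `qual`
#'   (`qual` is the encoded quality string; decode with [phred_decode()]).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred")
  data.frame(id = names(x), seq = toupper(as.character(x)),
             qual = as.character(Biostrings::quality(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Write a reference database as FASTA plus rank-delimited taxonomy
#'
#' The taxonomy file uses the common `accession<TAB>k__...;p__...;...;s__...;`
#' dialect, one entry per line.
#'
#' @param db a `reference_db` object (see [build_reference_db()]).
#' @param dir output directory (created if absent).
#' @return the two file paths, invisibly.
#' @export
write_reference_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(db$name, "_", db$marker, ".fasta"))
  tax <- file.path(dir, paste0(db$name, "_", db$marker, ".tax"))
  write_fasta(data.frame(id = db$entries$accession, seq = db$entries$sequence),
              fa)
  pref <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  lin <- apply(db$entries[, RANKS], 1, function(r) {
    paste0(paste0(pref, r, collapse = ";"), ";")
  })
  writeLines(paste(db$entries$accession, lin, sep = "\t"), tax)
  invisible(c(fasta = fa, taxonomy = tax))
}

#' Read a rank-delimited taxonomy file
#'
#' @param path taxonomy file written by [write_reference_db()].
#' @return data.frame with `accession` plus one column per rank.
#' @export
read_taxonomy <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad)) {
    stop(sprintf("malformed taxonomy line %d in %s: expected 'accession<TAB>lineage'",
                 bad[1], path))
  }
  acc <- vapply(parts, `[[`, character(1), 1)
  lin <- vapply(parts, `[[`, character(1), 2)
  fields <- strsplit(sub(";$", "", lin), ";", fixed = TRUE)
  if (any(lengths(fields) != length(RANKS))) {
    stop(sprintf("malformed lineage in %s: expected %d ranks", path, length(RANKS)))
  }
  m <- do.call(rbind, fields)
  m <- sub("^[a-z]__", "", m)
  out <- data.frame(accession = acc, m, stringsAsFactors = FALSE)
  names(out) <- c("accession", RANKS)
  out
}

#' Write a tab-separated table
#'
#' Thin wrapper fixing the dialect (no quotes, no row names) used for all
#' pipeline outputs (truth tables, OTU memberships, calls, metrics, sweeps).
#'
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
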