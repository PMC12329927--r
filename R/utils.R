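#' @keywords internal
NULL

# Taxonomic ranks used throughout, outermost first.
RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus", "species")

# Placeholder suffix conventions for unannotated names: a species entry
# truncated at genus carries "<Genus> sp"; a rank with no information at all
# carries "unclassified".
UNANNOTATED_SPECIES_SUFFIX <- " sp"
UNCLASSIFIED <- "unclassified"

#' Derive a reproducible sub-seed for one operation on one entity
#'
#' Every stochastic operation draws from its own RNG stream seeded by
#' (global seed, operation name, entity id), so regenerating one entity is
#' independent of generation order.
#'
#' @param global_seed integer master seed.
#' @param op operation name, e.g. "simulate_reads".
#' @param entity entity identifier, e.g. a DMC id.
#' @return a positive integer seed below 2^31.
#' @export
derive_seed <- function(global_seed, op, entity = "") {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1)
  mod <- 2147483629
  s <- utf8ToInt(paste(op, entity, sep = "/"))
  h <- 0
  for (ch in s) h <- (h * 131 + ch) %% mod
  h <- (h + (abs(global_seed) %% mod) * 1103) %% mod
  as.integer(h %% (mod - 2L) + 1L)
}

#' Reverse complement of plain nucleotide strings
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Random nucleotide string(s); assumes the RNG is already seeded.
random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Substitute n_edits randomly chosen positions with a different base.
mutate_seq <- function(seq, n_edits) {
  if (n_edits <= 0) return(seq)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(bases), min(n_edits, length(bases)))
  for (p in pos) {
    bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
  }
  paste(bases, collapse = "")
}

#' Phred+33 encoding helpers
#'
#' @param q integer vector of Phred qualities, or a quality string.
#' @return `phred_encode` gives a Sanger-encoded string; `phred_decode` the
#'   integer qualities.
#' @export
phred_encode <- function(q) intToUtf8(as.integer(q) + 33L)

#' @rdname phred_encode
#' @export
phred_decode <- function(q) utf8ToInt(q) - 33L

# First whitespace token of a binomial = genus.
genus_of <- function(species) sub("\\s.*$", "", species)

# Longest single-base run length of each sequence.
longest_homopolymer <- function(x) {
  vapply(x, function(s) {
    r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

# Count of non-ACGT symbols per sequence (case-folded upstream).
count_ambiguities <- function(x) {
  nchar(x) - nchar(gsub("[^ACGT]", "", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
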