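# Read preprocessing: quality trimming, pair merging, marker extraction by
# flank (anchor) trimming, and ambiguity/homopolymer screening. Every input
# read is accounted for exactly once in the stage logs.

#' Quality-trim a single read
#'
#' Trimming order is LEADING, then TRAILING, then SLIDINGWINDOW: leading and
#' trailing bases below their thresholds are removed; the survivor is then
#' scanned 5'->3' and cut at the start of the first window of `window` bases
#' whose mean quality falls below `window_q`. Survivors shorter than
#' `min_len` are dropped.
#'
#' @param seq nucleotide string.
#' @param qual integer Phred qualities (same length as `seq`).
#' @param leading_q,trailing_q,window,window_q,min_len trimming thresholds.
#' @return list(`status` = "kept"/"dropped", `seq`, `qual`).
#' @export
quality_trim <- function(seq, qual, leading_q = 10, trailing_q = 10,
                         window = 4, window_q = 20, min_len = 10) {
  if (is.character(qual)) qual <- phred_decode(qual)
  if (length(qual) != nchar(seq)) {
    stop("quality_trim: qualities must match sequence length")
  }
  from <- 1L
  while (from <= length(qual) && qual[from] < leading_q) from <- from + 1L
  to <- length(qual)
  while (to >= from && qual[to] < trailing_q) to <- to - 1L
  if (to >= from) {
    q <- qual[from:to]
    n <- length(q)
    if (n >= window) {
      cs <- cumsum(q)
      means <- (cs[window:n] - c(0, cs)[1:(n - window + 1)]) / window
      bad <- which(means < window_q)
      if (length(bad)) to <- from + bad[1] - 2L
    }
  }
  if (to - from + 1L < min_len) {
    return(list(status = "dropped", seq = "", qual = integer()))
  }
  list(status = "kept", seq = substr(seq, from, to), qual = qual[from:to])
}

#' Quality-trim paired reads, keeping only intact pairs
#'
#' A pair is dropped as soon as either mate is dropped, so downstream
#' merging always sees both mates.
#'
#' @param fwd,rev data.frames with `id`, `seq`, `qual` (encoded string).
#' @param ... thresholds passed to [quality_trim()].
#' @return list(`fwd`, `rev`, `log` with per-pair status).
#' @export
quality_trim_pairs <- function(fwd, rev, ...) {
  stopifnot(nrow(fwd) == nrow(rev))
  # identical quality strings trim identically; memoise the trim window
  memo <- new.env(parent = emptyenv())
  n <- nrow(fwd)
  keep <- logical(n)
  fs <- fr <- character(n); fq <- rq <- character(n)
  for (i in seq_len(n)) {
    tf <- quality_trim_cached(memo, fwd$seq[i], fwd$qual[i], ...)
    if (tf$status == "dropped") next
    tr <- quality_trim_cached(memo, rev$seq[i], rev$qual[i], ...)
    if (tr$status == "dropped") next
    keep[i] <- TRUE
    fs[i] <- tf$seq; fq[i] <- tf$qual
    fr[i] <- tr$seq; rq[i] <- tr$qual
  }
  list(
    fwd = data.frame(id = fwd$id[keep], seq = fs[keep], qual = fq[keep],
                     stringsAsFactors = FALSE),
    rev = data.frame(id = rev$id[keep], seq = fr[keep], qual = rq[keep],
                     stringsAsFactors = FALSE),
    log = data.frame(id = fwd$id, status = ifelse(keep, "kept", "dropped"),
                     stringsAsFactors = FALSE)
  )
}

# Memoised coordinate trimming: the simulator's quality profile is shared by
# all reads of a run, so the trim window depends only on the quality string.
quality_trim_cached <- function(memo, seq, qual_str, ...) {
  got <- memo[[qual_str]]
  if (is.null(got)) {
    got <- trim_bounds(phred_decode(qual_str), ...)
    memo[[qual_str]] <- got
  }
  if (got$status == "dropped") return(list(status = "dropped"))
  list(status = "kept",
       seq = substr(seq, got$from, got$to),
       qual = substr(qual_str, got$from, got$to))
}

trim_bounds <- function(qual, leading_q = 10, trailing_q = 10,
                        window = 4, window_q = 20, min_len = 10) {
  from <- 1L
  while (from <= length(qual) && qual[from] < leading_q) from <- from + 1L
  to <- length(qual)
  while (to >= from && qual[to] < trailing_q) to <- to - 1L
  if (to >= from) {
    q <- qual[from:to]
    n <- length(q)
    if (n >= window) {
      cs <- cumsum(q)
      means <- (cs[window:n] - c(0, cs)[1:(n - window + 1)]) / window
      bad <- which(means < window_q)
      if (length(bad)) to <- from + bad[1] - 2L
    }
  }
  if (to - from + 1L < min_len) list(status = "dropped")
  else list(status = "kept", from = from, to = to)
}

#' Merge one read pair into a contig
#'
#' The reverse mate is reverse-complemented, then slid along the forward
#' read without gaps; the overlap maximising matches-minus-mismatches wins.
#' At overlap mismatches the base with the higher quality is kept; quality
#' ties give 'N'. Pairs with no acceptable overlap are reported unmerged
#' (an outcome, not an error).
#'
#' @param fwd_seq,fwd_qual,rev_seq,rev_qual sequences and qualities (encoded
#'   strings or integer vectors); `rev_*` as sequenced (will be
#'   reverse-complemented here).
#' @param min_overlap minimal overlap length (default 10).
#' @return list(`status`, and for merged pairs `seq` and `qual` string).
#' @export
merge_pair <- function(fwd_seq, fwd_qual, rev_seq, rev_qual, min_overlap = 10) {
  qf <- if (is.character(fwd_qual)) phred_decode(fwd_qual) else as.integer(fwd_qual)
  qr <- if (is.character(rev_qual)) phred_decode(rev_qual) else as.integer(rev_qual)
  res <- merge_pair_cpp(fwd_seq, revcomp(rev_seq), qf, rev(qr),
                        min_overlap = min_overlap)
  if (res$status != "merged") return(list(status = "unmerged"))
  list(status = "merged", seq = res$seq, qual = phred_encode(res$qual))
}

#' Merge all pairs of a run
#'
#' @param fwd,rev data.frames (`id`, `seq`, `qual`).
#' @param min_overlap minimal overlap length.
#' @return list(`contigs` data.frame (`id`, `seq`, `qual`), `log`).
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 10) {
  n <- nrow(fwd)
  seqs <- character(n); quals <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_pair(fwd$seq[i], fwd$qual[i], rev$seq[i], rev$qual[i],
                    min_overlap = min_overlap)
    if (m$status == "merged") {
      ok[i] <- TRUE; seqs[i] <- m$seq; quals[i] <- m$qual
    }
  }
  id <- sub("/[12]$", "", fwd$id)
  list(contigs = data.frame(id = id[ok], seq = seqs[ok], qual = quals[ok],
                            stringsAsFactors = FALSE),
       log = data.frame(id = id, status = ifelse(ok, "merged", "unmerged"),
                        stringsAsFactors = FALSE))
}

#' Extract the marker region between conserved flank anchors
#'
#' Returns the subsequence strictly between the best ungapped matches of the
#' 5' and 3' anchors, each allowing up to `max_mismatch` mismatches. A
#' contig whose 5' anchor is partially eroded is still accepted when at
#' least `min_anchor` of the anchor's trailing bases match at its very
#' start, emulating extraction software occasionally failing to recognise
#' the first conserved bases.
#'
#' @param contig nucleotide string.
#' @param flank5,flank3 anchor sequences.
#' @param max_mismatch mismatches tolerated per anchor (default 2).
#' @param min_anchor minimal eroded 5' anchor length accepted (default 15).
#' @return list(`status` = "extracted"/"rejected", `seq`, `reason`).
#' @export
extract_marker <- function(contig, flank5, flank3,
                           max_mismatch = 2, min_anchor = 15) {
  contig <- toupper(contig)
  l5 <- nchar(flank5)
  hit5 <- find_anchor_cpp(contig, flank5)
  start <- NA_integer_
  if (hit5[2] >= 0 && hit5[2] <= max_mismatch) {
    start <- hit5[1] + l5
  } else {
    # eroded 5' anchor: contig begins inside the anchor
    for (keep in seq(l5 - 1, min_anchor)) {
      if (nchar(contig) < keep) next
      tail5 <- substr(flank5, l5 - keep + 1, l5)
      if (hamming_cpp(substr(contig, 1, keep), tail5) <= max_mismatch) {
        start <- keep + 1L
        break
      }
    }
  }
  if (is.na(start)) {
    return(list(status = "rejected", reason = "missing_5prime_anchor"))
  }
  rest <- substr(contig, start, nchar(contig))
  hit3 <- find_anchor_cpp(rest, flank3)
  if (hit3[2] < 0 || hit3[2] > max_mismatch) {
    return(list(status = "rejected", reason = "missing_3prime_anchor"))
  }
  marker <- substr(rest, 1, hit3[1] - 1)
  if (nchar(marker) == 0) {
    return(list(status = "rejected", reason = "empty_marker"))
  }
  list(status = "extracted", seq = marker, reason = NA_character_)
}

#' Extract markers from all contigs
#'
#' @param contigs data.frame (`id`, `seq`).
#' @param flank5,flank3 anchors (see [MARKER_FLANKS] defaults via
#'   [preprocess_reads()]).
#' @param ... passed to [extract_marker()].
#' @return list(`markers` data.frame (`id`, `seq`), `log`).
#' @export
extract_markers <- function(contigs, flank5, flank3, ...) {
  n <- nrow(contigs)
  out <- character(n); reason <- character(n); ok <- logical(n)
  # contigs are highly redundant; extract once per unique sequence
  uniq <- !duplicated(contigs$seq)
  cache <- new.env(parent = emptyenv())
  for (s in contigs$seq[uniq]) {
    cache[[s]] <- extract_marker(s, flank5, flank3, ...)
  }
  for (i in seq_len(n)) {
    r <- cache[[contigs$seq[i]]]
    if (r$status == "extracted") { ok[i] <- TRUE; out[i] <- r$seq }
    else reason[i] <- r$reason
  }
  list(markers = data.frame(id = contigs$id[ok], seq = out[ok],
                            stringsAsFactors = FALSE),
       log = data.frame(id = contigs$id,
                        status = ifelse(ok, "extracted", "rejected"),
                        reason = ifelse(ok, NA_character_, reason),
                        stringsAsFactors = FALSE))
}

#' Screen sequences for ambiguities and homopolymers
#'
#' A sequence is removed iff it has more than `max_ambiguities` non-ACGT
#' symbols or a single-base run longer than `max_homopolymer` bases (both
#' bounds inclusive on the retained side). Screening is order-independent
#' and idempotent.
#'
#' @param seqs data.frame (`id`, `seq`).
#' @param max_ambiguities,max_homopolymer screening thresholds (default 10).
#' @return list(`kept` data.frame, `log` recording which rule fired).
#' @export
screen_sequences <- function(seqs, max_ambiguities = 10, max_homopolymer = 10) {
  stopifnot(max_ambiguities >= 0, max_homopolymer >= 0)
  s <- toupper(seqs$seq)
  amb <- count_ambiguities(s)
  # regex probe first (cheap), exact run length only for suspects
  suspect <- grepl(sprintf("([ACGTN])\\1{%d}", max_homopolymer), s)
  run <- rep(0L, length(s))
  run[suspect] <- longest_homopolymer(s[suspect])
  bad_amb <- amb > max_ambiguities
  bad_run <- run > max_homopolymer
  rule <- ifelse(bad_amb & bad_run, "ambiguities+homopolymer",
                 ifelse(bad_amb, "ambiguities",
                        ifelse(bad_run, "homopolymer", NA_character_)))
  keep <- !(bad_amb | bad_run)
  list(kept = seqs[keep, , drop = FALSE],
       log = data.frame(id = seqs$id, status = ifelse(keep, "kept", "removed"),
                        rule = rule, stringsAsFactors = FALSE))
}

#' Run the full preprocessing chain on one community's paired reads
#'
#' quality trimming -> pair merging -> marker extraction -> screening.
#' The returned log counts satisfy the pipeline conservation invariant:
#' every input pair is accounted for exactly once at each stage.
#'
#' @param fwd,rev paired reads (`id`, `seq`, `qual`).
#' @param marker "ITS1" or "ITS2" (selects the default anchors).
#' @param flanks optional c(5' anchor, 3' anchor) overriding the defaults.
#' @param ... thresholds for the stages.
#' @return list(`markers`, `counts`, `logs`).
#' @export
preprocess_reads <- function(fwd, rev, marker, flanks = NULL, ...) {
  flanks <- flanks %||% MARKER_FLANKS[[marker]]
  tr <- quality_trim_pairs(fwd, rev)
  mg <- merge_pairs(tr$fwd, tr$rev)
  sc0 <- mg$contigs
  ex <- extract_markers(sc0, flanks[1], flanks[2])
  sc <- screen_sequences(ex$markers)
  counts <- c(pairs_in = nrow(fwd), pairs_trimmed = nrow(tr$fwd),
              merged = nrow(mg$contigs), extracted = nrow(ex$markers),
              screened = nrow(sc$kept))
  list(markers = sc$kept, counts = counts,
       logs = list(trim = tr$log, merge = mg$log, extract = ex$log,
                   screen = sc$log))
}
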