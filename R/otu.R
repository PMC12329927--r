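# OTU construction: dereplication, abundance-aware pre-clustering, de novo
# chimera removal, pairwise distances, MCC-optimising clustering at 0.03,
# rare-OTU filtering and representative selection.

#' Collapse identical sequences into weighted unique records
#'
#' Exact-string grouping; the weight of a record is the number of collapsed
#' reads and its id the first-seen read id. Total weight is conserved.
#'
#' @param seqs data.frame (`id`, `seq`), optionally with a `weight` column
#'   (default 1 per record).
#' @return data.frame (`id`, `seq`, `weight`) ordered by decreasing weight,
#'   ties by sequence.
#' @export
dereplicate <- function(seqs) {
  w <- seqs$weight %||% rep(1L, nrow(seqs))
  agg <- tapply(w, seqs$seq, sum)
  first <- !duplicated(seqs$seq)
  ids <- setNames(seqs$id[first], seqs$seq[first])
  out <- data.frame(id = unname(ids[names(agg)]), seq = names(agg),
                    weight = as.integer(agg), stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Absorb rare error variants into abundant sequences (pre-clustering)
#'
#' Sequences are processed in decreasing weight (ties broken by
#' lexicographic sequence order); each sequence merges its weight into the
#' first already-retained sequence within `max_diffs` ungapped differences
#' (Hamming for equal lengths; for unequal lengths the best ungapped overlay,
#' with the length difference counting toward the budget). Total weight is
#' conserved.
#'
#' @param derep dereplicated data.frame (`id`, `seq`, `weight`).
#' @param max_diffs mismatch budget (default 2).
#' @return list(`seqs` = retained records with augmented weights, `log` =
#'   data.frame mapping each absorbed child to its parent).
#' @export
precluster <- function(derep, max_diffs = 2) {
  ord <- order(-derep$weight, derep$seq)
  d <- derep[ord, , drop = FALSE]
  n <- nrow(d)
  parent <- rep(NA_integer_, n)
  retained <- integer(0)
  for (i in seq_len(n)) {
    hit <- 0L
    for (r in retained) {
      if (abs(nchar(d$seq[i]) - nchar(d$seq[r])) > max_diffs) next
      if (overlay_diffs_cpp(d$seq[i], d$seq[r], max_diffs) <= max_diffs) {
        hit <- r
        break
      }
    }
    if (hit > 0L) parent[i] <- hit else retained <- c(retained, i)
  }
  w <- d$weight
  for (i in which(!is.na(parent))) {
    # parents are always retained (processed earlier, by weight order)
    w[parent[i]] <- w[parent[i]] + w[i]
  }
  keep <- is.na(parent)
  merged <- which(!keep)
  log <- data.frame(child_id = d$id[merged], parent_id = d$id[parent[merged]],
                    child_weight = d$weight[merged], stringsAsFactors = FALSE)
  out <- data.frame(id = d$id[keep], seq = d$seq[keep],
                    weight = as.integer(w[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  list(seqs = out, log = log)
}

#' De novo two-parent chimera detection
#'
#' Queries are screened in ascending weight against candidate parent pairs
#' of at least `parent_ratio` times the query weight. A query is flagged
#' chimeric when some single-crossover combination of one parent's prefix
#' and another's suffix explains it with at least `min_improvement` fewer
#' mismatches than the best single parent, and each side shows at least
#' `min_side_identity` identity to its parent segment.
#'
#' @param seqs weighted, pre-clustered data.frame (`id`, `seq`, `weight`).
#' @param parent_ratio minimal parent/query weight ratio (default 2).
#' @param min_improvement required mismatch improvement (default 4).
#' @param min_side_identity per-side identity floor (default 0.8).
#' @return list(`kept`, `flagged`, `log`).
#' @export
detect_chimeras <- function(seqs, parent_ratio = 2, min_improvement = 4,
                            min_side_identity = 0.8) {
  n <- nrow(seqs)
  flagged <- logical(n)
  ord <- order(seqs$weight, seqs$seq) # ascending weight
  for (qi in ord) {
    parents <- which(!flagged & seqs$weight >= parent_ratio * seqs$weight[qi])
    parents <- setdiff(parents, qi)
    if (length(parents) < 2) next
    q <- seqs$seq[qi]
    lq <- nchar(q)
    pm <- lapply(parents, function(p) prefix_mismatch_cpp(q, seqs$seq[p]))
    tot <- vapply(pm, function(v) v[lq + 1], numeric(1))
    best_single <- min(tot)
    found <- FALSE
    for (ai in seq_along(parents)) {
      for (bi in seq_along(parents)) {
        if (ai == bi) next
        prefA <- pm[[ai]]
        prefB <- pm[[bi]]
        cross <- seq_len(lq - 1)
        mmA <- prefA[cross + 1]                 # mismatches on q[1..c]
        mmB <- tot[bi] - prefB[cross + 1]       # mismatches on q[(c+1)..lq]
        total <- mmA + mmB
        okA <- (cross - mmA) / cross >= min_side_identity
        okB <- ((lq - cross) - mmB) / (lq - cross) >= min_side_identity
        good <- total <= best_single - min_improvement & okA & okB
        if (any(good)) { found <- TRUE; break }
      }
      if (found) break
    }
    flagged[qi] <- found
  }
  list(kept = seqs[!flagged, , drop = FALSE],
       flagged = seqs[flagged, , drop = FALSE],
       log = data.frame(id = seqs$id, chimeric = flagged,
                        stringsAsFactors = FALSE))
}

#' Pairwise distances between marker sequences
#'
#' Distance = 1 - identity from a global alignment (match +1, mismatch -1,
#' gap open -2, gap extend -1). Identity counts matches over the aligned
#' columns with terminal gap columns excluded and each run of internal gap
#' columns compressed to a single difference (the dialect of the usual OTU
#' distance tools).
#'
#' @param seqs character vector of sequences (>= 2).
#' @return symmetric distance matrix.
#' @export
pairwise_distances <- function(seqs) {
  n <- length(seqs)
  if (n < 2) stop("pairwise_distances: need at least two sequences")
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    st <- align_batch_cpp(seqs[i], seqs[(i + 1):n],
                          match = 1, mismatch = -1, gap_open = -2, gap_ext = -1,
                          free_ends = FALSE)
    den <- st[, "matches"] + st[, "mismatches"] + st[, "gap_runs"]
    d <- ifelse(den > 0, (st[, "mismatches"] + st[, "gap_runs"]) / den, 1)
    D[i, (i + 1):n] <- d
    D[(i + 1):n, i] <- d
  }
  D
}

# Matthews correlation of a partition against the "within cutoff" pair
# relation. close: logical matrix (i, j close); assign: integer cluster ids.
partition_mcc <- function(close, assign) {
  n <- length(assign)
  together <- outer(assign, assign, "==")
  ut <- upper.tri(close)
  tp <- sum(close[ut] & together[ut])
  fp <- sum(!close[ut] & together[ut])
  fn <- sum(close[ut] & !together[ut])
  tn <- sum(!close[ut] & !together[ut])
  if (fp == 0 && fn == 0) return(1) # perfect partition (degenerate cases included)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Cluster sequences into OTUs
#'
#' `method = "opticlust"` starts from one OTU per sequence and repeatedly
#' moves single sequences (in decreasing-weight order, ties by id) to the
#' assignment maximising the Matthews correlation between "clustered
#' together" and "within the distance cutoff", until no move improves the
#' MCC or `max_iter` sweeps are done. `method = "greedy_baseline"` is
#' abundance-sorted complete linkage, kept as a comparison oracle.
#'
#' @param D distance matrix from [pairwise_distances()].
#' @param weights sequence weights (defaults to 1).
#' @param ids sequence ids for the deterministic tie order.
#' @param cutoff distance cutoff (default 0.03).
#' @param method "opticlust" or "greedy_baseline".
#' @param max_iter sweep limit for opticlust (default 100).
#' @return integer cluster assignment (1-based, renumbered by first use).
#' @export
cluster_otus <- function(D, weights = NULL, ids = NULL, cutoff = 0.03,
                         method = c("opticlust", "greedy_baseline"),
                         max_iter = 100) {
  method <- match.arg(method)
  n <- nrow(D)
  weights <- weights %||% rep(1, n)
  ids <- ids %||% as.character(seq_len(n))
  if (n == 1) return(1L)
  ord <- order(-weights, ids)
  close <- D <= cutoff
  diag(close) <- FALSE
  if (method == "greedy_baseline") {
    assign <- rep(0L, n)
    nxt <- 1L
    for (i in ord) {
      placed <- FALSE
      for (cl in seq_len(nxt - 1L)) {
        memb <- which(assign == cl)
        if (length(memb) && all(close[i, memb])) {
          assign[i] <- cl
          placed <- TRUE
          break
        }
      }
      if (!placed) { assign[i] <- nxt; nxt <- nxt + 1L }
    }
  } else {
    assign <- seq_len(n)
    best_mcc <- partition_mcc(close, assign)
    for (iter in seq_len(max_iter)) {
      improved <- FALSE
      for (i in ord) {
        cand <- unique(c(assign[-i], max(assign) + 1L))
        cur <- assign[i]
        best_c <- cur
        for (cl in cand) {
          if (cl == cur) next
          trial <- assign
          trial[i] <- cl
          m <- partition_mcc(close, trial)
          if (m > best_mcc + 1e-12) {
            best_mcc <- m
            best_c <- cl
          }
        }
        if (best_c != cur) {
          assign[i] <- best_c
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  as.integer(match(assign, unique(assign)))
}

#' Assemble OTUs from clustered sequences
#'
#' @param seqs data.frame (`id`, `seq`, `weight`).
#' @param assign cluster assignment from [cluster_otus()].
#' @param dmc_id community the sequences came from.
#' @return list(`table` one row per OTU with `otu_id`, `dmc_id`,
#'   `total_count`, `rep_id`, `rep_seq`; `members` one row per sequence).
#' @export
build_otus <- function(seqs, assign, dmc_id = NA_character_) {
  stopifnot(nrow(seqs) == length(assign))
  otus <- sort(unique(assign))
  reps <- pick_representatives(seqs, assign)
  tab <- data.frame(
    otu_id = sprintf("%s_OTU%03d", ifelse(is.na(dmc_id), "X", dmc_id), otus),
    dmc_id = dmc_id,
    total_count = as.integer(tapply(seqs$weight, assign, sum)[as.character(otus)]),
    rep_id = reps$id,
    rep_seq = reps$seq,
    stringsAsFactors = FALSE
  )
  members <- data.frame(otu_id = tab$otu_id[match(assign, otus)],
                        seq_id = seqs$id, weight = seqs$weight,
                        dmc_id = dmc_id, stringsAsFactors = FALSE)
  list(table = tab, members = members)
}

#' Representative sequence per OTU
#'
#' The member with maximal weight; ties go to the lexicographically smaller
#' sequence.
#'
#' @param seqs data.frame (`id`, `seq`, `weight`).
#' @param assign cluster assignment.
#' @return data.frame (`id`, `seq`), one row per cluster in cluster order.
#' @export
pick_representatives <- function(seqs, assign) {
  if (nrow(seqs) == 0 || !length(assign)) {
    stop("pick_representatives: empty OTU set")
  }
  otus <- sort(unique(assign))
  rows <- vapply(otus, function(cl) {
    memb <- which(assign == cl)
    if (!length(memb)) stop("pick_representatives: empty OTU")
    memb[order(-seqs$weight[memb], seqs$seq[memb])][1]
  }, integer(1))
  data.frame(id = seqs$id[rows], seq = seqs$seq[rows], stringsAsFactors = FALSE)
}

#' Remove rare OTUs
#'
#' An OTU is removed iff it is a singleton (when `drop_singletons`) or its
#' abundance fraction is at or below the threshold (inclusive `<=`). The
#' threshold can be overridden for sweep analyses; Sanger-mode runs skip
#' this filter entirely.
#'
#' @param otu_table data.frame with `total_count`.
#' @param min_fraction default threshold 0.0005 (0.05%).
#' @param drop_singletons remove OTUs of a single sequence (default TRUE).
#' @param threshold_override optional sweep threshold replacing
#'   `min_fraction`.
#' @return the surviving rows of `otu_table`.
#' @export
filter_rare <- function(otu_table, min_fraction = 0.0005,
                        drop_singletons = TRUE, threshold_override = NULL) {
  total <- sum(otu_table$total_count)
  if (total <= 0) stop("filter_rare: total read count must be positive")
  thr <- threshold_override %||% min_fraction
  frac <- otu_table$total_count / total
  drop <- (drop_singletons & otu_table$total_count == 1) | frac <= thr
  otu_table[!drop, , drop = FALSE]
}
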