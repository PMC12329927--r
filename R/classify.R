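# Three classification back-ends over a reference database: top-hit
# alignment search (strict/loose adjudication happens downstream), k-mer
# naive-Bayes with bootstrap confidence, and 1-nearest-neighbour. All three
# return a `classification_result` carrying an assigned lineage, the leading
# equivalence group of species names, and per-rank unclassified flags.

ALIGN_SCORING <- c(match = 2, mismatch = -3, gap_open = -5, gap_ext = -2)

new_classification_result <- function(otu_id, method, db, marker,
                                      species = NA_character_,
                                      genus = NA_character_,
                                      group = character(),
                                      identity = NA_real_, score = NA_real_,
                                      confidence = NULL,
                                      reason = NA_character_,
                                      hits = NULL, tie_note = NA_character_) {
  structure(list(otu_id = otu_id, method = method, db = db, marker = marker,
                 species = species, genus = genus, group = group,
                 identity = identity, score = score, confidence = confidence,
                 reason = reason, hits = hits, tie_note = tie_note),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<%s/%s %s: species=%s genus=%s group=%d%s>\n",
              x$method, x$db, x$otu_id,
              x$species %||% NA, x$genus %||% NA, length(x$group),
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

# Alignment statistics of one query against all database sequences.
# identity = matches / end-trimmed aligned columns (each gap column counts);
# coverage = fraction of the query inside the end-trimmed region.
query_db_alignments <- function(query, db, scoring = ALIGN_SCORING) {
  st <- align_batch_cpp(query, db$entries$sequence,
                        match = scoring[["match"]],
                        mismatch = scoring[["mismatch"]],
                        gap_open = scoring[["gap_open"]],
                        gap_ext = scoring[["gap_ext"]])
  identity <- ifelse(st[, "cols"] > 0, st[, "matches"] / st[, "cols"], 0)
  coverage <- (st[, "q_to"] - st[, "q_from"] + 1) / nchar(query)
  data.frame(accession = db$entries$accession,
             species = db$entries$species, genus = db$entries$genus,
             identity = identity, coverage = pmax(coverage, 0),
             score = st[, "score"], stringsAsFactors = FALSE)
}

#' Top-hit alignment search
#'
#' Aligns the query to every database entry (global, free end gaps, match
#' +2 / mismatch -3 / gap open -5 / gap extend -2), discards hits below the
#' identity and coverage floors, sorts the rest by (score, identity)
#' descending and returns the leading equivalence group: all hits tied with
#' the best on both identity and score. An empty hit list gives an
#' unclassified result with reason "no_hit".
#'
#' @param query representative sequence.
#' @param db a `reference_db`.
#' @param otu_id id recorded on the result.
#' @param min_identity,min_coverage hit retention floors (defaults 0.95,
#'   0.80).
#' @param hits precomputed [query_db_alignments()] table (optional reuse).
#' @return a `classification_result`; `group` holds the equivalence group's
#'   species names (unique, sorted).
#' @export
tophit_search <- function(query, db, otu_id = NA_character_,
                          min_identity = 0.95, min_coverage = 0.80,
                          hits = NULL) {
  if (nrow(db$entries) == 0) stop("tophit_search: empty database")
  h <- hits %||% query_db_alignments(query, db)
  h <- h[h$identity >= min_identity & h$coverage >= min_coverage, , drop = FALSE]
  if (nrow(h) == 0) {
    return(new_classification_result(otu_id, "tophit", db$name, db$marker,
                                     reason = "no_hit"))
  }
  h <- h[order(-h$score, -h$identity, h$accession), , drop = FALSE]
  tied <- h$score == h$score[1] & h$identity == h$identity[1]
  grp <- h[tied, , drop = FALSE]
  species <- sort(unique(grp$species))
  new_classification_result(
    otu_id, "tophit", db$name, db$marker,
    species = if (length(species) == 1) species else NA_character_,
    genus = if (length(unique(grp$genus)) == 1) grp$genus[1] else NA_character_,
    group = species, identity = grp$identity[1], score = grp$score[1],
    hits = h)
}

#' Fit the k-mer naive-Bayes model of a reference database
#'
#' Per-species k-mer presence model with add-half smoothing against the
#' database-wide k-mer prior: the probability of word w in species s is
#' (m(w, s) + Pw) / (M(s) + 1) with Pw = (n(w) + 0.5) / (N + 1), where m
#' counts the species' entries containing w, M the species' entries, n the
#' database entries containing w, and N all entries.
#'
#' @param db a `reference_db`.
#' @param k k-mer size (default 8).
#' @return model object used by [nb_classify()].
#' @export
nb_fit <- function(db, k = 8) {
  stopifnot(k >= 1)
  seqs <- db$entries$sequence
  sets <- lapply(seqs, kmer_set, k = k)
  vocab <- sort(unique(unlist(sets)))
  n_entries <- length(seqs)
  nw <- table(factor(unlist(lapply(sets, unique)), levels = vocab))
  pw <- (as.numeric(nw) + 0.5) / (n_entries + 1)
  species <- db$entries$species
  usp <- unique(species)
  m <- matrix(0L, length(usp), length(vocab),
              dimnames = list(usp, NULL))
  for (i in seq_along(seqs)) {
    j <- match(sets[[i]], vocab)
    m[species[i], j] <- m[species[i], j] + 1L
  }
  Ms <- as.numeric(table(factor(species, levels = usp)))
  # log word probabilities per species (species x vocab)
  logp <- log(sweep(m, 2, pw, "+")) - log(Ms + 1)
  lineages <- db$entries[!duplicated(db$entries$species), c(RANKS)]
  rownames(lineages) <- db$entries$species[!duplicated(db$entries$species)]
  structure(list(k = k, vocab = vocab, logp = logp, pw = pw, Ms = Ms,
                 species = usp, lineages = lineages,
                 db_name = db$name, marker = db$marker),
            class = "nb_model")
}

kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character())
  km <- substring(seq, 1:(L - k + 1), k:L)
  unique(km[!grepl("[^ACGT]", km)])
}

#' Naive-Bayes bootstrap classification
#'
#' The full-length posterior picks the best species model; `bootstrap_iters`
#' iterations each rescore a random 1/`k` subsample (with replacement) of
#' the query's k-mers, and the per-rank confidence is the fraction of
#' iterations agreeing with the full-data assignment at that rank. The
#' lineage is truncated below the deepest rank with confidence at or above
#' the cutoff; truncation above kingdom leaves the query unclassified at all
#' ranks.
#'
#' @param query sequence to classify.
#' @param model an [nb_fit()] model.
#' @param otu_id id recorded on the result.
#' @param bootstrap_iters bootstrap iterations (default 100).
#' @param bootstrap_cutoff confidence cutoff (default 0.8).
#' @param seed integer seed (per-query RNG stream).
#' @return a `classification_result` with per-rank `confidence`.
#' @export
nb_classify <- function(query, model, otu_id = NA_character_,
                        bootstrap_iters = 100, bootstrap_cutoff = 0.8,
                        seed = 1) {
  km <- kmer_set(query, model$k)
  idx <- match(km, model$vocab)
  known <- !is.na(idx)
  if (!any(known)) {
    return(new_classification_result(otu_id, "wang", model$db_name,
                                     model$marker, reason = "no_kmers"))
  }
  idx <- idx[known]
  set.seed(derive_seed(seed, "nb_classify", paste(model$db_name, otu_id)))
  sc <- model$logp[, idx, drop = FALSE]
  full_best <- which.max(rowSums(sc))
  full_lineage <- unlist(model$lineages[model$species[full_best], ])
  nsub <- max(1L, floor(length(idx) / model$k))
  votes <- matrix(0, bootstrap_iters, length(RANKS))
  for (b in seq_len(bootstrap_iters)) {
    take <- sample.int(length(idx), nsub, replace = TRUE)
    bs <- rowSums(sc[, take, drop = FALSE])
    top <- which(bs == max(bs))
    bb <- if (length(top) > 1) top[sample.int(length(top), 1)] else top
    bl <- unlist(model$lineages[model$species[bb], ])
    votes[b, ] <- bl == full_lineage
  }
  conf <- colMeans(votes)
  names(conf) <- RANKS
  # confidence aggregates upward: agreement at a deep rank implies agreement
  # at the shallower ones, so enforce the cumulative reading
  conf <- rev(cummax(rev(conf)))
  keep <- conf >= bootstrap_cutoff
  deepest <- if (any(keep)) max(which(keep)) else 0L
  lineage <- full_lineage
  if (deepest < length(RANKS)) {
    lineage[(deepest + 1):length(RANKS)] <- NA_character_
  }
  if (deepest == 0L) {
    return(new_classification_result(otu_id, "wang", model$db_name,
                                     model$marker, confidence = conf,
                                     reason = "below_cutoff"))
  }
  sp <- lineage[["species"]]
  new_classification_result(
    otu_id, "wang", model$db_name, model$marker,
    species = sp, genus = lineage[["genus"]],
    group = if (!is.na(sp)) sp else character(),
    confidence = conf,
    reason = if (is.na(sp)) "below_cutoff" else NA_character_)
}

#' 1-nearest-neighbour classification
#'
#' Assigns the full lineage of the reference closest in the OTU-pipeline
#' alignment distance, with no confidence filtering. Distance ties are
#' broken by higher identity, then accession order, and recorded.
#'
#' @param query sequence to classify.
#' @param db a `reference_db`.
#' @param otu_id id recorded on the result.
#' @param hits precomputed [query_db_alignments()] table with the distance
#'   scoring (optional reuse).
#' @return a `classification_result` (never unclassified on a non-empty,
#'   fully annotated database).
#' @export
knn_classify <- function(query, db, otu_id = NA_character_, hits = NULL) {
  if (nrow(db$entries) == 0) stop("knn_classify: empty database")
  h <- hits %||% knn_distances(query, db)
  ord <- order(h$distance, -h$identity, h$accession)
  h <- h[ord, , drop = FALSE]
  tie <- sum(h$distance == h$distance[1] & h$identity == h$identity[1])
  best <- h[1, ]
  new_classification_result(
    otu_id, "knn", db$name, db$marker,
    species = best$species, genus = best$genus,
    group = best$species, identity = best$identity, score = -best$distance,
    tie_note = if (tie > 1) sprintf("%d tied neighbours", tie) else NA_character_)
}

knn_distances <- function(query, db) {
  st <- align_batch_cpp(query, db$entries$sequence,
                        match = 1, mismatch = -1, gap_open = -2, gap_ext = -1,
                        free_ends = FALSE)
  den <- st[, "matches"] + st[, "mismatches"] + st[, "gap_runs"]
  dist <- ifelse(den > 0, (st[, "mismatches"] + st[, "gap_runs"]) / den, 1)
  identity <- ifelse(st[, "cols"] > 0, st[, "matches"] / st[, "cols"], 0)
  data.frame(accession = db$entries$accession, species = db$entries$species,
             genus = db$entries$genus, distance = dist, identity = identity,
             stringsAsFactors = FALSE)
}

#' Mark placeholder names as unclassified
#'
#' Database conventions leave unannotated levels as a species name ending
#' in " sp" or any rank named "unclassified". Such names give no information
#' at their rank: the result is marked unclassified there (and below, for a
#' genus placeholder).
#'
#' @param result a `classification_result`.
#' @return the adjusted result.
#' @export
truncate_unannotated <- function(result) {
  unann_sp <- function(x) {
    !is.na(x) & (endsWith(x, UNANNOTATED_SPECIES_SUFFIX) |
                   endsWith(x, UNCLASSIFIED))
  }
  if (!is.na(result$genus) && result$genus == UNCLASSIFIED) {
    result$genus <- NA_character_
    result$species <- NA_character_
    result$group <- character()
    result$reason <- "unannotated"
    return(result)
  }
  if (length(result$group)) {
    annotated <- result$group[!unann_sp(result$group)]
    if (length(annotated) < length(result$group)) {
      result$group <- annotated
      if (length(annotated) == 1) {
        result$species <- annotated
      } else if (length(annotated) == 0) {
        result$species <- NA_character_
        if (is.na(result$reason)) result$reason <- "unannotated"
      }
    }
  }
  if (unann_sp(result$species)) {
    result$species <- NA_character_
    if (is.na(result$reason)) result$reason <- "unannotated"
  }
  result
}

#' Flatten classification results into a hits table
#'
#' One row per result: assigned names, equivalence-group size and members,
#' identity/score or bootstrap confidence, and the unclassified reason.
#' This is the classification stage's on-disk interface (write with
#' [write_tsv()]).
#'
#' @param results list of `classification_result` (e.g. [classify_otus()]).
#' @return data.frame.
#' @export
classification_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(otu_id = r$otu_id, method = r$method, db = r$db,
               marker = r$marker,
               species = r$species %||% NA_character_,
               genus = r$genus %||% NA_character_,
               equivalence_group = paste(r$group, collapse = ";"),
               equivalence_group_size = length(r$group),
               identity = r$identity %||% NA_real_,
               score = r$score %||% NA_real_,
               species_confidence =
                 if (!is.null(r$confidence)) r$confidence[["species"]] else NA_real_,
               unclassified_reason = r$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify one set of OTU representatives with all three back-ends
#'
#' Alignment statistics against the database are computed once per
#' representative and shared between the top-hit and nearest-neighbour
#' back-ends.
#'
#' @param reps data.frame (`otu_id` or `id`, `seq`).
#' @param db a `reference_db`.
#' @param methods subset of c("tophit", "wang", "knn").
#' @param nb_model optional prefitted [nb_fit()] model.
#' @param seed integer seed for the naive-Bayes bootstrap.
#' @return list of `classification_result`, named `otu_id.method`.
#' @export
classify_otus <- function(reps, db, methods = c("tophit", "wang", "knn"),
                          nb_model = NULL, seed = 1) {
  ids <- reps$otu_id %||% reps$id
  if ("wang" %in% methods && is.null(nb_model)) nb_model <- nb_fit(db)
  out <- list()
  for (i in seq_len(nrow(reps))) {
    q <- reps$seq[i]
    if ("tophit" %in% methods || "knn" %in% methods) {
      kh <- knn_distances(q, db)
      th <- query_db_alignments(q, db)
    }
    for (m in methods) {
      res <- switch(m,
        tophit = tophit_search(q, db, ids[i], hits = th),
        wang = nb_classify(q, nb_model, ids[i], seed = seed),
        knn = knn_classify(q, db, ids[i], hits = kh))
      out[[paste(ids[i], m, sep = ".")]] <- truncate_unannotated(res)
    }
  }
  out
}
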