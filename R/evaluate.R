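# Adjudication of classifications against mock-community ground truth:
# synonym canonicalisation, strict/loose verdicts at species and genus
# level, subgeneric rescue, two-marker consensus, confusion counts,
# precision/recall/F1, L1 abundance distances and threshold sweeps.
# The counting unit is the OTU (the taxon for the consensus approach);
# a false negative is an unclassified OTU, an incorrect classification a
# false positive.

#' Canonicalise taxon names through a synonym map
#'
#' Both call and truth names are mapped to a canonical representative
#' before comparison, so a classification naming either synonym matches.
#' Chains (A -> B, B -> C) are followed to their fixpoint.
#'
#' @param taxon character vector of names.
#' @param synonym_map named character vector (alias -> canonical).
#' @return canonicalised names.
#' @export
apply_synonyms <- function(taxon, synonym_map = character()) {
  if (!length(synonym_map)) return(taxon)
  out <- taxon
  for (i in seq_along(out)) {
    seen <- character()
    while (!is.na(out[i]) && out[i] %in% names(synonym_map) &&
           !(out[i] %in% seen)) {
      seen <- c(seen, out[i])
      out[i] <- synonym_map[[out[i]]]
    }
  }
  out
}

# Project a classification result to one taxonomic level: the assigned name
# and the (deduplicated, canonicalised) equivalence group at that level.
level_names <- function(result, level, synonym_map = character()) {
  if (level == "species") {
    grp <- apply_synonyms(result$group, synonym_map)
  } else {
    grp <- result$group
    if (!length(grp) && !is.na(result$genus)) grp <- result$genus
    grp <- genus_of(apply_synonyms(grp, synonym_map))
  }
  sort(unique(grp[!is.na(grp)]))
}

truth_at_level <- function(members, level, synonym_map = character()) {
  m <- apply_synonyms(members, synonym_map)
  if (level == "genus") m <- genus_of(m)
  unique(m)
}

#' Adjudicate one classification against community truth
#'
#' Strict setting: a single (level-unique) top name that is a community
#' member is a true positive; a single non-member name a false positive;
#' several tied names, or an unclassified result, count as a false negative
#' ("unclassified"). Loose setting: a member anywhere in the leading
#' equivalence group is a true positive; a group without members is a false
#' positive whose reported taxon is a seeded random group member;
#' unclassified stays a false negative. For single-assignment classifiers
#' the assigned lineage acts as a group of one, so both settings coincide.
#'
#' @param result a `classification_result`.
#' @param community one registry row ([build_mock_communities()]).
#' @param level "species" or "genus".
#' @param setting "strict" or "loose".
#' @param synonym_map alias -> canonical map.
#' @param seed seed for the loose false-positive representative (drawn per
#'   (otu, db, method) for reproducibility).
#' @return one-row data.frame (an adjudicated call).
#' @export
adjudicate <- function(result, community, level = c("species", "genus"),
                       setting = c("strict", "loose"),
                       synonym_map = character(), seed = 1) {
  level <- match.arg(level)
  setting <- match.arg(setting)
  members <- truth_at_level(community$members[[1]], level, synonym_map)
  grp <- level_names(result, level, synonym_map)
  call <- data.frame(otu_id = result$otu_id, dmc_id = community$dmc_id,
                     method = result$method, db = result$db,
                     marker = result$marker, level = level, setting = setting,
                     verdict = "FN_unclassified", matched_taxon = NA_character_,
                     group_size = length(grp), notes = NA_character_,
                     stringsAsFactors = FALSE)
  if (length(grp) == 0) {
    call$notes <- result$reason
    return(call)
  }
  if (setting == "strict") {
    if (length(grp) > 1) {
      call$notes <- "equivalent_top_hits"
      return(call)
    }
    call$verdict <- if (grp %in% members) "TP" else "FP"
    call$matched_taxon <- grp
    return(call)
  }
  hit <- intersect(grp, members)
  if (length(hit)) {
    call$verdict <- "TP"
    call$matched_taxon <- hit[1]
  } else {
    call$verdict <- "FP"
    set.seed(derive_seed(seed, "loose_fp",
                         paste(result$otu_id, result$db, result$method, level)))
    call$matched_taxon <- if (length(grp) == 1) grp else sample(grp, 1)
    if (length(grp) > 1) call$notes <- "random_group_representative"
  }
  call
}

#' Rescue near-miss species calls at a subgeneric rank
#'
#' A species-level call that is not a true positive becomes a subgeneric
#' true positive when every name in its leading equivalence group maps to
#' the same section/series/species-complex as some community member.
#' Species lacking a map entry leave the call unchanged (logged in `notes`).
#'
#' @param call an adjudicated species-level call (one row).
#' @param result the underlying `classification_result`.
#' @param community the registry row.
#' @param subgeneric_map data.frame (`species`, `subgeneric_kind`,
#'   `subgeneric_name`).
#' @param synonym_map alias -> canonical map.
#' @return the call with `level = "subgeneric"` and a possibly upgraded
#'   verdict.
#' @export
map_subgeneric <- function(call, result, community, subgeneric_map,
                           synonym_map = character()) {
  stopifnot(call$level == "species")
  out <- call
  out$level <- "subgeneric"
  if (call$verdict == "TP") return(out) # already correct at species
  grp <- level_names(result, "species", synonym_map)
  if (!length(grp)) return(out)
  sect <- subgeneric_map$subgeneric_name[match(grp, subgeneric_map$species)]
  if (anyNA(sect)) {
    out$notes <- "subgeneric_map_missing"
    return(out)
  }
  members <- truth_at_level(community$members[[1]], "species", synonym_map)
  msect <- subgeneric_map$subgeneric_name[match(members, subgeneric_map$species)]
  if (length(unique(sect)) == 1 && sect[1] %in% stats::na.omit(msect)) {
    out$verdict <- "TP"
    out$matched_taxon <- sect[1]
    out$notes <- "subgeneric_rescue"
  }
  out
}

#' Two-marker consensus verdicts for one community and combination
#'
#' Operates at the taxon level (OTUs of different markers cannot be linked
#' read-wise): a taxon is a consensus true positive iff it is a
#' true-positive taxon for both markers at the same level; a taxon called
#' (TP or FP) in at least one marker that is neither a consensus TP nor a
#' community member is a consensus false positive; community members that
#' are not consensus TPs are the false negatives.
#'
#' @param calls_its1,calls_its2 adjudicated call tables for the two markers
#'   (same community, database, method, setting, level).
#' @param community the registry row.
#' @param level "species" or "genus".
#' @param synonym_map alias -> canonical map.
#' @return list(`counts` one-row TP/FP/FN data.frame, `tp_taxa`, `fp_taxa`,
#'   `fn_taxa`).
#' @export
consensus_combine <- function(calls_its1, calls_its2, community,
                              level = "species", synonym_map = character()) {
  members <- truth_at_level(community$members[[1]], level, synonym_map)
  tp_taxa <- function(calls) {
    unique(calls$matched_taxon[calls$verdict == "TP" & calls$level == level])
  }
  called_taxa <- function(calls) {
    unique(calls$matched_taxon[calls$verdict %in% c("TP", "FP") &
                                 calls$level == level])
  }
  tp <- intersect(tp_taxa(calls_its1), tp_taxa(calls_its2))
  called <- union(called_taxa(calls_its1), called_taxa(calls_its2))
  fp <- setdiff(setdiff(called, tp), members)
  fn <- setdiff(members, tp)
  list(counts = data.frame(dmc_id = community$dmc_id, level = level,
                           TP = length(tp), FP = length(fp), FN = length(fn),
                           stringsAsFactors = FALSE),
       tp_taxa = tp, fp_taxa = fp, fn_taxa = fn)
}

#' Tally adjudicated calls into per-community confusion counts
#'
#' @param calls adjudicated call table (one row per OTU).
#' @return data.frame per (dmc_id, level, db, method, setting, marker) with
#'   TP, FP, FN.
#' @export
confusion_counts <- function(calls) {
  key <- interaction(calls$dmc_id, calls$level, calls$db, calls$method,
                     calls$setting, calls$marker, drop = TRUE)
  rows <- lapply(split(calls, key), function(g) {
    data.frame(dmc_id = g$dmc_id[1], level = g$level[1], db = g$db[1],
               method = g$method[1], setting = g$setting[1],
               marker = g$marker[1],
               TP = sum(g$verdict == "TP"), FP = sum(g$verdict == "FP"),
               FN = sum(g$verdict == "FN_unclassified"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Precision, recall and F1 from confusion counts
#'
#' Precision = TP/(TP+FP) * 100%, recall = TP/(TP+FN) * 100%,
#' F1 = 2*TP/(2*TP+FP+FN) (stored as a fraction). A metric whose
#' denominator is zero is undefined (NA) and excluded from aggregates.
#'
#' @param counts data.frame with TP, FP, FN columns.
#' @return `counts` with `precision`, `recall` (percent) and `f1` columns.
#' @export
metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  counts$precision <- ifelse(tp + fp > 0, tp / (tp + fp) * 100, NA_real_)
  counts$recall <- ifelse(tp + fn > 0, tp / (tp + fn) * 100, NA_real_)
  counts$f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn),
                      NA_real_)
  counts
}

#' Aggregate per-community metrics into combination means
#'
#' Mean and sample standard deviation over communities, with
#' undefined-denominator entries excluded per metric.
#'
#' @param m table from [metrics()].
#' @param by grouping columns (default the combination key).
#' @return one row per combination with mean/sd/n per metric.
#' @export
metrics_summary <- function(m, by = c("level", "db", "method", "setting",
                                      "marker")) {
  by <- intersect(by, names(m))
  key <- interaction(m[by], drop = TRUE)
  rows <- lapply(split(m, key), function(g) {
    agg <- function(x) c(mean = mean(x, na.rm = TRUE),
                         sd = sd(x, na.rm = TRUE),
                         n = sum(!is.na(x)))
    p <- agg(g$precision); r <- agg(g$recall); f <- agg(g$f1)
    cbind(g[1, by, drop = FALSE],
          data.frame(precision_mean = p[1], precision_sd = p[2],
                     recall_mean = r[1], recall_sd = r[2],
                     f1_mean = f[1], f1_sd = f[2], n_dmcs = p[3]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Observed-vs-theoretical abundance comparison for one community
#'
#' Reads of unclassified OTUs are excluded; remaining reads are attributed
#' to their called (post-synonym) taxon and renormalised over classified
#' reads. L1 = sum over taxa of |observed - theoretical|, where the
#' theoretical fraction is 1/size per member species (aggregated per genus
#' at genus level) and 0 for non-members; it ranges from 0 (identical
#' estimates) to 2 (only incorrect taxa observed).
#'
#' @param otu_table OTU table with `otu_id`, `total_count`.
#' @param calls adjudicated calls for one (community, combination, level).
#' @param community the registry row.
#' @param synonym_map alias -> canonical map.
#' @param level "species" or "genus".
#' @return list(`observed`, `theoretical`, `l1`) or NULL when no OTU is
#'   classified (excluded from aggregates).
#' @export
abundance_profile <- function(otu_table, calls, community,
                              synonym_map = character(), level = "species") {
  cls <- calls[calls$verdict %in% c("TP", "FP") & calls$level == level, ,
               drop = FALSE]
  cls <- cls[!is.na(cls$matched_taxon), , drop = FALSE]
  counts <- otu_table$total_count[match(cls$otu_id, otu_table$otu_id)]
  ok <- !is.na(counts)
  cls <- cls[ok, , drop = FALSE]; counts <- counts[ok]
  if (!nrow(cls) || sum(counts) == 0) return(NULL)
  obs <- tapply(counts, cls$matched_taxon, sum)
  obs <- obs / sum(obs)
  theo_sp <- theoretical_abundances(community)
  nm <- apply_synonyms(names(theo_sp), synonym_map)
  if (level == "genus") nm <- genus_of(nm)
  theo <- tapply(as.numeric(theo_sp), nm, sum)
  theo <- setNames(as.numeric(theo), names(theo))
  taxa <- union(names(obs), names(theo))
  o <- setNames(rep(0, length(taxa)), taxa); o[names(obs)] <- obs
  t <- setNames(rep(0, length(taxa)), taxa); t[names(theo)] <- theo
  list(observed = o, theoretical = t, l1 = sum(abs(o - t)))
}

#' Abundance-filter threshold sweep
#'
#' Re-applies the rare-OTU filter at each threshold of the grid (default 0
#' to 1% in 0.05% increments), restricts the adjudicated calls to the
#' surviving OTUs, and recomputes the per-community metrics. Emits tidy
#' long-format rows for plotting.
#'
#' @param otu_tables named list (by dmc_id) of pre-filter OTU tables.
#' @param calls adjudicated calls computed on all pre-filter OTUs.
#' @param thresholds sweep grid (default `seq(0, 0.01, by = 5e-04)`).
#' @param drop_singletons apply the singleton rule at every threshold
#'   (default TRUE).
#' @return data.frame: one [metrics_summary()] block per threshold, plus a
#'   `threshold` column and per-threshold surviving-OTU counts.
#' @export
threshold_sweep <- function(otu_tables, calls,
                            thresholds = seq(0, 0.01, by = 5e-04),
                            drop_singletons = TRUE) {
  stopifnot(!is.unsorted(thresholds), all(thresholds >= 0 & thresholds <= 1))
  out <- list()
  for (thr in thresholds) {
    surviving <- unlist(lapply(otu_tables, function(tab) {
      filter_rare(tab, drop_singletons = drop_singletons,
                  threshold_override = thr)$otu_id
    }), use.names = FALSE)
    sub <- calls[calls$otu_id %in% surviving, , drop = FALSE]
    if (!nrow(sub)) next
    ms <- metrics_summary(metrics(confusion_counts(sub)))
    ms$threshold <- thr
    ms$n_otus <- length(surviving)
    out[[length(out) + 1]] <- ms
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
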