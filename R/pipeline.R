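# End-to-end orchestration: a run configuration binds the synthetic-data,
# preprocessing, OTU, classification and evaluation stages into one
# reproducible benchmark run. Reruns with the same configuration are
# deterministic; a manifest records seeds, parameters and per-stage record
# counts.

#' Build a benchmark run configuration
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @param n_genera,species_per_genus taxonomy profile (see
#'   [generate_taxonomy()]).
#' @param n_communities,community_size,n_genus_violations registry profile
#'   (see [build_mock_communities()]).
#' @param markers markers to sequence and evaluate.
#' @param reads_per_community,substitution_error_rate,chimera_rate,copy_number_skew
#'   read-simulation settings (see [read_sim_params()]).
#' @param confusable_groups,d_conf,homopolymer_plants marker-sequence
#'   constraints (see [generate_marker_sequences()]).
#' @param databases list of database profiles; each a list with `name`,
#'   `completeness`, `unannotated_fraction`, `synonym_renames`.
#' @param methods classifier back-ends to run.
#' @param settings adjudication settings applied to the top-hit back-end.
#' @param min_fraction rare-OTU threshold (0.0005).
#' @param sanger_mode in-silico single-sequence mixes: markers are taken
#'   directly from the species pool at weight 1 and the rare-OTU filter is
#'   skipped.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(seed = 1,
                             n_genera = 35, species_per_genus = NULL,
                             n_communities = 37, community_size = 5,
                             n_genus_violations = 4,
                             markers = c("ITS1", "ITS2"),
                             reads_per_community = 1000,
                             substitution_error_rate = 0,
                             chimera_rate = 0,
                             copy_number_skew = FALSE,
                             confusable_groups = list(),
                             d_conf = 0.03,
                             homopolymer_plants = NULL,
                             databases = list(
                               list(name = "refA", completeness = 1,
                                    unannotated_fraction = 0,
                                    synonym_renames = character()),
                               list(name = "refB", completeness = 0.9,
                                    unannotated_fraction = 0.1,
                                    synonym_renames = character())),
                             methods = c("tophit", "wang", "knn"),
                             settings = c("strict", "loose"),
                             min_fraction = 0.0005,
                             sanger_mode = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "benchmark_config"
  cfg
}

# Stable short hash of a configuration, stamped on every output.
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", derive_seed(0, "config", s))
}

#' Generate all synthetic inputs of a run
#'
#' @param cfg a [benchmark_config()].
#' @return list(`taxa`, `communities`, `dbs` (per marker x database)).
#' @export
generate_inputs <- function(cfg) {
  taxa <- generate_taxonomy(cfg$n_genera, cfg$species_per_genus, seed = cfg$seed)
  taxa <- generate_marker_sequences(
    taxa, markers = cfg$markers, confusable_groups = cfg$confusable_groups,
    d_conf = cfg$d_conf, homopolymer_plants = cfg$homopolymer_plants,
    seed = cfg$seed)
  communities <- build_mock_communities(
    taxa, cfg$n_communities, cfg$community_size,
    n_genus_violations = cfg$n_genus_violations, seed = cfg$seed)
  dbs <- list()
  for (marker in cfg$markers) {
    for (dbp in cfg$databases) {
      dbs[[paste(dbp$name, marker, sep = ".")]] <- build_reference_db(
        taxa, marker, completeness = dbp$completeness,
        unannotated_fraction = dbp$unannotated_fraction,
        synonym_renames = dbp$synonym_renames, name = dbp$name,
        seed = cfg$seed)
    }
  }
  list(taxa = taxa, communities = communities, dbs = dbs)
}

#' Run the OTU pipeline for one community and marker
#'
#' Illumina mode simulates paired reads, then trims, merges, extracts,
#' screens, dereplicates, pre-clusters, removes chimeras and clusters at
#' the cutoff. Sanger mode starts from the members' marker sequences at
#' weight 1 (skipping read-level stages and, downstream, the rare-OTU
#' filter). The returned OTU table is pre-filter; apply [filter_rare()] (or
#' a sweep) at evaluation time.
#'
#' @param community registry row.
#' @param taxa species table with marker sequences.
#' @param marker "ITS1" or "ITS2".
#' @param cfg a [benchmark_config()].
#' @param reads optional precomputed [simulate_reads()] output (reused by
#'   replicate-stability checks).
#' @return list(`otus`, `counts`, `truth`, `chimera_log`).
#' @export
run_dmc_pipeline <- function(community, taxa, marker, cfg, reads = NULL) {
  if (cfg$sanger_mode) {
    members <- community$members[[1]]
    idx <- match(members, taxa$species)
    flanks <- MARKER_FLANKS[[marker]]
    contigs <- data.frame(id = sprintf("%s_%s_sanger%02d", community$dmc_id,
                                       marker, seq_along(members)),
                          seq = paste0(flanks[1], taxa[[marker]][idx], flanks[2]),
                          stringsAsFactors = FALSE)
    ex <- extract_markers(contigs, flanks[1], flanks[2])
    sc <- screen_sequences(ex$markers)
    derep <- dereplicate(sc$kept)
    counts <- c(pairs_in = nrow(contigs), merged = nrow(contigs),
                extracted = nrow(ex$markers), screened = nrow(sc$kept))
    truth <- data.frame(read_id = contigs$id, dmc_id = community$dmc_id,
                        species = members, is_chimera = FALSE,
                        stringsAsFactors = FALSE)
    chim <- list(kept = derep,
                 log = data.frame(id = derep$id, chimeric = FALSE))
  } else {
    if (is.null(reads)) {
      params <- read_sim_params(
        reads_per_community = cfg$reads_per_community,
        substitution_error_rate = cfg$substitution_error_rate,
        chimera_rate = cfg$chimera_rate,
        copy_number_skew = cfg$copy_number_skew, seed = cfg$seed)
      reads <- simulate_reads(community, taxa, marker, params)
    }
    pp <- preprocess_reads(reads$fwd, reads$rev, marker)
    derep <- dereplicate(pp$markers)
    pc <- precluster(derep)
    chim <- detect_chimeras(pc$seqs)
    derep <- chim$kept
    counts <- c(pp$counts, preclustered = nrow(pc$seqs),
                post_chimera = nrow(chim$kept))
    truth <- reads$truth
  }
  if (nrow(derep) == 0) {
    return(list(otus = NULL, counts = counts, truth = truth,
                chimera_log = chim$log))
  }
  if (nrow(derep) == 1) {
    assign <- 1L
  } else {
    D <- pairwise_distances(derep$seq)
    assign <- cluster_otus(D, derep$weight, derep$id)
  }
  otus <- build_otus(derep, assign, community$dmc_id)
  counts <- c(counts, otus = nrow(otus$table))
  list(otus = otus, counts = counts, truth = truth, chimera_log = chim$log)
}

# Expand the evaluation grid of one classification result set into
# adjudicated calls at both levels. The top-hit back-end is adjudicated
# under each configured setting; the single-assignment back-ends use the
# strict machinery (their group size is one) and are labelled by method.
adjudicate_results <- function(results, community, cfg, synonym_map) {
  rows <- list()
  for (res in results) {
    settings <- if (res$method == "tophit") cfg$settings else "strict"
    for (setting in settings) {
      for (level in c("species", "genus")) {
        rows[[length(rows) + 1]] <-
          adjudicate(res, community, level, setting, synonym_map,
                     seed = cfg$seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full benchmark
#'
#' simulate -> preprocess -> OTU -> classify (full database x method x
#' setting grid) -> adjudicate, for every community and marker. Returns all
#' intermediate tables plus per-combination summaries; pass the result to
#' [threshold_sweep()] via its `otu_tables`/`calls` fields for sweep
#' analyses.
#'
#' @param cfg a [benchmark_config()].
#' @param inputs optional precomputed [generate_inputs()] value.
#' @param progress print one line per community.
#' @return list of class `benchmark_run`: `cfg`, `inputs`, `otu_tables`
#'   (pre-filter, per dmc x marker), `calls` (post rare-filter),
#'   `calls_prefilter`, `hits` (per-OTU classification table), `confusion`,
#'   `metrics`, `summary`, `l1`, `consensus`, `truth`, `manifest`.
#' @export
run_benchmark <- function(cfg = benchmark_config(), inputs = NULL,
                          progress = FALSE) {
  inputs <- inputs %||% generate_inputs(cfg)
  taxa <- inputs$taxa
  communities <- inputs$communities
  dbs <- inputs$dbs
  nb_models <- list()
  if ("wang" %in% cfg$methods) {
    for (nm in names(dbs)) nb_models[[nm]] <- nb_fit(dbs[[nm]])
  }
  otu_tables <- list()
  truth <- list()
  all_calls <- list()
  all_hits <- list()
  stage_counts <- list()
  for (ci in seq_len(nrow(communities))) {
    community <- communities[ci, , drop = FALSE]
    for (marker in cfg$markers) {
      run <- run_dmc_pipeline(community, taxa, marker, cfg)
      key <- paste(community$dmc_id, marker, sep = ".")
      stage_counts[[key]] <- run$counts
      truth[[key]] <- run$truth
      if (is.null(run$otus)) next
      otu_tables[[key]] <- run$otus$table
      reps <- data.frame(otu_id = run$otus$table$otu_id,
                         seq = run$otus$table$rep_seq,
                         stringsAsFactors = FALSE)
      for (dbk in names(dbs)) {
        db <- dbs[[dbk]]
        if (db$marker != marker) next
        results <- classify_otus(reps, db, methods = cfg$methods,
                                 nb_model = nb_models[[dbk]], seed = cfg$seed)
        all_hits[[paste(key, dbk, sep = ".")]] <- classification_table(results)
        calls <- adjudicate_results(results, community, cfg, db$synonym_map)
        all_calls[[paste(key, dbk, sep = ".")]] <- calls
      }
    }
    if (progress) {
      message(sprintf("%s done (%s)", community$dmc_id,
                      paste(cfg$markers, collapse = "/")))
    }
  }
  calls_prefilter <- do.call(rbind, all_calls)
  rownames(calls_prefilter) <- NULL
  hits <- do.call(rbind, all_hits)
  rownames(hits) <- NULL
  # default rare-OTU filter (skipped in Sanger mode)
  if (cfg$sanger_mode) {
    surviving <- unlist(lapply(otu_tables, function(t) t$otu_id))
  } else {
    surviving <- unlist(lapply(otu_tables, function(t) {
      filter_rare(t, min_fraction = cfg$min_fraction)$otu_id
    }))
  }
  calls <- calls_prefilter[calls_prefilter$otu_id %in% surviving, , drop = FALSE]
  confusion <- confusion_counts(calls)
  mets <- metrics(confusion)
  summary <- metrics_summary(mets)
  # per-community L1 distances (per marker x db x method x setting x level)
  l1 <- l1_table(otu_tables, calls, communities, dbs)
  consensus <- consensus_table(calls, communities, dbs, cfg)
  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   n_communities = nrow(communities),
                   n_species = nrow(taxa),
                   n_genera = length(unique(taxa$genus)),
                   stage_counts = stage_counts)
  structure(list(cfg = cfg, inputs = inputs, otu_tables = otu_tables,
                 calls = calls, calls_prefilter = calls_prefilter,
                 hits = hits, confusion = confusion, metrics = mets,
                 summary = summary, l1 = l1, consensus = consensus,
                 truth = truth, manifest = manifest),
            class = "benchmark_run")
}

#' @export
print.benchmark_run <- function(x, ...) {
  cat(sprintf("<benchmark_run: %d communities, %d OTU tables, %d calls, hash %s>\n",
              x$manifest$n_communities, length(x$otu_tables), nrow(x$calls),
              x$manifest$config_hash))
  invisible(x)
}

# L1 abundance distances for every (community, marker, db, method, setting,
# level) with at least one classified OTU.
l1_table <- function(otu_tables, calls, communities, dbs) {
  rows <- list()
  syn_of <- function(dbname, marker) {
    dbs[[paste(dbname, marker, sep = ".")]]$synonym_map
  }
  key <- interaction(calls$dmc_id, calls$marker, calls$db, calls$method,
                     calls$setting, calls$level, drop = TRUE)
  for (g in split(calls, key)) {
    community <- communities[communities$dmc_id == g$dmc_id[1], , drop = FALSE]
    tab <- otu_tables[[paste(g$dmc_id[1], g$marker[1], sep = ".")]]
    prof <- abundance_profile(tab, g, community,
                              syn_of(g$db[1], g$marker[1]), g$level[1])
    if (is.null(prof)) next
    rows[[length(rows) + 1]] <- data.frame(
      dmc_id = g$dmc_id[1], marker = g$marker[1], db = g$db[1],
      method = g$method[1], setting = g$setting[1], level = g$level[1],
      l1 = prof$l1, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Consensus confusion counts per (community, db, method, setting, level),
# requiring both markers to be present in the run.
consensus_table <- function(calls, communities, dbs, cfg) {
  if (length(cfg$markers) < 2) return(NULL)
  m1 <- cfg$markers[1]; m2 <- cfg$markers[2]
  rows <- list()
  key <- interaction(calls$dmc_id, calls$db, calls$method, calls$setting,
                     calls$level, drop = TRUE)
  for (g in split(calls, key)) {
    c1 <- g[g$marker == m1, , drop = FALSE]
    c2 <- g[g$marker == m2, , drop = FALSE]
    community <- communities[communities$dmc_id == g$dmc_id[1], , drop = FALSE]
    syn <- dbs[[paste(g$db[1], m1, sep = ".")]]$synonym_map
    cc <- consensus_combine(c1, c2, community, g$level[1], syn)
    row <- cbind(cc$counts,
                 data.frame(db = g$db[1], method = g$method[1],
                            setting = g$setting[1], marker = "consensus",
                            stringsAsFactors = FALSE))
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  metrics(out)
}
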