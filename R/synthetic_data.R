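# Synthetic study inputs: taxonomies, marker sequences, reference databases
# and mock-community registries. The defaults emulate the benchmark's study
# conditions: a pool of 51 species over 35 genera, 37 five-species
# communities at equal 20% theoretical abundance (four of them sharing one
# genus between two members, and one identical-composition replicate pair),
# confusable congener groups, and planted long homopolymers.

#' Conserved flank anchors per marker
#'
#' Fixed 25-base anchors standing in for the conserved flanking rRNA/primer
#' regions of each marker; a simulated amplicon is 5' anchor + marker + 3'
#' anchor, enabling exact flank trimming during marker extraction.
#'
#' @format named list: marker -> c(5' anchor, 3' anchor).
#' @export
MARKER_FLANKS <- list(
  ITS1 = c("TCCGTAGGTGAACCTGCGGAAGGAT", "CATTTAGAGGAAGTAAAAGTCGTAA"),
  ITS2 = c("GCATCGATGAAGAACGCAGCGAAAT", "TCCTCCGCTTATTGATATGCTTAAG")
)

#' Generate a synthetic fungal taxonomy skeleton
#'
#' Species names are synthetic binomials ("Genus07 fictum2"); the genus is
#' always the first whitespace token, so rank logic never depends on real
#' nomenclature. The default profile yields exactly 51 species over 35
#' genera (23 monotypic genera, 8 genera of two species, 4 genera of three),
#' and assigns subgeneric sections within multi-species genera (three
#' consecutive species per section), plus per-species marker copy-number
#' weights drawn log-uniformly in [0.5, 2] (applied only when copy-number
#' skew is switched on during read simulation).
#'
#' @param n_genera number of genera (>= 1).
#' @param species_per_genus integer vector of length `n_genera` (recycled), or
#'   NULL for the default 51-species profile (requires `n_genera = 35`).
#' @param seed integer seed; output is deterministic per seed.
#' @return data.frame: `species`, `genus`, `epithet`, `subgeneric_kind`,
#'   `subgeneric_name` (NA for monotypic genera), `copy_number_weight`.
#' @export
generate_taxonomy <- function(n_genera = 35, species_per_genus = NULL, seed = 1) {
  if (!is.numeric(n_genera) || n_genera < 1) {
    stop("generate_taxonomy: n_genera must be a positive integer")
  }
  n_genera <- as.integer(n_genera)
  set.seed(derive_seed(seed, "generate_taxonomy"))
  if (is.null(species_per_genus)) {
    if (n_genera == 35) {
      sizes <- sample(c(rep(3L, 4), rep(2L, 8), rep(1L, 23))) # 51 species
    } else {
      sizes <- sample(1:3, n_genera, replace = TRUE)
    }
  } else {
    if (any(species_per_genus < 1)) {
      stop("generate_taxonomy: species_per_genus must be positive")
    }
    sizes <- as.integer(rep_len(species_per_genus, n_genera))
  }
  genus <- sprintf("Genus%02d", seq_len(n_genera))
  rows <- do.call(rbind, lapply(seq_len(n_genera), function(g) {
    k <- sizes[g]
    ep <- sprintf("fictum%d", seq_len(k))
    sect <- if (k >= 2) sprintf("%s sect. %d", genus[g], ceiling(seq_len(k) / 3)) else NA
    data.frame(
      species = paste(genus[g], ep),
      genus = genus[g],
      epithet = ep,
      subgeneric_kind = ifelse(k >= 2, "section", NA_character_),
      subgeneric_name = if (k >= 2) sect else NA_character_,
      stringsAsFactors = FALSE
    )
  }))
  rows$copy_number_weight <- exp(runif(nrow(rows), log(0.5), log(2)))
  rownames(rows) <- NULL
  rows
}

#' Generate marker sequences for a taxonomy skeleton
#'
#' Each genus receives an independent random ancestor per marker (length
#' drawn around the empirical ITS subregion mean of ~280 bp); species mutate
#' the genus ancestor by substitutions at the species-level divergence rate,
#' so inter-genus distances exceed intra-genus distances in expectation.
#' Members of a confusable group instead share a single group ancestor and
#' each receives at most `floor(d_conf * length / 2)` substitutions, which
#' bounds every within-group pairwise distance by `d_conf` (with `d_conf = 0`
#' the group's markers are identical — complete indistinguishability).
#' Homopolymer plants overwrite a run of the requested base verbatim at an
#' interior position.
#'
#' @param taxa data.frame from [generate_taxonomy()].
#' @param markers markers to generate ("ITS1", "ITS2").
#' @param species_divergence substitution rate separating congeners (default
#'   0.05).
#' @param confusable_groups list of character vectors of species names, each
#'   within one genus.
#' @param d_conf maximal within-group pairwise distance (default 0.03).
#' @param homopolymer_plants data.frame with columns `species`, `marker`,
#'   `base`, `run_length` (run_length >= 1).
#' @param length_mean,length_sd,length_range amplicon marker length model
#'   (normal, clipped).
#' @param seed integer seed.
#' @return `taxa` with one additional character column per marker plus a
#'   `confusable_group` index column (NA outside groups).
#' @export
generate_marker_sequences <- function(taxa, markers = c("ITS1", "ITS2"),
                                      species_divergence = 0.05,
                                      confusable_groups = list(),
                                      d_conf = 0.03,
                                      homopolymer_plants = NULL,
                                      length_mean = 280, length_sd = 40,
                                      length_range = c(180, 420),
                                      seed = 1) {
  for (grp in confusable_groups) {
    if (length(unique(genus_of(grp))) != 1) {
      stop("generate_marker_sequences: confusable group spans genera: ",
           paste(grp, collapse = ", "))
    }
    if (!all(grp %in% taxa$species)) {
      stop("generate_marker_sequences: unknown species in confusable group")
    }
  }
  if (!is.null(homopolymer_plants) && nrow(homopolymer_plants) > 0 &&
      any(homopolymer_plants$run_length < 1)) {
    stop("generate_marker_sequences: homopolymer run_length must be >= 1")
  }
  group_of <- rep(NA_integer_, nrow(taxa))
  for (i in seq_along(confusable_groups)) {
    group_of[taxa$species %in% confusable_groups[[i]]] <- i
  }
  taxa$confusable_group <- group_of
  for (marker in markers) {
    set.seed(derive_seed(seed, "generate_marker_sequences", marker))
    seqs <- character(nrow(taxa))
    for (g in unique(taxa$genus)) {
      idx <- which(taxa$genus == g)
      len <- round(min(max(stats::rnorm(1, length_mean, length_sd),
                           length_range[1]), length_range[2]))
      ancestor <- random_seq(len)
      done <- rep(FALSE, length(idx))
      # confusable groups within this genus share a group ancestor
      for (gi in unique(stats::na.omit(group_of[idx]))) {
        members <- which(group_of[idx] == gi)
        grp_anc <- mutate_seq(ancestor, round(species_divergence * len))
        edits <- floor(d_conf * nchar(grp_anc) / 2)
        for (m in members) seqs[idx[m]] <- mutate_seq(grp_anc, edits)
        done[members] <- TRUE
      }
      for (m in which(!done)) {
        repeat {
          s <- mutate_seq(ancestor, round(species_divergence * len))
          if (!s %in% seqs[idx]) break
        }
        seqs[idx[m]] <- s
      }
    }
    if (!is.null(homopolymer_plants) && nrow(homopolymer_plants) > 0) {
      hp <- homopolymer_plants[homopolymer_plants$marker == marker, , drop = FALSE]
      for (r in seq_len(nrow(hp))) {
        i <- match(hp$species[r], taxa$species)
        if (is.na(i)) stop("homopolymer plant for unknown species ", hp$species[r])
        s <- seqs[i]
        run <- strrep(hp$base[r], hp$run_length[r])
        pos <- sample(seq(20, nchar(s) - 20 - hp$run_length[r]), 1)
        seqs[i] <- paste0(substr(s, 1, pos - 1), run,
                          substr(s, pos + hp$run_length[r], nchar(s)))
      }
    }
    taxa[[marker]] <- seqs
  }
  taxa
}

#' Build a reference database from a species pool
#'
#' Produces accessioned entries binding each included species' marker
#' sequence to a full ranked lineage (kingdom Fungi; synthetic phylum /
#' class / order / family derived deterministically from the genus).
#' `completeness` subsamples the species pool (seeded); an
#' `unannotated_fraction` of the included entries is truncated at genus with
#' the "<Genus> sp" species placeholder. `synonym_renames` renames entries to
#' an alias binomial and records the alias in the database's synonym map.
#'
#' @param taxa species table from [generate_marker_sequences()].
#' @param marker which marker the database covers.
#' @param completeness fraction of species included (in [0, 1]).
#' @param unannotated_fraction fraction of included entries truncated at
#'   genus (in [0, 1]).
#' @param synonym_renames named character vector: names are pool species,
#'   values the alias binomial the database uses instead.
#' @param name database name (used in accessions and output files).
#' @param seed integer seed for the inclusion subsample.
#' @return object of class `reference_db`: list with `entries` (accession,
#'   ranks, sequence), `synonym_map` (alias -> canonical, closed both ways by
#'   the evaluation module), `subgeneric_map`, `name`, `marker`.
#' @export
build_reference_db <- function(taxa, marker, completeness = 1,
                               unannotated_fraction = 0,
                               synonym_renames = character(),
                               name = "refdb", seed = 1) {
  if (nrow(taxa) == 0) stop("build_reference_db: empty species list")
  if (completeness < 0 || completeness > 1 ||
      unannotated_fraction < 0 || unannotated_fraction > 1) {
    stop("build_reference_db: fractions must lie in [0, 1]")
  }
  if (!marker %in% names(taxa)) {
    stop("build_reference_db: taxa lack sequences for marker ", marker)
  }
  set.seed(derive_seed(seed, "build_reference_db", paste(name, marker)))
  n_keep <- round(completeness * nrow(taxa))
  keep <- sort(sample(nrow(taxa), n_keep))
  ent <- taxa[keep, , drop = FALSE]
  genus_idx <- match(ent$genus, sort(unique(taxa$genus)))
  entries <- data.frame(
    accession = sprintf("%s-%s-%04d", name, marker, seq_len(nrow(ent))),
    kingdom = "Fungi",
    phylum = sprintf("Phylum%d", (genus_idx %% 3) + 1),
    class = sprintf("Class%d", (genus_idx %% 6) + 1),
    order = sprintf("Order%02d", (genus_idx %% 12) + 1),
    family = sprintf("Family%02d", ceiling(genus_idx / 2)),
    genus = ent$genus,
    species = ent$species,
    sequence = ent[[marker]],
    stringsAsFactors = FALSE
  )
  n_unann <- round(unannotated_fraction * nrow(entries))
  if (n_unann > 0) {
    ua <- sample(nrow(entries), n_unann)
    entries$species[ua] <- paste0(entries$genus[ua], UNANNOTATED_SPECIES_SUFFIX)
  }
  synonym_map <- character()
  if (length(synonym_renames)) {
    for (sp in names(synonym_renames)) {
      i <- which(entries$species == sp)
      alias <- synonym_renames[[sp]]
      if (length(i)) {
        entries$species[i] <- alias
        entries$genus[i] <- genus_of(alias)
      }
      synonym_map[alias] <- sp
    }
  }
  sub <- taxa[!is.na(taxa$subgeneric_name),
              c("species", "subgeneric_kind", "subgeneric_name")]
  structure(list(entries = entries, synonym_map = synonym_map,
                 subgeneric_map = sub, name = name, marker = marker),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db '%s' marker=%s: %d entries, %d unannotated, %d synonyms>\n",
              x$name, x$marker, nrow(x$entries),
              sum(endsWith(x$entries$species, UNANNOTATED_SPECIES_SUFFIX)),
              length(x$synonym_map)))
  invisible(x)
}

#' Build the registry of defined mock communities
#'
#' Each community holds five distinct species at equal theoretical abundance
#' (0.20). By default members come from five different genera; exactly
#' `n_genus_violations` communities (ids mirroring the benchmark layout:
#' positions 1, 18, 19, 34) instead contain two congeners, i.e. four genera.
#' When `include_replicate_pair` is on, the last two communities are an
#' identical-composition technical replicate pair.
#'
#' @param taxa species pool (needs `species`, `genus`).
#' @param n_communities number of communities (default 37).
#' @param size members per community (default 5).
#' @param n_genus_violations communities with one shared genus (default 4).
#' @param include_replicate_pair duplicate the final composition (default TRUE).
#' @param seed integer seed.
#' @return data.frame with `dmc_id`, `replicate_of`, and list-column
#'   `members`; attribute `theoretical_abundance` = 1/size.
#' @export
build_mock_communities <- function(taxa, n_communities = 37, size = 5,
                                   n_genus_violations = 4,
                                   include_replicate_pair = TRUE, seed = 1) {
  genera <- unique(taxa$genus)
  if (length(genera) < size) {
    stop("build_mock_communities: pool has too few genera for the distinct-genus rule")
  }
  multi <- names(which(table(taxa$genus) >= 2))
  if (n_genus_violations > 0 && length(multi) == 0) {
    stop("build_mock_communities: genus-rule violations need a genus with >= 2 species")
  }
  set.seed(derive_seed(seed, "build_mock_communities"))
  n_unique <- n_communities - as.integer(include_replicate_pair)
  violation_at <- intersect(c(1L, 18L, 19L, 34L), seq_len(n_unique))
  violation_at <- head(violation_at, n_genus_violations)
  extra <- n_genus_violations - length(violation_at)
  if (extra > 0) {
    avail <- setdiff(seq_len(n_unique), violation_at)
    violation_at <- c(violation_at, head(avail, extra))
  }
  members <- vector("list", n_communities)
  for (i in seq_len(n_unique)) {
    if (i %in% violation_at) {
      g2 <- sample(multi, 1)
      pair <- sample(taxa$species[taxa$genus == g2], 2)
      others_g <- sample(setdiff(genera, g2), size - 2)
      singles <- vapply(others_g, function(g) {
        sample(taxa$species[taxa$genus == g], 1)
      }, character(1))
      members[[i]] <- sort(c(pair, unname(singles)))
    } else {
      gs <- sample(genera, size)
      members[[i]] <- sort(vapply(gs, function(g) {
        sample(taxa$species[taxa$genus == g], 1)
      }, character(1), USE.NAMES = FALSE))
    }
  }
  replicate_of <- rep(NA_character_, n_communities)
  if (include_replicate_pair) {
    members[[n_communities]] <- members[[n_unique]]
    replicate_of[n_communities] <- sprintf("DMC%02d", n_unique)
  }
  out <- data.frame(dmc_id = sprintf("DMC%02d", seq_len(n_communities)),
                    replicate_of = replicate_of, stringsAsFactors = FALSE)
  out$members <- members
  attr(out, "theoretical_abundance") <- 1 / size
  out
}

#' Theoretical abundance vector of one community
#'
#' @param community one row of the registry from [build_mock_communities()].
#' @return named numeric vector (each member at 1/size).
#' @export
theoretical_abundances <- function(community) {
  members <- community$members[[1]]
  setNames(rep(1 / length(members), length(members)), members)
}
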