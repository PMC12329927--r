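# Paired-end amplicon read simulator. Emulates a 250-bp paired-end protocol:
# per-species read counts are multinomial on theoretical abundances
# (optionally skewed by marker copy-number weights), substitution errors are
# i.i.d. per base at a rate modulated by a linearly decaying quality profile,
# and chimeric reads join a prefix of one member's amplicon to a suffix of
# another's at a uniform breakpoint. Every read carries its true species and
# chimera status in a sidecar truth table.

#' Read-simulation parameters
#'
#' @param reads_per_community read pairs per community (default 1000).
#' @param substitution_error_rate mean per-base substitution probability.
#' @param chimera_rate fraction of reads drawn as two-parent chimeras.
#' @param copy_number_skew multiply abundances by per-species marker
#'   copy-number weights before normalising.
#' @param read_length fixed read length (default 250).
#' @param quality_from,quality_to expected Phred quality at read start/end;
#'   the profile decays linearly, matching the higher error rates towards
#'   read ends on short-read platforms.
#' @param seed integer seed.
#' @return list of class `read_sim_params`.
#' @export
read_sim_params <- function(reads_per_community = 1000,
                            substitution_error_rate = 0,
                            chimera_rate = 0,
                            copy_number_skew = FALSE,
                            read_length = 250,
                            quality_from = 38, quality_to = 18,
                            seed = 1) {
  stopifnot(reads_per_community >= 1,
            substitution_error_rate >= 0, substitution_error_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  structure(list(reads_per_community = as.integer(reads_per_community),
                 substitution_error_rate = substitution_error_rate,
                 chimera_rate = chimera_rate,
                 copy_number_skew = isTRUE(copy_number_skew),
                 read_length = as.integer(read_length),
                 quality_from = quality_from, quality_to = quality_to,
                 seed = seed),
            class = "read_sim_params")
}

# Per-position error-probability weights: proportional to the Phred error
# probability of the quality profile, normalised to mean 1 so that the mean
# per-base substitution probability equals the configured rate.
quality_profile <- function(params) {
  q <- seq(params$quality_from, params$quality_to,
           length.out = params$read_length)
  p <- 10^(-q / 10)
  list(qual = as.integer(round(q)), weight = p / mean(p))
}

apply_substitutions <- function(seqs, perr) {
  if (all(perr == 0)) return(seqs)
  n <- length(seqs)
  out <- seqs
  for (i in seq_len(n)) {
    len <- nchar(out[i])
    hits <- which(runif(len) < perr[seq_len(len)])
    if (length(hits)) {
      bases <- strsplit(out[i], "", fixed = TRUE)[[1]]
      for (p in hits) bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
      out[i] <- paste(bases, collapse = "")
    }
  }
  out
}

#' Simulate paired reads for one mock community
#'
#' @param community one row of the registry from [build_mock_communities()].
#' @param taxa species table carrying marker sequences and copy-number
#'   weights.
#' @param marker "ITS1" or "ITS2".
#' @param params a [read_sim_params()] object.
#' @return list with data.frames `fwd` and `rev` (`id`, `seq`, `qual`), the
#'   `truth` table (`read_id`, `dmc_id`, `species`, `is_chimera`), and
#'   `warnings` (overlap warnings for over-long amplicons).
#' @export
simulate_reads <- function(community, taxa, marker, params = read_sim_params()) {
  members <- community$members[[1]]
  dmc_id <- community$dmc_id
  miss <- setdiff(members, taxa$species)
  if (length(miss)) {
    stop("simulate_reads: community members lack ", marker, " sequences: ",
         paste(miss, collapse = ", "))
  }
  idx <- match(members, taxa$species)
  flanks <- MARKER_FLANKS[[marker]]
  amplicons <- paste0(flanks[1], taxa[[marker]][idx], flanks[2])
  names(amplicons) <- members
  rl <- params$read_length
  warnings <- character()
  too_long <- nchar(amplicons) > 2 * rl - 10
  if (any(too_long)) {
    warnings <- sprintf("amplicon of %s (%d bp) leaves < 10 bp overlap for %d bp reads",
                        members[too_long], nchar(amplicons)[too_long], rl)
  }

  set.seed(derive_seed(params$seed, "simulate_reads", paste(dmc_id, marker)))
  abund <- theoretical_abundances(community)
  if (params$copy_number_skew) {
    abund <- abund * taxa$copy_number_weight[idx]
    abund <- abund / sum(abund)
  }
  n <- params$reads_per_community
  counts <- as.vector(rmultinom(1, n, abund))
  species_per_read <- rep(members, counts)
  is_chimera <- runif(n) < params$chimera_rate
  # chimeras need two distinct parents; single-species edge communities keep
  # every read clean
  if (length(members) < 2) is_chimera[] <- FALSE

  templates <- character(n)
  templates[!is_chimera] <- amplicons[species_per_read[!is_chimera]]
  for (i in which(is_chimera)) {
    pa <- species_per_read[i]
    pb <- sample(setdiff(members, pa), 1)
    la <- nchar(amplicons[pa]); lb <- nchar(amplicons[pb])
    lo <- min(20, floor(min(la, lb) / 3))
    bp <- sample(seq(lo, min(la, lb) - lo), 1)
    templates[i] <- paste0(substr(amplicons[pa], 1, bp),
                           substr(amplicons[pb], bp + 1, lb))
  }

  prof <- quality_profile(params)
  fwd <- substr(templates, 1, pmin(rl, nchar(templates)))
  rev_raw <- substr(templates, pmax(1, nchar(templates) - rl + 1), nchar(templates))
  rev <- revcomp(rev_raw)
  perr <- params$substitution_error_rate * prof$weight
  fwd <- apply_substitutions(fwd, perr)
  rev <- apply_substitutions(rev, perr)
  qstr <- phred_encode(prof$qual)
  base_id <- sprintf("%s_%s_r%05d", dmc_id, marker, seq_len(n))
  list(
    fwd = data.frame(id = paste0(base_id, "/1"), seq = fwd,
                     qual = substring(qstr, 1, nchar(fwd)),
                     stringsAsFactors = FALSE),
    rev = data.frame(id = paste0(base_id, "/2"), seq = rev,
                     qual = substring(qstr, 1, nchar(rev)),
                     stringsAsFactors = FALSE),
    truth = data.frame(read_id = base_id, dmc_id = dmc_id,
                       species = species_per_read, is_chimera = is_chimera,
                       stringsAsFactors = FALSE),
    warnings = warnings
  )
}
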