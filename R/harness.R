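# End-to-end experiment harnesses: generate a synthetic study, build the
# competing databases, run searches and collect the benchmark quantities.
# These drive the package's evaluation suites and the acceptance script.

sig_counts_by_class <- function(psms, db, q_threshold = 0.01) {
  cls <- classify_psms(psms, db)
  sig <- filter_significant(cls, q_threshold)
  c(human = nrow(sig[classification == "human"]),
    bacterial = nrow(sig[classification == "bacterial"]))
}

db_with_decoy_index <- function(db, params) {
  recs <- rbindlist(list(db$records[, .(record_id, sequence, species,
                                        strain, genus, category, source)],
                         build_decoys(db)), use.names = TRUE)
  build_peptide_index(recs, params)
}

#' Run one synthetic multi-sample database-strategy benchmark
#'
#' Generates a species universe and `n_samples` communities, simulates
#' two-replicate spectra per sample, builds the five compared databases
#' (pooled and sample-matched public-sequence, pooled and sample-matched
#' shotgun, hybrid), searches every sample against each database (one-step
#' target-decoy search), and counts significant human and bacterial PSMs.
#' Also computes the weighted tryptic-peptide completeness metric W per
#' sample from the public repository.
#'
#' @param seed Integer seed for the whole fixture.
#' @param n_samples Communities per fixture.
#' @param n_spectra Spectra per sample (both replicates together).
#' @param config Optional [community_config()]; by default a config with
#'   `dominant_uncultivated = TRUE` (a high-abundance uncultivated species
#'   per sample) and the given seed.
#' @param strategies Subset of the five strategy names to evaluate.
#' @param params [search_params()].
#' @param q_threshold Significance threshold.
#' @return List with `counts` (`sample_id`, `strategy`, `psm_type`,
#'   `count`), `weighted` (`sample_id`, `W`, `sm_count`, `hybrid_count`)
#'   and `profiles`.
#' @export
run_strategy_benchmark <- function(seed, n_samples = 6L, n_spectra = 800L,
                                   config = NULL,
                                   strategies = FIVE_STRATEGIES,
                                   params = search_params(),
                                   q_threshold = 0.01) {
  if (is.null(config))
    config <- community_config(seed = seed, n_spectra = n_spectra,
                               dominant_uncultivated = TRUE)
  repo <- generate_repository(config)
  host <- generate_host_set(config)
  core <- core_set(host_records = host)
  cont <- contaminant_records()

  samples <- lapply(seq_len(n_samples), function(i) {
    comm <- generate_community(config, repo, sample_index = i)
    cat_i <- generate_shotgun_catalog(comm, config)
    sim <- simulate_spectra(comm, host, cont, config)
    list(community = comm, catalog = cat_i, sim = sim)
  })
  profiles <- lapply(samples, function(s) s$community$profile)

  dbs_per_sample <- lapply(samples, function(s) {
    sm <- suppressWarnings(build_sample_matched_16s(
      s$community$profile, repo, core = core))
    sh <- build_shotgun(s$catalog, pooled = FALSE, core = core,
                        sample_id = s$community$sample_id)
    hy <- build_hybrid(sm, sh)
    list(sample_matched_16s = sm, shotgun_sample_matched = sh,
         hybrid_sample_matched = hy)
  })
  shared_dbs <- list()
  if ("pooled_16s" %in% strategies)
    shared_dbs$pooled_16s <- suppressWarnings(
      build_pooled_16s(profiles, repo, core = core))
  if ("shotgun_pooled" %in% strategies)
    shared_dbs$shotgun_pooled <- build_shotgun(
      lapply(samples, function(s) s$catalog), pooled = TRUE, core = core)
  shared_idx <- lapply(shared_dbs, db_with_decoy_index, params = params)

  counts <- list(); weighted <- list()
  pep_counts <- unique_tryptic_peptides(repo)
  for (i in seq_len(n_samples)) {
    s <- samples[[i]]
    sid <- s$community$sample_id
    per_sample <- c(dbs_per_sample[[i]], shared_dbs)
    for (strat in intersect(strategies, names(per_sample))) {
      db <- per_sample[[strat]]
      idx <- shared_idx[[strat]] %||% db_with_decoy_index(db, params)
      psms <- compute_qvalues(search_spectra(s$sim$spectra, db, params,
                                             index = idx))
      n <- sig_counts_by_class(psms, db, q_threshold)
      counts[[length(counts) + 1]] <- data.table(
        sample_id = sid, strategy = strat,
        psm_type = c("human", "bacterial"), count = as.integer(n))
    }
    W <- weighted_tryptic_metric(s$community$profile, pep_counts)$value
    cdt <- rbindlist(counts)[sample_id == sid & psm_type == "bacterial"]
    weighted[[i]] <- data.table(
      sample_id = sid, W = W,
      sm_count = cdt[strategy == "sample_matched_16s", sum(count)],
      hybrid_count = cdt[strategy == "hybrid_sample_matched", sum(count)])
  }
  list(counts = rbindlist(counts), weighted = rbindlist(weighted),
       profiles = profiles)
}

#' Empirical FDR-control experiment
#'
#' For each fixture: one synthetic community, its hybrid sample-matched
#' database, a one-step target-decoy search of the sample's spectra, and
#' the fraction of PSMs accepted at `q < q_threshold` whose peptide differs
#' from the ground-truth peptide of the spectrum.
#'
#' @param seed Base seed; fixture `i` uses a derived sub-seed.
#' @param n_fixtures Number of independent fixtures.
#' @param n_spectra Spectra per fixture.
#' @param q_threshold Acceptance threshold.
#' @param params [search_params()].
#' @return List with `per_fixture` table (`fixture`, `n_accepted`,
#'   `n_incorrect`, `error_rate`) and `mean_error_rate`.
#' @export
run_fdr_experiment <- function(seed, n_fixtures = 20L, n_spectra = 2000L,
                               q_threshold = 0.01,
                               params = search_params()) {
  rows <- vector("list", n_fixtures)
  for (i in seq_len(n_fixtures)) {
    config <- community_config(seed = sub_seed(seed, 31 * i),
                               n_spectra = n_spectra)
    repo <- generate_repository(config)
    host <- generate_host_set(config)
    core <- core_set(host_records = host)
    comm <- generate_community(config, repo, sample_index = 1L)
    cat1 <- generate_shotgun_catalog(comm, config)
    sim <- simulate_spectra(comm, host, contaminant_records(), config)
    sm <- suppressWarnings(build_sample_matched_16s(comm$profile, repo,
                                                    core = core))
    hy <- build_hybrid(sm, build_shotgun(cat1, FALSE, core,
                                         comm$sample_id))
    psms <- compute_qvalues(search_spectra(sim$spectra, hy, params))
    acc <- psms[q_value < q_threshold & !is_decoy]
    truth_pep <- setNames(sim$truth$peptide, sim$truth$spectrum_id)
    incorrect <- acc$peptide != truth_pep[acc$spectrum_id]
    rows[[i]] <- data.table(fixture = i, n_accepted = nrow(acc),
                            n_incorrect = sum(incorrect),
                            error_rate = if (nrow(acc)) mean(incorrect)
                                         else NA_real_)
  }
  per <- rbindlist(rows)
  list(per_fixture = per,
       mean_error_rate = mean(per$error_rate, na.rm = TRUE))
}

#' Generate strain and species genome pools for augmentation experiments
#'
#' The strain pool holds genomes of additional strains of one anchor
#' species: each shares a configured fraction of identical sequences with
#' the anchor proteome (and hence with each other), so the pool adds few
#' distinct sequences. The species pool holds genomes of unrelated species
#' with entirely novel sequences.
#'
#' @param seed Integer seed.
#' @param anchor_proteome Protein record table of the anchor strain (its
#'   sequences seed the strain redundancy). If `NULL` a random anchor is
#'   generated.
#' @param n_genomes Genomes per pool.
#' @param proteins_per_genome Records per genome.
#' @param protein_length Length range.
#' @param strain_shared_fraction Within-strain-pool redundancy.
#' @return List with `strain_pool` and `species_pool` record tables
#'   carrying `genome_id`.
#' @export
generate_genome_pools <- function(seed, anchor_proteome = NULL,
                                  n_genomes = 103L,
                                  proteins_per_genome = 12L,
                                  protein_length = c(60L, 140L),
                                  strain_shared_fraction = 0.8) {
  with_seed(sub_seed(seed, 77), {
    if (is.null(anchor_proteome)) {
      anchor <- random_sequences(proteins_per_genome, protein_length)
    } else {
      anchor <- head(anchor_proteome$sequence, proteins_per_genome)
      if (length(anchor) < proteins_per_genome)
        anchor <- c(anchor, random_sequences(
          proteins_per_genome - length(anchor), protein_length))
    }
    strain <- rbindlist(lapply(seq_len(n_genomes), function(g) {
      shared <- runif(proteins_per_genome) < strain_shared_fraction
      seqs <- anchor
      if (any(!shared))
        seqs[!shared] <- random_sequences(sum(!shared), protein_length)
      data.table(record_id = sprintf("STRG%03d_p%02d", g,
                                     seq_len(proteins_per_genome)),
                 sequence = seqs, species = "Anchor_species",
                 strain = sprintf("aug%03d", g), genus = "Anchor_genus",
                 category = "bacterial", source = "public",
                 genome_id = sprintf("STRG%03d", g))
    }))
    species <- rbindlist(lapply(seq_len(n_genomes), function(g) {
      data.table(record_id = sprintf("SPG%03d_p%02d", g,
                                     seq_len(proteins_per_genome)),
                 sequence = random_sequences(proteins_per_genome,
                                             protein_length),
                 species = sprintf("Augment_species_%03d", g), strain = "s1",
                 genus = sprintf("Augment_genus_%03d", g),
                 category = "bacterial", source = "public",
                 genome_id = sprintf("SPG%03d", g))
    }))
    list(strain_pool = strain, species_pool = species)
  })
}

#' Database-bloat (strains versus species) experiment on a synthetic study
#'
#' Builds a sample-matched public database as the baseline, pools of
#' additional strain and species genomes, and runs the augmentation
#' experiment over the combined spectra of `n_samples` communities.
#'
#' @param seed Integer seed.
#' @param sizes Genome counts to add.
#' @param n_replicates Random databases per cell.
#' @param n_samples Communities contributing spectra.
#' @param n_spectra Spectra per sample.
#' @param params [search_params()].
#' @return The [strains_vs_species_experiment()] table.
#' @export
run_bloat_experiment <- function(seed, sizes = c(20, 40, 60, 80, 100),
                                 n_replicates = 3L, n_samples = 2L,
                                 n_spectra = 1500L,
                                 params = search_params()) {
  config <- community_config(seed = seed, n_spectra = n_spectra,
                             fraction_uncultivated = 0)
  repo <- generate_repository(config)
  host <- generate_host_set(config)
  core <- core_set(host_records = host)
  spectra <- list(); profile1 <- NULL
  for (i in seq_len(n_samples)) {
    comm <- generate_community(config, repo, sample_index = i)
    if (i == 1) profile1 <- comm$profile
    sim <- simulate_spectra(comm, host, contaminant_records(), config)
    spectra[[i]] <- sim$spectra
  }
  spectra <- rbindlist(spectra)
  baseline <- suppressWarnings(build_sample_matched_16s(profile1, repo,
                                                        core = core))
  anchor_sp <- profile1$species[which.max(profile1$relative_abundance)]
  anchor <- repo[species == anchor_sp & strain == "s1"]
  pools <- generate_genome_pools(seed, anchor_proteome = anchor)
  strains_vs_species_experiment(baseline, pools$strain_pool,
                                pools$species_pool, spectra, sizes = sizes,
                                n_replicates = n_replicates,
                                params = params, seed = seed)
}

#' Graded-coverage correlation experiment
#'
#' Runs fixtures whose public-repository coverage of the community is
#' graded (fraction of uncultivated species stepped from 0 towards
#' `max_uncultivated`), computes per sample the weighted tryptic-peptide
#' metric W and the 16S-sample-matched / hybrid significant bacterial PSM
#' ratio, and returns the Spearman correlation between the two across all
#' samples.
#'
#' @param seed Base seed.
#' @param n_fixtures Number of coverage grades.
#' @param n_samples Samples per fixture.
#' @param n_spectra Spectra per sample.
#' @param max_uncultivated Largest uncultivated fraction.
#' @param params [search_params()].
#' @return List with `data` (per-sample table) and `correlation`
#'   ([weighted_metric_correlation()] output).
#' @export
run_coverage_experiment <- function(seed, n_fixtures = 10L, n_samples = 2L,
                                    n_spectra = 800L,
                                    max_uncultivated = 0.6,
                                    params = search_params()) {
  grades <- seq(0, max_uncultivated, length.out = n_fixtures)
  rows <- list()
  for (i in seq_len(n_fixtures)) {
    config <- community_config(seed = sub_seed(seed, 53 * i),
                               n_spectra = n_spectra,
                               fraction_uncultivated = grades[i])
    res <- run_strategy_benchmark(
      seed = config$seed, n_samples = n_samples, n_spectra = n_spectra,
      config = config,
      strategies = c("sample_matched_16s", "hybrid_sample_matched"),
      params = params)
    w <- res$weighted
    w[, sample_id := sprintf("F%02d_%s", i, sample_id)]
    rows[[i]] <- w
  }
  data <- rbindlist(rows)
  list(data = data, correlation = weighted_metric_correlation(data))
}
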