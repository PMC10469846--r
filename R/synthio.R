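#' Configuration of a synthetic microbial community
#'
#' Describes a synthetic species universe and sampling process emulating the
#' statistical structure of a low-diversity (vaginal-like) microbiome study:
#' a public proteome repository with uneven genome coverage (including
#' uncultivated species with zero published genomes), per-sample abundance
#' profiles drawn from a symmetric Dirichlet, shotgun ORF catalogs that
#' partially sample the expressed proteome, and two-replicate tandem mass
#' spectra with ground truth.
#'
#' @param n_species Number of bacterial species in the universe.
#' @param strains_per_species Integer range `c(lo, hi)`: strains per
#'   cultivated species.
#' @param proteins_per_strain Integer range: proteins per strain.
#' @param protein_length Integer range: protein length in residues.
#' @param richness_range Integer range `c(lo, hi)`: number of species
#'   present per sample (drawn from the universe); communities differ in
#'   membership, as across study participants.
#' @param abundance_concentration Symmetric Dirichlet concentration; small
#'   values give communities dominated by one species (Lactobacillus-like),
#'   large values give even (BV-like) communities.
#' @param fraction_uncultivated Fraction of species with zero public genomes.
#' @param strain_shared_fraction Fraction of a strain's proteins identical to
#'   the species' type strain (strain redundancy).
#' @param shotgun_capture_fraction Baseline probability that an expressed
#'   protein appears in the translated shotgun ORF catalog (attained at
#'   uniform abundance; more abundant species are captured more often).
#' @param shotgun_unresolved_fraction Fraction of catalog ORFs whose taxonomy
#'   cannot be resolved and is labeled `"Unknown"`.
#' @param replicate_shared_fraction Fraction of source peptides observed in
#'   both injection replicates.
#' @param n_spectra Total spectra generated across the two replicates.
#' @param host_protein_count Number of synthetic host proteins.
#' @param host_abundance,contaminant_abundance Fraction of total spectral
#'   signal drawn from host and contaminant proteins.
#' @param noise List with `drop_rate` (probability a true fragment peak is
#'   missing) and `spurious_rate` (expected spurious peaks per true peak).
#' @param dominant_uncultivated If `TRUE` the most abundant species of each
#'   sample is forced to be uncultivated (emulating a community dominated by
#'   a taxon with no published genome).
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A list of class `community_config`.
#' @export
community_config <- function(n_species = 16L,
                             strains_per_species = c(2L, 4L),
                             proteins_per_strain = c(12L, 20L),
                             protein_length = c(60L, 140L),
                             richness_range = c(2L, 5L),
                             abundance_concentration = 0.3,
                             fraction_uncultivated = 0.25,
                             strain_shared_fraction = 0.25,
                             shotgun_capture_fraction = 0.97,
                             shotgun_unresolved_fraction = 0.15,
                             replicate_shared_fraction = 0.52,
                             n_spectra = 2000L,
                             host_protein_count = 30L,
                             host_abundance = 0.25,
                             contaminant_abundance = 0.05,
                             noise = list(drop_rate = 0.68,
                                          spurious_rate = 3),
                             dominant_uncultivated = FALSE,
                             seed = 1L) {
  if (n_species < 1) stop("n_species must be positive")
  if (n_spectra < 1) stop("n_spectra must be >= 1")
  assert_range(strains_per_species, "strains_per_species")
  assert_range(richness_range, "richness_range")
  if (richness_range[2] > n_species)
    stop("richness_range upper bound exceeds n_species")
  assert_range(proteins_per_strain, "proteins_per_strain")
  assert_range(protein_length, "protein_length")
  if (abundance_concentration <= 0)
    stop("abundance_concentration must be positive")
  for (f in c("fraction_uncultivated", "strain_shared_fraction",
              "shotgun_capture_fraction", "shotgun_unresolved_fraction",
              "replicate_shared_fraction", "host_abundance",
              "contaminant_abundance"))
    assert_fraction(get(f), f)
  assert_fraction(noise$drop_rate, "noise$drop_rate")
  if (noise$spurious_rate < 0) stop("noise$spurious_rate must be >= 0")
  if (host_abundance + contaminant_abundance >= 1)
    stop("host_abundance + contaminant_abundance must be < 1")
  structure(list(
    n_species = as.integer(n_species),
    strains_per_species = as.integer(strains_per_species),
    proteins_per_strain = as.integer(proteins_per_strain),
    protein_length = as.integer(protein_length),
    richness_range = as.integer(richness_range),
    abundance_concentration = abundance_concentration,
    fraction_uncultivated = fraction_uncultivated,
    strain_shared_fraction = strain_shared_fraction,
    shotgun_capture_fraction = shotgun_capture_fraction,
    shotgun_unresolved_fraction = shotgun_unresolved_fraction,
    replicate_shared_fraction = replicate_shared_fraction,
    n_spectra = as.integer(n_spectra),
    host_protein_count = as.integer(host_protein_count),
    host_abundance = host_abundance,
    contaminant_abundance = contaminant_abundance,
    noise = noise,
    dominant_uncultivated = isTRUE(dominant_uncultivated),
    seed = as.integer(seed)), class = "community_config")
}

# Full species universe: every species' strains and proteomes, including the
# unpublished proteomes of uncultivated species. Deterministic in config.
generate_universe <- function(config) {
  with_seed(sub_seed(config$seed, 1), {
    n <- config$n_species
    species <- sprintf("Species_%02d", seq_len(n))
    genus <- sprintf("Genus_%02d", ceiling(seq_len(n) / 2))
    n_unc <- round(config$fraction_uncultivated * n)
    unc <- if (n_unc > 0) sample(n, n_unc) else integer(0)
    cultivated <- !(seq_len(n) %in% unc)
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      n_strain <- sample_range(config$strains_per_species[1],
                               config$strains_per_species[2])
      n_prot <- sample_range(config$proteins_per_strain[1],
                             config$proteins_per_strain[2])
      type_seqs <- random_sequences(n_prot, config$protein_length)
      strain_list <- vector("list", n_strain)
      for (s in seq_len(n_strain)) {
        if (s == 1) {
          seqs <- type_seqs
        } else {
          shared <- runif(n_prot) < config$strain_shared_fraction
          seqs <- type_seqs
          if (any(!shared))
            seqs[!shared] <- random_sequences(sum(!shared),
                                              config$protein_length)
        }
        strain_list[[s]] <- data.table(
          record_id = sprintf("%s_s%d_p%03d", species[i], s,
                              seq_len(n_prot)),
          sequence = seqs,
          species = species[i], strain = sprintf("s%d", s),
          genus = genus[i], category = "bacterial", source = "public")
      }
      recs[[i]] <- rbindlist(strain_list)
    }
    universe <- rbindlist(recs)
    cult_species <- species[cultivated]
    universe[, cultivated := species %in% cult_species]
    attr(universe, "species_table") <-
      data.table(species = species, genus = genus, cultivated = cultivated)
    universe
  })
}

#' Generate the synthetic public proteome repository
#'
#' Emulates a public sequence repository: every cultivated species
#' contributes all its strains' proteins; uncultivated species contribute
#' nothing (their proteomes exist in the community but are unpublished).
#' Byte-identical output under a fixed config seed.
#'
#' @param config A [community_config()].
#' @return `data.table` of protein records (columns `record_id`, `sequence`,
#'   `species`, `strain`, `genus`, `category`, `source`).
#' @export
generate_repository <- function(config) {
  universe <- generate_universe(config)
  out <- universe[cultivated == TRUE,
                  .(record_id, sequence, species, strain, genus, category,
                    source)]
  out[]
}

#' Generate a community sample: abundance profile and expressed proteome
#'
#' Each sample contains a random subset of the species universe (the
#' community's richness), with relative abundances drawn from a symmetric
#' Dirichlet (gamma draws normalised to the simplex). Every present species
#' expresses the proteome of one of its strains - including uncultivated
#' species whose proteins are absent from the repository - so communities
#' differ both in membership and in the strain actually present. Each
#' expressed protein carries an expression weight proportional to its
#' species' abundance.
#'
#' @param config A [community_config()].
#' @param repository The repository from [generate_repository()] (used to
#'   check the species universe matches).
#' @param sample_index Integer index selecting the per-sample random stream;
#'   different indices give different samples from the same universe.
#' @return List of class `community` with elements `profile` (columns
#'   `sample_id`, `taxon`, `species`, `genus`, `relative_abundance`; one row
#'   per present species), `proteome` (expressed protein records plus
#'   `weight` and `cultivated`), `sample_id`.
#' @export
generate_community <- function(config, repository, sample_index = 1L) {
  if (config$n_species < 1) stop("empty species universe")
  universe <- generate_universe(config)
  sp <- attr(universe, "species_table")
  if (!all(unique(repository$species) %in% sp$species))
    stop("repository does not match the configured species universe")
  sample_id <- sprintf("S%02d", sample_index)
  with_seed(sub_seed(config$seed, 100 + sample_index), {
    r <- sample_range(config$richness_range[1], config$richness_range[2])
    present <- sort(sample(config$n_species, r))
    if (config$dominant_uncultivated && any(!sp$cultivated) &&
        !any(!sp$cultivated[present])) {
      # guarantee an uncultivated species is part of the community
      unc_all <- which(!sp$cultivated)
      add <- unc_all[sample.int(length(unc_all), 1)]
      present[1] <- add
      present <- sort(unique(present))
    }
    a <- rgamma(length(present), shape = config$abundance_concentration)
    if (all(a == 0)) a[sample.int(length(present), 1)] <- 1
    a <- a / sum(a)
    if (config$dominant_uncultivated && any(!sp$cultivated[present])) {
      i_max <- which.max(a)
      if (sp$cultivated[present][i_max]) {
        unc_idx <- which(!sp$cultivated[present])
        j <- unc_idx[which.max(a[unc_idx])]
        tmp <- a[i_max]; a[i_max] <- a[j]; a[j] <- tmp
      }
    }
    profile <- data.table(sample_id = sample_id,
                          taxon = sp$species[present],
                          species = sp$species[present],
                          genus = sp$genus[present],
                          relative_abundance = a)
    # one expressed strain per present species
    strain_by_sp <- vapply(sp$species[present], function(s) {
      strains <- unique(universe[species == s, strain])
      strains[sample.int(length(strains), 1)]
    }, character(1))
    proteome <- universe[species %in% sp$species[present] &
                           strain == strain_by_sp[species],
                         .(record_id, sequence, species, strain, genus,
                           category, source, cultivated)]
    proteome[, weight := profile$relative_abundance[
      match(species, profile$species)]]
    structure(list(profile = profile, proteome = proteome,
                   sample_id = sample_id, config = config),
              class = "community")
  })
}

#' Generate a translated shotgun ORF catalog for a sample
#'
#' Each expressed bacterial protein is captured independently with
#' probability `capture^( (1/S) / a_i )` where `a_i` is its species'
#' relative abundance and `S` the number of species present: the configured
#' capture
#' fraction is attained at uniform abundance and capture improves
#' monotonically with abundance. A configured fraction of captured ORFs is
#' taxonomically unresolved and labeled `"Unknown"`. ORFs retain the true
#' amino-acid sequence under new `ORF_` record ids.
#'
#' @param community A [generate_community()] result.
#' @param config The same [community_config()].
#' @return `data.table` of protein records with `category =
#'   "translated_ORF"`, `source = "shotgun"`.
#' @export
generate_shotgun_catalog <- function(community, config) {
  prot <- community$proteome
  if (nrow(prot) == 0) stop("expressed proteome is empty")
  cap <- config$shotgun_capture_fraction
  idx <- as.integer(sub("S", "", community$sample_id))
  with_seed(sub_seed(config$seed, 500 + idx), {
    if (cap <= 0) {
      p <- rep(0, nrow(prot))
    } else if (cap >= 1) {
      p <- rep(1, nrow(prot))
    } else {
      abar <- 1 / max(1, nrow(community$profile))
      a <- pmax(prot$weight, 1e-12)
      p <- cap^(abar / a)
    }
    keep <- runif(nrow(prot)) < p
    cat_dt <- prot[keep, .(sequence, species, strain, genus)]
    if (nrow(cat_dt) > 0) {
      unres <- runif(nrow(cat_dt)) < config$shotgun_unresolved_fraction
      cat_dt[unres, `:=`(species = "Unknown", genus = "Unknown",
                         strain = "")]
      cat_dt[, record_id := sprintf("ORF_%s_%04d", community$sample_id,
                                    seq_len(.N))]
    } else {
      cat_dt[, record_id := character(0)]
    }
    cat_dt[, `:=`(category = "translated_ORF", source = "shotgun")]
    cat_dt[, .(record_id, sequence, species, strain, genus, category,
               source)][]
  })
}

#' Generate a synthetic host protein set
#'
#' @param config A [community_config()].
#' @return Protein records with `category = "host"`, `source = "core"`.
#' @export
generate_host_set <- function(config) {
  with_seed(sub_seed(config$seed, 7), {
    n <- config$host_protein_count
    data.table(record_id = sprintf("HOST_H%03d", seq_len(n)),
               sequence = random_sequences(n, config$protein_length),
               species = rep("Homo sapiens", n), strain = "",
               genus = "Homo", category = "host", source = "core")
  })
}

#' Simulate two replicate spectrum sets with ground truth
#'
#' Samples distinct fully tryptic source peptides (length 6-30, at most one
#' missed cleavage) from the expressed bacterial proteome, host set and
#' contaminant set, with sampling weight proportional to species abundance
#' (host and contaminant signal fractions set by the config). The configured
#' fraction of source peptides is observed in both replicates; the remainder
#' is split between them. Each spectrum holds the neutral precursor mass and
#' a singly charged b/y fragment-mass multiset with dropped-peak and
#' spurious-peak noise.
#'
#' @param community A [generate_community()] result.
#' @param host_set,contaminant_set Protein record tables (see
#'   [generate_host_set()], [contaminant_records()]).
#' @param config The [community_config()].
#' @return List of class `spectrum_sim`: `spectra` (both replicates; columns
#'   `spectrum_id`, `sample_id`, `replicate`, `precursor_mass`,
#'   `fragment_masses` as a `;`-joined string) and `truth` (one row per
#'   spectrum: true peptide, source protein id, taxon).
#' @export
simulate_spectra <- function(community, host_set, contaminant_set, config) {
  if (nrow(community$proteome) == 0) stop("expressed proteome is empty")
  pools <- list(
    community$proteome[, .(record_id, sequence, species,
                           w = weight * (1 - config$host_abundance -
                                           config$contaminant_abundance))],
    data.table(record_id = host_set$record_id, sequence = host_set$sequence,
               species = "Host",
               w = config$host_abundance / max(1, nrow(host_set))),
    data.table(record_id = contaminant_set$record_id,
               sequence = contaminant_set$sequence, species = "Contaminant",
               w = config$contaminant_abundance /
                 max(1, nrow(contaminant_set))))
  prot <- rbindlist(pools)
  frags <- tryptic_fragments(prot$sequence)
  base <- data.table(pidx = rep(seq_len(nrow(prot)), lengths(frags)),
                     peptide = unlist(frags))
  # allow one missed cleavage in the source-peptide pool
  mc1 <- base[, if (.N > 1) .(peptide = paste0(peptide[-.N], peptide[-1]))
              else NULL, by = pidx]
  pool <- rbindlist(list(base, mc1), use.names = TRUE)
  pool <- pool[nchar(peptide) >= 6 & nchar(peptide) <= 30]
  if (nrow(pool) == 0)
    stop("no tryptic peptide of length >= 6 in the proteome")
  pool[, `:=`(record_id = prot$record_id[pidx], species = prot$species[pidx],
              w = prot$w[pidx])]
  # one row per distinct peptide; truth source = heaviest contributing protein
  setorder(pool, peptide, -w, record_id)
  pep <- pool[, .(record_id = record_id[1], taxon = species[1],
                  w = sum(w)), by = peptide]
  idx <- as.integer(sub("S", "", community$sample_id))
  with_seed(sub_seed(config$seed, 900 + idx), {
    shared <- config$replicate_shared_fraction
    n_distinct <- max(2, min(nrow(pep),
                             floor(config$n_spectra / (1.5 * (1 + shared)))))
    sel <- pep[sample.int(nrow(pep), n_distinct, prob = pep$w)]
    n_both <- round(shared * n_distinct)
    assign_rep <- rep(list(1:2), n_both)
    rest <- n_distinct - n_both
    if (rest > 0)
      assign_rep <- c(assign_rep,
                      as.list(rep_len(c(1L, 2L), rest)))
    sel[, reps := assign_rep]
    # base draws: every selected peptide appears once in each assigned
    # replicate, so the configured overlap is recovered essentially exactly
    draws <- sel[, .(peptide = rep(peptide, lengths(reps)),
                     record_id = rep(record_id, lengths(reps)),
                     taxon = rep(taxon, lengths(reps)),
                     w = rep(w, lengths(reps)),
                     replicate = unlist(reps))]
    extra_n <- config$n_spectra - nrow(draws)
    if (extra_n > 0) {
      ei <- sample.int(nrow(draws), extra_n, replace = TRUE,
                       prob = draws$w)
      draws <- rbindlist(list(draws, draws[ei]))
    } else if (extra_n < 0) {
      draws <- draws[seq_len(config$n_spectra)]
    }
    setorder(draws, replicate)
    draws[, spectrum_id := sprintf("%s_r%d_%05d", community$sample_id,
                                   replicate,
                                   seq_len(.N)), by = replicate]
    drop_rate <- config$noise$drop_rate
    spur_rate <- config$noise$spurious_rate
    frag_str <- character(nrow(draws))
    prec <- numeric(nrow(draws))
    for (i in seq_len(nrow(draws))) {
      p <- draws$peptide[i]
      theo <- by_fragments_cpp(p)
      keep <- runif(length(theo)) >= drop_rate
      if (!any(keep)) keep[sample.int(length(theo), 1)] <- TRUE
      obs <- theo[keep]
      n_spur <- rpois(1, spur_rate * length(theo))
      if (n_spur > 0) obs <- c(obs, runif(n_spur, 100, 1900))
      obs <- round_mass(sort(obs))
      frag_str[i] <- paste(sprintf("%.6f", obs), collapse = ";")
      prec[i] <- round_mass(peptide_mass_cpp(p))
    }
    spectra <- data.table(spectrum_id = draws$spectrum_id,
                          sample_id = community$sample_id,
                          replicate = draws$replicate,
                          precursor_mass = prec,
                          fragment_masses = frag_str)
    truth <- data.table(spectrum_id = draws$spectrum_id,
                        sample_id = community$sample_id,
                        replicate = draws$replicate,
                        peptide = draws$peptide,
                        record_id = draws$record_id,
                        taxon = draws$taxon)
    structure(list(spectra = spectra, truth = truth,
                   sample_id = community$sample_id), class = "spectrum_sim")
  })
}

#' Write synthetic-community artifacts to plain-text files
#'
#' Repository and catalogs go to FASTA (canonical pipe-delimited headers),
#' the abundance profile, spectra and ground truth to TSV. Reading the files
#' back with the matching readers reproduces the in-memory objects exactly.
#'
#' @param dir Output directory (created if needed).
#' @param repository,catalog,profile,spectra,truth Optional artifacts; only
#'   supplied ones are written.
#' @return Invisible named character vector of the paths written.
#' @export
write_fixture <- function(dir, repository = NULL, catalog = NULL,
                          profile = NULL, spectra = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  paths <- c()
  if (!is.null(repository)) {
    p <- file.path(dir, "repository.fasta")
    write_protein_fasta(repository, p); paths["repository"] <- p
  }
  if (!is.null(catalog)) {
    p <- file.path(dir, "catalog.fasta")
    write_protein_fasta(catalog, p); paths["catalog"] <- p
  }
  if (!is.null(profile)) {
    p <- file.path(dir, "profile.tsv")
    fwrite(as.data.table(profile)[, .(sample_id, taxon, species, genus,
                                      relative_abundance = format_full(
                                        relative_abundance))],
           p, sep = "\t"); paths["profile"] <- p
  }
  if (!is.null(spectra)) {
    p <- file.path(dir, "spectra.tsv")
    dt <- as.data.table(spectra)
    dt <- dt[, .(spectrum_id, sample_id, replicate,
                 precursor_mass = sprintf("%.6f", precursor_mass),
                 fragment_masses)]
    fwrite(dt, p, sep = "\t"); paths["spectra"] <- p
  }
  if (!is.null(truth)) {
    p <- file.path(dir, "truth.tsv")
    fwrite(as.data.table(truth), p, sep = "\t"); paths["truth"] <- p
  }
  invisible(paths)
}

#' @rdname write_fixture
#' @param path File path to read.
#' @export
read_abundance_profile <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("sample_id", "taxon",
                                              "species", "genus")))
  dt[, relative_abundance := as.numeric(relative_abundance)]
  dt[]
}

#' @rdname write_fixture
#' @export
read_spectra <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("spectrum_id", "sample_id",
                                              "fragment_masses")))
  dt[, `:=`(replicate = as.integer(replicate),
            precursor_mass = as.numeric(precursor_mass))]
  dt[]
}

#' @rdname write_fixture
#' @export
read_truth <- function(path) {
  fread(path, sep = "\t", colClasses = "character")[
    , replicate := as.integer(replicate)][]
}

# Parse a ";"-joined fragment string into a sorted numeric vector.
parse_fragments <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(v) sort(as.numeric(v)))
}
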