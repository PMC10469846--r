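# Small fixtures shared across the suite. Everything is generated in code.

library(data.table)

toy_config <- function(seed = 1L, ...) {
  args <- list(n_species = 6L, strains_per_species = c(1L, 2L),
               proteins_per_strain = c(5L, 8L),
               protein_length = c(40L, 80L), richness_range = c(2L, 4L),
               n_spectra = 200L, host_protein_count = 8L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(community_config, args)
}

toy_records <- function(ids, seqs, species = "Species_X", strain = "s1",
                        genus = "Genus_X", category = "bacterial",
                        source = "public") {
  protein_records(record_id = ids, sequence = seqs, species = species,
                  strain = strain, genus = genus, category = category,
                  source = source)
}

random_toy_records <- function(n, seed, species = "Species_X",
                               len = c(30L, 60L)) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      L <- sample(len[1]:len[2], 1)
      paste(sample(c("A", "C", "D", "E", "G", "K", "L", "P", "R", "S"),
                   L, replace = TRUE), collapse = "")
    }, character(1))
    toy_records(sprintf("P%03d", seq_len(n)), seqs, species = species)
  })
}

toy_psms <- function(scores, decoy, probs = NULL, ids = NULL) {
  n <- length(scores)
  data.table(
    spectrum_id = ids %||% sprintf("spec%03d", seq_len(n)),
    sample_id = "S01", replicate = 1L,
    peptide = sprintf("PEPTIDEK%03d", seq_len(n)),
    protein_ids = sprintf("P%03d", seq_len(n)),
    is_decoy = decoy,
    raw_score = as.integer(scores),
    spectral_probability = probs %||% rep(0.5, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force q-value oracle: for every candidate threshold
# (each PSM's rank position in the sorted list), FDR = D/max(1, T) among
# PSMs at or above; q at a rank is the minimum FDR over that rank and all
# worse ranks.
oracle_qvalues <- function(scores, decoy, probs, ids) {
  ord <- order(-scores, probs, ids)
  d <- decoy[ord]
  fdr <- cumsum(d) / pmax(1, cumsum(!d))
  q <- numeric(length(fdr))
  m <- Inf
  for (i in rev(seq_along(fdr))) {
    m <- min(m, fdr[i])
    q[i] <- min(1, m)
  }
  q[order(ord)]
}

greedy_oracle <- function(valid, db, prob_threshold = 1e-15) {
  # independent reimplementation with plain lists, same visit order
  recs <- db$records
  seq_groups <- split(recs$record_id, recs$sequence)
  reps <- vapply(seq_groups, function(g) sort(g)[1], "")
  rep_of <- unlist(lapply(seq_along(seq_groups), function(i)
    setNames(rep(reps[i], length(seq_groups[[i]])), seq_groups[[i]])))
  prot_peps <- list()
  for (i in seq_len(nrow(valid))) {
    for (m in strsplit(valid$protein_ids[i], ";")[[1]]) {
      r <- rep_of[m]
      if (is.na(r)) next
      prot_peps[[r]] <- union(prot_peps[[r]], valid$peptide[i])
    }
  }
  occ <- setNames(valid$n_psms, valid$peptide)
  mp <- setNames(valid$min_prob, valid$peptide)
  ord <- names(prot_peps)[order(-lengths(prot_peps), names(prot_peps))]
  pool <- unique(valid$peptide)
  counted <- character(0)
  for (p in ord) {
    peps <- intersect(prot_peps[[p]], pool)
    if (!length(peps)) next
    if (length(peps) >= 2 || any(occ[peps] >= 2) ||
        any(mp[peps] < prob_threshold)) {
      counted <- c(counted, p)
      pool <- setdiff(pool, peps)
    }
  }
  counted
}

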