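FIVE_STRATEGIES <- c("pooled_16s", "sample_matched_16s", "shotgun_pooled",
                     "shotgun_sample_matched", "hybrid_sample_matched")

#' Relative identification rates across database strategies
#'
#' For each sample and PSM type, divides each strategy's significant PSM
#' count by the sample's mean count over the five compared strategies
#' (pooled and sample-matched public, pooled and sample-matched shotgun,
#' hybrid). By construction the rates average to 1 within each
#' (sample, type).
#'
#' @param results `data.frame` with columns `sample_id`, `strategy`,
#'   `psm_type` (human|bacterial), `count`.
#' @return `data.table` with a `rate` column added.
#' @export
relative_identification_rate <- function(results) {
  dt <- as.data.table(results)
  miss <- dt[, .(ok = all(FIVE_STRATEGIES %in% strategy)),
             by = .(sample_id, psm_type)]
  if (any(!miss$ok))
    stop("each (sample, psm_type) must carry exactly the five compared ",
         "strategies")
  dt <- dt[strategy %in% FIVE_STRATEGIES]
  dt[, rate := {
    m <- mean(count)
    if (m == 0) stop("zero mean significant PSMs for sample ", sample_id[1])
    count / m
  }, by = .(sample_id, psm_type)]
  dt[]
}

#' Pairwise database comparison by paired Wilcoxon signed-rank tests
#'
#' Two-sided Wilcoxon signed-rank tests on paired per-sample significant
#' PSM counts for every strategy pair and PSM type; a pair is flagged
#' significant at `P < alpha` with the direction of the median difference.
#' All-zero difference vectors are reported as non-significant with a note.
#'
#' @param results As in [relative_identification_rate()].
#' @param alpha Significance level (default 0.01).
#' @return `data.table`: `psm_type`, `strategy_a`, `strategy_b`, `p_value`,
#'   `direction` (+1 a>b, -1 a<b, 0), `significant`, `note`.
#' @export
pairwise_db_comparison <- function(results, alpha = 0.01) {
  dt <- as.data.table(results)
  strategies <- sort(unique(dt$strategy))
  out <- list()
  for (type in unique(dt$psm_type)) {
    sub <- dt[psm_type == type]
    wide <- data.table::dcast(sub, sample_id ~ strategy,
                              value.var = "count")
    for (i in seq_along(strategies)) for (j in seq_along(strategies)) {
      if (i >= j) next
      a <- wide[[strategies[i]]]; b <- wide[[strategies[j]]]
      d <- a - b
      if (all(d == 0)) {
        out[[length(out) + 1]] <- data.table(
          psm_type = type, strategy_a = strategies[i],
          strategy_b = strategies[j], p_value = NA_real_, direction = 0L,
          significant = FALSE, note = "all paired differences zero")
        next
      }
      p <- suppressWarnings(wilcox.test(a, b, paired = TRUE)$p.value)
      out[[length(out) + 1]] <- data.table(
        psm_type = type, strategy_a = strategies[i],
        strategy_b = strategies[j], p_value = p,
        direction = as.integer(sign(median(d))),
        significant = p < alpha, note = "")
    }
  }
  rbindlist(out)
}

#' Presumptive false-positive rate of a database search
#'
#' Percentage of significant bacterial PSMs in a sample that exclusively
#' match taxa below the abundance cutoff (default genus rank, <0.1%),
#' likely representing false positives. Taxa absent from the profile
#' (including `"Unknown"`) count as zero abundance.
#'
#' @param psms Significant bacterial PSM table carrying `genus_set` /
#'   `species_set` (see [assign_taxa()]) and `sample_id`.
#' @param profile The sample's abundance profile.
#' @param cutoff Abundance cutoff (default 0.001).
#' @param rank `"genus"` or `"species"`.
#' @return Percentage (scalar, 0-100); `NA` when the sample has zero
#'   bacterial PSMs.
#' @export
presumptive_false_positive_rate <- function(psms, profile, cutoff = 0.001,
                                            rank = c("genus", "species")) {
  rank <- match.arg(rank)
  psms <- as.data.table(psms)
  if (nrow(psms) == 0) return(NA_real_)
  profile <- as.data.table(profile)
  ab <- if (rank == "genus")
    profile[, .(taxon = genus, a = sum(relative_abundance)), by = genus][
      , .(taxon, a)]
  else profile[, .(taxon = species, a = relative_abundance)]
  ab_by <- setNames(ab$a, ab$taxon)
  sets <- strsplit(psms[[paste0(rank, "_set")]], ";", fixed = TRUE)
  low <- vapply(sets, function(s) {
    a <- ab_by[s]; a[is.na(a)] <- 0
    all(a < cutoff)
  }, logical(1))
  100 * mean(low)
}

#' Functional differential abundance from spectral counts
#'
#' Assigns each PSM the annotation terms of its first matched protein,
#' totals spectral counts per term and sample, normalises by the sample's
#' total PSMs of the same category, log2-transforms (zeros handled as
#' `log2(x + eps)` with `eps` = half the smallest nonzero relative
#' abundance) and tests each term between two groups with a Mann-Whitney U
#' test. Terms absent in all samples are excluded.
#'
#' @param psms Classified significant PSM table of one category across
#'   samples.
#' @param annotation_map `data.frame` with `protein_id`, `term_id`.
#' @param groups Named vector mapping `sample_id` to one of two group
#'   labels.
#' @param alpha Significance level (default 0.01).
#' @param adjust If `TRUE`, apply Benjamini-Hochberg correction before
#'   thresholding (off by default).
#' @return List with `per_term` table (`term_id`, `p_value`, `direction`,
#'   `significant`) and `n_significant`.
#' @export
functional_differential_abundance <- function(psms, annotation_map, groups,
                                              alpha = 0.01,
                                              adjust = FALSE) {
  ann <- as.data.table(annotation_map)
  if (nrow(ann) == 0) stop("empty annotation map")
  psms <- as.data.table(psms)
  samples <- names(groups)
  first_prot <- vapply(strsplit(psms$protein_ids, ";", fixed = TRUE),
                       `[`, "", 1)
  dt <- data.table(sample_id = psms$sample_id, protein_id = first_prot)
  totals <- dt[, .(total = .N), by = sample_id]
  dt <- merge(dt, ann, by = "protein_id", allow.cartesian = TRUE)
  if (nrow(dt) == 0)
    return(list(per_term = data.table(term_id = character(0),
                                      p_value = numeric(0),
                                      direction = integer(0),
                                      significant = logical(0)),
                n_significant = 0L))
  counts <- dt[, .(count = .N), by = .(sample_id, term_id)]
  full <- data.table::CJ(sample_id = samples,
                         term_id = unique(counts$term_id))
  counts <- merge(full, counts, by = c("sample_id", "term_id"),
                  all.x = TRUE)
  counts[is.na(count), count := 0L]
  counts <- merge(counts, totals, by = "sample_id", all.x = TRUE)
  counts[is.na(total) | total == 0, total := 1L]
  counts[, rel := count / total]
  nz <- counts[rel > 0, rel]
  eps <- if (length(nz)) min(nz) / 2 else 1e-6
  counts[, value := log2(rel + eps)]
  res <- counts[, {
    g <- groups[sample_id]
    x <- value[g == sort(unique(groups))[1]]
    y <- value[g == sort(unique(groups))[2]]
    p <- if (all(value == value[1])) NA_real_
    else suppressWarnings(wilcox.test(x, y)$p.value)
    .(p_value = p, direction = as.integer(sign(median(x) - median(y))))
  }, by = term_id]
  if (adjust) res[, p_value := p.adjust(p_value, "BH")]
  res[, significant := !is.na(p_value) & p_value < alpha]
  list(per_term = res[], n_significant = sum(res$significant))
}

#' Correlation between database completeness and relative performance
#'
#' Per sample, the relative performance of the public sample-matched
#' database is its significant bacterial PSM count divided by its hybrid
#' counterpart's. Spearman's rank-order correlation is computed between the
#' weighted tryptic-peptide metric W and that ratio; the expected direction
#' is positive (more public sequence, less benefit from shotgun data).
#'
#' @param data `data.frame` with `sample_id`, `W`, `sm_count`,
#'   `hybrid_count`.
#' @return List with `rho`, `p_value`, `n`, `ratios` table.
#' @export
weighted_metric_correlation <- function(data) {
  dt <- as.data.table(data)
  if (any(dt$hybrid_count == 0)) {
    warning("dropping sample(s) with zero hybrid PSM count: ",
            paste(dt[hybrid_count == 0, sample_id], collapse = ", "))
    dt <- dt[hybrid_count > 0]
  }
  if (nrow(dt) < 5) stop("fewer than 5 usable samples")
  dt[, ratio := sm_count / hybrid_count]
  ct <- suppressWarnings(cor.test(dt$W, dt$ratio, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = nrow(dt),
       ratios = dt[])
}

#' Share of samples where the hybrid database dominates
#'
#' Percent of samples in which the hybrid database identified as many or
#' more significant bacterial PSMs than the public sample-matched database,
#' rounded to integer percent.
#'
#' @param sm_counts,hybrid_counts Paired per-sample counts.
#' @return Integer percentage.
#' @export
hybrid_dominance_share <- function(sm_counts, hybrid_counts) {
  stopifnot(length(sm_counts) == length(hybrid_counts))
  as.integer(round(100 * mean(hybrid_counts >= sm_counts)))
}

#' Overlap of spectra identified by two database strategies
#'
#' Partitions the union of significantly identified spectra into A-only,
#' B-only and both (percentages). For the A-only spectra also reports the
#' fraction that strategy B assigned the same peptide sequence but at
#' `q >=` the threshold - the diagnostic separating "new identifications"
#' from "identifications lost to a stricter significance threshold".
#'
#' @param psms_a,psms_b Full PSM tables (with q-values) from the two
#'   strategies over the same spectra.
#' @param q_threshold Significance threshold.
#' @return List with `percentages` (only_a, only_b, both), `counts`, and
#'   `same_peptide_insignificant_fraction`.
#' @export
exclusive_spectra_overlap <- function(psms_a, psms_b, q_threshold = 0.01) {
  a <- as.data.table(psms_a); b <- as.data.table(psms_b)
  sig_a <- a[q_value < q_threshold & !is_decoy, spectrum_id]
  sig_b <- b[q_value < q_threshold & !is_decoy, spectrum_id]
  only_a <- setdiff(sig_a, sig_b); only_b <- setdiff(sig_b, sig_a)
  both <- intersect(sig_a, sig_b)
  u <- length(only_a) + length(only_b) + length(both)
  counts <- c(only_a = length(only_a), only_b = length(only_b),
              both = length(both))
  pct <- if (u > 0) 100 * counts / u else counts * NA_real_
  frac <- NA_real_
  if (length(only_a)) {
    bm <- b[match(only_a, spectrum_id)]
    am <- a[match(only_a, spectrum_id)]
    same <- !is.na(bm$peptide) & bm$peptide == am$peptide &
      bm$q_value >= q_threshold
    frac <- mean(same)
  }
  list(counts = counts, percentages = pct,
       same_peptide_insignificant_fraction = frac)
}

#' Strains-versus-species database augmentation experiment
#'
#' Augments a baseline database with protein sequences from randomly chosen
#' genomes out of a strain pool (strains of one species, high sequence
#' redundancy) or a species pool (distinct species), at several sizes with
#' replicate random databases, runs one-step searches and reports the
#' fold-change in significant (q < 0.01, non-decoy) PSMs relative to the
#' baseline, along with database sizes in distinct sequences.
#'
#' @param baseline A `protein_db`.
#' @param strain_pool,species_pool Record tables with `genome_id` columns.
#' @param spectra Spectrum table to search.
#' @param sizes Genome counts to add.
#' @param n_replicates Random databases per cell.
#' @param params [search_params()].
#' @param seed Base seed.
#' @param q_threshold Significance threshold.
#' @return `data.table`: `pool`, `size`, `rep`, `n_psm`, `fold_change`,
#'   `db_sequences`.
#' @export
strains_vs_species_experiment <- function(baseline, strain_pool,
                                          species_pool, spectra,
                                          sizes = c(20, 40, 60, 80, 100),
                                          n_replicates = 3,
                                          params = search_params(),
                                          seed = 1L, q_threshold = 0.01) {
  for (pool_dt in list(strain_pool, species_pool))
    if (length(unique(as.data.table(pool_dt)$genome_id)) < max(sizes))
      stop("pool smaller than the largest requested size")
  count_sig <- function(db) {
    psms <- compute_qvalues(search_spectra(spectra, db, params))
    nrow(psms[q_value < q_threshold & !is_decoy])
  }
  base_n <- count_sig(baseline)
  out <- list()
  pools <- list(strains = strain_pool, species = species_pool)
  for (pn in names(pools)) {
    for (k in sizes) {
      for (r in seq_len(n_replicates)) {
        if (k == 0) {
          db <- baseline
        } else {
          db <- build_augmented(baseline, pools[[pn]], k,
                                seed = sub_seed(seed, 1000 * k + r +
                                                  ifelse(pn == "strains",
                                                         0, 7)))
        }
        n <- count_sig(db)
        out[[length(out) + 1]] <- data.table(
          pool = pn, size = k, rep = r, n_psm = n,
          fold_change = if (base_n > 0) n / base_n else NA_real_,
          db_sequences = database_stats(db)$distinct_sequences)
      }
    }
  }
  res <- rbindlist(out)
  attr(res, "baseline_psms") <- base_n
  res[]
}

#' Write benchmark report tables
#'
#' Serialises computed metric tables to deterministic TSV files (one per
#' metric) in an output directory.
#'
#' @param metrics Named list of data.frames.
#' @param outdir Output directory.
#' @return Invisible character vector of paths written.
#' @export
report_tables <- function(metrics, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(metrics)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    fwrite(as.data.table(metrics[[nm]]), p, sep = "\t")
    paths[nm] <- p
  }
  invisible(paths)
}
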