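CLASS_LEVELS <- c("decoy", "contaminant", "human", "fungal", "trichomonas",
                  "bacterial")

# record_id -> category/species/genus lookup for a database (decoys added).
category_index <- function(db) {
  recs <- if (inherits(db, "protein_db")) db$records else as.data.table(db)
  idx <- recs[, .(record_id, category, species, genus)]
  dec <- idx[, .(record_id = paste0("XXX_", record_id), category = "decoy",
                 species = species, genus = genus)]
  rbindlist(list(idx, dec))
}

#' Hierarchical PSM classification
#'
#' Each PSM receives exactly one label by precedence over the categories of
#' its matched proteins: any decoy match makes it a decoy; otherwise any
#' contaminant match makes it a contaminant; otherwise any host match makes
#' it human, then fungal, then trichomonas (parasite); a PSM matching only
#' bacterial proteins (translated ORFs included) is bacterial.
#'
#' @param psms PSM table.
#' @param db The searched `protein_db` (used to resolve protein categories).
#' @return The PSM table with a `classification` column.
#' @export
classify_psms <- function(psms, db) {
  psms <- as.data.table(psms)
  idx <- category_index(db)
  cat_by_id <- setNames(idx$category, idx$record_id)
  prots <- strsplit(psms$protein_ids, ";", fixed = TRUE)
  all_ids <- unique(unlist(prots))
  unresolved <- setdiff(all_ids, names(cat_by_id))
  if (length(unresolved))
    stop("unresolvable protein id(s): ",
         paste(head(unresolved, 5), collapse = ", "))
  lab <- vapply(prots, function(p) {
    cats <- cat_by_id[p]
    if (any(cats == "decoy")) "decoy"
    else if (any(cats == "contaminant")) "contaminant"
    else if (any(cats == "host")) "human"
    else if (any(cats == "fungal")) "fungal"
    else if (any(cats == "parasite")) "trichomonas"
    else "bacterial"
  }, character(1))
  psms[, classification := lab]
  psms[]
}

#' Filter PSMs at a q-value threshold
#'
#' Strict inequality `q < q_threshold`. Decoy and contaminant PSMs are
#' removed after being counted; the removed counts are attached as the
#' `"audit"` attribute.
#'
#' @param psms Classified PSM table with `q_value`.
#' @param q_threshold Significance threshold (default 0.01).
#' @return Filtered PSM table (audit counts in `attr(, "audit")`).
#' @export
filter_significant <- function(psms, q_threshold = 0.01) {
  psms <- as.data.table(psms)
  if (nrow(psms) == 0) {
    out <- copy(psms)
    setattr(out, "audit", data.table(classification = character(0),
                                     n = integer(0)))
    return(out)
  }
  sig <- psms[q_value < q_threshold]
  audit <- sig[, .(n = .N), by = classification]
  out <- if ("classification" %in% names(sig))
    sig[!classification %in% c("decoy", "contaminant")] else sig
  setattr(out, "audit", audit)
  out[]
}

#' Peptides passing the validity rules
#'
#' A peptide from the significant PSM set is carried forward if (i) any
#' supporting PSM has spectral probability below `prob_threshold`, or (ii)
#' some matched protein has at least two distinct significant peptides (each
#' such peptide then qualifies under the two-peptide rule).
#'
#' @param psms Significant, classified PSM table (decoys/contaminants
#'   removed).
#' @param prob_threshold Spectral-probability cutoff (default 1e-15).
#' @return `data.table`: `peptide`, `rule` (probability | two_peptide),
#'   `n_psms`, `min_prob`, `protein_ids` (union over supporting PSMs).
#' @export
valid_peptides <- function(psms, prob_threshold = 1e-15) {
  psms <- as.data.table(psms)
  if (nrow(psms) == 0)
    return(data.table(peptide = character(0), rule = character(0),
                      n_psms = integer(0), min_prob = numeric(0),
                      protein_ids = character(0)))
  pep <- psms[, .(n_psms = .N, min_prob = min(spectral_probability),
                  protein_ids = paste(sort(unique(unlist(
                    strsplit(protein_ids, ";", fixed = TRUE)))),
                    collapse = ";")),
              by = peptide]
  long <- pep[, .(record_id = strsplit(protein_ids, ";", fixed = TRUE)[[1]]),
              by = peptide]
  multi <- long[, .(n_pep = length(unique(peptide))), by = record_id]
  two_prot <- multi[n_pep >= 2, record_id]
  two_pep <- unique(long[record_id %in% two_prot, peptide])
  pep[, rule := ifelse(min_prob < prob_threshold, "probability",
                       ifelse(peptide %in% two_pep, "two_peptide",
                              NA_character_))]
  out <- pep[!is.na(rule), .(peptide, rule, n_psms, min_prob, protein_ids)]
  setorder(out, peptide)
  out[]
}

#' Greedy unique-protein counting
#'
#' Iterates over the non-redundant proteins (identical sequences collapsed)
#' in deterministic order - descending number of distinct supporting valid
#' peptides, ties by ascending record id - and counts a protein as
#' identified if, against the current peptide pool, (i) more than one
#' non-identical peptide matches it, (ii) a matching peptide was identified
#' more than once, or (iii) a matching peptide has spectral probability
#' below the threshold. Once counted, all peptides matching the protein
#' leave the pool, so shared peptides support at most one counted protein.
#'
#' @param valid Output of [valid_peptides()].
#' @param db The searched `protein_db`.
#' @param prob_threshold Spectral-probability cutoff for rule (iii).
#' @return List with `counts` (named: human, bacterial) and `proteins`
#'   (`data.table` of counted representatives with category and rule).
#' @export
count_unique_proteins <- function(valid, db, prob_threshold = 1e-15) {
  recs <- if (inherits(db, "protein_db")) db$records else as.data.table(db)
  empty <- list(counts = c(human = 0L, bacterial = 0L),
                proteins = data.table(record_id = character(0),
                                      category = character(0),
                                      rule = character(0)))
  if (nrow(valid) == 0) return(empty)
  # collapse identical sequences; representative = smallest record_id
  recs <- as.data.table(recs)
  grp <- recs[, .(members = list(sort(record_id))), by = sequence]
  grp[, record_id := vapply(members, `[`, "", 1)]
  grp[, category := recs$category[match(record_id, recs$record_id)]]
  member_of <- setNames(rep(grp$record_id, lengths(grp$members)),
                        unlist(grp$members))
  long <- valid[, .(member = strsplit(protein_ids, ";", fixed = TRUE)[[1]]),
                by = .(peptide, n_psms, min_prob)]
  long[, rep_id := member_of[member]]
  long <- long[!is.na(rep_id)]
  if (nrow(long) == 0) return(empty)
  pep_by_prot <- split(long$peptide, long$rep_id)
  pep_by_prot <- lapply(pep_by_prot, unique)
  pep_stats <- unique(long[, .(peptide, n_psms, min_prob)])
  n_occ <- setNames(pep_stats$n_psms, pep_stats$peptide)
  minp <- setNames(pep_stats$min_prob, pep_stats$peptide)
  ord <- order(-lengths(pep_by_prot), names(pep_by_prot))
  pool <- unique(long$peptide)
  counted <- character(0); rules <- character(0)
  for (pid in names(pep_by_prot)[ord]) {
    peps <- intersect(pep_by_prot[[pid]], pool)
    if (!length(peps)) next
    rule <- if (length(peps) >= 2) "multi_peptide"
    else if (any(n_occ[peps] >= 2)) "repeat_observation"
    else if (any(minp[peps] < prob_threshold)) "probability"
    else NA_character_
    if (!is.na(rule)) {
      counted <- c(counted, pid); rules <- c(rules, rule)
      pool <- setdiff(pool, peps)
    }
  }
  proteins <- data.table(record_id = counted,
                         category = grp$category[match(counted,
                                                       grp$record_id)],
                         rule = rules)
  counts <- c(human = sum(proteins$category == "host"),
              bacterial = sum(proteins$category %in%
                                c("bacterial", "translated_ORF")))
  list(counts = counts, proteins = proteins)
}

#' Taxonomic assignment of bacterial PSMs
#'
#' For each PSM, collects the species and genus of every matched protein
#' ("all potential protein hits") and flags whether the PSM is exclusive to
#' a single species or genus. Unresolved ORFs propagate the label
#' `"Unknown"`, which blocks exclusivity.
#'
#' @param psms PSM table (bacterial classifications are the intended input).
#' @param db The searched `protein_db`.
#' @return The table with `species_set`, `genus_set` (`;`-joined, sorted)
#'   and `species_exclusive`, `genus_exclusive` flags.
#' @export
assign_taxa <- function(psms, db) {
  psms <- as.data.table(psms)
  idx <- category_index(db)
  sp_by_id <- setNames(idx$species, idx$record_id)
  gen_by_id <- setNames(idx$genus, idx$record_id)
  prots <- strsplit(psms$protein_ids, ";", fixed = TRUE)
  sp_sets <- lapply(prots, function(p) sort(unique(sp_by_id[p])))
  gen_sets <- lapply(prots, function(p) sort(unique(gen_by_id[p])))
  psms[, `:=`(
    species_set = vapply(sp_sets, paste, "", collapse = ";"),
    genus_set = vapply(gen_sets, paste, "", collapse = ";"),
    species_exclusive = lengths(sp_sets) == 1L &
      !vapply(sp_sets, function(s) "Unknown" %in% s, logical(1)),
    genus_exclusive = lengths(gen_sets) == 1L &
      !vapply(gen_sets, function(s) "Unknown" %in% s, logical(1)))]
  psms[]
}

#' Replicate-overlap partition of valid peptides
#'
#' Partitions the union of the two replicates' peptide sets into
#' first-only, second-only and both, reporting counts and percentages of
#' the union rounded to one decimal.
#'
#' @param peptides1,peptides2 Character vectors (peptide sets per
#'   replicate).
#' @return List with `counts` and `percentages` (named: first_only,
#'   second_only, both) and `union_size`.
#' @export
replicate_overlap <- function(peptides1, peptides2) {
  p1 <- unique(peptides1); p2 <- unique(peptides2)
  if (!length(p1) && !length(p2))
    stop("both replicate peptide sets are empty: partition undefined")
  both <- intersect(p1, p2)
  counts <- c(first_only = length(setdiff(p1, p2)),
              second_only = length(setdiff(p2, p1)),
              both = length(both))
  u <- sum(counts)
  list(counts = counts,
       percentages = round(100 * counts / u, 1),
       union_size = u)
}
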