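#' Search engine parameters
#'
#' Tolerances and candidate-generation rules for the lightweight
#' target-decoy search engine. Candidate peptides are tryptic digests with
#' up to `max_missed_cleavages` missed cleavages; with `semi_tryptic = TRUE`
#' peptides with a tryptic boundary (or protein terminus) at only one end
#' are also considered ("at least partially tryptic"). The precursor window
#' is isotope-tolerant: a candidate may be off by -1 to +2 neutron masses.
#'
#' @param precursor_tol Precursor mass tolerance in Da.
#' @param fragment_tol Fragment mass tolerance in Da.
#' @param max_missed_cleavages Missed-cleavage cap for candidates.
#' @param min_length,max_length Candidate peptide length bounds (residues).
#' @param semi_tryptic Allow semi-tryptic candidates.
#' @param isotope_range Integer range of allowed precursor isotope errors.
#' @param mass_range Fragment m/z range used by the Poisson null model.
#' @return List of class `search_params`.
#' @export
search_params <- function(precursor_tol = 0.05, fragment_tol = 0.5,
                          max_missed_cleavages = 2L, min_length = 6L,
                          max_length = 30L, semi_tryptic = TRUE,
                          isotope_range = c(-1L, 2L),
                          mass_range = c(100, 1900)) {
  structure(list(precursor_tol = precursor_tol, fragment_tol = fragment_tol,
                 max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length),
                 semi_tryptic = isTRUE(semi_tryptic),
                 isotope_range = as.integer(isotope_range),
                 mass_range = mass_range), class = "search_params")
}

NEUTRON <- 1.003355

#' Build the decoy record set for a database
#'
#' One decoy per target record: the full protein sequence reversed, id
#' prefixed `XXX_`, category `decoy`. Reversal is deterministic and
#' preserves length and composition.
#'
#' @param db A `protein_db` or a protein record table.
#' @return Decoy record `data.table`, same size as the target set.
#' @export
build_decoys <- function(db) {
  recs <- if (inherits(db, "protein_db")) db$records else as.data.table(db)
  if (nrow(recs) == 0) stop("database is empty")
  data.table(record_id = paste0("XXX_", recs$record_id),
             sequence = reverse_strings(recs$sequence),
             species = recs$species, strain = recs$strain,
             genus = recs$genus, category = "decoy", source = recs$source)
}

#' Theoretical b/y fragment masses of a peptide
#'
#' Singly charged monoisotopic b and y ions, sorted ascending.
#' @param peptide Amino-acid string.
#' @return Numeric vector of length `2 * (nchar(peptide) - 1)`.
#' @export
fragment_masses <- function(peptide) by_fragments_cpp(peptide)

#' Neutral monoisotopic peptide mass
#' @param peptides Character vector of peptides.
#' @return Numeric vector (Da).
#' @export
peptide_mass <- function(peptides) peptide_mass_cpp(peptides)

spectral_prob <- function(raw_score, n_obs, pep_len, params) {
  width <- diff(params$mass_range)
  lambda <- n_obs * (2 * params$fragment_tol) * (2 * (pep_len - 1)) / width
  p <- ppois(raw_score - 1, lambda, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Score one peptide against one spectrum
#'
#' `raw_score` is the number of theoretical b/y fragment masses matching an
#' observed peak within tolerance, each observed peak usable at most once
#' (maximum matching of sorted lists). The spectral probability is the
#' survival probability of at least `raw_score` matches under a Poisson null
#' with rate `n_peaks * 2 * tol * n_fragments / mass_range`; it plays the
#' role of a search engine's spectral E-value analog: smaller is more
#' significant.
#'
#' @param spectrum One spectrum: a list/row with `fragment_masses`
#'   (`;`-joined string or numeric vector).
#' @param peptide Candidate peptide.
#' @param params [search_params()].
#' @return List with `raw_score` and `spectral_probability`.
#' @export
score_match <- function(spectrum, peptide, params = search_params()) {
  obs <- spectrum$fragment_masses %||% spectrum[["fragment_masses"]]
  if (is.character(obs)) obs <- parse_fragments(obs)[[1]]
  obs <- sort(as.numeric(obs))
  theo <- by_fragments_cpp(peptide)
  s <- match_count_cpp(theo, obs, params$fragment_tol)
  list(raw_score = s,
       spectral_probability = spectral_prob(s, length(obs), nchar(peptide),
                                            params))
}

#' Build a peptide candidate index for a record set
#'
#' Digests every record (targets and decoys alike) into candidate peptides
#' under the search parameters and returns a mass-sorted peptide table plus
#' the peptide-to-protein map. Building the index once and passing it to
#' [search_spectra()] saves time when many samples are searched against the
#' same database.
#'
#' @param records Protein record table (typically targets + decoys).
#' @param params [search_params()].
#' @return List of class `peptide_index`.
#' @export
build_peptide_index <- function(records, params = search_params()) {
  records <- as.data.table(records)
  frags <- tryptic_fragments(records$sequence)
  nfr <- lengths(frags)
  base <- data.table(ridx = rep(seq_len(nrow(records)), nfr),
                     peptide = unlist(frags))
  parts <- list(base)
  if (params$max_missed_cleavages > 0) {
    pep <- base$peptide; grp <- base$ridx
    joined_prev <- pep
    for (m in seq_len(params$max_missed_cleavages)) {
      n <- length(pep)
      if (n <= m) break
      keep <- seq_len(n - m)
      keep <- keep[grp[keep] == grp[keep + m]]
      if (!length(keep)) break
      joined <- joined_prev[keep]
      joined <- paste0(joined, pep[keep + m])
      parts[[m + 1]] <- data.table(ridx = grp[keep], peptide = joined)
      joined_prev_full <- rep(NA_character_, n)
      joined_prev_full[keep] <- joined
      joined_prev <- joined_prev_full
    }
  }
  tryp <- rbindlist(parts)
  tryp <- tryp[!is.na(peptide) & nchar(peptide) >= params$min_length &
                 nchar(peptide) <= params$max_length]
  if (params$semi_tryptic && nrow(tryp) > 0) {
    semi <- semi_tryptic_cpp(tryp$peptide, params$min_length)
    cand <- data.table(ridx = tryp$ridx[semi$parent],
                       peptide = semi$peptide)
  } else {
    cand <- tryp
  }
  cand <- unique(cand)
  cand[, record_id := records$record_id[ridx]]
  is_dec <- records$category == "decoy"
  pep_tab <- cand[, .(is_decoy_only = all(is_dec[ridx])), by = peptide]
  pep_tab[, mass := round_mass(peptide_mass_cpp(peptide))]
  setorder(pep_tab, mass)
  map <- cand[, .(peptide, record_id)]
  setkey(map, peptide)
  structure(list(peptides = pep_tab, map = map, params = params,
                 categories = records[, .(record_id, category, species,
                                          genus)]),
            class = "peptide_index")
}

#' Search spectra against a database with concurrent decoys
#'
#' For each spectrum, candidate peptides within the isotope-tolerant
#' precursor window are scored and the best-scoring peptide is retained as
#' the spectrum's PSM, with all protein ids (target and decoy) containing
#' that peptide. Ties break deterministically: lower spectral probability,
#' then lexicographically smallest peptide. Spectra with an empty candidate
#' set are omitted. Decoys are built internally (full reversal) unless an
#' index over targets + decoys is supplied.
#'
#' @param spectra Spectrum table (see [simulate_spectra()] /
#'   [read_spectra()]).
#' @param db A `protein_db`.
#' @param params [search_params()].
#' @param index Optional prebuilt [build_peptide_index()] over the db's
#'   targets plus decoys.
#' @return PSM `data.table`: `spectrum_id`, `sample_id`, `replicate`,
#'   `peptide`, `protein_ids` (`;`-joined), `is_decoy`, `raw_score`,
#'   `spectral_probability` (no q-values yet; see [compute_qvalues()]).
#' @export
search_spectra <- function(spectra, db, params = search_params(),
                           index = NULL) {
  if (inherits(db, "protein_db") && nrow(db$records) == 0)
    stop("database is empty")
  if (is.null(index)) {
    recs <- rbindlist(list(db$records[, .(record_id, sequence, species,
                                          strain, genus, category, source)],
                           build_decoys(db)), use.names = TRUE)
    index <- build_peptide_index(recs, params)
  }
  spectra <- as.data.table(spectra)
  if (nrow(spectra) == 0)
    return(empty_psm_table())
  obs_list <- parse_fragments(spectra$fragment_masses)
  masses <- index$peptides$mass
  offsets <- seq(params$isotope_range[1], params$isotope_range[2])
  pairs <- vector("list", length(offsets))
  for (k in seq_along(offsets)) {
    centre <- spectra$precursor_mass - offsets[k] * NEUTRON
    lo <- findInterval(centre - params$precursor_tol, masses)
    hi <- findInterval(centre + params$precursor_tol, masses)
    n_cand <- hi - lo
    has <- n_cand > 0
    if (!any(has)) next
    pairs[[k]] <- data.table(
      spec_idx = rep(which(has), n_cand[has]),
      pep_idx = unlist(lapply(which(has),
                              function(i) (lo[i] + 1L):hi[i])))
  }
  pairs <- rbindlist(pairs[!vapply(pairs, is.null, logical(1))])
  if (nrow(pairs) == 0) return(empty_psm_table())
  pairs <- unique(pairs)
  pairs[, peptide := index$peptides$peptide[pep_idx]]
  pairs[, raw_score := score_pairs_cpp(peptide, spec_idx, obs_list,
                                       params$fragment_tol)]
  pairs[, spectral_probability := spectral_prob(
    raw_score, lengths(obs_list)[spec_idx], nchar(peptide), params)]
  setorder(pairs, spec_idx, -raw_score, spectral_probability, peptide)
  best <- pairs[, .SD[1], by = spec_idx]
  map <- index$map
  prot <- map[best$peptide,
              .(protein_ids = paste(sort(record_id), collapse = ";"),
                is_decoy = any(startsWith(record_id, "XXX_"))),
              by = .EACHI]
  out <- data.table(spectrum_id = spectra$spectrum_id[best$spec_idx],
                    sample_id = spectra$sample_id[best$spec_idx],
                    replicate = spectra$replicate[best$spec_idx],
                    peptide = best$peptide,
                    protein_ids = prot$protein_ids[match(best$peptide,
                                                         prot$peptide)],
                    is_decoy = prot$is_decoy[match(best$peptide,
                                                   prot$peptide)],
                    raw_score = best$raw_score,
                    spectral_probability = best$spectral_probability)
  out[]
}

empty_psm_table <- function() {
  data.table(spectrum_id = character(0), sample_id = character(0),
             replicate = integer(0), peptide = character(0),
             protein_ids = character(0), is_decoy = logical(0),
             raw_score = integer(0), spectral_probability = numeric(0))
}

#' Compute target-decoy q-values for a PSM table
#'
#' PSMs are ranked by decreasing raw score (ties by increasing spectral
#' probability, then spectrum id). At each rank the FDR estimate is
#' `#decoys at or above / max(1, #targets at or above)`; the q-value is the
#' minimum FDR at that rank or any worse rank (monotonized), capped at 1.
#' Decoy PSMs retain their q-values for audit.
#'
#' @param psms PSM table with `raw_score`, `spectral_probability`,
#'   `is_decoy`.
#' @return The table with a `q_value` column, in ranked order.
#' @export
compute_qvalues <- function(psms) {
  psms <- as.data.table(psms)
  if (nrow(psms) == 0) {
    psms[, q_value := numeric(0)]
    return(psms[])
  }
  setorder(psms, -raw_score, spectral_probability, spectrum_id)
  n_dec <- cumsum(psms$is_decoy)
  n_tar <- cumsum(!psms$is_decoy)
  fdr <- n_dec / pmax(1, n_tar)
  psms[, q_value := pmin(1, rev(cummin(rev(fdr))))]
  psms[]
}

#' Two-step database search
#'
#' Step 1 searches the full database and records every matched target
#' protein regardless of statistical significance. A subset database is
#' built from those proteins plus the core set, fresh decoys are generated
#' from the subset, and step 2 re-searches the spectra against it. The
#' returned table is the step-2 result with q-values.
#'
#' @param spectra Spectrum table.
#' @param db A `protein_db`.
#' @param params [search_params()].
#' @return List with `psms` (final table), `subset_db`, `step1` (step-1
#'   table with q-values).
#' @export
two_step_search <- function(spectra, db, params = search_params()) {
  step1 <- compute_qvalues(search_spectra(spectra, db, params))
  if (nrow(step1) == 0) {
    warning("step-1 search yielded zero matches")
    return(list(psms = step1, subset_db = db, step1 = step1))
  }
  hit_ids <- unique(unlist(strsplit(step1$protein_ids, ";", fixed = TRUE)))
  hit_ids <- sub("^XXX_", "", hit_ids)
  keep <- db$records$record_id %in% hit_ids | db$records$source == "core"
  subset_db <- new_protein_db(paste0(db$name, "_subset"), db$strategy,
                              db$records[keep], sample_id = db$sample_id)
  psms <- compute_qvalues(search_spectra(spectra, subset_db, params))
  list(psms = psms, subset_db = subset_db, step1 = step1)
}

#' Condense per-chunk search results into one PSM table
#'
#' When a large database is searched in chunks, the same spectrum may carry
#' one PSM per chunk; the single PSM with the highest raw score survives
#' (ties as in [compute_qvalues()]) and q-values are recomputed on the
#' condensed table.
#'
#' @param chunks List of PSM tables covering the same spectra.
#' @return Condensed PSM table with recomputed q-values.
#' @export
condense_results <- function(chunks) {
  if (is.data.frame(chunks)) chunks <- list(chunks)
  all_psms <- rbindlist(lapply(chunks, as.data.table), use.names = TRUE,
                        fill = TRUE)
  if (nrow(all_psms) == 0) return(compute_qvalues(all_psms))
  setorder(all_psms, spectrum_id, -raw_score, spectral_probability, peptide,
           protein_ids)
  best <- all_psms[, .SD[1], by = spectrum_id]
  compute_qvalues(best)
}

#' Combine the two replicate searches of one sample
#'
#' Concatenates the PSM tables (replicate labels preserved) and recomputes
#' q-values on the union, the form consumed by downstream classification.
#'
#' @param psms1,psms2 PSM tables for replicates 1 and 2 of one sample.
#' @return Combined PSM table with recomputed q-values.
#' @export
merge_replicates <- function(psms1, psms2) {
  psms1 <- as.data.table(psms1); psms2 <- as.data.table(psms2)
  s1 <- unique(psms1$sample_id); s2 <- unique(psms2$sample_id)
  if (length(s1) && length(s2) && !identical(sort(s1), sort(s2)))
    stop("sample_id mismatch between replicate tables")
  compute_qvalues(rbindlist(list(psms1, psms2), use.names = TRUE))
}

# --- MS-GF+ TSV import ----------------------------------------------------

#' Import an MS-GF+ TSV result file
#'
#' Maps the MS-GF+ TSV dialect onto the internal PSM table: `SpecID` becomes
#' the spectrum id, `Protein` (``;``-separated) the matched ids (decoys are
#' recognised by the `XXX_` prefix), `SpecEValue` the spectral probability
#' and `QValue` the q-value. Peptide flanking annotations (`K.PEPTIDER.A`)
#' are stripped to the bare sequence.
#'
#' @param path TSV file path.
#' @return PSM `data.table`.
#' @export
read_msgf_tsv <- function(path) {
  dt <- fread(path, sep = "\t", colClasses = "character")
  required <- c("#SpecFile", "SpecID", "ScanNum", "Peptide", "Protein",
                "SpecEValue", "QValue")
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("missing mandatory MS-GF+ column(s): ",
         paste(missing, collapse = ", "))
  pep <- sub("^[A-Z_-]\\.", "", dt$Peptide)
  pep <- sub("\\.[A-Z_-]$", "", pep)
  prot <- strsplit(dt$Protein, ";", fixed = TRUE)
  out <- data.table(
    spectrum_id = dt$SpecID,
    sample_id = dt$`#SpecFile`,
    replicate = NA_integer_,
    scan_num = as.integer(dt$ScanNum),
    peptide = pep,
    protein_ids = vapply(prot, function(p) paste(sort(p), collapse = ";"),
                         character(1)),
    is_decoy = vapply(prot, function(p) any(startsWith(p, "XXX_")),
                      logical(1)),
    raw_score = if ("MSGFScore" %in% names(dt)) as.integer(dt$MSGFScore)
                else NA_integer_,
    spectral_probability = as.numeric(dt$SpecEValue),
    q_value = as.numeric(dt$QValue))
  out[]
}

#' @rdname read_msgf_tsv
#' @param psms PSM table to export in the MS-GF+ TSV dialect.
#' @export
write_msgf_tsv <- function(psms, path) {
  psms <- as.data.table(psms)
  out <- data.table(
    `#SpecFile` = psms$sample_id,
    SpecID = psms$spectrum_id,
    ScanNum = if ("scan_num" %in% names(psms)) psms$scan_num
              else seq_len(nrow(psms)),
    Peptide = psms$peptide,
    Protein = psms$protein_ids,
    MSGFScore = psms$raw_score,
    SpecEValue = format_full(psms$spectral_probability),
    QValue = format_full(if ("q_value" %in% names(psms)) psms$q_value
                         else rep(NA_real_, nrow(psms))))
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write / read the internal PSM TSV format
#' @param psms PSM table.
#' @param path File path.
#' @return `read_psm_tsv()` returns a PSM `data.table`.
#' @export
write_psm_tsv <- function(psms, path) {
  dt <- copy(as.data.table(psms))
  dt[, spectral_probability := format_full(spectral_probability)]
  if ("q_value" %in% names(dt)) dt[, q_value := format_full(q_value)]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("spectrum_id", "sample_id",
                                              "peptide", "protein_ids")))
  dt[, `:=`(replicate = as.integer(replicate),
            is_decoy = as.logical(is_decoy),
            raw_score = as.integer(raw_score),
            spectral_probability = as.numeric(spectral_probability))]
  if ("q_value" %in% names(dt)) dt[, q_value := as.numeric(q_value)]
  dt[]
}
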