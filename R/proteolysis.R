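#' Tryptic digestion parameters
#'
#' Trypsin cleaves C-terminal to lysine (K) or arginine (R); by convention a
#' cleavage is suppressed when the next residue is proline. These parameters
#' control in silico digestion throughout the package.
#'
#' @param max_missed_cleavages Maximum number of internal (missed) cleavage
#'   sites allowed in an emitted peptide. Nonnegative integer.
#' @param min_length Minimum peptide length in residues; shorter peptides are
#'   dropped from the output.
#' @param suppress_cleavage_before_proline Logical; skip K/R cleavage when the
#'   following residue is proline (the standard trypsin rule).
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(max_missed_cleavages = 0L, min_length = 1L,
                          suppress_cleavage_before_proline = TRUE) {
  if (min_length < 1) stop("min_length must be >= 1")
  if (max_missed_cleavages < 0) stop("max_missed_cleavages must be >= 0")
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 suppress_cleavage_before_proline =
                   isTRUE(suppress_cleavage_before_proline)),
            class = "digest_params")
}

# Vectorised base tryptic fragments (0 missed cleavages, no length filter).
# Returns a list of character vectors, one per input sequence.
tryptic_fragments <- function(sequences, suppress_proline = TRUE) {
  pattern <- if (suppress_proline) "(?<=[KR])(?!P)" else "(?<=[KR])"
  strsplit(sequences, pattern, perl = TRUE)
}

#' In silico tryptic digestion of one protein
#'
#' Cleaves C-terminal to K or R (optionally suppressed before proline) and
#' emits every peptide with at most `max_missed_cleavages` internal cleavage
#' sites, ordered by start position and then by missed-cleavage count.
#' Peptides shorter than `min_length` are excluded. With zero missed
#' cleavages and `min_length = 1` the output concatenates back to the input.
#'
#' @param sequence Nonempty uppercase amino-acid string (20 standard
#'   residues).
#' @param params A [digest_params()] object.
#' @return Character vector of peptides.
#' @examples
#' digest_protein("AKRLEK", digest_params(0, 1))   # "AK"  "R"  "LEK"
#' digest_protein("AKPLLR", digest_params(0, 1))   # "AKPLLR" (K before P)
#' @export
digest_protein <- function(sequence, params = digest_params()) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence))
    stop("sequence must be a single nonempty string")
  if (grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), sequence))
    stop("sequence contains non-amino-acid characters")
  frags <- tryptic_fragments(sequence,
                             params$suppress_cleavage_before_proline)[[1]]
  n <- length(frags)
  out <- character(0)
  for (i in seq_len(n)) {
    for (m in 0:params$max_missed_cleavages) {
      j <- i + m
      if (j > n) break
      out <- c(out, paste(frags[i:j], collapse = ""))
    }
  }
  out[nchar(out) >= params$min_length]
}

#' Unique tryptic peptides per species
#'
#' Digests every protein fully tryptically (0 missed cleavages) and counts,
#' for each species, the distinct peptide sequences passing the length
#' filter. Duplicate peptides within and across proteins of one species
#' count once. The default length filter keeps peptides longer than five
#' residues, the convention used for the database-completeness metric.
#'
#' @param records A protein record table (see [protein_records()]) with
#'   `species` and `sequence` columns.
#' @param params A [digest_params()]; defaults to 0 missed cleavages and
#'   `min_length = 6`.
#' @return `data.table` with columns `species`, `n_peptides`.
#' @export
unique_tryptic_peptides <- function(records,
                                    params = digest_params(0L, 6L)) {
  records <- as.data.table(records)
  if (nrow(records) == 0)
    return(data.table(species = character(0), n_peptides = integer(0)))
  frags <- tryptic_fragments(records$sequence,
                             params$suppress_cleavage_before_proline)
  dt <- data.table(species = rep(records$species, lengths(frags)),
                   peptide = unlist(frags))
  if (params$max_missed_cleavages > 0) {
    # rebuild per-protein fragment runs to honour missed cleavages
    idx <- rep(seq_len(nrow(records)), lengths(frags))
    extra <- list()
    for (m in seq_len(params$max_missed_cleavages)) {
      pep <- dt$peptide
      grp <- idx
      n <- length(pep)
      keep <- seq_len(n - m)
      keep <- keep[grp[keep] == grp[keep + m]]
      if (!length(keep)) break
      joined <- pep[keep]
      for (s in seq_len(m)) joined <- paste0(joined, pep[keep + s])
      extra[[m]] <- data.table(species = dt$species[keep], peptide = joined)
    }
    dt <- rbindlist(c(list(dt), extra))
  }
  dt <- dt[nchar(peptide) >= params$min_length]
  out <- dt[, .(n_peptides = length(unique(peptide))), by = species]
  setorder(out, species)
  out[]
}

#' Weighted tryptic-peptide completeness of a sample-matched database
#'
#' Computes `W = sum_i ln(1 + G_i) * A_i`, where `G_i` is the number of
#' unique tryptic peptides (longer than five residues) available in the
#' public repository for species `i` and `A_i` its relative abundance in the
#' sample. `W` summarises how much searchable sequence the public repository
#' offers for the community actually present; it is monotone nondecreasing
#' in each `G_i` and linear in each `A_i`.
#'
#' @param profile An abundance profile (`data.frame` with `species` and
#'   `relative_abundance`).
#' @param counts Per-species peptide counts: either the table returned by
#'   [unique_tryptic_peptides()] or a named numeric vector.
#' @param missing_as_zero Treat profile species absent from `counts` as
#'   having zero peptides (the situation of taxa with no sequenced genome).
#' @return List of class `weighted_peptide_score` with elements `value` (W),
#'   `per_species` table and `n`.
#' @examples
#' p <- data.frame(species = "A", relative_abundance = 1)
#' weighted_tryptic_metric(p, c(A = 1))$value  # log(2)
#' @export
weighted_tryptic_metric <- function(profile, counts, missing_as_zero = TRUE) {
  profile <- as.data.table(profile)
  if (any(profile$relative_abundance < 0))
    stop("negative relative abundance in profile")
  if (is.data.frame(counts)) {
    cv <- setNames(as.numeric(counts$n_peptides), counts$species)
  } else {
    cv <- counts
  }
  g <- cv[profile$species]
  if (anyNA(g)) {
    if (!missing_as_zero)
      stop("profile species without a peptide count: ",
           paste(profile$species[is.na(g)], collapse = ", "))
    g[is.na(g)] <- 0
  }
  per <- data.table(species = profile$species, G = as.numeric(g),
                    A = profile$relative_abundance)
  structure(list(value = sum(log1p(per$G) * per$A), per_species = per,
                 n = nrow(per)),
            class = "weighted_peptide_score")
}
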