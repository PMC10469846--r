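#' Protein record tables
#'
#' The atom of every database is a protein record: a sequence with taxonomy
#' and provenance labels. Records are kept in a `data.table` with columns
#' `record_id`, `sequence`, `species`, `strain`, `genus`, `category` (one of
#' host, bacterial, fungal, parasite, contaminant, translated_ORF, decoy)
#' and `source` (public, shotgun, core). The taxon `"Unknown"` is permitted
#' only for translated ORFs.
#'
#' @param record_id,sequence,species,strain,genus,category,source Field
#'   vectors, recycled to a common length.
#' @return A `data.table` of protein records.
#' @export
protein_records <- function(record_id, sequence, species = "",
                            strain = "", genus = "", category = "bacterial",
                            source = "public") {
  dt <- data.table(record_id = record_id, sequence = sequence,
                   species = species, strain = strain, genus = genus,
                   category = category, source = source)
  validate_records(dt)
  dt
}

RECORD_CATEGORIES <- c("host", "bacterial", "fungal", "parasite",
                       "contaminant", "translated_ORF", "decoy")

validate_records <- function(dt) {
  stopifnot(all(c("record_id", "sequence", "species", "strain", "genus",
                  "category", "source") %in% names(dt)))
  if (any(!nzchar(dt$sequence)))
    stop("empty sequence in protein records")
  bad <- setdiff(unique(dt$category), RECORD_CATEGORIES)
  if (length(bad)) stop("unknown record category: ",
                        paste(bad, collapse = ", "))
  unk <- dt$species == "Unknown" & dt$category != "translated_ORF"
  if (any(unk))
    stop("taxon 'Unknown' is only permitted for translated_ORF records")
  invisible(dt)
}

#' Normalize raw protein records
#'
#' Rewrites records into the canonical dialect: whitespace and stop/`*`
#' characters are stripped from sequences, sequences are uppercased, and
#' duplicate record ids are disambiguated deterministically by suffixing
#' `_1`, `_2`, ... in order of appearance. Public records must carry species
#' taxonomy. The operation is idempotent.
#'
#' @param raw A data.frame/data.table with at least `record_id`, `sequence`
#'   and taxonomy columns.
#' @return Normalized protein record `data.table`.
#' @export
normalize_records <- function(raw) {
  dt <- as.data.table(as.data.frame(raw))
  for (col in c("species", "strain", "genus"))
    if (!col %in% names(dt)) data.table::set(dt, j = col, value = "")
  if (!"category" %in% names(dt))
    data.table::set(dt, j = "category", value = "bacterial")
  if (!"source" %in% names(dt))
    data.table::set(dt, j = "source", value = "public")
  dt[, sequence := toupper(gsub("[*[:space:].]", "", sequence))]
  dt[is.na(species), species := ""]
  pub <- dt$source == "public" & dt$category != "host"
  if (any(pub & !nzchar(dt$species)))
    stop("missing species taxonomy on public record(s): ",
         paste(head(dt$record_id[pub & !nzchar(dt$species)], 5),
               collapse = ", "))
  dup <- duplicated(dt$record_id)
  if (any(dup)) {
    idx <- stats::ave(seq_len(nrow(dt)), dt$record_id, FUN = seq_along) - 1L
    dt[idx > 0, record_id := sprintf("%s_%d", record_id, idx[idx > 0])]
  }
  validate_records(dt)
  dt[, .(record_id, sequence, species, strain, genus, category, source)][]
}

# The minimal contaminant set: trypsins, chymotrypsinogens, albumins and
# keratins commonly introduced during sample handling. The identifiers are
# the standard accessions; the sequences shipped here are synthetic
# placeholders generated under a fixed internal seed (real sequences can be
# supplied through `normalize_records()` + a custom core set).
CONTAMINANT_IDS <- c(
  "TRYP_PIG", "Trypa1", "Trypa2", "Trypa3", "Trypa4", "Trypa5", "Trypa6",
  "TRYP_BOVIN", "CTRA_BOVIN", "CTRB_BOVIN", "ALBU_HUMAN", "ALBU_BOVIN",
  "K2C1_HUMAN", "K22E_HUMAN", "K1C9_HUMAN", "K1C10_HUMAN")

#' Contaminant protein records
#'
#' Returns the 16-entry contaminant set included in every database built by
#' this package (trypsins and trypsin artifacts, chymotrypsinogens, serum
#' albumins and human keratins). Sequences are synthetic placeholders unless
#' a replacement table is supplied to the builders.
#'
#' @return Protein record `data.table` with 16 rows, `category =
#'   "contaminant"`, `source = "core"`.
#' @export
contaminant_records <- function() {
  species <- c("Sus scrofa", rep("synthetic construct", 6),
               rep("Bos taurus", 3), "Homo sapiens", "Bos taurus",
               rep("Homo sapiens", 4))
  seqs <- with_seed(424243L, random_sequences(length(CONTAMINANT_IDS),
                                              c(80L, 160L)))
  data.table(record_id = CONTAMINANT_IDS, sequence = seqs,
             species = species, strain = "",
             genus = vapply(strsplit(species, " "), `[`, "", 1),
             category = "contaminant", source = "core")
}

#' Core host + contaminant record set
#'
#' Every database strategy includes this core: host proteins plus exactly 16
#' contaminant records. If no host table is supplied a synthetic host set is
#' generated under a fixed internal seed.
#'
#' @param host_records Optional protein record table of host proteins
#'   (`category` is forced to `"host"`, `source` to `"core"`).
#' @param host_protein_count Size of the synthetic host set when
#'   `host_records` is `NULL`.
#' @return Protein record `data.table`.
#' @export
core_set <- function(host_records = NULL, host_protein_count = 30L) {
  cont <- contaminant_records()
  if (nrow(cont) != 16)
    stop("internal consistency error: contaminant list length != 16")
  if (is.null(host_records)) {
    host <- with_seed(515151L, data.table(
      record_id = sprintf("HOST_H%03d", seq_len(host_protein_count)),
      sequence = random_sequences(host_protein_count, c(80L, 200L)),
      species = "Homo sapiens", strain = "", genus = "Homo",
      category = "host", source = "core"))
  } else {
    host <- as.data.table(host_records)
    host[, `:=`(category = "host", source = "core")]
  }
  rbindlist(list(host, cont), use.names = TRUE)
}

new_protein_db <- function(name, strategy, records, sample_id = "") {
  records <- as.data.table(records)
  if (anyDuplicated(records$record_id))
    stop("duplicate record ids in database '", name, "'")
  structure(list(name = name, strategy = strategy, records = records,
                 sample_id = sample_id), class = "protein_db")
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<protein_db '%s'> strategy=%s sample=%s records=%d\n",
              x$name, x$strategy,
              if (nzchar(x$sample_id)) x$sample_id else "-",
              nrow(x$records)))
  invisible(x)
}

#' Build a sample-matched public-sequence database
#'
#' Includes the core set plus all repository records of species present in
#' the sample's abundance profile strictly above the cutoff (default 0.1%).
#' Profile species with no repository records (uncultivated taxa) are
#' skipped with a warning; species on the exclusion list are dropped.
#'
#' @param profile Abundance profile for one sample.
#' @param repository Protein record table (the public repository).
#' @param cutoff Strict relative-abundance threshold in (0, 1).
#' @param exclusion_list Character vector of species to exclude.
#' @param core Core record set (see [core_set()]).
#' @return A `protein_db` with strategy `"sample_matched_16s"`.
#' @export
build_sample_matched_16s <- function(profile, repository, cutoff = 0.001,
                                     exclusion_list = character(0),
                                     core = core_set()) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0, 1)")
  profile <- as.data.table(profile)
  repository <- as.data.table(repository)
  keep <- profile[relative_abundance > cutoff &
                    !(species %in% exclusion_list), species]
  missing <- setdiff(keep, unique(repository$species))
  if (length(missing))
    warning("species without repository records skipped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  keep <- setdiff(keep, missing)
  recs <- rbindlist(list(core, repository[species %in% keep]),
                    use.names = TRUE)
  sid <- unique(profile$sample_id)[1] %||% ""
  new_protein_db(paste0("16S_Sample-Matched_", sid), "sample_matched_16s",
                 recs, sample_id = sid)
}

#' Build the pooled public-sequence database
#'
#' The union of the bacterial records of every sample-matched database,
#' plus optional extra-taxa records (e.g. common fungi and parasites) and
#' the core set.
#'
#' @param profiles List of per-sample abundance profiles.
#' @param repository Public repository record table.
#' @param extra_records Optional protein record table for extra taxa.
#' @param cutoff,exclusion_list,core As in [build_sample_matched_16s()].
#' @return A `protein_db` with strategy `"pooled_16s"`.
#' @export
build_pooled_16s <- function(profiles, repository, extra_records = NULL,
                             cutoff = 0.001, exclusion_list = character(0),
                             core = core_set()) {
  if (!length(profiles)) stop("at least one profile required")
  if (is.data.frame(profiles)) profiles <- list(profiles)
  repository <- as.data.table(repository)
  keep <- unique(unlist(lapply(profiles, function(p) {
    p <- as.data.table(p)
    p[relative_abundance > cutoff & !(species %in% exclusion_list), species]
  })))
  keep <- intersect(keep, unique(repository$species))
  parts <- list(core, repository[species %in% keep])
  if (!is.null(extra_records)) parts <- c(parts, list(as.data.table(
    extra_records)))
  new_protein_db("16S_Pooled", "pooled_16s",
                 rbindlist(parts, use.names = TRUE))
}

#' Extra taxa included in the pooled public database by convention
#'
#' Nine organisms commonly added to broad vaginal databases: one parasite,
#' two bacterial pathogens and six fungi.
#' @return Character vector of nine taxon names.
#' @export
vaginal_extra_taxa <- function() {
  c("Trichomonas vaginalis", "Chlamydia trachomatis",
    "Neisseria gonorrhoeae", "Alternaria alternata", "Candida albicans",
    "Candida glabrata", "Candida tropicalis", "Pichia kudriavzevii",
    "Saccharomyces cerevisiae")
}

#' Build a reference-strain-only database
#'
#' As [build_sample_matched_16s()] but restricted, per species, to the
#' proteins of its reference strain. Species with a single available strain
#' default to that strain; the sentinel `"A"` in the map marks this case
#' explicitly. A mapped strain absent from the repository is an error.
#'
#' @param profile Abundance profile for one sample.
#' @param repository Public repository record table.
#' @param reference_strain_map Named character vector or data.frame
#'   (`species`, `strain`) assigning at most one reference strain per
#'   species.
#' @param cutoff,core As in [build_sample_matched_16s()].
#' @return A `protein_db` with strategy `"reference_16s"`.
#' @export
build_reference_16s <- function(profile, repository,
                                reference_strain_map = NULL, cutoff = 0.001,
                                core = core_set()) {
  profile <- as.data.table(profile)
  repository <- as.data.table(repository)
  if (is.data.frame(reference_strain_map)) {
    reference_strain_map <- setNames(reference_strain_map$strain,
                                     reference_strain_map$species)
  }
  keep <- profile[relative_abundance > cutoff, species]
  keep <- intersect(keep, unique(repository$species))
  parts <- list(core)
  for (sp in keep) {
    strains <- unique(repository[species == sp, strain])
    ref <- reference_strain_map[sp]
    if (is.null(reference_strain_map) || is.na(ref) || ref == "A") {
      if (length(strains) == 1) {
        ref <- strains
      } else if (is.null(reference_strain_map) || is.na(ref)) {
        stop("no reference strain mapped for multi-strain species ", sp)
      } else {
        stop("sentinel 'A' used for multi-strain species ", sp)
      }
    }
    if (!ref %in% strains)
      stop("mapped reference strain '", ref, "' absent from repository for ",
           sp)
    parts <- c(parts, list(repository[species == sp & strain == ref]))
  }
  sid <- unique(profile$sample_id)[1] %||% ""
  new_protein_db(paste0("16S_Reference_", sid), "reference_16s",
                 rbindlist(parts, use.names = TRUE), sample_id = sid)
}

#' Build a translated-shotgun database (sample-matched or pooled)
#'
#' @param catalogs One ORF catalog (`data.table`) or a list of per-sample
#'   catalogs.
#' @param pooled If `TRUE`, pool all catalogs into one database; otherwise a
#'   single catalog is expected.
#' @param core Core record set.
#' @param sample_id Sample id for the sample-matched case.
#' @return A `protein_db` with strategy `"shotgun_pooled"` or
#'   `"shotgun_sample_matched"`.
#' @export
build_shotgun <- function(catalogs, pooled = FALSE, core = core_set(),
                          sample_id = "") {
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  if (!length(catalogs)) stop("catalog collection is empty")
  if (!pooled && length(catalogs) != 1)
    stop("sample-matched shotgun database expects exactly one catalog")
  recs <- rbindlist(c(list(core), lapply(catalogs, as.data.table)),
                    use.names = TRUE)
  if (pooled) {
    new_protein_db("Shotgun_Pooled", "shotgun_pooled", recs)
  } else {
    new_protein_db(paste0("Shotgun_Sample-Matched_", sample_id),
                   "shotgun_sample_matched", recs, sample_id = sample_id)
  }
}

#' Build a hybrid database from a sample's public and shotgun databases
#'
#' Sequence-level union: shotgun records whose sequence already occurs in
#' the public sample-matched database collapse onto the public record (whose
#' taxonomy is resolvable), with the shotgun id recorded in the `aliases`
#' column. The result contains no two records with identical sequences, so
#' the operation is idempotent.
#'
#' @param sm_16s,sm_shotgun `protein_db` objects for the same sample.
#' @return A `protein_db` with strategy `"hybrid_sample_matched"`.
#' @export
build_hybrid <- function(sm_16s, sm_shotgun) {
  if (!identical(sm_16s$sample_id, sm_shotgun$sample_id))
    stop("sample_id mismatch between the two databases")
  a <- copy(sm_16s$records)
  b <- copy(sm_shotgun$records)
  if (!"aliases" %in% names(a)) a[, aliases := ""]
  if (!"aliases" %in% names(b)) b[, aliases := ""]
  all_recs <- rbindlist(list(a, b), use.names = TRUE)
  collapsed <- all_recs[, {
    ali <- sort(unique(c(record_id[-1],
                         unlist(strsplit(aliases[nzchar(aliases)], ";")))))
    c(.SD[1, .(record_id, species, strain, genus, category, source)],
      list(aliases = paste(ali, collapse = ";")))
  }, by = sequence]
  recs <- collapsed[, .(record_id, sequence, species, strain, genus,
                        category, source, aliases)]
  new_protein_db(paste0("Hybrid_Sample-Matched_", sm_16s$sample_id),
                 "hybrid_sample_matched", recs,
                 sample_id = sm_16s$sample_id)
}

#' Build the global database
#'
#' Core set plus every repository record, regardless of any sample profile.
#'
#' @param repository_all_taxa Full repository record table.
#' @param core Core record set.
#' @return A `protein_db` with strategy `"global"`.
#' @export
build_global <- function(repository_all_taxa, core = core_set()) {
  recs <- rbindlist(list(core, as.data.table(repository_all_taxa)),
                    use.names = TRUE)
  new_protein_db("Global", "global", recs)
}

#' Augment a database with randomly chosen genomes
#'
#' Adds `k` genomes sampled without replacement from a pool (a record table
#' with a `genome_id` column grouping records into genomes). Deterministic
#' under a fixed seed.
#'
#' @param baseline A `protein_db`.
#' @param pool Record table with a `genome_id` column.
#' @param k Number of genomes to add.
#' @param seed Integer seed.
#' @return A `protein_db` with strategy `"custom"`.
#' @export
build_augmented <- function(baseline, pool, k, seed = 1L) {
  pool <- as.data.table(pool)
  genomes <- unique(pool$genome_id)
  if (k > length(genomes)) stop("k exceeds pool size")
  if (k == 0) {
    recs <- copy(baseline$records)
  } else {
    chosen <- with_seed(seed, sample(genomes, k))
    add <- pool[genome_id %in% chosen,
                .(record_id, sequence, species, strain, genus, category,
                  source)]
    recs <- rbindlist(list(baseline$records, add), use.names = TRUE,
                      fill = TRUE)
  }
  new_protein_db(sprintf("%s_plus%d", baseline$name, k), "custom", recs,
                 sample_id = baseline$sample_id)
}

#' Database size summary
#'
#' @param db A `protein_db`.
#' @return List with `total`, `by_category`, `by_source` and
#'   `distinct_sequences`.
#' @export
database_stats <- function(db) {
  recs <- db$records
  list(total = nrow(recs),
       by_category = table(factor(recs$category,
                                  levels = RECORD_CATEGORIES)),
       by_source = table(factor(recs$source,
                                levels = c("public", "shotgun", "core"))),
       distinct_sequences = length(unique(recs$sequence)))
}

# --- FASTA I/O (canonical header dialect) ---------------------------------

#' Read and write protein records as FASTA
#'
#' The canonical header dialect is
#' `>{record_id}|{category}|{genus}|{species}|{strain}` (pipe-delimited, no
#' internal pipes in fields). `source` is inferred on read: translated ORFs
#' are `shotgun`, host/contaminant records are `core`, everything else
#' `public`.
#'
#' @param records Protein record table.
#' @param path FASTA file path.
#' @return `read_protein_fasta()` returns a protein record `data.table`;
#'   `write_protein_fasta()` returns the path invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  records <- as.data.table(records)
  fields <- records[, .(record_id, category, genus, species, strain)]
  if (any(vapply(fields, function(col) any(grepl("|", col, fixed = TRUE)),
                 logical(1))))
    stop("header fields must not contain '|'")
  headers <- do.call(paste, c(fields, sep = "|"))
  seqs <- Biostrings::AAStringSet(records$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, filepath = path, width = 80)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  # sentinel keeps trailing empty fields (e.g. an empty strain)
  parts <- strsplit(paste0(names(seqs), "|\r"), "|", fixed = TRUE)
  if (any(lengths(parts) != 6))
    stop("malformed canonical FASTA header in ", path)
  m <- do.call(rbind, lapply(parts, `[`, 1:5))
  dt <- data.table(record_id = m[, 1], sequence = as.character(seqs),
                   species = m[, 4], strain = m[, 5], genus = m[, 3],
                   category = m[, 2])
  dt[, source := ifelse(category == "translated_ORF", "shotgun",
                        ifelse(category %in% c("host", "contaminant"),
                               "core", "public"))]
  dt[]
}
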