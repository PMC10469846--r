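test_that("normalization strips stops, suffixes duplicate ids, idempotent", {
  raw <- data.frame(record_id = c("x", "x", "y"),
                    sequence = c("MK R*", "AAAK", "ml lr."),
                    species = "Species_X", strain = "s1",
                    genus = "Genus_X")
  out <- normalize_records(raw)
  expect_equal(out$sequence, c("MKR", "AAAK", "MLLR"))
  expect_equal(out$record_id, c("x", "x_1", "y"))
  expect_identical(normalize_records(out), out)
  expect_error(normalize_records(data.frame(record_id = "z",
                                            sequence = "MK",
                                            species = "")),
               "missing species")
})

test_that("the core set holds the 16 contaminants plus host proteins", {
  cont <- contaminant_records()
  expect_equal(nrow(cont), 16L)
  expect_true(all(c("TRYP_PIG", "K1C10_HUMAN", "ALBU_BOVIN") %in%
                    cont$record_id))
  core <- core_set(host_records = NULL, host_protein_count = 5)
  expect_equal(sum(core$category == "contaminant"), 16L)
  expect_equal(sum(core$category == "host"), 5L)
  # empty host set still yields the 16 contaminants
  core0 <- core_set(host_records = contaminant_records()[0],
                    host_protein_count = 0)
  expect_equal(nrow(core0), 16L)
})

make_profile <- function(ab, sample_id = "S01") {
  data.frame(sample_id = sample_id, taxon = names(ab), species = names(ab),
             genus = paste0("G_", names(ab)), relative_abundance = ab)
}

test_that("sample-matched databases apply the strict abundance cutoff", {
  repo <- rbind(toy_records("a1", "MKAAAAAR", species = "A"),
                toy_records("b1", "MKCCCCCR", species = "B"))
  prof <- make_profile(c(A = 0.5, B = 0.0005))
  db <- build_sample_matched_16s(prof, repo)
  expect_true("a1" %in% db$records$record_id)
  expect_false("b1" %in% db$records$record_id)
  # boundary: exactly at the cutoff is excluded
  db2 <- build_sample_matched_16s(make_profile(c(A = 0.5, B = 0.001)),
                                  repo)
  expect_false("b1" %in% db2$records$record_id)
  # species without repository records is skipped with a warning
  expect_warning(
    db3 <- build_sample_matched_16s(make_profile(c(A = 0.5, NoGenome = 0.3)),
                                    repo),
    "NoGenome")
  expect_false("NoGenome" %in% db3$records$species)
})

test_that("every builder includes the full core set exactly once", {
  repo <- toy_records(c("a1", "a2"), c("MKAAAAAR", "MKDDDDDR"),
                      species = "A")
  prof <- make_profile(c(A = 1))
  core <- core_set(host_protein_count = 3)
  orf <- toy_records("o1", "MKEEEEER", species = "A",
                     category = "translated_ORF", source = "shotgun")
  dbs <- list(build_sample_matched_16s(prof, repo, core = core),
              build_pooled_16s(list(prof), repo, core = core),
              build_reference_16s(prof, repo, core = core),
              build_shotgun(orf, FALSE, core, "S01"),
              build_global(repo, core = core))
  for (db in dbs) {
    got <- db$records[db$records$record_id %in% core$record_id, ]
    expect_equal(nrow(got), nrow(core))
  }
  hyb <- build_hybrid(dbs[[1]], dbs[[4]])
  expect_equal(sum(hyb$records$record_id %in% core$record_id), nrow(core))
})

test_that("pooled database is the union of the per-sample bacterial sets", {
  repo <- rbind(toy_records("a1", "MKAAAAAR", species = "A"),
                toy_records("b1", "MKCCCCCR", species = "B"))
  p1 <- make_profile(c(A = 0.9), "S01")
  p2 <- make_profile(c(B = 0.9), "S02")
  pool <- build_pooled_16s(list(p1, p2), repo)
  sm1 <- build_sample_matched_16s(p1, repo)
  sm2 <- build_sample_matched_16s(p2, repo)
  bact <- function(db) db$records$record_id[db$records$category ==
                                              "bacterial"]
  expect_setequal(bact(pool), union(bact(sm1), bact(sm2)))
  expect_equal(length(bact(pool)), length(bact(sm1)) + length(bact(sm2)))
  expect_gte(nrow(pool$records), nrow(sm1$records))
  one <- build_pooled_16s(list(p1), repo)
  expect_setequal(bact(one), bact(sm1))
})

test_that("reference databases keep only the mapped strain per species", {
  repo <- rbind(toy_records(c("a1", "a2", "a3"),
                            c("MKAAAAAR", "MKDDDDDR", "MKEEEEER"),
                            species = "A", strain = c("s1", "s2", "s3")),
                toy_records("b1", "MKCCCCCR", species = "B",
                            strain = "s9"))
  prof <- make_profile(c(A = 0.6, B = 0.3))
  db <- build_reference_16s(prof, repo,
                            reference_strain_map = c(A = "s2", B = "A"))
  bact <- db$records[db$records$category == "bacterial", ]
  expect_setequal(bact$record_id, c("a2", "b1"))
  # single-strain species defaults to its only genome
  db2 <- build_reference_16s(make_profile(c(B = 0.9)), repo)
  expect_true("b1" %in% db2$records$record_id)
  # subset of the matched database
  sm <- build_sample_matched_16s(prof, repo)
  expect_lte(nrow(db$records), nrow(sm$records))
  expect_error(build_reference_16s(prof, repo,
                                   reference_strain_map = c(A = "s7",
                                                            B = "A")),
               "absent")
})

test_that("hybrid construction collapses identical sequences with aliases", {
  core <- core_set(host_protein_count = 2)
  a <- build_sample_matched_16s(make_profile(c(A = 1)),
                                toy_records("a1", "MKAAAAAR",
                                            species = "A"), core = core)
  orf_same <- toy_records("o1", "MKAAAAAR", species = "Unknown",
                          genus = "Unknown", category = "translated_ORF",
                          source = "shotgun")
  b <- build_shotgun(orf_same, FALSE, core, "S01")
  hyb <- build_hybrid(a, b)
  rec <- hyb$records[hyb$records$sequence == "MKAAAAAR", ]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$record_id, "a1")           # public identity kept
  expect_equal(rec$aliases, "o1")             # shotgun id recorded
  expect_equal(anyDuplicated(hyb$records$sequence), 0L)

  # disjoint sequences: size = sum
  orf_new <- toy_records("o2", "MKGGGGGR", species = "Unknown",
                         genus = "Unknown", category = "translated_ORF",
                         source = "shotgun")
  b2 <- build_shotgun(orf_new, FALSE, core_set(host_protein_count = 0)[0],
                      "S01")
  hyb2 <- build_hybrid(a, b2)
  expect_equal(nrow(hyb2$records), nrow(a$records) + 1L)

  # idempotence
  hyb3 <- build_hybrid(hyb, b)
  expect_equal(as.data.frame(hyb3$records), as.data.frame(hyb$records))
  expect_error(build_hybrid(a, build_shotgun(orf_new, FALSE, core, "S99")),
               "mismatch")
})

test_that("global database is a superset and handles empty repositories", {
  repo <- rbind(toy_records("a1", "MKAAAAAR", species = "A"),
                toy_records("b1", "MKCCCCCR", species = "B"))
  core <- core_set(host_protein_count = 2)
  glob <- build_global(repo, core = core)
  sm <- build_sample_matched_16s(make_profile(c(A = 1)), repo, core = core)
  expect_true(all(sm$records$record_id %in% glob$records$record_id))
  expect_equal(nrow(glob$records), nrow(repo) + nrow(core))
  empty <- build_global(repo[0], core = core)
  expect_equal(nrow(empty$records), nrow(core))
})

test_that("augmentation samples genomes deterministically", {
  base <- build_global(toy_records("a1", "MKAAAAAR", species = "A"),
                       core = core_set(host_protein_count = 1))
  pools <- generate_genome_pools(seed = 2, n_genomes = 10,
                                 proteins_per_genome = 4)
  expect_identical(build_augmented(base, pools$species_pool, 0)$records,
                   base$records)
  d1 <- build_augmented(base, pools$species_pool, 3, seed = 9)
  d2 <- build_augmented(base, pools$species_pool, 3, seed = 9)
  expect_identical(d1$records, d2$records)
  expect_error(build_augmented(base, pools$species_pool, 11), "exceeds")
})

test_that("strain pools add distinct sequences slower than species pools", {
  pools <- generate_genome_pools(seed = 4, n_genomes = 40,
                                 proteins_per_genome = 8)
  n_distinct <- function(pool, k) {
    length(unique(pool$sequence[pool$genome_id %in%
                                  unique(pool$genome_id)[seq_len(k)]]))
  }
  for (k in c(10, 20, 40))
    expect_lt(n_distinct(pools$strain_pool, k),
              n_distinct(pools$species_pool, k))
})

test_that("database stats are conserved counts", {
  repo <- toy_records(c("a1", "a2"), c("MKAAAAAR", "MKDDDDDR"),
                      species = "A")
  db <- build_global(repo, core = core_set(host_protein_count = 3))
  st <- database_stats(db)
  expect_equal(st$total, 2 + 3 + 16)
  expect_equal(sum(st$by_category), st$total)
  expect_equal(sum(st$by_source), st$total)
  empty <- build_global(repo[0], core = core_set(host_protein_count = 0)[0])
  st0 <- database_stats(empty)
  expect_equal(st0$total, 0L)
  expect_true(all(st0$by_category == 0))
})

test_that("canonical FASTA headers round-trip all taxonomy fields", {
  recs <- rbind(
    toy_records("a1", "MKAAAAAR", species = "Species_01", strain = "s1",
                genus = "Genus_01"),
    toy_records("o1", "MKCCCCCR", species = "Unknown", strain = "",
                genus = "Unknown", category = "translated_ORF",
                source = "shotgun"))
  f <- tempfile(fileext = ".fasta")
  write_protein_fasta(recs, f)
  back <- read_protein_fasta(f)
  expect_equal(as.data.frame(back), as.data.frame(recs))
  expect_error(write_protein_fasta(
    toy_records("bad|id", "MKAAAAAR"), tempfile()), "must not contain")
})
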