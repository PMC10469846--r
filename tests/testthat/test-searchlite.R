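test_that("decoys are full reversals, one per target", {
  db <- toy_records(c("p1", "p2"), c("MKR", "AAAAAR"))
  dec <- build_decoys(db)
  expect_equal(dec$sequence, c("RKM", "RAAAAA"))
  expect_equal(dec$record_id, c("XXX_p1", "XXX_p2"))
  expect_equal(nrow(dec), nrow(db))
  expect_true(all(dec$category == "decoy"))
  # palindromic sequence: decoy equals the target but keeps the prefix
  pal <- build_decoys(toy_records("p3", "AKA"))
  expect_equal(pal$sequence, "AKA")
  expect_equal(pal$record_id, "XXX_p3")
})

test_that("raw score counts matched b/y ions with single-use peaks", {
  pep <- "AAALKDDDR"
  spec <- list(fragment_masses = fragment_masses(pep))
  s <- score_match(spec, pep)
  expect_equal(s$raw_score, 2 * (nchar(pep) - 1))
  spec0 <- list(fragment_masses = c(5000, 6000))
  s0 <- score_match(spec0, pep)
  expect_equal(s0$raw_score, 0L)
  expect_equal(s0$spectral_probability, 1)
})

test_that("raw score equals an exhaustive matching oracle", {
  # brute-force maximum matching by enumerating observed-peak permutations
  oracle_score <- function(theo, obs, tol) {
    if (!length(obs)) return(0L)
    best <- 0L
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    for (p in perms(seq_along(obs))) {
      used <- logical(length(obs)); cnt <- 0L
      for (t in theo) {
        for (j in p) {
          if (!used[j] && abs(obs[j] - t) <= tol) {
            used[j] <- TRUE; cnt <- cnt + 1L; break
          }
        }
      }
      best <- max(best, cnt)
    }
    best
  }
  withr::with_seed(31, {
    for (i in 1:25) {
      theo <- sort(runif(sample(2:5, 1), 100, 500))
      obs <- sort(runif(sample(1:5, 1), 100, 500))
      tol <- runif(1, 5, 60)
      got <- metaprotdb:::match_count_cpp(theo, obs, tol)
      expect_equal(got, oracle_score(theo, obs, tol))
    }
  })
  # hand-computed 4-peak toy: theo {100,200,300,400}, obs {100.2,199.9,305,401}
  expect_equal(metaprotdb:::match_count_cpp(c(100, 200, 300, 400),
                                            c(100.2, 199.9, 305, 401),
                                            0.5), 2L)
})

test_that("q-values match the stated worked example and brute force", {
  psms <- toy_psms(c(10, 9, 8, 7), c(FALSE, FALSE, TRUE, FALSE))
  out <- compute_qvalues(psms)
  out <- out[order(-out$raw_score)]
  expect_equal(out$q_value, c(0, 0, 1 / 3, 1 / 3))
  # all targets -> all zero
  expect_true(all(compute_qvalues(toy_psms(5:1, rep(FALSE, 5)))$q_value ==
                    0))
  # all decoys above all targets -> target q capped at 1
  mix <- compute_qvalues(toy_psms(c(9, 8, 3, 2), c(TRUE, TRUE, FALSE,
                                                   FALSE)))
  expect_true(all(mix[!mix$is_decoy]$q_value == 1))
})

test_that("q-value computation equals the oracle on random instances", {
  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(3:40, 1)
      scores <- sample(1:15, n, replace = TRUE)
      decoy <- runif(n) < 0.4
      probs <- round(runif(n), 3)
      psms <- toy_psms(scores, decoy, probs)
      got <- compute_qvalues(psms)
      exp_q <- oracle_qvalues(scores, decoy, probs, psms$spectrum_id)
      expect_equal(got$q_value[match(psms$spectrum_id, got$spectrum_id)],
                   exp_q)
    }
  })
})

test_that("q-values never increase with score rank", {
  withr::with_seed(13, {
    for (i in 1:20) {
      psms <- toy_psms(sample(1:20, 30, replace = TRUE), runif(30) < 0.5,
                       runif(30))
      out <- compute_qvalues(psms)
      expect_true(all(diff(out$q_value) >= -1e-12))
    }
  })
})

make_search_fixture <- function(seed = 1, n_spectra = 150) {
  cfg <- toy_config(seed = seed, n_spectra = n_spectra,
                    fraction_uncultivated = 0)
  repo <- generate_repository(cfg)
  host <- generate_host_set(cfg)
  core <- core_set(host_records = host)
  comm <- generate_community(cfg, repo, 1)
  sim <- simulate_spectra(comm, host, contaminant_records(), cfg)
  db <- suppressWarnings(build_sample_matched_16s(comm$profile, repo,
                                                  core = core))
  list(cfg = cfg, db = db, sim = sim)
}

test_that("search returns the true peptide for noise-free spectra", {
  cfg <- toy_config(seed = 2, n_spectra = 60,
                    noise = list(drop_rate = 0, spurious_rate = 0),
                    fraction_uncultivated = 0)
  repo <- generate_repository(cfg)
  host <- generate_host_set(cfg)
  comm <- generate_community(cfg, repo, 1)
  sim <- simulate_spectra(comm, host, contaminant_records(), cfg)
  db <- suppressWarnings(build_sample_matched_16s(
    comm$profile, repo, core = core_set(host_records = host)))
  psms <- search_spectra(sim$spectra, db)
  tp <- setNames(sim$truth$peptide, sim$truth$spectrum_id)
  hit <- psms$peptide == tp[psms$spectrum_id]
  expect_gt(mean(hit), 0.95)
  # the true source protein is among the matches
  tr <- setNames(sim$truth$record_id, sim$truth$spectrum_id)
  ok <- mapply(function(prot, rid) rid %in% strsplit(prot, ";")[[1]],
               psms$protein_ids[hit], tr[psms$spectrum_id[hit]])
  expect_true(all(ok))
})

test_that("shared peptides list every containing protein", {
  core <- core_set(host_protein_count = 0)
  db <- metaprotdb:::new_protein_db("toy", "custom", rbind(
    toy_records(c("p1", "p2"), c("MMMKAAALLKDDDR", "CCCKAAALLKDDDR"),
                species = c("A", "B")), core), "S01")
  pep <- "AAALLK"
  spec <- data.table(spectrum_id = "s1", sample_id = "S01", replicate = 1L,
                     precursor_mass = round(peptide_mass(pep), 6),
                     fragment_masses = paste(
                       sprintf("%.6f", fragment_masses(pep)),
                       collapse = ";"))
  psms <- search_spectra(spec, db)
  expect_equal(psms$peptide, pep)
  ids <- strsplit(psms$protein_ids, ";")[[1]]
  expect_true(all(c("p1", "p2") %in% ids))
})

test_that("spectra without candidates are omitted", {
  core <- core_set(host_protein_count = 0)
  db <- metaprotdb:::new_protein_db("toy", "custom", rbind(
    toy_records("p1", "MMMAAALKDDDR"), core), "S01")
  spec <- data.table(spectrum_id = "s1", sample_id = "S01", replicate = 1L,
                     precursor_mass = 9999.9,
                     fragment_masses = "200.5;300.5")
  expect_equal(nrow(search_spectra(spec, db)), 0L)
})

test_that("two-step search is a fixed point on already-minimal databases", {
  fx <- make_search_fixture(seed = 3, n_spectra = 120)
  res <- two_step_search(fx$sim$spectra, fx$db)
  # step-2 database only holds step-1 hits plus the core
  hit1 <- unique(unlist(strsplit(res$step1$protein_ids, ";")))
  hit1 <- unique(sub("^XXX_", "", hit1))
  extra <- setdiff(res$subset_db$records$record_id, hit1)
  expect_true(all(res$subset_db$records[
    res$subset_db$records$record_id %in% extra, "source"] == "core"))
  # re-running on the subset returns the identical database
  res2 <- two_step_search(fx$sim$spectra, res$subset_db)
  expect_setequal(res2$subset_db$records$record_id,
                  res$subset_db$records$record_id)
  expect_equal(res2$psms$q_value, res$psms$q_value)
})

test_that("the second search pass accepts at least as many PSMs", {
  fx <- make_search_fixture(seed = 1, n_spectra = 300)
  res <- two_step_search(fx$sim$spectra, fx$db)
  n1 <- nrow(res$step1[res$step1$q_value < 0.01 & !res$step1$is_decoy])
  n2 <- nrow(res$psms[res$psms$q_value < 0.01 & !res$psms$is_decoy])
  expect_gte(n2, n1)
})

test_that("condensation keeps the per-spectrum maximum", {
  p1 <- toy_psms(c(12, 5), c(FALSE, FALSE), ids = c("s1", "s2"))
  p2 <- toy_psms(c(9, 8), c(FALSE, FALSE), ids = c("s1", "s2"))
  out <- condense_results(list(p1, p2))
  expect_equal(out[out$spectrum_id == "s1"]$raw_score, 12L)
  expect_equal(out[out$spectrum_id == "s2"]$raw_score, 8L)
  one <- condense_results(list(p1))
  expect_equal(sort(one$spectrum_id), sort(p1$spectrum_id))
  expect_equal(one[order(one$spectrum_id)]$raw_score,
               p1[order(p1$spectrum_id)]$raw_score)
})

test_that("condensation equals a brute-force per-spectrum maximum", {
  withr::with_seed(41, {
    for (i in 1:100) {
      n_spec <- sample(2:8, 1)
      chunks <- lapply(1:3, function(ch) {
        take <- sample(n_spec, sample(n_spec, 1))
        toy_psms(sample(1:20, length(take), replace = TRUE),
                 runif(length(take)) < 0.3,
                 probs = round(runif(length(take)), 4),
                 ids = sprintf("s%d", take))
      })
      out <- condense_results(chunks)
      all_psms <- data.table::rbindlist(chunks)
      for (sid in unique(all_psms$spectrum_id)) {
        sub <- all_psms[all_psms$spectrum_id == sid]
        expect_equal(out[out$spectrum_id == sid]$raw_score,
                     max(sub$raw_score))
      }
      expect_equal(nrow(out), length(unique(all_psms$spectrum_id)))
    }
  })
})

test_that("MS-GF+ TSV import maps columns and strips flanks", {
  f <- tempfile(fileext = ".tsv")
  writeLines(paste(
    c("#SpecFile\tSpecID\tScanNum\tPeptide\tProtein\tSpecEValue\tQValue",
      "run1.mzML\tspec1\t10\tK.AAAAAR.L\tP1;XXX_P2\t1e-12\t0.001",
      "run1.mzML\tspec2\t11\tR.CCCCCK.A\tP3\t1e-3\t0.2"),
    collapse = "\n"), f)
  psms <- read_msgf_tsv(f)
  expect_equal(psms$peptide, c("AAAAAR", "CCCCCK"))
  expect_equal(psms$is_decoy, c(TRUE, FALSE))
  expect_equal(psms$spectral_probability, c(1e-12, 1e-3))
  bad <- tempfile(fileext = ".tsv")
  writeLines("#SpecFile\tSpecID\tScanNum\tPeptide\tProtein\tSpecEValue",
             bad)
  expect_error(read_msgf_tsv(bad), "QValue")
})

test_that("PSM tables round-trip through both TSV dialects", {
  psms <- compute_qvalues(toy_psms(c(9, 5, 3), c(FALSE, TRUE, FALSE),
                                   probs = c(1e-20, 0.2, 1e-4)))
  f1 <- tempfile(fileext = ".tsv")
  write_psm_tsv(psms, f1)
  back <- read_psm_tsv(f1)
  expect_equal(as.data.frame(back), as.data.frame(psms))
  f2 <- tempfile(fileext = ".tsv")
  write_msgf_tsv(psms, f2)
  back2 <- read_msgf_tsv(f2)
  expect_equal(back2$peptide, psms$peptide)
  expect_equal(back2$spectral_probability, psms$spectral_probability)
  expect_equal(back2$q_value, psms$q_value)
})

test_that("replicate merging concatenates and recomputes q-values", {
  r1 <- toy_psms(c(9, 7), c(FALSE, FALSE), ids = c("a1", "a2"))
  r2 <- toy_psms(c(8, 2), c(FALSE, TRUE), ids = c("b1", "b2"))
  comb <- merge_replicates(r1, r2)
  expect_equal(nrow(comb), 4L)
  expect_true("q_value" %in% names(comb))
  empty <- r2[0]
  expect_equal(nrow(merge_replicates(r1, empty)), nrow(r1))
  r3 <- data.table::copy(r2); r3$sample_id <- "S99"
  expect_error(merge_replicates(r1, r3), "mismatch")
})

test_that("appending irrelevant proteins does not inflate significant PSMs", {
  fx <- make_search_fixture(seed = 5, n_spectra = 400)
  n_sig <- function(db) {
    p <- compute_qvalues(search_spectra(fx$sim$spectra, db))
    nrow(p[p$q_value < 0.01 & !p$is_decoy])
  }
  base_n <- n_sig(fx$db)
  pools <- generate_genome_pools(seed = 6, n_genomes = 40,
                                 proteins_per_genome = 10)
  bloated <- build_augmented(fx$db, pools$species_pool, 40, seed = 8)
  expect_lte(n_sig(bloated), base_n)
})
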