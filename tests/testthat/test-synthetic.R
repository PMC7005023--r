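test_that("simulated reference lineages respect the separation contract", {
  db <- simulate_reference_lineages(20, min_sep = 0.15, cryptic_pairs = 0,
                                    seed = 7)
  expect_equal(nrow(db$records), 20)
  # brute-force pairwise check of all 190 distances via the K2P oracle
  m <- k2p_matrix(setNames(db$records$sequence, db$records$lineage_id))
  off <- m[upper.tri(m)]
  expect_length(off, 190)
  expect_true(all(off > 0.15))

  # determinism
  db2 <- simulate_reference_lineages(20, min_sep = 0.15, cryptic_pairs = 0,
                                     seed = 7)
  expect_identical(db$records, db2$records)

  # two lineages, wide separation
  db3 <- simulate_reference_lineages(2, min_sep = 0.15, seed = 1,
                                     cryptic_pairs = 0)
  d <- k2p_distance(db3$records$sequence[1], db3$records$sequence[2])$k2p
  expect_gt(d, 0.15)

  expect_error(simulate_reference_lineages(5, min_sep = 0.05, seed = 1),
               "min_sep")
})

test_that("cryptic pairs sit above threshold but share a taxon name", {
  db <- simulate_reference_lineages(12, cryptic_pairs = 2, seed = 13)
  expect_equal(nrow(db$records), 12)
  rec <- db$records
  for (k in 1:2) {
    a <- rec[rec$lineage_id == sprintf("L%02d", k), ]
    b <- rec[rec$lineage_id == sprintf("L%02db", k), ]
    expect_identical(a$taxon_name, b$taxon_name)
    d <- k2p_distance(a$sequence, b$sequence)$k2p
    expect_gt(d, threshold_for(db, a$lineage_id))  # genetically distinct
    expect_lt(d, 0.15)                             # but a close pair
  }
})

test_that("site communities are multinomial, nested and deterministic", {
  db <- simulate_reference_lineages(4, cryptic_pairs = 0, seed = 3)
  w <- setNames(c(1, 1, 0, 0), db$records$lineage_id)
  prof <- community_profile("even", w, "stream")

  # 50/50 weights: frequency within 3 standard errors of one half
  tr <- simulate_site_community(prof, 10000, seed = 5)
  f <- mean(tr$specimens$lineage_id == db$records$lineage_id[1])
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(f - 0.5), 3 * se)
  expect_equal(sum(tr$counts$n), 10000)

  # single-lineage degenerate draw
  prof1 <- community_profile("one", setNames(1, db$records$lineage_id[1]),
                             "stream")
  tr1 <- simulate_site_community(prof1, 33, seed = 1)
  expect_true(all(tr1$specimens$lineage_id == db$records$lineage_id[1]))

  # nesting: first 33 of a 66-specimen draw is the 33-specimen draw
  t33 <- simulate_site_community(prof, 33, site_id = "s", seed = 11)
  t66 <- simulate_site_community(prof, 66, site_id = "s", seed = 11)
  expect_identical(t66$specimens$lineage_id[1:33],
                   t33$specimens$lineage_id)

  # determinism
  expect_identical(simulate_site_community(prof, 50, seed = 2)$specimens,
                   simulate_site_community(prof, 50, seed = 2)$specimens)

  expect_error(community_profile("bad", numeric(0), "stream"),
               "empty community")
})

test_that("error-free reads reconstruct their template exactly", {
  db <- simulate_reference_lineages(5, cryptic_pairs = 0, seed = 21)
  prof <- community_profile("p", setNames(rep(1, 5), db$records$lineage_id),
                            "stream")
  tr <- simulate_site_community(prof, 10, site_id = "sA", seed = 2)
  sch <- tag_scheme(tr$specimens$specimen_id, "sA", seed = 4)
  cfg <- sim_config(per_base_error = 0, chimera_rate = 0,
                    reads_per_specimen = 20)
  dir <- withr::local_tempdir()
  rr <- generate_reads(tr, sch, cfg, db, dir = dir, seed = 6)
  expect_equal(nrow(rr$read_truth) %% 1, 0)

  merged <- read_fastq_pairs(rr$r1, rr$r2) |>
    demultiplex(sch) |>
    merge_pairs()
  tpl <- setNames(db$records$sequence, db$records$lineage_id)
  want <- tpl[tr$specimens$lineage_id[match(merged$specimen_id,
                                            tr$specimens$specimen_id)]]
  expect_true(all(merged$sequence == want))

  # byte-identical FASTQ on rerun with the same seed
  dir2 <- withr::local_tempdir()
  rr2 <- generate_reads(tr, sch, cfg, db, dir = dir2, seed = 6)
  expect_identical(readLines(rr$r1), readLines(rr2$r1))
  expect_identical(readLines(rr$r2), readLines(rr2$r2))

  # missing tag entry is an error
  sch2 <- sch; sch2$entries <- sch2$entries[-1, ]
  expect_error(generate_reads(tr, sch2, cfg, db, dir = dir, seed = 1),
               "untagged specimen")
})

test_that("chimeric read fraction follows the configured rate", {
  db <- simulate_reference_lineages(4, cryptic_pairs = 0, seed = 31)
  prof <- community_profile("p", setNames(rep(1, 4), db$records$lineage_id),
                            "stream")
  tr <- simulate_site_community(prof, 2, site_id = "sB", seed = 3)
  cfg <- sim_config(per_base_error = 0, chimera_rate = 0.05,
                    reads_per_specimen = 5000)
  sch <- tag_scheme(tr$specimens$specimen_id, "sB", seed = 5)
  rr <- generate_reads(tr, sch, cfg, db, dir = withr::local_tempdir(),
                       seed = 8)
  n <- nrow(rr$read_truth)
  n_chim <- sum(rr$read_truth$origin == "chimera")
  se <- sqrt(n * 0.05 * 0.95)
  expect_lt(abs(n_chim - n * 0.05), 3 * se)
  # read-level truth partitions all reads
  expect_true(all(rr$read_truth$origin %in% c("template", "chimera")))
  expect_true(all(!is.na(rr$read_truth$parent_b[
    rr$read_truth$origin == "chimera"])))
})

test_that("morphological coarsening merges cryptic pairs and conserves counts", {
  db <- simulate_reference_lineages(8, cryptic_pairs = 1, seed = 17)
  w <- setNames(rep(1, nrow(db$records)), db$records$lineage_id)
  prof <- community_profile("p", w, "stream")
  tr <- simulate_site_community(prof, 200, site_id = "sC", seed = 9)

  # identity when nothing is unresolved and the pair is absent
  no_cryptic <- simulate_reference_lineages(6, cryptic_pairs = 0, seed = 18)
  w2 <- setNames(rep(1, 6), no_cryptic$records$lineage_id)
  tr2 <- simulate_site_community(community_profile("q", w2, "stream"),
                                 100, site_id = "sD", seed = 10)
  morph2 <- coarsen_to_morphology(tr2, no_cryptic, unresolved_rate = 0,
                                  seed = 1)
  truth2 <- community_from_truth(tr2, no_cryptic)
  expect_equal(sort(morph2$count), sort(truth2$count))
  expect_equal(sum(morph2$count), 100)

  # cryptic pair members fall under one morphological label
  morph <- coarsen_to_morphology(tr, db, unresolved_rate = 0, seed = 1)
  pair_name <- db$records$taxon_name[db$records$lineage_id == "L01"]
  n_pair <- sum(tr$specimens$lineage_id %in% c("L01", "L01b"))
  expect_equal(morph$count[morph$label == pair_name], n_pair)

  # counts conserved under demotion
  morph3 <- coarsen_to_morphology(tr, db, unresolved_rate = 0.5, seed = 2)
  expect_equal(sum(morph3$count), 200)
  expect_true(any(grepl("g\\. sp\\.", morph3$label)))
})
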