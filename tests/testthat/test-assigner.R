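test_that("dereplication counts and orders uniques", {
  merged <- tibble::tibble(sequence = c("ACGT", "ACGT", "ACGA", "ACGT"))
  u <- dereplicate(merged)
  expect_equal(u$sequence, c("ACGT", "ACGA"))
  expect_equal(u$count, c(3L, 1L))

  expect_equal(nrow(dereplicate(tibble::tibble(sequence = character(0)))), 0)

  # ties broken lexicographically; counts conserved
  m2 <- tibble::tibble(sequence = c("TTTT", "AAAA", "TTTT", "AAAA"))
  u2 <- dereplicate(m2)
  expect_equal(u2$sequence, c("AAAA", "TTTT"))
  expect_equal(sum(u2$count), 4)
})

test_that("two-parent splices are flagged chimeric, parents are kept", {
  a <- rand_seq(313, seed = 81)
  b <- rand_seq(313, seed = 82)
  splice <- paste0(substr(a, 1, 150), substr(b, 151, 313))
  uniq <- tibble::tibble(sequence = c(a, b, splice),
                         count = c(100L, 90L, 9L))
  out <- remove_chimeras(uniq)
  expect_equal(out$sequence, c(a, b))
  expect_equal(attr(out, "n_chimeric"), 1)
  expect_equal(out$count, c(100L, 90L))  # retained counts unchanged

  # a near-duplicate of the dominant sequence is not chimeric
  err <- a
  substr(err, 7, 7) <- setdiff(c("A", "C", "G", "T"), substr(a, 7, 7))[1]
  uniq2 <- tibble::tibble(sequence = c(a, b, err), count = c(100L, 90L, 2L))
  expect_equal(nrow(remove_chimeras(uniq2)), 3)

  # abundance gate: parents must be at least twice the query's count
  uniq3 <- tibble::tibble(sequence = c(a, b, splice),
                          count = c(100L, 90L, 60L))
  expect_equal(nrow(remove_chimeras(uniq3)), 3)
})

test_that("simulated chimeras between abundant parents are removed", {
  db <- simulate_reference_lineages(2, cryptic_pairs = 0, seed = 91)
  prof <- community_profile("p", setNames(c(1, 1), db$records$lineage_id),
                            "stream")
  # one specimen of each lineage, built directly
  specimens <- tibble::tibble(specimen_id = c("sF_SP001", "sF_SP002"),
                              lineage_id = db$records$lineage_id)
  tr <- structure(list(site_id = "sF", habitat = "stream", profile_name = "p",
                       specimens = specimens,
                       counts = dplyr::count(specimens, lineage_id, name = "n")),
                  class = "site_truth")
  cfg <- sim_config(per_base_error = 0, chimera_rate = 0.05,
                    reads_per_specimen = 400)
  sch <- tag_scheme(tr$specimens$specimen_id, "sF", seed = 7)
  rr <- generate_reads(tr, sch, cfg, db, dir = withr::local_tempdir(),
                       seed = 14)
  # pool both specimens so both chimera parents are abundant
  merged <- read_fastq_pairs(rr$r1, rr$r2) |>
    demultiplex(sch) |>
    merge_pairs()
  uniq <- dereplicate(merged)
  kept <- remove_chimeras(uniq)

  tpl <- db$records$sequence
  chim_uniques <- setdiff(uniq$sequence, tpl)
  removed <- setdiff(uniq$sequence, kept$sequence)
  expect_gte(length(removed) / length(chim_uniques), 0.9)
  expect_true(all(tpl %in% kept$sequence))     # no false parent removal

  # zero-rate dataset: nothing removed
  cfg0 <- sim_config(per_base_error = 0, chimera_rate = 0,
                     reads_per_specimen = 100)
  rr0 <- generate_reads(tr, sch, cfg0, db, dir = withr::local_tempdir(),
                        seed = 15)
  u0 <- read_fastq_pairs(rr0$r1, rr0$r2) |>
    demultiplex(sch) |>
    merge_pairs() |>
    dereplicate()
  expect_equal(attr(remove_chimeras(u0), "n_chimeric"), 0)
})

test_that("greedy 97% clustering splits at the identity threshold", {
  a <- rand_seq(313, seed = 95)
  one_off <- a
  substr(one_off, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                     substr(a, 10, 10))[1]
  # 312/313 = 0.997: one OTU
  o1 <- cluster_otus(tibble::tibble(sequence = c(a, one_off),
                                    count = c(10L, 2L)))
  expect_equal(nrow(o1), 1)
  expect_equal(o1$member_count, 12L)
  expect_equal(o1$representative, a)

  # 31 mismatches: 282/313 ~ 0.901 < 0.97: two OTUs
  far <- a
  for (i in 1:31) {
    substr(far, i * 10, i * 10) <-
      setdiff(c("A", "C", "G", "T"), substr(far, i * 10, i * 10))[1]
  }
  o2 <- cluster_otus(tibble::tibble(sequence = c(a, far),
                                    count = c(10L, 5L)))
  expect_equal(nrow(o2), 2)

  # single sequence: itself
  o3 <- cluster_otus(tibble::tibble(sequence = a, count = 1L))
  expect_equal(o3$representative, a)
})

test_that("dominant OTU selection applies min_reads and tie-breaking", {
  o <- tibble::tibble(representative = c("CCC", "AAA"),
                      member_count = c(120L, 3L))
  expect_equal(dominant_otu(o)$barcode, "CCC")

  expect_equal(dominant_otu(tibble::tibble(representative = "AAA",
                                           member_count = 5L),
                            min_reads = 10)$status, "failed")

  tie <- tibble::tibble(representative = c("TTT", "AAA"),
                        member_count = c(50L, 50L))
  expect_equal(dominant_otu(tie)$barcode, "AAA")
})

test_that("threshold assignment follows per-genus rules and ties", {
  db <- make_test_db()
  tub <- db$records$sequence[db$records$lineage_id == "TUB1"]
  nais <- db$records$sequence[db$records$lineage_id == "NAIS1"]

  # 27 transitions = K2P 0.0947: inside 0.10, outside 0.08
  q_tub <- transition_mutate(tub, 27)
  a1 <- assign_lineage(q_tub, db)
  expect_equal(a1$lineage_id, "TUB1")
  expect_equal(a1$route, "local_db")
  expect_lt(a1$distance, 0.10)
  expect_gt(a1$distance, 0.08)

  q_nais <- transition_mutate(nais, 27)
  a2 <- assign_lineage(q_nais, db)
  expect_equal(a2$route, "unassigned")
  expect_true(is.na(a2$lineage_id))

  # identical to a reference: distance zero
  a3 <- assign_lineage(tub, db)
  expect_equal(a3$distance, 0)
  expect_equal(a3$lineage_id, "TUB1")

  # secondary database fallback
  sec_rec <- db$records[db$records$lineage_id == "NAIS1", ]
  sec_rec$lineage_id <- "GB1"
  sec_rec$genus <- "Genbankia"
  sec_rec$taxon_name <- "Genbankia demo"
  sec <- reference_db(sec_rec)
  a4 <- assign_lineage(q_nais, db, secondary = sec)
  expect_equal(a4$lineage_id, "GB1")
  expect_equal(a4$route, "secondary_db")
})

test_that("unassigned barcodes cluster into stable new lineages", {
  db <- make_test_db()
  x <- rand_seq(313, seed = 201)
  x2 <- transition_mutate(x, 6)     # K2P ~0.019 from x: same new lineage
  y <- rand_seq(313, seed = 202)    # far away: its own lineage
  asg <- tibble::tibble(
    specimen_id = c("s1", "s2", "s3"), barcode = c(x, x2, y),
    lineage_id = NA_character_, distance = 0.5, route = "unassigned")
  out <- cluster_new_lineages(asg, db)
  expect_equal(out$lineage_id[1], out$lineage_id[2])
  expect_false(out$lineage_id[3] == out$lineage_id[1])
  expect_match(out$lineage_id[1], "^NEW_")

  # stable across reruns on identical input
  expect_identical(cluster_new_lineages(asg, db), out)
})
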