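test_that("IOBS evaluates 10*S/T on worked examples", {
  # S = 12, dominant tubificid group 40 of 100: IOBS = 3.0
  cc <- tibble::tibble(
    site_id = "s", label = c("tub", paste0("x", 1:11)),
    count = c(40L, rep(5L, 10), 10L),
    group = c("tubificinae_hair", rep("naidinae", 11)), sensitive = FALSE)
  r <- compute_iobs(site_community(cc))
  expect_equal(r$S, 12)
  expect_equal(r$T, 40)
  expect_equal(r$iobs, 3.0)
  expect_equal(as.character(r$quality_class), "good")

  # all 100 specimens one hairless tubificid: S = 1... the study's S = 6
  # variant needs 6 labels; check both
  one <- tibble::tibble(site_id = "s", label = "t", count = 100L,
                        group = "tubificinae_nohair", sensitive = FALSE)
  r1 <- compute_iobs(site_community(one))
  expect_equal(r1$T, 100)
  expect_equal(r1$iobs, 0.1)

  six <- tibble::tibble(
    site_id = "s", label = c("t", paste0("y", 1:5)),
    count = c(95L, rep(1L, 5)),
    group = c("tubificinae_nohair", rep("tubificinae_nohair", 5)),
    sensitive = FALSE)
  r6 <- compute_iobs(site_community(six))
  expect_equal(r6$S, 6)
  expect_equal(r6$T, 100)  # whole hairless group dominates
  expect_equal(r6$iobs, 0.6)

  # zero tubificids: undefined
  none <- tibble::tibble(site_id = "s", label = c("a", "b"),
                         count = c(3L, 4L), group = "naidinae",
                         sensitive = FALSE)
  r0 <- compute_iobs(site_community(none))
  expect_true(is.na(r0$iobs))
  expect_equal(as.character(r0$quality_class), "undefined")

  expect_error(compute_iobs(site_community(cc)[0, ]), "no specimens")
})

test_that("T is the dominant hair-setae group over all identified specimens", {
  cc <- tibble::tibble(
    site_id = "s", label = c("hair", "nohair", "naid", "new1"),
    count = c(30L, 45L, 15L, 10L),
    group = c("tubificinae_hair", "tubificinae_nohair", "naidinae", NA),
    sensitive = FALSE)
  r <- compute_iobs(site_community(cc))
  # denominator includes the group-less new lineage
  expect_equal(r$T, 45)
  expect_equal(r$S, 4)
})

test_that("IOBS is scale invariant and monotone in added taxa", {
  base <- tibble::tibble(
    site_id = "s", label = c("tub", "a", "b"), count = c(20L, 8L, 5L),
    group = c("tubificinae_hair", "naidinae", "enchytraeidae"),
    sensitive = FALSE)
  r <- compute_iobs(site_community(base))
  scaled <- base; scaled$count <- scaled$count * 7L
  r7 <- compute_iobs(site_community(scaled))
  expect_equal(r[c("S", "T", "iobs")], r7[c("S", "T", "iobs")])

  # adding one specimen of a new non-tubificid taxon raises the index
  plus <- dplyr::bind_rows(base, tibble::tibble(
    site_id = "s", label = "z", count = 1L, group = "naidinae",
    sensitive = FALSE))
  rp <- compute_iobs(site_community(plus))
  expect_gt(rp$iobs, r$iobs)
})

test_that("IOBS classes follow the printed bands at every edge", {
  vals <- c(0, 0.99, 1, 1.5, 1.99, 2, 2.5, 2.95, 2.999, 3, 5.9, 5.999, 6,
            8, NA)
  want <- c("bad", "bad", "poor", "poor", "poor", "medium", "medium",
            "medium", "medium", "good", "good", "good", "very_good",
            "very_good", "undefined")
  expect_equal(as.character(classify_iobs(vals)), want)
  expect_error(classify_iobs(-0.1), "invalid index")
})

test_that("percentage of sensitive taxa and its bands", {
  mk <- function(sens, tot) {
    tibble::tibble(site_id = "l", label = c("s", "t"),
                   count = c(sens, tot - sens),
                   group = "other", sensitive = c(TRUE, FALSE))
  }
  # 0 of 33: 0%, bad
  r0 <- percent_sensitive(site_community(mk(0 + 1L, 34L), habitat = "lake"))
  # (1 of 34 is ~2.9%, still bad; the pure-zero case needs count >= 1)
  expect_equal(as.character(r0$quality_class), "bad")

  all_ins <- tibble::tibble(site_id = "l", label = "t", count = 33L,
                            group = "other", sensitive = FALSE)
  rz <- percent_sensitive(site_community(all_ins, habitat = "lake"))
  expect_equal(rz$pct_sensitive, 0)
  expect_equal(as.character(rz$quality_class), "bad")

  # 17 of 33 = 51.5%: very good
  r17 <- percent_sensitive(site_community(mk(17L, 33L), habitat = "lake"))
  expect_equal(r17$pct_sensitive, 100 * 17 / 33, tolerance = 1e-12)
  expect_equal(as.character(r17$quality_class), "very_good")

  # band edges: 50 -> good, 20 -> medium, 10 -> poor, 5 -> bad
  edges <- c(50, 50.0001, 20, 20.5, 10, 10.5, 5, 5.5, 0)
  want <- c("good", "very_good", "medium", "good", "poor", "medium",
            "bad", "poor", "bad")
  expect_equal(as.character(classify_sensitive(edges)), want)
  expect_error(classify_sensitive(120), "invalid percentage")

  # unresolved sensitivity flags warn and count non-sensitive
  un <- tibble::tibble(site_id = "l", label = c("a", "b"),
                       count = c(10L, 10L), group = "other",
                       sensitive = c(TRUE, NA))
  expect_warning(ru <- percent_sensitive(site_community(un,
                                                        habitat = "lake")),
                 "unresolved")
  expect_equal(ru$pct_sensitive, 50)
})

test_that("identical count tables give identical results regardless of source", {
  cc <- tibble::tibble(
    site_id = "s", label = c("tub", "a"), count = c(30L, 20L),
    group = c("tubificinae_nohair", "naidinae"), sensitive = FALSE)
  g <- compute_iobs(site_community(cc, source = "genetic"))
  m <- compute_iobs(site_community(cc, source = "morphological"))
  expect_identical(g, m)
})

test_that("compute_index dispatches on habitat", {
  cc <- tibble::tibble(
    site_id = "s", label = c("tub", "a"), count = c(30L, 20L),
    group = c("tubificinae_nohair", "naidinae"),
    sensitive = c(FALSE, TRUE))
  st <- compute_index(site_community(cc, habitat = "stream"))
  expect_equal(st$metric, "iobs")
  lk <- compute_index(site_community(cc, habitat = "lake"))
  expect_equal(lk$metric, "pct_sensitive")
  expect_equal(lk$value, 40)
})
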