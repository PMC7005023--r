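# Shared fixtures, built in code.

rand_seq <- function(width = 313L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
}

# mutate exactly n sites by transition (A<->G, C<->T), at deterministic
# positions; gives an exactly known K2P distance (P = n/width, Q = 0)
transition_mutate <- function(seq, n, from = 1L) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- seq(from, by = 3L, length.out = n)
  stopifnot(max(idx) <= length(ch))
  ch[idx] <- chartr("ACGT", "GTAC", ch[idx])
  paste(ch, collapse = "")
}

k2p_transitions_only <- function(p) -0.5 * log((1 - 2 * p) * sqrt(1))

# a small handcrafted database: one Tubifex, one Nais, plus filler taxa
make_test_db <- function(seed = 101) {
  set.seed(seed)
  base <- vapply(1:4, function(i) rand_seq(313), character(1))
  recs <- tibble::tibble(
    lineage_id = c("TUB1", "NAIS1", "ENCH1", "LUMB1"),
    taxon_name = c("Tubifex demo", "Nais demo", "Enchytraeus demo",
                   "Lumbriculus demo"),
    rank = "species",
    genus = c("Tubifex", "Nais", "Enchytraeus", "Lumbriculus"),
    group = c("tubificinae_nohair", "naidinae", "enchytraeidae",
              "lumbriculidae"),
    sensitive = c(FALSE, FALSE, TRUE, TRUE),
    sequence = base)
  reference_db(recs)
}

# uniform-quality FASTQ pair tibble for one read
make_pair <- function(fwd, rev, q = 38L, id = "r1") {
  tibble::tibble(read_id = id,
                 fwd_seq = fwd, fwd_qual = strrep(intToUtf8(q + 33L), nchar(fwd)),
                 rev_seq = rev, rev_qual = strrep(intToUtf8(q + 33L), nchar(rev)))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# stream community counts with S taxa and dominant tubificid percentage
# exactly T (percent); uses 100*k specimens so every (S, T) is feasible
iobs_grid_community <- function(S, T, k = 10L) {
  tot <- 100L * k
  t_count <- as.integer(T * k)
  rest <- tot - t_count
  stopifnot(S >= 1, (S == 1 && t_count == tot) || rest >= S - 1)
  if (S == 1) {
    counts <- tibble::tibble(label = "tub1", count = tot,
                             group = "tubificinae_nohair")
  } else {
    others <- S - 1L
    cnt <- c(rep(1L, others - 1L), rest - (others - 1L))
    counts <- tibble::tibble(
      label = c("tub1", paste0("x", seq_len(others))),
      count = c(t_count, cnt),
      group = c("tubificinae_nohair", rep("naidinae", others)))
  }
  counts$site_id <- "g"
  counts$sensitive <- FALSE
  site_community(counts, habitat = "stream")
}
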