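# Read processing: FASTQ input, mean-quality filter, exact dual-tag
# demultiplexing, quality-aware ungapped pair merging.

#' Read a pair of FASTQ files into a read-pair table
#'
#' Phred+33 quality encoding is assumed; files whose quality characters lie
#' outside the Phred+33 printable range are rejected.
#'
#' @param r1,r2 Paths to the forward and reverse FASTQ (plain or gzipped).
#' @return Tibble: read_id, fwd_seq, fwd_qual, rev_seq, rev_qual.
#' @export
read_fastq_pairs <- function(r1, r2) {
  f <- Biostrings::readDNAStringSet(r1, format = "fastq",
                                    with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(r2, format = "fastq",
                                    with.qualities = TRUE)
  if (length(f) != length(r)) stop("R1/R2 read counts differ")
  fq <- as.character(S4Vectors::mcols(f)$qualities)
  rq <- as.character(S4Vectors::mcols(r)$qualities)
  top <- max(utf8ToInt(paste(c(substr(fq, 1, 50), substr(rq, 1, 50)),
                             collapse = "")))
  if (top > 75) stop("unsupported quality encoding (Phred+33 expected)")
  tibble::tibble(read_id = sub("\\s.*$", "", names(f)),
                 fwd_seq = as.character(f), fwd_qual = fq,
                 rev_seq = as.character(r), rev_qual = rq)
}

mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

#' Mean-quality filter for read pairs
#'
#' A pair is kept iff both mates have mean Phred quality at or above
#' `min_mean_q` and neither mate contains an ambiguous base (N). The
#' threshold is inclusive: a mean of exactly 30 passes.
#'
#' @param pairs Read-pair tibble as from [read_fastq_pairs()].
#' @param min_mean_q Minimum mean quality score per mate.
#' @return The kept pairs; the number discarded is in attribute
#'   `n_discarded`.
#' @export
quality_filter <- function(pairs, min_mean_q = 30) {
  bad_len <- nchar(pairs$fwd_seq) != nchar(pairs$fwd_qual) |
    nchar(pairs$rev_seq) != nchar(pairs$rev_qual)
  if (any(bad_len)) stop("malformed read: ",
                         paste(head(pairs$read_id[bad_len]), collapse = ", "))
  keep <- mean_phred(pairs$fwd_qual) >= min_mean_q &
    mean_phred(pairs$rev_qual) >= min_mean_q &
    !grepl("N", pairs$fwd_seq, fixed = TRUE) &
    !grepl("N", pairs$rev_seq, fixed = TRUE)
  out <- pairs[keep, , drop = FALSE]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

# does each sequence match the (possibly degenerate) pattern exactly,
# starting at `start`? Zero mismatches against the IUPAC sets.
iupac_match_at <- function(seqs, pattern, start = 1L) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  ok <- nchar(seqs) >= start + length(pat) - 1L
  for (j in seq_along(pat)) {
    allowed <- IUPAC[[pat[j]]]
    if (is.null(allowed)) stop("invalid primer character: ", pat[j])
    ch <- substr(seqs, start + j - 1L, start + j - 1L)
    ok <- ok & ch %in% allowed
  }
  ok
}

#' Demultiplex read pairs to specimens by exact dual-tag match
#'
#' A pair is assigned to specimen s iff the forward read starts exactly with
#' s's forward tag followed by the forward primer AND the reverse read
#' starts exactly with s's reverse tag followed by the reverse primer. Zero
#' mismatches are tolerated (IUPAC degeneracy in the primers is honoured;
#' tags are literal). Tags and primers are trimmed from assigned reads; all
#' other pairs are rejected and counted.
#'
#' @param pairs Read-pair tibble (typically after [quality_filter()]).
#' @param scheme A [tag_scheme()].
#' @return Tibble of assigned reads (specimen_id, read_id, fwd_seq,
#'   fwd_qual, rev_seq, rev_qual, trimmed); attribute `n_rejected` counts
#'   rejected pairs.
#' @export
demultiplex <- function(pairs, scheme) {
  stopifnot(inherits(scheme, "tag_scheme"))
  ent <- scheme$entries
  combo <- paste(ent$fwd_tag, ent$rev_tag, sep = "+")
  if (anyDuplicated(combo)) stop("ambiguous scheme")
  tlf <- nchar(ent$fwd_tag[1]); tlr <- nchar(ent$rev_tag[1])
  fp <- scheme$fwd_primer; rp <- scheme$rev_primer

  key <- paste(substr(pairs$fwd_seq, 1, tlf),
               substr(pairs$rev_seq, 1, tlr), sep = "+")
  hit <- match(key, combo)
  ok <- !is.na(hit) &
    iupac_match_at(pairs$fwd_seq, fp, start = tlf + 1L) &
    iupac_match_at(pairs$rev_seq, rp, start = tlr + 1L)

  out <- pairs[ok, , drop = FALSE]
  out$specimen_id <- ent$specimen_id[hit[ok]]
  cutf <- tlf + nchar(fp); cutr <- tlr + nchar(rp)
  out$fwd_seq <- substr(out$fwd_seq, cutf + 1L, nchar(out$fwd_seq))
  out$fwd_qual <- substr(out$fwd_qual, cutf + 1L, nchar(out$fwd_qual))
  out$rev_seq <- substr(out$rev_seq, cutr + 1L, nchar(out$rev_seq))
  out$rev_qual <- substr(out$rev_qual, cutr + 1L, nchar(out$rev_qual))
  out <- dplyr::relocate(out, "specimen_id")
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Merge read pairs by best ungapped overlap
#'
#' The reverse mate is reverse-complemented and slid along the forward mate;
#' among overlaps of at least `min_overlap` bases the one with maximal
#' quality-weighted score (matches minus mismatches, weighted by the mean of
#' the two base qualities) is chosen. Disagreeing overlap positions take the
#' higher-quality base, with merged quality the maximum of the two. Pairs
#' whose best overlap has a mismatch fraction above
#' `max_overlap_mismatch_frac` (or no overlap of the minimum length) are
#' dropped and counted in attribute `n_dropped`.
#'
#' @param reads Demultiplexed, trimmed read-pair tibble.
#' @param min_overlap Minimum acceptable overlap length.
#' @param max_overlap_mismatch_frac Maximum mismatch fraction in the chosen
#'   overlap.
#' @return Tibble: specimen_id (if present), read_id, sequence, quality,
#'   overlap_len, overlap_mismatches.
#' @export
merge_pairs <- function(reads, min_overlap = 20L,
                        max_overlap_mismatch_frac = 0.1) {
  if (nrow(reads) == 0) {
    out <- tibble::tibble(read_id = character(0), sequence = character(0),
                          quality = character(0), overlap_len = integer(0),
                          overlap_mismatches = integer(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  has_sp <- "specimen_id" %in% names(reads)
  grp <- paste(nchar(reads$fwd_seq), nchar(reads$rev_seq))
  pieces <- lapply(split(seq_len(nrow(reads)), grp), function(idx) {
    res <- merge_block(reads[idx, , drop = FALSE], min_overlap,
                       max_overlap_mismatch_frac)
    res
  })
  out <- dplyr::bind_rows(pieces)
  out <- out[order(match(out$read_id, reads$read_id)), , drop = FALSE]
  if (has_sp) out <- dplyr::relocate(out, "specimen_id")
  attr(out, "n_dropped") <- nrow(reads) - nrow(out)
  out
}

merge_block <- function(reads, min_overlap, max_frac) {
  la <- nchar(reads$fwd_seq[1]); lb <- nchar(reads$rev_seq[1])
  n <- nrow(reads)
  FM <- seq_matrix(reads$fwd_seq)
  QF <- qual_matrix(reads$fwd_qual)
  RM <- seq_matrix(revcomp(reads$rev_seq))
  QR <- qual_matrix(reads$rev_qual)[, lb:1, drop = FALSE]

  max_o <- min(la, lb)
  best_sc <- rep(-Inf, n); best_o <- rep(NA_integer_, n)
  best_m <- rep(NA_integer_, n)
  if (max_o >= min_overlap) {
    for (o in seq(min_overlap, max_o)) {
      iF <- seq(la - o + 1L, la)
      cmp <- FM[, iF, drop = FALSE] == RM[, seq_len(o), drop = FALSE]
      W <- (QF[, iF, drop = FALSE] + QR[, seq_len(o), drop = FALSE]) / 2
      sc <- 2 * rowSums(W * cmp) - rowSums(W)
      m <- o - as.integer(rowSums(cmp))
      upd <- sc > best_sc
      best_sc[upd] <- sc[upd]; best_o[upd] <- o; best_m[upd] <- m[upd]
    }
  }
  ok <- is.finite(best_sc) & best_m / best_o <= max_frac
  if (!any(ok)) {
    return(tibble::tibble(read_id = character(0), sequence = character(0),
                          quality = character(0), overlap_len = integer(0),
                          overlap_mismatches = integer(0)))
  }
  pieces <- lapply(unique(best_o[ok]), function(o) {
    rows <- which(ok & best_o == o)
    iF <- seq(la - o + 1L, la)
    fo <- FM[rows, iF, drop = FALSE]; ro <- RM[rows, seq_len(o), drop = FALSE]
    qf <- QF[rows, iF, drop = FALSE]; qr <- QR[rows, seq_len(o), drop = FALSE]
    take_f <- qf >= qr
    cons <- ifelse(take_f, fo, ro)
    consq <- pmax(qf, qr)
    pre <- FM[rows, seq_len(la - o), drop = FALSE]
    preq <- QF[rows, seq_len(la - o), drop = FALSE]
    suf <- RM[rows, seq(o + 1L, length.out = lb - o), drop = FALSE]
    sufq <- QR[rows, seq(o + 1L, length.out = lb - o), drop = FALSE]
    sm <- cbind(pre, cons, suf); qm <- cbind(preq, consq, sufq)
    res <- tibble::tibble(read_id = reads$read_id[rows],
                          sequence = matrix_seq(sm),
                          quality = matrix_qual(qm),
                          overlap_len = o,
                          overlap_mismatches = best_m[rows])
    if ("specimen_id" %in% names(reads)) {
      res$specimen_id <- reads$specimen_id[rows]
    }
    res
  })
  dplyr::bind_rows(pieces)
}
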