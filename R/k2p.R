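# Kimura two-parameter distances on ungapped, end-trimmed comparisons.
# Barcodes are a fixed-length amplicon, so sequences of unequal length are
# compared over their common prefix; positions with non-ACGT characters in
# either sequence are excluded.

PURINE_CODES <- c(65L, 71L)  # A, G
ACGT_CODES <- c(65L, 67L, 71L, 84L)

# core: integer code vectors, already end-trimmed to equal length
k2p_core <- function(av, bv, min_sites = 100L) {
  valid <- av %in% ACGT_CODES & bv %in% ACGT_CODES
  ns <- sum(valid)
  if (ns < min_sites) stop("insufficient overlap")
  diff <- valid & av != bv
  ts <- diff & ((av %in% PURINE_CODES) == (bv %in% PURINE_CODES))
  p <- sum(ts) / ns
  q <- (sum(diff) - sum(ts)) / ns
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  d <- if (w1 <= 0 || w2 <= 0) Inf else -0.5 * log(w1 * sqrt(w2))
  list(p = p, q = q, k2p = d, compared_sites = ns)
}

trim_pair <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  list(a = utf8ToInt(substr(a, 1L, n)), b = utf8ToInt(substr(b, 1L, n)))
}

#' Kimura two-parameter distance between two barcodes
#'
#' Computes the transition proportion P, the transversion proportion Q and
#' the K2P distance \eqn{-\frac{1}{2}\ln((1-2P-Q)\sqrt{1-2Q})} over the
#' ungapped comparison of the two sequences (end-trimmed to the shorter
#' length; positions where either sequence has an ambiguity character are
#' excluded). Saturated comparisons, where the logarithm's argument is not
#' positive, yield `k2p = Inf` (`saturated = TRUE`): the distance exceeds any
#' assignment threshold.
#'
#' @param a,b DNA strings.
#' @param min_sites Minimum number of compared sites; fewer is an
#'   "insufficient overlap" error.
#' @return A one-row tibble: `p_transitions`, `q_transversions`, `k2p`,
#'   `compared_sites`, `saturated`.
#' @export
#' @examples
#' k2p_distance("ACGTACGTACGT", "ACGTACGAACGT", min_sites = 10)
k2p_distance <- function(a, b, min_sites = 100L) {
  tp <- trim_pair(a, b)
  st <- k2p_core(tp$a, tp$b, min_sites)
  tibble::tibble(p_transitions = st$p, q_transversions = st$q,
                 k2p = st$k2p, compared_sites = st$compared_sites,
                 saturated = !is.finite(st$k2p))
}

# distances from one query to many subjects; returns numeric vector
k2p_to_many <- function(query, subjects, min_sites = 100L) {
  vapply(subjects, function(s) {
    tp <- trim_pair(query, s)
    k2p_core(tp$a, tp$b, min_sites)$k2p
  }, numeric(1), USE.NAMES = FALSE)
}

#' Pairwise K2P distance matrix
#'
#' @param seqs Named character vector of DNA strings.
#' @param min_sites Minimum compared sites per pair.
#' @param saturated Value substituted for saturated pairs; the default `Inf`
#'   marks them as beyond any threshold, while tree construction uses a
#'   large finite ceiling.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(seqs, min_sites = 100L, saturated = Inf) {
  n <- length(seqs)
  labs <- names(seqs) %||% as.character(seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tp <- trim_pair(seqs[[i]], seqs[[j]])
      d <- k2p_core(tp$a, tp$b, min_sites)$k2p
      if (!is.finite(d)) d <- saturated
      m[i, j] <- m[j, i] <- d
    }
  }
  m
}

# K2P matrix from an alignment given as a character matrix (taxa x sites);
# used by the bootstrap, which resamples columns. Saturated pairs take a
# finite ceiling so the agglomeration stays defined.
k2p_matrix_from_alignment <- function(aln, min_sites = 100L,
                                      saturated = 5) {
  seqs <- apply(aln, 1, paste, collapse = "")
  k2p_matrix(seqs, min_sites = min_sites, saturated = saturated)
}
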