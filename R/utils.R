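# Internal helpers: DNA strings as plain character vectors, with integer
# matrices (utf8 codes) for vectorised comparison.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> allowed bases (I, inosine in some primers, is read as N)
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"), I = c("A", "C", "G", "T")
)

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
  }, character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# equal-width character strings -> integer matrix of utf8 codes (n x width)
seq_matrix <- function(x) {
  if (length(x) == 0) return(matrix(integer(0), nrow = 0, ncol = 0))
  w <- unique(nchar(x))
  stopifnot(length(w) == 1)
  matrix(utf8ToInt(paste(x, collapse = "")), ncol = w, byrow = TRUE)
}

# integer matrix rows -> character strings
matrix_seq <- function(m) {
  if (nrow(m) == 0) return(character(0))
  vapply(seq_len(nrow(m)), function(i) intToUtf8(m[i, ]), character(1))
}

# Phred+33 quality string -> integer scores
phred_to_int <- function(q) utf8ToInt(q) - 33L
int_to_phred <- function(q) intToUtf8(q + 33L)

qual_matrix <- function(x) seq_matrix(x) - 33L
matrix_qual <- function(m) {
  if (nrow(m) == 0) return(character(0))
  vapply(seq_len(nrow(m)), function(i) intToUtf8(m[i, ] + 33L), character(1))
}

reverse_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Deterministic 31-bit seed derived from a master seed and string context,
# so per-site / per-stage streams are independent of execution order.
derive_seed <- function(master, ...) {
  ctx <- paste(c(master, ...), collapse = "/")
  codes <- utf8ToInt(ctx)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483629
  as.integer((h + master) %% 2147483629 + 1)
}

hamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(av), length(bv))
  sum(av[seq_len(n)] != bv[seq_len(n)]) + abs(length(av) - length(bv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
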