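# Per-specimen barcode determination and K2P threshold lineage assignment.

#' Collapse exact duplicate reads
#'
#' @param merged Tibble with a `sequence` column (one specimen's merged
#'   reads).
#' @return Tibble (sequence, count), sorted by descending count, ties broken
#'   lexicographically by sequence.
#' @export
dereplicate <- function(merged) {
  if (nrow(merged) == 0) {
    return(tibble::tibble(sequence = character(0), count = integer(0)))
  }
  merged |>
    dplyr::count(.data$sequence, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
}

# cumulative mismatch profile between equal-length strings a and b
mismatch_cumsum <- function(av, bv) cumsum(av != bv)

#' De novo two-parent chimera removal
#'
#' A query sequence is flagged chimeric when some split point yields a left
#' segment within one mismatch of the prefix of a sequence at least twice as
#' abundant, and a right segment within one mismatch of the suffix of a
#' different sequence at least twice as abundant, while the full query
#' differs from both putative parents by at least three mismatches. Flagged
#' sequences are removed; retained counts are unchanged.
#'
#' @param uniques Tibble (sequence, count), sorted by descending abundance.
#' @return The non-chimeric subset, same columns; attribute `n_chimeric`
#'   counts removed uniques.
#' @export
remove_chimeras <- function(uniques) {
  n <- nrow(uniques)
  if (n < 3) {
    attr(uniques, "n_chimeric") <- 0L
    return(uniques)
  }
  lens <- nchar(uniques$sequence)
  chars <- strsplit(uniques$sequence, "", fixed = TRUE)
  chim <- rep(FALSE, n)
  for (qi in seq_len(n)) {
    cand <- which(uniques$count >= 2 * uniques$count[qi] &
                    lens == lens[qi] & seq_len(n) != qi & !chim)
    if (length(cand) < 2) next
    L <- lens[qi]
    profs <- lapply(cand, function(ci) mismatch_cumsum(chars[[qi]], chars[[ci]]))
    tot <- vapply(profs, function(p) p[L], numeric(1))
    par_ok <- tot >= 3
    if (sum(par_ok) < 2) next
    cand <- cand[par_ok]; profs <- profs[par_ok]; tot <- tot[par_ok]
    # left_ok[s] for parent A, right_ok[s] for parent B, split after site s
    ss <- seq_len(L - 1L)
    left_ok <- lapply(profs, function(p) p[ss] <= 1)
    right_ok <- lapply(seq_along(profs),
                       function(k) (tot[k] - profs[[k]][ss]) <= 1)
    found <- FALSE
    for (a in seq_along(cand)) {
      if (!any(left_ok[[a]])) next
      for (b in seq_along(cand)) {
        if (a == b) next
        if (any(left_ok[[a]] & right_ok[[b]])) { found <- TRUE; break }
      }
      if (found) break
    }
    chim[qi] <- found
  }
  out <- uniques[!chim, , drop = FALSE]
  attr(out, "n_chimeric") <- sum(chim)
  out
}

pairwise_identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  av <- utf8ToInt(substr(a, 1, n)); bv <- utf8ToInt(substr(b, 1, n))
  sum(av == bv) / n
}

#' Greedy abundance-ordered OTU clustering
#'
#' Each sequence, in descending abundance order, joins the first centroid
#' with pairwise identity at or above `identity` (matches over compared
#' sites, ungapped, end-trimmed to the shorter length), else founds a new
#' centroid. Clustering is per specimen: the unit of analysis is the tagged
#' specimen.
#'
#' @param seqs Tibble (sequence, count), chimera-filtered, sorted by
#'   descending abundance.
#' @param identity Identity threshold, default 0.97.
#' @return Tibble of OTUs (representative, member_count).
#' @export
cluster_otus <- function(seqs, identity = 0.97) {
  if (nrow(seqs) == 0) {
    return(tibble::tibble(representative = character(0),
                          member_count = integer(0)))
  }
  reps <- character(0); counts <- integer(0)
  for (i in seq_len(nrow(seqs))) {
    s <- seqs$sequence[i]; cnt <- seqs$count[i]
    placed <- FALSE
    for (j in seq_along(reps)) {
      if (pairwise_identity(s, reps[j]) >= identity) {
        counts[j] <- counts[j] + cnt; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, s); counts <- c(counts, as.integer(cnt)) }
  }
  tibble::tibble(representative = reps, member_count = counts)
}

#' Dominant OTU of a specimen
#'
#' The specimen's barcode is the representative of its highest-count OTU
#' (ties broken by the lexicographically smallest representative). Specimens
#' whose best OTU has fewer than `min_reads` members are failed.
#'
#' @param otus Tibble from [cluster_otus()].
#' @param min_reads Minimum member count of the dominant OTU.
#' @return One-row tibble (barcode, read_count, status); `status` is
#'   `"ok"` or `"failed"` (barcode `NA`).
#' @export
dominant_otu <- function(otus, min_reads = 10L) {
  if (nrow(otus) == 0 || max(otus$member_count) < min_reads) {
    return(tibble::tibble(barcode = NA_character_, read_count = 0L,
                          status = "failed"))
  }
  top <- otus[otus$member_count == max(otus$member_count), , drop = FALSE]
  top <- top[order(top$representative), , drop = FALSE]
  tibble::tibble(barcode = top$representative[1],
                 read_count = top$member_count[1], status = "ok")
}

#' Determine one specimen's barcode from its merged reads
#'
#' Convenience chain: dereplicate, remove chimeras, cluster OTUs at 97%,
#' take the dominant OTU.
#'
#' @param merged Tibble of one specimen's merged reads.
#' @param identity OTU identity threshold.
#' @param min_reads Minimum dominant-OTU read count.
#' @return One-row tibble (barcode, read_count, status).
#' @export
specimen_barcode <- function(merged, identity = 0.97, min_reads = 10L) {
  merged |>
    dereplicate() |>
    remove_chimeras() |>
    cluster_otus(identity = identity) |>
    dominant_otu(min_reads = min_reads)
}

#' Assign a barcode to a reference lineage by K2P threshold
#'
#' The barcode is compared to every record of the local database; the
#' minimum-distance record assigns its lineage when the distance is below
#' that record's effective threshold (genus overrides apply). Otherwise the
#' secondary database, if given, is tried the same way; else the barcode is
#' unassigned. Ties at the minimum distance prefer a record whose threshold
#' admits the match, then the lexicographically smallest lineage_id.
#'
#' @param barcode DNA string.
#' @param db Local `reference_db`.
#' @param secondary Optional fallback `reference_db` (stands in for a public
#'   database lookup).
#' @param min_sites Minimum compared sites for a distance.
#' @return One-row tibble (lineage_id, distance, route) with route one of
#'   `local_db`, `secondary_db`, `unassigned`.
#' @export
assign_lineage <- function(barcode, db, secondary = NULL, min_sites = 100L) {
  stopifnot(inherits(db, "reference_db"), nrow(db$records) >= 1)
  try_db <- function(d, route) {
    dist <- k2p_to_many(barcode, d$records$sequence, min_sites = min_sites)
    thr <- genus_threshold(d$policy, d$records$genus)
    dmin <- min(dist)
    at_min <- which(dist <= dmin + 1e-12)
    admits <- at_min[dist[at_min] < thr[at_min]]
    pick <- if (length(admits)) admits else at_min
    pick <- pick[order(d$records$lineage_id[pick])][1]
    if (dist[pick] < thr[pick]) {
      tibble::tibble(lineage_id = d$records$lineage_id[pick],
                     distance = dist[pick], route = route)
    } else NULL
  }
  hit <- try_db(db, "local_db")
  if (is.null(hit) && !is.null(secondary)) {
    hit <- try_db(secondary, "secondary_db")
  }
  if (is.null(hit)) {
    dist <- k2p_to_many(barcode, db$records$sequence, min_sites = min_sites)
    hit <- tibble::tibble(lineage_id = NA_character_, distance = min(dist),
                          route = "unassigned")
  }
  hit
}

#' Assign every specimen barcode of a site
#'
#' @param barcodes Tibble (specimen_id, barcode, status) as produced by
#'   [specimen_barcode()] per specimen; failed specimens pass through with
#'   route `"failed"`.
#' @param db,secondary Reference databases, as in [assign_lineage()].
#' @param min_sites Minimum compared sites.
#' @return Tibble (specimen_id, barcode, lineage_id, distance, route).
#' @export
assign_specimens <- function(barcodes, db, secondary = NULL,
                             min_sites = 100L) {
  res <- purrr::map(seq_len(nrow(barcodes)), function(i) {
    if (!is.na(barcodes$status[i]) && barcodes$status[i] == "failed") {
      return(tibble::tibble(lineage_id = NA_character_,
                            distance = NA_real_, route = "failed"))
    }
    assign_lineage(barcodes$barcode[i], db, secondary, min_sites)
  })
  dplyr::bind_cols(barcodes[, c("specimen_id", "barcode")],
                   dplyr::bind_rows(res))
}

#' Cluster unassigned barcodes into new lineages
#'
#' Single-linkage clustering under the same-species rule (K2P below the
#' default threshold); each cluster receives a stable label
#' `NEW_<ordinal>`, numbered by first appearance in the input, and the
#' specimens are relabelled.
#'
#' @param assignments Tibble from [assign_specimens()]; only rows with route
#'   `"unassigned"` are relabelled.
#' @param db `reference_db` supplying the default threshold.
#' @param min_sites Minimum compared sites.
#' @return `assignments` with `lineage_id` filled for unassigned rows.
#' @export
cluster_new_lineages <- function(assignments, db, min_sites = 100L) {
  un <- which(assignments$route == "unassigned" &
                !is.na(assignments$barcode))
  if (!length(un)) return(assignments)
  seqs <- assignments$barcode[un]
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  thr <- db$policy$default
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        tp <- trim_pair(seqs[i], seqs[j])
        if (k2p_core(tp$a, tp$b, min_sites)$k2p < thr) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lab <- match(roots, unique(roots))
  assignments$lineage_id[un] <- sprintf("NEW_%02d", lab)
  assignments
}
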