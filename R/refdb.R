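#' Threshold policy for lineage assignment
#'
#' Species-level assignment of a COI barcode uses a divergence threshold:
#' barcodes diverging by less than 10% from a reference are treated as the
#' same species, except in genera where interspecific divergence is known to
#' be lower (here \emph{Nais} and \emph{Uncinais}, 8%).
#'
#' @param default Default K2P divergence threshold (fraction), 0.10.
#' @param overrides Named numeric vector of per-genus thresholds; defaults to
#'   `c(Nais = 0.08, Uncinais = 0.08)`.
#' @return An object of class `threshold_policy`.
#' @export
#' @examples
#' threshold_policy()
threshold_policy <- function(default = 0.10,
                             overrides = c(Nais = 0.08, Uncinais = 0.08)) {
  stopifnot(default > 0, default < 0.5)
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(nzchar(names(overrides))),
              all(overrides > 0 & overrides < 0.5))
  }
  structure(list(default = default, overrides = overrides),
            class = "threshold_policy")
}

valid_groups <- c("tubificinae_hair", "tubificinae_nohair", "naidinae",
                  "pristininae", "lumbriculidae", "enchytraeidae", "other")

validate_reference_records <- function(records) {
  needed <- c("lineage_id", "taxon_name", "rank", "genus", "group",
              "sensitive", "sequence")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    stop("traits table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(records$lineage_id)) {
    stop("duplicate reference: ",
         paste(unique(records$lineage_id[duplicated(records$lineage_id)]),
               collapse = ", "))
  }
  if (any(grepl("[^ACGT]", records$sequence))) {
    bad <- records$lineage_id[grepl("[^ACGT]", records$sequence)]
    stop("ambiguous reference sequence: ", paste(bad, collapse = ", "))
  }
  bad_rank <- !records$rank %in% c("species", "genus", "subfamily", "family")
  if (any(bad_rank)) stop("invalid rank for: ",
                          paste(records$lineage_id[bad_rank], collapse = ", "))
  no_genus <- records$rank == "species" & (is.na(records$genus) | !nzchar(records$genus))
  if (any(no_genus)) stop("species-rank record without genus: ",
                          paste(records$lineage_id[no_genus], collapse = ", "))
  bad_group <- !records$group %in% valid_groups
  if (any(bad_group)) stop("unknown trait group for: ",
                           paste(records$lineage_id[bad_group], collapse = ", "))
  odd_len <- nchar(records$sequence) != 313L
  if (any(odd_len)) {
    warning(sum(odd_len), " reference sequence(s) differ from the nominal ",
            "313 bp amplicon length")
  }
  invisible(records)
}

#' Build a COI reference database from records
#'
#' @param records Data frame with columns `lineage_id`, `taxon_name`, `rank`
#'   (`species`/`genus`/`subfamily`/`family`), `genus` (may be `NA` below
#'   genus rank), `group` (one of the hair-setae / subfamily trait groups or
#'   `other`), `sensitive` (logical, lake sensitivity-list membership) and
#'   `sequence` (unambiguous A/C/G/T barcode).
#' @param policy A [threshold_policy()].
#' @return A `reference_db` object; `$records` is a tibble.
#' @export
reference_db <- function(records, policy = threshold_policy()) {
  records <- tibble::as_tibble(records)
  records$sequence <- toupper(records$sequence)
  records$sensitive <- as.logical(records$sensitive)
  validate_reference_records(records)
  stopifnot(inherits(policy, "threshold_policy"))
  structure(
    list(records = records, policy = policy,
         sensitive_list = sort(unique(records$taxon_name[records$sensitive]))),
    class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat("COI reference database:", nrow(x$records), "lineages\n")
  cat("  default threshold:", x$policy$default, "\n")
  if (length(x$policy$overrides)) {
    cat("  genus overrides:",
        paste(names(x$policy$overrides), x$policy$overrides,
              sep = "=", collapse = ", "), "\n")
  }
  cat("  sensitive taxa:", length(x$sensitive_list), "\n")
  invisible(x)
}

#' Load a reference database from FASTA + traits table
#'
#' FASTA identifiers must match the `lineage_id` column of the tab-separated
#' traits table. Every FASTA entry must have exactly one traits row.
#'
#' @param fasta Path to the reference FASTA.
#' @param traits Path to a TSV with header `lineage_id`, `taxon_name`,
#'   `rank`, `genus`, `group`, `sensitive`.
#' @param policy A [threshold_policy()].
#' @return A `reference_db` object.
#' @export
load_reference_db <- function(fasta, traits, policy = threshold_policy()) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tab <- tibble::as_tibble(read.delim(traits, sep = "\t",
                                      stringsAsFactors = FALSE))
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate reference: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing <- setdiff(ids, tab$lineage_id)
  if (length(missing)) {
    stop("unannotated reference: ", paste(missing, collapse = ", "))
  }
  tab <- tab[match(ids, tab$lineage_id), , drop = FALSE]
  tab$genus <- as.character(tab$genus)
  tab$sequence <- unname(toupper(as.character(seqs)))
  reference_db(tab, policy)
}

#' Write a reference database to FASTA + traits table
#'
#' Inverse of [load_reference_db()]; a load/write/load round trip reproduces
#' all records.
#'
#' @param db A `reference_db`.
#' @param fasta,traits Output paths.
#' @return Invisibly, the two paths.
#' @export
write_reference_db <- function(db, fasta, traits) {
  stopifnot(inherits(db, "reference_db"))
  seqs <- Biostrings::DNAStringSet(setNames(db$records$sequence,
                                            db$records$lineage_id))
  Biostrings::writeXStringSet(seqs, fasta)
  out <- db$records[, c("lineage_id", "taxon_name", "rank", "genus",
                        "group", "sensitive")]
  write.table(out, traits, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, traits = traits))
}

#' Effective assignment threshold for a reference record
#'
#' Returns the genus override where one exists, else the default threshold.
#'
#' @param db A `reference_db`.
#' @param lineage_id One or more lineage identifiers present in `db`.
#' @return Numeric vector of divergence thresholds (fractions).
#' @export
#' @examples
#' db <- simulate_reference_lineages(6, seed = 1)
#' threshold_for(db, db$records$lineage_id[1])
threshold_for <- function(db, lineage_id) {
  stopifnot(inherits(db, "reference_db"))
  i <- match(lineage_id, db$records$lineage_id)
  if (anyNA(i)) stop("unknown lineage_id: ",
                     paste(lineage_id[is.na(i)], collapse = ", "))
  genus_threshold(db$policy, db$records$genus[i])
}

genus_threshold <- function(policy, genus) {
  thr <- rep(policy$default, length(genus))
  if (length(policy$overrides)) {
    j <- match(genus, names(policy$overrides))
    thr[!is.na(j)] <- policy$overrides[j[!is.na(j)]]
  }
  thr
}
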