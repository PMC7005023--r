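# Synthetic-data module: reference databases, site communities, tagged
# paired-end reads and a coarsened morphological observer, all with known
# ground truth. Defaults mirror the study design: 313 bp COI amplicon, 8 nt
# tags, 2x250 paired-end reads, 33 or 66 specimens per site.

family_of_group <- c(
  tubificinae_hair = "Tubificinae",
  tubificinae_nohair = "Tubificinae",
  naidinae = "Naidinae",
  pristininae = "Pristininae",
  lumbriculidae = "Lumbriculidae",
  enchytraeidae = "Enchytraeidae",
  other = "other")

genus_pool <- list(
  tubificinae_nohair = c("Tubifex", "Limnodrilus"),
  tubificinae_hair = c("Spirosperma", "Psammoryctides"),
  naidinae = c("Nais", "Uncinais"),
  enchytraeidae = c("Enchytraeus", "Fridericia"),
  lumbriculidae = c("Lumbriculus", "Stylodrilus"),
  pristininae = "Pristina")

# number of substitutions giving expected K2P distance d under a uniform
# substitution choice (transition:transversion drawn 1:2, which makes the
# expected K2P equal the Jukes-Cantor value)
n_substitutions_for <- function(d, width) {
  s <- 0.75 * (1 - exp(-4 * d / 3))
  max(1L, round(s * width))
}

mutate_to_distance <- function(seq, d) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(length(ch), n_substitutions_for(d, length(ch)))
  ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(DNA_BASES, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

#' Simulate a COI reference database with known divergence structure
#'
#' Generates `n_lineages` reference barcodes whose pairwise K2P distances all
#' exceed `min_sep`, except for designated cryptic pairs placed at
#' `cryptic_distance` (above the species threshold, so genetically distinct)
#' that share one morphological taxon name — emulating cryptic species
#' complexes that a morphological observer cannot separate. Trait groups
#' (tubificid hair-setae classes, other subfamilies/families) cycle over the
#' lineages; lineages in Lumbriculidae, Enchytraeidae, Pristininae and the
#' genus \emph{Spirosperma} are flagged pollution-sensitive; one naidine
#' lineage receives genus \emph{Nais} so the 8% genus override is exercised.
#'
#' @param n_lineages Number of lineages (>= 2).
#' @param min_sep Minimum pairwise K2P separation between non-cryptic
#'   lineages; must exceed every assignment threshold.
#' @param cryptic_pairs Number of cryptic pairs among the lineages.
#' @param cryptic_distance Target K2P distance within a cryptic pair.
#' @param amplicon_length Barcode length in bases.
#' @param policy A [threshold_policy()].
#' @param seed Integer seed; identical seeds give identical databases.
#' @return A `reference_db`.
#' @export
#' @examples
#' db <- simulate_reference_lineages(8, seed = 42)
#' db
simulate_reference_lineages <- function(n_lineages, min_sep = 0.15,
                                        cryptic_pairs = 1,
                                        cryptic_distance = 0.12,
                                        amplicon_length = 313L,
                                        policy = threshold_policy(),
                                        seed = 1L) {
  stopifnot(n_lineages >= 2, cryptic_pairs >= 0,
            cryptic_pairs < n_lineages)
  max_thr <- max(policy$default, policy$overrides, 0)
  if (min_sep <= max_thr) {
    stop("min_sep must exceed the largest assignment threshold")
  }
  # a random pair of this length has expected distance far above min_sep;
  # infeasible requests (tiny amplicons) exhaust the retry budget
  set.seed(seed)
  n_base <- n_lineages - cryptic_pairs
  base <- character(n_base)
  for (i in seq_len(n_base)) {
    ok <- FALSE
    for (try in 1:100) {
      cand <- random_dna(1, amplicon_length)
      seps <- if (i == 1) numeric(0) else
        k2p_to_many(cand, base[seq_len(i - 1)],
                    min_sites = min(100L, amplicon_length))
      if (all(seps > min_sep)) { base[i] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("cannot satisfy min_sep")
  }

  groups <- rep(c("tubificinae_nohair", "tubificinae_hair", "naidinae",
                  "enchytraeidae", "lumbriculidae", "pristininae"),
                length.out = n_base)
  genus <- vapply(seq_len(n_base), function(i) {
    pool <- genus_pool[[groups[i]]]
    pool[((i - 1L) %/% 6L) %% length(pool) + 1L]
  }, character(1))
  taxon <- paste0(genus, " sp. ", seq_len(n_base))

  recs <- tibble::tibble(
    lineage_id = sprintf("L%02d", seq_len(n_base)),
    taxon_name = taxon, rank = "species", genus = genus,
    group = groups,
    sensitive = groups %in% c("lumbriculidae", "enchytraeidae",
                              "pristininae") | genus == "Spirosperma",
    sequence = base)

  if (cryptic_pairs > 0) {
    part <- recs[seq_len(cryptic_pairs), , drop = FALSE]
    part$lineage_id <- sprintf("L%02db", seq_len(cryptic_pairs))
    for (k in seq_len(cryptic_pairs)) {
      ok <- FALSE
      for (try in 1:100) {
        cand <- mutate_to_distance(recs$sequence[k], cryptic_distance)
        others <- setdiff(seq_len(n_base), k)
        seps <- if (length(others)) {
          k2p_to_many(cand, recs$sequence[others],
                      min_sites = min(100L, amplicon_length))
        } else numeric(0)
        d_base <- k2p_to_many(cand, recs$sequence[k],
                              min_sites = min(100L, amplicon_length))
        if (all(seps > min_sep) && d_base > max_thr) {
          part$sequence[k] <- cand; ok <- TRUE; break
        }
      }
      if (!ok) stop("cannot satisfy min_sep")
    }
    recs <- dplyr::bind_rows(recs, part)
  }
  reference_db(recs, policy)
}

#' Define a site community profile
#'
#' Relative lineage abundances for one simulated site along a pollution
#' gradient: impacted sites load weight on tolerant tubificids, clean sites
#' on sensitive taxa.
#'
#' @param profile_name Label for the profile.
#' @param lineage_weights Named non-negative weights over lineage ids of a
#'   companion reference database (sum must be positive).
#' @param habitat `"stream"` or `"lake"`.
#' @return A `community_profile` object.
#' @export
community_profile <- function(profile_name, lineage_weights,
                              habitat = c("stream", "lake")) {
  habitat <- match.arg(habitat)
  if (length(lineage_weights) == 0 || sum(lineage_weights) <= 0) {
    stop("empty community")
  }
  stopifnot(!is.null(names(lineage_weights)), all(lineage_weights >= 0))
  structure(list(profile_name = profile_name,
                 lineage_weights = lineage_weights, habitat = habitat),
            class = "community_profile")
}

#' Draw the specimens of one site
#'
#' Specimen lineages are drawn one at a time from the normalized profile
#' weights, so draws are nested: the first 33 specimens of a 66-specimen
#' draw with the same seed are exactly the 33-specimen draw. This reproduces
#' the study design in which two sets of 33 specimens were sorted at the
#' 66-specimen sites.
#'
#' @param profile A [community_profile()].
#' @param n_specimens Number of specimens (33, 66 or 100 in the study).
#' @param site_id Site label.
#' @param seed Integer seed.
#' @return A `site_truth` object: `$specimens` (specimen_id, lineage_id),
#'   `$counts` (lineage_id, n), plus site_id and habitat.
#' @export
simulate_site_community <- function(profile, n_specimens, site_id = "site1",
                                    seed = 1L) {
  stopifnot(inherits(profile, "community_profile"), n_specimens >= 1)
  w <- profile$lineage_weights
  if (sum(w) <= 0) stop("empty community")
  p <- w / sum(w)
  set.seed(seed)
  u <- runif(n_specimens)
  idx <- findInterval(u, cumsum(p)) + 1L
  idx[idx > length(p)] <- length(p)
  specimens <- tibble::tibble(
    specimen_id = sprintf("%s_SP%03d", site_id, seq_len(n_specimens)),
    lineage_id = names(p)[idx])
  counts <- dplyr::count(specimens, .data$lineage_id, name = "n")
  structure(list(site_id = site_id, habitat = profile$habitat,
                 profile_name = profile$profile_name,
                 specimens = specimens, counts = counts),
            class = "site_truth")
}

#' @export
print.site_truth <- function(x, ...) {
  cat("site_truth:", x$site_id, sprintf("(%s)", x$habitat),
      nrow(x$specimens), "specimens,", nrow(x$counts), "lineages\n")
  invisible(x)
}

# degenerate metazoan COI primer pair used in the study
#' @rdname tag_scheme
#' @export
default_primers <- function() {
  c(fwd = "GGWACWGGWTGAACWGTWTAYCCYCC",   # mlCOIintF
    rev = "TANACYTCNGGRTGNCCRAARAAYCA")   # jgHCO2198, inosine as N
}

disambiguate_primer <- function(p) {
  ch <- strsplit(p, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(b) IUPAC[[b]][1], character(1)), collapse = "")
}

random_tags <- function(k, width = 8L, min_dist = 3L) {
  tags <- character(0)
  for (tries in 1:10000) {
    cand <- random_dna(1, width)
    if (all(vapply(tags, function(t) hamming(t, cand), numeric(1)) >= min_dist)) {
      tags <- c(tags, cand)
      if (length(tags) == k) return(tags)
    }
  }
  stop("could not generate ", k, " well-separated tags")
}

#' Tag scheme: specimen to dual 8-nt tag combination
#'
#' Assigns each specimen a unique (forward tag, reverse tag) combination,
#' Latin-square style: individual 8-mers are reused across specimens but
#' every combination is unique within the site library. Tags are generated
#' at pairwise Hamming distance >= 3 so a single sequencing error cannot turn
#' one valid tag into another. `default_primers()` returns the degenerate
#' metazoan COI primer pair used for the 313 bp fragment.
#'
#' @param specimen_ids Character vector of specimen identifiers.
#' @param site_id Site label.
#' @param fwd_primer,rev_primer Primer sequences (IUPAC codes allowed).
#' @param tag_length Tag width in bases.
#' @param seed Integer seed.
#' @return A `tag_scheme`: `$entries` tibble (specimen_id, fwd_tag, rev_tag)
#'   plus primers and their fixed disambiguations used when simulating reads.
#' @export
tag_scheme <- function(specimen_ids, site_id = "site1",
                       fwd_primer = default_primers()[["fwd"]],
                       rev_primer = default_primers()[["rev"]],
                       tag_length = 8L, seed = 1L) {
  n <- length(specimen_ids)
  stopifnot(n >= 1, !anyDuplicated(specimen_ids))
  set.seed(seed)
  k <- ceiling(sqrt(n))
  fwd_tags <- random_tags(k, tag_length)
  rev_tags <- random_tags(k, tag_length)
  i <- seq_len(n) - 1L
  entries <- tibble::tibble(
    specimen_id = specimen_ids,
    fwd_tag = fwd_tags[i %/% k + 1L],
    rev_tag = rev_tags[i %% k + 1L])
  structure(list(site_id = site_id, entries = entries,
                 fwd_primer = fwd_primer, rev_primer = rev_primer,
                 fwd_primer_real = disambiguate_primer(fwd_primer),
                 rev_primer_real = disambiguate_primer(rev_primer)),
            class = "tag_scheme")
}

#' Simulation configuration
#'
#' Study-design defaults: 313 bp amplicon, 8 nt tags, 2x250 reads, mean
#' depth 50 read pairs per specimen. The error model is substitution-only by
#' default (MiSeq errors are substitution-dominated); quality scores are a
#' two-tier high/low mixture whose mean error rate equals `per_base_error`,
#' so the mean-Q30 filter is exercised meaningfully.
#'
#' @param reads_per_specimen Mean Poisson depth (floor of 1 pair).
#' @param per_base_error Mean substitution probability per base.
#' @param chimera_rate Fraction of reads that are two-parent splices.
#' @param indel_rate Per-read probability of a single indel (default 0).
#' @param dropout_rate Per-specimen probability of total amplification
#'   failure (default 0; the study reports >99% specimen success).
#' @param tag_length,amplicon_length,read_length Design constants.
#' @return A `sim_config` list.
#' @export
sim_config <- function(reads_per_specimen = 50, per_base_error = 0.001,
                       chimera_rate = 0.01, indel_rate = 0,
                       dropout_rate = 0, tag_length = 8L,
                       amplicon_length = 313L, read_length = 250L) {
  stopifnot(per_base_error >= 0, per_base_error <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            indel_rate >= 0, indel_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(reads_per_specimen = reads_per_specimen,
                 per_base_error = per_base_error,
                 chimera_rate = chimera_rate, indel_rate = indel_rate,
                 dropout_rate = dropout_rate, tag_length = tag_length,
                 amplicon_length = amplicon_length,
                 read_length = read_length),
            class = "sim_config")
}

# two-tier quality mixture with mean error per_base_error
error_tiers <- function(p) {
  q_hi <- 38L; q_lo <- 15L
  e_hi <- 10^(-q_hi / 10); e_lo <- 10^(-q_lo / 10)
  if (p <= 0) return(list(w = 0, q_hi = 40L, q_lo = 40L, e_hi = 0, e_lo = 0))
  if (p <= e_hi) {
    q <- as.integer(round(-10 * log10(p)))
    return(list(w = 0, q_hi = q, q_lo = q, e_hi = p, e_lo = p))
  }
  list(w = (p - e_hi) / (e_lo - e_hi), q_hi = q_hi, q_lo = q_lo,
       e_hi = e_hi, e_lo = e_lo)
}

#' Generate tagged paired-end reads for one site
#'
#' Each specimen yields ~Poisson(`reads_per_specimen`) read pairs (floor 1).
#' The forward read is forward tag + forward primer + amplicon prefix; the
#' reverse read is reverse tag + reverse primer + reverse-complemented
#' amplicon suffix; both truncated to `read_length`. Substitutions are
#' i.i.d. at the configured mean rate with Phred+33 qualities consistent
#' with the error model; a `chimera_rate` fraction of reads are two-parent
#' splices at a uniform breakpoint (the second parent drawn from the other
#' lineages at the site).
#'
#' @param truth A `site_truth` from [simulate_site_community()].
#' @param scheme A [tag_scheme()] covering every specimen.
#' @param config A [sim_config()].
#' @param db The companion `reference_db` providing template sequences.
#' @param dir Output directory for the two FASTQ files.
#' @param seed Integer seed; identical seeds give byte-identical FASTQ.
#' @return List: `r1`, `r2` (FASTQ paths) and `read_truth`, a tibble with
#'   one row per pair (read_id, specimen_id, origin, parent_a, parent_b).
#' @export
generate_reads <- function(truth, scheme, config, db, dir = tempdir(),
                           seed = 1L) {
  stopifnot(inherits(truth, "site_truth"), inherits(scheme, "tag_scheme"),
            inherits(config, "sim_config"), inherits(db, "reference_db"))
  sp <- truth$specimens
  miss <- setdiff(sp$specimen_id, scheme$entries$specimen_id)
  if (length(miss)) stop("untagged specimen: ", paste(miss, collapse = ", "))
  templates <- setNames(db$records$sequence, db$records$lineage_id)
  if (anyNA(match(sp$lineage_id, names(templates)))) {
    stop("specimen lineage missing from reference database")
  }
  fp <- scheme$fwd_primer_real; rp <- scheme$rev_primer_real
  ins_len_f <- config$read_length - config$tag_length - nchar(fp)
  ins_len_r <- config$read_length - config$tag_length - nchar(rp)
  if (ins_len_f < 20 || ins_len_r < 20) stop("read_length too short")

  set.seed(seed)
  depth <- pmax(1L, rpois(nrow(sp), config$reads_per_specimen))
  if (config$dropout_rate > 0) {
    depth[runif(nrow(sp)) < config$dropout_rate] <- 0L
  }
  ridx <- rep(seq_len(nrow(sp)), depth)
  n_reads <- length(ridx)
  if (n_reads == 0) stop("no reads generated")

  ent <- scheme$entries[match(sp$specimen_id[ridx],
                              scheme$entries$specimen_id), ]
  lineage <- sp$lineage_id[ridx]
  tmpl <- unname(templates[lineage])
  L <- nchar(templates[1])

  is_chim <- runif(n_reads) < config$chimera_rate
  parent_b <- rep(NA_character_, n_reads)
  if (any(is_chim)) {
    all_l <- unique(c(names(templates)))
    bp <- sample(seq(30L, L - 30L), sum(is_chim), replace = TRUE)
    pb <- vapply(which(is_chim), function(j) {
      pool <- setdiff(unique(sp$lineage_id), lineage[j])
      if (!length(pool)) pool <- setdiff(all_l, lineage[j])
      sample(pool, 1)
    }, character(1))
    parent_b[is_chim] <- pb
    tmpl[is_chim] <- paste0(substr(tmpl[is_chim], 1, bp),
                            substr(unname(templates[pb]), bp + 1L, L))
  }

  if (config$indel_rate > 0) {
    has_indel <- runif(n_reads) < config$indel_rate
    for (j in which(has_indel)) {
      pos <- sample(nchar(tmpl[j]) - 1L, 1)
      if (runif(1) < 0.5) {
        tmpl[j] <- paste0(substr(tmpl[j], 1, pos - 1),
                          substr(tmpl[j], pos + 1, nchar(tmpl[j])))
      } else {
        tmpl[j] <- paste0(substr(tmpl[j], 1, pos),
                          sample(DNA_BASES, 1),
                          substr(tmpl[j], pos + 1, nchar(tmpl[j])))
      }
    }
  }

  fwd <- paste0(ent$fwd_tag, fp, substr(tmpl, 1, ins_len_f))
  rev_ins <- revcomp(substr(tmpl, nchar(tmpl) - ins_len_r + 1L, nchar(tmpl)))
  rev <- paste0(ent$rev_tag, rp, rev_ins)

  noisy <- function(seqs) {
    m <- seq_matrix(seqs)
    tiers <- error_tiers(config$per_base_error)
    nb <- length(m)
    low <- if (tiers$w > 0) runif(nb) < tiers$w else rep(FALSE, nb)
    q <- matrix(ifelse(low, tiers$q_lo, tiers$q_hi), nrow(m), ncol(m))
    e <- matrix(ifelse(low, tiers$e_lo, tiers$e_hi), nrow(m), ncol(m))
    err <- which(matrix(runif(nb), nrow(m)) < e)
    if (length(err)) {
      cur <- m[err]
      m[err] <- vapply(cur, function(b) {
        utf8ToInt(sample(setdiff(DNA_BASES, intToUtf8(b)), 1))
      }, integer(1))
    }
    list(seq = matrix_seq(m), qual = matrix_qual(q))
  }
  f <- noisy(fwd); r <- noisy(rev)

  read_id <- sprintf("%s_read%06d", truth$site_id, seq_len(n_reads))
  r1 <- file.path(dir, paste0(truth$site_id, "_R1.fastq"))
  r2 <- file.path(dir, paste0(truth$site_id, "_R2.fastq"))
  write_fastq(read_id, f$seq, f$qual, r1)
  write_fastq(read_id, r$seq, r$qual, r2)

  read_truth <- tibble::tibble(
    read_id = read_id, specimen_id = sp$specimen_id[ridx],
    origin = ifelse(is_chim, "chimera", "template"),
    parent_a = lineage, parent_b = parent_b)
  list(r1 = r1, r2 = r2, read_truth = read_truth)
}

write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Coarsen genetic ground truth into a morphological observation
#'
#' Emulates a morphological observer examining the same specimens: members
#' of a cryptic pair are merged under their shared taxon name, and a
#' fraction of specimens cannot be identified to species and are demoted to
#' subfamily/family-level labels (hair-setae state remains observable for
#' tubificids, so demoted specimens keep their trait group; their
#' sensitivity flag is lost). Counts are conserved.
#'
#' @param truth A `site_truth`.
#' @param db The companion `reference_db`.
#' @param unresolved_rate Fraction of specimens demoted to family level.
#' @param seed Integer seed.
#' @return A site community tibble (site_id, habitat, source, label, group,
#'   sensitive, count) with `source = "morphological"`.
#' @export
coarsen_to_morphology <- function(truth, db, unresolved_rate = 0.1,
                                  seed = 1L) {
  stopifnot(inherits(truth, "site_truth"), inherits(db, "reference_db"),
            unresolved_rate >= 0, unresolved_rate <= 1)
  rec <- db$records
  i <- match(truth$specimens$lineage_id, rec$lineage_id)
  lab <- rec$taxon_name[i]
  grp <- rec$group[i]
  sens <- rec$sensitive[i]
  set.seed(seed)
  demote <- runif(length(lab)) < unresolved_rate
  fam <- unname(family_of_group[grp])
  hair <- ifelse(grp == "tubificinae_hair", " with hair setae",
                 ifelse(grp == "tubificinae_nohair", " without hair setae", ""))
  lab[demote] <- paste0(fam[demote], " g. sp.", hair[demote])
  sens[demote] <- FALSE
  tibble::tibble(site_id = truth$site_id, habitat = truth$habitat,
                 source = "morphological", label = lab, group = grp,
                 sensitive = sens) |>
    dplyr::count(.data$site_id, .data$habitat, .data$source, .data$label,
                 .data$group, .data$sensitive, name = "count")
}

#' Site community from simulated ground truth
#'
#' Lineage-level counts straight from the simulated specimens, labelled as a
#' genetic-source community; the reference for end-to-end recovery checks.
#'
#' @param truth A `site_truth`.
#' @param db The companion `reference_db`.
#' @return A site community tibble with `source = "genetic"`.
#' @export
community_from_truth <- function(truth, db) {
  rec <- db$records
  i <- match(truth$counts$lineage_id, rec$lineage_id)
  tibble::tibble(site_id = truth$site_id, habitat = truth$habitat,
                 source = "genetic", label = truth$counts$lineage_id,
                 group = rec$group[i], sensitive = rec$sensitive[i],
                 count = truth$counts$n)
}
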