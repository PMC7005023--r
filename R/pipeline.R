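# End-to-end orchestration: simulate -> demultiplex -> assign -> indices ->
# concordance, with deterministic per-site, per-stage seed derivation from a
# single master seed.

#' Pipeline configuration
#'
#' Stage parameters default to the study's values: mean quality 30, 8 nt
#' tags, 313 bp amplicon, 97% OTU identity, thresholds 0.10 with the 8%
#' Nais/Uncinais overrides (carried by the reference database), minimum 10
#' reads for a specimen barcode.
#'
#' @param db Local `reference_db`.
#' @param profiles Named list of [community_profile()]s, one per site id.
#' @param specimens_per_site Integer, recycled over sites (33, 66 or 100 in
#'   the study design).
#' @param sim A [sim_config()].
#' @param secondary_db Optional fallback `reference_db`.
#' @param min_mean_q,min_reads,identity,min_sites Stage parameters.
#' @param unresolved_rate Morphological observer demotion rate.
#' @param seed Master seed; per-site, per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(db, profiles, specimens_per_site = 33L,
                            sim = sim_config(), secondary_db = NULL,
                            min_mean_q = 30, min_reads = 10L,
                            identity = 0.97, min_sites = 100L,
                            unresolved_rate = 0.1, seed = 1L,
                            out_dir = tempfile("oligotag_study_")) {
  stopifnot(inherits(db, "reference_db"), length(profiles) >= 1,
            !is.null(names(profiles)))
  specimens_per_site <- rep(as.integer(specimens_per_site),
                            length.out = length(profiles))
  names(specimens_per_site) <- names(profiles)
  structure(list(db = db, profiles = profiles,
                 specimens_per_site = specimens_per_site, sim = sim,
                 secondary_db = secondary_db, min_mean_q = min_mean_q,
                 min_reads = min_reads, identity = identity,
                 min_sites = min_sites, unresolved_rate = unresolved_rate,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  sprintf("%08x", derive_seed(0L, txt))
}

write_stamped_tsv <- function(df, path, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# oligotag seed=%d config=%s", config$seed,
                     config_hash(config)), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# genetic site community from specimen assignments
community_from_assignments <- function(assignments, db, site_id, habitat) {
  ok <- assignments[!assignments$route %in% c("failed") &
                      !is.na(assignments$lineage_id), , drop = FALSE]
  cc <- dplyr::count(ok, label = .data$lineage_id, name = "count")
  rec <- db$records
  i <- match(cc$label, rec$lineage_id)
  tibble::tibble(site_id = site_id, habitat = habitat, source = "genetic",
                 label = cc$label,
                 group = rec$group[i],          # NA for NEW_* lineages
                 sensitive = ifelse(is.na(i), FALSE, rec$sensitive[i]),
                 count = cc$count)
}

#' Run the full pipeline for one site
#'
#' Simulates the site's specimens and tagged reads, then runs quality
#' filtering, exact-tag demultiplexing, pair merging, per-specimen barcode
#' determination, threshold assignment, new-lineage clustering, and the
#' habitat's quality index, alongside the coarsened morphological
#' observation of the same specimens. All stage seeds derive from the
#' master seed, so reruns are bit-for-bit reproducible.
#'
#' @param config A [pipeline_config()].
#' @param site_id Name of a profile in `config$profiles`.
#' @return A `site_report` list: stage statistics, assignment table,
#'   genetic/morphological/true communities and their index results.
#' @export
run_site <- function(config, site_id) {
  stopifnot(inherits(config, "pipeline_config"))
  profile <- config$profiles[[site_id]]
  if (is.null(profile)) stop("unknown site: ", site_id)
  site_dir <- file.path(config$out_dir, site_id)
  dir.create(site_dir, recursive = TRUE, showWarnings = FALSE)
  sd <- function(stage) derive_seed(config$seed, site_id, stage)

  truth <- simulate_site_community(profile,
                                   config$specimens_per_site[[site_id]],
                                   site_id = site_id, seed = sd("community"))
  scheme <- tag_scheme(truth$specimens$specimen_id, site_id = site_id,
                       tag_length = config$sim$tag_length, seed = sd("tags"))
  rr <- generate_reads(truth, scheme, config$sim, config$db, dir = site_dir,
                       seed = sd("reads"))

  pairs <- read_fastq_pairs(rr$r1, rr$r2)
  filt <- quality_filter(pairs, min_mean_q = config$min_mean_q)
  dmx <- demultiplex(filt, scheme)
  merged <- merge_pairs(dmx)

  barcodes <- merged |>
    dplyr::group_by(.data$specimen_id) |>
    dplyr::group_modify(~ specimen_barcode(.x, identity = config$identity,
                                           min_reads = config$min_reads)) |>
    dplyr::ungroup()
  absent <- setdiff(truth$specimens$specimen_id, barcodes$specimen_id)
  if (length(absent)) {
    barcodes <- dplyr::bind_rows(
      barcodes,
      tibble::tibble(specimen_id = absent, barcode = NA_character_,
                     read_count = 0L, status = "failed"))
  }
  barcodes <- barcodes[order(barcodes$specimen_id), , drop = FALSE]

  assignments <- assign_specimens(barcodes, config$db, config$secondary_db,
                                  min_sites = config$min_sites) |>
    cluster_new_lineages(config$db, min_sites = config$min_sites)
  assignments$true_lineage <-
    truth$specimens$lineage_id[match(assignments$specimen_id,
                                     truth$specimens$specimen_id)]

  genetic <- community_from_assignments(assignments, config$db, site_id,
                                        truth$habitat)
  morph <- coarsen_to_morphology(truth, config$db,
                                 unresolved_rate = config$unresolved_rate,
                                 seed = sd("morph"))
  truth_comm <- community_from_truth(truth, config$db)

  n_failed <- sum(assignments$route == "failed")
  stats <- tibble::tibble(
    site_id = site_id, habitat = truth$habitat,
    n_specimens = nrow(truth$specimens),
    n_pairs = nrow(pairs),
    n_quality_discarded = attr(filt, "n_discarded"),
    n_assigned_reads = nrow(dmx),
    n_rejected_reads = attr(dmx, "n_rejected"),
    n_merge_dropped = attr(merged, "n_dropped"),
    n_failed_specimens = n_failed,
    success_rate = 1 - n_failed / nrow(truth$specimens))

  report <- structure(list(
    site_id = site_id, stats = stats, assignments = assignments,
    genetic_community = genetic, morph_community = morph,
    truth_community = truth_comm,
    genetic_index = compute_index(genetic),
    morph_index = compute_index(morph),
    truth_index = compute_index(truth_comm),
    seed = config$seed), class = "site_report")

  write_stamped_tsv(assignments, file.path(site_dir, "assignments.tsv"),
                    config)
  write_stamped_tsv(genetic, file.path(site_dir, "genetic_community.tsv"),
                    config)
  write_stamped_tsv(stats, file.path(site_dir, "stats.tsv"), config)
  report
}

#' @export
print.site_report <- function(x, ...) {
  cat("site_report:", x$site_id, "\n")
  print(x$stats)
  invisible(x)
}

#' Study-scale site design: streams and lakes along a pollution gradient
#'
#' Builds one community profile per site over the lineages of `db`:
#' impacted sites weight tolerant tubificids heavily, clean sites weight
#' sensitive taxa, with log-normal site-to-site noise. The default 13
#' stream and 7 lake sites mirror the study's 20-site layout.
#'
#' @param db A `reference_db`.
#' @param n_stream,n_lake Site counts.
#' @param seed Integer seed.
#' @return Named list of [community_profile()]s.
#' @export
study_design <- function(db, n_stream = 13L, n_lake = 7L, seed = 1L) {
  rec <- db$records
  tol <- rec$group %in% c("tubificinae_hair", "tubificinae_nohair")
  set.seed(seed)
  make_profile <- function(site, gradient, habitat) {
    z <- stats::rnorm(nrow(rec), 0, 0.5)
    bias <- ifelse(tol, 3 * gradient - 1.5, 0) +
      ifelse(rec$sensitive, 1.5 - 3 * gradient, 0)
    w <- exp(z + bias)
    community_profile(site, setNames(w, rec$lineage_id), habitat)
  }
  sites <- c(sprintf("stream%02d", seq_len(n_stream)),
             sprintf("lake%02d", seq_len(n_lake)))
  gradient <- c(seq(0, 1, length.out = n_stream),
                seq(0, 1, length.out = n_lake))
  habitat <- rep(c("stream", "lake"), c(n_stream, n_lake))
  profiles <- lapply(seq_along(sites), function(i) {
    make_profile(sites[i], gradient[i], habitat[i])
  })
  setNames(profiles, sites)
}

#' Run a multi-site study with concordance analysis
#'
#' Runs every site of the configuration, then compares the morphological
#' and genetic diagnoses: log-linearized IOBS regression over stream sites,
#' percentage-of-sensitive-taxa regression over lake sites, and the
#' quality-class agreement table over all sites.
#'
#' @param config A [pipeline_config()].
#' @return A `study_report`: `sites` (list of site reports), `summary`
#'   (one row per site), `regressions` (glances of the per-metric fits),
#'   `fits`, and `agreement` from [class_agreement()].
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  reports <- lapply(names(config$profiles),
                    function(s) run_site(config, s))
  names(reports) <- names(config$profiles)

  summary <- purrr::map_dfr(reports, function(r) {
    dplyr::bind_cols(
      r$stats[, c("site_id", "habitat", "n_specimens", "success_rate")],
      tibble::tibble(
        genetic_value = r$genetic_index$value,
        genetic_class = as.character(r$genetic_index$quality_class),
        morph_value = r$morph_index$value,
        morph_class = as.character(r$morph_index$quality_class),
        truth_value = r$truth_index$value,
        truth_class = as.character(r$truth_index$quality_class)))
  })

  fits <- list()
  for (m in c("iobs", "pct_sensitive")) {
    hab <- if (m == "iobs") "stream" else "lake"
    sub <- summary[summary$habitat == hab, , drop = FALSE]
    pairs <- tibble::tibble(site_id = sub$site_id, x = sub$morph_value,
                            y = sub$genetic_value)
    if (nrow(pairs) >= 3) {
      fits[[m]] <- concordance_regression(pairs, metric_name = m)
    }
  }
  regressions <- purrr::map_dfr(fits, glance)

  agreement <- class_agreement(
    tibble::tibble(site_id = summary$site_id,
                   quality_class = summary$morph_class),
    tibble::tibble(site_id = summary$site_id,
                   quality_class = summary$genetic_class))

  write_stamped_tsv(summary, file.path(config$out_dir, "summary.tsv"),
                    config)
  if (nrow(regressions)) {
    write_stamped_tsv(regressions,
                      file.path(config$out_dir, "regressions.tsv"), config)
  }
  write_stamped_tsv(agreement$per_site,
                    file.path(config$out_dir, "agreement.tsv"), config)

  structure(list(sites = reports, summary = summary,
                 regressions = regressions, fits = fits,
                 agreement = agreement, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", nrow(x$summary), "sites\n")
  print(x$summary)
  if (nrow(x$regressions)) print(x$regressions)
  print(x$agreement$counts)
  invisible(x)
}
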