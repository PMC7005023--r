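# Abundance-based sediment quality metrics: IOBS for streams, percentage of
# sensitive taxa for lakes, and their quality classes. Identical arithmetic
# for morphological and genetic count tables.

QUALITY_LEVELS <- c("bad", "poor", "medium", "good", "very_good")

quality_factor <- function(x) {
  factor(x, levels = c(QUALITY_LEVELS, "undefined"), ordered = TRUE)
}

#' Build a site community table
#'
#' @param counts Data frame with columns site_id, label, count and
#'   optionally habitat, source, group, sensitive.
#' @param traits Optional data frame (label, group, sensitive) used to fill
#'   missing trait columns; a `reference_db` may be given instead, in which
#'   case labels are matched against its lineage ids.
#' @param habitat,source Defaults applied when the columns are absent.
#' @return A site community tibble.
#' @export
site_community <- function(counts, traits = NULL, habitat = "stream",
                           source = "genetic") {
  out <- tibble::as_tibble(counts)
  stopifnot(all(c("site_id", "label", "count") %in% names(out)))
  if (!"habitat" %in% names(out)) out$habitat <- habitat
  if (!"source" %in% names(out)) out$source <- source
  if (!is.null(traits)) {
    if (inherits(traits, "reference_db")) {
      traits <- tibble::tibble(label = traits$records$lineage_id,
                               group = traits$records$group,
                               sensitive = traits$records$sensitive)
    }
    i <- match(out$label, traits$label)
    out$group <- traits$group[i]
    out$sensitive <- traits$sensitive[i]
  }
  if (!"group" %in% names(out)) out$group <- NA_character_
  if (!"sensitive" %in% names(out)) out$sensitive <- NA
  stopifnot(all(out$count >= 1))
  out
}

#' IOBS stream index
#'
#' IOBS = 10 S / T, where S is the number of taxa among the identified
#' specimens of the sample and T is the percentage (of all identified
#' specimens, mature and immature combined) of the dominant tubificid group
#' — tubificids with or without hair setae, whichever is larger. Labels
#' lacking a hair-setae group (e.g. new lineages) count in S and in T's
#' denominator but not in its numerator. T = 0 yields an undefined index.
#'
#' @param community A site community tibble (habitat `"stream"`); multiple
#'   sites are computed per `site_id`.
#' @return Tibble: site_id, S, T, iobs, quality_class.
#' @export
#' @examples
#' cc <- tibble::tibble(site_id = "s1",
#'   label = c("a", "b", "c"), count = c(40, 40, 20),
#'   group = c("tubificinae_hair", "naidinae", "lumbriculidae"),
#'   sensitive = FALSE)
#' compute_iobs(site_community(cc))
compute_iobs <- function(community) {
  if (nrow(community) == 0) stop("no specimens")
  community |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      S = dplyr::n_distinct(.data$label),
      T = {
        tot <- sum(.data$count)
        100 * max(
          sum(.data$count[.data$group %in% "tubificinae_hair"]),
          sum(.data$count[.data$group %in% "tubificinae_nohair"])) / tot
      },
      .groups = "drop") |>
    dplyr::mutate(
      iobs = ifelse(.data$T > 0, 10 * .data$S / .data$T, NA_real_),
      quality_class = classify_iobs(.data$iobs))
}

#' IOBS quality class
#'
#' Printed scale: IOBS >= 6 very good, 3-5.9 good, 2-2.9 medium, 1-1.9
#' poor, < 1 bad; read as the half-open bands [6,Inf), [3,6), [2,3), [1,2),
#' [0,1) so that every non-negative value has a class. `NA` (undefined
#' index) passes through as `"undefined"`.
#'
#' @param iobs Numeric vector of index values.
#' @return Ordered factor of quality classes.
#' @export
classify_iobs <- function(iobs) {
  if (any(!is.na(iobs) & iobs < 0)) stop("invalid index")
  cls <- ifelse(is.na(iobs), "undefined",
         ifelse(iobs >= 6, "very_good",
         ifelse(iobs >= 3, "good",
         ifelse(iobs >= 2, "medium",
         ifelse(iobs >= 1, "poor", "bad")))))
  quality_factor(cls)
}

#' Percentage of sensitive taxa (lake metric)
#'
#' 100 times the share of identified specimens whose label is flagged
#' pollution-sensitive. Labels with an unresolved sensitivity flag are
#' counted non-sensitive, with a warning.
#'
#' @param community A site community tibble (habitat `"lake"`).
#' @return Tibble: site_id, pct_sensitive, quality_class.
#' @export
percent_sensitive <- function(community) {
  if (nrow(community) == 0) stop("no specimens")
  if (any(is.na(community$sensitive))) {
    warning("labels with unresolved sensitivity counted non-sensitive: ",
            paste(unique(community$label[is.na(community$sensitive)]),
                  collapse = ", "))
  }
  community |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      pct_sensitive = 100 * sum(.data$count[.data$sensitive %in% TRUE]) /
        sum(.data$count),
      .groups = "drop") |>
    dplyr::mutate(quality_class = classify_sensitive(.data$pct_sensitive))
}

#' Quality class for the percentage of sensitive taxa
#'
#' Printed scale: > 50 very good, 21-50 good, 11-20 medium, 6-10 poor,
#' 0-5 bad; read as the bands (50,100], (20,50], (10,20], (5,10], [0,5].
#'
#' @param pct Numeric vector of percentages (0-100).
#' @return Ordered factor of quality classes.
#' @export
classify_sensitive <- function(pct) {
  if (any(!is.na(pct) & (pct < 0 | pct > 100))) stop("invalid percentage")
  cls <- ifelse(is.na(pct), "undefined",
         ifelse(pct > 50, "very_good",
         ifelse(pct > 20, "good",
         ifelse(pct > 10, "medium",
         ifelse(pct > 5, "poor", "bad")))))
  quality_factor(cls)
}

#' Quality metric for a community, dispatched on habitat
#'
#' Streams get the IOBS; lakes get the percentage of sensitive taxa. Both
#' results carry a `metric` column and a `value` column alongside the
#' metric-specific ones.
#'
#' @param community A site community tibble with a `habitat` column.
#' @return Tibble with site_id, metric, value, quality_class (plus S and T
#'   for streams).
#' @export
compute_index <- function(community) {
  hab <- unique(community$habitat)
  stopifnot(length(hab) == 1)
  if (hab == "stream") {
    compute_iobs(community) |>
      dplyr::mutate(metric = "iobs", value = .data$iobs)
  } else {
    percent_sensitive(community) |>
      dplyr::mutate(metric = "pct_sensitive", value = .data$pct_sensitive)
  }
}
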