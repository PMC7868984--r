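#' Stringent quality filtering of SV calls
#'
#' Applies the high-confidence filter used for long-read SV call sets in
#' highly duplicated plant genomes: translocations and duplications are
#' removed (they are dominated by reference mis-assembly artefacts),
#' only records the caller scored `PASS` are kept, and every retained record
#' must carry within-alignment (`AL`) read support — split-read-only events
#' are discarded as potentially complex or mis-placed. Size bounds restrict
#' the call set to the small- to mid-scale range studied (30 bp to 30 kbp by
#' default); set them to `NULL` to disable.
#'
#' The filter is a pointwise predicate: each record is kept or dropped on
#' its own fields, so the operation is idempotent and order-independent.
#'
#' @param calls SV call tibble.
#' @param drop_types Character vector of SV types to remove
#'   (default `c("TRA", "DUP")`).
#' @param require_pass Keep only `FILTER == "PASS"` records (default `TRUE`).
#' @param require_support Support class that must be present in `SUPTYPE`
#'   (default `"AL"`); `NULL` disables the check.
#' @param min_size,max_size Inclusive bounds on `svlen` in bp
#'   (defaults 30 and 30000); `NULL` disables a bound.
#' @return The retained records, in input order.
#' @export
sv_filter <- function(calls, drop_types = c("TRA", "DUP"),
                      require_pass = TRUE, require_support = "AL",
                      min_size = 30, max_size = 30000) {
  validate_sv_calls(calls)
  keep <- !calls$svtype %in% drop_types
  if (isTRUE(require_pass)) keep <- keep & calls$filter == "PASS"
  if (!is.null(require_support)) {
    keep <- keep & has_support(calls$support, require_support)
  }
  if (!is.null(min_size)) {
    keep <- keep & !is.na(calls$svlen) & calls$svlen >= min_size
  }
  if (!is.null(max_size)) {
    keep <- keep & !is.na(calls$svlen) & calls$svlen <= max_size
  }
  calls[keep, , drop = FALSE]
}

#' Size class of an SV
#'
#' Classifies SV lengths into the small (30–10 000 bp) and mid
#' (10 001–30 000 bp) scale classes; the two classes partition the studied
#' range, with 10 000 bp belonging to "small" and 30 000 bp to "mid".
#' Lengths outside 30–30 000 bp are labelled `out_of_range`.
#'
#' @param svlen Positive SV length(s) in bp.
#' @return Character vector of labels in `{small, mid, out_of_range}`.
#' @export
sv_size_class <- function(svlen) {
  if (any(is.na(svlen)) || any(svlen <= 0)) {
    abort("`svlen` must be positive")
  }
  dplyr::case_when(
    svlen >= 30 & svlen <= 10000 ~ "small",
    svlen > 10000 & svlen <= 30000 ~ "mid",
    TRUE ~ "out_of_range"
  )
}

#' Per-sample summary of a filtered SV call set
#'
#' Computes the per-genotype summary columns reported for long-read SV
#' panels: number of calls, median and maximum size, counts per size class,
#' and the fraction of calls in the 100–1000 bp range that short-read
#' methods struggle to resolve.
#'
#' @param calls SV call tibble (typically after [sv_filter()]).
#' @param by_sample Summarize per `sample_id` (default) or over the whole
#'   set as a single row with `sample_id = NA`.
#' @return A tibble with columns `sample_id`, `n_sv`, `median_size`,
#'   `max_size`, `n_small`, `n_mid`, `frac_100_1000`. Size fields are `NA`
#'   when `n_sv` is 0. The median is the standard middle-order statistic
#'   (mean of the two central values for even counts); `frac_100_1000`
#'   uses inclusive bounds.
#' @export
sv_summary <- function(calls, by_sample = TRUE) {
  validate_sv_calls(calls)
  if (!by_sample) calls$sample_id <- NA_character_
  if (nrow(calls) == 0) {
    return(tibble(
      sample_id = character(), n_sv = integer(), median_size = double(),
      max_size = integer(), n_small = integer(), n_mid = integer(),
      frac_100_1000 = double()
    ))
  }
  calls %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      n_sv = dplyr::n(),
      median_size = median(.data$svlen),
      max_size = max(.data$svlen),
      n_small = sum(sv_size_class(.data$svlen) == "small"),
      n_mid = sum(sv_size_class(.data$svlen) == "mid"),
      frac_100_1000 = mean(.data$svlen >= 100 & .data$svlen <= 1000),
      .groups = "drop"
    )
}

#' SV size implied by a PCR amplicon pair
#'
#' For a locus-specific PCR assay spanning a putative deletion or insertion,
#' the size of the event is the absolute difference between the amplicon
#' lengths of the two alleles (e.g. 900 bp vs 200 bp products imply a
#' 700 bp deletion).
#'
#' @param amplicon_ref,amplicon_alt Amplicon lengths in bp (positive).
#' @return Implied SV size(s) in bp.
#' @export
pcr_implied_size <- function(amplicon_ref, amplicon_alt) {
  if (any(amplicon_ref <= 0) || any(amplicon_alt <= 0)) {
    abort("amplicon lengths must be positive")
  }
  abs(amplicon_ref - amplicon_alt)
}
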