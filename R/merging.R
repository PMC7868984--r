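#' Merge SV call sets by breakpoint proximity
#'
#' Single-linkage clustering of SV records across samples, reproducing the
#' SURVIVOR-merge semantics used to combine long-read call sets: two records
#' are linked when they lie on the same chromosome (and share the SV type
#' when `type_aware`), their left breakpoints differ by at most `max_dist`
#' bp and their right breakpoints differ by at most `max_dist` bp. Clusters
#' are the connected components of this link relation, so every input
#' record belongs to exactly one cluster and unmatched records form
#' singleton clusters (minimum supporting caller = 1).
#'
#' @param calls SV call tibble covering one or more samples (bind rows of
#'   per-sample call sets).
#' @param max_dist Maximum breakpoint distance in bp (default 1000).
#' @param type_aware Cluster within SV type strata (default `TRUE`).
#' @return The input records with a `cluster_id` column added; cluster ids
#'   are assigned in (chrom, representative pos) order. The merge
#'   parameters are attached as attributes `max_dist` and `type_aware`.
#' @seealso [sv_clusters()], [sv_presence()], [sv_force_call()]
#' @export
sv_merge <- function(calls, max_dist = 1000, type_aware = TRUE) {
  validate_sv_calls(calls)
  if (max_dist < 0) abort("`max_dist` must be >= 0")
  if (nrow(calls) == 0) {
    out <- dplyr::mutate(calls, cluster_id = character())
    attr(out, "max_dist") <- max_dist
    attr(out, "type_aware") <- type_aware
    return(out)
  }
  stratum <- if (type_aware) {
    paste(calls$chrom, calls$svtype, sep = "\r")
  } else {
    calls$chrom
  }
  comp <- integer(nrow(calls))
  offset <- 0L
  for (idx in split(seq_len(nrow(calls)), stratum)) {
    comp[idx] <- offset + link_components(calls$pos[idx], calls$end[idx], max_dist)
    offset <- max(comp[idx])
  }
  # Order clusters by (chrom, median pos) and assign stable ids.
  reps <- tibble(comp = comp, chrom = calls$chrom, pos = calls$pos) %>%
    dplyr::group_by(.data$comp) %>%
    dplyr::summarise(
      chrom = .data$chrom[1], rep_pos = median(.data$pos), .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$rep_pos, .data$comp)
  id_map <- setNames(
    sprintf("SVC%06d", seq_len(nrow(reps))),
    as.character(reps$comp)
  )
  out <- dplyr::mutate(calls, cluster_id = unname(id_map[as.character(comp)]))
  attr(out, "max_dist") <- max_dist
  attr(out, "type_aware") <- type_aware
  out
}

# Single-linkage connected components for one (chrom [, svtype]) stratum.
# Records i, j are linked iff |pos_i - pos_j| <= d and |end_i - end_j| <= d.
# Union-find over candidate pairs found by a sorted sweep on pos (pairs
# farther than d on pos cannot link, so the sweep is exhaustive).
link_components <- function(pos, end, d) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(pos, end)
  p <- pos[ord]
  e <- end[ord]
  for (i in seq_len(n)) {
    j <- i + 1L
    while (j <= n && p[j] - p[i] <= d) {
      if (abs(e[j] - e[i]) <= d) {
        ri <- find(ord[i])
        rj <- find(ord[j])
        if (ri != rj) parent[rj] <- ri
      }
      j <- j + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Summarize merged SV records into clusters
#'
#' One row per cluster with representative coordinates (member medians,
#' rounded to integer bp), member counts and the set of samples carrying
#' the cluster.
#'
#' @param merged Output of [sv_merge()].
#' @return Tibble with columns `cluster_id`, `chrom`, `svtype`, `rep_pos`,
#'   `rep_end`, `rep_len`, `n_records`, `n_samples`, `samples` (list
#'   column), sorted by (chrom, rep_pos).
#' @export
sv_clusters <- function(merged) {
  if (!"cluster_id" %in% names(merged)) {
    abort("`merged` must come from sv_merge() (missing cluster_id)")
  }
  merged %>%
    dplyr::group_by(.data$cluster_id) %>%
    dplyr::summarise(
      chrom = .data$chrom[1],
      svtype = .data$svtype[1],
      rep_pos = as.integer(round(median(.data$pos))),
      rep_end = as.integer(round(median(.data$end))),
      rep_len = as.integer(round(median(.data$svlen))),
      n_records = dplyr::n(),
      n_samples = dplyr::n_distinct(.data$sample_id),
      samples = list(sort(unique(.data$sample_id))),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$rep_pos, .data$cluster_id)
}

#' Presence/absence of each cluster in each sample
#'
#' @param merged Output of [sv_merge()].
#' @param samples Optional character vector fixing the sample universe and
#'   order (samples with no record anywhere get all-absent rows); defaults
#'   to the samples observed in `merged`.
#' @return Long tibble `cluster_id`, `sample_id`, `present` covering the
#'   full clusters x samples grid.
#' @export
sv_presence <- function(merged, samples = NULL) {
  samples <- samples %||% sort(unique(merged$sample_id))
  clusters <- sort(unique(merged$cluster_id))
  grid <- tidyr::expand_grid(cluster_id = clusters, sample_id = samples)
  seen <- merged %>%
    dplyr::distinct(.data$cluster_id, .data$sample_id) %>%
    dplyr::mutate(present = TRUE)
  grid %>%
    dplyr::left_join(seen, by = c("cluster_id", "sample_id")) %>%
    dplyr::mutate(present = !is.na(.data$present))
}

#' Force-call merged clusters in a call set
#'
#' Geometric re-genotyping: a cluster is called present in a sample when
#' the sample's call set contains a record of the cluster's type (when
#' `type_aware`) with both breakpoints within `max_dist` of the cluster
#' representatives. Each record supports at most one cluster — the nearest
#' by `|dpos| + |dend|`, ties broken toward the leftmost cluster.
#'
#' @param clusters Cluster tibble from [sv_clusters()].
#' @param calls One sample's SV call tibble.
#' @param max_dist Maximum breakpoint distance in bp (default 1000).
#' @param type_aware Match SV types (default `TRUE`).
#' @return Tibble `cluster_id`, `present` in cluster order.
#' @export
sv_force_call <- function(clusters, calls, max_dist = 1000, type_aware = TRUE) {
  validate_sv_calls(calls)
  out <- tibble(cluster_id = clusters$cluster_id, present = FALSE)
  if (nrow(calls) == 0 || nrow(clusters) == 0) {
    return(out)
  }
  by <- if (type_aware) c("chrom", "svtype") else "chrom"
  cand <- calls %>%
    dplyr::select("sv_id", "chrom", "svtype", "pos", "end") %>%
    dplyr::inner_join(
      dplyr::select(
        clusters, "cluster_id", "chrom", "svtype", "rep_pos", "rep_end"
      ),
      by = by, suffix = c("", ".cl"), relationship = "many-to-many"
    ) %>%
    dplyr::filter(
      abs(.data$pos - .data$rep_pos) <= max_dist,
      abs(.data$end - .data$rep_end) <= max_dist
    ) %>%
    dplyr::mutate(dist = abs(.data$pos - .data$rep_pos) + abs(.data$end - .data$rep_end)) %>%
    dplyr::group_by(.data$sv_id) %>%
    dplyr::arrange(.data$dist, .data$rep_pos, .data$cluster_id, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()
  out$present <- out$cluster_id %in% cand$cluster_id
  out
}

#' Cross-platform concordance of force-called presence vectors
#'
#' Counts merged clusters genotyped as present in both of two call sets
#' (e.g. ONT and PacBio libraries of the same genotype) and reports the
#' percentage of the merged total supported by both.
#'
#' @param presence_a,presence_b Tibbles `cluster_id`, `present` over the
#'   same clusters (output of [sv_force_call()]), or plain logical vectors
#'   of equal length.
#' @return One-row tibble `n_total`, `n_both`, `pct_both` (percentage,
#'   one decimal). `pct_both` is `NA` with a warning when there are no
#'   clusters.
#' @export
sv_concordance <- function(presence_a, presence_b) {
  if (is.data.frame(presence_a)) {
    joined <- dplyr::inner_join(
      presence_a, presence_b,
      by = "cluster_id", suffix = c("_a", "_b")
    )
    if (nrow(joined) != nrow(presence_a) || nrow(joined) != nrow(presence_b)) {
      abort("presence vectors must cover the same clusters")
    }
    a <- joined$present_a
    b <- joined$present_b
  } else {
    if (length(presence_a) != length(presence_b)) {
      abort("presence vectors must have equal length")
    }
    a <- presence_a
    b <- presence_b
  }
  n_total <- length(a)
  n_both <- sum(a & b)
  if (n_total == 0) {
    warn("no clusters: concordance percentage undefined")
    pct <- NA_real_
  } else {
    pct <- round(100 * n_both / n_total, 1)
  }
  tibble(n_total = n_total, n_both = n_both, pct_both = pct)
}
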