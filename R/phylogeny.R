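#' Build the samples x clusters presence/absence matrix
#'
#' Converts long force-called presence into the binary matrix used for
#' presence/absence-variation phylogenetics. Invariant columns (all 0 or
#' all 1) are retained; [sv_matrix_values()] extracts the plain integer
#' matrix.
#'
#' @param presence Long tibble `cluster_id`, `sample_id`, `present`
#'   covering the full grid (see [sv_presence()]).
#' @param samples Optional character vector fixing row order.
#' @return A tibble of class `sv_matrix`: `sample_id` column plus one
#'   integer 0/1 column per cluster, in cluster-id order.
#' @export
build_sv_matrix <- function(presence, samples = NULL) {
  samples <- samples %||% sort(unique(presence$sample_id))
  if (anyDuplicated(samples)) abort("duplicate sample ids")
  wide <- presence %>%
    dplyr::mutate(present = as.integer(.data$present)) %>%
    tidyr::pivot_wider(
      names_from = "cluster_id", values_from = "present",
      id_cols = "sample_id"
    )
  wide <- wide[match(samples, wide$sample_id), , drop = FALSE]
  if (anyNA(wide$sample_id)) abort("`samples` not all present in `presence`")
  cluster_cols <- sort(setdiff(names(wide), "sample_id"))
  out <- wide[, c("sample_id", cluster_cols), drop = FALSE]
  class(out) <- c("sv_matrix", class(out))
  out
}

#' Extract the integer matrix from an `sv_matrix`
#'
#' @param m An `sv_matrix` tibble.
#' @return Integer matrix with sample ids as rownames.
#' @export
sv_matrix_values <- function(m) {
  vals <- as.matrix(m[, setdiff(names(m), "sample_id"), drop = FALSE])
  storage.mode(vals) <- "integer"
  rownames(vals) <- m$sample_id
  vals
}

sanitize_phylip_names <- function(x) {
  clean <- gsub("[^A-Za-z0-9_.]", "_", x)
  out <- substr(clean, 1, 10)
  # Truncated names that collide are disambiguated with a numeric suffix.
  for (nm in unique(out[duplicated(out)])) {
    idx <- which(out == nm)
    suffix <- paste0("_", seq_along(idx))
    out[idx] <- paste0(substr(clean[idx], 1, 10 - nchar(suffix)), suffix)
  }
  if (anyDuplicated(out)) {
    dups <- unique(out[duplicated(out)])
    abort(sprintf(
      "sample names collide after truncation to 10 characters: %s",
      paste(dups, collapse = ", ")
    ))
  }
  out
}

#' Export a presence/absence matrix to relaxed PHYLIP
#'
#' Writes the relaxed sequential PHYLIP format consumed by phylogeny
#' programs: a header line `n_samples n_sites`, then one line per sample
#' with the (sanitized, <= 10 character) name and its 0/1 character string.
#'
#' @param m An `sv_matrix` tibble from [build_sv_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(m, path) {
  vals <- sv_matrix_values(m)
  names_out <- sanitize_phylip_names(rownames(vals))
  lines <- c(
    sprintf("%d %d", nrow(vals), ncol(vals)),
    paste(
      formatC(names_out, width = 10, flag = "-"),
      apply(vals, 1, paste, collapse = "")
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a relaxed sequential PHYLIP binary matrix
#'
#' Inverse of [write_phylip()] up to column names (site columns are
#' relabelled `site_1 ... site_n`).
#'
#' @param path Path to a PHYLIP file.
#' @return An `sv_matrix` tibble.
#' @export
read_phylip <- function(path) {
  lines <- readr::read_lines(path)
  dims <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) != dims[1]) abort("PHYLIP header does not match body")
  parts <- strsplit(trimws(body), "\\s+")
  samples <- vapply(parts, `[[`, character(1), 1)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), character(1))
  if (any(nchar(seqs) != dims[2])) abort("PHYLIP sequence length mismatch")
  vals <- do.call(rbind, lapply(strsplit(seqs, ""), as.integer))
  colnames(vals) <- sprintf("site_%d", seq_len(dims[2]))
  out <- dplyr::bind_cols(tibble(sample_id = samples), as_tibble(vals))
  class(out) <- c("sv_matrix", class(out))
  out
}

#' Hamming distances between samples
#'
#' Pairwise proportion of presence/absence sites at which two samples
#' differ.
#'
#' @param m An `sv_matrix` tibble.
#' @return A `dist` object over samples.
#' @export
sv_distance <- function(m) {
  vals <- sv_matrix_values(m)
  if (ncol(vals) == 0) abort("matrix has no sites")
  dist(vals, method = "manhattan") / ncol(vals)
}

#' Neighbor-joining tree from SV distances
#'
#' Builds an unrooted NJ tree over the samples. For fewer than three
#' samples a trivial tree is returned with a warning.
#'
#' @param d A `dist` object (e.g. from [sv_distance()]).
#' @return An `ape::phylo` tree.
#' @export
sv_nj_tree <- function(d) {
  labels <- attr(d, "Labels")
  n <- attr(d, "Size")
  if (n < 3) {
    warn("fewer than 3 samples: returning trivial tree")
    txt <- if (n == 2) {
      sprintf("(%s:%f,%s:%f);", labels[1], as.numeric(d) / 2, labels[2], as.numeric(d) / 2)
    } else {
      sprintf("(%s);", labels[1])
    }
    return(ape::read.tree(text = txt))
  }
  ape::nj(d)
}

#' Midpoint-root a tree
#'
#' NJ trees are unrooted; rooting at the midpoint of the longest
#' tip-to-tip path gives a declared, deterministic rooting for monophyly
#' checks.
#'
#' @param tree An `ape::phylo` tree.
#' @return A rooted `ape::phylo` tree.
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree)
}

#' Are planted groups monophyletic?
#'
#' Checks, on a rooted tree, whether each group's samples form a clade.
#'
#' @param tree A rooted `ape::phylo` tree (see [midpoint_root()]).
#' @param groups Tibble `sample_id`, `group`.
#' @return Tibble `group`, `monophyletic`.
#' @export
groups_monophyletic <- function(tree, groups) {
  groups %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(
      monophyletic = ape::is.monophyletic(tree, .data$sample_id),
      .groups = "drop"
    )
}
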