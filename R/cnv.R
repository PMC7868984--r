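#' Read a bedGraph coverage track
#'
#' Reads per-base (or run-length encoded) read-depth from bedGraph text
#' (0-based half-open intervals, columns chrom/start/end/depth; optional
#' `track` header lines are skipped) into a 1-based inclusive run tibble.
#'
#' @param path Path to a bedGraph file.
#' @return Tibble `chrom`, `start`, `end`, `depth` with 1-based inclusive
#'   coordinates, sorted by (chrom, start).
#' @export
read_depth_track <- function(path) {
  lines_head <- readr::read_lines(path, n_max = 5)
  skip <- sum(grepl("^(track|browser|#)", lines_head))
  df <- readr::read_tsv(
    path,
    skip = skip, col_names = c("chrom", "start", "end", "depth"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), depth = readr::col_double()
    ),
    progress = FALSE
  )
  df %>%
    dplyr::mutate(start = .data$start + 1) %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Write a depth track as bedGraph
#'
#' @param track Depth tibble (`chrom`, `start`, `end`, `depth`; 1-based
#'   inclusive, as returned by [read_depth_track()] or
#'   [simulate_coverage()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- track %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::transmute(
      .data$chrom,
      start = format(.data$start - 1, scientific = FALSE, trim = TRUE),
      end = format(.data$end, scientific = FALSE, trim = TRUE),
      .data$depth
    )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Median read depth in fixed blocks
#'
#' Tiles each chromosome with non-overlapping blocks of `width` bp from
#' position 1 (final partial block uses its actual width) and computes the
#' per-block median of per-base depth — the block statistic underlying
#' read-depth CNV detection from long-read alignments.
#'
#' @param track Depth tibble (`chrom`, `start`, `end`, `depth`); runs must
#'   tile each chromosome without gaps or overlaps.
#' @param width Block width in bp (default 1000).
#' @return Tibble `chrom`, `block`, `start`, `end`, `median_depth`.
#' @export
block_medians <- function(track, width = 1000) {
  if (nrow(track) == 0) abort("empty depth track")
  track %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$start)
      widths <- df$end - df$start + 1
      if (any(widths < 1) || df$start[1] != 1 ||
        any(df$start[-1] != df$end[-nrow(df)] + 1)) {
        abort(sprintf(
          "depth track does not tile chromosome %s contiguously", key$chrom
        ))
      }
      depth <- rep(df$depth, times = widths)
      len <- length(depth)
      n_full <- len %/% width
      meds <- numeric(0)
      if (n_full > 0) {
        m <- matrix(depth[seq_len(n_full * width)], nrow = width)
        meds <- apply(m, 2, median)
      }
      if (len %% width > 0) {
        meds <- c(meds, median(depth[(n_full * width + 1):len]))
      }
      n_blocks <- length(meds)
      tibble(
        block = seq_len(n_blocks),
        start = as.integer((seq_len(n_blocks) - 1) * width + 1),
        end = as.integer(pmin(seq_len(n_blocks) * width, len)),
        median_depth = meds
      )
    }) %>%
    dplyr::ungroup()
}

#' Per-chromosome depth statistics
#'
#' Median and population standard deviation of the block medians of each
#' chromosome — the per-chromosome baseline against which duplicated
#' segments are called.
#'
#' @param blocks Block tibble from [block_medians()].
#' @return Tibble `chrom`, `n_blocks`, `median_depth`, `sd_depth`
#'   (population SD).
#' @export
chromosome_stats <- function(blocks) {
  counts <- dplyr::count(blocks, .data$chrom)
  if (any(counts$n < 2)) {
    abort(sprintf(
      "need >= 2 blocks per chromosome (offending: %s)",
      paste(counts$chrom[counts$n < 2], collapse = ", ")
    ))
  }
  blocks %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(
      n_blocks = dplyr::n(),
      sd_depth = sqrt(mean((.data$median_depth - mean(.data$median_depth))^2)),
      median_depth = median(.data$median_depth),
      .groups = "drop"
    ) %>%
    dplyr::relocate("sd_depth", .after = "median_depth")
}

#' Call duplicated segments from block medians
#'
#' Flags blocks whose median depth exceeds the chromosome median plus `k`
#' chromosome standard deviations and merges maximal runs of adjacent
#' flagged blocks into segments. With `sd_depth = 0` the threshold
#' degenerates to strictly above the median. Setting
#' `call = "deletion"` flags blocks below median minus `k` SD instead
#' (off the default path; read-depth loss calling is not symmetric in
#' noisy data and is provided for exploration only).
#'
#' @param blocks Block tibble from [block_medians()].
#' @param stats Per-chromosome stats from [chromosome_stats()]; computed
#'   from `blocks` when `NULL`.
#' @param k Threshold multiplier on the chromosome SD (default 1).
#' @param call `"duplication"` (default) or `"deletion"`.
#' @return Tibble `chrom`, `start`, `end`, `n_blocks`, `mean_block_depth`,
#'   `call`.
#' @export
call_duplications <- function(blocks, stats = NULL, k = 1,
                              call = c("duplication", "deletion")) {
  call <- match.arg(call)
  stats <- stats %||% chromosome_stats(blocks)
  df <- dplyr::left_join(
    blocks, dplyr::select(stats, "chrom", chrom_median = "median_depth",
      chrom_sd = "sd_depth"),
    by = "chrom"
  )
  flagged <- if (call == "duplication") {
    df$median_depth > df$chrom_median + k * df$chrom_sd
  } else {
    df$median_depth < df$chrom_median - k * df$chrom_sd
  }
  df$flagged <- flagged
  df %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$block)
      r <- rle(d$flagged)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- which(r$values)
      if (length(keep) == 0) {
        return(tibble(
          start = integer(), end = integer(), n_blocks = integer(),
          mean_block_depth = double()
        ))
      }
      tibble(
        start = d$start[starts[keep]],
        end = d$end[ends[keep]],
        n_blocks = r$lengths[keep],
        mean_block_depth = vapply(
          keep,
          function(i) mean(d$median_depth[starts[i]:ends[i]]),
          numeric(1)
        )
      )
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(call = call)
}

#' Detect whole-chromosome loss from depth
#'
#' Flags chromosomes whose median block depth falls below `loss_fraction`
#' of the genome-wide median block depth — the read-depth signature of a
#' chromosome deleted and replaced by its homoeologue in an allopolyploid.
#'
#' @param blocks Block tibble from [block_medians()] covering >= 2
#'   chromosomes.
#' @param loss_fraction Fraction of the genome median below which a
#'   chromosome is called lost (default 0.1).
#' @return Tibble `chrom`, `median_depth`, `genome_median`, `lost`.
#' @export
detect_chromosome_loss <- function(blocks, loss_fraction = 0.1) {
  if (dplyr::n_distinct(blocks$chrom) < 2) {
    abort("need blocks from >= 2 chromosomes")
  }
  genome_median <- median(blocks$median_depth)
  blocks %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::summarise(median_depth = median(.data$median_depth), .groups = "drop") %>%
    dplyr::mutate(
      genome_median = genome_median,
      lost = .data$median_depth < loss_fraction * genome_median
    )
}
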