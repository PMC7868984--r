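PIPELINE_KEYS <- c(
  "version", "seed", "output_dir", "samples", "gff", "chrom_sizes",
  "filter", "merge", "window_size", "promoter_flank", "cnv"
)
SAMPLE_KEYS <- c("id", "vcf", "group", "platform", "depth")
FILTER_KEYS <- c("drop_types", "min_size", "max_size")
MERGE_KEYS <- c("max_dist", "type_aware")
CNV_KEYS <- c("block_width", "k", "loss_fraction")

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown %s key(s): %s", where, paste(unknown, collapse = ", ")
    ))
  }
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with a versioned schema; unknown keys are errors
#' (silent misconfiguration being the main failure mode of batch
#' pipelines). Relative paths are resolved against the config file's
#' directory.
#'
#' @param path Path to a YAML config.
#' @return A validated config list of class `polysv_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | p == "" | grepl("^/", p), p, file.path(base, p))
  }
  check_keys(cfg, PIPELINE_KEYS, "config")
  if (is.null(cfg$samples) || length(cfg$samples) == 0) {
    abort("config error: empty sample table")
  }
  for (s in cfg$samples) check_keys(s, SAMPLE_KEYS, "sample")
  check_keys(cfg$filter %||% list(), FILTER_KEYS, "filter")
  check_keys(cfg$merge %||% list(), MERGE_KEYS, "merge")
  check_keys(cfg$cnv %||% list(), CNV_KEYS, "cnv")
  samples <- purrr::map_dfr(cfg$samples, function(s) {
    tibble(
      sample_id = s$id, vcf = resolve(s$vcf),
      group = s$group %||% "all", platform = s$platform %||% NA_character_,
      depth = resolve(s$depth %||% NA_character_)
    )
  })
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample ids in config")
  for (f in c(samples$vcf, stats::na.omit(samples$depth))) {
    if (!file.exists(f)) abort(sprintf("config error: file not found: %s", f))
  }
  for (f in c(cfg$gff, cfg$chrom_sizes)) {
    if (!is.null(f) && !file.exists(resolve(f))) {
      abort(sprintf("config error: file not found: %s", f))
    }
  }
  structure(
    list(
      version = cfg$version %||% 1,
      seed = cfg$seed %||% 1L,
      output_dir = resolve(cfg$output_dir %||% "polysv_out"),
      samples = samples,
      gff = if (is.null(cfg$gff)) NULL else resolve(cfg$gff),
      chrom_sizes = resolve(cfg$chrom_sizes),
      filter = utils::modifyList(
        list(drop_types = c("TRA", "DUP"), min_size = 30, max_size = 30000),
        cfg$filter %||% list()
      ),
      merge = utils::modifyList(
        list(max_dist = 1000, type_aware = TRUE),
        cfg$merge %||% list()
      ),
      window_size = cfg$window_size %||% 1e6,
      promoter_flank = cfg$promoter_flank %||% 2000,
      cnv = utils::modifyList(
        list(block_width = 1000, k = 1, loss_fraction = 0.1),
        cfg$cnv %||% list()
      )
    ),
    class = "polysv_config"
  )
}

stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full SV analysis pipeline
#'
#' Orchestrates filter, merge, annotation, window counts, subgenome
#' statistics, group Venn regions, presence/absence phylogeny and
#' (when depth tracks are configured) CNV and chromosome-loss detection,
#' writing every intermediate to `output_dir` so each stage is auditable.
#' Re-running with identical config and inputs is bit-identical.
#'
#' Outputs: `filtered/<id>.vcf`, `merged.vcf`, `summary.tsv` (per-sample
#' call counts and sizes), `per_chromosome_counts.tsv`,
#' `window_counts.tsv`, `subgenome_rates.tsv`, `venn_regions.tsv`,
#' `intragenic.tsv`, `matrix.phylip`, `tree.nwk`,
#' `cnv/<id>_segments.tsv`, `chromosome_loss.tsv` and `run_log.txt`.
#'
#' @param config Path to a YAML config or a `polysv_config` list.
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "filtered"), showWarnings = FALSE)
  layout <- read_chrom_sizes(config$chrom_sizes)
  genes <- if (!is.null(config$gff)) read_gene_models(config$gff) else NULL

  stage(quiet, "reading and filtering %d call sets", nrow(config$samples))
  filtered <- purrr::map(
    seq_len(nrow(config$samples)),
    function(i) {
      s <- config$samples[i, ]
      calls <- tryCatch(
        read_sniffles_vcf(s$vcf, s$sample_id),
        error = function(e) {
          abort(sprintf(
            "stage vcf_io failed for sample %s: %s", s$sample_id,
            conditionMessage(e)
          ))
        }
      )
      f <- sv_filter(
        calls,
        drop_types = config$filter$drop_types,
        min_size = config$filter$min_size,
        max_size = config$filter$max_size
      )
      write_sv_vcf(f, file.path(out, "filtered", paste0(s$sample_id, ".vcf")))
      f
    }
  )
  all_filtered <- dplyr::bind_rows(filtered)

  stage(quiet, "merging %d filtered records", nrow(all_filtered))
  merged <- sv_merge(
    all_filtered,
    max_dist = config$merge$max_dist,
    type_aware = config$merge$type_aware
  )
  clusters <- sv_clusters(merged)
  presence <- purrr::map_dfr(config$samples$sample_id, function(s) {
    sv_force_call(
      clusters, dplyr::filter(all_filtered, .data$sample_id == s),
      max_dist = config$merge$max_dist,
      type_aware = config$merge$type_aware
    ) %>%
      dplyr::mutate(sample_id = s)
  })
  write_multisample_vcf(
    clusters, presence, file.path(out, "merged.vcf"),
    samples = config$samples$sample_id
  )

  stage(quiet, "summaries and window counts")
  summary_tbl <- sv_summary(all_filtered) %>%
    dplyr::left_join(
      config$samples[, c("sample_id", "group", "platform")],
      by = "sample_id"
    ) %>%
    dplyr::relocate("sample_id", "group", "platform")
  per_chrom <- all_filtered %>%
    dplyr::count(.data$sample_id, .data$chrom) %>%
    tidyr::pivot_wider(
      names_from = "chrom", values_from = "n", values_fill = 0L
    )
  wc <- sv_window_counts(all_filtered, layout, window = config$window_size)
  rates <- subgenome_rates(all_filtered, layout)
  readr::write_tsv(summary_tbl, file.path(out, "summary.tsv"), progress = FALSE)
  readr::write_tsv(per_chrom, file.path(out, "per_chromosome_counts.tsv"),
    progress = FALSE
  )
  readr::write_tsv(wc, file.path(out, "window_counts.tsv"), progress = FALSE)
  readr::write_tsv(glance(rates), file.path(out, "subgenome_rates.tsv"),
    progress = FALSE
  )
  readr::write_tsv(tidy(rates), file.path(out, "subgenome_rates_per_chrom.tsv"),
    progress = FALSE
  )

  hits <- NULL
  venn <- NULL
  intragenic <- NULL
  if (!is.null(genes)) {
    stage(quiet, "annotating against %d gene models", nrow(genes))
    hits <- annotate_sv(all_filtered, genes,
      promoter_flank = config$promoter_flank
    )
    intragenic <- count_intragenic(hits, genes, by_sample = TRUE)
    readr::write_tsv(intragenic, file.path(out, "intragenic.tsv"),
      progress = FALSE
    )
    summary_tbl <- summary_tbl %>%
      dplyr::left_join(
        hits %>%
          dplyr::filter(.data$location %in% c("exonic", "intronic")) %>%
          dplyr::group_by(.data$sample_id) %>%
          dplyr::summarise(
            n_intragenic = dplyr::n_distinct(.data$sv_id),
            .groups = "drop"
          ),
        by = "sample_id"
      ) %>%
      dplyr::mutate(n_intragenic = tidyr::replace_na(.data$n_intragenic, 0L))
    readr::write_tsv(summary_tbl, file.path(out, "summary.tsv"),
      progress = FALSE
    )
    groups <- config$samples[, c("sample_id", "group")]
    if (dplyr::n_distinct(groups$group) >= 2 &&
      dplyr::n_distinct(groups$group) <= 4) {
      venn <- venn_regions(group_gene_sets(hits, groups))
      readr::write_tsv(venn, file.path(out, "venn_regions.tsv"),
        progress = FALSE
      )
    }
  }

  tree <- NULL
  mat <- NULL
  if (nrow(config$samples) >= 3 && nrow(clusters) > 0) {
    stage(quiet, "presence/absence matrix and NJ tree")
    mat <- build_sv_matrix(presence, samples = config$samples$sample_id)
    write_phylip(mat, file.path(out, "matrix.phylip"))
    tree <- sv_nj_tree(sv_distance(mat))
    ape::write.tree(tree, file.path(out, "tree.nwk"))
  }

  cnv_segments <- NULL
  loss <- NULL
  with_depth <- config$samples[!is.na(config$samples$depth), ]
  if (nrow(with_depth) > 0) {
    dir.create(file.path(out, "cnv"), showWarnings = FALSE)
    stage(quiet, "CNV calling for %d depth track(s)", nrow(with_depth))
    cnv_res <- purrr::map(seq_len(nrow(with_depth)), function(i) {
      s <- with_depth[i, ]
      track <- read_depth_track(s$depth)
      blocks <- block_medians(track, width = config$cnv$block_width)
      segs <- call_duplications(blocks, k = config$cnv$k) %>%
        dplyr::mutate(sample_id = s$sample_id, .before = 1)
      readr::write_tsv(
        segs, file.path(out, "cnv", paste0(s$sample_id, "_segments.tsv")),
        progress = FALSE
      )
      lost <- detect_chromosome_loss(
        blocks,
        loss_fraction = config$cnv$loss_fraction
      ) %>%
        dplyr::mutate(sample_id = s$sample_id, .before = 1)
      list(segments = segs, loss = lost)
    })
    cnv_segments <- dplyr::bind_rows(purrr::map(cnv_res, "segments"))
    loss <- dplyr::bind_rows(purrr::map(cnv_res, "loss"))
    readr::write_tsv(loss, file.path(out, "chromosome_loss.tsv"),
      progress = FALSE
    )
  }

  log_lines <- c(
    sprintf("polysv %s", as.character(utils::packageVersion("polysv"))),
    sprintf("seed: %s", config$seed),
    sprintf("samples: %s", paste(config$samples$sample_id, collapse = ", ")),
    sprintf(
      "filter: drop=%s size=[%s, %s]",
      paste(config$filter$drop_types, collapse = ","),
      config$filter$min_size, config$filter$max_size
    ),
    sprintf(
      "merge: max_dist=%s type_aware=%s",
      config$merge$max_dist, config$merge$type_aware
    ),
    sprintf("window_size: %s", config$window_size),
    sprintf("promoter_flank: %s", config$promoter_flank),
    sprintf(
      "cnv: block_width=%s k=%s loss_fraction=%s",
      config$cnv$block_width, config$cnv$k, config$cnv$loss_fraction
    )
  )
  readr::write_lines(log_lines, file.path(out, "run_log.txt"))
  stage(quiet, "pipeline complete: %s", out)
  invisible(list(
    summary = summary_tbl, clusters = clusters, presence = presence,
    window_counts = wc, subgenome = rates, hits = hits, venn = venn,
    intragenic = intragenic, matrix = mat, tree = tree,
    cnv_segments = cnv_segments, chromosome_loss = loss
  ))
}
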