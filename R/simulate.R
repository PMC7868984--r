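#' Genome layout table
#'
#' @param chrom Chromosome names.
#' @param length Chromosome lengths in bp.
#' @param subgenome Optional subgenome labels; inferred from the name
#'   prefix (`A01`–`A10` -> `A`, `C01`–`C09` -> `C`) when `NULL`.
#' @return Tibble `chrom`, `length`, `subgenome`.
#' @export
genome_layout <- function(chrom, length, subgenome = NULL) {
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(length <= 0)) abort("chromosome lengths must be positive")
  tibble(
    chrom = chrom, length = as.integer(length),
    subgenome = subgenome %||% infer_subgenome(chrom)
  )
}

#' Default 4-chromosome desk-scale layout
#'
#' Two A-subgenome and two C-subgenome chromosomes totalling 36 Mbp — a
#' scaled-down allotetraploid genome for simulation and testing.
#'
#' @return Tibble `chrom`, `length`, `subgenome`.
#' @export
default_layout <- function() {
  genome_layout(
    chrom = c("A01", "A02", "C01", "C02"),
    length = c(1e7, 8e6, 1e7, 8e6)
  )
}

#' Simulation parameters for a synthetic SV panel
#'
#' Bundles every knob of the truth-tracked generator. The defaults emulate
#' the structure of an ecotype-stratified long-read SV panel at desk scale:
#' 3 ecotype groups of 4 samples each, group-shared plus private SVs with a
#' ~300 bp median size over the 30 bp – 30 kbp range, a 1.3-fold
#' A-subgenome rate excess, decoy records that the quality filter should
#' remove (UNRESOLVED, split-read-only, translocations, duplications),
#' cross-platform breakpoint jitter, and 30x coverage with SD-2 noise.
#'
#' @param seed Master seed (mandatory; stage seeds are derived from it by
#'   fixed offsets so individual stages are reproducible).
#' @param layout Genome layout tibble (default [default_layout()]).
#' @param groups Character vector of group names.
#' @param samples_per_group Samples per group (default 4).
#' @param n_shared_per_group Group-shared SV loci per group (default 150).
#' @param n_private_per_sample Private SV loci per sample (default 50).
#' @param frac_intragenic Fraction of real loci planted inside genes
#'   (default 0.3).
#' @param size_range Inclusive SV size range in bp (default 30–30000).
#' @param size_median Target median SV size in bp (default 300). Sizes are
#'   drawn from a two-piece log-uniform (half the mass on each side of the
#'   median) so the configured median is exact in distribution.
#' @param type_mix Named proportions over DEL/INS/INV.
#' @param decoy_rates Named fractions (of each sample's real call count)
#'   of `unresolved`, `sr_only`, `tra` and `dup` decoy records.
#' @param platform_jitter_sd SD in bp of the normal breakpoint
#'   perturbation applied to each sample's realized records (default 30).
#' @param a_bias Multiplier on the per-Mbp SV rate of A-subgenome
#'   chromosomes relative to C (default 1.3).
#' @param gene_density Genes per Mbp (default 30).
#' @param exons_per_gene Exons per simulated gene (default 4).
#' @param gene_length_range Gene span range in bp.
#' @param coverage_mean,coverage_noise_sd Coverage model (default 30x,
#'   SD 2).
#' @param min_spacing Minimum gap in bp enforced between planted SV spans.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 42,
                       layout = default_layout(),
                       groups = c("winter", "semi_winter", "spring"),
                       samples_per_group = 4,
                       n_shared_per_group = 150,
                       n_private_per_sample = 50,
                       frac_intragenic = 0.3,
                       size_range = c(30, 30000),
                       size_median = 300,
                       type_mix = c(DEL = 0.45, INS = 0.45, INV = 0.10),
                       decoy_rates = c(
                         unresolved = 0.08, sr_only = 0.08,
                         tra = 0.04, dup = 0.04
                       ),
                       platform_jitter_sd = 30,
                       a_bias = 1.3,
                       gene_density = 30,
                       exons_per_gene = 4,
                       gene_length_range = c(1500, 4000),
                       coverage_mean = 30,
                       coverage_noise_sd = 2,
                       min_spacing = 100) {
  if (is.null(seed) || is.na(seed)) abort("`seed` is mandatory")
  fracs <- c(frac_intragenic, decoy_rates)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (size_range[1] < 1 || size_range[2] <= size_range[1]) {
    abort("invalid `size_range`")
  }
  if (size_median <= size_range[1] || size_median >= size_range[2]) {
    abort("`size_median` must lie strictly inside `size_range`")
  }
  if (abs(sum(type_mix) - 1) > 1e-6) abort("`type_mix` must sum to 1")
  structure(
    list(
      seed = as.integer(seed), layout = layout, groups = groups,
      samples_per_group = samples_per_group,
      n_shared_per_group = n_shared_per_group,
      n_private_per_sample = n_private_per_sample,
      frac_intragenic = frac_intragenic,
      size_range = size_range, size_median = size_median,
      type_mix = type_mix, decoy_rates = decoy_rates,
      platform_jitter_sd = platform_jitter_sd, a_bias = a_bias,
      gene_density = gene_density, exons_per_gene = exons_per_gene,
      gene_length_range = gene_length_range,
      coverage_mean = coverage_mean,
      coverage_noise_sd = coverage_noise_sd,
      min_spacing = min_spacing
    ),
    class = "sim_params"
  )
}

#' Sample sheet implied by simulation parameters
#'
#' @param params A `sim_params` object.
#' @return Tibble `sample_id`, `group`, `platform` (platforms alternate
#'   ONT/PacBio within each group).
#' @export
sample_sheet <- function(params) {
  tidyr::expand_grid(
    group = params$groups, idx = seq_len(params$samples_per_group)
  ) %>%
    dplyr::mutate(
      sample_id = paste0(.data$group, "_", .data$idx),
      platform = ifelse(.data$idx %% 2 == 1, "ONT", "PacBio")
    ) %>%
    dplyr::select("sample_id", "group", "platform")
}

# Two-piece log-uniform size draw: half the mass log-uniform on
# [lo, med], half on [med, hi]. Drawn by stratified inverse CDF (one
# draw per probability stratum, in random order) so the configured
# median holds tightly in every realization, not just in expectation.
rsv_sizes <- function(n, size_range, size_median) {
  lo <- log(size_range[1])
  hi <- log(size_range[2])
  md <- log(size_median)
  u <- (sample.int(n) - runif(n)) / n
  x <- exp(ifelse(
    u < 0.5,
    lo + (u / 0.5) * (md - lo),
    md + ((u - 0.5) / 0.5) * (hi - md)
  ))
  pmin(pmax(as.integer(round(x)), size_range[1]), size_range[2])
}

# Draw categories with exact marginal counts (largest-remainder
# apportionment), in random order.
rcategories <- function(n, probs) {
  counts <- floor(n * probs)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * probs - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  sample(rep(names(probs), times = counts))
}

#' Simulate gene models
#'
#' Places non-overlapping genes at the configured density, with
#' `exons_per_gene` exons per gene (exons and introns alternate as an
#' equal partition of the gene span) and alternating strand. Gene ids are
#' stable under the seed.
#'
#' @param params A `sim_params` object.
#' @return Nested gene tibble (same shape as [read_gene_models()]).
#' @export
simulate_genes <- function(params) {
  set.seed(params$seed + 1L)
  k <- params$exons_per_gene
  purrr::pmap_dfr(
    params$layout[, c("chrom", "length")],
    function(chrom, length) {
      n <- round(params$gene_density * length / 1e6)
      if (n < 1) abort(sprintf("gene density too low for chromosome %s", chrom))
      slot <- length %/% n
      glen <- pmin(
        sample(
          seq(params$gene_length_range[1], params$gene_length_range[2]),
          n,
          replace = TRUE
        ),
        slot - 200L
      )
      offset <- vapply(
        slot - glen - 100L,
        function(m) sample.int(max(m, 1L), 1L), integer(1)
      )
      start <- as.integer((seq_len(n) - 1) * slot + offset)
      tibble(
        gene_id = sprintf("%sg%04d", chrom, seq_len(n)),
        chrom = chrom,
        start = start,
        end = as.integer(start + glen - 1L),
        strand = ifelse(seq_len(n) %% 2 == 1, "+", "-")
      )
    }
  ) %>%
    dplyr::mutate(exons = purrr::map2(.data$start, .data$end, function(s, e) {
      n_seg <- 2L * k - 1L
      bounds <- floor(seq(s, e + 1, length.out = n_seg + 1))
      odd <- seq(1, n_seg, by = 2)
      tibble(
        start = as.integer(bounds[odd]),
        end = as.integer(bounds[odd + 1] - 1L)
      )
    }))
}

#' Write gene models to GFF3
#'
#' @param genes Nested gene tibble ([simulate_genes()] /
#'   [read_gene_models()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  gene_lines <- sprintf(
    "%s\tpolysv\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
    genes$chrom, genes$start, genes$end, genes$strand, genes$gene_id
  )
  exon_lines <- genes %>%
    dplyr::select("gene_id", "chrom", "strand", "exons") %>%
    tidyr::unnest("exons") %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(exon_n = dplyr::row_number()) %>%
    dplyr::ungroup()
  exon_lines <- sprintf(
    "%s\tpolysv\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
    exon_lines$chrom, exon_lines$start, exon_lines$end, exon_lines$strand,
    exon_lines$gene_id, exon_lines$exon_n, exon_lines$gene_id
  )
  readr::write_lines(c("##gff-version 3", gene_lines, exon_lines), path)
  invisible(path)
}

# Draw (chrom, pos) for loci, retrying until spans are non-overlapping
# with at least min_spacing between them. Loci with a target gene are
# constrained to start inside that gene.
place_loci <- function(loci, params, genes) {
  layout <- params$layout
  w <- layout$length * ifelse(layout$subgenome == "A", params$a_bias, 1)
  w <- w / sum(w)
  n <- nrow(loci)
  loci$chrom <- sample(layout$chrom, n, replace = TRUE, prob = w)
  # Intragenic loci: assign target genes without replacement so no gene
  # hosts two planted loci.
  free_genes <- genes$gene_id
  pick_gene <- function(ch) {
    pool <- intersect(free_genes, genes$gene_id[genes$chrom == ch])
    if (length(pool) == 0) {
      return(NA_character_)
    }
    g <- if (length(pool) == 1) pool else sample(pool, 1)
    free_genes <<- setdiff(free_genes, g)
    g
  }
  if (any(loci$intragenic)) {
    idx <- which(loci$intragenic)
    loci$target_gene[idx] <- vapply(loci$chrom[idx], pick_gene, character(1))
    loci$intragenic[idx] <- !is.na(loci$target_gene[idx])
  }
  draw_pos <- function(i) {
    if (loci$intragenic[i]) {
      g <- genes[genes$gene_id == loci$target_gene[i], ]
      as.integer(g$start + sample.int(max(g$end - g$start, 1L), 1L) - 1L)
    } else {
      len <- layout$length[layout$chrom == loci$chrom[i]]
      hi <- max(len - loci$svlen[i] - params$min_spacing, 1L)
      sample.int(hi, 1L)
    }
  }
  loci$pos <- vapply(seq_len(n), draw_pos, integer(1))
  for (iter in seq_len(200)) {
    span_end <- loci$pos + loci$svlen
    bad <- logical(n)
    for (ch in unique(loci$chrom)) {
      idx <- which(loci$chrom == ch)
      ord <- idx[order(loci$pos[idx])]
      gap_bad <- loci$pos[ord][-1] <= span_end[ord][-length(ord)] + params$min_spacing
      bad[ord[-1][gap_bad]] <- TRUE
    }
    if (!any(bad)) {
      return(loci)
    }
    for (i in which(bad)) {
      # After repeated failures an intragenic locus re-picks its gene:
      # neighbouring planted loci can make the original gene unplaceable.
      if (iter > 5 && loci$intragenic[i]) {
        g <- pick_gene(loci$chrom[i])
        if (!is.na(g)) {
          loci$target_gene[i] <- g
        } else {
          loci$intragenic[i] <- FALSE
          loci$target_gene[i] <- NA_character_
        }
      }
      loci$pos[i] <- draw_pos(i)
    }
  }
  abort("could not place all SV loci without overlap; reduce counts or sizes")
}

#' Simulate a truth-tracked multi-sample SV panel
#'
#' Generates per-sample Sniffles-dialect call sets with the statistical
#' structure the downstream analysis assumes: each sample's calls are its
#' ecotype group's shared SVs plus its own private SVs plus decoy records
#' (UNRESOLVED, split-read-only, translocation and duplication calls that
#' the quality filter should remove). Breakpoints of realized records are
#' jittered by a rounded normal perturbation; A-subgenome chromosomes
#' receive proportionally more loci by the configured bias factor; a
#' configurable fraction of real loci is planted inside simulated genes.
#' Everything is deterministic under (`seed`, params).
#'
#' @param params A `sim_params` object.
#' @param genes Optional pre-computed gene tibble; defaults to
#'   [simulate_genes()] under the same seed.
#' @return A list of class `sv_panel` with elements `calls` (all samples'
#'   SV call tibble), `truth` (realized records with `locus_id`, `role`,
#'   `owner`, `target_gene` bookkeeping), `genes`, `samples`
#'   (sample sheet), `layout` and `params`.
#' @export
simulate_panel <- function(params, genes = NULL) {
  genes <- genes %||% simulate_genes(params)
  samples <- sample_sheet(params)
  set.seed(params$seed + 2L)

  n_groups <- length(params$groups)
  n_samples <- nrow(samples)
  g <- params$n_shared_per_group
  p <- params$n_private_per_sample
  n_real_per_sample <- g + p
  decoy_counts <- vapply(
    params$decoy_rates, function(r) as.integer(round(r * n_real_per_sample)),
    integer(1)
  )

  roles <- c(
    rep("shared", n_groups * g),
    rep("private", n_samples * p),
    rep(paste0("decoy_", names(decoy_counts)),
      times = decoy_counts * n_samples
    )
  )
  owner <- c(
    rep(params$groups, each = g),
    rep(samples$sample_id, each = p),
    unlist(lapply(names(decoy_counts), function(d) {
      rep(samples$sample_id, each = decoy_counts[[d]])
    }))
  )
  n_loci <- length(roles)
  loci <- tibble(
    locus_id = sprintf("L%06d", seq_len(n_loci)),
    role = roles, owner = owner
  )
  # Types and sizes are drawn with exact marginals within each role class
  # (shared / private / decoy) so the configured type mix and size median
  # hold in every realization regardless of how often each class is
  # replicated across samples.
  loci$svtype <- NA_character_
  loci$svlen <- NA_integer_
  for (cls in unique(loci$role)) {
    idx <- which(loci$role == cls)
    loci$svtype[idx] <- rcategories(length(idx), params$type_mix)
    loci$svlen[idx] <- rsv_sizes(
      length(idx), params$size_range, params$size_median
    )
  }
  loci$svtype[loci$role == "decoy_tra"] <- "TRA"
  loci$svtype[loci$role == "decoy_dup"] <- "DUP"
  real <- loci$role %in% c("shared", "private")
  loci$intragenic <- real & runif(n_loci) < params$frac_intragenic
  loci$target_gene <- NA_character_
  loci <- place_loci(loci, params, genes)
  point <- loci$svtype %in% c("INS", "TRA")
  loci$end <- as.integer(ifelse(point, loci$pos, loci$pos + loci$svlen))
  # Evidence fields are locus-level draws so that samples sharing a locus
  # report it identically (platform jitter is the only per-sample noise).
  loci$filter <- ifelse(loci$role == "decoy_unresolved", "UNRESOLVED", "PASS")
  loci$support <- ifelse(runif(n_loci) < 0.3, "AL,SR", "AL")
  loci$support[loci$role == "decoy_sr_only"] <- "SR"
  loci$re <- rpois(n_loci, params$coverage_mean / 2) + 1L
  loci$precise <- runif(n_loci) < 0.9

  # Realize loci in samples.
  realized <- dplyr::bind_rows(
    loci %>%
      dplyr::filter(.data$role == "shared") %>%
      dplyr::inner_join(samples,
        by = c(owner = "group"),
        relationship = "many-to-many"
      ) %>%
      dplyr::mutate(owner_group = .data$owner),
    loci %>%
      dplyr::filter(.data$role != "shared") %>%
      dplyr::inner_join(samples, by = c(owner = "sample_id")) %>%
      dplyr::mutate(sample_id = .data$owner, owner_group = .data$group)
  ) %>%
    dplyr::arrange(.data$locus_id, .data$sample_id)

  n_rec <- nrow(realized)
  sdj <- params$platform_jitter_sd
  if (sdj > 0) {
    realized$pos <- pmax(1L, realized$pos + as.integer(round(rnorm(n_rec, 0, sdj))))
    non_point <- !realized$svtype %in% c("INS", "TRA")
    end_j <- realized$end + as.integer(round(rnorm(n_rec, 0, sdj)))
    new_len <- pmin(
      pmax(end_j - realized$pos, params$size_range[1]),
      params$size_range[2]
    )
    realized$svlen[non_point] <- new_len[non_point]
    realized$end <- as.integer(
      ifelse(non_point, realized$pos + realized$svlen, realized$pos)
    )
  }

  truth <- realized %>%
    dplyr::arrange(.data$sample_id, .data$chrom, .data$pos, .data$locus_id) %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::mutate(sv_id = sprintf("%s_%05d", .data$sample_id, dplyr::row_number())) %>%
    dplyr::ungroup() %>%
    dplyr::select(
      "sample_id", "sv_id", "locus_id", "role", "owner_group", "target_gene",
      "platform", "chrom", "pos", "end", "svtype", "svlen",
      "filter", "support", "re", "precise"
    )
  calls <- truth %>%
    dplyr::select(dplyr::all_of(SV_CALL_COLS)) %>%
    sort_sv_calls()
  validate_sv_calls(calls)
  structure(
    list(
      calls = calls, truth = truth, genes = genes,
      samples = samples, layout = params$layout, params = params
    ),
    class = "sv_panel"
  )
}

#' @export
print.sv_panel <- function(x, ...) {
  cat(sprintf(
    "Synthetic SV panel: %d samples in %d groups, %d calls (%d decoys), %d genes\n",
    nrow(x$samples), length(unique(x$samples$group)), nrow(x$calls),
    sum(startsWith(x$truth$role, "decoy")), nrow(x$genes)
  ))
  invisible(x)
}

# Multiply depth by `fold` over [dstart, dend], splitting runs at the
# boundaries so the folded span is exact.
apply_fold <- function(track, dchrom, dstart, dend, fold) {
  hit <- track$chrom == dchrom & track$end >= dstart & track$start <= dend
  if (!any(hit)) {
    return(track)
  }
  h <- track[hit, , drop = FALSE]
  # Each overlapped run yields up to three pieces: before / inside / after.
  mid_start <- pmax(h$start, dstart)
  mid_end <- pmin(h$end, dend)
  pieces <- tibble(
    chrom = rep(h$chrom, 3),
    start = c(h$start, mid_start, mid_end + 1L),
    end = c(mid_start - 1L, mid_end, h$end),
    depth = c(h$depth, h$depth * fold, h$depth)
  )
  pieces <- pieces[pieces$end >= pieces$start, , drop = FALSE]
  dplyr::bind_rows(track[!hit, , drop = FALSE], pieces) %>%
    dplyr::arrange(.data$chrom, .data$start)
}

#' Simulate a read-depth coverage track
#'
#' Per-base depth is `coverage_mean` plus rounded normal noise (floored at
#' zero), drawn on tiles of `noise_run` bp (1 = independent per-base
#' noise; larger runs emit smaller bedGraph files at coarser noise
#' resolution). Planted duplications multiply depth by their fold over
#' `n_blocks` blocks of `block_width` bp; lost chromosomes are scaled to
#' 2% of the mean.
#'
#' @param params A `sim_params` object (coverage model + seed).
#' @param duplications Optional tibble `chrom`, `start`, `n_blocks`,
#'   `fold` of planted duplications.
#' @param lost_chromosomes Character vector of chromosomes to deplete.
#' @param layout Layout to cover (default `params$layout`).
#' @param noise_run Noise tile width in bp (default 1).
#' @param block_width Block width used to size duplications (default
#'   1000).
#' @param seed_offset Stage seed offset, added to `params$seed` (vary per
#'   sample to get independent tracks).
#' @return List with `track` (depth tibble `chrom`, `start`, `end`,
#'   `depth`), `duplications` (truth tibble with realized `start`, `end`,
#'   `fold`) and `lost` (the lost chromosome names).
#' @export
simulate_coverage <- function(params, duplications = NULL,
                              lost_chromosomes = character(),
                              layout = params$layout, noise_run = 1,
                              block_width = 1000, seed_offset = 3L) {
  if (params$coverage_mean <= 0) abort("`coverage_mean` must be positive")
  set.seed(params$seed + seed_offset)
  track <- purrr::pmap_dfr(
    layout[, c("chrom", "length")],
    function(chrom, length) {
      n_runs <- ceiling(length / noise_run)
      depth <- pmax(
        0,
        round(rnorm(n_runs, params$coverage_mean, params$coverage_noise_sd))
      )
      if (chrom %in% lost_chromosomes) {
        depth <- pmax(0, round(depth * 0.02))
      }
      tibble(
        chrom = chrom,
        start = as.integer((seq_len(n_runs) - 1) * noise_run + 1),
        end = as.integer(pmin(seq_len(n_runs) * noise_run, length)),
        depth = depth
      )
    }
  )
  dup_truth <- tibble(
    chrom = character(), start = integer(), end = integer(), fold = double()
  )
  if (!is.null(duplications) && nrow(duplications) > 0) {
    dup_truth <- duplications %>%
      dplyr::mutate(
        end = as.integer(.data$start + .data$n_blocks * block_width - 1L)
      ) %>%
      dplyr::select("chrom", "start", "end", "fold")
    for (i in seq_len(nrow(dup_truth))) {
      track <- apply_fold(
        track, dup_truth$chrom[i], dup_truth$start[i],
        dup_truth$end[i], dup_truth$fold[i]
      )
    }
  }
  list(track = track, duplications = dup_truth, lost = lost_chromosomes)
}

#' Write chromosome sizes TSV
#'
#' @param layout Genome layout tibble.
#' @param path Output path (two columns: chrom, length; no header).
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  readr::write_tsv(
    layout[, c("chrom", "length")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read chromosome sizes TSV
#'
#' @param path Two-column TSV (chrom, length), no header.
#' @return Genome layout tibble (`chrom`, `length`, `subgenome` inferred
#'   from names).
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(
    path,
    col_names = c("chrom", "length"),
    col_types = readr::cols(
      chrom = readr::col_character(), length = readr::col_double()
    ),
    progress = FALSE
  )
  genome_layout(df$chrom, df$length)
}

#' Write a synthetic panel to disk
#'
#' Emits per-sample Sniffles-dialect VCFs, the gene models as GFF3, the
#' chromosome sizes TSV, the sample sheet and the truth table (JSON), so
#' the panel can be consumed by the file-based pipeline entry points.
#'
#' @param panel An `sv_panel` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths (`vcf` is a named vector per
#'   sample), invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcfs <- vapply(panel$samples$sample_id, function(s) {
    path <- file.path(dir, paste0(s, ".vcf"))
    write_sv_vcf(dplyr::filter(panel$calls, .data$sample_id == s), path)
    path
  }, character(1))
  gff <- file.path(dir, "genes.gff3")
  write_gff(panel$genes, gff)
  sizes <- file.path(dir, "chrom_sizes.tsv")
  write_chrom_sizes(panel$layout, sizes)
  sheet <- file.path(dir, "samples.tsv")
  readr::write_tsv(panel$samples, sheet, progress = FALSE)
  truth <- file.path(dir, "truth.json")
  jsonlite::write_json(panel$truth, truth, digits = NA)
  invisible(list(
    vcf = vcfs, gff = gff, chrom_sizes = sizes,
    samples = sheet, truth = truth
  ))
}
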