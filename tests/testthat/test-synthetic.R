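test_that("simulation is bit-identical under a fixed seed", {
  p <- small_panel_params(42)
  a <- simulate_panel(p)
  b <- simulate_panel(p)
  expect_identical(a$calls, b$calls)
  expect_identical(a$truth, b$truth)
  expect_identical(a$genes, b$genes)
  c <- simulate_panel(small_panel_params(43))
  expect_false(identical(a$calls, c$calls))
})

test_that("changing the seed preserves configured marginal counts exactly", {
  for (s in c(1, 2)) {
    p <- small_panel_params(s)
    panel <- simulate_panel(p)
    per_sample <- dplyr::count(panel$truth, sample_id, role) %>%
      tidyr::pivot_wider(names_from = role, values_from = n, values_fill = 0L)
    expect_true(all(per_sample$shared == p$n_shared_per_group))
    expect_true(all(per_sample$private == p$n_private_per_sample))
    n_real <- p$n_shared_per_group + p$n_private_per_sample
    expect_true(all(per_sample$decoy_unresolved ==
      round(p$decoy_rates[["unresolved"]] * n_real)))
    expect_true(all(per_sample$decoy_tra ==
      round(p$decoy_rates[["tra"]] * n_real)))
  }
})

test_that("a group with no private SVs, decoys or jitter has identical call sets", {
  p <- small_panel_params(
    5,
    n_private_per_sample = 0, platform_jitter_sd = 0,
    decoy_rates = c(unresolved = 0, sr_only = 0, tra = 0, dup = 0)
  )
  panel <- simulate_panel(p)
  per_sample <- split(
    panel$calls[, setdiff(names(panel$calls), c("sample_id", "sv_id"))],
    panel$calls$sample_id
  )
  members <- panel$samples$sample_id[panel$samples$group == panel$samples$group[1]]
  for (s in members[-1]) {
    expect_equal(
      as.data.frame(per_sample[[members[1]]]),
      as.data.frame(per_sample[[s]])
    )
  }
})

test_that("emitted files re-read through the I/O modules reproduce the panel", {
  panel <- simulate_panel(small_panel_params(77))
  dir <- withr::local_tempdir()
  files <- write_panel(panel, dir)
  s <- panel$samples$sample_id[1]
  back <- read_sniffles_vcf(files$vcf[[s]], s)
  orig <- dplyr::filter(panel$calls, sample_id == s)
  expect_equal(as.data.frame(back), as.data.frame(orig))
  genes_back <- read_gene_models(files$gff)
  expect_equal(genes_back$gene_id, panel$genes$gene_id)
  expect_equal(genes_back$start, panel$genes$start)
  expect_equal(
    genes_back$exons[[10]]$start, panel$genes$exons[[10]]$start
  )
  layout_back <- read_chrom_sizes(files$chrom_sizes)
  expect_equal(
    as.data.frame(layout_back), as.data.frame(panel$layout)
  )
})

test_that("size draw median tracks the configured target across seeds", {
  meds <- vapply(1:20, function(s) {
    set.seed(s)
    median(polysv:::rsv_sizes(500, c(30, 30000), 300))
  }, numeric(1))
  expect_true(all(abs(meds / 300 - 1) < 0.15))
  r <- range(polysv:::rsv_sizes(5000, c(30, 30000), 300))
  expect_gte(r[1], 30)
  expect_lte(r[2], 30000)
})

test_that("simulated genes never overlap and hit the configured density", {
  p <- small_panel_params(31)
  genes <- simulate_genes(p)
  expect_equal(
    nrow(genes),
    sum(round(p$gene_density * p$layout$length / 1e6))
  )
  by_chrom <- split(genes, genes$chrom)
  for (g in by_chrom) {
    g <- dplyr::arrange(g, start)
    expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # Exons stay inside the gene span.
  ex <- tidyr::unnest(genes[, c("gene_id", "start", "end", "exons")],
    exons,
    names_sep = "_"
  )
  expect_true(all(ex$exons_start >= ex$start & ex$exons_end <= ex$end))
})

test_that("A-subgenome rate bias is realized in planted locus placement", {
  p <- small_panel_params(99, a_bias = 2)
  panel <- simulate_panel(p)
  loci <- dplyr::distinct(
    dplyr::filter(panel$truth, role %in% c("shared", "private")),
    locus_id, chrom
  )
  counts <- dplyr::count(loci, chrom)
  layout <- panel$layout
  rates <- counts$n / (layout$length[match(counts$chrom, layout$chrom)] / 1e6)
  a_rate <- mean(rates[grepl("^A", counts$chrom)])
  c_rate <- mean(rates[grepl("^C", counts$chrom)])
  expect_gt(a_rate / c_rate, 1.4)
})

test_that("coverage simulation plants duplications and chromosome loss exactly", {
  p <- sim_params(
    seed = 3, layout = genome_layout(c("A01", "C02"), c(2e5, 1e5)),
    coverage_noise_sd = 0
  )
  cov <- simulate_coverage(
    p,
    duplications = tibble::tibble(
      chrom = "A01", start = 50001L, n_blocks = 20L, fold = 2
    ),
    lost_chromosomes = "C02"
  )
  bl <- block_medians(cov$track)
  dup_blocks <- dplyr::filter(bl, chrom == "A01", start >= 50001, end <= 70000)
  expect_true(all(dup_blocks$median_depth == 60))
  normal <- dplyr::filter(bl, chrom == "A01", end < 50001 | start > 70000)
  expect_true(all(normal$median_depth == 30))
  lost <- dplyr::filter(bl, chrom == "C02")
  expect_true(all(lost$median_depth <= 1))
  expect_equal(cov$duplications$end, 70000L)
  # Truth recovered end-to-end by the CNV caller.
  segs <- call_duplications(bl)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 50001L)
  expect_equal(segs$end, 70000L)
  flags <- detect_chromosome_loss(bl)
  expect_equal(flags$lost, c(FALSE, TRUE))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(sim_params(seed = NA), "mandatory")
  expect_error(sim_params(frac_intragenic = 1.2), "fractions")
  expect_error(sim_params(size_range = c(100, 50)), "size_range")
  expect_error(sim_params(size_median = 10), "size_median")
  expect_error(
    sim_params(type_mix = c(DEL = 0.5, INS = 0.2, INV = 0.1)),
    "sum to 1"
  )
  # Overcrowded genome cannot be placed.
  p <- sim_params(
    seed = 1, layout = genome_layout("A01", 5e4),
    n_shared_per_group = 400, n_private_per_sample = 0,
    gene_density = 20
  )
  expect_error(simulate_panel(p), "place")
})
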