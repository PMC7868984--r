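test_that("gene overlap labels match the documented semantics", {
  genes <- gene_fixture(
    "g1", "A01", 4000, 6000,
    exons = tibble::tibble(start = 4900L, end = 5100L)
  )
  del <- sv_record(pos = 5000L, svlen = 700L) # span 5000-5700, hits exon base 5100
  hits <- annotate_sv(del, genes)
  expect_equal(hits$gene_id, "g1")
  expect_equal(hits$location, "exonic")

  intron_del <- sv_record(pos = 5200L, svlen = 300L) # 5200-5500, intron only
  expect_equal(annotate_sv(intron_del, genes)$location, "intronic")

  ins_prom <- sv_record(pos = 5000L, svtype = "INS", svlen = 90L)
  plus_gene <- gene_fixture("g2", "A01", 6000, 7000)
  h <- annotate_sv(ins_prom, plus_gene, promoter_flank = 2000)
  expect_equal(h$location, "promoter")
  # Strand-aware: for a minus-strand gene the flank is downstream of end.
  minus_gene <- gene_fixture("g3", "A01", 6000, 7000, strand = "-")
  expect_equal(nrow(annotate_sv(ins_prom, minus_gene, 2000)), 0)
  ins_after <- sv_record(pos = 7500L, svtype = "INS", svlen = 90L)
  expect_equal(annotate_sv(ins_after, minus_gene, 2000)$location, "promoter")

  other_chrom <- sv_record(chrom = "C01", pos = 5000L, svlen = 700L)
  expect_equal(nrow(annotate_sv(other_chrom, genes)), 0)
})

test_that("annotation equals the all-pairs brute-force oracle", {
  withr::local_seed(77)
  for (rep in 1:10) {
    genes <- simulate_genes(sim_params(
      seed = rep, layout = genome_layout(c("A01", "C01"), c(2e5, 2e5)),
      gene_density = 100
    ))
    calls <- random_callset(100, chrom_len = 2e5, chroms = c("A01", "C01"))
    hits <- annotate_sv(calls, genes)
    oracle <- brute_force_hits(calls, genes)
    expect_equal(as.data.frame(hits), as.data.frame(oracle))
  }
})

test_that("exonic and intronic partition intragenic relations", {
  panel <- simulate_panel(small_panel_params(3))
  f <- sv_filter(panel$calls)
  hits <- annotate_sv(f, panel$genes)
  intr <- dplyr::filter(hits, location %in% c("exonic", "intronic"))
  expect_equal(
    sum(intr$location == "exonic") + sum(intr$location == "intronic"),
    nrow(intr)
  )
  stats <- count_intragenic(hits, panel$genes)
  expect_gt(stats$n_genes_hit, 0)
  expect_true(stats$exon_pct >= 0 && stats$exon_pct <= 100)
})

test_that("intragenic percentages follow from counts", {
  hits <- tibble::tibble(
    sample_id = "s1",
    sv_id = c("v1", "v2"),
    gene_id = c("g1", "g2"),
    location = c("exonic", "intronic")
  )
  genes <- dplyr::bind_rows(
    gene_fixture("g1", "A01", 1, 10),
    gene_fixture("g2", "A01", 100, 200),
    gene_fixture("g3", "A01", 300, 400)
  )
  res <- count_intragenic(hits, genes)
  expect_equal(res$pct_genes_hit, 100 * 2 / 3)
  expect_equal(res$exon_pct, 50)
  none <- count_intragenic(hits[0, ], genes)
  expect_true(is.na(none$exon_pct))
  expect_equal(none$n_genes_hit, 0L)
})

test_that("planted intragenic fraction is recovered from annotation", {
  params <- small_panel_params(13, frac_intragenic = 0.10)
  panel <- simulate_panel(params)
  f <- sv_filter(panel$calls)
  hits <- annotate_sv(f, panel$genes)
  stats <- count_intragenic(hits, panel$genes)
  planted_genes <- unique(stats::na.omit(panel$truth$target_gene))
  # All planted genes are recovered; unplanted SVs add incidental
  # intragenic hits on top, so the hit count brackets the planted count.
  hit_genes <- unique(hits$gene_id[hits$location %in% c("exonic", "intronic")])
  expect_true(all(planted_genes %in% hit_genes))
  expect_gte(stats$n_genes_hit, length(planted_genes))
  expect_lt(stats$n_genes_hit, 2.5 * length(planted_genes))
})

test_that("window counts tile correctly and conserve totals", {
  layout <- genome_layout(c("A01", "C01"), c(2500000, 3000000))
  sv <- sv_record(pos = 1500000L, svlen = 100L)
  wc <- sv_window_counts(sv, layout)
  expect_equal(sum(wc$n[wc$chrom == "A01"]), 1)
  hit_row <- wc[wc$n == 1, ]
  expect_equal(hit_row$window_start, 1000001L)
  expect_equal(hit_row$window_end, 2000000L)
  expect_equal(sum(wc$chrom == "A01" & wc$svtype == "DEL"), 3) # 2.5 Mb -> 3 windows

  withr::local_seed(21)
  calls <- random_callset(100, chroms = c("A01", "C01"), chrom_len = 2400000)
  wc2 <- sv_window_counts(calls, layout, types = c("DEL", "INS", "INV"))
  expect_equal(sum(wc2$n), nrow(calls))
  per_chrom <- dplyr::count(calls, chrom)
  agg <- dplyr::summarise(dplyr::group_by(wc2, chrom), n = sum(n))
  expect_equal(agg$n, per_chrom$n)
})

test_that("subgenome rate test behaves under null and planted signal", {
  layout <- genome_layout(
    c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9)),
    rep(1e6, 19)
  )
  # Exactly equal rates: maximal p for the exact test.
  calls <- dplyr::bind_rows(lapply(layout$chrom, function(ch) {
    sv_record(chrom = ch, pos = 1000L, svlen = 100L, sv_id = paste0(ch, "_1"))
  }))
  res <- subgenome_rates(calls, layout)
  expect_gte(res$p_value, 0.99)
  expect_equal(glance(res)$rate_ratio, 1)
  # Planted 2x A rate across seeds is detected.
  detected <- vapply(1:20, function(s) {
    set.seed(s)
    n_a <- rpois(10, 40)
    n_c <- rpois(9, 20)
    calls <- dplyr::bind_rows(lapply(seq_along(layout$chrom), function(i) {
      n <- c(n_a, n_c)[i]
      if (n == 0) {
        return(NULL)
      }
      tibble::tibble(
        sample_id = "s1", sv_id = sprintf("%s_%d", layout$chrom[i], 1:n),
        chrom = layout$chrom[i], pos = seq_len(n) * 1000L,
        end = seq_len(n) * 1000L + 100L, svtype = "DEL", svlen = 100L,
        filter = "PASS", support = "AL", re = 5L, precise = TRUE
      )
    }))
    subgenome_rates(calls, layout)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.95)
  # Single chromosome per subgenome is an error.
  tiny <- genome_layout(c("A01", "C01"), c(1e6, 1e6))
  expect_error(subgenome_rates(calls[1, ], tiny), "2 chromosomes")
})

test_that("venn regions match inclusion-exclusion on random sets", {
  sets <- list(a = c("g1", "g2"), b = c("g2", "g3"))
  v <- venn_regions(sets)
  expect_equal(v$n[v$region == "a&b"], 1L)
  expect_equal(v$n[v$region == "a"], 1L)
  expect_equal(v$n[v$region == "b"], 1L)

  same <- list(a = "g1", b = "g1", c = "g1", d = "g1")
  v4 <- venn_regions(same)
  expect_equal(v4$n[v4$region == "a&b&c&d"], 1L)
  expect_equal(sum(v4$n), 1L)

  withr::local_seed(2)
  for (rep in 1:10) {
    rs <- lapply(1:3, function(i) {
      sample(sprintf("g%02d", 1:30), sample(5:20, 1))
    })
    names(rs) <- c("x", "y", "z")
    v3 <- venn_regions(rs)
    expect_equal(sum(v3$n), length(unique(unlist(rs))))
    # Power-set oracle: check each region by direct set arithmetic.
    universe <- unique(unlist(rs))
    for (i in seq_len(nrow(v3))) {
      members <- strsplit(v3$region[i], "&", fixed = TRUE)[[1]]
      inside <- Reduce(intersect, rs[members], universe)
      outside <- unique(unlist(rs[setdiff(names(rs), members)]))
      expect_equal(v3$n[i], length(setdiff(inside, outside)))
    }
  }
  expect_error(venn_regions(rep(list(a = "g"), 5)), "1-4")
})

test_that("group gene sets union member samples by default", {
  hits <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    sv_id = c("v1", "v2", "v3"),
    gene_id = c("g1", "g2", "g2"),
    location = "exonic"
  )
  groups <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    group = c("w", "w", "sp")
  )
  sets <- group_gene_sets(hits, groups)
  expect_equal(sets$w, c("g1", "g2"))
  expect_equal(sets$sp, "g2")
  inter <- group_gene_sets(hits, groups, mode = "intersection")
  expect_equal(inter$w, character(0))
})

test_that("QTL candidate arithmetic matches the worked interval example", {
  # Synthetic annotation: 606 genes in the interval, 37 and 45 carrying SV
  # in the two parents, 17 in common.
  n <- 606
  start <- 6329426
  end <- 10659726
  step <- floor((end - start) / n)
  genes <- tibble::tibble(
    gene_id = sprintf("gC05_%03d", 1:n), chrom = "C05",
    start = as.integer(start + (seq_len(n) - 1) * step),
    end = as.integer(start + (seq_len(n) - 1) * step + 200L),
    strand = "+",
    exons = lapply(1:n, function(i) tibble::tibble(start = 1L, end = 2L))
  )
  set.seed(5)
  a <- sample(genes$gene_id, 37)
  b <- c(sample(a, 17), sample(setdiff(genes$gene_id, a), 28))
  res <- qtl_candidates(genes, "C05", start, end, a, b)
  g <- glance(res)
  expect_equal(g$interval_mbp, 4.3)
  expect_equal(g$n_genes, 606L)
  expect_equal(g$n_common, 17L)
  cand <- tidy(res)
  expect_equal(sum(cand$specific_to == "a"), 20)
  expect_equal(sum(cand$specific_to == "b"), 28)

  # Degenerate set relations.
  expect_equal(nrow(tidy(qtl_candidates(genes, "C05", start, end, a, a))), 0)
  disjoint <- qtl_candidates(
    genes, "C05", start, end, a, setdiff(genes$gene_id, a)[1:10]
  )
  expect_equal(nrow(tidy(disjoint)), 47)
  expect_error(qtl_candidates(genes, "C05", 100, 100, a, b), "interval")
})
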