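#' Read gene models from GFF3
#'
#' Imports `gene` and `exon` features. Exons are attached to their gene via
#' the `Parent` attribute, following one level of mRNA nesting when exons
#' point at transcripts rather than genes.
#'
#' @param path Path to a GFF3 file.
#' @return A nested tibble with one row per gene: `gene_id`, `chrom`,
#'   `start`, `end`, `strand` and a list column `exons` of tibbles with
#'   `start`, `end` (1-based inclusive, sorted).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  if (!"type" %in% names(df)) abort("GFF3 has no feature types")
  df$ID <- as.character(df$ID)
  parent <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) {
      if (length(p) == 0) NA_character_ else as.character(p)[1]
    }, character(1))
  } else {
    rep(NA_character_, nrow(df))
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  # Map transcript-level parents up to genes where needed.
  tx <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  tx_to_gene <- setNames(parent[df$type %in% c("mRNA", "transcript")], tx$ID)
  ex <- df[df$type == "exon", , drop = FALSE]
  ex_parent <- parent[df$type == "exon"]
  up <- ex_parent %in% names(tx_to_gene)
  ex_parent[up] <- tx_to_gene[ex_parent[up]]
  exon_tbl <- tibble(
    gene_id = ex_parent,
    start = ex$start, end = ex$end
  )
  tibble(
    gene_id = genes$ID,
    chrom = as.character(genes$seqnames),
    start = genes$start, end = genes$end,
    strand = as.character(genes$strand)
  ) %>%
    dplyr::mutate(exons = purrr::map(.data$gene_id, function(g) {
      exon_tbl %>%
        dplyr::filter(.data$gene_id == g) %>%
        dplyr::select("start", "end") %>%
        dplyr::arrange(.data$start)
    }))
}

sv_span_granges <- function(calls, levels = unique(calls$chrom)) {
  end <- ifelse(calls$svtype == "INS", calls$pos, calls$end)
  GenomicRanges::GRanges(
    seqnames = factor(calls$chrom, levels = levels),
    ranges = IRanges::IRanges(start = calls$pos, end = end)
  )
}

#' Overlap SV calls with gene models
#'
#' Computes every SV-to-gene relation with at least 1 bp of overlap
#' (bedtools-intersect default semantics). Deletions and inversions
#' contribute their full `[pos, end]` span; insertions contribute the
#' single insertion point. An intragenic SV is `exonic` when it overlaps at
#' least one exon base of that gene, otherwise `intronic`. An SV
#' overlapping no gene anywhere but lying within `promoter_flank` bp
#' upstream of a gene's 5' end (strand-aware) is labelled `promoter` for
#' that gene.
#'
#' @param calls Filtered SV call tibble.
#' @param genes Gene model tibble from [read_gene_models()] or
#'   [simulate_genes()].
#' @param promoter_flank Upstream flank in bp (default 2000).
#' @return Hits tibble with one row per (SV, gene) relation: `sample_id`,
#'   `sv_id`, `gene_id`, `location` in `{exonic, intronic, promoter}`.
#' @export
annotate_sv <- function(calls, genes, promoter_flank = 2000) {
  validate_sv_calls(calls)
  empty <- tibble(
    sample_id = character(), sv_id = character(),
    gene_id = character(), location = character()
  )
  if (nrow(calls) == 0 || nrow(genes) == 0) {
    return(empty)
  }
  # Shared seqlevels: SVs and genes on chromosomes unknown to the other
  # side simply produce no overlap.
  levels <- union(unique(calls$chrom), unique(genes$chrom))
  gr_sv <- sv_span_granges(calls, levels)
  gr_genes <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = levels),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end)
  )
  ov <- GenomicRanges::findOverlaps(gr_sv, gr_genes)
  sv_idx <- S4Vectors::queryHits(ov)
  gene_idx <- S4Vectors::subjectHits(ov)

  # Exon overlap, per (sv, gene) pair.
  exons <- genes %>%
    dplyr::select("gene_id", "chrom", "exons") %>%
    tidyr::unnest("exons")
  genic <- if (length(sv_idx) > 0) {
    if (nrow(exons) > 0) {
      gr_ex <- GenomicRanges::GRanges(
        seqnames = factor(exons$chrom, levels = levels),
        ranges = IRanges::IRanges(start = exons$start, end = exons$end)
      )
      ov_ex <- GenomicRanges::findOverlaps(gr_sv, gr_ex)
      exonic_pairs <- unique(paste(
        S4Vectors::queryHits(ov_ex),
        exons$gene_id[S4Vectors::subjectHits(ov_ex)]
      ))
    } else {
      exonic_pairs <- character()
    }
    tibble(
      sample_id = calls$sample_id[sv_idx],
      sv_id = calls$sv_id[sv_idx],
      gene_id = genes$gene_id[gene_idx],
      location = ifelse(
        paste(sv_idx, genes$gene_id[gene_idx]) %in% exonic_pairs,
        "exonic", "intronic"
      )
    )
  } else {
    empty
  }

  # Promoter relation for SVs with no gene-span overlap at all.
  nongenic <- setdiff(seq_len(nrow(calls)), unique(sv_idx))
  prom <- empty
  if (length(nongenic) > 0 && promoter_flank > 0) {
    prom_start <- ifelse(
      genes$strand == "-", genes$end + 1L, pmax(1L, genes$start - promoter_flank)
    )
    prom_end <- ifelse(
      genes$strand == "-", genes$end + promoter_flank, genes$start - 1L
    )
    valid <- prom_end >= prom_start
    if (any(valid)) {
      gr_prom <- GenomicRanges::GRanges(
        seqnames = factor(genes$chrom[valid], levels = levels),
        ranges = IRanges::IRanges(start = prom_start[valid], end = prom_end[valid])
      )
      ov_p <- GenomicRanges::findOverlaps(gr_sv[nongenic], gr_prom)
      if (length(ov_p) > 0) {
        svp <- nongenic[S4Vectors::queryHits(ov_p)]
        prom <- tibble(
          sample_id = calls$sample_id[svp],
          sv_id = calls$sv_id[svp],
          gene_id = genes$gene_id[valid][S4Vectors::subjectHits(ov_p)],
          location = "promoter"
        )
      }
    }
  }
  dplyr::bind_rows(genic, prom) %>%
    dplyr::arrange(.data$sample_id, .data$sv_id, .data$gene_id)
}

#' Intragenic SV statistics
#'
#' @param hits Hits tibble from [annotate_sv()].
#' @param genes Gene model tibble (defines the gene universe).
#' @param by_sample Summarize per sample (default `FALSE`: pooled).
#' @return Tibble with `n_genes_hit`, `n_intragenic_sv`, `pct_genes_hit`
#'   and `exon_pct` (percentage of intragenic SVs overlapping an exon; an
#'   SV hitting several genes is one event, exonic if exonic for any of
#'   them). `exon_pct` is `NA` when there are no intragenic SVs;
#'   percentages are unrounded.
#' @export
count_intragenic <- function(hits, genes, by_sample = FALSE) {
  n_genes_total <- nrow(genes)
  if (n_genes_total == 0) abort("gene universe is empty")
  intr <- dplyr::filter(hits, .data$location %in% c("exonic", "intronic"))
  grouping <- if (by_sample) "sample_id" else character()
  if (nrow(intr) == 0) {
    return(tibble(
      n_genes_hit = 0L, n_intragenic_sv = 0L,
      pct_genes_hit = 0, exon_pct = NA_real_
    ))
  }
  intr %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) %>%
    dplyr::summarise(
      n_genes_hit = dplyr::n_distinct(.data$gene_id),
      n_intragenic_sv = dplyr::n_distinct(.data$sv_id),
      exon_pct = {
        per_sv <- tapply(.data$location == "exonic", .data$sv_id, any)
        100 * mean(per_sv)
      },
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      pct_genes_hit = 100 * .data$n_genes_hit / n_genes_total
    ) %>%
    dplyr::relocate(dplyr::any_of(c(
      grouping, "n_genes_hit", "n_intragenic_sv", "pct_genes_hit", "exon_pct"
    )))
}

#' Count SVs in fixed genomic windows
#'
#' Tiles each chromosome with windows of `window` bp starting at position 1
#' (last window truncated at the chromosome end) and counts SVs of the
#' requested types by the window containing their left breakpoint, so
#' per-chromosome window sums equal per-chromosome call counts.
#'
#' @param calls SV call tibble.
#' @param layout Genome layout tibble with columns `chrom`, `length`
#'   (and optionally `subgenome`); see [genome_layout()].
#' @param window Window size in bp (default 1e6).
#' @param types SV types to count (default `c("DEL", "INS")`).
#' @return Tibble `chrom`, `window_start`, `window_end`, `svtype`, `n`
#'   covering every window x type combination (zero-filled).
#' @export
sv_window_counts <- function(calls, layout, window = 1e6,
                             types = c("DEL", "INS")) {
  validate_sv_calls(calls)
  grid <- layout %>%
    dplyr::select("chrom", "length") %>%
    dplyr::mutate(n_win = pmax(1L, as.integer(ceiling(.data$length / window)))) %>%
    dplyr::rowwise() %>%
    dplyr::reframe(
      chrom = .data$chrom,
      window_start = as.integer((seq_len(.data$n_win) - 1) * window + 1),
      window_end = as.integer(pmin(seq_len(.data$n_win) * window, .data$length))
    ) %>%
    tidyr::expand_grid(svtype = types)
  counts <- calls %>%
    dplyr::filter(.data$svtype %in% types, .data$chrom %in% layout$chrom) %>%
    dplyr::mutate(
      window_start = as.integer(((.data$pos - 1) %/% window) * window + 1)
    ) %>%
    dplyr::count(.data$chrom, .data$window_start, .data$svtype)
  grid %>%
    dplyr::left_join(counts, by = c("chrom", "window_start", "svtype")) %>%
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
    dplyr::arrange(.data$chrom, .data$window_start, .data$svtype)
}

#' Subgenome SV rate comparison
#'
#' Computes per-chromosome SV rates (calls per Mbp of chromosome length)
#' and compares the A-subgenome chromosomes against the C-subgenome
#' chromosomes with a two-sided Wilcoxon rank-sum test (exact when there
#' are no ties), the distribution-free test appropriate for ~10 vs ~9
#' chromosomes.
#'
#' @param calls SV call tibble (pool samples as desired before calling).
#' @param layout Genome layout tibble with `chrom`, `length`, `subgenome`.
#' @return An object of class `subgenome_rates`: use [tidy()] for the
#'   per-chromosome rate table and [glance()] for the one-row summary
#'   (`rate_A`, `rate_C`, `rate_ratio`, `statistic`, `p_value`).
#' @export
subgenome_rates <- function(calls, layout) {
  validate_sv_calls(calls)
  if (!"subgenome" %in% names(layout)) {
    layout <- dplyr::mutate(layout, subgenome = infer_subgenome(.data$chrom))
  }
  per_chrom <- layout %>%
    dplyr::select("chrom", "length", "subgenome") %>%
    dplyr::left_join(dplyr::count(calls, .data$chrom), by = "chrom") %>%
    dplyr::mutate(
      n = tidyr::replace_na(.data$n, 0L),
      rate = .data$n / (.data$length / 1e6)
    )
  n_a <- sum(per_chrom$subgenome == "A")
  n_c <- sum(per_chrom$subgenome == "C")
  if (n_a < 2 || n_c < 2) {
    abort("need at least 2 chromosomes per subgenome")
  }
  ra <- per_chrom$rate[per_chrom$subgenome == "A"]
  rc <- per_chrom$rate[per_chrom$subgenome == "C"]
  if (length(unique(c(ra, rc))) == 1) {
    # Fully tied rates carry no evidence either way.
    test <- list(
      statistic = length(ra) * length(rc) / 2, p.value = 1,
      method = "Wilcoxon rank sum test (degenerate: all rates tied)"
    )
  } else {
    exact <- !any(duplicated(c(ra, rc)))
    test <- wilcox.test(ra, rc, alternative = "two.sided", exact = exact)
  }
  structure(
    list(
      per_chrom = per_chrom,
      rate_A = sum(per_chrom$n[per_chrom$subgenome == "A"]) /
        (sum(per_chrom$length[per_chrom$subgenome == "A"]) / 1e6),
      rate_C = sum(per_chrom$n[per_chrom$subgenome == "C"]) /
        (sum(per_chrom$length[per_chrom$subgenome == "C"]) / 1e6),
      statistic = unname(test$statistic),
      p_value = test$p.value,
      method = test$method
    ),
    class = "subgenome_rates"
  )
}

#' @exportS3Method generics::tidy
tidy.subgenome_rates <- function(x, ...) x$per_chrom

#' @exportS3Method generics::glance
glance.subgenome_rates <- function(x, ...) {
  tibble(
    rate_A = x$rate_A, rate_C = x$rate_C,
    rate_ratio = x$rate_A / x$rate_C,
    statistic = x$statistic, p_value = x$p_value
  )
}

#' @export
print.subgenome_rates <- function(x, ...) {
  cat("Subgenome SV rate comparison (Wilcoxon rank-sum)\n")
  cat(sprintf(
    "  rate A = %.2f SV/Mbp, rate C = %.2f SV/Mbp (ratio %.2f)\n",
    x$rate_A, x$rate_C, x$rate_A / x$rate_C
  ))
  cat(sprintf("  W = %g, p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}

infer_subgenome <- function(chrom) {
  dplyr::case_when(
    grepl("^A\\d+$", chrom) ~ "A",
    grepl("^C\\d+$", chrom) ~ "C",
    TRUE ~ "other"
  )
}

#' Per-group gene sets carrying intragenic SVs
#'
#' @param hits Hits tibble from [annotate_sv()] (only exonic/intronic rows
#'   are used).
#' @param groups Tibble `sample_id`, `group` assigning each sample to an
#'   ecotype group.
#' @param mode Combine member samples by `"union"` (default: a gene counts
#'   for the group when any member carries an SV in it) or
#'   `"intersection"`.
#' @return Named list of gene-id character vectors, one per group.
#' @export
group_gene_sets <- function(hits, groups, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  intr <- dplyr::filter(hits, .data$location %in% c("exonic", "intronic"))
  per_sample <- intr %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(genes = list(unique(.data$gene_id)), .groups = "drop")
  split(groups$sample_id, groups$group) %>%
    purrr::map(function(members) {
      sets <- per_sample$genes[match(members, per_sample$sample_id)]
      sets[vapply(sets, is.null, logical(1))] <- list(character())
      if (mode == "union") {
        sort(unique(unlist(sets)))
      } else {
        sort(purrr::reduce(sets, intersect))
      }
    })
}

#' Venn region cardinalities for up to four sets
#'
#' @param sets Named list of 2–4 character vectors (e.g. from
#'   [group_gene_sets()]).
#' @return Tibble `region` (group names joined by `&`), `n_groups`, `n`:
#'   the number of elements belonging to exactly that combination of sets.
#'   Regions sum to the size of the union.
#' @export
venn_regions <- function(sets) {
  k <- length(sets)
  if (k < 1 || k > 4) {
    abort("venn_regions() supports 1-4 sets; report pairwise for more groups")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("`sets` must be named")
  }
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  key <- apply(membership, 1, function(m) paste(names(sets)[m], collapse = "&"))
  combos <- unlist(lapply(seq_len(k), function(i) {
    apply(utils::combn(names(sets), i), 2, paste, collapse = "&")
  }))
  counts <- table(factor(key, levels = combos))
  tibble(
    region = combos,
    n_groups = lengths(strsplit(combos, "&", fixed = TRUE)),
    n = as.integer(counts[combos])
  )
}

#' Prioritize QTL-interval candidate genes from SV contrasts
#'
#' For a QTL confidence interval and two contrasted genotypes, candidate
#' genes are those inside the interval carrying an SV in exactly one of the
#' two genotypes (genes structurally variable in both cannot explain the
#' phenotypic contrast and are dropped). Candidates can optionally be
#' narrowed by annotation keywords.
#'
#' @param genes Gene model tibble.
#' @param chrom,start,end QTL interval (1-based inclusive, one chromosome).
#' @param genes_a,genes_b Character vectors: genes carrying SV in genotype
#'   A and B respectively.
#' @param annotations Optional tibble `gene_id`, `annotation` used with
#'   `keywords`.
#' @param keywords Optional character vector; keep candidates whose
#'   annotation matches any keyword (case-insensitive).
#' @return Object of class `qtl_candidates`; [tidy()] returns the candidate
#'   tibble (`gene_id`, `specific_to`), [glance()] the one-row summary with
#'   `interval_mbp` (one decimal), `n_genes`, `n_a`, `n_b`, `n_common`,
#'   `n_candidates`.
#' @export
qtl_candidates <- function(genes, chrom, start, end, genes_a, genes_b,
                           annotations = NULL, keywords = NULL) {
  if (end <= start) abort("empty or inverted QTL interval")
  in_interval <- genes %>%
    dplyr::filter(
      .data$chrom == !!chrom, .data$start <= !!end, .data$end >= !!start
    )
  a <- intersect(genes_a, in_interval$gene_id)
  b <- intersect(genes_b, in_interval$gene_id)
  common <- intersect(a, b)
  cand <- dplyr::bind_rows(
    tibble(gene_id = setdiff(a, b), specific_to = "a"),
    tibble(gene_id = setdiff(b, a), specific_to = "b")
  )
  if (!is.null(keywords) && !is.null(annotations)) {
    pat <- paste(keywords, collapse = "|")
    keep <- annotations$gene_id[grepl(pat, annotations$annotation, ignore.case = TRUE)]
    cand <- dplyr::filter(cand, .data$gene_id %in% keep)
  }
  structure(
    list(
      candidates = cand,
      interval_mbp = round((end - start) / 1e6, 1),
      n_genes = nrow(in_interval),
      n_a = length(a), n_b = length(b), n_common = length(common)
    ),
    class = "qtl_candidates"
  )
}

#' @exportS3Method generics::tidy
tidy.qtl_candidates <- function(x, ...) x$candidates

#' @exportS3Method generics::glance
glance.qtl_candidates <- function(x, ...) {
  tibble(
    interval_mbp = x$interval_mbp, n_genes = x$n_genes,
    n_a = x$n_a, n_b = x$n_b, n_common = x$n_common,
    n_candidates = nrow(x$candidates)
  )
}

#' @export
print.qtl_candidates <- function(x, ...) {
  cat(sprintf(
    "QTL interval of %.1f Mbp with %d genes: %d + %d SV-carrying, %d common, %d candidates\n",
    x$interval_mbp, x$n_genes, x$n_a, x$n_b, x$n_common, nrow(x$candidates)
  ))
  invisible(x)
}
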