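# Fixture builders and independent oracles used across the suite.

# A bare SV record tibble with sensible defaults.
sv_record <- function(sample_id = "s1", chrom = "A01", pos = 1000L,
                      svtype = "DEL", svlen = 700L,
                      end = NULL, filter = "PASS", support = "AL",
                      re = 10L, precise = TRUE, sv_id = NULL) {
  end <- end %||% if (svtype %in% c("INS", "TRA")) pos else pos + svlen
  tibble::tibble(
    sample_id = sample_id,
    sv_id = sv_id %||% paste0(sample_id, "_", pos, "_", svtype),
    chrom = chrom, pos = as.integer(pos), end = as.integer(end),
    svtype = svtype, svlen = as.integer(svlen), filter = filter,
    support = support, re = as.integer(re), precise = precise
  )
}

`%||%` <- rlang::`%||%`

# Random call set over a small genome; used for round-trip and merge
# property tests.
random_callset <- function(n, sample_id = "s1", chroms = c("A01", "C01"),
                           chrom_len = 1e6, types = c("DEL", "INS", "INV")) {
  svtype <- sample(types, n, replace = TRUE)
  svlen <- sample(30:5000, n, replace = TRUE)
  pos <- sample.int(chrom_len - 6000L, n, replace = TRUE)
  chrom <- sample(chroms, n, replace = TRUE)
  end <- ifelse(svtype == "INS", pos, pos + svlen)
  tibble::tibble(
    sample_id = sample_id,
    sv_id = sprintf("%s_%04d", sample_id, seq_len(n)),
    chrom = chrom, pos = as.integer(pos), end = as.integer(end),
    svtype = svtype, svlen = as.integer(svlen),
    filter = sample(c("PASS", "UNRESOLVED"), n, replace = TRUE, prob = c(0.8, 0.2)),
    support = sample(c("AL", "AL,SR", "SR"), n, replace = TRUE),
    re = sample(5:40, n, replace = TRUE),
    precise = sample(c(TRUE, FALSE), n, replace = TRUE)
  )
}

# O(n^2) single-linkage clustering oracle: builds the full link graph and
# takes connected components with igraph — an implementation-independent
# route to the same partition sv_merge() must produce.
brute_force_clusters <- function(calls, max_dist, type_aware = TRUE) {
  n <- nrow(calls)
  if (n == 0) {
    return(integer())
  }
  same_stratum <- outer(calls$chrom, calls$chrom, "==")
  if (type_aware) {
    same_stratum <- same_stratum & outer(calls$svtype, calls$svtype, "==")
  }
  linked <- same_stratum &
    abs(outer(calls$pos, calls$pos, "-")) <= max_dist &
    abs(outer(calls$end, calls$end, "-")) <= max_dist
  g <- igraph::graph_from_adjacency_matrix(linked, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

# Two labelings describe the same partition iff co-membership matrices agree.
same_partition <- function(a, b) {
  identical(outer(a, a, "=="), outer(b, b, "=="))
}

# All-pairs brute-force SV x gene overlap oracle mirroring the documented
# semantics: span overlap >= 1 bp, exonic if any exon base overlapped,
# else intronic; promoter only for SVs overlapping no gene at all.
brute_force_hits <- function(calls, genes, promoter_flank = 2000) {
  res <- list()
  sv_start <- calls$pos
  sv_end <- ifelse(calls$svtype == "INS", calls$pos, calls$end)
  genic_sv <- rep(FALSE, nrow(calls))
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(genes))) {
      if (calls$chrom[i] != genes$chrom[j]) next
      if (sv_end[i] >= genes$start[j] && sv_start[i] <= genes$end[j]) {
        genic_sv[i] <- TRUE
        ex <- genes$exons[[j]]
        exonic <- any(sv_end[i] >= ex$start & sv_start[i] <= ex$end)
        res[[length(res) + 1]] <- tibble::tibble(
          sample_id = calls$sample_id[i], sv_id = calls$sv_id[i],
          gene_id = genes$gene_id[j],
          location = if (exonic) "exonic" else "intronic"
        )
      }
    }
  }
  for (i in which(!genic_sv)) {
    for (j in seq_len(nrow(genes))) {
      if (calls$chrom[i] != genes$chrom[j]) next
      ps <- if (genes$strand[j] == "-") genes$end[j] + 1 else max(1, genes$start[j] - promoter_flank)
      pe <- if (genes$strand[j] == "-") genes$end[j] + promoter_flank else genes$start[j] - 1
      if (pe >= ps && sv_end[i] >= ps && sv_start[i] <= pe) {
        res[[length(res) + 1]] <- tibble::tibble(
          sample_id = calls$sample_id[i], sv_id = calls$sv_id[i],
          gene_id = genes$gene_id[j], location = "promoter"
        )
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      sample_id = character(), sv_id = character(),
      gene_id = character(), location = character()
    ))
  }
  dplyr::arrange(out, sample_id, sv_id, gene_id)
}

# Small gene tibble fixture.
gene_fixture <- function(gene_id, chrom, start, end, strand = "+",
                         exons = NULL) {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand,
    exons = list(exons %||% tibble::tibble(
      start = as.integer(start), end = as.integer(end)
    ))
  )
}

# A small panel configuration for fast planted-truth tests; any
# sim_params() argument can be overridden through `...`.
small_panel_params <- function(seed, ...) {
  args <- list(
    seed = seed,
    layout = genome_layout(
      c("A01", "A02", "C01", "C02"), c(3e6, 2e6, 3e6, 2e6)
    ),
    n_shared_per_group = 40,
    n_private_per_sample = 10,
    gene_density = 20
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_params, args)
}
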