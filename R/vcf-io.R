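#' Read a Sniffles-dialect structural-variant VCF
#'
#' Parses a single-sample VCF as emitted by the Sniffles long-read SV caller
#' (or by [write_sv_vcf()]) into the tidy SV-call tibble used by every other
#' function in the package. Negative `SVLEN` values (the deletion convention)
#' are stored as positive magnitudes; insertions use `end = pos`.
#'
#' The dialect expects the INFO keys `SVTYPE`, `SVLEN`, `END`, `RE` and
#' `SUPTYPE` plus a leading `PRECISE`/`IMPRECISE` flag. Unknown INFO keys are
#' ignored. A record without `SUPTYPE` is treated as split-read-only (`SR`),
#' the conservative choice for the within-alignment support filter. FILTER
#' values other than `PASS`/`UNRESOLVED` are mapped to `UNRESOLVED` with a
#' warning.
#'
#' @param path Path to a VCF file.
#' @param sample_id Sample identifier attached to every record.
#' @return A tibble with one row per VCF data line and columns
#'   `sample_id`, `sv_id`, `chrom`, `pos`, `end`, `svtype`, `svlen`,
#'   `filter`, `support`, `re`, `precise`, sorted by (chrom, pos).
#' @seealso [write_sv_vcf()], [sv_filter()]
#' @export
read_sniffles_vcf <- function(path, sample_id) {
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  n_data <- count_vcf_data_lines(path)
  if (n_data == 0) {
    return(empty_sv_calls())
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)

  svtype <- unname(vcfR::extract.info(vcf, "SVTYPE"))
  if (any(is.na(svtype))) {
    abort(sprintf(
      "malformed record: missing SVTYPE at data line(s) %s of %s",
      paste(which(is.na(svtype)), collapse = ", "), path
    ))
  }
  pos <- as.integer(fix$POS)
  svlen_raw <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "SVLEN")))
  end_raw <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "END")))
  non_tra <- svtype != "TRA"
  if (any(non_tra & (is.na(svlen_raw) | is.na(end_raw)))) {
    abort(sprintf(
      "malformed record: SVLEN/END required for non-TRA records at line(s) %s of %s",
      paste(which(non_tra & (is.na(svlen_raw) | is.na(end_raw))), collapse = ", "),
      path
    ))
  }
  svlen <- as.integer(abs(svlen_raw))
  end <- as.integer(end_raw)
  end[svtype == "INS"] <- pos[svtype == "INS"]
  end[is.na(end)] <- pos[is.na(end)]

  filt <- fix$FILTER
  bad_filter <- !filt %in% c("PASS", "UNRESOLVED")
  if (any(bad_filter)) {
    warn(sprintf(
      "%d record(s) with FILTER outside {PASS, UNRESOLVED} mapped to UNRESOLVED",
      sum(bad_filter)
    ))
    filt[bad_filter] <- "UNRESOLVED"
  }

  support <- unname(vcfR::extract.info(vcf, "SUPTYPE"))
  support[is.na(support) | support == ""] <- "SR"
  re <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "RE")))
  re[is.na(re)] <- 0L
  precise <- grepl("(^|;)PRECISE($|;)", fix$INFO)

  ids <- fix$ID
  need_id <- is.na(ids) | ids == "."
  ids[need_id] <- sprintf("%s_%05d", sample_id, which(need_id))

  calls <- tibble(
    sample_id = sample_id, sv_id = ids, chrom = fix$CHROM, pos = pos,
    end = end, svtype = svtype, svlen = svlen, filter = filt,
    support = support, re = re, precise = precise
  )
  validate_sv_calls(calls)
  sort_sv_calls(calls)
}

# Count non-header lines of a VCF without fully parsing it.
count_vcf_data_lines <- function(path) {
  lines <- readr::read_lines(path)
  if (!any(startsWith(lines, "#CHROM"))) {
    abort(sprintf("not a VCF (no #CHROM header line): %s", path))
  }
  sum(!startsWith(lines, "#") & nzchar(lines))
}

vcf_header_lines <- function(extra_info = character(), format = FALSE,
                             samples = character()) {
  info <- c(
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of SV (negative for deletions)\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=RE,Number=1,Type=Integer,Description=\"Number of supporting reads\">",
    "##INFO=<ID=SUPTYPE,Number=1,Type=String,Description=\"Type of read support: AL, SR, NR\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise breakpoints\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">"
  )
  filt <- c(
    "##FILTER=<ID=PASS,Description=\"All filters passed\">",
    "##FILTER=<ID=UNRESOLVED,Description=\"Unresolved by the caller\">"
  )
  fmt <- if (format) {
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  } else {
    character()
  }
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (format) cols <- c(cols, "FORMAT", samples)
  c(
    "##fileformat=VCFv4.2",
    "##source=polysv",
    info, filt, fmt, extra_info,
    paste(cols, collapse = "\t")
  )
}

#' Write an SV call set as a Sniffles-dialect VCF
#'
#' Emits the dialect read by [read_sniffles_vcf()]: `SVLEN` is written
#' negative for deletions, insertions carry `END = POS`, and the
#' `PRECISE`/`IMPRECISE` flag leads the INFO field. Writing then reading a
#' call set is the identity.
#'
#' @param calls An SV call tibble (see [read_sniffles_vcf()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path) {
  validate_sv_calls(calls)
  calls <- dplyr::arrange(calls, .data$chrom, .data$pos, .data$end, .data$sv_id)
  header <- vcf_header_lines()
  if (nrow(calls) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  svlen_out <- ifelse(calls$svtype == "DEL", -calls$svlen, calls$svlen)
  info <- paste0(
    ifelse(calls$precise, "PRECISE", "IMPRECISE"),
    ";SVTYPE=", calls$svtype,
    ";SVLEN=", svlen_out,
    ";END=", calls$end,
    ";RE=", calls$re,
    ";SUPTYPE=", calls$support
  )
  body <- paste(
    calls$chrom, calls$pos, calls$sv_id, "N",
    paste0("<", calls$svtype, ">"), ".", calls$filter, info,
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write merged SV clusters as a multi-sample VCF
#'
#' One line per cluster with a `GT` genotype column per sample: `1/1` where
#' the cluster is present in that sample, `0/0` where it is absent — the
#' presence/absence encoding used for the PAV phylogeny.
#'
#' @param clusters Cluster tibble from [sv_clusters()].
#' @param presence Long presence tibble with columns `cluster_id`,
#'   `sample_id`, `present` covering every cluster/sample pair (see
#'   [sv_presence()] or [sv_force_call()] output bound over samples).
#' @param path Output file path.
#' @param samples Optional character vector fixing sample column order;
#'   defaults to sorted unique sample ids in `presence`.
#' @return `path`, invisibly.
#' @export
write_multisample_vcf <- function(clusters, presence, path, samples = NULL) {
  samples <- samples %||% sort(unique(presence$sample_id))
  n_pairs <- nrow(dplyr::distinct(presence, .data$cluster_id, .data$sample_id))
  covers <- setequal(unique(presence$sample_id), samples) &&
    setequal(unique(presence$cluster_id), clusters$cluster_id) &&
    n_pairs == nrow(clusters) * length(samples) &&
    n_pairs == nrow(presence)
  if (nrow(clusters) > 0 && !covers) {
    abort("`presence` must cover exactly the clusters x samples grid")
  }
  header <- vcf_header_lines(format = TRUE, samples = samples)
  if (nrow(clusters) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  wide <- presence %>%
    dplyr::mutate(gt = ifelse(.data$present, "1/1", "0/0")) %>%
    dplyr::select("cluster_id", "sample_id", "gt") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "gt")
  wide <- wide[match(clusters$cluster_id, wide$cluster_id), , drop = FALSE]
  svlen_out <- ifelse(clusters$svtype == "DEL", -clusters$rep_len, clusters$rep_len)
  info <- paste0(
    "PRECISE;SVTYPE=", clusters$svtype,
    ";SVLEN=", svlen_out,
    ";END=", clusters$rep_end,
    ";RE=0;SUPTYPE=AL"
  )
  gt_cols <- as.matrix(wide[, samples, drop = FALSE])
  body <- paste(
    clusters$chrom, clusters$rep_pos, clusters$cluster_id, "N",
    paste0("<", clusters$svtype, ">"), ".", "PASS", info, "GT",
    apply(gt_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample presence/absence VCF
#'
#' Inverse of [write_multisample_vcf()]: recovers the cluster table and the
#' long presence tibble from the `GT` columns.
#'
#' @param path Path to a multi-sample VCF.
#' @return A list with elements `clusters` (tibble: `cluster_id`, `chrom`,
#'   `svtype`, `rep_pos`, `rep_end`, `rep_len`) and `presence` (long tibble:
#'   `cluster_id`, `sample_id`, `present`).
#' @export
read_multisample_vcf <- function(path) {
  n_data <- count_vcf_data_lines(path)
  header <- readr::read_lines(path)
  chrom_line <- header[startsWith(header, "#CHROM")][1]
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character()
  if (n_data == 0) {
    return(list(
      clusters = tibble(
        cluster_id = character(), chrom = character(), svtype = character(),
        rep_pos = integer(), rep_end = integer(), rep_len = integer()
      ),
      presence = tibble(
        cluster_id = character(), sample_id = character(), present = logical()
      )
    ))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  clusters <- tibble(
    cluster_id = fix$ID,
    chrom = fix$CHROM,
    svtype = unname(vcfR::extract.info(vcf, "SVTYPE")),
    rep_pos = as.integer(fix$POS),
    rep_end = as.integer(vcfR::extract.info(vcf, "END")),
    rep_len = as.integer(abs(as.numeric(vcfR::extract.info(vcf, "SVLEN"))))
  )
  gt <- vcf@gt[, samples, drop = FALSE]
  presence <- as_tibble(gt) %>%
    dplyr::mutate(cluster_id = clusters$cluster_id) %>%
    tidyr::pivot_longer(
      cols = dplyr::all_of(samples),
      names_to = "sample_id", values_to = "gt"
    ) %>%
    dplyr::mutate(present = .data$gt == "1/1") %>%
    dplyr::select("cluster_id", "sample_id", "present")
  list(clusters = clusters, presence = presence)
}
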