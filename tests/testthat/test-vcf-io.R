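test_that("a Sniffles deletion line is parsed with sign-magnitude SVLEN", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "A01\t1000\t.\tN\t<DEL>\t.\tPASS\tPRECISE;SVTYPE=DEL;SVLEN=-700;END=1700;RE=12;SUPTYPE=AL"
  ), path)
  calls <- read_sniffles_vcf(path, "s1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos, 1000L)
  expect_equal(calls$end, 1700L)
  expect_equal(calls$svlen, 700L)
  expect_equal(calls$svtype, "DEL")
  expect_equal(calls$filter, "PASS")
  expect_equal(calls$support, "AL")
  expect_equal(calls$re, 12L)
  expect_true(calls$precise)
})

test_that("header-only VCF gives an empty call set and empty set round-trips", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), path)
  calls <- read_sniffles_vcf(path, "s1")
  expect_equal(nrow(calls), 0)
  out <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(calls, out)
  expect_equal(nrow(read_sniffles_vcf(out, "s1")), 0)
})

test_that("missing SVTYPE raises a malformed-record error naming the line", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "A01\t1000\t.\tN\t<DEL>\t.\tPASS\tSVLEN=-700;END=1700"
  ), path)
  expect_error(read_sniffles_vcf(path, "s1"), "SVTYPE.*1")
})

test_that("insertion END convention and IMPRECISE flag survive writing", {
  calls <- sv_record(svtype = "INS", pos = 5000L, svlen = 90L, precise = FALSE)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sv_vcf(calls, path)
  line <- readLines(path)
  line <- line[!startsWith(line, "#")]
  expect_match(line, "SVTYPE=INS;SVLEN=90;END=5000")
  expect_match(line, "IMPRECISE")
  back <- read_sniffles_vcf(path, "s1")
  expect_equal(back$end, back$pos)
  expect_false(back$precise)
})

test_that("write-then-read is the identity on random call sets", {
  withr::local_seed(101)
  for (n in c(1, 20, 200)) {
    calls <- sort_calls <- random_callset(n, sample_id = "sampleX")
    path <- withr::local_tempfile(fileext = ".vcf")
    write_sv_vcf(calls, path)
    back <- read_sniffles_vcf(path, "sampleX")
    sorted <- dplyr::arrange(calls, chrom, pos, end, sv_id)
    expect_equal(as.data.frame(back), as.data.frame(sorted))
  }
})

test_that("records are returned sorted and line count is conserved", {
  calls <- dplyr::bind_rows(
    sv_record(pos = 9000L), sv_record(pos = 100L),
    sv_record(chrom = "C01", pos = 50L), sv_record(pos = 5000L)
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  # Write deliberately unsorted lines.
  header <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf(
    "%s\t%d\t%s\tN\t<DEL>\t.\tPASS\tPRECISE;SVTYPE=DEL;SVLEN=-%d;END=%d;RE=5;SUPTYPE=AL",
    calls$chrom, calls$pos, calls$sv_id, calls$svlen, calls$end
  )
  writeLines(c(header, body), path)
  back <- read_sniffles_vcf(path, "s1")
  expect_equal(nrow(back), nrow(calls))
  resorted <- dplyr::arrange(back, chrom, pos)
  expect_equal(back$pos, resorted$pos)
  expect_equal(back$chrom, resorted$chrom)
})

test_that("absent SUPTYPE is treated as SR and odd FILTER maps to UNRESOLVED", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "A01\t1000\t.\tN\t<DEL>\t.\tq5\tPRECISE;SVTYPE=DEL;SVLEN=-700;END=1700;RE=12"
  ), path)
  expect_warning(calls <- read_sniffles_vcf(path, "s1"), "UNRESOLVED")
  expect_equal(calls$support, "SR")
  expect_equal(calls$filter, "UNRESOLVED")
})

test_that("multi-sample VCF encodes presence as genotypes in sample order", {
  clusters <- tibble::tibble(
    cluster_id = "SVC000001", chrom = "A01", svtype = "DEL",
    rep_pos = 1000L, rep_end = 1700L, rep_len = 700L
  )
  presence <- tibble::tibble(
    cluster_id = "SVC000001",
    sample_id = c("s1", "s2", "s3"),
    present = c(TRUE, TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_multisample_vcf(clusters, presence, path, samples = c("s1", "s2", "s3"))
  line <- readLines(path)
  data <- line[!startsWith(line, "#")]
  fields <- strsplit(data, "\t")[[1]]
  expect_length(fields, 9 + 3)
  expect_equal(fields[10:12], c("1/1", "1/1", "0/0"))
  back <- read_multisample_vcf(path)
  expect_equal(back$presence$present, c(TRUE, TRUE, FALSE))
  expect_equal(back$clusters$rep_len, 700L)
})

test_that("zero clusters produce a header-only multi-sample file", {
  clusters <- tibble::tibble(
    cluster_id = character(), chrom = character(), svtype = character(),
    rep_pos = integer(), rep_end = integer(), rep_len = integer()
  )
  presence <- tibble::tibble(
    cluster_id = character(), sample_id = character(), present = logical()
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  write_multisample_vcf(clusters, presence, path, samples = c("s1", "s2"))
  lines <- readLines(path)
  expect_true(all(startsWith(lines, "#")))
})

test_that("presence grid mismatch is a consistency error", {
  clusters <- tibble::tibble(
    cluster_id = c("c1", "c2"), chrom = "A01", svtype = "DEL",
    rep_pos = c(1L, 2L), rep_end = c(10L, 20L), rep_len = c(10L, 19L)
  )
  presence <- tibble::tibble(
    cluster_id = "c1", sample_id = "s1", present = TRUE
  )
  expect_error(
    write_multisample_vcf(clusters, presence, tempfile()),
    "grid"
  )
})
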