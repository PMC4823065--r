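test_that("variant tables round-trip through TSV and preserve row order", {
  calls <- make_calls(3, pos = c(10L, 5L, 99L), gene = c("A", "B", "C"),
    var_reads = c(4L, 5L, 6L), ref_reads = c(10L, 11L, 12L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(calls, f)
  back <- read_variant_table(f)
  expect_equal(nrow(back), 3)
  expect_equal(back$pos, c(10L, 5L, 99L))
  expect_equal(back$gene, c("A", "B", "C"))
  # second write reproduces the file byte-identically
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("TSV readers enforce the schema and report parse errors by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  header <- paste(c(
    "sample_id", "chrom", "pos", "ref", "alt", "gene", "effect",
    "var_reads", "ref_reads", "mapping_quality", "base_quality"
  ), collapse = "\t")
  # header only -> empty table
  writeLines(header, f)
  expect_equal(nrow(read_variant_table(f)), 0)
  # NA read count -> parse error naming column and line
  writeLines(c(header,
    "S\tchr1\t100\tA\tG\tG1\tnonsynonymous\tNA\t10\t60\t30"), f)
  expect_error(read_variant_table(f), "var_reads.*line 1",
    class = "relapsekit_parse_error")
  # missing column -> schema error naming it
  writeLines(paste(c("sample_id", "chrom", "pos"), collapse = "\t"), f)
  expect_error(read_variant_table(f), "missing column.*ref",
    class = "relapsekit_schema_error")
  # extra column -> schema error naming it
  writeLines(c(paste(header, "bonus", sep = "\t")), f)
  expect_error(read_variant_table(f), "unexpected column.*bonus",
    class = "relapsekit_schema_error")
})

test_that("readcount tables require blast_pct exactly on tumor-stage rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "patient\tgene\taa_change\tstage\tblast_pct\tvar_reads\twt_reads"
  writeLines(c(hdr,
    "P1\tG1\tp.A1B\tdiagnosis\t90\t23\t18",
    "P1\tG1\tp.A1B\tCR\t\t0\t83"), f)
  rc <- read_readcount_table(f)
  expect_equal(rc$blast_pct, c(90, NA))
  writeLines(c(hdr, "P1\tG1\tp.A1B\tCR\t50\t0\t83"), f)
  expect_error(read_readcount_table(f), "CR rows",
    class = "relapsekit_value_error")
  writeLines(c(hdr, "P1\tG1\tp.A1B\tdiagnosis\t\t23\t18"), f)
  expect_error(read_readcount_table(f), "blast_pct",
    class = "relapsekit_value_error")
})

test_that("minimal VCF import maps AD and expands multi-allelic records", {
  skip_if_not_installed("vcfR")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t50\tPASS\tEFF=nonsynonymous\tGT:AD\t0/1:18,23",
    "chr2\t200\t.\tC\tT,G\t50\tPASS\tEFF=frameshift\tGT:AD\t1/2:10,5,7"
  ), f)
  calls <- import_vcf_minimal(f, "S1", effect_info_key = "EFF")
  expect_equal(nrow(calls), 3) # multi-allelic expanded to one row per ALT
  expect_equal(calls$ref_reads[1], 18L)
  expect_equal(calls$var_reads[1], 23L)
  expect_equal(calls$effect[1], "nonsynonymous")
  multi <- calls[calls$chrom == "chr2", ]
  expect_equal(multi$alt, c("T", "G"))
  expect_equal(multi$var_reads, c(5L, 7L))
  expect_equal(multi$ref_reads, c(10L, 10L))
  expect_equal(calls$pos, c(100L, 200L, 200L)) # 1-based positions preserved
  expect_error(import_vcf_minimal(f, "NOSUCH"), "not in VCF",
    class = "relapsekit_value_error")
  # record-less VCF -> empty call table
  f0 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1"
  ), f0)
  expect_equal(nrow(import_vcf_minimal(f0, "S1")), 0)
})

test_that("packaged study tables match their published row and gene counts", {
  t3 <- load_fixture("table3")
  expect_equal(nrow(t3), 75) # 25 confirmed mutations x 3 stages
  expect_equal(length(unique(paste(t3$patient, t3$gene, t3$aa_change))), 25)
  expect_setequal(unique(t3$patient), c("ALL001", "ALL002", "ALL003"))
  expect_equal(sum(t3$formula_discordant), 2)
  expect_true(all(is.na(t3$blast_pct[t3$stage == "CR"])))
  expect_true(all(!is.na(t3$blast_pct[t3$stage != "CR"])))
  expect_true(all(t3$source_table == "T3"))

  t2 <- load_fixture("table2")
  expect_equal(length(unique(t2$gene)), 10)
  expect_setequal(unique(t2$gene), c(
    "CREBBP", "KRAS", "PTPN21", "KDM6A", "USP54", "NR3C1", "MYC", "TBX21",
    "SETD2", "PAX5"
  ))
  expect_equal(attr(t2, "group_sizes"), c(relapsed = 31, non_relapsed = 30))
  # 13 mutated relapsed patients in the extension cohort, 4 non-relapsed listed
  ext <- t2[t2$cohort == "extension", ]
  expect_equal(length(unique(ext$patient[ext$group == "relapsed"])), 13)
  expect_equal(length(unique(ext$patient[ext$group == "non_relapsed"])), 4)

  t1 <- load_fixture("table1")
  all001 <- t1[t1$patient == "ALL001", ]
  expect_equal(sum(all001$category == "shared"), 7)
  expect_equal(sum(all001$category != "shared"), 0)
  expect_error(load_fixture("table9"))
})
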