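test_that("trimming removes shared allele sequence and flags identities", {
  v <- trim_spdi(spdi_variant("S.1", 10, "AC", "AG"))
  expect_identical(c(v$position, v$deleted, v$inserted), c("11", "C", "G"))
  v <- trim_spdi(spdi_variant("S.1", 10, "G", "A"))
  expect_identical(c(v$position, v$deleted, v$inserted), c("10", "G", "A"))
  id <- trim_spdi(spdi_variant("S.1", 10, "T", "T"))
  expect_true(is_identity_variant(id))
  # suffix trimming: TAC -> TGC shares T prefix and C suffix
  v <- trim_spdi(spdi_variant("S.1", 5, "TAC", "TGC"))
  expect_identical(c(v$position, v$deleted, v$inserted), c("6", "A", "G"))
  # idempotent
  expect_identical(trim_spdi(v), v)
})

test_that("rolling reproduces the published homopolymer placements", {
  del <- parse_spdi("NC_000007.14:117548628:T:")
  r <- roll_right(del, suite$catalog)
  expect_identical(r$position, 117548634)
  expect_identical(r$deleted, "T")
  l <- roll_left(parse_spdi("NC_000007.14:117548634:T:"), suite$catalog)
  expect_identical(l$position, 117548628)
  # idempotence
  expect_identical(roll_right(r, suite$catalog), r)
  expect_identical(roll_left(l, suite$catalog), l)
})

test_that("justification extent matches brute-force placement enumeration", {
  seg <- "GACGCATTTTTTTAGC"; origin <- 117548622
  ext <- justification_extent(parse_spdi("NC_000007.14:117548628:T:"),
                              suite$catalog)
  hits <- oracle_del_placements(seg, origin, 117548628, "T")
  expect_identical(ext$left_most, min(hits))
  expect_identical(ext$right_most, max(hits) + 1)
  expect_identical(ext$repeat_context, "TTTTTTT")

  # substitution: own single-base interval
  se <- justification_extent(parse_spdi("NC_000019.9:11200235:G:A"),
                             suite$catalog)
  expect_identical(c(se$left_most, se$right_most), c(11200235, 11200236))

  # non-repetitive deletion: extent equals its own span
  cat2 <- mini_catalog("NC_NR.1", 0, "GATCCAGT")
  ne <- justification_extent(spdi_variant("NC_NR.1", 3, "CC", ""), cat2)
  expect_identical(c(ne$left_most, ne$right_most), c(3, 5))

  # seeded random repeats, deletions and insertions, against the oracle
  set.seed(31)
  for (i in 1:40) {
    unit <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                         replace = TRUE), collapse = "")
    seqs <- paste0("GCX", strrep(unit, sample(2:5, 1)), "XCG")
    seqs <- chartr("X", setdiff(c("A", "C", "G", "T"),
                                c(substr(unit, 1, 1),
                                  substr(unit, nchar(unit), nchar(unit))))[1],
                   seqs)
    acc <- sprintf("NC_J%03d.1", i)
    ctl <- mini_catalog(acc, 0, seqs)
    ext <- justification_extent(spdi_variant(acc, 3, unit, ""), ctl)
    hits <- oracle_del_placements(seqs, 0, 3, unit)
    expect_identical(ext$left_most, min(hits))
    expect_identical(ext$right_most, max(hits) + nchar(unit))
    exti <- justification_extent(spdi_variant(acc, 3, "", unit), ctl)
    ihits <- oracle_ins_placements(seqs, 0, 3, unit)
    expect_identical(exti$left_most, min(ihits))
    expect_identical(exti$right_most, max(ihits))
  }
})

test_that("full justification yields the canonical form from any placement", {
  canon <- fully_justify(parse_spdi("NC_000007.14:117548634:T:"),
                         suite$catalog)
  expect_identical(format_spdi(canon),
                   "NC_000007.14:117548628:TTTTTTT:TTTTTT")
  for (p in 117548628:117548634)
    expect_identical(
      format_spdi(fully_justify(spdi_variant("NC_000007.14", p, "T", ""),
                                suite$catalog)),
      "NC_000007.14:117548628:TTTTTTT:TTTTTT")
  # idempotent on its own output
  expect_identical(fully_justify(canon, suite$catalog), canon)
  # substitutions are their own canonical form, with no catalog required
  sub <- parse_spdi("NC_000019.9:11200235:G:A")
  expect_identical(fully_justify(sub, suite$catalog), trim_spdi(sub))
  expect_identical(format_spdi(fully_justify(sub)), format_spdi(sub))
  # delins with no rollable unit returns the trimmed form unchanged
  cat2 <- mini_catalog("NC_NR.1", 0, "GATCCAGT")
  di <- spdi_variant("NC_NR.1", 3, "CC", "TG")
  expect_identical(fully_justify(di, cat2), trim_spdi(di))
})

test_that("insertions in repeat context expand like deletions", {
  # inserting one T into the seven-T run: extent is the whole run
  ins <- spdi_variant("NC_000007.14", 117548630, "", "T")
  canon <- fully_justify(ins, suite$catalog)
  expect_identical(format_spdi(canon),
                   "NC_000007.14:117548628:TTTTTTT:TTTTTTTT")
  # any placement in the run maps to the same canonical form
  for (p in 117548628:117548635)
    expect_identical(fully_justify(spdi_variant("NC_000007.14", p, "", "T"),
                                   suite$catalog), canon)
})

test_that("rolling across N raises ambiguous-context, not a silent stop", {
  ctn <- mini_catalog("NC_N.1", 0, "GGTTNTTAA")
  expect_error(roll_right(spdi_variant("NC_N.1", 2, "T", ""), ctn),
               class = "gn_ambiguous_context")
  expect_error(fully_justify(spdi_variant("NC_N.1", 5, "T", ""), ctn),
               class = "gn_ambiguous_context")
  # rolling that never reaches the N is fine
  expect_identical(roll_left(spdi_variant("NC_N.1", 8, "A", ""), ctn)$position, 7)
})

test_that("HGVS -> SPDI reproduces the published conversions", {
  expect_identical(
    format_spdi(hgvs_g_to_spdi(parse_hgvs("NC_000019.9:g.11200236G>A"),
                               suite$catalog)),
    "NC_000019.9:11200235:G:A")
  expect_identical(
    format_spdi(hgvs_g_to_spdi(parse_hgvs("NC_000005.10:g.112766335A>T"),
                               suite$catalog)),
    "NC_000005.10:112766334:A:T")
  expect_identical(
    format_spdi(hgvs_g_to_spdi(parse_hgvs("NC_000005.9:g.112102032A>T"),
                               suite$catalog)),
    "NC_000005.9:112102031:A:T")
  # interbase insertion convention
  ctl <- mini_catalog("NC_I.1", 0, "GATCCAGTAA")
  v <- hgvs_g_to_spdi(parse_hgvs("NC_I.1:g.5_6insT"), ctl)
  expect_identical(c(v$position, v$deleted, v$inserted), c("5", "", "T"))
})

test_that("stated reference alleles are validated when covered, trusted when not", {
  expect_error(
    hgvs_g_to_spdi(parse_hgvs("NC_000019.9:g.11200236C>A"), suite$catalog),
    class = "gn_reference_disagreement")
  # uncovered substitution: stated ref trusted in auto mode
  v <- hgvs_g_to_spdi(parse_hgvs("NC_000019.9:g.999G>A"), suite$catalog)
  expect_identical(v$position, 998)
  expect_error(
    hgvs_g_to_spdi(parse_hgvs("NC_000019.9:g.999G>A"), suite$catalog,
                   validate = "always"),
    class = "gn_coverage_error")
  # indel justification always requires context
  expect_error(
    hgvs_g_to_spdi(parse_hgvs("NC_000019.9:g.999del"), suite$catalog),
    class = "gn_coverage_error")
})

test_that("SPDI -> HGVS places indels 3'-most and detects duplications", {
  expect_identical(
    format_hgvs(spdi_to_hgvs_g(parse_spdi("NC_000019.9:11200235:G:A"),
                               suite$catalog)),
    "NC_000019.9:g.11200236G>A")
  expect_identical(
    format_hgvs(spdi_to_hgvs_g(parse_spdi("NC_000005.9:112102031:A:T"),
                               suite$catalog)),
    "NC_000005.9:g.112102032A>T")
  # canonical homopolymer deletion: 3'-most single-base del. The deleted
  # base is the last T of the run at 0-based 117548634, i.e. 1-based
  # 117548635 (brute-force check below).
  canon <- parse_spdi("NC_000007.14:117548628:TTTTTTT:TTTTTT")
  hv <- spdi_to_hgvs_g(canon, suite$catalog)
  expect_identical(format_hgvs(hv), "NC_000007.14:g.117548635del")
  hits <- oracle_del_placements("GACGCATTTTTTTAGC", 117548622, 117548628, "T")
  expect_identical(hv$start, max(hits) + 1)
  # insertion equal to the 5'-adjacent span is spelled dup
  ctl <- mini_catalog("NC_D.1", 0, "GATCCAGT")
  dup <- spdi_to_hgvs_g(spdi_variant("NC_D.1", 6, "", "CA"), ctl)
  expect_identical(format_hgvs(dup), "NC_D.1:g.5_6dup")
  # a genuinely novel insertion stays ins
  ins <- spdi_to_hgvs_g(spdi_variant("NC_D.1", 5, "", "TT"), ctl)
  expect_identical(format_hgvs(ins), "NC_D.1:g.5_6insTT")
})

test_that("HGVS and SPDI substitution conversion are mutually inverse", {
  set.seed(41)
  for (i in 1:100) {
    pos <- sample(1:1e6, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    hv <- hgvs_g_variant("NC_R.1", "sub", pos, pos, ref, alt)
    sp <- hgvs_g_to_spdi(hv)   # no catalog: trust stated ref
    expect_identical(sp$position, pos - 1)
    expect_identical(format_hgvs(spdi_to_hgvs_g(sp)), format_hgvs(hv))
  }
})

test_that("VCF rows convert through anchor-base trimming", {
  v <- vcf_row_to_spdi("NC_000019.9", 11200236, "G", "A")
  expect_identical(format_spdi(v), "NC_000019.9:11200235:G:A")
  d <- vcf_row_to_spdi("NC_X.1", 100, "AT", "A")
  expect_identical(c(d$position, d$deleted, d$inserted), c("100", "T", ""))
  expect_error(vcf_row_to_spdi("NC_X.1", 100, "<DEL>", "A"),
               class = "gn_unsupported_syntax")
  expect_error(vcf_row_to_spdi("NC_X.1", 100, "A", "A]3:100]"),
               class = "gn_unsupported_syntax")

  # file reader with contig map and multi-allelic split
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "mini.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT",
               "fix1\t122\t.\tG\tA,C"), vcf)
  vars <- read_vcf_variants(vcf, suite$contig_map, build = "fixture37")
  expect_length(vars, 2)
  expect_identical(format_spdi(vars[[1]]), "NC_FX0001.37:121:G:A")
  expect_identical(format_spdi(vars[[2]]), "NC_FX0001.37:121:G:C")
  expect_error(read_vcf_variants(vcf, data.frame(chrom = "other",
                                                 accession = "X.1")),
               class = "gn_not_found")
})
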