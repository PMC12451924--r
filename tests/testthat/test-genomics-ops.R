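SNOMED <- "http://snomed.info/sct"
DO <- "https://disease-ontology.org/"

fresh_store <- function() {
  st <- genomics_store()
  ingest_patient_variants(st, "m123", suite$demo$transcript_hgvs,
                          suite$alignments, suite$catalog)
  ingest_patient_hla(st, "m123", "DRB1*13:AKBAR", suite$hla_db)
  st
}

test_that("ingestion stores raw next to normalization, with statuses", {
  st <- genomics_store()
  rep1 <- ingest_patient_variants(st, "s1",
                                  c(suite$demo$transcript_hgvs, "garbage!!"),
                                  suite$alignments, suite$catalog)
  expect_identical(rep1$status[1], "ok")
  expect_match(rep1$status[2], "gn_parse_error")
  entries <- st$patients[["s1"]]$variants
  expect_length(entries, 2)
  expect_identical(entries[[2]]$raw, "garbage!!")   # raw survives failure
  expect_null(entries[[2]]$bundle)

  rep2 <- ingest_patient_hla(st, "s1", c("DRB1*13:AKBAR", "Bw4"),
                             suite$hla_db)
  expect_identical(rep2$status[1], "ok")
  expect_match(rep2$status[2], "gn_unsupported_syntax")
  expect_identical(st$patients[["s1"]]$hla[[1]]$lgx,
                   "DRB1*13:02/DRB1*13:36/DRB1*13:67/DRB1*13:96/DRB1*13:109")
  expect_identical(st$patients[["s1"]]$hla[[2]]$raw, "Bw4")
  expect_true(is.na(st$patients[["s1"]]$hla[[2]]$lgx))

  # duplicate ingestion is idempotent
  ingest_patient_variants(st, "s1", suite$demo$transcript_hgvs,
                          suite$alignments, suite$catalog)
  ingest_patient_hla(st, "s1", "DRB1*13:AKBAR", suite$hla_db)
  expect_length(st$patients[["s1"]]$variants, 2)
  expect_length(st$patients[["s1"]]$hla, 2)
})

test_that("a variant ingested once is found under every spelling", {
  st <- fresh_store()
  spellings <- c(suite$demo$transcript_hgvs, suite$demo$b37_hgvs,
                 suite$demo$b38_hgvs, suite$demo$b37_spdi,
                 suite$demo$b38_spdi)
  res <- find_subject_specific_variants(st, "m123", spellings,
                                        suite$alignments, suite$catalog)
  for (r in res) {
    expect_true(r$present)
    expect_identical(r$status, "ok")
  }
  expect_identical(vapply(res, function(r) r$raw, ""), spellings)

  # the VCF spelling reaches the same canonical key
  vr <- suite$demo$vcf_row
  vs <- format_spdi(vcf_row_to_spdi("NC_FX0001.37", vr$pos, vr$ref, vr$alt))
  rv <- find_subject_specific_variants(st, "m123", vs, suite$alignments,
                                       suite$catalog)
  expect_true(rv[[1]]$present)

  # an absent variant reports present = FALSE
  ref50 <- get_slice(suite$catalog, "NC_FX0001.37", 130, 131)
  alt50 <- setdiff(c("A", "C", "G", "T"), ref50)[1]
  ra <- find_subject_specific_variants(
    st, "m123", sprintf("NC_FX0001.37:g.131%s>%s", ref50, alt50),
    suite$alignments, suite$catalog)
  expect_false(ra[[1]]$present)

  # per-item errors leave other items answered
  mixed <- find_subject_specific_variants(
    st, "m123", c("NG_009060.1:g.5180G>A", suite$demo$b37_spdi),
    suite$alignments, suite$catalog)
  expect_match(mixed[[1]]$status, "gn_unsupported_reference")
  expect_true(is.na(mixed[[1]]$present))
  expect_true(mixed[[2]]$present)

  expect_error(find_subject_specific_variants(st, "nobody", "x",
                                              suite$alignments,
                                              suite$catalog),
               class = "gn_not_found")
})

test_that("population haplotype queries match every published spelling", {
  st <- fresh_store()
  res <- find_population_specific_haplotypes(
    st, c("DRB1*13:AKBAR", "DRB1*13:36", "DRB1*13:02:01:02"),
    include_patient_list = TRUE, db = suite$hla_db)
  for (r in res) {
    expect_identical(r$count, 1L)
    expect_identical(r$subjects, "m123")
  }
  none <- find_population_specific_haplotypes(st, "B*57:01",
                                              include_patient_list = TRUE,
                                              db = suite$hla_db)
  expect_identical(none[[1]]$count, 0L)
  bare <- find_population_specific_haplotypes(st, "DRB1*13:36",
                                              db = suite$hla_db)
  expect_null(bare[[1]]$subjects)
})

test_that("therapeutic implications match through terminology expansion", {
  st <- suite$store
  by_snomed <- find_subject_tx_implications(
    st, suite$knowledge, "CA12345", variants = suite$demo$transcript_hgvs,
    conditions = data.frame(system = SNOMED, code = "1259727001"),
    registry = suite$concept_maps, db = suite$alignments,
    catalog = suite$catalog)
  by_doid <- find_subject_tx_implications(
    st, suite$knowledge, "CA12345", variants = suite$demo$transcript_hgvs,
    conditions = data.frame(system = DO, code = "DOID : 3908"),
    registry = suite$concept_maps, db = suite$alignments,
    catalog = suite$catalog)
  expect_length(by_snomed, 1)
  expect_identical(by_snomed, by_doid)

  # translation never reduces results: expanded set superset of native-only
  no_map <- find_subject_tx_implications(
    st, suite$knowledge, "CA12345", variants = suite$demo$transcript_hgvs,
    conditions = data.frame(system = SNOMED, code = "1259727001"),
    registry = concept_map_registry(), db = suite$alignments,
    catalog = suite$catalog)
  expect_true(length(by_snomed) >= length(no_map))

  # untranslatable condition with no native match: empty
  miss <- find_subject_tx_implications(
    st, suite$knowledge, "CA12345", variants = suite$demo$transcript_hgvs,
    conditions = data.frame(system = SNOMED, code = "999000"),
    registry = suite$concept_maps, db = suite$alignments,
    catalog = suite$catalog)
  expect_length(miss, 0)

  # query variant absent from the patient: empty
  ref50 <- get_slice(suite$catalog, "NC_FX0001.37", 130, 131)
  alt50 <- setdiff(c("A", "C", "G", "T"), ref50)[1]
  other <- find_subject_tx_implications(
    st, suite$knowledge, "CA12345",
    variants = sprintf("NC_FX0001.37:g.131%s>%s", ref50, alt50),
    conditions = data.frame(system = SNOMED, code = "1259727001"),
    registry = suite$concept_maps, db = suite$alignments,
    catalog = suite$catalog)
  expect_length(other, 0)

  expect_error(find_subject_tx_implications(
    st, suite$knowledge, "nobody", conditions = data.frame(
      system = SNOMED, code = "1259727001"),
    registry = suite$concept_maps, db = suite$alignments,
    catalog = suite$catalog), class = "gn_not_found")
})

test_that("store snapshots expose raw strings unchanged", {
  st <- fresh_store()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "store.json")
  write_store_snapshot(st, path)
  snap <- jsonlite::read_json(path)
  expect_identical(snap$m123$variants[[1]]$raw, suite$demo$transcript_hgvs)
  expect_identical(snap$m123$hla[[1]]$raw, "DRB1*13:AKBAR")
  expect_identical(snap$m123$variants[[1]]$fields$b38SPDI,
                   "NC_FX0001.38:171:G:A")
})
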