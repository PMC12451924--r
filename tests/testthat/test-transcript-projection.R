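# Shared toy alignments from the fixture suite:
#   NM_FIX1.1 (+): exons g 100-200 / 250-350 / 400-500 <-> t 0-300, cds 10
#   NM_FIX2.1 (-): exons g 600-660 / 520-580 (transcript order), cds 5
aln1_37 <- function() transcript_alignments(suite$alignments, "NM_FIX1.1")[["fixture37"]]
aln1_38 <- function() transcript_alignments(suite$alignments, "NM_FIX1.1")[["fixture38"]]
aln2_37 <- function() transcript_alignments(suite$alignments, "NM_FIX2.1")[["fixture37"]]

# Re-derive the transcript sequence from the genome by splicing; used as the
# projection oracle (mutate one side, compare to mutating the other).
splice_oracle <- function(aln, gseq) {
  b <- aln$blocks
  parts <- vapply(seq_len(nrow(b)), function(i)
    substr(gseq, b$g_start[i] + 1, b$g_end[i]), "")
  if (aln$strand == "-") parts <- vapply(parts, oracle_revcomp, "")
  paste(parts, collapse = "")
}

test_that("CDS positions resolve through the exon map", {
  a <- aln1_37()
  r <- cds_to_transcript(cds_position(1), a)
  expect_identical(r$kind, "exonic")
  expect_identical(r$t_offset, 10)       # cds_start + 1 - 1
  expect_identical(r$genomic, 110)

  # intronic: exon 1 ends at g 200 (half-open); its last base is g 199,
  # c.90; c.90+2 sits two bases into the intron, 0-based genomic 201
  ri <- cds_to_transcript(cds_position(90, 2), a)
  expect_identical(ri$kind, "intronic")
  expect_identical(ri$genomic, 201)

  expect_error(cds_to_transcript(cds_position(5000), a),
               class = "gn_out_of_transcript")
  # an "intronic" offset that lands on exon sequence is rejected
  expect_error(cds_to_transcript(cds_position(50, 2), a),
               class = "gn_validation_error")
})

test_that("projection preserves the sequence change on both strands", {
  gseq37 <- get_slice(suite$catalog, "NC_FX0001.37", 0, 700)
  set.seed(51)
  for (aln in list(aln1_37(), aln2_37())) {
    tseq <- splice_oracle(aln, gseq37)
    n_cds <- aln$t_length - aln$cds_start
    for (i in 1:25) {
      base <- sample(seq_len(n_cds), 1)
      t <- aln$cds_start + base - 1
      ref <- substr(tseq, t + 1, t + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      cv <- hgvs_c_variant(aln$transcript_accession, "sub",
                           cds_position(base), cds_position(base), ref, alt)
      gv <- project_c_to_g(cv, aln)
      # oracle: mutate the genome, re-splice, compare to mutating the
      # transcript directly
      gmut <- oracle_apply(gseq37, 0, gv$start - 1, gv$ref, gv$alt)
      expect_false(is.null(gmut))
      tmut_direct <- oracle_apply(tseq, 0, t, ref, alt)
      expect_identical(splice_oracle(aln, gmut), tmut_direct)
    }
  }
})

test_that("genomic-to-transcript projection inverts c.-to-g on both strands", {
  set.seed(52)
  for (aln in list(aln1_37(), aln2_37())) {
    n_cds <- aln$t_length - aln$cds_start
    for (i in 1:25) {
      base <- sample(seq_len(n_cds), 1)
      cv <- hgvs_c_variant(aln$transcript_accession, "sub",
                           cds_position(base), cds_position(base), "A", "C")
      gv <- project_c_to_g(cv, aln)
      back <- project_g_to_c(gv, aln)
      expect_identical(format_hgvs(back), format_hgvs(cv))
    }
  }
  # intronic positions come back with nearest-exon offsets
  a <- aln1_37()
  for (off in c(1, 2, -2, -1)) {
    cv <- hgvs_c_variant("NM_FIX1.1", "sub",
                         cds_position(if (off > 0) 90 else 91, off),
                         cds_position(if (off > 0) 90 else 91, off),
                         "A", "C")
    gv <- project_c_to_g(cv, a)
    expect_identical(format_hgvs(project_g_to_c(gv, a)), format_hgvs(cv))
  }
})

test_that("edits spanning an exon junction are rejected", {
  a <- aln1_37()
  # c.90 is the last base of exon 1, c.91 the first of exon 2
  cv <- hgvs_c_variant("NM_FIX1.1", "del", cds_position(90),
                       cds_position(91))
  expect_error(project_c_to_g(cv, a), class = "gn_junction_unsupported")
  gv <- hgvs_g_variant("NC_FX0001.37", "del", 195, 255)
  expect_error(project_g_to_c(gv, a), class = "gn_junction_unsupported")
  # but an exon-edge + adjacent-intron deletion is supported
  ok <- hgvs_c_variant("NM_FIX1.1", "del", cds_position(90),
                       cds_position(90, 1))
  gok <- project_c_to_g(ok, a)
  expect_identical(c(gok$start, gok$end), c(200, 201))
  # upstream of the transcript: projection gap
  expect_error(project_g_to_c(hgvs_g_variant("NC_FX0001.37", "sub", 50, 50,
                                             "A", "C"), a),
               class = "gn_projection_gap")
})

test_that("transcript selection prefers MANE, then overlap, then accession", {
  gv <- hgvs_g_variant("NC_FX0001.37", "sub", 122, 122, "G", "A")
  sel <- select_transcript(gv, suite$alignments)
  expect_identical(sel$transcript_accession, "NM_FIX1.1")  # MANE beats FIX3
  expect_error(select_transcript(hgvs_g_variant("NC_FX0001.37", "sub", 50,
                                                50, "A", "C"),
                                 suite$alignments),
               class = "gn_no_transcript")
  # no MANE anywhere: lexicographically smaller accession wins the tie
  b <- data.frame(g_start = 0, g_end = 100, t_start = 0, t_end = 100)
  db2 <- alignment_db(list(
    transcript_alignment("NM_B.1", "NC_T.1", "fixture37", "+", b, 0),
    transcript_alignment("NM_A.1", "NC_T.1", "fixture37", "+", b, 0)))
  pick <- select_transcript(hgvs_g_variant("NC_T.1", "sub", 10, 10, "A", "C"),
                            db2)
  expect_identical(pick$transcript_accession, "NM_A.1")
})

test_that("alignment database JSON round-trips with invariants enforced", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "aln.json")
  write_alignment_db(suite$alignments, path)
  back <- read_alignment_db(path)
  expect_length(back$alignments, length(suite$alignments$alignments))
  a0 <- aln1_37(); a1 <- transcript_alignments(back, "NM_FIX1.1")[["fixture37"]]
  expect_identical(a1$blocks$g_start, a0$blocks$g_start)
  expect_identical(a1$strand, a0$strand)
  expect_identical(a1$cds_start, a0$cds_start)
  # invariant violations refuse to construct
  bad <- data.frame(g_start = 0, g_end = 10, t_start = 0, t_end = 5)
  expect_error(transcript_alignment("NM_X.1", "NC_T.1", "b", "+", bad, 0),
               class = "gn_validation_error")
})

test_that("the bundle pipeline emits all four fields for fixture variants", {
  b <- normalize_variant_bundle("NM_FIX1.1:c.12G>A", suite$alignments,
                                suite$catalog)
  expect_identical(unlist(b$status, use.names = FALSE), rep("ok", 4))
  expect_identical(b$fields$b37SPDI, "NC_FX0001.37:121:G:A")
  expect_identical(b$fields$b38SPDI, "NC_FX0001.38:171:G:A")
  expect_identical(b$fields$b37HGVS, "NC_FX0001.37:g.122G>A")
  expect_identical(b$fields$b38HGVS, "NC_FX0001.38:g.172G>A")
  expect_identical(b$raw, "NM_FIX1.1:c.12G>A")

  # SPDI fields are fully justified: run the planted exon-2 homopolymer
  # deletion through the pipeline (TTTTT at g37 300-305)
  bd <- normalize_variant_bundle("NC_FX0001.37:g.302del", suite$alignments,
                                 suite$catalog)
  expect_identical(bd$fields$b37SPDI, "NC_FX0001.37:300:TTTTT:TTTT")
  expect_identical(bd$fields$b38SPDI, "NC_FX0001.38:350:TTTTT:TTTT")
  expect_identical(bd$fields$b37HGVS, "NC_FX0001.37:g.305del")  # 3'-most
})

test_that("every spelling of one variant produces the identical bundle", {
  ref <- normalize_variant_bundle(suite$demo$transcript_hgvs,
                                  suite$alignments, suite$catalog)
  for (sp in c(suite$demo$b37_hgvs, suite$demo$b38_hgvs,
               suite$demo$b37_spdi, suite$demo$b38_spdi)) {
    b <- normalize_variant_bundle(sp, suite$alignments, suite$catalog)
    expect_identical(b$fields, ref$fields)
    expect_identical(b$raw, sp)   # raw input echoed unchanged
  }
  vr <- suite$demo$vcf_row
  vspdi <- vcf_row_to_spdi("NC_FX0001.37", vr$pos, vr$ref, vr$alt)
  bv <- normalize_variant_bundle(format_spdi(vspdi), suite$alignments,
                                 suite$catalog)
  expect_identical(bv$fields, ref$fields)
})

test_that("bundle failures are per-field with taxonomy reasons, never silent", {
  # chromosome variant with no overlapping transcript: same-build ok
  ref50 <- get_slice(suite$catalog, "NC_FX0001.37", 50, 51)
  alt50 <- setdiff(c("A", "C", "G", "T"), ref50)[1]
  b <- normalize_variant_bundle(sprintf("NC_FX0001.37:g.51%s>%s", ref50, alt50),
                                suite$alignments, suite$catalog)
  expect_identical(b$status$b37SPDI, "ok")
  expect_identical(b$status$b38SPDI, "no transcript alignment")
  expect_identical(b$status$b38HGVS, "no transcript alignment")
  expect_true(is.na(b$fields$b38SPDI))

  # unknown transcript: bundle-level failure
  b2 <- normalize_variant_bundle("NM_unknown.9:c.1A>G", suite$alignments,
                                 suite$catalog)
  expect_identical(b2$failure, "transcript not in alignment database")
  expect_true(all(unlist(b2$status) == b2$failure))

  # totally unparseable input raises
  expect_error(normalize_variant_bundle("hello", suite$alignments,
                                        suite$catalog),
               class = "gn_parse_error")
})

test_that("liftover through the shared transcript round-trips", {
  start <- normalize_variant_bundle(suite$demo$b37_hgvs, suite$alignments,
                                    suite$catalog)
  lifted <- normalize_variant_bundle(start$fields$b38HGVS, suite$alignments,
                                     suite$catalog)
  expect_identical(lifted$fields, start$fields)
  back <- normalize_variant_bundle(lifted$fields$b37HGVS, suite$alignments,
                                   suite$catalog)
  expect_identical(back$fields, start$fields)
})
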