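# Deterministic fixture builders. Content anchored to published coordinates uses real
# accession names with sparse segments (only the bases the examples need);
# purely synthetic content uses clearly fake names (FX_/FXEQ_/NM_FIX
# accessions, fixture37/fixture38 build labels) so no invented coordinate
# is mistaken for a real genome position. Building twice with the same
# seed yields byte-identical fixtures.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

.set_base <- function(seq, idx0, base) {  # idx0: 0-based
  substr(seq, idx0 + 1, idx0 + 1) <- base
  seq
}

# Apply an SPDI edit to a plain sequence string whose first base sits at
# interbase offset `origin` (deletion must match).
.apply_edit <- function(seq, origin, pos, deleted, inserted) {
  i <- pos - origin
  stopifnot(substr(seq, i + 1, i + nchar(deleted)) == deleted)
  paste0(substr(seq, 1, i), inserted,
         substr(seq, i + nchar(deleted) + 1, nchar(seq)))
}

#' Build the deterministic fixture suite
#'
#' Aggregates every fixture the package's pipelines need:
#' \itemize{
#'   \item sparse segments for the real accessions of the worked examples
#'     (the seven-T homopolymer of `NC_000007.14` at interbase
#'     117548628-117548635 with non-T flanks, and the substitution contexts
#'     on `NC_000019.9/.10` and `NC_000005.9/.10`);
#'   \item two toy chromosomes `NC_FX0001.37`/`NC_FX0001.38` (builds
#'     `fixture37`/`fixture38`) differing by a 50-base offset, with a forced
#'     `G` at the demo-variant position and a planted `TTTTT` homopolymer
#'     inside exon 2;
#'   \item toy transcripts aligned to both builds on both strands
#'     (`NM_FIX1.1` +, MANE; `NM_FIX2.1` -; `NM_FIX3.1` +, non-MANE,
#'     overlapping `NM_FIX1.1`);
#'   \item an HLA allele-group database seeded from the published DRB1*13
#'     expansion lists plus A and B locus group examples;
#'   \item concept maps (SNOMED/ICD10CM to Disease Ontology and MedGen,
#'     RxNorm to NCIt); non-published codes are synthetic placeholders;
#'   \item a patient store (`m123`, `CA12345`) and a toy knowledge base.
#' }
#'
#' @param seed integer seed; the suite is a pure function of it.
#' @return A list of class `fixture_suite` with elements `catalog`,
#'   `alignments`, `hla_db`, `concept_maps`, `store`, `knowledge`,
#'   `contig_map` and `demo` (equivalent spellings of the demo variant).
#' @export
build_fixture_suite <- function(seed = 1L) {
  .with_seed(seed, {
    catalog <- seq_catalog()

    # --- sparse segments at published coordinates ------------------------------------
    catalog <- register_segment(catalog, "NC_000007.14", 117548622,
                                "GACGCATTTTTTTAGC", build = "GRCh38",
                                chromosome = "7")
    catalog <- register_segment(catalog, "NC_000019.9", 11200230,
                                "CATGCGATCG", build = "GRCh37",
                                chromosome = "19")
    catalog <- register_segment(catalog, "NC_000019.10", 11089554,
                                "CATGCGATCG", build = "GRCh38",
                                chromosome = "19")
    catalog <- register_segment(catalog, "NC_000005.9", 112102026,
                                "TGCATAGGCT", build = "GRCh37",
                                chromosome = "5")
    catalog <- register_segment(catalog, "NC_000005.10", 112766329,
                                "TGCATAGGCT", build = "GRCh38",
                                chromosome = "5")

    # --- toy builds ---------------------------------------------------------
    core <- .rand_bases(700)
    core <- .set_base(core, 121, "G")            # demo substitution ref base
    for (i in 300:304) core <- .set_base(core, i, "T")  # exon-2 homopolymer
    core <- .set_base(core, 299, "A")
    core <- .set_base(core, 305, "C")
    seq37 <- core
    seq38 <- paste0(.rand_bases(50), core)        # build offset +50
    catalog <- register_segment(catalog, "NC_FX0001.37", 0, seq37,
                                build = "fixture37", chromosome = "fix1")
    catalog <- register_segment(catalog, "NC_FX0001.38", 0, seq38,
                                build = "fixture38", chromosome = "fix1")

    blocks1 <- data.frame(g_start = c(100, 250, 400),
                          g_end   = c(200, 350, 500),
                          t_start = c(0, 100, 200),
                          t_end   = c(100, 200, 300))
    shift <- function(b, k) { b$g_start <- b$g_start + k; b$g_end <- b$g_end + k; b }
    blocks2 <- data.frame(g_start = c(600, 520), g_end = c(660, 580),
                          t_start = c(0, 60), t_end = c(60, 120))
    blocks3 <- data.frame(g_start = 90, g_end = 490, t_start = 0, t_end = 400)
    alignments <- alignment_db(list(
      transcript_alignment("NM_FIX1.1", "NC_FX0001.37", "fixture37", "+",
                           blocks1, cds_start = 10, mane = TRUE),
      transcript_alignment("NM_FIX1.1", "NC_FX0001.38", "fixture38", "+",
                           shift(blocks1, 50), cds_start = 10, mane = TRUE),
      transcript_alignment("NM_FIX2.1", "NC_FX0001.37", "fixture37", "-",
                           blocks2, cds_start = 5, mane = TRUE),
      transcript_alignment("NM_FIX2.1", "NC_FX0001.38", "fixture38", "-",
                           shift(blocks2, 50), cds_start = 5, mane = TRUE),
      transcript_alignment("NM_FIX3.1", "NC_FX0001.37", "fixture37", "+",
                           blocks3, cds_start = 0, mane = FALSE),
      transcript_alignment("NM_FIX3.1", "NC_FX0001.38", "fixture38", "+",
                           shift(blocks3, 50), cds_start = 0, mane = FALSE)))

    # spliced transcript sequences (reverse-complemented on -)
    splice <- function(blocks, seq, neg = FALSE) {
      parts <- vapply(seq_len(nrow(blocks)), function(i)
        substr(seq, blocks$g_start[i] + 1, blocks$g_end[i]), "")
      if (neg) parts <- vapply(parts, .revcomp, "")
      paste(parts, collapse = "")
    }
    catalog <- register_segment(catalog, "NM_FIX1.1", 0,
                                splice(blocks1, seq37), build = "fixture")
    catalog <- register_segment(catalog, "NM_FIX2.1", 0,
                                splice(blocks2, seq37, neg = TRUE),
                                build = "fixture")

    # --- HLA allele-group database -----------------------------------------
    drb_13_02 <- c(sprintf("DRB1*13:02:01:%02d", 1:14),
                   sprintf("DRB1*13:02:%02d", 2:22))
    drb_13_96 <- c("DRB1*13:96:01", "DRB1*13:96:02")
    a_01_01 <- c("A*01:01:01:01", "A*01:01:01:02")
    a_01_23 <- c("A*01:23:01", "A*01:23:02")
    a_01_69 <- c("A*01:69:01", "A*01:69:02", "A*01:69:03")
    b_15 <- c("B*15:01:01", "B*15:01:03", "B*15:04", "B*15:07",
              "B*15:26N", "B*15:27")
    hla_db <- allele_group_db(
      alleles = c(drb_13_02, "DRB1*13:36", "DRB1*13:67", drb_13_96,
                  "DRB1*13:109", a_01_01, a_01_23, a_01_69, b_15),
      g_groups = list("DRB1*13:02:01G" = drb_13_02,
                      "A*01:01:01G" = a_01_01,
                      "A*01:23:01G" = a_01_23),
      p_groups = list("DRB1*13:02P" = drb_13_02,
                      "DRB1*13:96P" = drb_13_96,
                      "A*01:69P" = a_01_69),
      serology = {
        s <- list()
        for (k in c("DRB1*13:02", "DRB1*13:36", "DRB1*13:67",
                    "DRB1*13:96", "DRB1*13:109"))
          s[[k]] <- c("DR6", "DR13")
        s[["A*01:01"]] <- "A1"
        s
      },
      mac = list("DRB1*13:AKBAR" = c("DRB1*13:02", "DRB1*13:36",
                                     "DRB1*13:67", "DRB1*13:96",
                                     "DRB1*13:109")),
      db_version = sprintf("fixture-%d", seed))

    # --- concept maps -------------------------------------------------------
    sys_snomed <- "http://snomed.info/sct"
    sys_do     <- "https://disease-ontology.org/"
    sys_medgen <- "https://www.ncbi.nlm.nih.gov/medgen/"
    sys_icd    <- "http://hl7.org/fhir/sid/icd-10-cm"
    sys_rxnorm <- "http://www.nlm.nih.gov/research/umls/rxnorm"
    sys_ncit   <- "https://ncithesaurus.nci.nih.gov/"
    cm <- function(src, tgt, code, target, display, id)
      concept_map(src, tgt, data.frame(code = code, target = target,
                                       display = display,
                                       stringsAsFactors = FALSE),
                  id = id, version = "fixture")
    concept_maps <- concept_map_registry(list(
      cm(sys_snomed, sys_do,
         code = c("1259727001", "126949007", "1259754003"),
         target = c("DOID : 3908", "DOID : 12689", "DOID : 3907"),
         display = c("Lung Non-small Cell Carcinoma", "Acoustic Neuroma",
                     "Lung squamous cell carcinoma"),
         id = "snomed-to-do"),
      cm(sys_snomed, sys_medgen,
         code = "716318002", target = "MGSYN0001",  # synthetic MedGen code
         display = "Lynch Syndrome", id = "snomed-to-medgen"),
      cm(sys_icd, sys_do,
         code = "C34.90", target = "DOID : 3908",
         display = "Lung Non-small Cell Carcinoma", id = "icd10cm-to-do"),
      cm(sys_icd, sys_medgen,
         code = "C18.9", target = "MGSYN0002",      # synthetic MedGen code
         display = "Colorectal Neoplasm", id = "icd10cm-to-medgen"),
      cm(sys_rxnorm, sys_ncit,
         code = "999999", target = "CSYN0001",      # synthetic pair
         display = "Fixture Compound", id = "rxnorm-to-ncit")))

    # --- demo variant in every spelling ------------------------------------
    # NM_FIX1.1 c.12: t = 10 + 12 - 1 = 21 -> g37 121 (0-based), g38 171
    demo <- list(
      transcript_hgvs = "NM_FIX1.1:c.12G>A",
      b37_hgvs = "NC_FX0001.37:g.122G>A",
      b38_hgvs = "NC_FX0001.38:g.172G>A",
      b37_spdi = "NC_FX0001.37:121:G:A",
      b38_spdi = "NC_FX0001.38:171:G:A",
      vcf_row = list(chrom = "fix1", pos = 122, ref = "G", alt = "A"))
    contig_map <- data.frame(
      chrom = c("fix1", "fix1"),
      build = c("fixture37", "fixture38"),
      accession = c("NC_FX0001.37", "NC_FX0001.38"),
      stringsAsFactors = FALSE)

    # --- patient store and knowledge ---------------------------------------
    store <- genomics_store()
    ingest_patient_variants(store, "m123", demo$transcript_hgvs,
                            alignments, catalog)
    ingest_patient_hla(store, "m123", "DRB1*13:AKBAR", hla_db)
    ingest_patient_variants(store, "CA12345", demo$transcript_hgvs,
                            alignments, catalog)
    demo_bundle <- normalize_variant_bundle(demo$transcript_hgvs,
                                            alignments, catalog)
    knowledge <- list(knowledge_entry(
      variant_key = demo_bundle$fields$b38SPDI,
      condition_system = sys_do, condition_code = "DOID : 3908",
      treatment_system = sys_ncit, treatment_code = "CSYN0001",
      implication = "fixture therapeutic implication"))

    structure(list(catalog = catalog, alignments = alignments,
                   hla_db = hla_db, concept_maps = concept_maps,
                   store = store, knowledge = knowledge,
                   contig_map = contig_map, demo = demo, seed = seed),
              class = "fixture_suite")
  })
}

#' Write fixture files
#'
#' Serializes a suite to the on-disk formats every loader consumes:
#' `sequences.fa` + `sequences.json` (sparse catalog), `alignments.json`,
#' `hla_db.json`, `concept_maps.json`, `contig_map.json`.
#'
#' @param suite a [build_fixture_suite()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_fixture_files <- function(suite, dir) {
  stopifnot(inherits(suite, "fixture_suite"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_seq_catalog(suite$catalog, file.path(dir, "sequences.fa"),
                    file.path(dir, "sequences.json"))
  write_alignment_db(suite$alignments, file.path(dir, "alignments.json"))
  write_allele_db(suite$hla_db, file.path(dir, "hla_db.json"))
  write_concept_maps(suite$concept_maps, file.path(dir, "concept_maps.json"))
  jsonlite::write_json(suite$contig_map, file.path(dir, "contig_map.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Seeded generator of variant equivalence classes
#'
#' Each case plants a tandem repeat (unit length 1-3, 3-6 copies) in a
#' random sequence with repeat-breaking flanks, applies a one-unit deletion
#' or insertion, and spells the same sequence change several ways: SPDI at
#' the leftmost, rightmost and a middle placement, an HGVS g. spelling, and
#' a VCF-style anchor-base row. Placements are enumerated by brute force
#' (apply-and-compare against the mutated sequence), so by construction all
#' members denote the same change.
#'
#' @param seed integer seed.
#' @param n number of cases, `>= 1`.
#' @return List of cases; each is a list with `accession`, `sequence`,
#'   `catalog`, `kind` (`"del"`/`"ins"`), `members` (SPDI/HGVS strings),
#'   `vcf` (list `accession`, `pos`, `ref`, `alt`) and `mutated` (the
#'   edited sequence).
#' @export
random_equivalence_cases <- function(seed, n) {
  stopifnot(n >= 1)
  .with_seed(seed, lapply(seq_len(n), function(i) {
    u <- sample(1:3, 1)
    m <- sample(3:6, 1)
    unit <- .rand_bases(u)
    flank_l <- .rand_bases(6)
    flank_r <- .rand_bases(6)
    # break the repeat at both flanks
    repl <- function(avoid) sample(setdiff(c("A", "C", "G", "T"), avoid), 1)
    flank_l <- .set_base(flank_l, 5, repl(substr(unit, u, u)))
    flank_r <- .set_base(flank_r, 0, repl(substr(unit, 1, 1)))
    seqs <- paste0(flank_l, strrep(unit, m), flank_r)
    L <- nchar(seqs)
    kind <- sample(c("del", "ins"), 1)
    acc <- sprintf("NC_FXEQ%04d.1", i)
    catalog <- register_segment(seq_catalog(), acc, 0, seqs)
    rs <- 6  # repeat start (0-based)

    if (kind == "del") {
      mutated <- .apply_edit(seqs, 0, rs, unit, "")
      placements <- list()
      for (q in 0:(L - u)) {
        d <- substr(seqs, q + 1, q + u)
        ok <- tryCatch(identical(.apply_edit(seqs, 0, q, d, ""), mutated),
                       error = function(e) FALSE)
        if (ok) placements[[length(placements) + 1L]] <-
            list(pos = q, allele = d)
      }
    } else {
      mutated <- .apply_edit(seqs, 0, rs, "", unit)
      rots <- unique(vapply(seq_len(u), function(k)
        paste0(substr(unit, k, u), substr(unit, 1, k - 1)), ""))
      placements <- list()
      for (q in 0:L) for (a in rots) {
        if (identical(.apply_edit(seqs, 0, q, "", a), mutated))
          placements[[length(placements) + 1L]] <-
            list(pos = q, allele = a)
      }
    }
    ps <- vapply(placements, function(p) p$pos, 0)
    pick <- placements[c(which.min(ps), which.max(ps),
                         order(ps)[ceiling(length(ps) / 2)])]
    spdi_of <- function(p) {
      if (kind == "del") paste0(acc, ":", p$pos, ":", p$allele, ":")
      else paste0(acc, ":", p$pos, "::", p$allele)
    }
    right <- placements[[which.max(ps)]]
    hgvs <- if (kind == "del") {
      if (u == 1) sprintf("%s:g.%ddel", acc, right$pos + 1)
      else sprintf("%s:g.%d_%ddel", acc, right$pos + 1, right$pos + u)
    } else {
      left <- placements[[which.min(ps)]]
      sprintf("%s:g.%d_%dins%s", acc, left$pos, left$pos + 1, left$allele)
    }
    leftp <- placements[[which.min(ps)]]
    anchor <- substr(seqs, leftp$pos, leftp$pos)  # base before the edit
    vcf <- if (kind == "del")
      list(accession = acc, pos = leftp$pos,
           ref = paste0(anchor, leftp$allele), alt = anchor)
    else
      list(accession = acc, pos = leftp$pos,
           ref = anchor, alt = paste0(anchor, leftp$allele))
    list(accession = acc, sequence = seqs, catalog = catalog, kind = kind,
         members = unique(c(vapply(pick, spdi_of, ""), hgvs)),
         vcf = vcf, mutated = mutated)
  }))
}
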