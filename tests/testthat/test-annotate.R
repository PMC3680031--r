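write_bed <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path); path
}

test_that("BED sets load with native coordinates; degenerate records rejected", {
  db <- load_bed(annotation_db(), write_bed("chr1\t100\t200\tpromA"),
                 "promoter")
  expect_equal(attr(db, "n_loaded"), 1)
  expect_equal(db$records$start, 100L)   # 0-based passes through
  expect_equal(db$records$end, 200L)
  expect_equal(db$records$chrom, "1")
  expect_equal(db$records$name, "promA")

  expect_warning(
    db0 <- load_bed(annotation_db(),
                    write_bed(c("chr1\t100\t100\tz", "chr1\t5\t6\ta")), "tfbs"),
    "rejected")
  expect_equal(attr(db0, "n_loaded"), 1)
})

gtf_line <- function(type, start, end, strand, tx, frame = ".") {
  sprintf("1\ttest\t%s\t%d\t%d\t.\t%s\t%s\tgene_id \"g\"; transcript_id \"%s\"; gene_name \"g\";",
          type, start, end, strand, frame, tx)
}

test_that("gene models assemble from GTF with derived exon/intron/UTR records", {
  # single-exon transcript fully CDS: 1 model, 1 exon, no introns/UTRs
  p1 <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("exon", 101, 160, "+", "t1"),
               gtf_line("CDS", 101, 160, "+", "t1", 0)), p1)
  db <- load_gtf(annotation_db(), p1)
  expect_equal(attr(db, "n_models"), 1)
  expect_equal(db$models$phase_offset, 0L)
  expect_equal(db$models$cds[[1]], tibble::tibble(start = 100L, end = 160L))
  cats <- table(db$records$category)
  expect_equal(as.integer(cats[c("gene", "exon")]), c(1L, 1L))
  expect_false("intron" %in% names(cats))
  expect_false("utr" %in% names(cats))

  # two-exon transcript with UTR: intron is the gap, UTR = exonic - CDS
  p2 <- tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("exon", 101, 200, "+", "t2"),
               gtf_line("exon", 301, 400, "+", "t2"),
               gtf_line("CDS", 151, 200, "+", "t2", 0),
               gtf_line("CDS", 301, 350, "+", "t2", 0)), p2)
  db2 <- load_gtf(annotation_db(), p2)
  introns <- dplyr::filter(db2$records, category == "intron")
  expect_equal(nrow(introns), 1)
  expect_equal(c(introns$start, introns$end), c(200L, 300L))
  utrs <- dplyr::filter(db2$records, category == "utr")
  expect_equal(nrow(utrs), 2)
  expect_setequal(utrs$start, c(100L, 350L))
})

test_that("CDS without transcript_id is skipped with a warning", {
  p <- tempfile(fileext = ".gtf")
  writeLines(c("1\ttest\tCDS\t10\t30\t.\t+\t0\tgene_id \"x\";",
               gtf_line("CDS", 101, 160, "+", "t1", 0)), p)
  expect_warning(db <- load_gtf(annotation_db(), p), "without transcript_id")
  expect_equal(attr(db, "n_models"), 1)
})

test_that("variant overlap respects half-open footprints", {
  db <- load_bed(annotation_db(), write_bed("1\t100\t200\trec"), "promoter")
  expect_equal(nrow(annotate_variant(db, "1", 150, "A")), 1)  # inside
  expect_equal(nrow(annotate_variant(db, "1", 101, "A")), 1)  # first base
  expect_equal(nrow(annotate_variant(db, "1", 200, "A")), 1)  # last covered base (0-based 199)
  expect_equal(nrow(annotate_variant(db, "1", 201, "A")), 0)  # past half-open end
  expect_equal(nrow(annotate_variant(db, "1", 100, "A")), 0)  # before 0-based start 100
})

test_that("deletion footprints straddling a record boundary hit it", {
  db <- load_bed(annotation_db(), write_bed("1\t100\t200\trec"), "promoter")
  # 5 bp deletion with footprint [97,102) straddles record start 100
  expect_equal(nrow(annotate_variant(db, "1", 98, "AAAAA")), 1)
  # footprint ending exactly at record start misses
  expect_equal(nrow(annotate_variant(db, "1", 96, "AAAAA")), 0)
  expect_equal(nrow(annotate_variant(db, "1", 150, "A", categories = "gene")), 0)
  expect_equal(nrow(annotate_variant(db, "2", 150, "A")), 0)  # unknown chrom
})

test_that("interval queries equal a brute-force overlap scan", {
  set.seed(99)
  db <- annotation_db()
  n <- 800
  recs <- tibble::tibble(
    chrom = sample(c("1", "2"), n, replace = TRUE),
    start = sample(0:9999, n, replace = TRUE))
  recs$end <- recs$start + sample(1:500, n, replace = TRUE)
  bed <- sprintf("%s\t%d\t%d\tr%d", recs$chrom, recs$start, recs$end, seq_len(n))
  db <- load_bed(db, write_bed(bed), "regulatory")
  for (i in 1:150) {
    chrom <- sample(c("1", "2"), 1)
    pos <- sample(1:10500, 1)
    w <- sample(1:6, 1)
    got <- annotate_variant(db, chrom, pos, strrep("A", w))
    want <- oracle_overlaps(db$records, chrom, pos - 1L, pos - 1L + w)
    expect_setequal(got$record_id, db$records$record_id[want])
  }
})

# --- effect classification on a hand-built gene ---------------------------

# reference with a plus-strand gene at 11..28 (CDS, phase 0) encoding
# ATG CTG GAT TAA and a minus-strand copy further right whose transcript
# reads the same codons
effect_fixture <- function() {
  lead <- strrep("T", 10)
  cds_plus <- "ATGCTGGATTAA"
  mid <- strrep("C", 8)
  cds_minus_genomic <- oracle_revcomp("ATGCTGGATTAA")
  tail <- strrep("G", 10)
  seq <- paste0(lead, cds_plus, mid, cds_minus_genomic, tail)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">1", seq), fa)
  gtf <- tempfile(fileext = ".gtf")
  minus_start <- nchar(lead) + nchar(cds_plus) + nchar(mid) + 1L
  writeLines(c(
    gtf_line("exon", 11, 22, "+", "tplus"),
    gtf_line("CDS", 11, 22, "+", "tplus", 0),
    gtf_line("exon", minus_start, minus_start + 11L, "-", "tminus"),
    gtf_line("CDS", minus_start, minus_start + 11L, "-", "tminus", 0)), gtf)
  db <- load_gtf(annotation_db(), gtf)
  list(db = db, ref = Biostrings::readDNAStringSet(fa),
       minus_start = minus_start, seq = seq)
}

test_that("codon-level synonymous/non-synonymous calls match hand translation", {
  fx <- effect_fixture()
  # CTG codon at positions 14-16 (Leu): third base G>A -> CTA still Leu
  expect_equal(classify_effect(fx$db, "1", 16, "G", "A", fx$ref), "synonymous")
  expect_equal(CODON_TABLE[["CTG"]], CODON_TABLE[["CTA"]])
  # second base T>C -> CCG Pro
  expect_equal(classify_effect(fx$db, "1", 15, "T", "C", fx$ref), "non_synonymous")
  expect_false(CODON_TABLE[["CTG"]] == CODON_TABLE[["CCG"]])
  # stop loss on TAA (positions 20-22): A>C at third base -> TAC Tyr
  expect_equal(classify_effect(fx$db, "1", 22, "A", "C", fx$ref), "non_synonymous")
})

test_that("minus-strand classification reverse-complements correctly", {
  fx <- effect_fixture()
  # transcript-space CTG codon third base is genomic position
  # minus_start + 11 - 5 (transcript coords 3..5 map back from the right)
  g <- fx$minus_start + 11L - 5L
  genomic_ref <- substr(fx$seq, g, g)
  expect_equal(genomic_ref, "C")   # complement of transcript G
  # genomic C>T means transcript G>A: CTG -> CTA, synonymous
  expect_equal(classify_effect(fx$db, "1", g, "C", "T", fx$ref), "synonymous")
  # genomic C>G means transcript G>C: CTG -> CTC, also Leu
  expect_equal(classify_effect(fx$db, "1", g, "C", "G", fx$ref), "synonymous")
  # middle base of the same codon: genomic A>G -> transcript T>C -> CCG
  expect_equal(classify_effect(fx$db, "1", g + 1L, "A", "G", fx$ref),
               "non_synonymous")
})

test_that("indels and extragenic variants classify by location", {
  fx <- effect_fixture()
  expect_equal(classify_effect(fx$db, "1", 3, "T", "A", fx$ref), "non_coding")
  expect_equal(classify_effect(fx$db, "1", 14, "C", "CAT", fx$ref),
               "non_synonymous")  # insertion in CDS
  expect_equal(classify_effect(fx$db, "1", 3, "TT", "T", fx$ref), "non_coding")
  # reference integrity check
  expect_error(classify_effect(fx$db, "1", 16, "C", "A", fx$ref),
               "reference mismatch")
})

test_that("effect classification is a pure function of its inputs", {
  fx <- effect_fixture()
  a <- classify_effect(fx$db, "1", 16, "G", "A", fx$ref)
  b <- classify_effect(fx$db, "1", 16, "G", "A", fx$ref)
  expect_identical(a, b)
})

test_that("annotation summaries concatenate names without duplicates", {
  db <- load_bed(annotation_db(),
                 write_bed(c("1\t10\t50\tpromA", "1\t30\t70\tpromB",
                             "1\t40\t90\tpromC")), "promoter")
  expect_equal(annotation_summary(db, character(0)),
               "novel region (no annotation)")
  s1 <- annotation_summary(db, db$records$record_id[1])
  expect_match(s1, "promA")
  expect_match(s1, "promoter")
  s3 <- annotation_summary(db, db$records$record_id)
  for (nm in c("promA", "promB", "promC"))
    expect_equal(lengths(regmatches(s3, gregexpr(nm, s3))), 1L)
})

test_that("annotate_collapsed labels variants and lists overlapping records", {
  fx <- effect_fixture()
  db <- load_bed(fx$db, write_bed("1\t12\t20\tpromX"), "promoter")
  col <- tibble::tibble(
    chrom = "1", pos = c(16L, 3L), ref = c("G", "T"), alt = c("A", "A"),
    vtype = "snv", n_carriers = 1L, carriers = list("T1", "T1"),
    tumor_freq = 0.5, normal_freq = 0, effect = "unassigned")
  ann <- annotate_collapsed(db, col, fx$ref)
  expect_equal(ann$effect, c("synonymous", "non_coding"))
  expect_match(ann$overlapping_records[1], "promX")
  expect_match(ann$overlapping_records[1], "\\[gene\\]")
  expect_equal(ann$overlapping_records[2], "")
})
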