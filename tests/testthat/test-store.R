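test_that("sample import enforces pairing and identity invariants", {
  vs <- import_samples(variant_store(), tibble::tibble(
    sample_id = c("T1", "N1"), cohort = "c", status = c("tumor", "normal"),
    matched_id = c("N1", "T1")))
  expect_equal(attr(vs, "n_loaded"), 2)
  expect_equal(nrow(vs$samples), 2)

  expect_error(
    import_samples(variant_store(), tibble::tibble(
      sample_id = "T1", cohort = "c", status = "tumor", matched_id = "NX")),
    "nonexistent")
  expect_error(
    import_samples(vs, tibble::tibble(
      sample_id = "T1", cohort = "c", status = "tumor", matched_id = NA)),
    "duplicate")
  expect_error(
    import_samples(variant_store(), tibble::tibble(
      sample_id = c("T1", "T2"), cohort = "c", status = c("tumor", "tumor"),
      matched_id = c("T2", "T1"))),
    "identical status")
})

test_that("one-directional matched links are mirrored", {
  vs <- import_samples(variant_store(), tibble::tibble(
    sample_id = c("T1", "N1"), cohort = "c", status = c("tumor", "normal"),
    matched_id = c("N1", NA)))
  expect_equal(vs$samples$matched_id[vs$samples$sample_id == "N1"], "T1")
})

test_that("a simulated cohort metadata table loads completely", {
  cfg <- sim_config(seed = 5, genome_length = 20000L, cohorts = c(A = 10L),
                    n_genes = 2L, polymorphism_set_size = 10L,
                    poly_overlap_n = 0L, hotspots = list())
  sim <- simulate_cohort(cfg, simulate_reference(cfg, tempfile(fileext = ".fa")),
                         tempfile("simmeta"))
  vs <- import_samples(variant_store(), sim$metadata_path)
  expect_equal(attr(vs, "n_loaded"), 20)
})

test_that("VCF import splits multi-allelic records and maps depths", {
  vs <- tiny_store()
  p <- write_test_vcf(c(vcf_rec("1", 100, "A", "G", dp = 30, ad = 12)),
                      sample_id = "T1")
  vs <- import_vcf(vs, p, "T1")
  expect_equal(attr(vs, "n_loaded"), 1)
  expect_equal(vs$variants$total_depth, 30L)
  expect_equal(vs$variants$alt_depth, 12L)
  expect_equal(vs$variants$vtype, "snv")

  p2 <- write_test_vcf(vcf_rec("1", 200, "C", "A,T"), sample_id = "T1")
  vs <- import_vcf(vs, p2, "T1")
  expect_equal(attr(vs, "n_loaded"), 2)
  both <- dplyr::filter(vs$variants, pos == 200)
  expect_setequal(both$alt, c("A", "T"))
  # missing depths recorded as zero
  expect_equal(both$total_depth, c(0L, 0L))

  expect_error(import_vcf(vs, p, "nobody"), "unknown sample_id")
  p3 <- write_test_vcf(c(vcf_rec("1", 50, "A", "<DEL>"),
                         vcf_rec("1", 60, "G", "C")))
  expect_warning(vs <- import_vcf(vs, p3, "T2"), "skipped")
  expect_equal(attr(vs, "n_loaded"), 1)
  expect_equal(attr(vs, "n_skipped"), 1)
})

test_that("chromosome dialects are normalized at import", {
  vs <- tiny_store()
  p <- write_test_vcf(vcf_rec("chr1", 100, "A", "G"))
  vs <- import_vcf(vs, p, "T1")
  expect_equal(vs$variants$chrom, "1")
})

test_that("polymorphism sets deduplicate and reject duplicate names", {
  vs <- tiny_store()
  empty <- write_test_vcf(character(0))
  vs <- import_polymorphism_set(vs, empty, "empty")
  expect_equal(attr(vs, "n_loaded"), 0)
  dupd <- write_test_vcf(c(vcf_rec("1", 10, "A", "T"), vcf_rec("1", 10, "A", "T")))
  vs <- import_polymorphism_set(vs, dupd, "dbsnp")
  expect_equal(attr(vs, "n_loaded"), 1)
  expect_error(import_polymorphism_set(vs, dupd, "dbsnp"), "already present")
})

test_that("allele normalization trims and left-aligns indels", {
  # trailing shared base trimmed: GAT>GAC is really T>C at pos+2
  n1 <- normalize_alleles(100L, "TAG", "TAC")
  expect_equal(n1$pos, 102L); expect_equal(n1$ref, "G"); expect_equal(n1$alt, "C")
  # insertion in homopolymer left-shifts to the run start
  refseq <- paste0(strrep("G", 4), "AAAA", strrep("T", 10))  # A run at 5..8
  n2 <- normalize_alleles(8L, "A", "AA", refseq)
  expect_equal(n2$pos, 4L)
  expect_equal(n2$ref, "G"); expect_equal(n2$alt, "GA")
  expect_equal(n2$vtype, "ins")
})

make_filter_store <- function() {
  vs <- tiny_store()
  vs <- import_vcf(vs, write_test_vcf(c(
    vcf_rec("1", 100, "A", "G"),    # somatic (nowhere else)
    vcf_rec("1", 200, "C", "T"),    # in unrelated normal N7
    vcf_rec("1", 300, "G", "A"),    # in matched normal N1 (germline)
    vcf_rec("1", 400, "T", "C")     # in dbsnp
  )), "T1")
  vs <- import_vcf(vs, write_test_vcf(vcf_rec("1", 100, "A", "G")), "T2")
  vs <- import_vcf(vs, write_test_vcf(vcf_rec("1", 300, "G", "A")), "N1")
  vs <- import_vcf(vs, write_test_vcf(vcf_rec("1", 200, "C", "T")), "N7")
  vs <- import_polymorphism_set(vs, write_test_vcf(vcf_rec("1", 400, "T", "C")),
                                "dbsnp")
  vs
}

test_that("cancer-exclusive extraction filters normals and polymorphism sets", {
  vs <- make_filter_store()
  ex <- extract_cancer_exclusive(vs, "lymphoma", "dbsnp")
  expect_equal(nrow(ex), 1)
  expect_equal(ex$pos, 100L)
  expect_equal(ex$carriers[[1]], c("T1", "T2"))
  expect_equal(ex$tumor_freq, 1)          # 2 carriers / 2 cohort tumors
  expect_equal(ex$normal_freq, 0)
  expect_equal(ex$effect, "unassigned")

  germ <- extract_germline(vs, "lymphoma")
  expect_equal(germ$pos, c(200L, 300L))   # both normal-carried alleles
  expect_true(all(germ$normal_freq > 0))

  expect_error(extract_cancer_exclusive(vs, "nope"), "unknown cohort")
  expect_error(extract_cancer_exclusive(vs, "lymphoma", "nope"),
               "unknown polymorphism set")
})

test_that("extraction matches brute-force set algebra and is idempotent", {
  set.seed(42)
  vs <- tiny_store()
  mk <- function(n) vapply(seq_len(n), function(i)
    vcf_rec("1", sample(1000, 1), sample(c("A", "C", "G", "T"), 1), "N"),
    character(1))
  # alt N invalid; use fixed alt distinct from ref
  mk <- function(n) {
    pos <- sample(1000, n)
    ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
    sprintf("1\t%d\t.\t%s\t%s\t.\tPASS\t.", pos, ref, alt)
  }
  for (s in c("T1", "T2", "N1", "N2", "N7"))
    vs <- import_vcf(vs, write_test_vcf(mk(40)), s)
  vs <- import_polymorphism_set(vs, write_test_vcf(mk(20)), "dbsnp")
  ex <- extract_cancer_exclusive(vs, "lymphoma", "dbsnp")

  keyify <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  tumor_keys <- unique(keyify(dplyr::filter(vs$variants,
                                            sample_id %in% c("T1", "T2"))))
  normal_keys <- keyify(dplyr::filter(vs$variants,
                                      sample_id %in% c("N1", "N2", "N7")))
  poly_keys <- keyify(vs$polymorphisms)
  expected <- setdiff(tumor_keys, union(normal_keys, poly_keys))
  expect_setequal(keyify(ex), expected)
  # soundness re-check on outputs
  expect_false(any(keyify(ex) %in% c(normal_keys, poly_keys)))
  # frequency bound
  expect_true(all(ex$tumor_freq >= 0.5 & ex$tumor_freq <= 1))
  # ordered output and idempotence
  expect_equal(ex, dplyr::arrange(ex, chrom, pos, ref, alt))
  expect_identical(ex, extract_cancer_exclusive(vs, "lymphoma", "dbsnp"))
})

test_that("recurrence table sorts by carrier count then position", {
  col <- tibble::tibble(
    chrom = "1", pos = c(10L, 20L, 30L), ref = "A", alt = "T", vtype = "snv",
    n_carriers = c(1L, 3L, 2L),
    carriers = list("T1", c("T1", "T2", "T3"), c("T1", "T2")),
    tumor_freq = 1, normal_freq = 0, effect = "unassigned")
  rt <- recurrence_table(col)
  expect_equal(rt$n_carriers, c(3L, 2L, 1L))
  expect_equal(nrow(recurrence_table(col[0, ])), 0)
})

test_that("extraction TSVs round-trip through write/read", {
  vs <- make_filter_store()
  ex <- extract_cancer_exclusive(vs, "lymphoma", "dbsnp")
  d <- tempfile("extr"); paths <- write_extraction(ex, d)
  back <- read_extraction(paths)
  expect_equal(back$pos, ex$pos)
  expect_equal(back$carriers, ex$carriers)
})
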