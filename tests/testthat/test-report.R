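empty_collapsed <- function() {
  tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                 alt = character(), vtype = character(), n_carriers = integer(),
                 carriers = list(), tumor_freq = numeric(),
                 normal_freq = numeric(), effect = character())
}

empty_results <- function() {
  tibble::tibble(hotspot_id = character(), chrom = character(),
                 start = integer(), end = integer(), region_name = character(),
                 region_category = character(), k = integer(), n = numeric(),
                 p_raw = numeric(), q_value = numeric(), rank = integer())
}

empty_verdicts <- function() {
  tibble::tibble(hotspot_id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character(), sample = character(),
                 status = character(), tumor_alt = integer(),
                 tumor_depth = integer(), normal_alt = integer(),
                 normal_depth = integer(), low_conf = logical())
}

test_that("custom tracks carry headers and 0-based coordinates", {
  d <- tempfile("tr")
  paths <- write_tracks(empty_collapsed(), empty_results(), empty_verdicts(), d)
  for (p in paths) {
    lines <- readLines(p)
    expect_length(lines, 1)
    expect_match(lines[1], "^track name=")
  }

  snv <- tibble::tibble(chrom = "1", pos = 100L, ref = "A", alt = "G",
                        vtype = "snv", n_carriers = 1L, carriers = list("T1"),
                        tumor_freq = 1, normal_freq = 0, effect = "unassigned")
  res <- tibble::tibble(hotspot_id = "HS0001", chrom = "1", start = 90L,
                        end = 120L, region_name = "g", region_category = "gene",
                        k = 1L, n = 300, p_raw = 0.001, q_value = 0.001,
                        rank = 1L)
  verd <- tibble::tibble(hotspot_id = "HS0001", chrom = "1", pos = 100L,
                         ref = "A", alt = "G", sample = "T1",
                         status = c("somatic"), tumor_alt = 5L,
                         tumor_depth = 20L, normal_alt = 0L,
                         normal_depth = 20L, low_conf = FALSE)
  paths <- write_tracks(snv, res, verd, tempfile("tr2"))
  all_snvs <- readLines(paths["all_snvs"])
  expect_equal(all_snvs[2], "1\t99\t100\tA>G")   # 1-based 100 -> BED 99..100
  verified <- readLines(paths["verified"])
  expect_length(verified, 2)
  # a somatic verdict outside every hotspot span is not a verified-track line
  verd_out <- dplyr::mutate(verd, pos = 5000L)
  p3 <- write_tracks(snv, res, verd_out, tempfile("tr3"))
  expect_length(readLines(p3["verified"]), 1)
})

test_that("track 3 line count equals somatic verdicts inside hotspot spans", {
  cfg <- sim_config(seed = 31, genome_length = 30000L, cohorts = c(A = 4L),
                    n_genes = 2L, polymorphism_set_size = 10L,
                    poly_overlap_n = 2L,
                    hotspots = list(list(start = 3001L, end = 3400L,
                                         fold = 60, min_carriers = 3L)))
  fa <- simulate_reference(cfg, tempfile(fileext = ".fa"))
  sim <- simulate_cohort(cfg, fa, tempfile("tracks"))
  som <- dplyr::filter(sim$truth, label == "somatic")
  res <- tibble::tibble(hotspot_id = "HS0001", chrom = "1", start = 3000L,
                        end = 3400L, region_name = "hs", region_category = "novel",
                        k = 1L, n = 1, p_raw = 0.5, q_value = 0.5, rank = 1L)
  verd <- tibble::tibble(hotspot_id = "HS0001", chrom = "1", pos = som$pos,
                         ref = som$ref, alt = som$alt, sample = "T001",
                         status = "somatic", tumor_alt = 5L, tumor_depth = 20L,
                         normal_alt = 0L, normal_depth = 20L, low_conf = FALSE)
  paths <- write_tracks(empty_collapsed(), res, verd, tempfile("tr4"))
  inside <- sum(som$pos - 1L >= 3000 & som$pos - 1L < 3400)
  expect_equal(length(readLines(paths["verified"])) - 1L, inside)
})

test_that("the ranked report is well-formed, ordered, and linked to QC pages", {
  d <- tempfile("rep")
  dir.create(file.path(d, "qc"), recursive = TRUE)
  # report with no hotspots is still valid markup
  p0 <- write_report(empty_results(), d)
  expect_no_error(xml2::read_html(paste(readLines(p0), collapse = "\n")))

  res <- tibble::tibble(
    hotspot_id = c("HS0002", "HS0001"), chrom = "1",
    start = c(500L, 100L), end = c(600L, 200L),
    region_name = c("geneB", "geneA & co"), region_category = "gene",
    k = c(9L, 2L), n = 1000, p_raw = c(1e-8, 1e-3),
    q_value = c(2e-8, 1e-3), rank = c(1L, 2L),
    n_samples = c(4L, 1L), group_counts = "A=1;",
    group_pvalues = "A=1.00e-02;", summary = "geneB (gene, 1:500-600)")
  writeLines("<html><body>qc</body></html>", file.path(d, "qc", "HS0002.html"))
  expect_warning(p <- write_report(res, d), "QC page missing for HS0001")
  html <- paste(readLines(p), collapse = "\n")
  doc <- xml2::read_html(html)
  rows <- xml2::xml_find_all(doc, "//tbody/tr")
  expect_length(rows, 2)
  # row order follows rank
  first_cells <- xml2::xml_text(xml2::xml_find_all(rows[[1]], "td"))
  expect_equal(first_cells[1], "1")
  expect_match(first_cells[2], "1:501-600")
  # rank anchor resolves to the QC file inside the bundle
  href <- xml2::xml_attr(xml2::xml_find_first(rows[[1]], "td/a"), "href")
  expect_true(file.exists(file.path(d, href)))
  # user text is escaped
  expect_match(html, "geneA &amp; co")
  # track links at the top
  for (t in c("tracks/all_snvs.bed", "tracks/target_regions.bed",
              "tracks/verified_variations.bed"))
    expect_match(html, t, fixed = TRUE)
})

test_that("germline reports keep germline verdicts sorted by position", {
  p <- write_germline_report(empty_verdicts(), tempfile(fileext = ".tsv"))
  expect_length(readLines(p), 1)   # header only
  verd <- tibble::tibble(
    hotspot_id = "HS0001", chrom = "1", pos = c(300L, 100L, 200L, 150L),
    ref = "A", alt = "G", sample = "T1",
    status = c("germline", "germline", "somatic", "germline"),
    tumor_alt = 5L, tumor_depth = 20L, normal_alt = 4L, normal_depth = 20L,
    low_conf = FALSE)
  p2 <- write_germline_report(verd, tempfile(fileext = ".tsv"))
  back <- readr::read_tsv(p2, show_col_types = FALSE)
  expect_equal(nrow(back), 3)
  expect_equal(back$pos, c(100L, 150L, 300L))
  expect_true(all(back$status == "germline"))
})

test_that("report bundles are deterministic and internally linked", {
  res <- tibble::tibble(
    hotspot_id = "HS0001", chrom = "1", start = 100L, end = 200L,
    region_name = "geneA", region_category = "gene", k = 3L, n = 1000,
    p_raw = 1e-5, q_value = 1e-5, rank = 1L)
  snv <- tibble::tibble(chrom = "1", pos = 150L, ref = "A", alt = "G",
                        vtype = "snv", n_carriers = 1L, carriers = list("T1"),
                        tumor_freq = 1, normal_freq = 0, effect = "synonymous")
  verd <- tibble::tibble(hotspot_id = "HS0001", chrom = "1", pos = 150L,
                         ref = "A", alt = "G", sample = "T1", status = "somatic",
                         tumor_alt = 5L, tumor_depth = 20L, normal_alt = 0L,
                         normal_depth = 20L, low_conf = FALSE)
  d1 <- tempfile("b1"); d2 <- tempfile("b2")
  for (d in c(d1, d2)) {
    dir.create(file.path(d, "qc"), recursive = TRUE)
    writeLines("<html><body>qc</body></html>", file.path(d, "qc", "HS0001.html"))
    write_bundle(res, snv, verd, d)
  }
  files <- list.files(d1, recursive = TRUE)
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  # link closure: every href points inside the bundle
  doc <- xml2::read_html(paste(readLines(file.path(d1, "report.html")),
                               collapse = "\n"))
  hrefs <- xml2::xml_attr(xml2::xml_find_all(doc, "//a"), "href")
  local <- hrefs[!grepl("^https?://", hrefs)]
  expect_gt(length(local), 0)
  for (h in local) expect_true(file.exists(file.path(d1, h)))
})
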