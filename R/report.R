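#' Write the three UCSC custom-track BED files
#'
#' Track 1: every cancer-exclusive SNV as a 1 bp feature. Track 2: the
#' hotspot (target) region spans. Track 3: variants with somatic
#' verdicts lying inside hotspot regions. Each file starts with a
#' `track name=... description=...` header; coordinates are 0-based
#' half-open.
#'
#' @param all_snvs collapsed-variant tibble (only `vtype == "snv"` rows
#'   are written).
#' @param results scored hotspot tibble (`chrom, start, end,
#'   hotspot_id`).
#' @param verified verdict tibble; rows with `status == "somatic"`
#'   inside a hotspot span are written.
#' @param dir output directory (a `tracks/` subdirectory is created).
#' @return invisible named character vector of the three paths.
#' @export
write_tracks <- function(all_snvs, results, verified, dir) {
  tdir <- file.path(dir, "tracks")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(tdir, "all_snvs.bed")
  p2 <- file.path(tdir, "target_regions.bed")
  p3 <- file.path(tdir, "verified_variations.bed")

  snvs <- filter(all_snvs, .data$vtype == "snv")
  writeLines(c(
    "track name=all_snvs description=\"All cancer-exclusive SNVs\"",
    if (nrow(snvs) > 0)
      sprintf("%s\t%d\t%d\t%s>%s", snvs$chrom, snvs$pos - 1L, snvs$pos,
              snvs$ref, snvs$alt)
  ), p1)

  writeLines(c(
    "track name=target_regions description=\"Mutational hotspot regions\"",
    if (nrow(results) > 0)
      sprintf("%s\t%d\t%d\t%s", results$chrom, results$start, results$end,
              results$hotspot_id)
  ), p2)

  ver <- filter(verified, .data$status == "somatic")
  if (nrow(ver) > 0 && nrow(results) > 0) {
    inside <- vapply(seq_len(nrow(ver)), function(i) {
      any(results$chrom == ver$chrom[i] &
            results$start <= ver$pos[i] - 1L & ver$pos[i] - 1L < results$end)
    }, logical(1))
    ver <- ver[inside, , drop = FALSE] |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt)
  } else ver <- ver[0, , drop = FALSE]
  writeLines(c(
    "track name=verified_variations description=\"Somatic-verified variants in target regions\"",
    if (nrow(ver) > 0)
      sprintf("%s\t%d\t%d\t%s>%s", ver$chrom, ver$pos - 1L,
              ver$pos - 1L + nchar(ver$ref), ver$ref, ver$alt)
  ), p3)
  invisible(c(all_snvs = p1, target_regions = p2, verified = p3))
}

ucsc_position <- function(chrom, start, end) {
  sprintf("https://genome.ucsc.edu/cgi-bin/hgTracks?position=%s%%3A%d-%d",
          chrom, start + 1L, end)
}

#' Write the ranked hotspot HTML report
#'
#' One table row per hotspot, sorted by rank: the rank cell links to the
#' region's QC page, the coordinate cell to a UCSC position query;
#' region name/category, observation count, carriers, per-cohort
#' counts, raw p and q-value and the annotation summary follow. The
#' three custom-track links sit at the top of the page. Output is
#' deterministic (no timestamps) and all user text is HTML-escaped.
#'
#' @param results a `hotspot_results` tibble sorted by rank (columns
#'   `summary` and `group_counts`/`group_pvalues` used when present).
#' @param dir bundle directory; QC pages are expected under
#'   `<dir>/qc/<hotspot_id>.html` and tracks under `<dir>/tracks/`.
#' @return the path of `report.html`, invisibly.
#' @export
write_report <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "report.html")
  has <- function(col) col %in% names(results)
  rows <- character(0)
  for (i in seq_len(nrow(results))) {
    hid <- results$hotspot_id[i]
    qc_rel <- file.path("qc", paste0(hid, ".html"))
    qc_ok <- file.exists(file.path(dir, qc_rel))
    if (!qc_ok) warn(paste0("QC page missing for ", hid))
    rank_cell <- if (qc_ok)
      sprintf("<a href=\"%s\">%d</a>", qc_rel, results$rank[i])
    else sprintf("%d <span class=\"broken\">[missing QC]</span>", results$rank[i])
    coord <- sprintf("%s:%d-%d", results$chrom[i], results$start[i] + 1L,
                     results$end[i])
    coord_cell <- sprintf("<a href=\"%s\">%s</a>",
                          ucsc_position(results$chrom[i], results$start[i],
                                        results$end[i]),
                          html_escape(coord))
    rows <- c(rows, paste0(
      "<tr><td>", rank_cell, "</td><td>", coord_cell, "</td><td>",
      html_escape(results$region_name[i]), "</td><td>",
      html_escape(results$region_category[i]), "</td><td>",
      results$k[i], "</td><td>",
      if (has("n_samples")) results$n_samples[i] else "", "</td><td>",
      if (has("group_counts")) html_escape(results$group_counts[i]) else "",
      "</td><td>", fmt_p(results$p_raw[i]), "</td><td>",
      fmt_p(results$q_value[i]), "</td><td>",
      if (has("group_pvalues")) html_escape(results$group_pvalues[i]) else "",
      "</td><td>",
      if (has("summary")) html_escape(results$summary[i]) else "",
      "</td></tr>"))
  }
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'/><title>Mutational hotspot report</title>",
    "<style>table{border-collapse:collapse}td,th{border:1px solid #999;padding:3px 8px}.broken{color:#c00}</style>",
    "</head><body>",
    "<h1>Mutational hotspot report</h1>",
    "<p>",
    "<a href=\"tracks/all_snvs.bed\">All SNVs track</a> | ",
    "<a href=\"tracks/target_regions.bed\">Target regions track</a> | ",
    "<a href=\"tracks/verified_variations.bed\">Verified Variations in target regions</a>",
    "</p>",
    "<table><thead><tr><th>Rank</th><th>Coordinate</th><th>Region</th>",
    "<th>Category</th><th>k</th><th>Samples</th><th>Group counts</th>",
    "<th>p</th><th>q</th><th>Group enrichment</th><th>Annotation summary</th>",
    "</tr></thead><tbody>",
    rows,
    "</tbody></table></body></html>")
  writeLines(html, path)
  invisible(path)
}

#' Write the germline report TSV
#'
#' Germline verdicts are processed separately, not discarded:
#' predisposing mutations may be of interest in their own right.
#'
#' @param germline verdict tibble (rows with `status == "germline"` are
#'   written; pass a pre-filtered tibble to keep all rows).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_germline_report <- function(germline, path) {
  g <- filter(germline, .data$status == "germline") |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt, .data$sample)
  write_tsv_plain(
    select(g, "chrom", "pos", "ref", "alt", "sample", "status",
           "tumor_alt", "tumor_depth", "normal_alt", "normal_depth",
           "low_conf", dplyr::any_of("hotspot_id")),
    path)
  invisible(path)
}

#' Assemble the final report bundle
#'
#' Writes the three UCSC tracks, the ranked HTML report and the
#' germline TSV into one directory (QC pages are written earlier by
#' [validate_hotspots()] into `<dir>/qc`).
#'
#' @param results scored, enriched hotspot results.
#' @param all_snvs collapsed-variant table (for track 1).
#' @param verdicts full verdict table.
#' @param dir bundle directory.
#' @return a `report_bundle` list: `html_path`, `track_paths`, `qc_dir`,
#'   `germline_path`.
#' @export
write_bundle <- function(results, all_snvs, verdicts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tracks <- write_tracks(all_snvs, results, verdicts, dir)
  germ <- write_germline_report(verdicts, file.path(dir, "germline.tsv"))
  html <- write_report(results, dir)
  structure(list(html_path = html, track_paths = tracks,
                 qc_dir = file.path(dir, "qc"), germline_path = germ),
            class = "report_bundle")
}
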