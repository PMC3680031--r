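#' Level-one clustering: group variants by genomic proximity
#'
#' Single-linkage chaining per chromosome: walking the position-sorted
#' variants, a new cluster starts whenever the gap from the previous
#' variant exceeds `gap_bp`. Every variant belongs to exactly one
#' cluster; singletons are allowed.
#'
#' @param collapsed collapsed-variant tibble (from
#'   [extract_cancer_exclusive()] or [annotate_collapsed()]), sorted or
#'   not — it is re-sorted by (chrom, pos).
#' @param gap_bp positive integer, maximum intra-cluster gap between
#'   consecutive variant positions.
#' @return the input rows with added columns `cluster_id`; cluster spans
#'   are available via [cluster_spans()].
#' @export
cluster_by_proximity <- function(collapsed, gap_bp = 1000L) {
  if (!is.numeric(gap_bp) || length(gap_bp) != 1 || gap_bp <= 0)
    abort("gap_bp must be a positive number")
  out <- arrange(collapsed, .data$chrom, .data$pos, .data$ref, .data$alt)
  if (nrow(out) == 0) {
    out$cluster_id <- character()
    return(out)
  }
  new_chrom <- c(TRUE, out$chrom[-1] != out$chrom[-nrow(out)])
  gap <- c(0L, diff(out$pos))
  breaks <- new_chrom | gap > gap_bp
  idx <- cumsum(breaks)
  out$cluster_id <- sprintf("PC%04d", idx)
  out
}

#' Cluster spans and carrier unions for level-one clusters
#'
#' @param clustered output of [cluster_by_proximity()].
#' @return one row per cluster: `cluster_id, chrom, start` (0-based
#'   inclusive, leftmost variant), `end` (0-based exclusive, rightmost
#'   footprint end), `n_variants`, `carrier_union` (list-column).
#' @export
cluster_spans <- function(clustered) {
  clustered |>
    group_by(.data$cluster_id, .data$chrom) |>
    summarise(
      start = min(.data$pos) - 1L,
      end = max(.data$pos - 1L + nchar(.data$ref)),
      n_variants = n(),
      carrier_union = list(sort(unique(unlist(.data$carriers)))),
      .groups = "drop"
    ) |>
    arrange(.data$chrom, .data$start)
}

#' Level-two clustering: group proximity clusters by annotated region
#'
#' Every proximity cluster overlapping (by at least 1 bp) an annotation
#' record of a target category is attached to that record; clusters
#' attaching to the same record merge into one hotspot. A cluster
#' overlapping k records contributes to k hotspots (multi-assignment).
#' Clusters overlapping no target record become novel-region hotspots
#' spanning exactly their own extent — so every variant is guaranteed a
#' hotspot.
#'
#' @param clustered output of [cluster_by_proximity()].
#' @param db an `annotation_db`.
#' @param target_categories categories to attach to (e.g.
#'   `c("gene", "promoter", "utr")`). Must all exist in the database.
#' @return one row per hotspot: `hotspot_id, chrom, start, end` (0-based
#'   half-open), `region_name, region_category, record_id` (NA for novel
#'   regions), `cluster_ids` (list), `variants` (list of row indices into
#'   `clustered`), `n_variants`, `carrier_union` (list).
#' @export
cluster_by_function <- function(clustered, db, target_categories) {
  stopifnot(inherits(db, "annotation_db"))
  known <- unique(db$records$category)
  unknown <- setdiff(target_categories, known)
  if (length(unknown) > 0)
    abort(paste0("unknown annotation category: ",
                 paste(unknown, collapse = ", ")))
  spans <- cluster_spans(clustered)
  recs <- filter(db$records, .data$category %in% target_categories)
  assignments <- vector("list", nrow(spans))
  if (nrow(recs) > 0 && nrow(spans) > 0) {
    gr_rec <- GenomicRanges::GRanges(recs$chrom,
                                     IRanges::IRanges(recs$start + 1L, recs$end))
    gr_cl <- GenomicRanges::GRanges(spans$chrom,
                                    IRanges::IRanges(spans$start + 1L, spans$end))
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_cl, gr_rec))
    for (i in seq_along(S4Vectors::queryHits(hits))) {
      q <- S4Vectors::queryHits(hits)[i]
      assignments[[q]] <- c(assignments[[q]], S4Vectors::subjectHits(hits)[i])
    }
  }
  rows <- list()
  # annotated hotspots: one per hit record, merging all attached clusters
  hit_records <- sort(unique(unlist(assignments)))
  for (r in hit_records) {
    cl_idx <- which(vapply(assignments, function(a) r %in% a, logical(1)))
    member_rows <- which(clustered$cluster_id %in% spans$cluster_id[cl_idx])
    rows[[length(rows) + 1L]] <- tibble(
      chrom = recs$chrom[r],
      start = min(spans$start[cl_idx], recs$start[r]),
      end = max(spans$end[cl_idx], recs$end[r]),
      region_name = recs$name[r], region_category = recs$category[r],
      record_id = recs$record_id[r],
      cluster_ids = list(spans$cluster_id[cl_idx]),
      variants = list(member_rows)
    )
  }
  # novel hotspots: clusters with no target-record overlap
  for (q in which(vapply(assignments, is.null, logical(1)))) {
    member_rows <- which(clustered$cluster_id == spans$cluster_id[q])
    rows[[length(rows) + 1L]] <- tibble(
      chrom = spans$chrom[q], start = spans$start[q], end = spans$end[q],
      region_name = paste0("novel_", spans$chrom[q], "_", spans$start[q]),
      region_category = "novel", record_id = NA_character_,
      cluster_ids = list(spans$cluster_id[q]),
      variants = list(member_rows)
    )
  }
  if (length(rows) == 0) {
    return(tibble(hotspot_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  region_name = character(), region_category = character(),
                  record_id = character(), cluster_ids = list(),
                  variants = list(), n_variants = integer(),
                  carrier_union = list()))
  }
  hs <- bind_rows(rows) |>
    arrange(.data$chrom, .data$start, .data$region_name) |>
    mutate(
      hotspot_id = sprintf("HS%04d", row_number()),
      n_variants = map_int(.data$variants, length),
      carrier_union = map(.data$variants, function(v)
        sort(unique(unlist(clustered$carriers[v]))))
    ) |>
    select("hotspot_id", "chrom", "start", "end", "region_name",
           "region_category", "record_id", "cluster_ids", "variants",
           "n_variants", "carrier_union")
  hs
}

#' Count distinct mutated samples per cohort in a hotspot
#'
#' A sample carrying several variants inside the hotspot counts once.
#'
#' @param carrier_union character vector of carrier sample ids (one
#'   hotspot's `carrier_union` entry).
#' @param samples the store's sample table.
#' @return named integer vector, cohort -> distinct mutated samples.
#' @export
count_group_samples <- function(carrier_union, samples) {
  carrier_union <- unique(unlist(carrier_union))
  missing_ids <- setdiff(carrier_union, samples$sample_id)
  if (length(missing_ids) > 0)
    abort(paste0("carrier(s) not in sample table: ",
                 paste(missing_ids, collapse = ", ")))
  coh <- samples$cohort[match(carrier_union, samples$sample_id)]
  tab <- table(coh)
  setNames(as.integer(tab), names(tab))
}

#' Add per-cohort mutated-sample counts to a hotspot table
#'
#' @param hotspots output of [cluster_by_function()].
#' @param samples the store's sample table.
#' @return hotspots with `n_samples` and a `group_counts` column
#'   formatted as `cohort=count;` pairs.
#' @export
add_group_counts <- function(hotspots, samples) {
  gc <- map(hotspots$carrier_union, count_group_samples, samples = samples)
  hotspots$n_samples <- map_int(hotspots$carrier_union,
                                function(x) length(unique(unlist(x))))
  hotspots$group_counts <- map_chr(gc, function(g)
    paste0(names(g), "=", g, ";", collapse = ""))
  hotspots
}

#' Write hotspot table as TSV and BED
#'
#' @param hotspots output of [cluster_by_function()] (ideally after
#'   [add_group_counts()]).
#' @param dir output directory.
#' @return invisible character vector `(tsv, bed)` of paths.
#' @export
write_hotspots <- function(hotspots, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- hotspots |>
    mutate(cluster_ids = map_chr(.data$cluster_ids, paste, collapse = ","),
           carriers = map_chr(.data$carrier_union, paste, collapse = ",")) |>
    select("hotspot_id", "chrom", "start", "end", "region_name",
           "region_category", "n_variants",
           dplyr::any_of(c("n_samples", "group_counts")),
           "cluster_ids", "carriers")
  tsv <- file.path(dir, "hotspots.tsv")
  bed <- file.path(dir, "hotspots.bed")
  write_tsv_plain(flat, tsv)
  writeLines(sprintf("%s\t%d\t%d\t%s", flat$chrom, flat$start, flat$end,
                     flat$hotspot_id), bed)
  invisible(c(tsv, bed))
}
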