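#' Build a pipeline run configuration
#'
#' Collects every input path and tuning knob of the five-phase run.
#' Also constructible from a YAML file via [read_run_config()].
#'
#' @param metadata sample metadata TSV.
#' @param vcfs named character vector, sample_id -> VCF path.
#' @param reference reference FASTA.
#' @param gtf gene-model GTF (optional).
#' @param beds list of `list(path, category)` BED annotation sets.
#' @param polymorphisms named character vector, set_name -> VCF path.
#' @param cohort cohort to extract.
#' @param exclude_sets polymorphism set names to filter against.
#' @param gap_bp level-one clustering gap threshold (bp).
#' @param target_categories level-two clustering categories.
#' @param thresholds a [quality_thresholds()] object.
#' @param callable_length callable genome length (bp); defaults to the
#'   reference length.
#' @param alpha FDR significance level used in the run log.
#' @param tumor_alignments,normal_alignments named character vectors,
#'   sample_id -> SAM/BAM path (optional; phase four is skipped without
#'   them and all extracted variants are treated as somatic).
#' @param out_dir output directory; intermediate TSVs land here, the
#'   report bundle under `<out_dir>/report`.
#' @return a `run_config` list.
#' @export
run_config <- function(metadata, vcfs, reference, out_dir,
                       gtf = NULL, beds = list(),
                       polymorphisms = character(), cohort,
                       exclude_sets = names(polymorphisms),
                       gap_bp = 1000L,
                       target_categories = c("gene", "promoter", "utr"),
                       thresholds = quality_thresholds(),
                       callable_length = NULL, alpha = 0.05,
                       tumor_alignments = NULL, normal_alignments = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [run_config()]'s arguments
#'   (`vcfs`, `polymorphisms`, `tumor_alignments`, `normal_alignments`
#'   as name -> path maps; `thresholds` as a map of
#'   [quality_thresholds()] arguments).
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  as_map <- function(x) if (is.null(x)) NULL else unlist(x)
  run_config(
    metadata = y$metadata, vcfs = as_map(y$vcfs), reference = y$reference,
    out_dir = y$out_dir, gtf = y$gtf,
    beds = y$beds %||% list(),
    polymorphisms = as_map(y$polymorphisms) %||% character(),
    cohort = y$cohort,
    exclude_sets = y$exclude_sets %||% names(as_map(y$polymorphisms)),
    gap_bp = y$gap_bp %||% 1000L,
    target_categories = y$target_categories %||% c("gene", "promoter", "utr"),
    thresholds = do.call(quality_thresholds,
                         lapply(y$thresholds %||% list(), as.integer)),
    callable_length = y$callable_length, alpha = y$alpha %||% 0.05,
    tumor_alignments = as_map(y$tumor_alignments),
    normal_alignments = as_map(y$normal_alignments)
  )
}

phase_try <- function(phase, expr) {
  tryCatch(expr, error = function(e)
    abort(paste0(phase, ": ", conditionMessage(e))))
}

#' Run the five-phase hotspot pipeline end to end
#'
#' Phase one imports samples, VCFs and polymorphism sets and extracts
#' the cancer-exclusive variant set; phase two annotates and
#' effect-classifies it; phase three clusters by proximity and by
#' annotated region; phase four validates each (variant, carrier) pair
#' against tumor/matched-normal pileups (skipped when no alignments are
#' configured); phase five scores regions against the background rate,
#' corrects with Benjamini-Hochberg, tests per-cohort enrichment and
#' writes the ranked HTML report with UCSC custom tracks. Each phase
#' writes its TSV under `out_dir` so any phase can be re-run from its
#' predecessor's output; a one-line-per-phase log with record counts is
#' written to `<out_dir>/pipeline.log`.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return a `report_bundle` (see [write_bundle()]) with the scored
#'   results attached as `$results` and verdicts as `$verdicts`.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) inform(line)
  }

  # ---- phase one: store + cancer-exclusive extraction
  collapsed <- NULL; store <- NULL
  phase_try("phase one (extraction)", {
    for (p in c(cfg$metadata, cfg$vcfs, cfg$reference, unname(cfg$polymorphisms)))
      if (!file.exists(p)) stop("input file not found: ", p)
    store <- variant_store() |>
      attach_reference(cfg$reference) |>
      import_samples(cfg$metadata)
    for (s in names(cfg$vcfs)) store <- import_vcf(store, cfg$vcfs[[s]], s)
    for (ps in names(cfg$polymorphisms))
      store <- import_polymorphism_set(store, cfg$polymorphisms[[ps]], ps)
    collapsed <- extract_cancer_exclusive(store, cfg$cohort, cfg$exclude_sets)
    germ1 <- extract_germline(store, cfg$cohort)
    write_extraction(collapsed, cfg$out_dir, "exclusive")
    write_extraction(germ1, cfg$out_dir, "germline_candidates")
    say("phase one: %d samples, %d variants in store, %d cancer-exclusive, %d germline-candidate",
        nrow(store$samples), nrow(store$variants), nrow(collapsed), nrow(germ1))
  })

  # ---- phase two: annotation + effect labels
  db <- NULL
  phase_try("phase two (annotation)", {
    db <- annotation_db()
    if (!is.null(cfg$gtf)) db <- load_gtf(db, cfg$gtf)
    for (b in cfg$beds) db <- load_bed(db, b$path, b$category)
    collapsed <- annotate_collapsed(db, collapsed, store$reference)
    write_tsv_plain(
      mutate(collapsed, carriers = map_chr(.data$carriers, paste, collapse = ",")),
      file.path(cfg$out_dir, "annotated.tsv"))
    say("phase two: %d annotation records, %d gene models; %d/%d variants annotated",
        nrow(db$records), nrow(db$models),
        sum(collapsed$overlapping_records != ""), nrow(collapsed))
  })

  # ---- phase three: two-level clustering
  clustered <- NULL; hotspots <- NULL
  phase_try("phase three (clustering)", {
    clustered <- cluster_by_proximity(collapsed, cfg$gap_bp)
    cats <- intersect(cfg$target_categories, unique(db$records$category))
    hotspots <- cluster_by_function(clustered, db, cats) |>
      add_group_counts(store$samples)
    write_hotspots(hotspots, cfg$out_dir)
    say("phase three: %d proximity clusters -> %d hotspots (%d novel)",
        length(unique(clustered$cluster_id)), nrow(hotspots),
        sum(hotspots$region_category == "novel"))
  })

  # ---- phase four: pileup validation
  verdicts <- NULL
  phase_try("phase four (validation)", {
    if (!is.null(cfg$tumor_alignments) && !is.null(cfg$normal_alignments)) {
      verdicts <- validate_hotspots(
        hotspots, clustered, store$samples,
        cfg$tumor_alignments, cfg$normal_alignments, cfg$thresholds,
        qc_dir = file.path(cfg$out_dir, "report", "qc"))
      write_tsv_plain(verdicts, file.path(cfg$out_dir, "verdicts.tsv"))
      say("phase four: %d pairs validated (%d somatic, %d germline, %d artifact, %d unknown)",
          nrow(verdicts), sum(verdicts$status == "somatic"),
          sum(verdicts$status == "germline"),
          sum(verdicts$status == "artifact"),
          sum(verdicts$status == "unknown"))
    } else {
      say("phase four: skipped (no alignments configured)")
    }
  })

  # ---- phase five: scoring, ranking, report
  bundle <- NULL
  phase_try("phase five (scoring/report)", {
    n_tumor <- sum(store$samples$cohort == cfg$cohort &
                     store$samples$status == "tumor")
    callable <- cfg$callable_length %||%
      sum(Biostrings::width(store$reference))
    k <- count_somatic_observations(hotspots, verdicts, clustered)
    n_obs <- if (!is.null(verdicts)) sum(verdicts$status == "somatic")
             else sum(map_int(collapsed$carriers, length))
    bg <- estimate_background(max(n_obs, 1L), callable, n_tumor)
    results <- score_hotspots(hotspots, k, bg) |>
      add_group_enrichment(store$samples)
    results$summary <- map_chr(seq_len(nrow(results)), function(i) {
      rid <- results$record_id[i]
      if (is.na(rid)) "novel region (no annotation)"
      else annotation_summary(db, rid)
    })
    write_results(results, file.path(cfg$out_dir, "results.tsv"))
    bdir <- file.path(cfg$out_dir, "report")
    if (is.null(verdicts) || nrow(verdicts) == 0) {
      # without a validation phase every extracted variant counts as somatic
      pseudo <- tibble(
        chrom = clustered$chrom, pos = clustered$pos, ref = clustered$ref,
        alt = clustered$alt, sample = map_chr(clustered$carriers, 1),
        status = "somatic", tumor_alt = NA_integer_,
        tumor_depth = NA_integer_, normal_alt = NA_integer_,
        normal_depth = NA_integer_, low_conf = NA)
      bundle <- write_bundle(results, collapsed, pseudo, bdir)
    } else {
      bundle <- write_bundle(results, collapsed, verdicts, bdir)
    }
    say("phase five: background %.3g /bp/sample; %d hotspots scored, %d at q < %g",
        bg$per_base_rate, nrow(results), sum(results$q_value < cfg$alpha),
        cfg$alpha)
    bundle$results <- results
    bundle$verdicts <- verdicts
  })
  writeLines(log_lines, file.path(cfg$out_dir, "pipeline.log"))
  bundle
}
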