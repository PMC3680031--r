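# per-session cache of SAM -> sorted/indexed BAM conversions
.aln_cache <- new.env(parent = emptyenv())

# Accepts .sam or .bam; returns a sorted, indexed BAM path.
alignment_bam <- function(path) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  key <- normalizePath(path)
  if (!is.null(.aln_cache[[key]]) && file.exists(.aln_cache[[key]]))
    return(.aln_cache[[key]])
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
  } else {
    if (!file.exists(paste0(path, ".bai")))
      Rsamtools::indexBam(path)
    path
  }
  .aln_cache[[key]] <- bam
  bam
}

#' Quality thresholds for pileup-based validation
#'
#' All thresholds are manual knobs of the validation phase; these are
#' the package defaults.
#'
#' @param min_mapq minimum read mapping quality (phred).
#' @param min_baseq minimum base-call quality (phred).
#' @param min_alt_tumor minimum passing alt-supporting reads in the
#'   tumor for a call not to be an artifact.
#' @param min_alt_normal passing alt-supporting reads in the normal at
#'   or above which the call is germline.
#' @param min_normal_depth passing normal depth below which the verdict
#'   is flagged low-confidence.
#' @return a `quality_thresholds` list.
#' @export
quality_thresholds <- function(min_mapq = 20L, min_baseq = 10L,
                               min_alt_tumor = 2L, min_alt_normal = 2L,
                               min_normal_depth = 8L) {
  th <- list(min_mapq = min_mapq, min_baseq = min_baseq,
             min_alt_tumor = min_alt_tumor, min_alt_normal = min_alt_normal,
             min_normal_depth = min_normal_depth)
  if (any(unlist(th) < 0)) abort("quality thresholds must be non-negative")
  structure(th, class = "quality_thresholds")
}

#' Pileup column at one position of an alignment file
#'
#' One entry per read covering the position with an aligned base; reads
#' with a deletion spanning the position contribute a gap entry
#' (`base == "-"`, `base_quality` NA) which is excluded from base
#' counting. The `indel` column records an insertion immediately after
#' the position (`"+SEQ"`) or a deletion starting immediately after it
#' (`"-<length>"`), for allele-exact indel support counting. Entries are
#' unfiltered — quality filtering happens at verdict time.
#'
#' @param alignments path to a coordinate-sorted SAM or BAM file.
#' @param chrom chromosome name (as in the alignment header).
#' @param pos 1-based position.
#' @return a tibble with columns `chrom, pos, base, base_quality,
#'   mapping_quality, read_id, indel`.
#' @export
pileup_at <- function(alignments, chrom, pos) {
  bam <- alignment_bam(alignments)
  header_chroms <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  if (!chrom %in% header_chroms)
    abort(paste0("chromosome ", chrom, " absent from alignment header of ",
                 alignments))
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)),
    what = c("qname", "pos", "cigar", "seq", "qual", "mapq")
  )
  reads <- Rsamtools::scanBam(bam, param = param)[[1]]
  empty <- tibble(chrom = character(), pos = integer(), base = character(),
                  base_quality = integer(), mapping_quality = integer(),
                  read_id = character(), indel = character())
  if (length(reads$qname) == 0) return(empty)
  rows <- list()
  for (i in seq_along(reads$qname)) {
    ent <- read_base_at(reads$pos[i], as.character(reads$cigar[i]),
                        as.character(reads$seq[[i]]),
                        as.character(reads$qual[[i]]), pos)
    if (is.null(ent)) next
    rows[[length(rows) + 1L]] <- tibble(
      chrom = chrom, pos = as.integer(pos), base = ent$base,
      base_quality = ent$baseq, mapping_quality = as.integer(reads$mapq[i]),
      read_id = reads$qname[i], indel = ent$indel
    )
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows)
}

# CIGAR walk: the base (and any immediately following indel) a read
# contributes at reference position target. NULL when the read does not
# align across target.
read_base_at <- function(read_start, cigar, seq, qual, target) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  kinds <- sub("\\d+", "", ops)
  rpos <- read_start   # next reference position
  qpos <- 1L           # next query position
  for (k in seq_along(kinds)) {
    kind <- kinds[k]; len <- lens[k]
    if (kind %in% c("M", "=", "X")) {
      if (target >= rpos && target < rpos + len) {
        qi <- qpos + (target - rpos)
        indel <- NA_character_
        if (target == rpos + len - 1L && k < length(kinds)) {
          nk <- kinds[k + 1L]
          if (nk == "I")
            indel <- paste0("+", substr(seq, qpos + len, qpos + len + lens[k + 1L] - 1L))
          else if (nk == "D")
            indel <- paste0("-", lens[k + 1L])
        }
        return(list(base = substr(seq, qi, qi),
                    baseq = utf8ToInt(substr(qual, qi, qi)) - 33L,
                    indel = indel))
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (kind == "I") {
      qpos <- qpos + len
    } else if (kind %in% c("D", "N")) {
      if (target >= rpos && target < rpos + len && kind == "D")
        return(list(base = "-", baseq = NA_integer_, indel = NA_character_))
      rpos <- rpos + len
    } else if (kind == "S") {
      qpos <- qpos + len
    }
  }
  NULL
}

# alt-supporting entries for an allele within a (filtered) pileup tibble
alt_support <- function(pileup, ref, alt) {
  if (nrow(pileup) == 0) return(0L)
  if (nchar(ref) == 1L && nchar(alt) == 1L)
    sum(pileup$base == alt, na.rm = TRUE)
  else if (nchar(alt) > nchar(ref))   # insertion after the anchor base
    sum(pileup$indel == paste0("+", substr(alt, 2L, nchar(alt))), na.rm = TRUE)
  else                                 # deletion of length nchar(ref)-1
    sum(pileup$indel == paste0("-", nchar(ref) - 1L), na.rm = TRUE)
}

filter_pileup <- function(pileup, th) {
  filter(pileup,
         .data$mapping_quality >= th$min_mapq,
         is.na(.data$base_quality) | .data$base_quality >= th$min_baseq,
         .data$base != "-")
}

#' Classify one variant from tumor and matched-normal pileups
#'
#' After dropping entries below the mapping- or base-quality thresholds,
#' the decision rule is applied in order: (1) fewer than
#' `min_alt_tumor` alt-supporting tumor entries — `artifact`; (2) at
#' least `min_alt_normal` alt-supporting normal entries — `germline`;
#' (3) otherwise — `somatic`. A passing normal depth below
#' `min_normal_depth` sets `low_conf` (the status is still assigned).
#'
#' @param tumor,normal pileup tibbles from [pileup_at()], both at the
#'   variant's position.
#' @param chrom,pos,ref,alt the variant.
#' @param th a [quality_thresholds()] object.
#' @return one-row tibble: `chrom, pos, ref, alt, status, tumor_alt,
#'   tumor_depth, normal_alt, normal_depth, low_conf`.
#' @export
classify_variant <- function(tumor, normal, chrom, pos, ref, alt,
                             th = quality_thresholds()) {
  for (p in list(tumor, normal))
    if (nrow(p) > 0 && (any(p$pos != pos) || any(p$chrom != chrom)))
      abort("pileup column position does not match variant position")
  tf <- filter_pileup(tumor, th)
  nf <- filter_pileup(normal, th)
  t_alt <- alt_support(tf, ref, alt)
  n_alt <- alt_support(nf, ref, alt)
  status <- if (t_alt < th$min_alt_tumor) "artifact"
            else if (n_alt >= th$min_alt_normal) "germline"
            else "somatic"
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
         status = status,
         tumor_alt = as.integer(t_alt), tumor_depth = nrow(tf),
         normal_alt = as.integer(n_alt), normal_depth = nrow(nf),
         low_conf = nrow(nf) < th$min_normal_depth)
}

#' Validate all variants of a hotspot table against alignments
#'
#' Each (variant, carrier) pair is re-examined jointly in the carrier's
#' tumor alignment and its matched normal's alignment and classified
#' somatic / germline / artifact. Pairs whose alignment files are
#' missing are retained with status `unknown` and a logged warning.
#' One side-by-side tumor/normal alignment-profile HTML page is written
#' per hotspot under `qc_dir`. Hotspots are processed independently (no
#' shared mutable state), so regions may be batched or parallelized by
#' the caller.
#'
#' @param hotspots output of [cluster_by_function()].
#' @param clustered the clustered variant table the hotspots index into.
#' @param samples the store's sample table (for matched-pair lookup).
#' @param tumor_alignments named character vector, tumor sample_id ->
#'   SAM/BAM path.
#' @param normal_alignments named character vector, normal sample_id ->
#'   SAM/BAM path.
#' @param th a [quality_thresholds()] object.
#' @param qc_dir directory for per-region QC HTML (created).
#' @return a tibble of verdicts: `hotspot_id, chrom, pos, ref, alt,
#'   sample, status, tumor_alt, tumor_depth, normal_alt, normal_depth,
#'   low_conf`.
#' @export
validate_hotspots <- function(hotspots, clustered, samples,
                              tumor_alignments, normal_alignments,
                              th = quality_thresholds(), qc_dir = NULL) {
  if (!is.null(qc_dir)) dir.create(qc_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  for (h in seq_len(nrow(hotspots))) {
    vrows <- hotspots$variants[[h]]
    verdicts <- list(); profiles <- list()
    for (v in vrows) {
      chrom <- clustered$chrom[v]; pos <- clustered$pos[v]
      ref <- clustered$ref[v]; alt <- clustered$alt[v]
      for (carrier in clustered$carriers[[v]]) {
        matched <- samples$matched_id[match(carrier, samples$sample_id)]
        tpath <- tumor_alignments[carrier]
        npath <- if (!is.na(matched)) normal_alignments[matched] else NA
        if (is.na(tpath) || is.na(npath) ||
            !file.exists(tpath) || !file.exists(npath)) {
          warn(paste0("missing alignment for ", carrier, " at ",
                      chrom, ":", pos, "; pair left unvalidated"))
          verdicts[[length(verdicts) + 1L]] <- tibble(
            chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
            status = "unknown", tumor_alt = NA_integer_,
            tumor_depth = NA_integer_, normal_alt = NA_integer_,
            normal_depth = NA_integer_, low_conf = TRUE, sample = carrier)
          next
        }
        tp <- pileup_at(tpath, chrom, pos)
        np <- pileup_at(npath, chrom, pos)
        vd <- classify_variant(tp, np, chrom, pos, ref, alt, th)
        vd$sample <- carrier
        verdicts[[length(verdicts) + 1L]] <- vd
        profiles[[length(profiles) + 1L]] <- list(
          variant = sprintf("%s:%d %s>%s", chrom, pos, ref, alt),
          sample = carrier, status = vd$status, tumor = tp, normal = np)
      }
    }
    vt <- if (length(verdicts) > 0) bind_rows(verdicts) else
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character(), status = character(), tumor_alt = integer(),
             tumor_depth = integer(), normal_alt = integer(),
             normal_depth = integer(), low_conf = logical(),
             sample = character())
    vt$hotspot_id <- rep(hotspots$hotspot_id[h], nrow(vt))
    out[[h]] <- vt
    if (!is.null(qc_dir))
      write_qc_html(hotspots$hotspot_id[h], hotspots$region_name[h],
                    profiles, file.path(qc_dir,
                                        paste0(hotspots$hotspot_id[h], ".html")))
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(hotspot_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  sample = character(), status = character(),
                  tumor_alt = integer(), tumor_depth = integer(),
                  normal_alt = integer(), normal_depth = integer(),
                  low_conf = logical()))
  }
  select(res, "hotspot_id", "chrom", "pos", "ref", "alt", "sample", "status",
         "tumor_alt", "tumor_depth", "normal_alt", "normal_depth", "low_conf")
}

# pileup text block: up to max_reads reads (first by read_id sort), one
# line per read: id, base, base quality, mapping quality
pileup_block <- function(pileup, max_reads = 50L) {
  if (nrow(pileup) == 0) return("(no coverage)")
  p <- arrange(pileup, .data$read_id)
  p <- head(p, max_reads)
  paste(sprintf("%-20s %s  bq=%-3s mq=%d", p$read_id, p$base,
                ifelse(is.na(p$base_quality), "-", p$base_quality),
                p$mapping_quality), collapse = "\n")
}

write_qc_html <- function(hotspot_id, region_name, profiles, path) {
  body <- character(0)
  for (pr in profiles) {
    body <- c(body, sprintf(
      "<h2>%s &mdash; sample %s (%s)</h2>",
      html_escape(pr$variant), html_escape(pr$sample), html_escape(pr$status)),
      "<table class='profile'><tr><th>tumor</th><th>matched normal</th></tr>",
      sprintf("<tr><td><pre>%s</pre></td><td><pre>%s</pre></td></tr></table>",
              html_escape(pileup_block(pr$tumor)),
              html_escape(pileup_block(pr$normal))))
  }
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'/>",
    sprintf("<title>QC %s</title>", html_escape(hotspot_id)),
    "<style>td{vertical-align:top;padding:4px 12px;border:1px solid #999}</style>",
    "</head><body>",
    sprintf("<h1>Alignment profiles: %s (%s)</h1>", html_escape(hotspot_id),
            html_escape(region_name)),
    if (length(body) > 0) body else "<p>No validated pairs.</p>",
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
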