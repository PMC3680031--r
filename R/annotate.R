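#' Create an empty annotation database
#'
#' Holds interval annotation records (genes, exons, introns, UTRs,
#' promoters, enhancers, TFBS, miRNA targets, regulatory regions, known
#' somatic sites, ...) and assembled gene models. Coordinates are stored
#' uniformly as 0-based half-open intervals; BED input passes through
#' unchanged, GTF/VCF input is converted at the boundary.
#'
#' @param chrom_style chromosome-name dialect; see [normalize_chrom()].
#' @return an object of class `annotation_db`.
#' @export
annotation_db <- function(chrom_style = c("strip", "chr", "asis")) {
  chrom_style <- match.arg(chrom_style)
  structure(
    list(
      records = tibble(
        record_id = character(), chrom = character(), start = integer(),
        end = integer(), category = character(), name = character(),
        strand = character()
      ),
      models = tibble(
        transcript_id = character(), gene_name = character(),
        chrom = character(), strand = character(), phase_offset = integer(),
        cds = list()
      ),
      chrom_style = chrom_style
    ),
    class = "annotation_db"
  )
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("<annotation_db>\n")
  cat("  records: ", nrow(x$records), " in ",
      length(unique(x$records$category)), " categories\n", sep = "")
  cat("  gene models: ", nrow(x$models), "\n", sep = "")
  invisible(x)
}

next_record_ids <- function(db, n, prefix) {
  paste0(prefix, seq(nrow(db$records) + 1L, length.out = n))
}

#' Load a BED annotation set into the database
#'
#' BED records keep their native 0-based half-open coordinates. Records
#' with non-positive width are rejected with a warning.
#'
#' @param db an `annotation_db`.
#' @param path BED3+ file path.
#' @param category annotation category to assign (e.g. `"promoter"`).
#' @return the database; `attr(db, "n_loaded")` holds the loaded count.
#' @export
load_bed <- function(db, path, category) {
  stopifnot(inherits(db, "annotation_db"), nzchar(category))
  gr <- rtracklayer::import(path, format = "bed")
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  ok <- start0 < end0
  if (any(!ok))
    warn(paste0(sum(!ok), " BED record(s) with start >= end rejected in ", path))
  nm <- if ("name" %in% names(S4Vectors::mcols(gr)))
    as.character(S4Vectors::mcols(gr)$name) else rep(NA_character_, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  new <- tibble(
    record_id = next_record_ids(db, sum(ok), "A"),
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))[ok],
                            db$chrom_style),
    start = start0[ok], end = end0[ok],
    category = category,
    name = ifelse(is.na(nm[ok]), paste0(category, "_", seq_len(sum(ok))), nm[ok]),
    strand = strand[ok]
  )
  db$records <- bind_rows(db$records, new)
  attr(db, "n_loaded") <- nrow(new)
  db
}

#' Load gene models from a GTF/GFF file
#'
#' Assembles one gene model per transcript from its CDS features and
#' derives exon, intron and UTR annotation records (introns are the gaps
#' between exons of one transcript; UTR is the exonic minus CDS
#' footprint), plus a gene-span record per transcript. GTF's 1-based
#' closed coordinates are converted to the internal 0-based half-open
#' form.
#'
#' @param db an `annotation_db`.
#' @param path GTF/GFF path.
#' @return the database; `attr(db, "n_models")` and
#'   `attr(db, "n_records")` hold the model and derived-record counts.
#' @export
load_gtf <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$seqid <- normalize_chrom(as.character(g$seqid), db$chrom_style)
  if (!"transcript_id" %in% names(g)) g$transcript_id <- NA_character_
  if (!"gene_name" %in% names(g))
    g$gene_name <- if ("gene_id" %in% names(g)) g$gene_id else g$transcript_id

  cds <- g[g$type == "CDS", , drop = FALSE]
  orphan <- is.na(cds$transcript_id) | cds$transcript_id == ""
  if (any(orphan))
    warn(paste0(sum(orphan), " CDS record(s) without transcript_id skipped"))
  cds <- cds[!orphan, , drop = FALSE]
  exons <- g[g$type == "exon" & !is.na(g$transcript_id), , drop = FALSE]
  if (nrow(exons) == 0) exons <- cds   # CDS-only files: exons default to CDS

  models <- list(); records <- list()
  for (tx in unique(cds$transcript_id)) {
    cc <- cds[cds$transcript_id == tx, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    strand <- as.character(cc$strand[1])
    chrom <- as.character(cc$seqid[1])
    gene <- as.character(cc$gene_name[1])
    seg <- tibble(start = as.integer(cc$start) - 1L, end = as.integer(cc$end))
    # phase of the 5'-most CDS base
    ph <- if (strand == "+") cc$phase[1] else cc$phase[nrow(cc)]
    ph <- suppressWarnings(as.integer(as.character(ph)))
    if (is.na(ph)) ph <- 0L
    models[[length(models) + 1L]] <- tibble(
      transcript_id = tx, gene_name = gene, chrom = chrom, strand = strand,
      phase_offset = ph, cds = list(seg)
    )
    ee <- exons[exons$transcript_id == tx, , drop = FALSE]
    ee <- ee[order(ee$start), , drop = FALSE]
    if (nrow(ee) == 0) ee <- cc
    ex <- tibble(start = as.integer(ee$start) - 1L, end = as.integer(ee$end))
    gene_span <- tibble(start = min(ex$start), end = max(ex$end),
                        category = "gene", name = gene)
    exon_rec <- mutate(ex, category = "exon",
                       name = paste0(tx, "_exon", seq_len(nrow(ex))))
    intron_rec <- if (nrow(ex) > 1)
      tibble(start = ex$end[-nrow(ex)], end = ex$start[-1],
             category = "intron",
             name = paste0(tx, "_intron", seq_len(nrow(ex) - 1L)))
    else tibble(start = integer(), end = integer(),
                category = character(), name = character())
    # UTR = exonic footprint minus CDS footprint
    utr <- interval_setdiff(ex, seg)
    utr_rec <- if (nrow(utr) > 0)
      mutate(utr, category = "utr", name = paste0(tx, "_utr", seq_len(nrow(utr))))
    else tibble(start = integer(), end = integer(),
                category = character(), name = character())
    recs <- bind_rows(gene_span, exon_rec, intron_rec, utr_rec)
    recs$chrom <- chrom; recs$strand <- strand
    records[[length(records) + 1L]] <- recs
  }
  new_models <- if (length(models) > 0) bind_rows(models) else db$models[0, ]
  new_records <- if (length(records) > 0) bind_rows(records) else
    tibble(start = integer(), end = integer(), category = character(),
           name = character(), chrom = character(), strand = character())
  if (nrow(new_records) > 0) {
    new_records$record_id <- next_record_ids(db, nrow(new_records), "G")
    new_records <- select(new_records, "record_id", "chrom", "start", "end",
                          "category", "name", "strand")
    db$records <- bind_rows(db$records, new_records)
  }
  db$models <- bind_rows(db$models, new_models)
  attr(db, "n_models") <- nrow(new_models)
  attr(db, "n_records") <- nrow(new_records)
  db
}

# set difference of 0-based half-open interval tibbles on one chrom
interval_setdiff <- function(a, b) {
  ia <- IRanges::IRanges(start = a$start + 1L, end = a$end)
  ib <- IRanges::IRanges(start = b$start + 1L, end = b$end)
  d <- IRanges::setdiff(ia, ib)
  tibble(start = IRanges::start(d) - 1L, end = IRanges::end(d))
}

records_granges <- function(db) {
  GenomicRanges::GRanges(
    seqnames = db$records$chrom,
    ranges = IRanges::IRanges(start = db$records$start + 1L, end = db$records$end)
  )
}

#' Annotation records overlapping one variant's reference footprint
#'
#' The footprint of a variant with reference allele `ref` at 1-based
#' `pos` is the 0-based half-open interval `[pos-1, pos-1+nchar(ref))`.
#' Overlap queries use an interval index (sublinear in store size).
#'
#' @param db an `annotation_db`.
#' @param chrom chromosome (any dialect; normalized internally).
#' @param pos 1-based position of the first affected base.
#' @param ref reference allele (length sets the footprint; default 1 bp).
#' @param categories optional restriction to these categories.
#' @return tibble of overlapping annotation records (possibly empty —
#'   novel territory).
#' @export
annotate_variant <- function(db, chrom, pos, ref = "N", categories = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  recs <- db$records
  if (!is.null(categories)) recs <- filter(recs, .data$category %in% categories)
  if (nrow(recs) == 0) return(recs)
  chrom <- normalize_chrom(chrom, db$chrom_style)
  gr <- GenomicRanges::GRanges(recs$chrom,
                               IRanges::IRanges(recs$start + 1L, recs$end))
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(pos, pos + nchar(ref) - 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, gr))
  recs[S4Vectors::subjectHits(hits), ]
}

#' Annotate and effect-classify a collapsed variant table (phase two)
#'
#' Adds `effect` (synonymous / non-synonymous / non-coding, from
#' [classify_effect()]) and `overlapping_records` (semicolon-joined
#' `name[category]` labels of all overlapping annotation records; empty
#' string for novel territory) to each variant.
#'
#' @param db an `annotation_db`.
#' @param collapsed output of [extract_cancer_exclusive()].
#' @param reference a `DNAStringSet` (or FASTA path) for codon lookup;
#'   `NULL` leaves all effects `non_coding` outside CDS logic disabled.
#' @return the input tibble with populated `effect` and a new
#'   `overlapping_records` column.
#' @export
annotate_collapsed <- function(db, collapsed, reference = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  if (is.character(reference)) reference <- Biostrings::readDNAStringSet(reference)
  if (!is.null(reference))
    names(reference) <- normalize_chrom(sub("\\s.*$", "", names(reference)),
                                        db$chrom_style)
  if (nrow(collapsed) == 0) {
    collapsed$overlapping_records <- character()
    return(collapsed)
  }
  recs <- db$records
  over <- character(nrow(collapsed))
  if (nrow(recs) > 0) {
    gr <- GenomicRanges::GRanges(recs$chrom,
                                 IRanges::IRanges(recs$start + 1L, recs$end))
    q <- GenomicRanges::GRanges(
      normalize_chrom(collapsed$chrom, db$chrom_style),
      IRanges::IRanges(collapsed$pos, collapsed$pos + nchar(collapsed$ref) - 1L)
    )
    hits <- suppressWarnings(GenomicRanges::findOverlaps(q, gr))
    lab <- paste0(recs$name, "[", recs$category, "]")
    by_q <- split(lab[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
    for (k in names(by_q)) over[as.integer(k)] <- paste(unique(by_q[[k]]),
                                                        collapse = ";")
  }
  collapsed$overlapping_records <- over
  collapsed$effect <- vapply(seq_len(nrow(collapsed)), function(i) {
    classify_effect(db, collapsed$chrom[i], collapsed$pos[i],
                    collapsed$ref[i], collapsed$alt[i], reference)
  }, character(1))
  collapsed
}

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Classify the coding effect of one variant
#'
#' An SNV falling inside any transcript's CDS has its codon translated
#' with the reference and alternate base (reverse-complemented for
#' minus-strand transcripts): an identical amino acid is `synonymous`,
#' anything else — including stop gain/loss — `non_synonymous`. When
#' overlapping transcripts disagree the most severe label wins
#' (`non_synonymous` > `synonymous` > `non_coding`). SNVs outside every
#' CDS and all indels outside CDS are `non_coding`; indels inside a CDS
#' are `non_synonymous` (no frameshift/in-frame distinction is made).
#'
#' @param db an `annotation_db` with gene models loaded.
#' @param chrom,pos,ref,alt the variant (1-based `pos`).
#' @param reference a `DNAStringSet`; required to translate codons. If
#'   the FASTA base disagrees with `ref` an error names the site.
#' @return one of `"synonymous"`, `"non_synonymous"`, `"non_coding"`.
#' @export
classify_effect <- function(db, chrom, pos, ref, alt, reference = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  chrom <- normalize_chrom(chrom, db$chrom_style)
  g0 <- pos - 1L                      # 0-based first affected base
  footprint_end <- g0 + nchar(ref)    # half-open
  models <- filter(db$models, .data$chrom == !!chrom)
  if (nrow(models) == 0) return("non_coding")
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L

  in_cds <- vapply(models$cds, function(seg)
    any(seg$start < footprint_end & g0 < seg$end), logical(1))
  if (!any(in_cds)) return("non_coding")
  if (!is_snv) return("non_synonymous")

  labels <- character(0)
  for (mi in which(in_cds)) {
    seg <- models$cds[[mi]]
    strand <- models$strand[mi]
    ph <- models$phase_offset[mi]
    widths <- seg$end - seg$start
    total <- sum(widths)
    si <- which(seg$start <= g0 & g0 < seg$end)
    if (length(si) == 0) next       # footprint touched CDS but base outside
    off <- if (si > 1) sum(widths[seq_len(si - 1L)]) else 0L
    off <- off + (g0 - seg$start[si])
    cpos <- if (strand == "+") off else total - 1L - off
    ce <- cpos - ph
    if (ce < 0) next                # before first complete codon
    codon_t <- ph + (ce %/% 3L) * 3L + 0:2
    if (any(codon_t >= total)) next # incomplete terminal codon
    # map transcript coords back to genomic 0-based positions
    gpos <- vapply(codon_t, function(tc) {
      go <- if (strand == "+") tc else total - 1L - tc
      cum <- cumsum(widths)
      k <- which(go < cum)[1]
      prev <- if (k > 1) cum[k - 1L] else 0L
      seg$start[k] + (go - prev)
    }, numeric(1))
    if (is.null(reference) || !chrom %in% names(reference))
      abort(paste0("reference sequence for chromosome ", chrom,
                   " required to classify coding effect"))
    rs <- reference[[chrom]]
    gbases <- vapply(gpos, function(p)
      as.character(Biostrings::subseq(rs, p + 1L, p + 1L)), character(1))
    ref_fa <- gbases[match(g0, gpos)]
    if (!is.na(ref_fa) && ref_fa != ref)
      abort(paste0("reference mismatch at ", chrom, ":", pos,
                   " (FASTA ", ref_fa, ", variant ref ", ref, ")"))
    # gbases are ordered by transcript coordinate already (the per-base
    # genomic mapping ran in transcript order), so minus-strand codons
    # need complementing only, not reversing
    tbases <- if (strand == "+") gbases else
      vapply(gbases, complement_base, character(1))
    ref_codon <- paste(tbases, collapse = "")
    within <- ce %% 3L
    alt_t <- if (strand == "+") alt else complement_base(alt)
    alt_bases <- tbases
    alt_bases[within + 1L] <- alt_t
    alt_codon <- paste(alt_bases, collapse = "")
    aa_ref <- Biostrings::GENETIC_CODE[[ref_codon]]
    aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
    labels <- c(labels, if (aa_ref == aa_alt) "synonymous" else "non_synonymous")
  }
  if (length(labels) == 0) return("non_coding")
  if (any(labels == "non_synonymous")) "non_synonymous" else "synonymous"
}

#' Free-text summary of a set of annotation records
#'
#' Concatenates name and category of each record into a single
#' descriptive blob for the final report; purely local, no external
#' lookups.
#'
#' @param db an `annotation_db`.
#' @param record_ids character vector of record ids (may be empty).
#' @return a single string.
#' @export
annotation_summary <- function(db, record_ids) {
  stopifnot(inherits(db, "annotation_db"))
  recs <- filter(db$records, .data$record_id %in% record_ids)
  if (nrow(recs) == 0) return("novel region (no annotation)")
  paste(unique(paste0(recs$name, " (", recs$category, ", ",
                      recs$chrom, ":", recs$start, "-", recs$end, ")")),
        collapse = "; ")
}
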