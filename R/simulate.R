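#' Simulation configuration for a synthetic tumor/normal cohort
#'
#' Defines the study conditions emulated by the simulator: a toy
#' reference, gene models, tumor/normal pairs with a background
#' per-base somatic rate, implanted hotspot regions at elevated rates,
#' planted germline leak-through and low-quality artifact sites, a
#' DBSNP-like polymorphism set, and read alignments whose pileups
#' support the planted truth.
#'
#' @param seed integer seed; every emitted file is byte-identical under
#'   a fixed seed.
#' @param genome_length reference length in bp (single chromosome "1").
#' @param cohorts named integer vector, cohort name -> number of
#'   tumor/normal pairs.
#' @param background_rate per-base per-sample somatic mutation
#'   probability.
#' @param hotspots list of `list(start, end, fold, min_carriers)`
#'   (1-based closed intervals, non-overlapping): extra somatic load at
#'   `fold` x background plus `min_carriers` recurrent carriers at two
#'   recurrent positions.
#' @param germline_fraction,artifact_fraction fractions of planted
#'   sites that are germline leak-through / low-quality artifacts
#'   (their sum must stay below 1).
#' @param germline_vcf_miss_rate probability that a germline site is
#'   missing from the matched normal's VCF (the caller-missed-it
#'   leak-through scenario caught at the validation phase); the site
#'   still shows ~50% VAF in the normal's reads.
#' @param polymorphism_set_size distinct sites in the DBSNP-like VCF.
#' @param poly_overlap_n how many polymorphism sites also appear in
#'   tumor calls (and must be removed by exclude-set filtering).
#' @param indel_fraction fraction of somatic sites planted as short
#'   indels rather than SNVs.
#' @param depth_mean Poisson mean read depth for alignment synthesis.
#' @param read_length read length in bp.
#' @param vaf_somatic,vaf_germline variant allele fractions used in
#'   read synthesis (conventional heterozygous-like values).
#' @param n_genes gene models written into the reference.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 200000L,
                       cohorts = c(cohortA = 10L),
                       background_rate = 2e-4,
                       hotspots = list(list(start = 10001L, end = 11000L,
                                            fold = 50, min_carriers = 5L)),
                       germline_fraction = 0.13,
                       artifact_fraction = 0,
                       germline_vcf_miss_rate = 0,
                       polymorphism_set_size = 200L,
                       poly_overlap_n = 40L,
                       indel_fraction = 0.05,
                       depth_mean = 40, read_length = 50L,
                       vaf_somatic = 0.4, vaf_germline = 0.5,
                       n_genes = 10L) {
  stopifnot(genome_length > 0, background_rate >= 0,
            germline_fraction >= 0, artifact_fraction >= 0,
            germline_fraction + artifact_fraction < 1,
            all(vapply(hotspots, function(h)
              h$start >= 1 && h$end <= genome_length && h$start < h$end,
              logical(1))))
  structure(as.list(environment()), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

write_fasta <- function(seq, path, name = "1") {
  lines <- substring(seq, seq(1L, nchar(seq), 60L),
                     pmin(seq(1L, nchar(seq), 60L) + 59L, nchar(seq)))
  writeLines(c(paste0(">", name), lines), path)
  invisible(path)
}

#' Simulate a uniform-random reference genome
#'
#' @param cfg a [sim_config()].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
simulate_reference <- function(cfg, path) {
  if (cfg$genome_length <= 0) abort("genome_length must be positive")
  set.seed(cfg$seed + 101L)
  seq <- paste(sample(BASES, cfg$genome_length, replace = TRUE), collapse = "")
  write_fasta(seq, path)
}

revcomp <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

#' Simulate gene models and write them into the reference
#'
#' Places non-overlapping multi-exon transcripts on both strands with a
#' valid CDS (start codon, no internal stops, terminal stop codon); the
#' CDS sequence is written into the reference, which is rewritten in
#' place. Emits a GTF with exon and CDS features.
#'
#' @param cfg a [sim_config()].
#' @param fasta_path reference FASTA (rewritten in place).
#' @param gtf_path output GTF path.
#' @return the GTF path, invisibly; the emitted structure (exon counts
#'   per transcript) is attached as `attr(,"structure")`.
#' @export
simulate_genes <- function(cfg, fasta_path, gtf_path) {
  set.seed(cfg$seed + 202L)
  L <- cfg$genome_length
  n <- cfg$n_genes
  block <- L %/% max(n, 1L)
  if (block < 600L) abort("genome too short for requested gene count")
  seq <- as.character(Biostrings::readDNAStringSet(fasta_path)[[1]])
  chars <- strsplit(seq, "")[[1]]
  gtf <- character(0)
  structure_rows <- list()
  for (gi in seq_len(n)) {
    n_exons <- sample(2:3, 1)
    exon_codons <- sample(5:15, n_exons, replace = TRUE)
    total_codons <- sum(exon_codons)
    codons <- c("ATG",
                sample(setdiff(names(Biostrings::GENETIC_CODE), STOPS),
                       total_codons - 2L, replace = TRUE),
                "TAA")
    cds_seq <- paste(codons, collapse = "")
    strand <- sample(c("+", "-"), 1)
    # lay exons left to right inside the gene's block with >=30 bp introns
    base0 <- (gi - 1L) * block + 50L
    exon_len <- exon_codons * 3L
    gaps <- sample(30:80, n_exons)    # gap before each exon
    starts <- base0 + cumsum(gaps) + c(0L, cumsum(exon_len))[seq_len(n_exons)]
    ends <- starts + exon_len - 1L    # 1-based closed
    # genomic sequence of the CDS: plus strand left->right, minus strand
    # reverse-complemented and filled right->left
    gseq <- if (strand == "+") cds_seq else revcomp(cds_seq)
    off <- 0L
    for (e in seq_len(n_exons)) {
      piece <- substr(gseq, off + 1L, off + exon_len[e])
      chars[starts[e]:ends[e]] <- strsplit(piece, "")[[1]]
      off <- off + exon_len[e]
    }
    tx <- paste0("g", gi, ".t1")
    attrs <- sprintf('gene_id "g%d"; transcript_id "%s"; gene_name "g%d";',
                     gi, tx, gi)
    cum_before <- c(0L, cumsum(exon_len))[seq_len(n_exons)]
    # GTF frame: bases to skip to reach the next full codon
    frames <- (3L - (cum_before %% 3L)) %% 3L
    if (strand == "-") {
      cum_after <- rev(c(0L, cumsum(rev(exon_len)))[seq_len(n_exons)])
      frames <- (3L - (cum_after %% 3L)) %% 3L
    }
    for (e in seq_len(n_exons)) {
      gtf <- c(gtf,
        sprintf("1\tsim\texon\t%d\t%d\t.\t%s\t.\t%s", starts[e], ends[e],
                strand, attrs),
        sprintf("1\tsim\tCDS\t%d\t%d\t.\t%s\t%d\t%s", starts[e], ends[e],
                strand, frames[e], attrs))
    }
    structure_rows[[gi]] <- tibble(transcript_id = tx, n_exons = n_exons,
                                   strand = strand,
                                   start = min(starts) - 1L, end = max(ends))
  }
  write_fasta(paste(chars, collapse = ""), fasta_path)
  writeLines(gtf, gtf_path)
  attr(gtf_path, "structure") <- bind_rows(structure_rows)
  invisible(gtf_path)
}

write_minimal_vcf <- function(sites, path, sample_id = NULL, genome_length) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=1,length=%d>", genome_length),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample_id)) cols <- c(cols, "FORMAT", sample_id)
  hdr <- c(hdr, paste(cols, collapse = "\t"))
  body <- character(0)
  if (nrow(sites) > 0) {
    sites <- arrange(sites, .data$pos, .data$ref, .data$alt)
    body <- if (is.null(sample_id))
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", sites$chrom, sites$pos,
              sites$ref, sites$alt)
    else
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD\t0/1:%d:%d,%d",
              sites$chrom, sites$pos, sites$ref, sites$alt,
              sites$dp, sites$dp - sites$ad, sites$ad)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

draw_allele <- function(chars, pos, is_indel, L) {
  ref_base <- chars[pos]
  if (!is_indel) {
    list(ref = ref_base, alt = sample(setdiff(BASES, ref_base), 1))
  } else if (runif(1) < 0.5 || pos + 3L > L) {   # insertion
    list(ref = ref_base,
         alt = paste0(ref_base, paste(sample(BASES, sample(1:3, 1),
                                             replace = TRUE), collapse = "")))
  } else {                                        # deletion
    len <- sample(1:3, 1)
    list(ref = paste(chars[pos:(pos + len)], collapse = ""), alt = ref_base)
  }
}

#' Simulate a tumor/normal cohort with planted truth
#'
#' Draws background somatic SNVs/indels per tumor at the background
#' rate; hotspot intervals receive `fold` x background plus recurrent
#' carriers; germline sites are written to carrier tumors and (up to
#' the VCF miss rate) their matched normals; artifact sites go to tumor
#' VCFs only; a DBSNP-like polymorphism VCF is written with a planted
#' subset also present in tumors. Everything is logged in a
#' machine-readable truth table.
#'
#' @param cfg a [sim_config()].
#' @param fasta_path the simulated reference.
#' @param out_dir output directory for VCFs, metadata and truth.
#' @return a list: `samples` (tibble + `metadata_path`), `vcfs` (named
#'   paths), `polymorphism_path`, `truth` (tibble + `truth_path`).
#' @export
simulate_cohort <- function(cfg, fasta_path, out_dir) {
  set.seed(cfg$seed + 303L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  L <- cfg$genome_length
  chars <- strsplit(as.character(
    Biostrings::readDNAStringSet(fasta_path)[[1]]), "")[[1]]

  samples <- list(); k <- 0L
  for (co in names(cfg$cohorts)) {
    for (i in seq_len(cfg$cohorts[[co]])) {
      k <- k + 1L
      samples[[length(samples) + 1L]] <- tibble(
        sample_id = c(sprintf("T%03d", k), sprintf("N%03d", k)),
        name = c(sprintf("tumor_%d", k), sprintf("normal_%d", k)),
        cohort = co, status = c("tumor", "normal"),
        matched_id = c(sprintf("N%03d", k), sprintf("T%03d", k)))
    }
  }
  samples <- bind_rows(samples)
  tumors <- samples$sample_id[samples$status == "tumor"]
  pair_of <- setNames(samples$matched_id, samples$sample_id)

  in_hotspot <- function(p) {
    for (j in seq_along(cfg$hotspots)) {
      h <- cfg$hotspots[[j]]
      if (p >= h$start && p <= h$end) return(sprintf("SIM_HS%d", j))
    }
    NA_character_
  }

  # --- somatic sites: background + hotspot excess + recurrent positions
  carriers_at <- list()   # pos(char) -> character vector of carriers
  add_carrier <- function(pos, s) {
    key <- as.character(pos)
    carriers_at[[key]] <<- unique(c(carriers_at[[key]], s))
  }
  for (s in tumors) {
    n_bg <- rbinom(1, L, cfg$background_rate)
    if (n_bg > 0) for (p in sample.int(L, n_bg)) add_carrier(p, s)
    for (h in cfg$hotspots) {
      len <- h$end - h$start + 1L
      extra <- rbinom(1, len, min(1, (h$fold - 1) * cfg$background_rate))
      if (extra > 0)
        for (p in h$start - 1L + sample.int(len, extra)) add_carrier(p, s)
    }
  }
  for (h in cfg$hotspots) {
    rec_pos <- h$start - 1L + sample.int(h$end - h$start + 1L,
                                         min(2L, h$end - h$start + 1L))
    for (p in rec_pos) {
      cs <- sample(tumors, min(h$min_carriers, length(tumors)))
      for (s in cs) add_carrier(p, s)
    }
  }
  somatic_pos <- sort(as.integer(names(carriers_at)))
  n_somatic <- length(somatic_pos)

  # --- germline / artifact / polymorphism-overlap site counts
  gf <- cfg$germline_fraction; af <- cfg$artifact_fraction
  n_total <- if (1 - gf - af > 0) round(n_somatic / (1 - gf - af)) else n_somatic
  n_germ <- round(n_total * gf); n_art <- round(n_total * af)
  used <- somatic_pos
  fresh_pos <- function(n) {
    if (n == 0) return(integer(0))
    avail <- setdiff(seq_len(L), used)
    p <- sort(sample(avail, n))
    used <<- c(used, p)
    p
  }
  germ_pos <- fresh_pos(n_germ)
  art_pos <- fresh_pos(n_art)
  poly_pos <- fresh_pos(cfg$polymorphism_set_size)
  poly_overlap <- if (cfg$poly_overlap_n > 0)
    sort(sample(poly_pos, min(cfg$poly_overlap_n, length(poly_pos)))) else integer(0)

  truth <- list()
  add_truth <- function(pos, ref, alt, label, carriers, hs = NA_character_) {
    truth[[length(truth) + 1L]] <<- tibble(
      chrom = "1", pos = as.integer(pos), ref = ref, alt = alt, label = label,
      carriers = paste(sort(carriers), collapse = ","), hotspot_id = hs)
  }

  # per-sample site accumulators
  calls <- setNames(vector("list", nrow(samples)), samples$sample_id)
  add_call <- function(sample, pos, ref, alt) {
    calls[[sample]][[length(calls[[sample]]) + 1L]] <<-
      tibble(chrom = "1", pos = as.integer(pos), ref = ref, alt = alt)
  }

  # planted alleles are emitted already left-normalized so that truth,
  # VCFs and synthesized reads share one canonical representation
  ref_str <- paste(chars, collapse = "")
  for (p in somatic_pos) {
    al <- draw_allele(chars, p, runif(1) < cfg$indel_fraction, L)
    nrm <- normalize_alleles(p, al$ref, al$alt, ref_str)
    cs <- carriers_at[[as.character(p)]]
    for (s in cs) add_call(s, nrm$pos, nrm$ref, nrm$alt)
    add_truth(nrm$pos, nrm$ref, nrm$alt, "somatic", cs, in_hotspot(nrm$pos))
  }
  for (p in germ_pos) {
    al <- draw_allele(chars, p, FALSE, L)
    cs <- sample(tumors, min(sample(1:3, 1), length(tumors)))
    for (s in cs) {
      add_call(s, p, al$ref, al$alt)
      if (runif(1) >= cfg$germline_vcf_miss_rate)
        add_call(pair_of[[s]], p, al$ref, al$alt)
    }
    add_truth(p, al$ref, al$alt, "germline", cs)
  }
  for (p in art_pos) {
    al <- draw_allele(chars, p, FALSE, L)
    cs <- sample(tumors, min(sample(1:2, 1), length(tumors)))
    for (s in cs) add_call(s, p, al$ref, al$alt)
    add_truth(p, al$ref, al$alt, "artifact", cs)
  }
  poly_sites <- tibble(chrom = "1", pos = poly_pos,
                       ref = chars[poly_pos],
                       alt = vapply(poly_pos, function(p)
                         sample(setdiff(BASES, chars[p]), 1), character(1)))
  for (p in poly_overlap) {
    i <- match(p, poly_sites$pos)
    cs <- sample(tumors, min(sample(1:3, 1), length(tumors)))
    for (s in cs) add_call(s, p, poly_sites$ref[i], poly_sites$alt[i])
    add_truth(p, poly_sites$ref[i], poly_sites$alt[i], "polymorphism", cs)
  }

  # --- write files
  vcfs <- character(0)
  for (s in samples$sample_id) {
    sites <- if (length(calls[[s]]) > 0) bind_rows(calls[[s]]) else
      tibble(chrom = character(), pos = integer(), ref = character(),
             alt = character())
    vaf <- if (samples$status[match(s, samples$sample_id)] == "tumor")
      cfg$vaf_somatic else cfg$vaf_germline
    sites$dp <- rep(as.integer(round(cfg$depth_mean)), nrow(sites))
    sites$ad <- as.integer(round(sites$dp * vaf))
    path <- file.path(out_dir, paste0(s, ".vcf"))
    write_minimal_vcf(sites, path, sample_id = s, genome_length = L)
    vcfs[s] <- path
  }
  poly_path <- file.path(out_dir, "polymorphisms.vcf")
  write_minimal_vcf(poly_sites, poly_path, genome_length = L)
  meta_path <- file.path(out_dir, "samples.tsv")
  write_tsv_plain(samples, meta_path)
  truth_tbl <- arrange(bind_rows(truth), .data$pos, .data$ref, .data$alt)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_tsv_plain(truth_tbl, truth_path)

  list(samples = samples, metadata_path = meta_path, vcfs = vcfs,
       polymorphism_path = poly_path, truth = truth_tbl,
       truth_path = truth_path)
}

qual_char <- function(q) intToUtf8(q + 33L)

# one read over a site: returns list(pos, cigar, seq, qual)
synth_read <- function(chars, L, site_pos, ref, alt, is_alt, read_length,
                       baseq, offset) {
  start <- max(1L, min(site_pos - offset, L - read_length + 1L))
  # too close to the genome end for a clean indel alignment: plain read
  if (is_alt && nchar(ref) != nchar(alt) && site_pos + read_length + 4L > L)
    is_alt <- FALSE
  if (!is_alt || nchar(ref) == nchar(alt)) {
    seq_chars <- chars[start:(start + read_length - 1L)]
    if (is_alt) seq_chars[site_pos - start + 1L] <- alt
    list(pos = start, cigar = paste0(read_length, "M"),
         seq = paste(seq_chars, collapse = ""),
         qual = strrep(qual_char(baseq), read_length))
  } else if (nchar(alt) > nchar(ref)) {      # insertion after anchor
    ins <- substr(alt, 2L, nchar(alt)); ilen <- nchar(ins)
    m1 <- site_pos - start + 1L
    m2 <- read_length - m1 - ilen
    if (m2 < 1L) { m1 <- max(1L, m1 - (1L - m2)); m2 <- read_length - m1 - ilen }
    m2 <- min(m2, L - site_pos)
    seq <- paste0(paste(chars[start:(start + m1 - 1L)], collapse = ""), ins,
                  paste(chars[(site_pos + 1L):(site_pos + m2)], collapse = ""))
    list(pos = start, cigar = sprintf("%dM%dI%dM", m1, ilen, m2),
         seq = seq, qual = strrep(qual_char(baseq), m1 + ilen + m2))
  } else {                                    # deletion after anchor
    dlen <- nchar(ref) - 1L
    m1 <- site_pos - start + 1L
    m2 <- min(read_length - m1, L - site_pos - dlen)
    seq <- paste0(paste(chars[start:(start + m1 - 1L)], collapse = ""),
                  paste(chars[(site_pos + dlen + 1L):(site_pos + dlen + m2)],
                        collapse = ""))
    list(pos = start, cigar = sprintf("%dM%dD%dM", m1, dlen, m2),
         seq = seq, qual = strrep(qual_char(baseq), m1 + m2))
  }
}

#' Simulate per-sample SAM alignments supporting the planted truth
#'
#' For each tumor/normal pair, reads of the configured length are drawn
#' at Poisson-distributed depth around every truth site the tumor
#' carries. Somatic sites show alt bases at the somatic VAF in tumor
#' reads only; germline sites at ~50% VAF in both tumor and matched
#' normal; artifact sites put all alt support on reads with low mapping
#' or base quality (below the default validation thresholds). Emitted
#' SAMs are coordinate-sorted with a valid header.
#'
#' @param cfg a [sim_config()].
#' @param truth the truth table from [simulate_cohort()].
#' @param samples the sample table from [simulate_cohort()].
#' @param fasta_path the (gene-updated) reference FASTA.
#' @param out_dir output directory.
#' @return named character vector, sample_id -> SAM path (tumors and
#'   their matched normals).
#' @export
simulate_alignments <- function(cfg, truth, samples, fasta_path, out_dir) {
  set.seed(cfg$seed + 404L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  L <- cfg$genome_length
  chars <- strsplit(as.character(
    Biostrings::readDNAStringSet(fasta_path)[[1]]), "")[[1]]
  rl <- cfg$read_length
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:1\tLN:%d", L))
  truth$carrier_list <- strsplit(truth$carriers, ",", fixed = TRUE)
  pair_of <- setNames(samples$matched_id, samples$sample_id)

  reads_by_sample <- setNames(vector("list", nrow(samples)), samples$sample_id)
  rid <- 0L
  emit <- function(sample, site_row, role) {
    # role: "tumor_carrier", "normal_of_carrier"
    lab <- truth$label[site_row]
    p <- truth$pos[site_row]; ref <- truth$ref[site_row]; alt <- truth$alt[site_row]
    n_reads <- rpois(1, cfg$depth_mean)
    if (n_reads == 0) return(invisible())
    vaf <- if (lab %in% c("germline", "polymorphism")) cfg$vaf_germline
           else if (role == "tumor_carrier") cfg$vaf_somatic else 0
    is_alt <- runif(n_reads) < vaf
    for (r in seq_len(n_reads)) {
      rid <<- rid + 1L
      artifact_read <- lab == "artifact" && is_alt[r]
      baseq <- if (artifact_read && runif(1) < 0.5) 2L else 35L
      mapq <- if (artifact_read && baseq > 2L) 5L else 60L
      offset <- sample.int(rl - nchar(ref) - 4L, 1) - 1L
      rd <- synth_read(chars, L, p, ref, alt, is_alt[r], rl, baseq, offset)
      reads_by_sample[[sample]][[length(reads_by_sample[[sample]]) + 1L]] <<-
        tibble(qname = sprintf("r%07d", rid), pos = rd$pos, mapq = mapq,
               cigar = rd$cigar, seq = rd$seq, qual = rd$qual)
    }
  }

  for (i in seq_len(nrow(truth))) {
    for (s in truth$carrier_list[[i]]) {
      if (!nzchar(s)) next
      emit(s, i, "tumor_carrier")
      emit(pair_of[[s]], i, "normal_of_carrier")
    }
  }

  paths <- character(0)
  for (s in names(reads_by_sample)) {
    if (is.null(reads_by_sample[[s]])) next
    rd <- bind_rows(reads_by_sample[[s]]) |> arrange(.data$pos, .data$qname)
    lines <- sprintf("%s\t0\t1\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     rd$qname, rd$pos, rd$mapq, rd$cigar, rd$seq, rd$qual)
    path <- file.path(out_dir, paste0(s, ".sam"))
    writeLines(c(header, lines), path)
    paths[s] <- path
  }
  paths
}

#' Run the whole simulator and write a fixture directory
#'
#' Convenience wrapper producing reference, gene models, cohort VCFs,
#' metadata, polymorphism set, truth table and SAM alignments under one
#' directory.
#'
#' @param cfg a [sim_config()].
#' @param out_dir target directory.
#' @param alignments also synthesize SAM alignments (the slowest part).
#' @return a list with `fasta`, `gtf`, `cohort` (the
#'   [simulate_cohort()] result) and `alignments` (named SAM paths or
#'   NULL).
#' @export
simulate_all <- function(cfg, out_dir, alignments = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(out_dir, "reference.fa")
  simulate_reference(cfg, fasta)
  gtf <- file.path(out_dir, "genes.gtf")
  simulate_genes(cfg, fasta, gtf)
  cohort <- simulate_cohort(cfg, fasta, out_dir)
  aln <- if (alignments)
    simulate_alignments(cfg, cohort$truth, cohort$samples, fasta,
                        file.path(out_dir, "alignments"))
  else NULL
  list(fasta = fasta, gtf = gtf, cohort = cohort, alignments = aln)
}
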