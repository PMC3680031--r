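# in-code fixture builders and independent oracles shared across tests

write_test_vcf <- function(records, path = tempfile(fileext = ".vcf"),
                           sample_id = NULL, gl = 100000L) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=1,length=%d>", gl),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(sample_id)) {
    cols <- c(cols, "FORMAT", sample_id)
    # pad site-only records with a genotype column
    short <- lengths(regmatches(records, gregexpr("\t", records))) == 7L
    records[short] <- paste0(records[short], "\tGT\t0/1")
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), records), path)
  path
}

# record helper: chrom pos ref alt with optional DP/AD sample field
vcf_rec <- function(chrom, pos, ref, alt, dp = NULL, ad = NULL) {
  base <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", chrom, pos, ref, alt)
  if (is.null(dp)) base
  else sprintf("%s\tGT:DP:AD\t0/1:%d:%d,%d", base, dp, dp - ad, ad)
}

write_test_meta <- function(df, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(df, path, na = "")
  path
}

# a two-pair store with a handful of variants placed directly
tiny_store <- function() {
  meta <- tibble::tibble(
    sample_id = c("T1", "N1", "T2", "N2", "N7"),
    cohort = c("lymphoma", "lymphoma", "lymphoma", "lymphoma", "other"),
    status = c("tumor", "normal", "tumor", "normal", "normal"),
    matched_id = c("N1", "T1", "N2", "T2", NA))
  vs <- import_samples(variant_store(), meta)
  vs
}

write_test_sam <- function(reads, path = tempfile(fileext = ".sam"),
                           gl = 100000L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:1\tLN:%d", gl))
  lines <- vapply(reads, function(r)
    sprintf("%s\t0\t1\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            r$qname, r$pos, r$mapq %||% 60L, r$cigar, r$seq,
            r$qual %||% strrep("I", nchar(gsub("\\d+[IDH]", "", r$seq)))),
    character(1))
  ord <- order(vapply(reads, function(r) r$pos, numeric(1)))
  writeLines(c(hdr, lines[ord]), path)
  path
}

sam_read <- function(qname, pos, seq, cigar = NULL, mapq = 60L, qual = NULL) {
  list(qname = qname, pos = pos, seq = seq,
       cigar = cigar %||% paste0(nchar(seq), "M"), mapq = mapq,
       qual = qual %||% strrep("I", nchar(seq)))
}

# hand-built pileup tibble for direct classify_variant tests
pileup_tbl <- function(bases, baseq = 35L, mapq = 60L, pos = 100L,
                       chrom = "1", indel = NA_character_) {
  n <- length(bases)
  tibble::tibble(chrom = chrom, pos = as.integer(pos), base = bases,
                 base_quality = as.integer(rep_len(baseq, n)),
                 mapping_quality = as.integer(rep_len(mapq, n)),
                 read_id = sprintf("r%03d", seq_len(n)),
                 indel = rep_len(indel, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent oracles -------------------------------------------------

# brute-force binomial upper tail by direct pmf summation in log space
oracle_binom_sf <- function(k, n, p) {
  if (k == 0) return(1)
  terms <- vapply(k:n, function(i) dbinom(i, n, p), numeric(1))
  sum(terms)
}

# log-space summation for large n (sums only a window around k)
oracle_binom_sf_log <- function(k, n, p, window = 2000L) {
  if (k == 0) return(1)
  hi <- min(n, k + window)
  lt <- vapply(k:hi, function(i) dbinom(i, n, p, log = TRUE), numeric(1))
  m <- max(lt)
  exp(m) * sum(exp(lt - m))
}

# direct step-up BH implementation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# union-find single-linkage partition over all position pairs within gap
oracle_proximity_partition <- function(pos, gap) {
  n <- length(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(pos[i] - pos[j]) <= gap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# brute-force overlap scan of 0-based half-open records vs a query
oracle_overlaps <- function(records, chrom, start0, end0) {
  which(records$chrom == chrom & records$start < end0 & start0 < records$end)
}

# hand codon translation (independent of Biostrings)
CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
    "")[[1]]
  codons <- character(64); i <- 0
  for (b1 in b) for (b2 in b) for (b3 in b) {
    i <- i + 1; codons[i] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
})

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
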