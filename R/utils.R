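#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join distinct n rename across desc row_number pull
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap walk
#' @importFrom stats pbinom p.adjust phyper rpois rbinom runif setNames
#' @importFrom utils head
NULL

#' Normalize a chromosome name to the store's canonical dialect
#'
#' Variant callers, annotation files and references disagree on the
#' `"chr1"` vs `"1"` dialect. All coordinates entering a store pass
#' through this function so that downstream joins are exact.
#'
#' @param chrom character vector of chromosome names.
#' @param style `"strip"` (default) removes a leading `"chr"`;
#'   `"chr"` adds one where missing; `"asis"` leaves names untouched.
#' @return character vector of canonical names.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "1", "chrX"))
normalize_chrom <- function(chrom, style = c("strip", "chr", "asis")) {
  style <- match.arg(style)
  switch(style,
    strip = sub("^chr", "", chrom),
    chr   = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
    asis  = chrom
  )
}

#' Normalize variant alleles (trim + optional reference left-shift)
#'
#' Collapses redundant allele representations so that identity filtering
#' (matched normal, panel of normals, polymorphism sets) is allele-exact.
#' Shared suffix bases are trimmed first, then shared prefix bases
#' (advancing `pos`). When `ref_seq` is supplied, pure insertions and
#' deletions are additionally shifted left while the flanking base
#' matches the last base of the varying sequence.
#'
#' @param pos integer vector, 1-based.
#' @param ref,alt character vectors of uppercase alleles.
#' @param ref_seq optional single reference sequence (character) for the
#'   variants' chromosome, enabling left-alignment of indels.
#' @return tibble with columns `pos`, `ref`, `alt`, `vtype`.
#' @export
normalize_alleles <- function(pos, ref, alt, ref_seq = NULL) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  ref <- toupper(ref); alt <- toupper(alt)
  last1 <- function(x) substr(x, nchar(x), nchar(x))
  out <- pmap(list(pos, ref, alt), function(p, r, a) {
    # canonical left alignment: while both alleles end with the same
    # base, truncate it; an emptied allele is refilled by extending both
    # left with the flanking reference base (needs ref_seq)
    repeat {
      if (nchar(r) > 0L && nchar(a) > 0L && last1(r) == last1(a) &&
          (min(nchar(r), nchar(a)) > 1L || (!is.null(ref_seq) && p > 1L))) {
        r <- substr(r, 1L, nchar(r) - 1L)
        a <- substr(a, 1L, nchar(a) - 1L)
        if (nchar(r) == 0L || nchar(a) == 0L) {
          p <- p - 1L
          flank <- substr(ref_seq, p, p)
          r <- paste0(flank, r); a <- paste0(flank, a)
        }
      } else break
    }
    # trim shared prefix, keeping one anchor base for indels
    while (nchar(r) > 1L && nchar(a) > 1L && substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a)); p <- p + 1L
    }
    vt <- if (nchar(r) == 1L && nchar(a) == 1L) "snv"
          else if (nchar(r) < nchar(a)) "ins" else "del"
    list(pos = as.integer(p), ref = r, alt = a, vtype = vt)
  })
  tibble(
    pos = map_int(out, "pos"), ref = map_chr(out, "ref"),
    alt = map_chr(out, "alt"), vtype = map_chr(out, "vtype")
  )
}

# site key string used for fast set membership, allele-exact
site_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

# write a tibble as TSV with stable formatting (no quoting surprises)
write_tsv_plain <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types %||% readr::cols(),
                  na = c("", "NA"), progress = FALSE,
                  show_col_types = FALSE)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

fmt_p <- function(p) formatC(p, format = "e", digits = 2)
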