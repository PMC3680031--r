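#' Create an empty variant store
#'
#' The store is the pipeline's working database: sample metadata with
#' tumor/normal pairing, per-sample variant calls, and named
#' known-polymorphism sets. It is an in-memory tabular object that can
#' be serialized to a directory of plain TSV files with [write_store()].
#'
#' @param chrom_style chromosome-name dialect applied to everything
#'   entering the store; see [normalize_chrom()].
#' @return an object of class `variant_store`.
#' @export
#' @examples
#' vs <- variant_store()
#' vs
variant_store <- function(chrom_style = c("strip", "chr", "asis")) {
  chrom_style <- match.arg(chrom_style)
  structure(
    list(
      samples = tibble(
        sample_id = character(), name = character(), cohort = character(),
        status = character(), matched_id = character()
      ),
      variants = tibble(
        sample_id = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character(), vtype = character(),
        total_depth = integer(), alt_depth = integer()
      ),
      polymorphisms = tibble(
        set_name = character(), chrom = character(), pos = integer(),
        ref = character(), alt = character()
      ),
      chrom_style = chrom_style,
      reference = NULL
    ),
    class = "variant_store"
  )
}

#' @export
print.variant_store <- function(x, ...) {
  cat("<variant_store>\n")
  cat("  samples:       ", nrow(x$samples),
      sprintf(" (%d tumor / %d normal)\n",
              sum(x$samples$status == "tumor"),
              sum(x$samples$status == "normal")), sep = "")
  cat("  variants:      ", nrow(x$variants), "\n", sep = "")
  cat("  polymorphism sets: ",
      paste(unique(x$polymorphisms$set_name), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Attach a reference genome to a store
#'
#' The reference enables left-alignment of indels at import time and
#' reference-consistency checks during effect classification.
#'
#' @param store a `variant_store`.
#' @param fasta path to a FASTA file.
#' @return the store with reference sequences attached.
#' @export
attach_reference <- function(store, fasta) {
  stopifnot(inherits(store, "variant_store"))
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- normalize_chrom(sub("\\s.*$", "", names(seqs)), store$chrom_style)
  store$reference <- seqs
  store
}

#' Import sample metadata (tumor/normal cohort table)
#'
#' Reads a TSV with columns `sample_id`, `cohort`, `status`,
#' `matched_id` (and optionally `name`). Matched pairing must link
#' samples of opposite status; one-directional links are repaired by
#' mirroring.
#'
#' @param store a `variant_store`.
#' @param metadata a TSV path or a data frame with the columns above.
#' @return the store with samples added; the number of records loaded is
#'   available as `attr(store, "n_loaded")`.
#' @export
import_samples <- function(store, metadata) {
  stopifnot(inherits(store, "variant_store"))
  tab <- if (is.character(metadata)) read_tsv_plain(metadata) else as_tibble(metadata)
  req <- c("sample_id", "cohort", "status", "matched_id")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0)
    abort(paste0("metadata table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  if (!"name" %in% names(tab)) tab$name <- tab$sample_id
  tab <- tab |>
    mutate(across(c("sample_id", "cohort", "status", "matched_id", "name"),
                  as.character)) |>
    mutate(matched_id = ifelse(is.na(.data$matched_id) | .data$matched_id == "",
                               NA_character_, .data$matched_id)) |>
    select("sample_id", "name", "cohort", "status", "matched_id")

  bad_status <- setdiff(unique(tab$status), c("tumor", "normal"))
  if (length(bad_status) > 0)
    abort(paste0("status must be 'tumor' or 'normal'; got: ",
                 paste(bad_status, collapse = ", ")))
  all_ids <- c(store$samples$sample_id, tab$sample_id)
  dup <- all_ids[duplicated(all_ids)]
  if (length(dup) > 0)
    abort(paste0("duplicate sample_id: ", paste(unique(dup), collapse = ", ")))

  combined <- bind_rows(store$samples, tab)
  status_of <- setNames(combined$status, combined$sample_id)
  for (i in seq_len(nrow(tab))) {
    m <- tab$matched_id[i]
    if (is.na(m)) next
    if (!m %in% combined$sample_id)
      abort(paste0("sample ", tab$sample_id[i],
                   " references nonexistent matched_id ", m))
    if (status_of[[m]] == tab$status[i])
      abort(paste0("matched pair ", tab$sample_id[i], "/", m,
                   " has identical status '", tab$status[i], "'"))
  }
  # repair one-directional links by mirroring
  for (i in seq_len(nrow(combined))) {
    m <- combined$matched_id[i]
    if (is.na(m)) next
    j <- match(m, combined$sample_id)
    if (is.na(combined$matched_id[j]))
      combined$matched_id[j] <- combined$sample_id[i]
    else if (combined$matched_id[j] != combined$sample_id[i])
      abort(paste0("asymmetric matched pairing around ", combined$sample_id[i]))
  }
  store$samples <- combined
  attr(store, "n_loaded") <- nrow(tab)
  store
}

# Parse a VCF into a site tibble (chrom/pos/ref/alt plus depths), one row
# per ALT allele; skips records with symbolic or non-ACGT alleles.
parse_vcf_sites <- function(path, sample_col = NULL, chrom_style = "strip",
                            ref_seqs = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_skipped <- 0L
  if (nrow(fix) == 0) {
    return(list(sites = tibble(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               vtype = character(), total_depth = integer(),
                               alt_depth = integer()),
                n_skipped = 0L))
  }
  dp <- rep(NA_character_, nrow(fix)); ad <- rep(NA_character_, nrow(fix))
  if (ncol(v@gt) >= 2) {
    col <- if (is.null(sample_col)) 2L else {
      idx <- match(sample_col, colnames(v@gt))
      if (is.na(idx)) 2L else idx
    }
    dp <- vcfR::extract.gt(v, element = "DP")[, col - 1L]
    ad <- vcfR::extract.gt(v, element = "AD")[, col - 1L]
  }
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- toupper(fix$REF[i]); alts_raw <- fix$ALT[i]
    if (is.na(ref) || is.na(alts_raw) || !grepl("^[ACGT]+$", ref)) {
      n_skipped <- n_skipped + 1L; next
    }
    alts <- strsplit(toupper(alts_raw), ",", fixed = TRUE)[[1]]
    tot <- suppressWarnings(as.integer(dp[i]))
    ads <- suppressWarnings(as.integer(strsplit(ad[i] %||% NA_character_, ",")[[1]]))
    for (j in seq_along(alts)) {
      a <- alts[j]
      if (!grepl("^[ACGT]+$", a)) { n_skipped <- n_skipped + 1L; next }
      rows[[length(rows) + 1L]] <- list(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]), ref = ref, alt = a,
        total_depth = if (is.na(tot)) 0L else tot,
        alt_depth = if (length(ads) >= j + 1L && !is.na(ads[j + 1L])) ads[j + 1L] else 0L
      )
    }
  }
  if (length(rows) == 0) {
    return(list(sites = tibble(chrom = character(), pos = integer(),
                               ref = character(), alt = character(),
                               vtype = character(), total_depth = integer(),
                               alt_depth = integer()),
                n_skipped = n_skipped))
  }
  sites <- bind_rows(lapply(rows, as_tibble))
  sites$chrom <- normalize_chrom(sites$chrom, chrom_style)
  sites$vtype <- NA_character_
  norm <- vector("list", nrow(sites))
  for (chr in unique(sites$chrom)) {
    idx <- which(sites$chrom == chr)
    rs <- if (!is.null(ref_seqs) && chr %in% names(ref_seqs))
      as.character(ref_seqs[[chr]]) else NULL
    nrm <- normalize_alleles(sites$pos[idx], sites$ref[idx], sites$alt[idx], rs)
    sites$pos[idx] <- nrm$pos; sites$ref[idx] <- nrm$ref
    sites$alt[idx] <- nrm$alt
    sites$vtype[idx] <- nrm$vtype
  }
  list(sites = select(sites, "chrom", "pos", "ref", "alt", "vtype",
                      "total_depth", "alt_depth"),
       n_skipped = n_skipped)
}

#' Import a per-sample VCF of variant calls
#'
#' Each record becomes one variant per ALT allele (multi-allelic records
#' are split). `DP`/`AD` are mapped to total/alt depth; absent depths are
#' stored as 0 and never used for filtering at this stage. Alleles are
#' normalized (and left-aligned when a reference is attached).
#'
#' @param store a `variant_store`.
#' @param path VCF path (plain or gzip).
#' @param sample_id the store sample these calls belong to; must exist.
#' @return the store with variants added; `attr(store, "n_loaded")`
#'   holds the count, `attr(store, "n_skipped")` the skipped-record count.
#' @export
import_vcf <- function(store, path, sample_id) {
  stopifnot(inherits(store, "variant_store"))
  if (!sample_id %in% store$samples$sample_id)
    abort(paste0("unknown sample_id: ", sample_id))
  parsed <- parse_vcf_sites(path, sample_col = sample_id,
                            chrom_style = store$chrom_style,
                            ref_seqs = store$reference)
  if (parsed$n_skipped > 0)
    warn(paste0(parsed$n_skipped, " unparsable record(s) skipped in ", path))
  sites <- parsed$sites
  if (nrow(sites) > 0) {
    sites$sample_id <- sample_id
    store$variants <- bind_rows(
      store$variants,
      select(sites, "sample_id", "chrom", "pos", "ref", "alt", "vtype",
             "total_depth", "alt_depth")
    )
  }
  attr(store, "n_loaded") <- nrow(sites)
  attr(store, "n_skipped") <- parsed$n_skipped
  store
}

#' Import a known-polymorphism set (DBSNP-like VCF)
#'
#' Stores the allele-exact site keys of every record under `set_name`,
#' for use as an exclusion filter during cancer-exclusive extraction.
#' Duplicate sites are deduplicated.
#'
#' @param store a `variant_store`.
#' @param path VCF path.
#' @param set_name unique name for this set.
#' @return the store; `attr(store, "n_loaded")` holds the distinct-site count.
#' @export
import_polymorphism_set <- function(store, path, set_name) {
  stopifnot(inherits(store, "variant_store"))
  if (set_name %in% store$polymorphisms$set_name)
    abort(paste0("polymorphism set already present: ", set_name))
  parsed <- parse_vcf_sites(path, chrom_style = store$chrom_style,
                            ref_seqs = store$reference)
  sites <- parsed$sites |>
    distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    mutate(set_name = set_name) |>
    select("set_name", "chrom", "pos", "ref", "alt")
  store$polymorphisms <- bind_rows(store$polymorphisms, sites)
  attr(store, "n_loaded") <- nrow(sites)
  store
}

#' Extract cancer-exclusive (putative somatic) variants for a cohort
#'
#' The phase-one filter: a site+allele is retained when it occurs in at
#' least one tumor sample of the cohort, in no normal sample anywhere in
#' the store (matched or unmatched — the panel of normals), and in none
#' of the named polymorphism sets. Variants are collapsed across
#' carriers; carrier frequency is computed over the cohort's tumor
#' samples.
#'
#' @param store a `variant_store`.
#' @param cohort cohort (cancer type) name.
#' @param exclude_sets character vector of polymorphism set names.
#' @return a tibble of collapsed variants sorted by (chrom, pos, ref,
#'   alt): columns `chrom, pos, ref, alt, vtype, n_carriers, carriers`
#'   (list-column), `tumor_freq, normal_freq, effect` (all
#'   `"unassigned"` at this stage). SNVs and indels are distinguished by
#'   `vtype` so they can be written to separate files.
#' @seealso [extract_germline()] for tumor variants seen in normals,
#'   [write_extraction()] for the two-file TSV output.
#' @export
extract_cancer_exclusive <- function(store, cohort, exclude_sets = character()) {
  stopifnot(inherits(store, "variant_store"))
  cohort_tumors <- store$samples |>
    filter(.data$cohort == !!cohort, .data$status == "tumor")
  if (nrow(cohort_tumors) == 0)
    abort(paste0("unknown cohort or cohort without tumor samples: ", cohort))
  unknown_sets <- setdiff(exclude_sets, unique(store$polymorphisms$set_name))
  if (length(unknown_sets) > 0)
    abort(paste0("unknown polymorphism set(s): ",
                 paste(unknown_sets, collapse = ", ")))

  normal_ids <- store$samples$sample_id[store$samples$status == "normal"]
  n_normals <- length(normal_ids)
  normal_keys <- with(filter(store$variants, .data$sample_id %in% normal_ids),
                      site_key(chrom, pos, ref, alt))
  poly_keys <- with(filter(store$polymorphisms, .data$set_name %in% exclude_sets),
                    site_key(chrom, pos, ref, alt))
  excluded <- unique(c(normal_keys, poly_keys))

  tv <- filter(store$variants, .data$sample_id %in% cohort_tumors$sample_id)
  collapsed <- tv |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$vtype) |>
    summarise(carriers = list(sort(unique(.data$sample_id))), .groups = "drop") |>
    mutate(n_carriers = map_int(.data$carriers, length),
           key = site_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    filter(!.data$key %in% excluded) |>
    mutate(
      tumor_freq = .data$n_carriers / nrow(cohort_tumors),
      normal_freq = 0,
      effect = "unassigned"
    ) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    select("chrom", "pos", "ref", "alt", "vtype", "n_carriers", "carriers",
           "tumor_freq", "normal_freq", "effect")
  collapsed
}

#' Extract the germline candidate list for a cohort
#'
#' Tumor variants of the cohort that are also present in at least one
#' normal sample are not discarded silently: they form a separate
#' germline list, since predisposing mutations may themselves be of
#' interest. `normal_freq` is the fraction of all store normals carrying
#' the allele.
#'
#' @inheritParams extract_cancer_exclusive
#' @return a tibble shaped like [extract_cancer_exclusive()]'s output
#'   with a populated `normal_freq`.
#' @export
extract_germline <- function(store, cohort) {
  stopifnot(inherits(store, "variant_store"))
  cohort_tumors <- store$samples |>
    filter(.data$cohort == !!cohort, .data$status == "tumor")
  if (nrow(cohort_tumors) == 0)
    abort(paste0("unknown cohort or cohort without tumor samples: ", cohort))
  normal_ids <- store$samples$sample_id[store$samples$status == "normal"]
  normals <- filter(store$variants, .data$sample_id %in% normal_ids) |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    summarise(n_normal = length(unique(.data$sample_id)), .groups = "drop") |>
    mutate(key = site_key(.data$chrom, .data$pos, .data$ref, .data$alt))

  tv <- filter(store$variants, .data$sample_id %in% cohort_tumors$sample_id)
  tv |>
    group_by(.data$chrom, .data$pos, .data$ref, .data$alt, .data$vtype) |>
    summarise(carriers = list(sort(unique(.data$sample_id))), .groups = "drop") |>
    mutate(n_carriers = map_int(.data$carriers, length),
           key = site_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    filter(.data$key %in% normals$key) |>
    left_join(select(normals, "key", "n_normal"), by = "key") |>
    mutate(
      tumor_freq = .data$n_carriers / nrow(cohort_tumors),
      normal_freq = if (length(normal_ids) > 0) .data$n_normal / length(normal_ids) else 0,
      effect = "unassigned"
    ) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    select("chrom", "pos", "ref", "alt", "vtype", "n_carriers", "carriers",
           "tumor_freq", "normal_freq", "effect")
}

#' Rank collapsed variants by recurrence
#'
#' @param collapsed output of [extract_cancer_exclusive()].
#' @return the same rows sorted by descending carrier count, ties broken
#'   by (chrom, pos).
#' @export
recurrence_table <- function(collapsed) {
  collapsed |>
    arrange(desc(.data$n_carriers), .data$chrom, .data$pos) |>
    select("chrom", "pos", "ref", "alt", "n_carriers")
}

#' Write the phase-one extraction as separate SNV and indel TSVs
#'
#' @param collapsed output of [extract_cancer_exclusive()] (or
#'   [extract_germline()]).
#' @param dir output directory (created if absent).
#' @param prefix file-name prefix; files are `<prefix>_snvs.tsv` and
#'   `<prefix>_indels.tsv`.
#' @return invisible character vector of the two paths.
#' @export
write_extraction <- function(collapsed, dir, prefix = "exclusive") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- collapsed |>
    mutate(carriers = map_chr(.data$carriers, paste, collapse = ","))
  snv_path <- file.path(dir, paste0(prefix, "_snvs.tsv"))
  ind_path <- file.path(dir, paste0(prefix, "_indels.tsv"))
  write_tsv_plain(filter(flat, .data$vtype == "snv"), snv_path)
  write_tsv_plain(filter(flat, .data$vtype != "snv"), ind_path)
  invisible(c(snv_path, ind_path))
}

#' Read a phase-one extraction TSV back into collapsed-variant form
#'
#' @param paths one or more TSV paths written by [write_extraction()].
#' @return a collapsed-variant tibble with a `carriers` list-column.
#' @export
read_extraction <- function(paths) {
  ct <- readr::cols(chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    ref = readr::col_character(),
                    alt = readr::col_character(),
                    vtype = readr::col_character(),
                    n_carriers = readr::col_integer(),
                    carriers = readr::col_character(),
                    tumor_freq = readr::col_double(),
                    normal_freq = readr::col_double(),
                    effect = readr::col_character())
  bind_rows(lapply(paths, read_tsv_plain, col_types = ct)) |>
    mutate(pos = as.integer(.data$pos),
           carriers = strsplit(as.character(.data$carriers), ",", fixed = TRUE)) |>
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
}

#' Serialize / restore a variant store as a directory of TSV files
#'
#' @param store a `variant_store`.
#' @param dir target directory.
#' @return `write_store()` the directory invisibly; `read_store()` a
#'   `variant_store`.
#' @export
write_store <- function(store, dir) {
  stopifnot(inherits(store, "variant_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_plain(store$samples, file.path(dir, "samples.tsv"))
  write_tsv_plain(store$variants, file.path(dir, "variants.tsv"))
  write_tsv_plain(store$polymorphisms, file.path(dir, "polymorphisms.tsv"))
  writeLines(store$chrom_style, file.path(dir, "chrom_style.txt"))
  invisible(dir)
}

#' @rdname write_store
#' @export
read_store <- function(dir) {
  st <- variant_store(chrom_style = readLines(file.path(dir, "chrom_style.txt"))[1])
  st$samples <- read_tsv_plain(file.path(dir, "samples.tsv"),
                               readr::cols(.default = readr::col_character()))
  st$variants <- read_tsv_plain(file.path(dir, "variants.tsv")) |>
    mutate(pos = as.integer(.data$pos),
           total_depth = as.integer(.data$total_depth),
           alt_depth = as.integer(.data$alt_depth))
  st$polymorphisms <- read_tsv_plain(file.path(dir, "polymorphisms.tsv")) |>
    mutate(pos = as.integer(.data$pos))
  st
}
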