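#' Estimate the background somatic mutation rate
#'
#' The background model is the per-base per-sample somatic mutation
#' probability: total validated somatic variant-sample observations
#' divided by (callable length x number of samples). Hotspot regions
#' are not excluded from the numerator — the global rate is the
#' conservative choice.
#'
#' @param n_observations total somatic variant-sample observations, or a
#'   verdict tibble (rows with `status == "somatic"` are counted).
#' @param callable_length callable genome length in bp (> 0).
#' @param n_samples number of tumor samples (> 0).
#' @return a `background_model` list with `per_base_rate`,
#'   `callable_length`, `n_samples`.
#' @export
estimate_background <- function(n_observations, callable_length, n_samples) {
  if (is.data.frame(n_observations))
    n_observations <- sum(n_observations$status == "somatic")
  if (callable_length <= 0) abort("callable_length must be positive")
  if (n_samples <= 0) abort("n_samples must be positive")
  if (n_observations < 1) abort("need at least one somatic observation")
  rate <- n_observations / (callable_length * n_samples)
  if (rate > 1) abort("background rate exceeds 1; check callable_length")
  structure(list(per_base_rate = rate, callable_length = callable_length,
                 n_samples = n_samples), class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> rate %.3g /bp/sample (%g bp x %d samples)\n",
              x$per_base_rate, x$callable_length, x$n_samples))
  invisible(x)
}

#' Binomial upper-tail probability P(X >= k)
#'
#' Exact survival function of Binomial(n, p), numerically stable for
#' very large n (delegates to the regularized incomplete beta via
#' `pbinom`). `P(X >= 0)` is exactly 1.
#'
#' @param k observed count (vectorized), `0 <= k <= n`.
#' @param n number of trials.
#' @param p success probability in (0, 1).
#' @return upper-tail p-value(s).
#' @export
#' @examples
#' binom_sf(2, 10, 0.1)
binom_sf <- function(k, n, p) {
  if (any(p <= 0 | p >= 1)) abort("p must be in (0, 1)")
  if (any(k < 0 | k > n)) abort("k must satisfy 0 <= k <= n")
  ifelse(k == 0, 1, pbinom(k - 1, n, p, lower.tail = FALSE))
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' @param p_values numeric vector with entries in (0, 1].
#' @return q-values in the input order, each `>=` its raw p and `<= 1`.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values) | p_values <= 0 | p_values > 1))
    abort("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Score hotspots against the background mutation rate (phase five)
#'
#' For each hotspot, `k` is the number of somatic variant-sample
#' observations in the region, `n = region_length x n_samples` binomial
#' trials, and `p_raw = P(X >= k)` under Binomial(n, background rate).
#' q-values are Benjamini-Hochberg across all scored hotspots; ranking
#' is by q, ties broken by raw p then by descending k.
#'
#' @param hotspots hotspot tibble (needs `hotspot_id, chrom, start,
#'   end`); region length is `end - start` with a floor of 1 bp.
#' @param k integer vector of somatic observation counts per hotspot
#'   (e.g. from [count_somatic_observations()]).
#' @param bg a [estimate_background()] model.
#' @return a `hotspot_results` tibble: the input columns plus `k, n,
#'   p_raw, q_value, rank`, sorted by rank.
#' @export
score_hotspots <- function(hotspots, k, bg) {
  stopifnot(inherits(bg, "background_model"), length(k) == nrow(hotspots))
  len <- pmax(hotspots$end - hotspots$start, 1L)
  if (any(len <= 0)) abort("hotspot region length must be positive")
  n <- len * bg$n_samples
  p_raw <- binom_sf(k, n, bg$per_base_rate)
  res <- hotspots
  res$k <- as.integer(k)
  res$n <- as.numeric(n)
  res$p_raw <- p_raw
  res$q_value <- benjamini_hochberg(p_raw)
  res <- arrange(res, .data$q_value, .data$p_raw, desc(.data$k),
                 .data$chrom, .data$start)
  res$rank <- seq_len(nrow(res))
  class(res) <- c("hotspot_results", class(res))
  res
}

#' Count somatic variant-sample observations per hotspot
#'
#' A site mutated in three samples contributes three observations
#' (matching the per-sample binomial-trials framing); set
#' `distinct_sites = TRUE` to count mutated sites instead.
#'
#' @param hotspots hotspot tibble from [cluster_by_function()].
#' @param verdicts verdict tibble from [validate_hotspots()]; only rows
#'   with `status == "somatic"` count. `NULL` falls back to all
#'   (variant, carrier) pairs (no validation phase).
#' @param clustered the clustered variant table (used for the fallback).
#' @param distinct_sites count distinct mutated sites instead of
#'   variant-sample observations.
#' @return integer vector aligned with `hotspots` rows.
#' @export
count_somatic_observations <- function(hotspots, verdicts = NULL,
                                       clustered = NULL,
                                       distinct_sites = FALSE) {
  vapply(seq_len(nrow(hotspots)), function(h) {
    if (!is.null(verdicts)) {
      vv <- filter(verdicts, .data$hotspot_id == hotspots$hotspot_id[h],
                   .data$status == "somatic")
      if (distinct_sites)
        nrow(distinct(vv, .data$chrom, .data$pos, .data$ref, .data$alt))
      else nrow(vv)
    } else {
      rows <- hotspots$variants[[h]]
      if (distinct_sites) length(rows)
      else sum(map_int(clustered$carriers[rows], length))
    }
  }, integer(1))
}

#' Per-cohort enrichment of a hotspot (one-sided Fisher exact test)
#'
#' For each cohort, the 2x2 table (mutated / unmutated) x (in cohort /
#' out of cohort) over tumor samples is tested with the one-sided
#' hypergeometric tail for enrichment of mutated samples in the cohort.
#'
#' @param carrier_union carrier sample ids of the hotspot.
#' @param samples the store's sample table; tumor samples define the
#'   universe. At least two cohorts must be present (a single-cohort
#'   store returns an empty map with a warning).
#' @return named numeric vector, cohort -> one-sided p-value.
#' @export
group_enrichment <- function(carrier_union, samples) {
  tumors <- filter(samples, .data$status == "tumor")
  cohorts <- unique(tumors$cohort)
  if (length(cohorts) < 2) {
    warn("fewer than two cohorts; enrichment not testable")
    return(setNames(numeric(0), character(0)))
  }
  carriers <- intersect(unique(unlist(carrier_union)), tumors$sample_id)
  m_total <- length(carriers)
  N <- nrow(tumors)
  vapply(setNames(cohorts, cohorts), function(co) {
    in_co <- tumors$sample_id[tumors$cohort == co]
    a <- length(intersect(carriers, in_co))
    # P(X >= a), X ~ Hypergeom(m_total mutated, N - m_total unmutated,
    # |cohort| drawn)
    phyper(a - 1, m_total, N - m_total, length(in_co), lower.tail = FALSE)
  }, numeric(1))
}

#' Attach per-cohort enrichment p-values to scored hotspots
#'
#' @param results a `hotspot_results` tibble (must carry
#'   `carrier_union`).
#' @param samples the store's sample table.
#' @return results with a `group_pvalues` column formatted as
#'   `cohort=p;` pairs (empty when a single cohort).
#' @export
add_group_enrichment <- function(results, samples) {
  multi <- length(unique(samples$cohort[samples$status == "tumor"])) >= 2
  results$group_pvalues <- map_chr(results$carrier_union, function(cu) {
    if (!multi) return("")
    p <- suppressWarnings(group_enrichment(cu, samples))
    paste0(names(p), "=", fmt_p(p), ";", collapse = "")
  })
  results
}

#' Write scored hotspot results as TSV
#'
#' @param results a `hotspot_results` tibble.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_results <- function(results, path) {
  flat <- as_tibble(results) |>
    mutate(region = sprintf("%s:%d-%d", .data$chrom, .data$start, .data$end)) |>
    select("rank", "hotspot_id", "region", "region_name", "region_category",
           "k", "n", "p_raw", "q_value",
           dplyr::any_of(c("n_samples", "group_counts", "group_pvalues")))
  write_tsv_plain(flat, path)
  invisible(path)
}

#' @method tidy hotspot_results
#' @export
tidy.hotspot_results <- function(x, ...) {
  as_tibble(x) |>
    select("rank", "hotspot_id", "chrom", "start", "end", "region_name",
           "region_category", "k", "n", "p_raw", "q_value",
           dplyr::any_of(c("n_samples", "group_counts", "group_pvalues")))
}

#' @method glance hotspot_results
#' @export
glance.hotspot_results <- function(x, ...) {
  tibble(
    n_hotspots = nrow(x),
    n_significant = sum(x$q_value < 0.05),
    min_q = if (nrow(x) > 0) min(x$q_value) else NA_real_,
    total_observations = sum(x$k)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
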