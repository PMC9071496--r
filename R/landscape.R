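# PTM landscape statistics: per-protein type-count profiles, modification
# densities, RBP-vs-background enrichment tests, multi-site fractions,
# per-type site-count CDFs, and type-combination rankings.

#' Per-protein PTM type-count profiles
#'
#' One row per protein in the proteome (zero profile for unmodified proteins)
#' with one count column per PTM type observed in the catalog, plus
#' `total_sites` and `n_types` (number of distinct types on the protein).
#'
#' @param sites unified sites (a `"ptm_catalog"` or site data.frame).
#' @param proteome proteome data.frame.
#' @return data.frame of profiles.
#' @export
type_count_profiles <- function(sites, proteome) {
  sites <- as_ptm_sites(sites)
  sites <- sites[sites$accession %in% proteome$accession, , drop = FALSE]
  types <- sort(unique(sites$ptm_type))
  tab <- table(factor(sites$accession, levels = proteome$accession),
               factor(sites$ptm_type, levels = types))
  counts <- as.data.frame.matrix(tab)
  out <- data.frame(accession = proteome$accession, stringsAsFactors = FALSE)
  for (t in types) out[[t]] <- as.integer(counts[[t]])
  m <- as.matrix(counts)
  out$total_sites <- as.integer(rowSums(m))
  out$n_types <- as.integer(rowSums(m > 0))
  rownames(out) <- NULL
  out
}

#' Per-protein modification density (sites per residue)
#'
#' Density is the protein's unified site count divided by its full length in
#' residues (modified or not).
#'
#' @param sites unified sites.
#' @param proteome proteome data.frame.
#' @return data.frame with `accession`, `n_sites`, `length`, `density`,
#'   `is_rbp`.
#' @export
modification_density <- function(sites, proteome) {
  sites <- as_ptm_sites(sites)
  n <- table(factor(sites$accession, levels = proteome$accession))
  data.frame(accession = proteome$accession,
             n_sites = as.integer(n),
             length = proteome$length,
             density = as.numeric(n) / proteome$length,
             is_rbp = proteome$is_rbp,
             stringsAsFactors = FALSE)
}

#' Compare modification density between RBPs and other proteins
#'
#' Welch two-sample t-test of per-protein density, RBP vs non-RBP.
#'
#' @param densities output of [modification_density()].
#' @return list with group means, group sizes, `statistic`, and `p_value`.
#' @export
density_group_comparison <- function(densities) {
  a <- densities$density[densities$is_rbp]
  b <- densities$density[!densities$is_rbp]
  if (length(a) < 2 || length(b) < 2)
    stop("both groups need at least 2 proteins")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(mean_rbp = mean(a), mean_other = mean(b),
       n_rbp = length(a), n_other = length(b),
       statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Per-type PTM enrichment tests (RBP vs non-RBP)
#'
#' For each PTM type with at least one modified protein, tests a 2x2 table of
#' modified-by-that-type proportion in RBPs versus non-RBPs (disjoint groups)
#' with Pearson's chi-squared (no continuity correction by default; set
#' `config$yates`). `config$overlapping_groups = TRUE` contrasts RBPs against
#' ALL proteins instead. Raw p-values are Bonferroni-adjusted with family
#' size m = number of types tested; significance is called at `config$alpha`.
#' A table with a zero margin is reported as degenerate (NA statistic) rather
#' than an error.
#'
#' @param sites unified sites.
#' @param rbpome character vector of RBP accessions.
#' @param proteome proteome data.frame.
#' @param config an [analysis_config()].
#' @return data.frame with one row per type: 2x2 counts, `statistic`,
#'   `p_value`, `p_adjusted`, `direction`, `significant`, `degenerate`.
#' @export
ptm_enrichment_tests <- function(sites, rbpome, proteome,
                                 config = analysis_config()) {
  sites <- as_ptm_sites(sites)
  sites <- sites[sites$accession %in% proteome$accession, , drop = FALSE]
  is_rbp <- proteome$accession %in% rbpome
  types <- sort(unique(sites$ptm_type))
  if (length(types) == 0) stop("no PTM types present in the catalog")
  m <- length(types)

  res <- lapply(types, function(t) {
    modified <- proteome$accession %in%
      unique(sites$accession[sites$ptm_type == t])
    if (config$overlapping_groups) {
      a <- sum(modified & is_rbp);  b <- sum(!modified & is_rbp)
      c_ <- sum(modified);          d <- sum(!modified)
    } else {
      a <- sum(modified & is_rbp);  b <- sum(!modified & is_rbp)
      c_ <- sum(modified & !is_rbp); d <- sum(!modified & !is_rbp)
    }
    tab <- matrix(c(a, b, c_, d), nrow = 2,
                  dimnames = list(c("modified", "unmodified"),
                                  c("rbp", "other")))
    degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
    if (degenerate) {
      stat <- NA_real_; p <- NA_real_
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = config$yates))
      stat <- unname(ct$statistic); p <- ct$p.value
    }
    prop_rbp <- if (a + b > 0) a / (a + b) else NA_real_
    prop_other <- if (c_ + d > 0) c_ / (c_ + d) else NA_real_
    direction <- if (is.na(prop_rbp) || is.na(prop_other) ||
                     prop_rbp == prop_other) "none"
    else if (prop_rbp > prop_other) "rbp" else "other"
    data.frame(ptm_type = t,
               n_rbp_modified = a, n_rbp_unmodified = b,
               n_other_modified = c_, n_other_unmodified = d,
               statistic = stat, p_value = p,
               direction = direction, degenerate = degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_value * m)
  out$significant <- !is.na(out$p_adjusted) & out$p_adjusted < config$alpha
  out[c("ptm_type", "n_rbp_modified", "n_rbp_unmodified",
        "n_other_modified", "n_other_unmodified", "statistic",
        "p_value", "p_adjusted", "direction", "significant", "degenerate")]
}

#' Fraction of modified proteins carrying multiple sites of one type
#'
#' Among proteins bearing at least one site of `ptm_type`, the fraction
#' bearing two or more.
#'
#' @param sites unified sites.
#' @param ptm_type one canonical PTM type label.
#' @return a number in [0, 1].
#' @export
multi_site_fraction <- function(sites, ptm_type) {
  sites <- as_ptm_sites(sites)
  sub <- sites[sites$ptm_type == ptm_type, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no protein is modified with '", ptm_type, "'")
  counts <- table(sub$accession)
  mean(counts >= 2)
}

#' Empirical CDF of per-protein site counts for one PTM type
#'
#' Over proteins modified with `ptm_type`, the cumulative fraction with at
#' most `threshold` sites, evaluated at integer thresholds up to the observed
#' maximum. The CDF is nondecreasing and terminates at 1.
#'
#' @param sites unified sites.
#' @param ptm_type one canonical PTM type label.
#' @return data.frame with `threshold` and `cum_fraction`.
#' @export
site_count_cdf <- function(sites, ptm_type) {
  sites <- as_ptm_sites(sites)
  sub <- sites[sites$ptm_type == ptm_type, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("no protein is modified with '", ptm_type, "'")
  counts <- as.integer(table(sub$accession))
  thresholds <- seq_len(max(counts))
  data.frame(threshold = thresholds,
             cum_fraction = vapply(thresholds,
                                   function(t) mean(counts <= t), numeric(1)))
}

#' Ranked PTM type combinations
#'
#' Each modified protein contributes its exact set of distinct PTM types
#' (joined with `+` in sorted label order); combinations are ranked by
#' protein count, ties broken lexicographically by the combination label.
#'
#' @param sites unified sites.
#' @return data.frame with `combination` and `n_proteins`, ranked.
#' @export
top_type_combinations <- function(sites) {
  sites <- as_ptm_sites(sites)
  if (nrow(sites) == 0)
    return(data.frame(combination = character(0), n_proteins = integer(0)))
  combos <- vapply(split(sites$ptm_type, sites$accession),
                   function(t) paste(sort(unique(t)), collapse = "+"),
                   character(1))
  tab <- table(combos)
  out <- data.frame(combination = names(tab),
                    n_proteins = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_proteins, out$combination), , drop = FALSE]
  rownames(out) <- NULL
  out
}
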