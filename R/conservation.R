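# Conservation contrast: per-protein comparison of conservation scores at
# PTM positions against randomly resampled background positions from the
# same protein, plus cohort-level summaries.

# Per-protein score lookup helpers -------------------------------------------

.one_profile <- function(conservation, accession) {
  prof <- conservation[conservation$accession == accession, , drop = FALSE]
  prof[!is.na(prof$score), , drop = FALSE]
}

#' Sample background positions from a protein's conservation profile
#'
#' Draws `n` positions uniformly from the protein's scored residues after
#' excluding the given positions (PTM positions never enter the background).
#' When fewer than `n` eligible positions remain, sampling falls back to
#' with-replacement (logged via a message). Reproducible for a fixed seed.
#'
#' @param profile per-residue score data.frame for one protein
#'   (`accession`, `position`, `score`).
#' @param n number of background positions (default 100).
#' @param seed integer seed.
#' @param exclude integer positions excluded from the pool.
#' @return integer vector of `n` sampled positions, with attribute
#'   `"replacement"` (logical).
#' @export
sample_background <- function(profile, n = 100L, seed = 1L,
                              exclude = integer(0)) {
  acc <- unique(profile$accession)
  if (length(acc) != 1) stop("profile must cover exactly one protein")
  pool <- sort(setdiff(profile$position[!is.na(profile$score)], exclude))
  if (length(pool) == 0)
    stop("empty background pool for protein ", acc)
  replace <- length(pool) < n
  if (replace)
    message("sample_background: pool of ", length(pool), " < n = ", n,
            " for ", acc, "; sampling with replacement")
  out <- with_seed(seed, {
    if (replace) sample(pool, n, replace = TRUE)
    else sample(pool, n, replace = FALSE)
  })
  attr(out, "replacement") <- replace
  out
}

#' Contrast PTM-site conservation against background for one protein
#'
#' Computes the mean conservation score over the protein's scored PTM
#' positions and over a seeded background sample (PTM positions excluded),
#' and whether the PTM mean strictly exceeds the background mean (ties count
#' as not more conserved). Proteins with no scored PTM position are skipped
#' (returns `NULL` with a message).
#'
#' The background seed is derived from `(config$seed, accession)`, so cohort
#' runs are independent of protein processing order.
#'
#' @param profile per-residue score data.frame for one protein.
#' @param ptm_positions integer vector of the protein's PTM positions.
#' @param config an [analysis_config()].
#' @return one-row data.frame (`accession`, `ptm_mean`, `background_mean`,
#'   `more_conserved`, `n_ptm`, `n_background`, `replacement`) with the raw
#'   score vectors in attributes `"ptm_scores"` and `"background_scores"`,
#'   or `NULL` when no PTM position is scored.
#' @export
protein_contrast <- function(profile, ptm_positions,
                             config = analysis_config()) {
  acc <- unique(profile$accession)
  if (length(acc) != 1) stop("profile must cover exactly one protein")
  scored <- profile[!is.na(profile$score), , drop = FALSE]
  ptm_scores <- scored$score[scored$position %in% ptm_positions]
  if (length(ptm_scores) == 0) {
    message("protein_contrast: no scored PTM positions for ", acc, "; skipped")
    return(NULL)
  }
  bg_pos <- sample_background(scored, n = config$background_n,
                              seed = derive_seed(config$seed, acc),
                              exclude = ptm_positions)
  bg_scores <- scored$score[match(bg_pos, scored$position)]
  out <- data.frame(accession = acc,
                    ptm_mean = mean(ptm_scores),
                    background_mean = mean(bg_scores),
                    more_conserved = mean(ptm_scores) > mean(bg_scores),
                    n_ptm = length(ptm_scores),
                    n_background = length(bg_scores),
                    replacement = isTRUE(attr(bg_pos, "replacement")),
                    stringsAsFactors = FALSE)
  attr(out, "ptm_scores") <- ptm_scores
  attr(out, "background_scores") <- bg_scores
  out
}

#' Run the conservation contrast over a cohort of proteins
#'
#' Applies [protein_contrast()] to every protein that has both conservation
#' scores and PTM sites (optionally restricted to `accessions`), pooling the
#' PTM and background scores for the cohort-level test.
#'
#' @param conservation per-residue score data.frame (any number of proteins).
#' @param sites unified sites.
#' @param config an [analysis_config()].
#' @param accessions optional restriction (e.g. the RBP-ome).
#' @return data.frame of per-protein contrasts with pooled score vectors in
#'   attributes `"ptm_scores"` and `"background_scores"`.
#' @export
conservation_contrasts <- function(conservation, sites,
                                   config = analysis_config(),
                                   accessions = NULL) {
  sites <- as_ptm_sites(sites)
  accs <- intersect(unique(conservation$accession), unique(sites$accession))
  if (!is.null(accessions)) accs <- intersect(accs, accessions)
  accs <- sort(accs)
  prof_split <- split(conservation, conservation$accession)
  pos_split <- split(sites$position, sites$accession)
  rows <- list(); ptm_pool <- list(); bg_pool <- list()
  for (acc in accs) {
    ctr <- protein_contrast(prof_split[[acc]],
                            unique(pos_split[[acc]]), config)
    if (is.null(ctr)) next
    rows[[acc]] <- ctr
    ptm_pool[[acc]] <- attr(ctr, "ptm_scores")
    bg_pool[[acc]] <- attr(ctr, "background_scores")
  }
  if (length(rows) == 0)
    stop("no protein had scored PTM positions")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ptm_scores") <- unlist(ptm_pool, use.names = FALSE)
  attr(out, "background_scores") <- unlist(bg_pool, use.names = FALSE)
  out
}

#' Cohort-level conservation summary
#'
#' Summarizes per-protein contrasts: the fraction of proteins whose PTM
#' sites are more conserved than their sampled background, the fraction
#' whose mean PTM-site score exceeds the high-conservation threshold
#' (default 0.9), and a two-sample Kolmogorov-Smirnov test between the
#' pooled PTM and pooled background score distributions.
#'
#' @param contrasts output of [conservation_contrasts()] (pooled scores are
#'   taken from its attributes).
#' @param config an [analysis_config()].
#' @return list with `n_proteins`, `more_conserved_fraction`,
#'   `high_conservation_fraction`, `ks_statistic`, `ks_p_value`.
#' @export
cohort_summary <- function(contrasts, config = analysis_config()) {
  if (nrow(contrasts) < 2) stop("need contrasts for at least 2 proteins")
  ptm <- attr(contrasts, "ptm_scores")
  bg <- attr(contrasts, "background_scores")
  if (is.null(ptm) || is.null(bg))
    stop("contrasts must carry pooled score attributes ",
         "(use conservation_contrasts())")
  ks <- suppressWarnings(stats::ks.test(ptm, bg))
  list(n_proteins = nrow(contrasts),
       more_conserved_fraction = mean(contrasts$more_conserved),
       high_conservation_fraction =
         mean(contrasts$ptm_mean > config$high_conservation_threshold),
       ks_statistic = unname(ks$statistic),
       ks_p_value = ks$p.value)
}
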