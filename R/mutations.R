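# Cancer-mutation proximity: intersect residue-level mutation records with
# PTM sites at the exact residue and within a +/-k window; rank mutated
# sites and build per-position mutation tracks.

.empty_hits <- function() {
  data.frame(accession = character(0), mutation_position = integer(0),
             site_position = integer(0), distance = integer(0),
             ptm_type = character(0), ref_aa = character(0),
             alt_aa = character(0), cancer_type = character(0),
             case_count = integer(0), mutation_id = integer(0),
             stringsAsFactors = FALSE)
}

.finish_hits <- function(hits, mutations) {
  o <- order(hits$accession, hits$mutation_position, hits$site_position,
             hits$ptm_type, hits$mutation_id)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_unique_mutations") <- length(unique(hits$mutation_id))
  attr(hits, "n_unique_proteins") <- length(unique(hits$accession))
  hits
}

#' Mutations coinciding with PTM sites (distance 0)
#'
#' One hit per (mutation, site) pair sharing (accession, position); a
#' mutation at a residue carrying two PTM types yields two hits. Companion
#' deduplicated counts (unique mutations, unique proteins) are attached as
#' attributes, mirroring "N mutations in M proteins" phrasing.
#'
#' @param mutations mutation data.frame (see [read_mutations()]); a
#'   `mutation_id` column is added if absent.
#' @param sites unified sites.
#' @return hit data.frame with `distance = 0`, plus attributes
#'   `"n_unique_mutations"` and `"n_unique_proteins"`.
#' @export
mutations_at_sites <- function(mutations, sites) {
  mutations_near_sites(mutations, sites, k = 0L)
}

#' Mutations within k residues of PTM sites
#'
#' Hits are all (mutation, site) pairs on the same protein with
#' `|mutation position - site position| <= k` (inclusive and symmetric).
#' The per-mutation nearest-site distance is attached as attribute
#' `"nearest"`.
#'
#' @param mutations mutation data.frame.
#' @param sites unified sites.
#' @param k nonnegative proximity radius in residues (default 10).
#' @return hit data.frame (`accession`, `mutation_position`,
#'   `site_position`, `distance`, `ptm_type`, mutation fields), with
#'   attributes `"n_unique_mutations"`, `"n_unique_proteins"`, `"nearest"`.
#' @export
mutations_near_sites <- function(mutations, sites, k = 10L) {
  k <- as.integer(k)
  if (is.na(k) || k < 0) stop("k must be a nonnegative integer")
  sites <- as_ptm_sites(sites)
  if (is.null(mutations$mutation_id))
    mutations$mutation_id <- seq_len(nrow(mutations))

  accs <- intersect(unique(mutations$accession), unique(sites$accession))
  out <- list()
  m_split <- split(mutations, mutations$accession)
  s_split <- split(sites, sites$accession)
  for (acc in accs) {
    m <- m_split[[acc]]; s <- s_split[[acc]]
    d <- abs(outer(m$position, s$position, "-"))
    idx <- which(d <= k, arr.ind = TRUE)
    if (nrow(idx) == 0) next
    out[[acc]] <- data.frame(
      accession = acc,
      mutation_position = m$position[idx[, 1]],
      site_position = s$position[idx[, 2]],
      distance = d[idx],
      ptm_type = s$ptm_type[idx[, 2]],
      ref_aa = m$ref_aa[idx[, 1]],
      alt_aa = m$alt_aa[idx[, 1]],
      cancer_type = m$cancer_type[idx[, 1]],
      case_count = m$case_count[idx[, 1]],
      mutation_id = m$mutation_id[idx[, 1]],
      stringsAsFactors = FALSE)
  }
  hits <- if (length(out)) do.call(rbind, out) else .empty_hits()
  hits <- .finish_hits(hits, mutations)
  if (nrow(hits)) {
    nearest <- tapply(hits$distance, hits$mutation_id, min)
    attr(hits, "nearest") <- data.frame(
      mutation_id = as.integer(names(nearest)),
      nearest_distance = as.integer(nearest))
  } else {
    attr(hits, "nearest") <- data.frame(mutation_id = integer(0),
                                        nearest_distance = integer(0))
  }
  hits
}

#' Per-residue mutation case-count track for one protein
#'
#' Position p of the returned vector holds the summed case counts of all
#' mutations at residue p, so the vector total equals the protein's retained
#' case count. Mutations beyond the protein length are dropped with a
#' message.
#'
#' @param mutations mutation data.frame.
#' @param accession protein accession.
#' @param length protein length in residues.
#' @return integer vector of length `length`.
#' @export
per_position_mutation_track <- function(mutations, accession, length) {
  length <- as.integer(length)
  m <- mutations[mutations$accession == accession, , drop = FALSE]
  beyond <- m$position > length
  if (any(beyond))
    message("per_position_mutation_track: dropped ", sum(beyond),
            " mutation(s) beyond length ", length, " of ", accession)
  m <- m[!beyond, , drop = FALSE]
  track <- integer(length)
  if (nrow(m)) {
    agg <- tapply(m$case_count, m$position, sum)
    track[as.integer(names(agg))] <- as.integer(agg)
  }
  track
}

#' Rank PTM-site mutations by cancer case count
#'
#' Aggregates distance-0 hits per (accession, position, ptm_type), summing
#' case counts (each (mutation, site) pair contributes its mutation's cases)
#' and collecting cancer types. Ranked by descending total cases, ties
#' broken by accession then position.
#'
#' @param hits distance-0 hit data.frame from [mutations_at_sites()].
#' @return ranked data.frame (`accession`, `position`, `ptm_type`,
#'   `total_cases`, `cancer_types`).
#' @export
rank_site_mutations <- function(hits) {
  hits <- hits[hits$distance == 0, , drop = FALSE]
  if (nrow(hits) == 0)
    return(data.frame(accession = character(0), position = integer(0),
                      ptm_type = character(0), total_cases = integer(0),
                      cancer_types = character(0), stringsAsFactors = FALSE))
  key <- paste(hits$accession, hits$site_position, hits$ptm_type, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  out <- data.frame(
    accession = hits$accession[first],
    position = hits$site_position[first],
    ptm_type = hits$ptm_type[first],
    total_cases = as.integer(tapply(hits$case_count, grp, sum)),
    cancer_types = vapply(split(hits$cancer_type, grp), join_multi,
                          character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$total_cases, out$accession, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
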