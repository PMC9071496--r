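# RNA-protein interface proximity: standardize reported crosslink ranges to
# fixed odd-width windows, relate PTM positions to window centers, compute
# distance-frequency statistics and family contrasts, and intersect eCLIP
# peaks with gene models strand-awarely.

#' Standardize crosslink ranges to fixed-width windows
#'
#' Crosslink studies report residue ranges at very different resolutions, so
#' every range is standardized to a `w`-position window centered on it: the
#' center is `floor((start + end) / 2)` (left-of-middle for even-length
#' ranges) and the window `[center - (w-1)/2, center + (w-1)/2]` is clipped
#' to `[1, length]` without re-centering. Ranges longer than `w` are thereby
#' truncated around their center (the window is a subset of the range);
#' shorter ranges are expanded.
#'
#' @param ranges crosslink data.frame (`accession`, `start`, `end`,
#'   `study`); 1-based inclusive coordinates.
#' @param proteome proteome data.frame (for protein lengths).
#' @param w odd window width (default 21).
#' @return data.frame of windows (`accession`, `center`, `start`, `end`,
#'   `src_start`, `src_end`, `study`).
#' @export
standardize_windows <- function(ranges, proteome, w = 21L) {
  w <- as.integer(w)
  if (is.na(w) || w < 1 || w %% 2L == 0L) stop("w must be a positive odd integer")
  L <- proteome$length[match(ranges$accession, proteome$accession)]
  if (anyNA(L))
    stop("crosslink ranges on accessions absent from the proteome: ",
         paste(unique(ranges$accession[is.na(L)]), collapse = ", "))
  bad <- which(ranges$start < 1 | ranges$end < ranges$start | ranges$end > L)
  if (length(bad))
    stop("crosslink range(s) outside the protein at row(s): ",
         paste(bad, collapse = ", "))
  center <- (ranges$start + ranges$end) %/% 2L
  half <- (w - 1L) %/% 2L
  data.frame(accession = ranges$accession,
             center = center,
             start = pmax(1L, center - half),
             end = pmin(as.integer(L), center + half),
             src_start = ranges$start,
             src_end = ranges$end,
             study = ranges$study,
             stringsAsFactors = FALSE)
}

#' Assign PTM sites to crosslink windows by center distance
#'
#' Every site lying inside a standardized window yields one record per
#' containing window, with `distance = |position - center|` (bounded by
#' `(w-1)/2`). Sites outside all windows are absent.
#'
#' @param sites unified sites.
#' @param windows standardized windows from [standardize_windows()].
#' @return data.frame (`accession`, `position`, `ptm_type`, `center`,
#'   `window_start`, `window_end`, `study`, `distance`).
#' @export
assign_ptm_distances <- function(sites, windows) {
  sites <- as_ptm_sites(sites)
  joined <- merge(sites[c("accession", "position", "ptm_type")],
                  windows[c("accession", "center", "start", "end", "study")],
                  by = "accession")
  keep <- joined$position >= joined$start & joined$position <= joined$end
  out <- joined[keep, , drop = FALSE]
  out$distance <- abs(out$position - out$center)
  names(out)[names(out) == "start"] <- "window_start"
  names(out)[names(out) == "end"] <- "window_end"
  o <- order(out$accession, out$position, out$center, out$ptm_type)
  out <- out[o, c("accession", "position", "ptm_type", "center",
                  "window_start", "window_end", "study", "distance")]
  rownames(out) <- NULL
  out
}

#' Residue-slot opportunities per center distance
#'
#' For each distance d in `0..(w-1)/2`, the number of residue slots at that
#' distance across all windows (one slot at d = 0, up to two at d > 0,
#' fewer where clipping removed a flank). Used to normalize bin counts.
#'
#' @param windows standardized windows.
#' @param w odd window width.
#' @return data.frame (`distance`, `opportunity`).
#' @export
distance_opportunities <- function(windows, w = 21L) {
  half <- (as.integer(w) - 1L) %/% 2L
  d <- 0:half
  opp <- vapply(d, function(dd) {
    left <- sum(windows$center - dd >= windows$start)
    right <- if (dd == 0) 0L else sum(windows$center + dd <= windows$end)
    left + right
  }, numeric(1))
  data.frame(distance = d, opportunity = as.integer(opp))
}

#' Distance-frequency statistics for PTMs around crosslink centers
#'
#' Bins assignment distances over `0..(w-1)/2` and computes the Spearman
#' rank correlation between distance and PTM frequency (average ranks for
#' ties, asymptotic p-value). When `windows` are supplied (default usage),
#' frequency is the bin count divided by the number of residue slots at that
#' distance ([distance_opportunities()]); this removes the structural
#' deficit of the d = 0 bin, which has one slot per window against two for
#' every other distance. With `windows = NULL` raw counts are correlated.
#'
#' All counts falling in a single bin, or fewer than two distinct observed
#' distances, make the correlation undefined; identical frequencies in all
#' bins are reported as rho = 0 under the all-ties convention. Both cases
#' are flagged rather than raised.
#'
#' @param assignments output of [assign_ptm_distances()].
#' @param windows standardized windows for opportunity normalization, or
#'   `NULL` for raw counts.
#' @param w odd window width (default 21).
#' @param ptm_type optional single type to restrict to.
#' @return list with `bins` (distance, count, opportunity, frequency),
#'   `rho`, `p_value`, `n_sites`, and `flag` (`"ok"`, `"all_ties"`, or
#'   `"insufficient"`).
#' @export
distance_frequency_stats <- function(assignments, windows = NULL, w = 21L,
                                     ptm_type = NULL) {
  half <- (as.integer(w) - 1L) %/% 2L
  if (!is.null(ptm_type))
    assignments <- assignments[assignments$ptm_type == ptm_type, , drop = FALSE]
  counts <- tabulate(assignments$distance + 1L, nbins = half + 1L)
  bins <- data.frame(distance = 0:half, count = counts)
  if (!is.null(windows)) {
    opp <- distance_opportunities(windows, w)
    bins$opportunity <- opp$opportunity
    bins$frequency <- ifelse(bins$opportunity > 0,
                             bins$count / bins$opportunity, NA_real_)
  } else {
    bins$opportunity <- NA_integer_
    bins$frequency <- bins$count
  }
  usable <- !is.na(bins$frequency)
  res <- list(bins = bins, n_sites = nrow(assignments))
  if (length(unique(assignments$distance)) < 2 || sum(usable) < 2) {
    res$rho <- NA_real_; res$p_value <- NA_real_; res$flag <- "insufficient"
    return(res)
  }
  if (stats::var(bins$frequency[usable]) == 0) {
    res$rho <- 0; res$p_value <- NA_real_; res$flag <- "all_ties"
    return(res)
  }
  ct <- suppressWarnings(stats::cor.test(bins$distance[usable],
                                         bins$frequency[usable],
                                         method = "spearman", exact = FALSE))
  res$rho <- unname(ct$estimate)
  res$p_value <- ct$p.value
  res$flag <- "ok"
  res
}

#' Nearest crosslink-center distance per PTM site
#'
#' For every site on a protein with at least one standardized window, the
#' minimum `|position - center|` over that protein's window centers
#' (unbounded — sites far from every window keep their true distance).
#' Proteins without windows are excluded.
#'
#' @param sites unified sites.
#' @param windows standardized windows.
#' @return data.frame (`accession`, `position`, `ptm_type`,
#'   `nearest_distance`).
#' @export
nearest_center_distances <- function(sites, windows) {
  sites <- as_ptm_sites(sites)
  centers <- split(windows$center, windows$accession)
  sub <- sites[sites$accession %in% names(centers), , drop = FALSE]
  nd <- vapply(seq_len(nrow(sub)), function(i)
    min(abs(sub$position[i] - centers[[sub$accession[i]]])), numeric(1))
  out <- data.frame(accession = sub$accession, position = sub$position,
                    ptm_type = sub$ptm_type,
                    nearest_distance = as.integer(nd),
                    stringsAsFactors = FALSE)
  o <- order(out$accession, out$position, out$ptm_type)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contrast nearest-center distances between protein families
#'
#' Welch two-sample t-test of per-site nearest-center distances between
#' sites on proteins carrying `tag` in their `family_tags` (e.g. "hnRNP")
#' and sites on all other proteins with windows.
#'
#' @param nearest output of [nearest_center_distances()].
#' @param proteome proteome data.frame (supplies `family_tags`).
#' @param tag family tag defining group A (default `"hnRNP"`).
#' @return list with `mean_a`, `mean_b`, `n_a`, `n_b`, `statistic`,
#'   `p_value`.
#' @export
interface_group_contrast <- function(nearest, proteome, tag = "hnRNP") {
  tags <- proteome$family_tags[match(nearest$accession, proteome$accession)]
  in_a <- !is.na(tags) & vapply(strsplit(ifelse(is.na(tags), "", tags), ";"),
                                function(x) tag %in% x, logical(1))
  a <- nearest$nearest_distance[in_a]
  b <- nearest$nearest_distance[!in_a]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 sites (tag '", tag, "': ",
         length(a), " vs ", length(b), ")")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b),
       statistic = unname(tt$statistic), p_value = tt$p.value)
}

# One replicate's qualifying (rbp, gene) pairs.
.replicate_hits <- function(peaks, genes, f) {
  if (nrow(peaks) == 0 || nrow(genes) == 0)
    return(character(0))
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L, peaks$end),
                               strand = peaks$strand)
  gn <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               strand = genes$strand)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(pk, gn))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (length(qi) == 0) return(character(0))
  ov_len <- pmin(peaks$end[qi], genes$end[si]) -
    pmax(peaks$start[qi], genes$start[si])
  frac <- ov_len / (peaks$end[qi] - peaks$start[qi])
  keep <- frac >= f
  unique(paste(peaks$rbp[qi[keep]], genes$gene_id[si[keep]], sep = "\r"))
}

#' Strand-aware eCLIP peak-gene intersection
#'
#' An (RBP, gene) pair is a hit iff in each replicate at least one of the
#' RBP's peaks overlaps the gene on the same strand with
#' `overlap length / peak length >= f`. Coordinates are 0-based half-open
#' (narrowPeak/BED convention); the overlap fraction's denominator is the
#' peak's own length. The two replicates are not required to contain the
#' same peak, only each to contain a qualifying one, and the result is
#' symmetric in replicate order.
#'
#' @param peaks_rep1,peaks_rep2 peak data.frames (see [read_narrowpeak()]).
#' @param genes gene model data.frame (see [read_gene_models()]).
#' @param f minimum peak-overlap fraction in (0, 1] (default 0.5).
#' @return data.frame of hits (`rbp`, `gene_id`), sorted.
#' @export
eclip_gene_hits <- function(peaks_rep1, peaks_rep2, genes, f = 0.5) {
  if (!is.numeric(f) || f <= 0 || f > 1) stop("f must be in (0, 1]")
  h1 <- .replicate_hits(peaks_rep1, genes, f)
  h2 <- .replicate_hits(peaks_rep2, genes, f)
  both <- sort(intersect(h1, h2))
  parts <- strsplit(both, "\r", fixed = TRUE)
  data.frame(rbp = vapply(parts, `[`, character(1), 1),
             gene_id = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}
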