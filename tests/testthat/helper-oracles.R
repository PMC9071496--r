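# Independent brute-force oracles. Deliberately naive (scalar loops,
# all-pairs scans) so they share no code path with the implementation.

oracle_window <- function(start, end, L, w = 21L) {
  center <- floor((start + end) / 2)
  half <- (w - 1) / 2
  c(center = center,
    start = max(1, center - half),
    end = min(L, center + half))
}

# Multiset of (site row, window row, distance) via per-window scan.
oracle_assignments <- function(sites, windows) {
  out <- list()
  for (i in seq_len(nrow(windows))) {
    for (j in seq_len(nrow(sites))) {
      if (sites$accession[j] != windows$accession[i]) next
      p <- sites$position[j]
      if (p >= windows$start[i] && p <= windows$end[i])
        out[[length(out) + 1L]] <- data.frame(
          accession = sites$accession[j], position = p,
          ptm_type = sites$ptm_type[j], center = windows$center[i],
          distance = abs(p - windows$center[i]),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(accession = character(0), position = integer(0),
                  ptm_type = character(0), center = integer(0),
                  distance = integer(0))
}

# All-pairs mutation/site proximity scan.
oracle_mutation_hits <- function(mutations, sites, k) {
  out <- list()
  for (i in seq_len(nrow(mutations))) {
    for (j in seq_len(nrow(sites))) {
      if (mutations$accession[i] != sites$accession[j]) next
      d <- abs(mutations$position[i] - sites$position[j])
      if (d <= k)
        out[[length(out) + 1L]] <- data.frame(
          accession = mutations$accession[i],
          mutation_position = mutations$position[i],
          site_position = sites$position[j],
          distance = d, ptm_type = sites$ptm_type[j],
          mutation_id = mutations$mutation_id[i],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(accession = character(0), mutation_position = integer(0),
                  site_position = integer(0), distance = integer(0),
                  ptm_type = character(0), mutation_id = integer(0))
}

# Cell-wise ME/M/E/none label via explicit neighborhood scan on the RAW
# (uncanonicalized) edge list.
oracle_me_label <- function(acc, type, sites, edges, enzymes,
                            nonenzymatic = c("oxidation", "sulfenic acid"),
                            writer_only = FALSE) {
  modified <- any(sites$accession == acc & sites$ptm_type == type)
  enz <- character(0)
  if (!type %in% nonenzymatic) {
    for (i in seq_len(nrow(enzymes))) {
      if (enzymes$ptm_type[i] != type) next
      if (writer_only && enzymes$role[i] != "writer") next
      enz <- c(enz, enzymes$accession[i])
    }
  }
  nb <- character(0)
  for (i in seq_len(nrow(edges))) {
    if (edges$accession_a[i] == acc) nb <- c(nb, edges$accession_b[i])
    if (edges$accession_b[i] == acc) nb <- c(nb, edges$accession_a[i])
  }
  has <- length(intersect(unique(nb), unique(enz))) > 0
  if (modified && has) "ME" else if (modified) "M" else if (has) "E" else "none"
}

# (modified protein, matching enzyme) pair count via double loop over unique
# protein/enzyme combinations.
oracle_interaction_count <- function(type, sites, edges, enzymes, rbpome,
                                     nonenzymatic = c("oxidation",
                                                      "sulfenic acid")) {
  if (type %in% nonenzymatic) return(0L)
  modset <- intersect(rbpome, unique(sites$accession[sites$ptm_type == type]))
  enz <- unique(enzymes$accession[enzymes$ptm_type == type])
  n <- 0L
  for (p in modset) for (e in enz) {
    linked <- any((edges$accession_a == p & edges$accession_b == e) |
                    (edges$accession_a == e & edges$accession_b == p))
    if (linked) n <- n + 1L
  }
  n
}

# All-pairs strand-aware interval check on 0-based half-open coordinates.
oracle_eclip_hits <- function(rep1, rep2, genes, f) {
  one <- function(peaks) {
    hits <- character(0)
    for (i in seq_len(nrow(peaks))) for (j in seq_len(nrow(genes))) {
      if (peaks$chrom[i] != genes$chrom[j]) next
      if (peaks$strand[i] != genes$strand[j]) next
      ov <- min(peaks$end[i], genes$end[j]) - max(peaks$start[i], genes$start[j])
      if (ov <= 0) next
      if (ov / (peaks$end[i] - peaks$start[i]) >= f)
        hits <- c(hits, paste(peaks$rbp[i], genes$gene_id[j], sep = "\r"))
    }
    unique(hits)
  }
  sort(intersect(one(rep1), one(rep2)))
}

# Canonical sortable key for hit/assignment multiset comparison.
multiset_key <- function(df, cols) {
  sort(do.call(paste, c(unname(as.list(df[cols])), sep = "\r")))
}
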