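# Enzyme-substrate pairing over the PPI network: ME/M/E classification of
# (RBP, PTM type) pairs, potentially-modifying interaction counts, per-enzyme
# RBP counts, and enzyme target-set overlaps.

#' Canonicalize an undirected edge list
#'
#' Orders each edge's endpoints lexicographically, drops self-loops, and
#' deduplicates edges reported by several source databases (sources merged
#' with ";"). All pairing statistics are invariant under edge direction flips
#' and cross-database duplication because they operate on this canonical set.
#'
#' @param edges edge data.frame (`accession_a`, `accession_b`, `source`).
#' @return canonical edge data.frame with `accession_a < accession_b`.
#' @export
canonical_edges <- function(edges) {
  a <- pmin(edges$accession_a, edges$accession_b)
  b <- pmax(edges$accession_a, edges$accession_b)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  src <- if ("source" %in% names(edges)) edges$source[keep]
  else rep(NA_character_, length(a))
  key <- paste(a, b, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  out <- data.frame(accession_a = a[first], accession_b = b[first],
                    source = vapply(split(src, grp), join_multi, character(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$accession_a, out$accession_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Accessions adjacent to `acc` in a canonical edge list.
.neighbors <- function(edges, acc) {
  unique(c(edges$accession_b[edges$accession_a %in% acc],
           edges$accession_a[edges$accession_b %in% acc]))
}

# Enzymes annotated as regulating `ptm_type`. "Regulating" accepts either
# the writer or the eraser role by default (config$writer_only restricts to
# writers); types with purely chemical deposition (config$nonenzymatic_types)
# have no matching enzymes by definition.
matching_enzymes <- function(enzymes, ptm_type, config = analysis_config()) {
  if (ptm_type %in% config$nonenzymatic_types) return(character(0))
  sel <- enzymes$ptm_type == ptm_type
  if (config$writer_only) sel <- sel & enzymes$role == "writer"
  unique(enzymes$accession[sel])
}

#' Classify one (protein, PTM type) pair as ME, M, E, or none
#'
#' `ME`: the protein carries the PTM and interacts with at least one enzyme
#' annotated for that PTM type; `M`: modified but no matching enzyme
#' neighbor; `E`: unmodified but interacting with a matching enzyme;
#' `none`: neither. For PTM types in `config$nonenzymatic_types` (deposited
#' by cellular chemistry, not enzymes) no enzyme ever matches, so labels are
#' restricted to M/none.
#'
#' @param accession protein accession.
#' @param ptm_type canonical PTM type label.
#' @param sites unified sites.
#' @param edges canonical (or raw) edge data.frame.
#' @param enzymes enzyme annotation data.frame (`accession`, `ptm_type`,
#'   `role`).
#' @param config an [analysis_config()].
#' @return one-row data.frame (`accession`, `ptm_type`, `label`,
#'   `supporting` — ";"-joined enzyme accessions, nonempty iff ME or E).
#' @export
classify_me <- function(accession, ptm_type, sites, edges, enzymes,
                        config = analysis_config()) {
  sites <- as_ptm_sites(sites)
  edges <- canonical_edges(edges)
  modified <- any(sites$accession == accession & sites$ptm_type == ptm_type)
  match_enz <- matching_enzymes(enzymes, ptm_type, config)
  supporting <- sort(intersect(.neighbors(edges, accession), match_enz))
  has_enz <- length(supporting) > 0
  label <- if (modified && has_enz) "ME"
  else if (modified) "M"
  else if (has_enz) "E"
  else "none"
  data.frame(accession = accession, ptm_type = ptm_type, label = label,
             supporting = if (has_enz) paste(supporting, collapse = ";")
             else NA_character_,
             stringsAsFactors = FALSE)
}

#' ME/M/E label matrix over the RBP-ome
#'
#' One row per RBP, one column per PTM type (union of enzyme-annotated types
#' and types observed on RBPs); each cell is the [classify_me()] label.
#' `{ME, M, E, none}` partitions every cell. A column whose type has no
#' enzyme annotation carries only M/none labels (noted via a message).
#'
#' @param rbpome character vector of RBP accessions.
#' @param sites unified sites.
#' @param edges edge data.frame.
#' @param enzymes enzyme annotation data.frame.
#' @param config an [analysis_config()].
#' @return character matrix (RBP x PTM type).
#' @export
me_matrix <- function(rbpome, sites, edges, enzymes,
                      config = analysis_config()) {
  sites <- as_ptm_sites(sites)
  edges <- canonical_edges(edges)
  rbpome <- sort(unique(rbpome))
  types <- sort(union(unique(enzymes$ptm_type),
                      unique(sites$ptm_type[sites$accession %in% rbpome])))
  mat <- matrix("none", nrow = length(rbpome), ncol = length(types),
                dimnames = list(rbpome, types))
  for (t in types) {
    modified <- rbpome %in% unique(sites$accession[sites$ptm_type == t])
    match_enz <- matching_enzymes(enzymes, t, config)
    if (length(match_enz) == 0 && !t %in% config$nonenzymatic_types)
      message("me_matrix: no enzyme annotation for '", t,
              "'; column restricted to {M, none}")
    interacts <- rbpome %in% .neighbors(edges, match_enz)
    mat[, t] <- ifelse(modified & interacts, "ME",
                       ifelse(modified, "M",
                              ifelse(interacts, "E", "none")))
  }
  mat
}

#' Count potentially modifying interactions per PTM type
#'
#' For each PTM type, the number of (modified RBP, matching enzyme neighbor)
#' pairs: an RBP with three kinase neighbors contributes three to
#' phosphorylation. Edges are deduplicated first, so each (protein, enzyme)
#' pair counts once regardless of how many databases report it.
#'
#' @inheritParams me_matrix
#' @return data.frame with `ptm_type` and `n_interactions` for every
#'   enzyme-annotated type.
#' @export
count_modifying_interactions <- function(sites, edges, enzymes, rbpome,
                                         config = analysis_config()) {
  sites <- as_ptm_sites(sites)
  edges <- canonical_edges(edges)
  types <- sort(unique(enzymes$ptm_type))
  n <- vapply(types, function(t) {
    modset <- intersect(rbpome,
                        unique(sites$accession[sites$ptm_type == t]))
    match_enz <- matching_enzymes(enzymes, t, config)
    if (length(modset) == 0 || length(match_enz) == 0) return(0L)
    sum((edges$accession_a %in% modset & edges$accession_b %in% match_enz) |
          (edges$accession_b %in% modset & edges$accession_a %in% match_enz))
  }, integer(1))
  data.frame(ptm_type = types, n_interactions = unname(n),
             stringsAsFactors = FALSE)
}

#' Count RBP substrates per enzyme
#'
#' For every annotated (enzyme, PTM type) pair, the number of RBPs that both
#' carry that PTM type and neighbor the enzyme in the PPI network.
#'
#' @inheritParams me_matrix
#' @return data.frame with `enzyme`, `ptm_type`, `role`, `n_rbps`.
#' @export
rbp_count_per_enzyme <- function(sites, edges, enzymes, rbpome,
                                 config = analysis_config()) {
  sites <- as_ptm_sites(sites)
  edges <- canonical_edges(edges)
  ann <- unique(enzymes[c("accession", "ptm_type", "role")])
  if (config$writer_only) ann <- ann[ann$role == "writer", , drop = FALSE]
  ann <- ann[!ann$ptm_type %in% config$nonenzymatic_types, , drop = FALSE]
  n <- integer(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    modset <- intersect(rbpome,
                        unique(sites$accession[sites$ptm_type == ann$ptm_type[i]]))
    n[i] <- length(intersect(.neighbors(edges, ann$accession[i]), modset))
  }
  out <- data.frame(enzyme = ann$accession, ptm_type = ann$ptm_type,
                    role = ann$role, n_rbps = n, stringsAsFactors = FALSE)
  out <- out[order(-out$n_rbps, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap between two enzymes' RBP target sets
#'
#' An enzyme's target set is the union, over its annotated PTM types, of
#' RBPs that carry the type and neighbor the enzyme (as in
#' [rbp_count_per_enzyme()]).
#'
#' @param enzyme_a,enzyme_b enzyme accessions (must be annotated).
#' @inheritParams me_matrix
#' @return list with `set_a`, `set_b`, `shared` (sorted accession vectors)
#'   and their sizes.
#' @export
enzyme_target_overlap <- function(enzyme_a, enzyme_b, sites, edges, enzymes,
                                  rbpome, config = analysis_config()) {
  sites <- as_ptm_sites(sites)
  edges <- canonical_edges(edges)
  target_set <- function(e) {
    ann_t <- unique(enzymes$ptm_type[enzymes$accession == e &
                                       (!config$writer_only |
                                          enzymes$role == "writer")])
    ann_t <- setdiff(ann_t, config$nonenzymatic_types)
    if (length(ann_t) == 0) return(character(0))
    nb <- .neighbors(edges, e)
    sort(unique(unlist(lapply(ann_t, function(t)
      intersect(intersect(rbpome, nb),
                unique(sites$accession[sites$ptm_type == t]))))))
  }
  for (e in c(enzyme_a, enzyme_b))
    if (!e %in% enzymes$accession) stop("unknown enzyme accession: ", e)
  set_a <- target_set(enzyme_a)
  set_b <- target_set(enzyme_b)
  shared <- intersect(set_a, set_b)
  list(set_a = set_a, set_b = set_b, shared = shared,
       n_a = length(set_a), n_b = length(set_b), n_shared = length(shared))
}
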