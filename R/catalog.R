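# PTM catalog harmonization: per-source readers (dialects), unification onto
# a canonical proteome, RBP-ome construction, and flat-file atlas export.

.rbptm_env <- new.env(parent = emptyenv())

.SITE_COLS <- c("accession", "position", "residue", "ptm_type",
                "source", "pmid", "cell_line", "sample_type",
                "body_site", "disease_state")

#' Register a PTM catalog dialect
#'
#' A dialect maps one source catalog's column names onto the canonical site
#' fields and declares which `evidence` values mark computational predictions
#' (which are always dropped: only experimentally determined sites enter the
#' analysis).
#'
#' @param name dialect name used in [load_ptm_catalog()].
#' @param columns named character vector mapping canonical field ->
#'   source column name. Must cover `accession`, `position`, `ptm_type`;
#'   `residue`, `pmid`, `evidence` and the context fields (`cell_line`,
#'   `sample_type`, `body_site`, `disease_state`) are optional.
#' @param prediction_values `evidence` values flagging a predicted site.
#' @return the dialect definition, invisibly.
#' @export
register_ptm_dialect <- function(name, columns,
                                 prediction_values = c("predicted",
                                                       "computational",
                                                       "in silico")) {
  need <- c("accession", "position", "ptm_type")
  miss <- setdiff(need, names(columns))
  if (length(miss)) stop("dialect must map columns: ",
                         paste(miss, collapse = ", "))
  d <- list(columns = columns, prediction_values = tolower(prediction_values))
  .rbptm_env$dialects[[name]] <- d
  invisible(d)
}

#' List registered PTM catalog dialects
#' @return character vector of dialect names.
#' @export
ptm_dialects <- function() names(.rbptm_env$dialects)

.default_dialects <- function() {
  register_ptm_dialect("generic", c(
    accession = "accession", position = "position", residue = "residue",
    ptm_type = "ptm_type", pmid = "pmid", evidence = "evidence",
    cell_line = "cell_line", sample_type = "sample_type",
    body_site = "body_site", disease_state = "disease_state"))
  # PhosphoSitePlus-like export dialect
  register_ptm_dialect("sitelist", c(
    accession = "ACC_ID", position = "MOD_RSD_POS", residue = "MOD_AA",
    ptm_type = "MOD_TYPE", pmid = "PUBMED", evidence = "EVIDENCE",
    cell_line = "CELL_LINE"))
}

.onLoad <- function(libname, pkgname) {
  .rbptm_env$dialects <- list()
  .default_dialects()
}

#' Load one PTM site catalog
#'
#' Reads a delimited source catalog under a registered dialect, drops rows
#' flagged as computational predictions, and normalizes PTM type labels to
#' the vocabulary. Rows whose label cannot be mapped are dropped with a
#' warning (never silently passed through); structurally malformed rows
#' (missing accession, non-positive position) are an error naming the row.
#'
#' @param path file path (TSV, or CSV when the extension is `.csv`).
#' @param dialect registered dialect name; see [ptm_dialects()].
#' @param vocabulary a `"ptm_vocabulary"`; defaults to the shipped one.
#' @param source_name provenance label recorded for every site; defaults to
#'   the dialect name.
#' @return data.frame of provenance-level site records (one row per source
#'   record), with a `"dropped"` attribute counting predicted and
#'   unmappable-label rows.
#' @export
load_ptm_catalog <- function(path, dialect,
                             vocabulary = default_ptm_vocabulary(),
                             source_name = dialect) {
  d <- .rbptm_env$dialects[[dialect]]
  if (is.null(d)) stop("unknown PTM catalog dialect: ", dialect,
                       " (registered: ", paste(ptm_dialects(), collapse = ", "), ")")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  if (nrow(tab) == 0) {
    out <- stats::setNames(
      data.frame(matrix(character(0), 0, length(.SITE_COLS)),
                 stringsAsFactors = FALSE), .SITE_COLS)
    out$position <- integer(0)
    attr(out, "dropped") <- c(predicted = 0L, unmapped = 0L)
    return(out)
  }
  miss <- setdiff(unname(d$columns[c("accession", "position", "ptm_type")]),
                  names(tab))
  if (length(miss)) stop("catalog ", path, " lacks required columns: ",
                         paste(miss, collapse = ", "))
  pick <- function(field) {
    col <- unname(d$columns[field])
    if (!is.na(col) && col %in% names(tab)) tab[[col]]
    else rep(NA_character_, nrow(tab))
  }
  out <- data.frame(accession = as.character(pick("accession")),
                    position = suppressWarnings(as.integer(pick("position"))),
                    residue = toupper(as.character(pick("residue"))),
                    ptm_type = as.character(pick("ptm_type")),
                    source = source_name,
                    pmid = as.character(pick("pmid")),
                    cell_line = as.character(pick("cell_line")),
                    sample_type = as.character(pick("sample_type")),
                    body_site = as.character(pick("body_site")),
                    disease_state = as.character(pick("disease_state")),
                    stringsAsFactors = FALSE)

  malformed <- which(is.na(out$accession) | !nzchar(out$accession) |
                       is.na(out$position) | out$position < 1)
  if (length(malformed))
    stop("malformed catalog row(s) in ", path, ": ",
         paste(malformed, collapse = ", "),
         " (need accession and positive position)")

  evidence <- tolower(as.character(pick("evidence")))
  predicted <- !is.na(evidence) & evidence %in% d$prediction_values
  n_pred <- sum(predicted)
  out <- out[!predicted, , drop = FALSE]

  canon <- normalize_ptm_label(vocabulary, out$ptm_type)
  n_unmapped <- sum(is.na(canon))
  if (n_unmapped > 0)
    warning(n_unmapped, " site(s) with unmappable PTM labels dropped from ",
            path, ": ", paste(unique(out$ptm_type[is.na(canon)]), collapse = ", "),
            call. = FALSE)
  out$ptm_type <- canon
  out <- out[!is.na(canon), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(predicted = n_pred, unmapped = n_unmapped)
  out
}

# Aggregate provenance-level rows into one site per (accession, position,
# ptm_type) with merged sources/pmids. Shared by unify_catalogs/import_atlas.
.aggregate_sites <- function(rows) {
  rows <- unique(rows[.SITE_COLS])
  if (nrow(rows) == 0) {
    sites <- data.frame(accession = character(0), position = integer(0),
                        residue = character(0), ptm_type = character(0),
                        sources = character(0), pmids = character(0),
                        stringsAsFactors = FALSE)
    return(list(sites = sites, provenance = rows))
  }
  # canonical row order first, so aggregation (and any first-non-NA choice)
  # is independent of catalog input order
  rows <- rows[do.call(order, unname(as.list(rows))), , drop = FALSE]
  key <- paste(rows$accession, rows$position, rows$ptm_type, sep = "\r")
  first <- !duplicated(key)
  grp <- match(key, key[first])
  first_non_na <- function(x) {
    x <- x[!is.na(x)]
    if (length(x)) x[[1]] else NA_character_
  }
  sites <- data.frame(
    accession = rows$accession[first],
    position = rows$position[first],
    residue = vapply(split(rows$residue, grp), first_non_na, character(1)),
    ptm_type = rows$ptm_type[first],
    sources = vapply(split(rows$source, grp), join_multi, character(1)),
    pmids = vapply(split(rows$pmid, grp), join_multi, character(1)),
    stringsAsFactors = FALSE)
  o <- order(sites$accession, sites$position, sites$ptm_type)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  prov <- rows[order(rows$accession, rows$position, rows$ptm_type,
                     rows$source, rows$pmid), , drop = FALSE]
  rownames(prov) <- NULL
  rownames(sites) <- NULL
  list(sites = sites, provenance = prov)
}

#' Unify PTM catalogs onto a proteome
#'
#' Merges provenance-level site records from any number of catalogs into one
#' non-redundant site set keyed by (accession, position, ptm_type); the same
#' residue carrying two PTM types therefore yields two sites. Sources and
#' PMIDs are merged per key; individual provenance records are retained for
#' atlas export. Sites on accessions absent from the proteome, sites beyond
#' the protein length, and (when the proteome carries sequences) sites whose
#' stated residue conflicts with the sequence are dropped with logged counts.
#'
#' Unification is idempotent and order-independent: permuting the input
#' catalogs yields an identical unified set.
#'
#' @param catalogs a single provenance-level site data.frame or a list of
#'   them (as returned by [load_ptm_catalog()]).
#' @param proteome proteome data.frame (see [read_proteome()]).
#' @param residue_conflict `"drop"` (default) or `"keep"` for sites whose
#'   residue disagrees with the proteome sequence.
#' @return an object of class `"ptm_catalog"`: a list with `sites` (one row
#'   per unified site, `sources`/`pmids` ";"-merged), `provenance` (one row
#'   per retained source record), and `log` (drop counts).
#' @export
unify_catalogs <- function(catalogs, proteome,
                           residue_conflict = c("drop", "keep")) {
  residue_conflict <- match.arg(residue_conflict)
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  if (nrow(proteome) == 0) stop("proteome must be nonempty")
  rows <- do.call(rbind, lapply(catalogs, function(x) x[.SITE_COLS]))

  idx <- match(rows$accession, proteome$accession)
  unknown <- is.na(idx)
  n_unknown <- sum(unknown)
  rows <- rows[!unknown, , drop = FALSE]
  idx <- idx[!unknown]

  too_far <- rows$position > proteome$length[idx]
  n_range <- sum(too_far)
  rows <- rows[!too_far, , drop = FALSE]
  idx <- idx[!too_far]

  n_conflict <- 0L
  seqs <- proteome$sequence[idx]
  has_seq <- !is.na(seqs) & !is.na(rows$residue) & nzchar(rows$residue)
  if (any(has_seq)) {
    actual <- substring(seqs[has_seq], rows$position[has_seq],
                        rows$position[has_seq])
    conflict <- actual != rows$residue[has_seq]
    n_conflict <- sum(conflict)
    if (n_conflict > 0 && residue_conflict == "drop") {
      drop_idx <- which(has_seq)[conflict]
      rows <- rows[-drop_idx, , drop = FALSE]
    }
  }
  if (n_unknown + n_range + n_conflict > 0)
    message("unify_catalogs: dropped ", n_unknown, " site(s) on unknown accessions, ",
            n_range, " beyond protein length, ", n_conflict,
            " residue conflicts (", residue_conflict, ")")

  agg <- .aggregate_sites(rows)
  structure(list(sites = agg$sites, provenance = agg$provenance,
                 log = list(unknown_accession = n_unknown,
                            beyond_length = n_range,
                            residue_conflict = n_conflict,
                            residue_conflict_action = residue_conflict)),
            class = "ptm_catalog")
}

#' @export
print.ptm_catalog <- function(x, ...) {
  cat("PTM catalog:", nrow(x$sites), "unified sites on",
      length(unique(x$sites$accession)), "proteins;",
      nrow(x$provenance), "provenance records\n")
  invisible(x)
}

# Accept a ptm_catalog or a plain site data.frame everywhere downstream.
as_ptm_sites <- function(x) {
  if (inherits(x, "ptm_catalog")) x$sites
  else if (is.data.frame(x)) x
  else stop("expected a ptm_catalog or a site data.frame")
}

#' Build the non-redundant RBP set (RBP-ome)
#'
#' Takes the union of several accession lists. When a proteome is supplied,
#' accessions absent from it are retained in the set but flagged with a
#' warning (and returned in the `"missing"` attribute).
#'
#' @param lists list of character vectors of accessions.
#' @param proteome optional proteome data.frame for cross-checking.
#' @return sorted character vector of unique accessions.
#' @seealso [annotate_rbpome()] to set `is_rbp` flags on the proteome.
#' @export
build_rbpome <- function(lists, proteome = NULL) {
  if (is.character(lists)) lists <- list(lists)
  rbpome <- sort(unique(unlist(lists, use.names = FALSE)))
  rbpome <- rbpome[!is.na(rbpome) & nzchar(rbpome)]
  if (!is.null(proteome)) {
    missing <- setdiff(rbpome, proteome$accession)
    if (length(missing)) {
      warning(length(missing), " RBP accession(s) not in proteome: ",
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) ", ...", call. = FALSE)
      attr(rbpome, "missing") <- missing
    }
  }
  rbpome
}

#' Set `is_rbp` flags on a proteome from an RBP-ome
#' @param proteome proteome data.frame.
#' @param rbpome character vector of RBP accessions.
#' @return the proteome with `is_rbp` updated.
#' @export
annotate_rbpome <- function(proteome, rbpome) {
  proteome$is_rbp <- proteome$accession %in% rbpome
  proteome
}

.ATLAS_COLS <- c("uniprot_id", "gene_name", "position", "pmid", "source",
                 "amino_acid", "modification_type", "cell_line",
                 "sample_type", "body_site", "disease_state")

#' Export the PTM atlas as a flat table
#'
#' Writes the 11-column atlas: Uniprot ID, gene name, position, PMID, source,
#' amino acid, modification type, cell line, sample type, body site, and
#' disease state. In `"evidence"` mode (default) each (site x provenance
#' record) pair is one row, mirroring per-entry publication of every evidence
#' record; `"site"` mode writes one row per unified site with sources and
#' PMIDs ";"-collapsed. Missing context fields are written as `NA`.
#' `strict_header = TRUE` reproduces the published header verbatim
#' (`Ssource` instead of `source`).
#'
#' @param catalog a `"ptm_catalog"` from [unify_catalogs()].
#' @param proteome proteome data.frame (provides gene names).
#' @param path output TSV path.
#' @param mode `"evidence"` or `"site"`.
#' @param strict_header reproduce the published column spelling.
#' @return number of rows written.
#' @export
export_atlas <- function(catalog, proteome, path,
                         mode = c("evidence", "site"), strict_header = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(catalog, "ptm_catalog"))
  if (mode == "evidence") {
    rows <- catalog$provenance
    tab <- data.frame(uniprot_id = rows$accession,
                      gene_name = proteome$gene_name[match(rows$accession,
                                                           proteome$accession)],
                      position = rows$position,
                      pmid = rows$pmid,
                      source = rows$source,
                      amino_acid = rows$residue,
                      modification_type = rows$ptm_type,
                      cell_line = rows$cell_line,
                      sample_type = rows$sample_type,
                      body_site = rows$body_site,
                      disease_state = rows$disease_state,
                      stringsAsFactors = FALSE)
  } else {
    s <- catalog$sites
    tab <- data.frame(uniprot_id = s$accession,
                      gene_name = proteome$gene_name[match(s$accession,
                                                           proteome$accession)],
                      position = s$position,
                      pmid = s$pmids,
                      source = s$sources,
                      amino_acid = s$residue,
                      modification_type = s$ptm_type,
                      cell_line = NA_character_, sample_type = NA_character_,
                      body_site = NA_character_, disease_state = NA_character_,
                      stringsAsFactors = FALSE)
  }
  names(tab) <- .ATLAS_COLS
  if (strict_header) names(tab)[names(tab) == "source"] <- "Ssource"
  write_tsv(tab, path)
  nrow(tab)
}

#' Re-import an exported atlas
#'
#' Reads an atlas written by [export_atlas()] (evidence mode) back into a
#' `"ptm_catalog"`; export followed by import reproduces the unified site
#' set exactly.
#'
#' @param path atlas TSV path.
#' @return a `"ptm_catalog"`.
#' @export
import_atlas <- function(path) {
  tab <- read_tsv(path)
  names(tab)[names(tab) == "Ssource"] <- "source"
  miss <- setdiff(.ATLAS_COLS, names(tab))
  if (length(miss)) stop("atlas file missing columns: ",
                         paste(miss, collapse = ", "))
  rows <- data.frame(accession = as.character(tab$uniprot_id),
                     position = as.integer(tab$position),
                     residue = as.character(tab$amino_acid),
                     ptm_type = as.character(tab$modification_type),
                     source = as.character(tab$source),
                     pmid = as.character(tab$pmid),
                     cell_line = as.character(tab$cell_line),
                     sample_type = as.character(tab$sample_type),
                     body_site = as.character(tab$body_site),
                     disease_state = as.character(tab$disease_state),
                     stringsAsFactors = FALSE)
  agg <- .aggregate_sites(rows)
  structure(list(sites = agg$sites, provenance = agg$provenance,
                 log = list()), class = "ptm_catalog")
}
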