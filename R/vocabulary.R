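# Controlled vocabulary of PTM type labels, residue compatibility, and the
# synonym table used to normalize source-catalog labels.

#' Construct a PTM vocabulary
#'
#' A vocabulary pins down the canonical PTM type labels, the amino acids each
#' modification can occur on (optional), and a synonym table mapping the label
#' dialects of source catalogs to the canonical labels. Labels are matched
#' case-insensitively.
#'
#' @param labels character vector of canonical PTM type labels (unique).
#' @param residues optional named list (by label) of one-letter amino-acid
#'   vectors; a label absent from the list has unrestricted compatibility.
#' @param synonyms optional named character vector mapping
#'   `synonym -> canonical label`.
#' @return an object of class `"ptm_vocabulary"`.
#' @examples
#' v <- ptm_vocabulary(c("phosphorylation", "acetylation"),
#'                     residues = list(phosphorylation = c("S", "T", "Y")),
#'                     synonyms = c(phospho = "phosphorylation"))
#' normalize_ptm_label(v, c("Phospho", "acetylation", "unknown"))
#' @export
ptm_vocabulary <- function(labels, residues = NULL, synonyms = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(tolower(labels)))
    stop("vocabulary labels must be unique (case-insensitive)")
  if (!is.null(residues)) {
    bad <- setdiff(names(residues), labels)
    if (length(bad)) stop("residues given for unknown labels: ",
                          paste(bad, collapse = ", "))
    if (any(lengths(residues) == 0))
      stop("residue compatibility sets, when present, must be nonempty")
  }
  if (!is.null(synonyms)) {
    if (is.null(names(synonyms)) || any(!nzchar(names(synonyms))))
      stop("synonyms must be a named character vector (synonym -> canonical)")
    bad <- setdiff(unname(synonyms), labels)
    if (length(bad)) stop("synonyms target unknown labels: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(labels = labels,
                 residues = residues %||% list(),
                 synonyms = synonyms %||% character(0)),
            class = "ptm_vocabulary")
}

#' The vocabulary shipped with the package
#'
#' Loads the versioned normalization table under `extdata/ptm_vocabulary.tsv`:
#' 16 PTM classes with residue compatibility and common label synonyms.
#'
#' @return a `"ptm_vocabulary"` object.
#' @export
default_ptm_vocabulary <- function() {
  path <- system.file("extdata", "ptm_vocabulary.tsv", package = "rbptm",
                      mustWork = TRUE)
  tab <- read_tsv(path)
  residues <- lapply(tab$residues, split_multi)
  names(residues) <- tab$label
  residues <- residues[lengths(residues) > 0]
  syn_lists <- lapply(tab$synonyms, split_multi)
  synonyms <- stats::setNames(rep(tab$label, lengths(syn_lists)),
                              unlist(syn_lists))
  ptm_vocabulary(tab$label, residues = residues, synonyms = synonyms)
}

#' Normalize PTM type labels to the vocabulary
#'
#' Canonical labels pass through (case-insensitively); synonyms map to their
#' canonical label; anything else becomes `NA` (callers decide whether to
#' warn, drop, or error — labels never silently pass).
#'
#' @param vocabulary a `"ptm_vocabulary"`.
#' @param labels character vector of raw labels.
#' @return character vector of canonical labels with `NA` for unmappable ones.
#' @export
normalize_ptm_label <- function(vocabulary, labels) {
  stopifnot(inherits(vocabulary, "ptm_vocabulary"))
  low <- tolower(trimws(as.character(labels)))
  canon <- vocabulary$labels[match(low, tolower(vocabulary$labels))]
  syn_idx <- match(low, tolower(names(vocabulary$synonyms)))
  use_syn <- is.na(canon) & !is.na(syn_idx)
  canon[use_syn] <- unname(vocabulary$synonyms[syn_idx[use_syn]])
  canon
}

#' Residues compatible with a PTM type
#'
#' @param vocabulary a `"ptm_vocabulary"`.
#' @param label one canonical label.
#' @return character vector of one-letter codes, or `NULL` when the
#'   vocabulary places no restriction on the label.
#' @export
vocabulary_residues <- function(vocabulary, label) {
  stopifnot(inherits(vocabulary, "ptm_vocabulary"))
  if (!label %in% vocabulary$labels) stop("unknown PTM label: ", label)
  vocabulary$residues[[label]]
}

#' @export
print.ptm_vocabulary <- function(x, ...) {
  cat("PTM vocabulary:", length(x$labels), "types,",
      length(x$synonyms), "synonyms\n")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}
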