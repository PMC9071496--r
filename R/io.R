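# Readers and writers for the flat-file dialects the pipeline consumes:
# proteome tables, RBP lists, PPI edge lists, enzyme annotations, residue-level
# mutation tables, crosslink ranges, conservation tracks, narrowPeak and BED.

#' Read a proteome table
#'
#' Expects a TSV with columns `accession`, `gene_name`, `length`, and
#' optionally `sequence`, `is_rbp`, `family_tags` (";"-separated). Positions
#' throughout the package are 1-based indices into this canonical sequence.
#'
#' @param path file path.
#' @return data.frame with one row per protein.
#' @export
read_proteome <- function(path) {
  tab <- read_tsv(path)
  need <- c("accession", "gene_name", "length")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("proteome table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$accession))
    stop("duplicate accessions in proteome: ",
         paste(unique(tab$accession[duplicated(tab$accession)]), collapse = ", "))
  tab$length <- as.integer(tab$length)
  if (any(is.na(tab$length) | tab$length < 1))
    stop("proteome lengths must be positive integers")
  if (is.null(tab$sequence)) tab$sequence <- NA_character_
  seq_ok <- is.na(tab$sequence) | nchar(tab$sequence) == tab$length
  if (!all(seq_ok))
    stop("sequence length disagrees with declared length for: ",
         paste(tab$accession[!seq_ok], collapse = ", "))
  if (is.null(tab$is_rbp)) tab$is_rbp <- FALSE
  tab$is_rbp <- as.logical(tab$is_rbp)
  if (is.null(tab$family_tags)) tab$family_tags <- NA_character_
  tab[c("accession", "gene_name", "length", "sequence", "is_rbp", "family_tags")]
}

#' @rdname read_proteome
#' @param proteome a proteome data.frame.
#' @export
write_proteome <- function(proteome, path) write_tsv(proteome, path)

#' Read an RBP accession list (one accession per line)
#' @param path file path.
#' @return character vector of accessions.
#' @export
read_rbp_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a protein-protein interaction edge list
#'
#' Three-column TSV (`accession_a`, `accession_b`, `source`). Edges are
#' undirected; see [canonical_edges()] for deduplication.
#' @param path file path.
#' @return data.frame of edges.
#' @export
read_ppi_edges <- function(path) {
  tab <- read_tsv(path)
  need <- c("accession_a", "accession_b", "source")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("PPI edge table missing columns: ",
                         paste(miss, collapse = ", "))
  tab[need]
}

#' Read enzyme annotations (accession, ptm_type, role)
#'
#' `role` must be `writer` or `eraser`; duplicated (accession, ptm_type, role)
#' triples are collapsed.
#' @param path file path.
#' @param vocabulary optional `"ptm_vocabulary"` used to normalize `ptm_type`.
#' @return data.frame of annotations.
#' @export
read_enzyme_annotations <- function(path, vocabulary = NULL) {
  tab <- read_tsv(path)
  need <- c("accession", "ptm_type", "role")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("enzyme table missing columns: ",
                         paste(miss, collapse = ", "))
  bad <- !tab$role %in% c("writer", "eraser")
  if (any(bad)) stop("enzyme roles must be 'writer' or 'eraser'; offending rows: ",
                     paste(which(bad), collapse = ", "))
  if (!is.null(vocabulary)) {
    canon <- normalize_ptm_label(vocabulary, tab$ptm_type)
    if (anyNA(canon))
      stop("unmappable enzyme PTM labels: ",
           paste(unique(tab$ptm_type[is.na(canon)]), collapse = ", "))
    tab$ptm_type <- canon
  }
  unique(tab[need])
}

#' Read a residue-level mutation table
#'
#' Minimal MAF-like dialect: `accession`, `position` (1-based residue),
#' `ref_aa`, `alt_aa`, `consequence`, `cancer_type`, `case_count`. A
#' `mutation_id` column (row index) is attached so that deduplicated
#' mutation counts survive pairing with multiple PTM sites.
#' @param path file path.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  tab <- read_tsv(path)
  need <- c("accession", "position", "ref_aa", "alt_aa", "consequence",
            "cancer_type", "case_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("mutation table missing columns: ",
                         paste(miss, collapse = ", "))
  tab$position <- as.integer(tab$position)
  tab$case_count <- as.integer(tab$case_count)
  bad <- is.na(tab$position) | tab$position < 1 |
    is.na(tab$case_count) | tab$case_count < 1
  if (any(bad)) stop("invalid mutation rows (position/case_count): ",
                     paste(which(bad), collapse = ", "))
  tab <- tab[need]
  tab$mutation_id <- seq_len(nrow(tab))
  tab
}

#' Read reported crosslink residue ranges
#'
#' TSV with `accession`, `start`, `end` (1-based inclusive), `study`.
#' @param path file path.
#' @return data.frame of crosslink ranges.
#' @export
read_crosslinks <- function(path) {
  tab <- read_tsv(path)
  need <- c("accession", "start", "end", "study")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("crosslink table missing columns: ",
                         paste(miss, collapse = ", "))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  bad <- is.na(tab$start) | is.na(tab$end) | tab$start < 1 | tab$end < tab$start
  if (any(bad)) stop("invalid crosslink ranges at rows: ",
                     paste(which(bad), collapse = ", "))
  tab[need]
}

#' Read a per-residue conservation track
#'
#' TSV with `accession`, `position`, `score`; scores are conservation
#' probabilities in [0, 1] (nucleotide-level tracks are assumed collapsed to
#' residues upstream, e.g. by averaging a codon's scores).
#' @param path file path.
#' @return data.frame of per-residue scores.
#' @export
read_conservation <- function(path) {
  tab <- read_tsv(path)
  need <- c("accession", "position", "score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("conservation table missing columns: ",
                         paste(miss, collapse = ", "))
  tab$position <- as.integer(tab$position)
  tab$score <- as.numeric(tab$score)
  ok <- is.na(tab$score) | (tab$score >= 0 & tab$score <= 1)
  if (!all(ok)) stop("conservation scores outside [0, 1] at rows: ",
                     paste(which(!ok), collapse = ", "))
  tab[need]
}

#' Read an ENCODE-style narrowPeak file
#'
#' Ten-column BED6+4: chrom, start (0-based), end (half-open), name, score,
#' strand, signalValue, pValue, qValue, peak. Malformed lines are reported by
#' line number. The RBP name defaults to the peak-name prefix before the
#' first underscore.
#'
#' @param path file path.
#' @param rbp optional RBP name applied to all peaks; when `NULL`, parsed
#'   from the name column.
#' @return data.frame of peaks with an `rbp` column.
#' @export
read_narrowpeak <- function(path, rbp = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != 10L)
  if (length(bad))
    stop("malformed narrowPeak line(s) ", paste(bad, collapse = ", "),
         " in ", path, " (expected 10 tab-separated fields)")
  tab <- utils::read.table(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "signal_value",
                                         "p_value", "q_value", "peak"))
  bad <- which(!(tab$start < tab$end))
  if (length(bad)) stop("narrowPeak start >= end at line(s) ",
                        paste(bad, collapse = ", "))
  bad <- which(!tab$strand %in% c("+", "-"))
  if (length(bad)) stop("narrowPeak strand must be '+' or '-' at line(s) ",
                        paste(bad, collapse = ", "))
  tab$rbp <- if (is.null(rbp)) sub("_.*$", "", tab$name) else rbp
  tab
}

#' Read gene models from BED6 or GTF
#'
#' BED6 (`chrom`, `start`, `end`, `name`, `score`, `strand`; 0-based
#' half-open) is read directly; `.gtf`/`.gff` files are imported through
#' rtracklayer (gene features only) when that package is available.
#'
#' @param path file path.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open coordinates).
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GTF/GFF gene models requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- S4Vectors::mcols(gr)$gene_id %||% S4Vectors::mcols(gr)$ID
    return(data.frame(gene_id = as.character(ids),
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE))
  }
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nf < 6L)
  if (length(bad)) stop("BED gene model needs >= 6 fields; line(s) ",
                        paste(bad, collapse = ", "))
  tab <- utils::read.table(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)[, 1:6]
  names(tab) <- c("chrom", "start", "end", "gene_id", "score", "strand")
  bad <- which(!(tab$start < tab$end) | !tab$strand %in% c("+", "-"))
  if (length(bad)) stop("invalid BED gene interval at line(s) ",
                        paste(bad, collapse = ", "))
  tab[c("gene_id", "chrom", "start", "end", "strand")]
}
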