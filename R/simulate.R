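# Seeded synthetic-data generator. Produces complete input bundles with
# planted statistical structure (RBP modification enrichment, enzyme-substrate
# edges, mutation hotspots at PTM sites, distance-decaying PTM placement
# around crosslink centers, conservation shift at PTM sites) so that every
# pipeline stage can be exercised and calibrated without external downloads.

.AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
         "T","V","W","Y")

.sim_defaults <- function() {
  list(
    n_proteins = 2000L,
    rbp_fraction = 0.12,          # ~ share of SwissProt proteins that are RBPs
    length_meanlog = 6.0,         # log-normal protein lengths, median ~400 aa
    length_sdlog = 0.6,
    min_length = 50L,
    # per-residue site rates by PTM type; phosphorylation dominates, as in
    # curated catalogs
    ptm_base_rates = c(phosphorylation = 0.0030, acetylation = 0.0012,
                       ubiquitination = 0.0015, methylation = 0.0010,
                       sumoylation = 6e-4, oxidation = 4e-4),
    rbp_enrichment_factor = 5,    # planted per-residue rate multiplier in RBPs
    hnrnp_fraction = 0.10,        # share of RBPs tagged as hnRNP family
    n_enzymes_per_type = 3L,
    p_planted = 0.3,              # enzyme-substrate edge prob. when modified
    p_background = 0.02,          # enzyme edge prob. otherwise
    n_background_edges = 2000L,   # plain protein-protein edges
    hotspot_rate = 0.02,          # per-residue mutation prob. near PTM sites
    background_mutation_rate = 0.002,
    proximity_k = 10L,            # hotspot radius (residues)
    cancer_types = c("BRCA", "UCEC", "LUAD", "COAD", "SKCM", "STAD"),
    case_count_geom = 0.5,        # case count ~ 1 + Geom(p)
    crosslinks_per_rbp = 2,       # Poisson mean of ranges per RBP
    crosslink_len_meanlog = log(18),
    crosslink_len_sdlog = 0.5,
    n_interface_sites = 5000L,    # PTM sites placed by the crosslink study
    interface_decay = 0.7,        # geometric success prob. of |offset| draws
    interface_uniform_share = 0.2,# share of interface sites placed uniformly
    conservation_delta = 0.2,     # additive conservation shift at PTM sites
    cons_beta_shape1 = 2,
    cons_beta_shape2 = 3,
    n_genes = 60L,                # eCLIP fixture: toy gene models
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    eclip_rbps = c("RBPA", "RBPB", "RBPC", "RBPD"),
    peaks_per_rbp = 150L,         # per replicate
    eclip_in_gene_prob = 0.6,     # peak planted inside a gene, same strand
    seed = 1L
  )
}

#' Create a validated simulation specification
#'
#' Parameters of the synthetic-data generator, with defaults sized so a full
#' bundle generates in well under a minute: ~2,000 proteins with log-normal
#' lengths (median ~400 residues), 12% RBPs, planted 5x per-residue PTM rate
#' enrichment in RBPs, enzyme-substrate edges at 0.3 vs 0.02 background,
#' 10x mutation hotspots within 10 residues of PTM sites, geometric
#' (decay 0.7) PTM placement around crosslink window centers, a +0.2
#' conservation shift at PTM sites over Beta(2,3) background noise, and a
#' two-chromosome eCLIP fixture.
#'
#' @param ... named overrides of the defaults (unknown keys are an error).
#' @return a list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(...) {
  over <- list(...)
  spec <- .sim_defaults()
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all overrides must be named")
    unknown <- setdiff(names(over), names(spec))
    if (length(unknown))
      stop("unknown simulation_spec fields: ", paste(unknown, collapse = ", "))
    spec[names(over)] <- over
  }
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(spec$n_proteins >= 1, "n_proteins must be >= 1")
  chk(spec$rbp_fraction >= 0 && spec$rbp_fraction <= 1,
      "rbp_fraction must be in [0, 1]")
  chk(all(spec$ptm_base_rates >= 0), "ptm_base_rates must be >= 0")
  chk(spec$rbp_enrichment_factor >= 1, "rbp_enrichment_factor must be >= 1")
  chk(spec$p_planted >= spec$p_background,
      "p_planted must be >= p_background")
  chk(spec$p_planted >= 0 && spec$p_planted <= 1 &&
        spec$p_background >= 0 && spec$p_background <= 1,
      "edge probabilities must be in [0, 1]")
  chk(spec$hotspot_rate >= 0 && spec$background_mutation_rate >= 0,
      "mutation rates must be >= 0")
  chk(spec$interface_decay > 0 && spec$interface_decay <= 1,
      "interface_decay must be in (0, 1]")
  chk(spec$interface_uniform_share >= 0 && spec$interface_uniform_share <= 1,
      "interface_uniform_share must be in [0, 1]")
  chk(spec$conservation_delta >= 0, "conservation_delta must be >= 0")
  if (length(problems))
    stop("invalid simulation spec:\n  - ",
         paste(problems, collapse = "\n  - "))
  spec$n_proteins <- as.integer(spec$n_proteins)
  spec$seed <- as.integer(spec$seed)
  structure(spec, class = "simulation_spec")
}

#' Generate a synthetic proteome
#'
#' Lengths are log-normal (floored at `min_length`); each protein is flagged
#' as an RBP with probability `rbp_fraction`, and a `hnrnp_fraction` share of
#' RBPs is tagged "hnRNP". Deterministic per spec seed.
#'
#' @param spec a [simulation_spec()].
#' @return proteome data.frame.
#' @export
generate_proteome <- function(spec = simulation_spec()) {
  with_seed(derive_seed(spec$seed, "proteome"), {
    n <- spec$n_proteins
    len <- pmax(spec$min_length,
                as.integer(round(stats::rlnorm(n, spec$length_meanlog,
                                               spec$length_sdlog))))
    is_rbp <- stats::runif(n) < spec$rbp_fraction
    tags <- rep(NA_character_, n)
    tags[is_rbp & stats::runif(n) < spec$hnrnp_fraction] <- "hnRNP"
    data.frame(accession = sprintf("P%05d", seq_len(n)),
               gene_name = sprintf("GENE%05d", seq_len(n)),
               length = len,
               sequence = NA_character_,
               is_rbp = is_rbp,
               family_tags = tags,
               stringsAsFactors = FALSE)
  })
}

# Context fields attached to generated site records.
.sim_context <- function(n) {
  list(cell_line = sample(c("HeLa", "K562", "HEK293", NA), n, replace = TRUE),
       sample_type = sample(c("cell line", "tissue", NA), n, replace = TRUE),
       body_site = sample(c(NA_character_, "blood", "liver"), n,
                          replace = TRUE, prob = c(0.7, 0.15, 0.15)),
       disease_state = sample(c("none", "cancer", NA), n, replace = TRUE))
}

#' Generate a synthetic PTM site catalog
#'
#' Per protein and PTM type, the site count is Poisson with rate
#' `base rate x length x enrichment factor` (the factor applies to RBPs
#' only); positions are uniform without replacement within each (protein,
#' type), and residues are drawn from the vocabulary's compatibility set.
#'
#' @param proteome proteome data.frame.
#' @param spec a [simulation_spec()].
#' @param enrichment_factor override of `spec$rbp_enrichment_factor`
#'   (1 gives the null with no planted RBP enrichment).
#' @param vocabulary residue-compatibility source.
#' @param seed_key sub-seed label, so repeated catalogs can be drawn from
#'   one spec (e.g. `seed_key = paste0("catalog", r)` for replicates).
#' @return provenance-level site data.frame (source `"synthetic"`).
#' @export
generate_ptm_catalog <- function(proteome, spec = simulation_spec(),
                                 enrichment_factor = NULL,
                                 vocabulary = default_ptm_vocabulary(),
                                 seed_key = "catalog") {
  fac <- enrichment_factor %||% spec$rbp_enrichment_factor
  rates <- spec$ptm_base_rates
  with_seed(derive_seed(spec$seed, seed_key), {
    n <- nrow(proteome)
    mult <- ifelse(proteome$is_rbp, fac, 1)
    acc_l <- list(); pos_l <- list(); res_l <- list(); type_l <- list()
    for (t in names(rates)) {
      if (rates[[t]] <= 0) next
      lam <- rates[[t]] * proteome$length * mult
      cnt <- stats::rpois(n, lam)
      over <- cnt > proteome$length
      if (any(over))
        stop("site rate exhausts positions for ",
             paste(proteome$accession[over][1], collapse = ", "),
             " (type ", t, ")")
      idx <- which(cnt > 0)
      if (length(idx) == 0) next
      pos <- unlist(lapply(idx, function(i)
        sample.int(proteome$length[i], cnt[i])), use.names = FALSE)
      compat <- vocabulary_residues(vocabulary, t) %||% .AA
      acc_l[[t]] <- rep(proteome$accession[idx], cnt[idx])
      pos_l[[t]] <- pos
      res_l[[t]] <- sample(compat, sum(cnt), replace = TRUE)
      type_l[[t]] <- rep(t, sum(cnt))
    }
    m <- length(unlist(acc_l, use.names = FALSE))
    ctx <- .sim_context(m)
    data.frame(accession = unlist(acc_l, use.names = FALSE) %||% character(0),
               position = as.integer(unlist(pos_l, use.names = FALSE)),
               residue = unlist(res_l, use.names = FALSE) %||% character(0),
               ptm_type = unlist(type_l, use.names = FALSE) %||% character(0),
               source = rep("synthetic", m),
               pmid = sprintf("PMID%06d", sample.int(999999L, m, replace = TRUE)),
               cell_line = ctx$cell_line,
               sample_type = ctx$sample_type,
               body_site = ctx$body_site,
               disease_state = ctx$disease_state,
               stringsAsFactors = FALSE)
  })
}

#' Generate enzyme annotations and a PPI edge list
#'
#' Creates `n_enzymes_per_type` enzymes for each PTM type in the spec's rate
#' table, alternating writer/eraser roles; an enzyme-protein edge is drawn
#' with probability `p_planted` when the protein carries that type, else
#' `p_background`, and `n_background_edges` plain protein-protein edges are
#' added. Enzyme accessions (`ENZ_<type>_<i>`) live outside the proteome.
#'
#' @param proteome proteome data.frame.
#' @param sites site data.frame (which proteins carry which types).
#' @param spec a [simulation_spec()].
#' @return list with `edges` (canonical) and `enzymes`.
#' @export
generate_interactions <- function(proteome, sites,
                                  spec = simulation_spec()) {
  sites <- as_ptm_sites(sites)
  with_seed(derive_seed(spec$seed, "interactions"), {
    types <- names(spec$ptm_base_rates)
    enz <- do.call(rbind, lapply(types, function(t) {
      k <- spec$n_enzymes_per_type
      data.frame(accession = sprintf("ENZ_%s_%02d",
                                     gsub("[^a-z0-9]+", "_", t), seq_len(k)),
                 ptm_type = t,
                 role = rep(c("writer", "eraser"), length.out = k),
                 stringsAsFactors = FALSE)
    }))
    edge_a <- list(); edge_b <- list()
    for (i in seq_len(nrow(enz))) {
      carries <- proteome$accession %in%
        sites$accession[sites$ptm_type == enz$ptm_type[i]]
      p <- ifelse(carries, spec$p_planted, spec$p_background)
      sel <- stats::runif(nrow(proteome)) < p
      if (any(sel)) {
        edge_a[[i]] <- rep(enz$accession[i], sum(sel))
        edge_b[[i]] <- proteome$accession[sel]
      }
    }
    nb <- spec$n_background_edges
    if (nb > 0 && nrow(proteome) >= 2) {
      i <- sample.int(nrow(proteome), nb, replace = TRUE)
      j <- sample.int(nrow(proteome), nb, replace = TRUE)
      keep <- i != j
      edge_a <- c(edge_a, list(proteome$accession[i[keep]]))
      edge_b <- c(edge_b, list(proteome$accession[j[keep]]))
    }
    ea <- unlist(edge_a, use.names = FALSE) %||% character(0)
    eb <- unlist(edge_b, use.names = FALSE) %||% character(0)
    edges <- data.frame(accession_a = ea, accession_b = eb,
                        source = rep("synthetic_ppi", length(ea)),
                        stringsAsFactors = FALSE)
    list(edges = canonical_edges(edges), enzymes = enz)
  })
}

#' Generate cancer mutation records with PTM-site hotspots
#'
#' Per residue, a mutation is drawn at `hotspot_rate` when the residue lies
#' within `proximity_k` of a PTM site and at `background_mutation_rate`
#' otherwise; cancer types are categorical and case counts
#' `1 + Geometric(case_count_geom)`.
#'
#' @param proteome proteome data.frame.
#' @param sites site data.frame.
#' @param spec a [simulation_spec()].
#' @return mutation data.frame (with `mutation_id`).
#' @export
generate_mutations <- function(proteome, sites, spec = simulation_spec()) {
  sites <- as_ptm_sites(sites)
  with_seed(derive_seed(spec$seed, "mutations"), {
    pos_split <- split(sites$position, sites$accession)
    k <- spec$proximity_k
    out_acc <- list(); out_pos <- list()
    for (i in seq_len(nrow(proteome))) {
      L <- proteome$length[i]
      sp <- pos_split[[proteome$accession[i]]]
      hot <- logical(L)
      for (p in unique(sp)) hot[max(1L, p - k):min(L, p + k)] <- TRUE
      rate <- ifelse(hot, spec$hotspot_rate, spec$background_mutation_rate)
      mut <- which(stats::runif(L) < rate)
      if (length(mut)) {
        out_acc[[i]] <- rep(proteome$accession[i], length(mut))
        out_pos[[i]] <- mut
      }
    }
    acc <- unlist(out_acc, use.names = FALSE) %||% character(0)
    pos <- as.integer(unlist(out_pos, use.names = FALSE))
    m <- length(acc)
    ref <- sample(.AA, m, replace = TRUE)
    alt <- sample(.AA, m, replace = TRUE)
    same <- ref == alt
    alt[same] <- .AA[(match(alt[same], .AA) %% length(.AA)) + 1L]
    data.frame(accession = acc, position = pos, ref_aa = ref, alt_aa = alt,
               consequence = "missense_variant",
               cancer_type = sample(spec$cancer_types, m, replace = TRUE),
               case_count = 1L + stats::rgeom(m, spec$case_count_geom),
               mutation_id = seq_len(m),
               stringsAsFactors = FALSE)
  })
}

#' Generate a crosslink study with distance-decaying PTM placement
#'
#' Places crosslink ranges on RBPs (Poisson count per RBP, log-normal
#' lengths) and generates `n_interface_sites` PTM site records: a
#' `1 - interface_uniform_share` share is placed at signed offsets from
#' standardized window centers, with |offset| geometric with success
#' probability `interface_decay` — P(|offset| = d) = decay * (1 - decay)^d,
#' so `interface_decay = 1` degenerately places every decayed site at the
#' center — and the rest placed uniformly over the protein. Offsets landing
#' outside the protein are redrawn (up to 100 attempts, then skipped with a
#' message).
#'
#' @param proteome proteome data.frame.
#' @param spec a [simulation_spec()].
#' @param w window width used for center placement (default 21).
#' @return list with `crosslinks` and `sites` (source
#'   `"synthetic_interface"`).
#' @export
generate_crosslink_study <- function(proteome, spec = simulation_spec(),
                                     w = 21L) {
  with_seed(derive_seed(spec$seed, "crosslinks"), {
    rbps <- proteome[proteome$is_rbp, , drop = FALSE]
    if (nrow(rbps) == 0) stop("proteome contains no RBPs to place ranges on")
    n_r <- stats::rpois(nrow(rbps), spec$crosslinks_per_rbp)
    acc <- rep(rbps$accession, n_r)
    L <- rep(rbps$length, n_r)
    len <- pmin(pmax(3L, as.integer(round(
      stats::rlnorm(length(acc), spec$crosslink_len_meanlog,
                    spec$crosslink_len_sdlog)))), L)
    start <- 1L + as.integer(floor(stats::runif(length(acc)) * (L - len + 1)))
    crosslinks <- data.frame(accession = acc, start = start,
                             end = start + len - 1L,
                             study = sample(paste0("study", 1:4),
                                            length(acc), replace = TRUE),
                             stringsAsFactors = FALSE)
    windows <- standardize_windows(crosslinks, proteome, w)

    n_s <- spec$n_interface_sites
    widx <- sample.int(nrow(windows), n_s, replace = TRUE)
    Lw <- proteome$length[match(windows$accession[widx], proteome$accession)]
    decayed <- stats::runif(n_s) >= spec$interface_uniform_share
    pos <- integer(n_s)
    pos[!decayed] <- 1L + as.integer(floor(stats::runif(sum(!decayed)) *
                                             Lw[!decayed]))
    todo <- which(decayed)
    attempts <- 0L
    while (length(todo) > 0 && attempts < 100L) {
      d <- stats::rgeom(length(todo), spec$interface_decay)
      sgn <- sample(c(-1L, 1L), length(todo), replace = TRUE)
      cand <- windows$center[widx[todo]] + sgn * d
      ok <- cand >= 1L & cand <= Lw[todo]
      pos[todo[ok]] <- as.integer(cand[ok])
      todo <- todo[!ok]
      attempts <- attempts + 1L
    }
    if (length(todo) > 0) {
      message("generate_crosslink_study: skipped ", length(todo),
              " site(s) after 100 placement attempts")
      keep <- setdiff(seq_len(n_s), todo)
    } else keep <- seq_len(n_s)

    types <- sample(names(spec$ptm_base_rates), n_s, replace = TRUE,
                    prob = spec$ptm_base_rates)
    vocab <- default_ptm_vocabulary()
    res <- vapply(types, function(t) {
      compat <- vocab$residues[[t]] %||% .AA
      sample(compat, 1)
    }, character(1))
    ctx <- .sim_context(length(keep))
    sites <- data.frame(accession = windows$accession[widx[keep]],
                        position = pos[keep],
                        residue = unname(res[keep]),
                        ptm_type = types[keep],
                        source = "synthetic_interface",
                        pmid = sprintf("PMID%06d",
                                       sample.int(999999L, length(keep),
                                                  replace = TRUE)),
                        cell_line = ctx$cell_line,
                        sample_type = ctx$sample_type,
                        body_site = ctx$body_site,
                        disease_state = ctx$disease_state,
                        stringsAsFactors = FALSE)
    list(crosslinks = crosslinks, sites = sites)
  })
}

#' Generate per-residue conservation profiles with a shift at PTM sites
#'
#' Background residue scores are Beta(`cons_beta_shape1`,
#' `cons_beta_shape2`); scores at PTM positions get `conservation_delta`
#' added (clipped to 1). Profiles are generated for the given accessions
#' (by default the RBPs, the group the conservation contrast targets).
#'
#' @param proteome proteome data.frame.
#' @param sites site data.frame.
#' @param spec a [simulation_spec()].
#' @param accessions accessions to profile; default all RBPs.
#' @return conservation data.frame (`accession`, `position`, `score`).
#' @export
generate_conservation <- function(proteome, sites, spec = simulation_spec(),
                                  accessions = NULL) {
  sites <- as_ptm_sites(sites)
  if (is.null(accessions))
    accessions <- proteome$accession[proteome$is_rbp]
  sub <- proteome[proteome$accession %in% accessions, , drop = FALSE]
  with_seed(derive_seed(spec$seed, "conservation"), {
    pos_split <- split(sites$position, sites$accession)
    out <- vector("list", nrow(sub))
    for (i in seq_len(nrow(sub))) {
      L <- sub$length[i]
      sc <- stats::rbeta(L, spec$cons_beta_shape1, spec$cons_beta_shape2)
      sp <- unique(pos_split[[sub$accession[i]]])
      sp <- sp[sp <= L]
      if (length(sp))
        sc[sp] <- pmin(1, stats::rbeta(length(sp), spec$cons_beta_shape1,
                                       spec$cons_beta_shape2) +
                         spec$conservation_delta)
      out[[i]] <- data.frame(accession = sub$accession[i],
                             position = seq_len(L), score = sc,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Generate the eCLIP fixture (gene models and two peak replicates)
#'
#' Toy chromosomes carry `n_genes` stranded gene models; for each RBP and
#' replicate, `peaks_per_rbp` peaks are drawn, each placed fully inside a
#' random gene on the gene's strand with probability `eclip_in_gene_prob`
#' and uniformly at random otherwise.
#'
#' @param spec a [simulation_spec()].
#' @return list with `genes`, `rep1`, `rep2` data.frames.
#' @export
generate_eclip <- function(spec = simulation_spec()) {
  with_seed(derive_seed(spec$seed, "eclip"), {
    chroms <- names(spec$chrom_lengths)
    ng <- spec$n_genes
    g_chrom <- sample(chroms, ng, replace = TRUE)
    g_len <- sample(2000:20000, ng, replace = TRUE)
    g_start <- vapply(seq_len(ng), function(i)
      sample.int(spec$chrom_lengths[[g_chrom[i]]] - g_len[i], 1), integer(1))
    genes <- data.frame(gene_id = sprintf("GENE%03d", seq_len(ng)),
                        chrom = g_chrom,
                        start = g_start, end = g_start + g_len,
                        strand = sample(c("+", "-"), ng, replace = TRUE),
                        stringsAsFactors = FALSE)
    one_rep <- function(rep_id) {
      rows <- list()
      for (rbp in spec$eclip_rbps) {
        np <- spec$peaks_per_rbp
        plen <- sample(50:400, np, replace = TRUE)
        in_gene <- stats::runif(np) < spec$eclip_in_gene_prob
        chrom <- character(np); start <- integer(np); strand <- character(np)
        gi <- sample.int(ng, np, replace = TRUE)
        for (j in seq_len(np)) {
          if (in_gene[j]) {
            g <- genes[gi[j], ]
            plen[j] <- min(plen[j], g$end - g$start)
            chrom[j] <- g$chrom
            start[j] <- g$start +
              sample.int(g$end - g$start - plen[j] + 1L, 1) - 1L
            strand[j] <- g$strand
          } else {
            chrom[j] <- sample(chroms, 1)
            start[j] <- sample.int(spec$chrom_lengths[[chrom[j]]] - plen[j], 1)
            strand[j] <- sample(c("+", "-"), 1)
          }
        }
        rows[[rbp]] <- data.frame(
          chrom = chrom, start = start, end = start + plen,
          name = sprintf("%s_rep%d_peak%d", rbp, rep_id, seq_len(np)),
          score = sample(100:1000, np, replace = TRUE),
          strand = strand,
          signal_value = round(stats::runif(np, 1, 10), 3),
          p_value = round(stats::runif(np, 2, 10), 3),
          q_value = round(stats::runif(np, 2, 10), 3),
          peak = as.integer(plen / 2),
          rbp = rbp,
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }
    list(genes = genes, rep1 = one_rep(1L), rep2 = one_rep(2L))
  })
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes and writes it in the exact
#' dialect each reader expects: proteome TSV, two overlapping PTM catalogs
#' plus the crosslink-study catalog, three overlapping RBP lists, PPI edge
#' list, enzyme annotations, mutations, crosslink ranges, conservation
#' track, gene BED and two narrowPeak replicates — plus `manifest.json`
#' with the spec, seed, and per-file MD5 checksums. Identical (spec, seed)
#' give identical checksums.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing nonempty directory.
#' @return the manifest list, invisibly.
#' @export
make_bundle <- function(spec = simulation_spec(), out_dir,
                        overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir,
         " exists and is not empty (use overwrite = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  proteome <- generate_proteome(spec)
  catalog <- generate_ptm_catalog(proteome, spec)
  study <- generate_crosslink_study(proteome, spec)
  all_sites <- rbind(catalog, study$sites)
  inter <- generate_interactions(proteome, catalog, spec)
  mutations <- generate_mutations(proteome, catalog, spec)
  conservation <- generate_conservation(proteome, all_sites, spec)
  eclip <- generate_eclip(spec)

  write_proteome(proteome, path("proteome.tsv"))

  # split the catalog into two overlapping source files to exercise
  # harmonization (10% of rows appear in both)
  with_seed(derive_seed(spec$seed, "bundle_split"), {
    in_a <- stats::runif(nrow(catalog)) < 0.5
    dup <- stats::runif(nrow(catalog)) < 0.1
    cat_a <- catalog[in_a | dup, , drop = FALSE]
    cat_b <- catalog[!in_a | dup, , drop = FALSE]
    cat_a$source <- "catalog_a"; cat_b$source <- "catalog_b"
    cat_a$evidence <- "experimental"; cat_b$evidence <- "experimental"
    write_tsv(cat_a, path("catalog_a.tsv"))
    write_tsv(cat_b, path("catalog_b.tsv"))
    ci <- study$sites
    ci$evidence <- "experimental"
    write_tsv(ci, path("catalog_interface.tsv"))

    rbps <- proteome$accession[proteome$is_rbp]
    l1 <- sort(sample(rbps, ceiling(0.6 * length(rbps))))
    l2 <- sort(sample(rbps, ceiling(0.6 * length(rbps))))
    l3 <- sort(sample(rbps, ceiling(0.6 * length(rbps))))
    l1 <- sort(union(l1, setdiff(rbps, union(l2, l3))))
    writeLines(l1, path("rbp_list_1.txt"))
    writeLines(l2, path("rbp_list_2.txt"))
    writeLines(l3, path("rbp_list_3.txt"))
  })

  write_tsv(inter$edges, path("ppi_edges.tsv"))
  write_tsv(inter$enzymes, path("enzyme_annotations.tsv"))
  write_tsv(mutations[setdiff(names(mutations), "mutation_id")],
            path("mutations.tsv"))
  write_tsv(study$crosslinks, path("crosslinks.tsv"))
  write_tsv(conservation, path("conservation.tsv"))

  bed <- eclip$genes[c("chrom", "start", "end", "gene_id", "strand")]
  bed$score <- 0L
  utils::write.table(bed[c("chrom", "start", "end", "gene_id", "score",
                           "strand")],
                     path("genes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  np_cols <- c("chrom", "start", "end", "name", "score", "strand",
               "signal_value", "p_value", "q_value", "peak")
  utils::write.table(eclip$rep1[np_cols], path("eclip_rep1.narrowPeak"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(eclip$rep2[np_cols], path("eclip_rep2.narrowPeak"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  files <- c("proteome.tsv", "catalog_a.tsv", "catalog_b.tsv",
             "catalog_interface.tsv", "rbp_list_1.txt", "rbp_list_2.txt",
             "rbp_list_3.txt", "ppi_edges.tsv", "enzyme_annotations.tsv",
             "mutations.tsv", "crosslinks.tsv", "conservation.tsv",
             "genes.bed", "eclip_rep1.narrowPeak", "eclip_rep2.narrowPeak")
  sums <- tools::md5sum(vapply(files, path, character(1)))
  manifest <- list(generator = "rbptm",
                   seed = spec$seed,
                   spec = unclass(spec),
                   files = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
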