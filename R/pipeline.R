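# End-to-end orchestration: run every analysis stage over a bundle directory,
# write tidy TSV reports, and persist a deterministic run manifest.

.PIPELINE_STAGES <- c("harmonize", "landscape", "conservation", "enzymes",
                      "mutations", "interface", "eclip", "export")

#' Run the full analysis pipeline over an input bundle
#'
#' Executes the stages in order — harmonize, landscape, conservation,
#' enzymes, mutations, interface, eclip, export — reading the bundle's
#' conventionally named inputs (as written by [make_bundle()]) and writing
#' one or more TSV reports per stage plus `run_manifest.json` (config
#' snapshot, input checksums, per-stage status and outputs). Stages whose
#' inputs are missing are skipped; a stage failure is recorded in the
#' manifest and later stages still run where their inputs allow. Given the
#' same inputs and `config$seed`, reruns are byte-identical.
#'
#' @param bundle_dir directory with the input files.
#' @param out_dir report directory (created if needed).
#' @param config an [analysis_config()].
#' @param stages subset of stages to run (order is fixed); the default runs
#'   all eight.
#' @return the run manifest list, invisibly. Attribute `"ok"` is `TRUE` iff
#'   no requested stage failed.
#' @export
run_pipeline <- function(bundle_dir, out_dir, config = analysis_config(),
                         stages = .PIPELINE_STAGES) {
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- function(f) file.path(bundle_dir, f)
  outp <- function(f) file.path(out_dir, f)

  state <- new.env(parent = emptyenv())
  manifest <- list(tool = "rbptm",
                   version = as.character(utils::packageVersion("rbptm")),
                   seed = config$seed,
                   config = unclass(config),
                   inputs = list(), stages = list())
  present <- list.files(bundle_dir)
  for (f in sort(present)) {
    p <- inp(f)
    if (!dir.exists(p))
      manifest$inputs[[f]] <- unname(tools::md5sum(p))
  }

  run_stage <- function(name, needs, fun) {
    if (!name %in% stages) return()
    missing_in <- needs[!file.exists(vapply(needs, inp, character(1)))]
    rec <- list(stage = name, status = "completed", outputs = character(0))
    if (length(missing_in)) {
      rec$status <- "skipped"
      rec$reason <- paste("missing input:", paste(missing_in, collapse = ", "))
      message("stage ", name, " skipped (", rec$reason, ")")
    } else {
      res <- tryCatch({
        rec$outputs <- fun()
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) {
        rec$status <- "failed"
        rec$reason <- res
        message("stage ", name, " failed: ", res)
      }
    }
    manifest$stages[[name]] <<- rec
  }

  run_stage("harmonize",
            c("proteome.tsv", "catalog_a.tsv"), function() {
    state$proteome <- read_proteome(inp("proteome.tsv"))
    cat_files <- sort(list.files(bundle_dir, pattern = "^catalog.*\\.tsv$"))
    catalogs <- lapply(cat_files, function(f)
      load_ptm_catalog(inp(f), dialect = "generic",
                       source_name = sub("\\.tsv$", "", f)))
    state$catalog <- unify_catalogs(catalogs, state$proteome,
                                    residue_conflict = config$residue_conflict)
    rbp_files <- sort(list.files(bundle_dir, pattern = "^rbp_list.*\\.txt$"))
    state$rbpome <- if (length(rbp_files))
      build_rbpome(lapply(rbp_files, function(f) read_rbp_list(inp(f))),
                   state$proteome)
    else state$proteome$accession[state$proteome$is_rbp]
    state$proteome <- annotate_rbpome(state$proteome, state$rbpome)
    write_tsv(state$catalog$sites, outp("unified_sites.tsv"))
    write_proteome(state$proteome, outp("proteome_annotated.tsv"))
    c("unified_sites.tsv", "proteome_annotated.tsv")
  })

  run_stage("landscape", character(0), function() {
    if (is.null(state$catalog)) stop("harmonize stage has not run")
    sites <- state$catalog
    profiles <- type_count_profiles(sites, state$proteome)
    write_tsv(profiles, outp("type_profiles.tsv"))
    dens <- modification_density(sites, state$proteome)
    write_tsv(dens, outp("densities.tsv"))
    cmp <- density_group_comparison(dens)
    write_tsv(as.data.frame(cmp), outp("density_comparison.tsv"))
    enr <- ptm_enrichment_tests(sites, state$rbpome, state$proteome, config)
    write_tsv(enr, outp("enrichment.tsv"))
    types <- sort(unique(sites$sites$ptm_type))
    msf <- data.frame(ptm_type = types,
                      multi_site_fraction =
                        vapply(types, function(t)
                          multi_site_fraction(sites, t), numeric(1)))
    write_tsv(msf, outp("multi_site_fractions.tsv"))
    combos <- top_type_combinations(sites)
    write_tsv(combos, outp("type_combinations.tsv"))
    top5 <- names(sort(table(sites$sites$ptm_type), decreasing = TRUE))
    top5 <- utils::head(top5, 5)
    cdfs <- do.call(rbind, lapply(top5, function(t) {
      x <- site_count_cdf(sites, t); x$ptm_type <- t; x
    }))
    write_tsv(cdfs, outp("site_count_cdf.tsv"))
    c("type_profiles.tsv", "densities.tsv", "density_comparison.tsv",
      "enrichment.tsv", "multi_site_fractions.tsv", "type_combinations.tsv",
      "site_count_cdf.tsv")
  })

  run_stage("conservation", "conservation.tsv", function() {
    if (is.null(state$catalog)) stop("harmonize stage has not run")
    cons <- read_conservation(inp("conservation.tsv"))
    contrasts <- conservation_contrasts(cons, state$catalog, config,
                                        accessions = state$rbpome)
    write_tsv(contrasts, outp("conservation_contrasts.tsv"))
    summ <- cohort_summary(contrasts, config)
    write_tsv(as.data.frame(summ), outp("conservation_summary.tsv"))
    c("conservation_contrasts.tsv", "conservation_summary.tsv")
  })

  run_stage("enzymes", c("ppi_edges.tsv", "enzyme_annotations.tsv"),
            function() {
    if (is.null(state$catalog)) stop("harmonize stage has not run")
    edges <- read_ppi_edges(inp("ppi_edges.tsv"))
    enzymes <- read_enzyme_annotations(inp("enzyme_annotations.tsv"))
    state$edges <- edges; state$enzymes <- enzymes
    rbps <- intersect(state$rbpome, state$proteome$accession)
    mat <- me_matrix(rbps, state$catalog, edges, enzymes, config)
    mat_df <- data.frame(accession = rownames(mat), mat, check.names = FALSE,
                         stringsAsFactors = FALSE)
    write_tsv(mat_df, outp("me_matrix.tsv"))
    cmi <- count_modifying_interactions(state$catalog, edges, enzymes,
                                        rbps, config)
    write_tsv(cmi, outp("modifying_interactions.tsv"))
    rpe <- rbp_count_per_enzyme(state$catalog, edges, enzymes, rbps, config)
    write_tsv(rpe, outp("rbp_per_enzyme.tsv"))
    c("me_matrix.tsv", "modifying_interactions.tsv", "rbp_per_enzyme.tsv")
  })

  run_stage("mutations", "mutations.tsv", function() {
    if (is.null(state$catalog)) stop("harmonize stage has not run")
    muts <- read_mutations(inp("mutations.tsv"))
    at <- mutations_at_sites(muts, state$catalog)
    near <- mutations_near_sites(muts, state$catalog, k = config$proximity_k)
    write_tsv(at, outp("mutation_hits_at_sites.tsv"))
    write_tsv(near, outp("mutation_hits_near_sites.tsv"))
    counts <- data.frame(
      measure = c("at_site_pairs", "at_site_unique_mutations",
                  "at_site_unique_proteins", "near_site_pairs",
                  "near_site_unique_mutations", "near_site_unique_proteins"),
      value = c(nrow(at), attr(at, "n_unique_mutations"),
                attr(at, "n_unique_proteins"), nrow(near),
                attr(near, "n_unique_mutations"),
                attr(near, "n_unique_proteins")))
    write_tsv(counts, outp("mutation_counts.tsv"))
    ranked <- rank_site_mutations(at)
    write_tsv(ranked, outp("ranked_site_mutations.tsv"))
    outs <- c("mutation_hits_at_sites.tsv", "mutation_hits_near_sites.tsv",
              "mutation_counts.tsv", "ranked_site_mutations.tsv")
    if (nrow(ranked) > 0) {
      top_acc <- ranked$accession[1]
      L <- state$proteome$length[state$proteome$accession == top_acc]
      track <- per_position_mutation_track(muts, top_acc, L)
      write_tsv(data.frame(accession = top_acc,
                           position = seq_along(track),
                           case_count = track),
                outp("top_protein_mutation_track.tsv"))
      outs <- c(outs, "top_protein_mutation_track.tsv")
    }
    outs
  })

  run_stage("interface", "crosslinks.tsv", function() {
    if (is.null(state$catalog)) stop("harmonize stage has not run")
    ranges <- read_crosslinks(inp("crosslinks.tsv"))
    windows <- standardize_windows(ranges, state$proteome,
                                   w = config$window_size)
    write_tsv(windows, outp("windows.tsv"))
    assn <- assign_ptm_distances(state$catalog, windows)
    write_tsv(assn, outp("ptm_distance_assignments.tsv"))
    stats_all <- distance_frequency_stats(assn, windows,
                                          w = config$window_size)
    write_tsv(stats_all$bins, outp("distance_bins.tsv"))
    types <- sort(unique(assn$ptm_type))
    per_type <- do.call(rbind, lapply(types, function(t) {
      s <- distance_frequency_stats(assn, windows, w = config$window_size,
                                    ptm_type = t)
      data.frame(ptm_type = t, rho = s$rho, p_value = s$p_value,
                 n_sites = s$n_sites, flag = s$flag,
                 stringsAsFactors = FALSE)
    }))
    overall <- data.frame(ptm_type = "all", rho = stats_all$rho,
                          p_value = stats_all$p_value,
                          n_sites = stats_all$n_sites,
                          flag = stats_all$flag, stringsAsFactors = FALSE)
    write_tsv(rbind(overall, per_type), outp("distance_correlations.tsv"))
    nearest <- nearest_center_distances(state$catalog, windows)
    write_tsv(nearest, outp("nearest_center_distances.tsv"))
    outs <- c("windows.tsv", "ptm_distance_assignments.tsv",
              "distance_bins.tsv", "distance_correlations.tsv",
              "nearest_center_distances.tsv")
    gc_res <- tryCatch(
      interface_group_contrast(nearest, state$proteome, tag = "hnRNP"),
      error = function(e) NULL)
    if (!is.null(gc_res)) {
      write_tsv(as.data.frame(gc_res), outp("group_contrast.tsv"))
      outs <- c(outs, "group_contrast.tsv")
    }
    outs
  })

  run_stage("eclip",
            c("eclip_rep1.narrowPeak", "eclip_rep2.narrowPeak", "genes.bed"),
            function() {
    rep1 <- read_narrowpeak(inp("eclip_rep1.narrowPeak"))
    rep2 <- read_narrowpeak(inp("eclip_rep2.narrowPeak"))
    genes <- read_gene_models(inp("genes.bed"))
    hits <- eclip_gene_hits(rep1, rep2, genes, f = config$overlap_fraction)
    write_tsv(hits, outp("eclip_gene_hits.tsv"))
    "eclip_gene_hits.tsv"
  })

  run_stage("export", character(0), function() {
    if (is.null(state$catalog)) stop("harmonize stage has not run")
    n <- export_atlas(state$catalog, state$proteome, outp("atlas.tsv"),
                      mode = "evidence")
    message("export: ", n, " atlas rows written")
    "atlas.tsv"
  })

  ok <- !any(vapply(manifest$stages, function(s) s$status == "failed",
                    logical(1)))
  jsonlite::write_json(manifest, outp("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!ok) warning("one or more pipeline stages failed; see run_manifest.json")
  attr(manifest, "ok") <- ok
  invisible(manifest)
}
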