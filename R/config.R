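# Analysis configuration: the handful of constants every stage shares.

.config_defaults <- function() {
  list(
    window_size = 21L,                  # standardized crosslink window width (odd)
    proximity_k = 10L,                  # mutation/PTM proximity radius, residues
    background_n = 100L,                # background positions sampled per protein
    overlap_fraction = 0.5,             # eCLIP peak-over-gene overlap fraction
    high_conservation_threshold = 0.9,  # "highly conserved" mean-score cutoff
    alpha = 0.05,
    seed = 1L,
    yates = FALSE,                      # continuity correction for 2x2 chi-squared
    overlapping_groups = FALSE,         # RBP vs ALL proteins instead of vs non-RBP
    writer_only = FALSE,                # restrict enzyme matching to writers
    nonenzymatic_types = c("oxidation", "sulfenic acid"),
    residue_conflict = "drop"           # or "keep": residue vs sequence mismatch
  )
}

#' Create a validated analysis configuration
#'
#' Bundles the tunable parameters shared across the pipeline stages. The
#' defaults encode the analysis conventions: a 21-residue standardized
#' crosslink window, a 10-residue mutation proximity radius, 100 background
#' positions per protein for the conservation contrast, a 50% peak-overlap
#' requirement for eCLIP hits, a 0.9 mean-score threshold for calling a
#' protein's PTM sites highly conserved, and a 0.05 significance level with
#' Bonferroni correction for the enrichment tests.
#'
#' @param ... named overrides of the defaults (see
#'   [validate_config()] for the full key list). Unknown keys are an error.
#' @return a list of class `"rbptm_config"`.
#' @examples
#' cfg <- analysis_config(seed = 42L)
#' cfg$window_size
#' @export
analysis_config <- function(...) {
  over <- list(...)
  cfg <- .config_defaults()
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("all configuration overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  .validate_config_values(cfg)
}

.validate_config_values <- function(cfg) {
  problems <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)

  cfg$window_size <- as.integer(cfg$window_size)
  cfg$proximity_k <- as.integer(cfg$proximity_k)
  cfg$background_n <- as.integer(cfg$background_n)
  cfg$seed <- as.integer(cfg$seed)

  chk(length(cfg$window_size) == 1 && !is.na(cfg$window_size) &&
        cfg$window_size >= 1, "window_size must be a positive integer")
  chk(is.na(cfg$window_size) || cfg$window_size %% 2L == 1L,
      "window_size must be odd")
  chk(length(cfg$proximity_k) == 1 && !is.na(cfg$proximity_k) &&
        cfg$proximity_k >= 0, "proximity_k must be a nonnegative integer")
  chk(length(cfg$background_n) == 1 && !is.na(cfg$background_n) &&
        cfg$background_n >= 1, "background_n must be a positive integer")
  chk(is.numeric(cfg$overlap_fraction) && length(cfg$overlap_fraction) == 1 &&
        cfg$overlap_fraction > 0 && cfg$overlap_fraction <= 1,
      "overlap_fraction must be in (0, 1]")
  chk(is.numeric(cfg$high_conservation_threshold) &&
        cfg$high_conservation_threshold >= 0 &&
        cfg$high_conservation_threshold <= 1,
      "high_conservation_threshold must be in [0, 1]")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0, 1)")
  chk(length(cfg$seed) == 1 && !is.na(cfg$seed), "seed must be an integer")
  chk(is.logical(cfg$yates) && length(cfg$yates) == 1,
      "yates must be TRUE or FALSE")
  chk(is.logical(cfg$overlapping_groups) && length(cfg$overlapping_groups) == 1,
      "overlapping_groups must be TRUE or FALSE")
  chk(is.logical(cfg$writer_only) && length(cfg$writer_only) == 1,
      "writer_only must be TRUE or FALSE")
  chk(is.character(cfg$nonenzymatic_types),
      "nonenzymatic_types must be a character vector")
  chk(is.character(cfg$residue_conflict) &&
        cfg$residue_conflict %in% c("drop", "keep"),
      "residue_conflict must be 'drop' or 'keep'")

  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "rbptm_config")
}

#' Read and validate a configuration file
#'
#' Reads a YAML or JSON configuration file, fills unspecified keys with the
#' defaults, and checks every invariant (odd window size, overlap fraction in
#' (0, 1], ...), reporting all violations at once.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file. An empty file
#'   yields the full default configuration.
#' @return a validated `"rbptm_config"` list.
#' @seealso [analysis_config()], [write_config()]
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a mapping of key: value")
  do.call(analysis_config, raw)
}

#' Write a configuration to a YAML file
#'
#' The written file round-trips through [validate_config()] unchanged.
#'
#' @param config an `"rbptm_config"` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "rbptm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.rbptm_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-28s %s\n", k, paste(v, collapse = ", ")))
  }
  invisible(x)
}
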