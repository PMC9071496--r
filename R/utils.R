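# Shared internal helpers: seeding, TSV I/O, small conveniences.

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' Sub-seeds make per-protein and per-module randomness independent of
#' processing order: regenerating one module (or contrasting one protein)
#' always sees the same stream. The derivation is a simple 31-multiplier
#' rolling hash over the key, folded into the master seed modulo 2^31 - 1,
#' so it is stable across platforms and R versions.
#'
#' @param seed integer master seed.
#' @param ... character fragments identifying the consumer (module name,
#'   accession, replicate id, ...); concatenated with "/".
#' @return a single integer in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  h <- as.double(abs(as.integer(seed)) %% 2147483647L)
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Canonical TSV writers/readers used by every report and fixture so that
# identical inputs give byte-identical files.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE, ...)
}

# Split a ";"-joined multi-value field; NA and "" give character(0).
split_multi <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

join_multi <- function(x) {
  x <- unique(x[!is.na(x) & nzchar(x)])
  if (length(x) == 0L) NA_character_ else paste(sort(x), collapse = ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
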