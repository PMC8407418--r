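# Internal helpers shared across modules.

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mc <- function(..., call. = FALSE) {
  stop(paste0(...), call. = call.)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed_mc <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive n reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed_mc(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Read/write plain TSVs with a uniform dialect (header, tab, no quoting).
read_tsv_mc <- function(path, ...) {
  if (!file.exists(path)) stop_mc("input file not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, ...))
}

write_tsv_mc <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
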