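#' @useDynLib dtiscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a child seed from a master seed
#'
#' Deterministic mixing of a master seed with a stream index, kept inside
#' the 32-bit signed integer range so the result is always a valid R seed.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index))
  as.integer((abs(master) %% 1000003L) * 2011L + (index %% 100000L) * 7L + 1L)
}

## 31-bit polynomial rolling hash of a character vector (deterministic,
## platform independent; used for fingerprint bit assignment and config
## fingerprints). Modulus 2^31 - 1, base 131.
poly_hash <- function(strings) {
  m <- 2147483647
  vapply(strings, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 131 + c) %% m
    h
  }, numeric(1), USE.NAMES = FALSE)
}

## Write a data.frame as CSV with a commented metadata block on top.
write_csv_meta <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s=%s", k, as.character(meta[[k]])), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

## Metadata block shared by all pipeline outputs: package version, a hash
## of the effective configuration and the master seed. No timestamps, so
## reruns are byte-identical.
run_meta <- function(config, seed) {
  list(
    tool = "dtiscreen",
    version = as.character(utils::packageVersion("dtiscreen")),
    config_hash = config_hash(config),
    master_seed = seed
  )
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  sprintf("%d", poly_hash(as.character(json)))
}
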