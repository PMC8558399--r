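# Small shared helpers: seed fan-out, content hashing, mean +/- sd.

# One user-facing seed fans out to per-stage streams so that adding a stage
# never perturbs the draws of another. Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 10007) %% 2147483629)
}

# Content hash of an arbitrary R object (md5 of its uncompressed
# serialization); used to key pipeline caches and stamp artifacts.
hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Mean and standard deviation of a metric vector
#'
#' The aggregation used in all summary tables; `NA` entries (failed
#' reconstructions for location error) are dropped and counted.
#' @param x Numeric vector.
#' @return Named list: `mean`, `sd`, `n`, `n_na`.
#' @export
mean_sd <- function(x) {
  ok <- !is.na(x)
  list(mean = if (any(ok)) mean(x[ok]) else NA_real_,
       sd = if (sum(ok) > 1) stats::sd(x[ok]) else NA_real_,
       n = sum(ok), n_na = sum(!ok))
}
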