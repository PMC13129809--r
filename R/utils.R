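#' @include AllClasses.R
NULL

# Derive a reproducible child seed from (seed, index); kept below 2^31.
deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %%
               2147483647)
}

# Row/col (0-based) -> linear pixel index into an H x W image matrix.
pixelIndex <- function(coords, dims) {
  coords[, 1] + 1L + coords[, 2] * dims[1]
}

# Weighted mean/sd with normalized weights; sd uses the weighted second
# central moment (population form).
weightedMoments <- function(x, w) {
  if (!length(x) || sum(w) <= 0) return(c(mean = NA_real_, sd = NA_real_))
  w <- w / sum(w)
  m <- sum(w * x)
  c(mean = m, sd = sqrt(max(sum(w * (x - m)^2), 0)))
}

# Row maxima without apply(); fast for small column counts.
rowMax <- function(m) {
  mx <- m[, 1L]
  for (k in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, k])
  mx
}

# log-sum-exp by rows of a matrix.
rowLogSumExp <- function(m) {
  mx <- rowMax(m)
  mx + log(rowSums(exp(m - mx)))
}

rowSoftmax <- function(m) {
  e <- exp(m - rowMax(m))
  e / rowSums(e)
}
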