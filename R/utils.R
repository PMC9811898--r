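# Internal helpers shared across modules.

# Evaluate `code` with a temporary RNG state seeded at `seed`; the caller's
# RNG state is restored on exit so simulations are reproducible without side
# effects.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a small offset, kept within the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647L)
}

# Order rows of a data frame by chromosome (in the order chromosomes first
# appear, or an explicit level vector) then by additional columns.
arrange_genomic <- function(df, chrom_levels = NULL, ...) {
  lv <- chrom_levels %||% unique(df$chrom)
  df$.chrom_ord <- match(df$chrom, lv)
  df <- dplyr::arrange(df, .data$.chrom_ord, ...)
  df$.chrom_ord <- NULL
  df
}

# stats::quantile type 7: linear interpolation between closest order
# statistics. Centralized so every module uses one quantile definition.
quantile_lin <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

stop_bad_line <- function(path, line_no, msg) {
  abort(sprintf("%s: line %d: %s", path, line_no, msg))
}

is_count_vector <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))
}

open_text <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Row-wise cumulative sums with a leading zero column; keeps matrix shape
# for one-row and one-column inputs (where apply() would drop dimensions).
row_cumsum0 <- function(m) {
  out <- m
  if (ncol(m) > 1) {
    out <- t(apply(m, 1, cumsum))
    if (nrow(m) == 1) out <- matrix(out, nrow = 1)
  }
  cbind(0, out)
}
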