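# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_rv <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
warn_rv <- function(...) warning(sprintf(...), call. = FALSE)

# deterministic child seed derived from a user seed and a stream label;
# kept below 2^31 so it is always a valid integer seed
child_seed <- function(seed, stream) {
  s <- (as.numeric(seed) * 48271 + sum(utf8ToInt(as.character(stream)))) %%
    2147483629
  as.integer(s)
}

# Otsu threshold on a numeric vector: maximizes the between-class variance
# over a 256-bin histogram between min and max. Returns a value such that
# `x > threshold` is the foreground class. Degenerate (constant) input
# returns max(x) so the foreground mask is empty.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop_rv("otsu_threshold: no finite values")
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(hi)
  h <- tabulate(pmin(nbins, floor((x - lo) / (hi - lo) * nbins) + 1L), nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- lo + (seq_len(nbins) - 0.5) * (hi - lo) / nbins
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)           # first bin index on ties: deterministic
  lo + k * (hi - lo) / nbins   # upper edge of the chosen bin
}

# 2D median filter with an odd square window (edge-replicated); used to
# smooth the detected skin surface laterally
median_filter2d <- function(m, w) {
  if (w <= 1L) return(m)
  r <- w %/% 2L
  ny <- nrow(m); nx <- ncol(m)
  out <- m
  for (j in seq_len(nx)) {
    js <- pmin(pmax(seq(j - r, j + r), 1L), nx)
    for (i in seq_len(ny)) {
      is <- pmin(pmax(seq(i - r, i + r), 1L), ny)
      out[i, j] <- stats::median(m[is, js], na.rm = TRUE)
    }
  }
  out
}
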