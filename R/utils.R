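# internal helpers

# half-up rounding for report display (base round() is banker's)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# lower-triangular Cholesky factor L with W = L %*% t(L)
chol_lower <- function(W) t(chol(W))
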