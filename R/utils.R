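# Internal helpers shared across modules.

# Evaluate expr under a fixed seed without disturbing the caller's RNG
# state. seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

stopIf <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

assertScalarNumber <- function(x, name, lower = -Inf, strict = FALSE) {
  stopIf(!is.numeric(x) || length(x) != 1L || !is.finite(x),
         name, " must be a finite scalar number")
  if (strict) stopIf(x <= lower, name, " must be > ", lower)
  else stopIf(x < lower, name, " must be >= ", lower)
  invisible(x)
}

# 32-bit FNV-1a over a character string; used only to derive a short run id
# from a serialized configuration.
fnv1a32 <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 0x811c9dc5
  for (b in bytes) {
    # xor touches only the low byte; keep h in double to avoid 32-bit limits
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    # 32-bit multiply by FNV prime 16777619, kept in double precision via
    # 16-bit limbs to avoid overflow
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Truncated normal via rejection; bounds assumed to have non-negligible mass.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, x[x > lower & x < upper])
  }
  out
}
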