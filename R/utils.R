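# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stopf("%s contains non-finite values", what)
  invisible(x)
}

# evaluate `code` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a child seed below 2^31 from a base seed and a stream label
child_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.double(seed) * 1000003 + offs) %% 2147483587
}

clip01 <- function(x) pmin(1, pmax(0, x))

# round-half-up at `digits`, the convention of printed results tables
# (base round() is half-to-even and cannot reproduce e.g. 0.125 -> 0.13)
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# per-column maxima without materialising apply() loops for wide matrices
col_max <- function(m) {
  n <- ncol(m)
  out <- m[1L, ]
  if (nrow(m) > 1L) for (i in 2L:nrow(m)) out <- pmax(out, m[i, ])
  out
}
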