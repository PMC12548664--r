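# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit seed derived from a master seed plus string tags, so a
# single master seed fans out to independent per-stage / per-repetition / per-run
# streams. DJB2-style rolling hash; all arithmetic stays exact in doubles.
derive_seed <- function(...) {
  parts <- paste(unlist(list(...)), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(parts)) h <- (h * 33 + ch) %% 2147483587
  as.integer(h) + 1L
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
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

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)

# Lightweight content hash (weighted byte sums over the serialized object)
# used to key stage caches in the runner; not cryptographic, just
# collision-resistant enough for cache addressing. Vectorized so hashing
# multi-megabyte tensors stays cheap.
content_hash <- function(x) {
  v <- as.integer(serialize(x, NULL, version = 2))
  w1 <- rep_len(c(1, 31, 961, 29791, 923521, 28629151, 887503681), length(v))
  w2 <- rep_len(c(1, 131, 17161, 2248091, 294499921, 523, 273529), length(v))
  chunk <- function(val) {
    idx <- ceiling(seq_along(val) / 4096)
    sums <- vapply(split(val, idx), function(z) sum(z) %% 2147483647, numeric(1))
    Reduce(function(a, b) (a * 69069 + b) %% 2147483647, sums, accumulate = FALSE, right = FALSE)
  }
  sprintf("%08x%08x%08x", as.integer(chunk(v * w1)), as.integer(chunk(v * w2)),
          length(v) %% 2147483647L)
}
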