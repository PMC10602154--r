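# Internal helpers shared across stages.

# Deterministically derive a 32-bit seed for a named RNG stream from the
# master seed. Each simulated object draws from its own stream so that, e.g.,
# changing the number of cells never perturbs the bulk matrix.
derive_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L)
  h <- (as.double(seed) %% 2147483647) * 1000003 %% 2147483647
  for (c in utf8ToInt(label)) {
    h <- (h * 31 + c) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, label).
with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, label))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# BH false discovery rate, thin wrapper kept for a single adjustment idiom.
bh_adjust <- function(p) p.adjust(p, method = "BH")
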