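# Internal helpers: seeded evaluation, seed substreams, logging.

# Evaluate `code` under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(code)
}

# Deterministic substream seed: global seed + stage name -> integer < 2^31.
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- utils::head(utf8ToInt(paste0(name, ":", format(seed, scientific = FALSE))), 64L)
  acc <- 0
  for (v in h) acc <- (acc * 131 + v) %% 2147483647
  as.integer((acc + abs(seed)) %% 2147483647) + 1L
}

kg_log <- function(..., verbose = getOption("kgrepur.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[kgrepur] ", ...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable string key for a (head, tail) entity pair.
pair_key <- function(h, t) paste(h, t, sep = "\r")
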