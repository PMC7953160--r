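#' @keywords internal
"_PACKAGE"

## Run code with a temporary RNG state so callers' streams are untouched.
## Used by every stochastic routine that takes an explicit `seed`.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Per-stage seed derivation: one user seed fans out to independent
## sub-seeds, kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  (as.integer(seed) * 1103L + as.integer(stage) * 12289L) %% 2147483562L
}

## Case-folded, whitespace-collapsed annotation string used to decide
## whether two same-family, same-species genes are "replicated".
normalize_annotation <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

msg <- function(...) message("[famexpress] ", sprintf(...))
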