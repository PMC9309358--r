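# Internal helpers shared across modules.

# Run code with a local RNG state seeded from `seed`, restoring the caller's
# .Random.seed afterwards so package functions never disturb user RNG flow.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic md5 of an R object via canonical JSON (no digest dependency).
configHash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

# z-score a vector; constant input is an error unless allowConstant.
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant variable")
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
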