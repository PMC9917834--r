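# Run code with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# field-level validation with the offending field named in the error
check_field <- function(ok, field, what) {
  if (!isTRUE(ok)) stop(sprintf("invalid field '%s': %s", field, what), call. = FALSE)
  invisible(TRUE)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

complement_allele <- function(a) {
  c(A = "T", T = "A", C = "G", G = "C")[a]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
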