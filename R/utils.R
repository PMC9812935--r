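# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so generator calls never perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("seed must be a single non-missing number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Tolerate the typographic minus that shows up in copy-pasted tables.
normalize_strand <- function(strand) {
  s <- as.character(strand)
  s[s == "−"] <- "-"
  s
}

check_strand <- function(strand, what = "strand") {
  s <- normalize_strand(strand)
  bad <- which(!(s %in% c("+", "-")))
  if (length(bad))
    stopf("%s must be '+' or '-', got '%s'", what, strand[bad[1]])
  s
}

is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
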