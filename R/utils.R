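## Internal helpers shared across modules.

# Deterministic sub-seed for a pipeline stage, kept inside 32-bit range.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 48271 + stage * 1009) %% 2147483629
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- rlang::`%||%`

assert_columns <- function(x, cols, what = deparse(substitute(x))) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

is_probability <- function(x) is.numeric(x) && all(x >= 0 & x <= 1)

CONTEXTS <- c("CG", "CHG", "CHH")

complement_base <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}
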