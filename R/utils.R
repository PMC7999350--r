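## Internal helpers: error signalling and seed plumbing.

# Signal a classed error whose message starts with a stable machine-readable
# code (e.g. "EMPTY_IMAGE: ..."), so callers can match on either the
# condition class "phcDepth_<CODE>" or the message prefix.
pdStop <- function(code, msg) {
  stop(errorCondition(
    paste0(code, ": ", msg),
    class = c(paste0("phcDepth_", code), "phcDepthError", "error", "condition")
  ))
}

pdWarn <- function(msg) {
  warning(warningCondition(msg, class = c("phcDepthWarning", "warning",
                                          "condition")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL uses the current stream.
withSeed <- function(seed, expr) {
  expr <- substitute(expr)
  if (is.null(seed)) return(eval(expr, parent.frame()))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  eval(expr, parent.frame())
}

# Derive a per-item sub-seed from a global seed and a string key, so adding
# items to a run does not perturb the streams of existing ones. Stays within
# 32-bit integer range.
deriveSeed <- function(seed, key) {
  h <- 0
  for (b in utf8ToInt(as.character(key))) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Labels for n depth bins; the canonical five mesophyll layers when n = 5.
binLabels <- function(n) {
  if (n == 5L) c("AD", "UM", "MM", "LM", "AB") else paste0("L", seq_len(n))
}
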