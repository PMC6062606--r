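# internal helpers shared across modules

# evaluate `expr` with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a per-stage seed from a global one; stays inside 32-bit range
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

check_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (allow_zero) "non-negative" else "positive"), call. = FALSE)
  }
  invisible(x)
}

# robust noise SD from lag-1 differences; insensitive to slow wave structure
noise_sd_diff <- function(y) {
  if (length(y) < 3L) return(0)
  1.4826 * stats::median(abs(diff(y))) / sqrt(2)
}

# centered rolling median over a window of `w` samples
rolling_median <- function(x, w) {
  n <- length(x)
  h <- w %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) out[i] <- stats::median(x[max(1L, i - h):min(n, i + h)])
  out
}

# md5 of a config object via its canonical JSON serialization
config_hash <- function(cfg) {
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(js, f)
  unname(tools::md5sum(f))
}
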