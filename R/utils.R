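#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit hash of strings/integers, used to derive independent
# RNG substreams (one per clutch, one per individual) from a base seed, so
# that adding individuals to a design never perturbs existing ones.
rng_substream <- function(seed, ...) {
  parts <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (code in utf8ToInt(parts)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rbind a list of data frames, dropping NULL entries; NULL when nothing
# remains (base rbind mangles the make.row.names argument otherwise).
rbind_rows <- function(lst) {
  lst <- lst[!vapply(lst, is.null, logical(1))]
  if (!length(lst)) return(NULL)
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Minutes in one day
#' @keywords internal
MIN_PER_DAY <- 1440
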