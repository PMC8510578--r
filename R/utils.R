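# internal helpers -----------------------------------------------------------

# classed conditions so callers can distinguish schema vs integrity vs domain
ll_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "larvalearn_error", "error", "condition")))
}

schema_error    <- function(fmt, ...) ll_stop("larvalearn_schema_error", fmt, ...)
integrity_error <- function(fmt, ...) ll_stop("larvalearn_integrity_error", fmt, ...)
domain_error    <- function(fmt, ...) ll_stop("larvalearn_domain_error", fmt, ...)

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
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

# deterministic per-stream seed derivation (Lehmer mixing, keeps values < 2^31-1;
# all intermediates stay below 2^53 so double arithmetic is exact)
mix_seed <- function(...) {
  x <- 1
  for (y in c(...)) {
    x <- ((x + as.double(y)) %% 2147483646 + 1) * 16807 %% 2147483647
    x <- x %% 2147483647
  }
  as.integer(x)
}

logit    <- function(p) log(p) - log1p(-p)
invlogit <- function(x) 1 / (1 + exp(-x))

# clamp a probability away from 0/1 before a logit transform
pclamp <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

# 32-bit rolling content hash as 8 hex digits (provenance stamps only)
content_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%08x", h)
}

format_p <- function(p, B = NULL) {
  if (!is.null(B) && p < 1 / B) sprintf("< %g", 1 / B) else format(p, digits = 4)
}
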