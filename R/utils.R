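#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%g, %g], got %g", name, lower, upper, x)
  if (!allow_zero && x == 0) stopf("'%s' must be non-zero", name)
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < lower)
    stopf("'%s' must be an integer >= %d", name, lower)
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (is.null(seed))
    stopf("'seed' is mandatory: simulators carry no global random state")
  check_count(seed, "seed", lower = 0L)
}

# FNV-1a 32-bit hash of a string; used for config fingerprints in manifests
# (deterministic across runs, unlike serialization-based hashes).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h as a double since
    # it exceeds R's signed-integer range
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Longest run of TRUE values in a logical vector (NA treated as FALSE).
max_run_length <- function(flag) {
  flag[is.na(flag)] <- FALSE
  if (!any(flag)) return(0L)
  r <- rle(flag)
  max(r$lengths[r$values])
}
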