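#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves the current global RNG state, seeds it with `seed`, evaluates
#' `code`, and restores the previous state on exit. With `seed = NULL`
#' the code runs on the ambient RNG stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# FNV-1a hash of a character scalar, returned as 8 hex digits.
# Used only to stamp run manifests; not cryptographic.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low byte only (b < 256), keeping h a double-safe int
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # 32-bit modular multiply by the FNV prime 16777619, done in doubles
    # split to stay within the 2^53 exact-integer range
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Align a clinical table to a vector of sample ids; hard error listing
# any sample without clinical data (alignment is always by id, never by
# column order).
align_clinical <- function(clin, sample_ids) {
  stopifnot(inherits(clin, "clinical_table"))
  idx <- match(sample_ids, clin$sample)
  if (anyNA(idx)) {
    missing <- sample_ids[is.na(idx)]
    stop("no clinical data for sample(s): ", paste(missing, collapse = ", "))
  }
  clin[idx, , drop = FALSE]
}

# Row means / sds ignoring NA, sample (n-1) convention.
row_moments <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  s <- sqrt(ss / pmax(n - 1, 1))
  s[n < 2] <- NA_real_
  list(mean = m, sd = s, n = n)
}

format_num <- function(x) {
  # full-precision, locale-independent textual form (round-trips doubles)
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  trimws(out)
}
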