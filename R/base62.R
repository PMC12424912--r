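#' Base62 positional encoding
#'
#' Fixed-width Base62 representation of non-negative integers over the
#' alphabet `0-9`, `A-Z`, `a-z` (in that order, so `"0" = 0`, `"A" = 10`,
#' `"a" = 36`). The stub identifier format uses Base62 to compress numeric
#' components: the subject ID (width 3, values up to 62^3 - 1 = 238327),
#' the species index (width 2) and the condition rank (width 3).
#'
#' @param n Vector of non-negative integers (each `< 62^width`).
#' @param width Token width; results are left-padded with `"0"`.
#' @return `base62_encode()` returns a character vector of `width`-character
#'   tokens; `base62_decode()` returns an integer-valued numeric vector.
#' @examples
#' base62_encode(1001, 3)   # "0G9"
#' base62_decode("0G9")     # 1001
#' @export
base62_encode <- function(n, width) {
  stopifnot(length(width) == 1L, width >= 1L)
  n <- as.numeric(n)
  if (any(is.na(n)) || any(n < 0) || any(n != floor(n))) {
    abort_range("base62_encode() requires non-negative integers")
  }
  if (any(n >= 62^width)) {
    abort_overflow(sprintf(
      "value %s does not fit in %d Base62 character(s) (max %s)",
      format(max(n), scientific = FALSE), width,
      format(62^width - 1, scientific = FALSE)
    ))
  }
  out <- matrix("", nrow = length(n), ncol = width)
  rem <- n
  for (i in seq_len(width)) {
    p <- 62^(width - i)
    d <- rem %/% p
    rem <- rem %% p
    out[, i] <- .base62_alphabet[d + 1L]
  }
  apply(out, 1L, paste0, collapse = "")
}

.base62_alphabet <- c(0:9, LETTERS, letters)

.base62_values <- stats::setNames(seq_along(.base62_alphabet) - 1L, .base62_alphabet)

#' @param token Character vector of Base62 tokens (any width >= 1).
#' @rdname base62_encode
#' @export
base62_decode <- function(token) {
  if (!is.character(token) || any(is.na(token)) || any(nchar(token) == 0L)) {
    abort_decode("base62_decode() requires non-empty character tokens")
  }
  vapply(token, function(tk) {
    digits <- .base62_values[strsplit(tk, "", fixed = TRUE)[[1L]]]
    if (anyNA(digits)) {
      abort_decode(sprintf("'%s' contains characters outside the Base62 alphabet", tk))
    }
    sum(digits * 62^(rev(seq_along(digits)) - 1L))
  }, numeric(1), USE.NAMES = FALSE)
}
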