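# QR code generation and read-back.
#
# A purpose-built byte-mode QR codec: versions 1-5, error-correction
# level L (a single Reed-Solomon block per symbol), mask pattern 0 on
# write. The reader handles clean, axis-aligned, uniformly scaled
# symbols with a quiet zone (exactly what the writer produces, at any
# integer scale), supports all eight mask patterns, and applies full
# Reed-Solomon error correction (Berlekamp-Massey / Chien / Forney), so
# moderate pixel damage is recovered. Identifiers are ASCII, well within
# the 106-character capacity of version 5-L.

# ---- GF(256) arithmetic (primitive polynomial x^8+x^4+x^3+x^2+1) ------------

.qr_gf <- local({
  exp <- integer(512)
  log <- integer(256)
  x <- 1L
  for (i in 0:254) {
    exp[i + 1L] <- x
    log[x + 1L] <- i
    x <- bitwShiftL(x, 1L)
    if (x >= 256L) x <- bitwXor(x, 0x11DL)
  }
  exp[256:510] <- exp[1:255]
  list(exp = exp, log = log)
})

gf_mul <- function(a, b) {
  if (a == 0L || b == 0L) return(0L)
  .qr_gf$exp[((.qr_gf$log[a + 1L] + .qr_gf$log[b + 1L]) %% 255L) + 1L]
}

gf_inv <- function(a) .qr_gf$exp[(255L - .qr_gf$log[a + 1L]) %% 255L + 1L]

gf_poly_mul <- function(p, q) {
  r <- integer(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] == 0L) next
    for (j in seq_along(q)) {
      r[i + j - 1L] <- bitwXor(r[i + j - 1L], gf_mul(p[i], q[j]))
    }
  }
  r
}

# coefficients highest-degree first; evaluate at x
gf_poly_eval <- function(p, x) {
  y <- p[1L]
  for (i in seq_along(p)[-1L]) y <- bitwXor(gf_mul(y, x), p[i])
  y
}

rs_generator <- function(nsym) {
  g <- 1L
  for (i in 0:(nsym - 1L)) g <- gf_poly_mul(g, c(1L, .qr_gf$exp[i + 1L]))
  g
}

rs_encode_block <- function(data, nsym) {
  gen <- rs_generator(nsym)
  buf <- c(data, integer(nsym))
  for (i in seq_along(data)) {
    coef <- buf[i]
    if (coef != 0L) {
      for (j in seq_along(gen)[-1L]) {
        buf[i + j - 1L] <- bitwXor(buf[i + j - 1L], gf_mul(gen[j], coef))
      }
    }
  }
  buf[(length(data) + 1L):length(buf)]
}

gf_pow <- function(x, p) {
  if (x == 0L) return(0L)
  .qr_gf$exp[((.qr_gf$log[x + 1L] * p) %% 255L) + 1L]
}

gf_poly_scale <- function(p, s) vapply(p, gf_mul, integer(1), b = s)

# XOR of two polynomials (coefficients highest-degree first)
gf_poly_add <- function(p, q) {
  len <- max(length(p), length(q))
  bitwXor(c(integer(len - length(p)), p), c(integer(len - length(q)), q))
}

# Correct a received codeword (data + ecc, highest-order first).
# Berlekamp-Massey error locator, Chien search, Forney magnitudes;
# signals a qr error when the error count exceeds floor(nsym/2).
rs_correct <- function(msg, nsym) {
  msg <- as.integer(msg)
  synd <- vapply(0:(nsym - 1L), function(i) gf_poly_eval(msg, gf_pow(2L, i)), integer(1))
  if (all(synd == 0L)) return(msg)
  # error locator (coefficients highest-degree first)
  err_loc <- 1L
  old_loc <- 1L
  for (i in seq_len(nsym)) {
    old_loc <- c(old_loc, 0L)
    delta <- synd[i]
    K <- length(err_loc)
    if (K > 1L) {
      for (j in seq_len(K - 1L)) {
        delta <- bitwXor(delta, gf_mul(err_loc[K - j], synd[i - j]))
      }
    }
    if (delta != 0L) {
      if (length(old_loc) > length(err_loc)) {
        new_loc <- gf_poly_scale(old_loc, delta)
        old_loc <- gf_poly_scale(err_loc, gf_inv(delta))
        err_loc <- new_loc
      }
      err_loc <- gf_poly_add(err_loc, gf_poly_scale(old_loc, delta))
    }
  }
  while (length(err_loc) > 1L && err_loc[1L] == 0L) err_loc <- err_loc[-1L]
  nerr <- length(err_loc) - 1L
  if (nerr == 0L || 2L * nerr > nsym) abort_qr("too many errors in QR symbol")
  # Chien search: roots of the locator give the error positions
  n <- length(msg)
  err_pos <- integer(0)
  loc_rev <- rev(err_loc)
  for (i in 0:(n - 1L)) {
    if (gf_poly_eval(loc_rev, gf_pow(2L, i)) == 0L) {
      err_pos <- c(err_pos, n - 1L - i)
    }
  }
  if (length(err_pos) != nerr) abort_qr("unreadable QR symbol: error locator has wrong root count")
  # Forney algorithm
  coef_pos <- n - 1L - err_pos
  loc <- 1L
  for (p in coef_pos) loc <- gf_poly_mul(loc, c(gf_pow(2L, p), 1L))
  # error evaluator = (reversed syndromes * locator) mod x^(nerr+1)
  prod <- gf_poly_mul(rev(synd), loc)
  err_eval <- prod[(length(prod) - nerr):length(prod)]
  X <- vapply(coef_pos, function(p) gf_pow(2L, p - 255L), integer(1))
  for (i in seq_along(X)) {
    xi_inv <- gf_inv(X[i])
    den <- 1L
    for (j in seq_along(X)) {
      if (j != i) den <- gf_mul(den, bitwXor(1L, gf_mul(xi_inv, X[j])))
    }
    if (den == 0L) abort_qr("unreadable QR symbol: zero denominator in error correction")
    # e_i = Omega(Xi^-1) / prod_{j != i} (1 + Xi^-1 Xj); the Xi factors of
    # the classical Forney formula cancel against Lambda'(Xi^-1) = Xi * prod
    y <- gf_poly_eval(err_eval, xi_inv)
    mag <- gf_mul(y, gf_inv(den))
    msg[err_pos[i] + 1L] <- bitwXor(msg[err_pos[i] + 1L], mag)
  }
  synd2 <- vapply(0:(nsym - 1L), function(i) gf_poly_eval(msg, gf_pow(2L, i)), integer(1))
  if (any(synd2 != 0L)) abort_qr("unreadable QR symbol: error correction failed")
  msg
}

# ---- symbol geometry --------------------------------------------------------

# version table, error-correction level L (single RS block)
.qr_versions <- data.frame(
  version = 1:5,
  size    = 17L + 4L * (1:5),
  total   = c(26L, 44L, 70L, 100L, 134L),
  ec      = c(7L, 10L, 15L, 20L, 26L)
)
.qr_versions$data <- .qr_versions$total - .qr_versions$ec
.qr_versions$capacity <- .qr_versions$data - 2L   # byte mode: 4-bit mode + 8-bit count

.qr_masks <- list(
  function(r, c) (r + c) %% 2L == 0L,
  function(r, c) r %% 2L == 0L,
  function(r, c) c %% 3L == 0L,
  function(r, c) (r + c) %% 3L == 0L,
  function(r, c) ((r %/% 2L) + (c %/% 3L)) %% 2L == 0L,
  function(r, c) (r * c) %% 2L + (r * c) %% 3L == 0L,
  function(r, c) ((r * c) %% 2L + (r * c) %% 3L) %% 2L == 0L,
  function(r, c) ((r + c) %% 2L + (r * c) %% 3L) %% 2L == 0L
)

# 15-bit format string (MSB first) for an EC level and mask id
qr_format_bits <- function(ec_level, mask) {
  ec_bits <- switch(ec_level, L = c(0L, 1L), M = c(0L, 0L), Q = c(1L, 1L), H = c(1L, 0L))
  data5 <- c(ec_bits, as.integer(intToBits(mask))[3:1])
  # BCH(15,5) remainder with generator 10100110111
  gen <- c(1L, 0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L)
  reg <- c(data5, integer(10L))
  for (i in 1:5) {
    if (reg[i] == 1L) {
      reg[i:(i + 10L)] <- bitwXor(reg[i:(i + 10L)], gen)
    }
  }
  bits <- c(data5, reg[6:15])
  bitwXor(bits, c(1L, 0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 1L, 0L))
}

# Function-pattern scaffold for a version: list(m = 0/1 matrix with
# function modules painted, fun = logical matrix of reserved positions).
# All coordinates are 0-indexed.
qr_scaffold <- function(version) {
  size <- 17L + 4L * version
  m <- matrix(0L, size, size)
  fun <- matrix(FALSE, size, size)
  put <- function(r, c, v) {
    m[r + 1L, c + 1L] <<- v
    fun[r + 1L, c + 1L] <<- TRUE
  }
  finder <- function(r0, c0) {
    for (r in -1:7) for (c in -1:7) {
      rr <- r0 + r; cc <- c0 + c
      if (rr < 0L || cc < 0L || rr >= size || cc >= size) next
      dark <- r >= 0L && r <= 6L && c >= 0L && c <= 6L &&
        (r %in% c(0L, 6L) || c %in% c(0L, 6L) || (r >= 2L && r <= 4L && c >= 2L && c <= 4L))
      put(rr, cc, as.integer(dark))
    }
  }
  finder(0L, 0L)
  finder(0L, size - 7L)
  finder(size - 7L, 0L)
  for (i in 8:(size - 9L)) {
    v <- as.integer(i %% 2L == 0L)
    if (!fun[7L, i + 1L]) put(6L, i, v)
    if (!fun[i + 1L, 7L]) put(i, 6L, v)
  }
  if (version >= 2L) {
    ctr <- 4L * version + 10L
    for (r in -2:2) for (c in -2:2) {
      dark <- max(abs(r), abs(c)) != 1L
      put(ctr + r, ctr + c, as.integer(dark))
    }
  }
  put(4L * version + 9L, 8L, 1L)  # dark module
  # reserve the format-information positions
  fmt <- qr_format_coords(size)
  for (xy in c(fmt$copy1, fmt$copy2)) {
    fun[xy[1L] + 1L, xy[2L] + 1L] <- TRUE
  }
  list(m = m, fun = fun, size = size)
}

qr_format_coords <- function(size) {
  copy1 <- c(
    lapply(c(0:5, 7L, 8L), function(c) c(8L, c)),
    lapply(c(7L, 5L, 4L, 3L, 2L, 1L, 0L), function(r) c(r, 8L))
  )
  copy2 <- c(
    lapply(1:7, function(i) c(size - i, 8L)),
    lapply(c(size - 8L + 0:7), function(c) c(8L, c))
  )
  list(copy1 = copy1, copy2 = copy2)
}

# Zigzag order of data-module coordinates (0-indexed), cached per version.
.qr_coord_cache <- new.env(parent = emptyenv())

qr_data_coords <- function(version, fun) {
  key <- as.character(version)
  if (!is.null(.qr_coord_cache[[key]])) return(.qr_coord_cache[[key]])
  size <- 17L + 4L * version
  coords <- matrix(0L, nrow = 0L, ncol = 2L)
  col <- size - 1L
  upward <- TRUE
  buf <- vector("list", 4096L)
  nb <- 0L
  while (col > 0L) {
    if (col == 6L) col <- col - 1L
    rows <- if (upward) (size - 1L):0L else 0L:(size - 1L)
    for (r in rows) {
      for (cc in c(col, col - 1L)) {
        if (!fun[r + 1L, cc + 1L]) {
          nb <- nb + 1L
          buf[[nb]] <- c(r, cc)
        }
      }
    }
    upward <- !upward
    col <- col - 2L
  }
  coords <- do.call(rbind, buf[seq_len(nb)])
  .qr_coord_cache[[key]] <- coords
  coords
}

bytes_to_bits <- function(bytes) {
  as.integer(vapply(bytes, function(b) as.integer(intToBits(b))[8:1], integer(8L)))
}

bits_to_bytes <- function(bits) {
  n <- length(bits) %/% 8L
  vapply(seq_len(n), function(i) {
    sum(bits[(8L * (i - 1L) + 1L):(8L * i)] * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
  }, integer(1))
}

# Build the module matrix (1 = dark) for a text payload.
qr_encode_matrix <- function(text) {
  bytes <- as.integer(charToRaw(text))
  if (length(bytes) == 0L) abort_qr("cannot encode an empty identifier")
  row <- .qr_versions[.qr_versions$capacity >= length(bytes), ][1L, ]
  if (is.na(row$version)) {
    abort_qr(sprintf("identifier of %d bytes exceeds the %d-byte capacity (version 5-L)",
                     length(bytes), max(.qr_versions$capacity)))
  }
  n_data <- row$data
  bits <- c(
    c(0L, 1L, 0L, 0L),                                   # byte mode
    as.integer(intToBits(length(bytes)))[8:1],            # 8-bit count
    bytes_to_bits(bytes)
  )
  bits <- c(bits, integer(min(4L, n_data * 8L - length(bits))))   # terminator
  if (length(bits) %% 8L != 0L) bits <- c(bits, integer(8L - length(bits) %% 8L))
  data_cw <- bits_to_bytes(bits)
  pad <- c(236L, 17L)
  i <- 1L
  while (length(data_cw) < n_data) {
    data_cw <- c(data_cw, pad[i])
    i <- 3L - i
  }
  codewords <- c(data_cw, rs_encode_block(data_cw, row$ec))
  sc <- qr_scaffold(row$version)
  coords <- qr_data_coords(row$version, sc$fun)
  all_bits <- c(bytes_to_bits(codewords), integer(nrow(coords) - 8L * length(codewords)))
  mask_id <- 0L
  maskf <- .qr_masks[[mask_id + 1L]]
  m <- sc$m
  for (k in seq_len(nrow(coords))) {
    r <- coords[k, 1L]; c <- coords[k, 2L]
    v <- all_bits[k]
    if (maskf(r, c)) v <- bitwXor(v, 1L)
    m[r + 1L, c + 1L] <- v
  }
  fmt <- qr_format_bits("L", mask_id)
  fc <- qr_format_coords(sc$size)
  for (i in seq_len(15L)) {
    m[fc$copy1[[i]][1L] + 1L, fc$copy1[[i]][2L] + 1L] <- fmt[i]
    m[fc$copy2[[i]][1L] + 1L, fc$copy2[[i]][2L] + 1L] <- fmt[i]
  }
  m
}

#' Generate a QR code for a ClarID identifier
#'
#' Writes a PNG containing a QR symbol (byte mode, error-correction
#' level L, versions 1-5) encoding the identifier, with a 4-module quiet
#' zone. [qr_read()] inverts it byte-exactly; both human and stub
#' identifiers are supported.
#'
#' @param id Non-empty ASCII identifier string (at most 106 bytes, the
#'   byte-mode capacity of version 5-L).
#' @param path Output PNG path.
#' @param scale Pixels per module.
#' @param border Quiet-zone width in modules.
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".png")
#' qr_generate("COPDStudy-01001-Case-J44.9-Male-A40_49", f)
#' qr_read(f)
#' @export
qr_generate <- function(id, path, scale = 4L, border = 4L) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    abort_qr("id must be a single non-empty string")
  }
  if (grepl("[^\x20-\x7E]", id)) abort_qr("id must be printable ASCII")
  m <- qr_encode_matrix(id)
  img <- kronecker(m, matrix(1L, scale, scale))
  full <- matrix(0L, nrow(img) + 2L * scale * border, ncol(img) + 2L * scale * border)
  off <- scale * border
  full[(off + 1L):(off + nrow(img)), (off + 1L):(off + ncol(img))] <- img
  png::writePNG(1 - full, path)
  invisible(path)
}

#' Read a ClarID identifier back from a QR code image
#'
#' Reads a single clean, axis-aligned QR symbol (any integer scale,
#' any quiet zone) from a PNG, applying Reed-Solomon error correction.
#'
#' @param path Path to a PNG image containing exactly one QR symbol.
#' @return The decoded identifier string.
#' @export
qr_read <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("image '%s' does not exist", path))
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) {
    img <- (img[, , 1L] + img[, , 2L] + img[, , 3L]) / 3
  }
  dark <- img < 0.5
  rows <- which(apply(dark, 1L, any))
  cols <- which(apply(dark, 2L, any))
  if (length(rows) == 0L) abort_qr("no QR symbol found in image")
  r0 <- min(rows); c0 <- min(cols)
  wid <- max(cols) - c0 + 1L
  hei <- max(rows) - r0 + 1L
  run <- 0L
  while (c0 + run <= ncol(dark) && dark[r0, c0 + run]) run <- run + 1L
  scale <- round(run / 7)
  if (scale < 1L) abort_qr("cannot estimate module size; not a QR symbol")
  size <- round(wid / scale)
  version <- (size - 17L) / 4L
  if (version != floor(version) || version < 1L || version > 5L ||
      abs(hei - wid) > scale) {
    abort_qr("image does not contain a supported QR symbol (versions 1-5)")
  }
  version <- as.integer(version)
  centers <- function(i) round(r0 - 1L + (i - 0.5) * scale) + 1L
  m <- matrix(0L, size, size)
  for (r in seq_len(size)) {
    rr <- round(r0 - 1 + (r - 0.5) * scale)
    for (c in seq_len(size)) {
      cc <- round(c0 - 1 + (c - 0.5) * scale)
      m[r, c] <- as.integer(dark[rr, cc])
    }
  }
  fc <- qr_format_coords(size)
  read_fmt <- function(coords) {
    vapply(coords, function(xy) m[xy[1L] + 1L, xy[2L] + 1L], integer(1))
  }
  candidates <- expand.grid(ec = c("L", "M", "Q", "H"), mask = 0:7,
                            stringsAsFactors = FALSE)
  best <- NULL
  for (copy in list(fc$copy1, fc$copy2)) {
    got <- read_fmt(copy)
    for (i in seq_len(nrow(candidates))) {
      want <- qr_format_bits(candidates$ec[i], candidates$mask[i])
      d <- sum(got != want)
      if (is.null(best) || d < best$d) {
        best <- list(d = d, ec = candidates$ec[i], mask = candidates$mask[i])
      }
    }
  }
  if (best$d > 3L) abort_qr("unreadable format information")
  if (best$ec != "L") {
    abort_qr(sprintf("unsupported error-correction level '%s' (only L symbols are read)", best$ec))
  }
  row <- .qr_versions[.qr_versions$version == version, ]
  sc <- qr_scaffold(version)
  coords <- qr_data_coords(version, sc$fun)
  maskf <- .qr_masks[[best$mask + 1L]]
  bits <- integer(nrow(coords))
  for (k in seq_len(nrow(coords))) {
    r <- coords[k, 1L]; c <- coords[k, 2L]
    v <- m[r + 1L, c + 1L]
    if (maskf(r, c)) v <- bitwXor(v, 1L)
    bits[k] <- v
  }
  codewords <- bits_to_bytes(bits[seq_len(8L * row$total)])
  corrected <- rs_correct(codewords, row$ec)
  data_cw <- corrected[seq_len(row$data)]
  dbits <- bytes_to_bits(data_cw)
  mode <- dbits[1:4]
  if (!identical(mode, c(0L, 1L, 0L, 0L))) {
    abort_qr("unsupported QR mode (only byte mode is read)")
  }
  len <- sum(dbits[5:12] * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L))
  if (len == 0L || 12L + 8L * len > length(dbits)) {
    abort_qr("corrupt QR payload length")
  }
  bytes <- bits_to_bytes(dbits[13:(12L + 8L * len)])
  rawToChar(as.raw(bytes))
}
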