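# SHA-256 in pure R. Ledgers are short, so throughput is irrelevant; what
# matters is correctness (checked against the FIPS 180-4 test vectors) and
# zero external dependencies. Words are doubles in [0, 2^32): R integers
# cannot represent -2^31 (it is the NA marker), so bitwise ops run on
# 16-bit halves and rotations/shifts are plain arithmetic.

SHA256_K <- c(
  0x428a2f98, 0x71374491, 0xb5c0fbcf, 0xe9b5dba5, 0x3956c25b, 0x59f111f1,
  0x923f82a4, 0xab1c5ed5, 0xd807aa98, 0x12835b01, 0x243185be, 0x550c7dc3,
  0x72be5d74, 0x80deb1fe, 0x9bdc06a7, 0xc19bf174, 0xe49b69c1, 0xefbe4786,
  0x0fc19dc6, 0x240ca1cc, 0x2de92c6f, 0x4a7484aa, 0x5cb0a9dc, 0x76f988da,
  0x983e5152, 0xa831c66d, 0xb00327c8, 0xbf597fc7, 0xc6e00bf3, 0xd5a79147,
  0x06ca6351, 0x14292967, 0x27b70a85, 0x2e1b2138, 0x4d2c6dfc, 0x53380d13,
  0x650a7354, 0x766a0abb, 0x81c2c92e, 0x92722c85, 0xa2bfe8a1, 0xa81a664b,
  0xc24b8b70, 0xc76c51a3, 0xd192e819, 0xd6990624, 0xf40e3585, 0x106aa070,
  0x19a4c116, 0x1e376c08, 0x2748774c, 0x34b0bcb5, 0x391c0cb3, 0x4ed8aa4a,
  0x5b9cca4f, 0x682e6ff3, 0x748f82ee, 0x78a5636f, 0x84c87814, 0x8cc70208,
  0x90befffa, 0xa4506ceb, 0xbef9a3f7, 0xc67178f2)

SHA256_H0 <- c(0x6a09e667, 0xbb67ae85, 0x3c6ef372, 0xa54ff53a,
               0x510e527f, 0x9b05688c, 0x1f83d9ab, 0x5be0cd19)

xor32 <- function(x, y) {
  bitwXor(as.integer(x %/% 65536), as.integer(y %/% 65536)) * 65536 +
    bitwXor(as.integer(x %% 65536), as.integer(y %% 65536))
}
and32 <- function(x, y) {
  bitwAnd(as.integer(x %/% 65536), as.integer(y %/% 65536)) * 65536 +
    bitwAnd(as.integer(x %% 65536), as.integer(y %% 65536))
}
not32 <- function(x) 4294967295 - x
rotr32 <- function(x, n) (x %/% 2^n + (x %% 2^n) * 2^(32 - n))
shr32 <- function(x, n) x %/% 2^n

#' SHA-256 digest of a string or raw vector
#'
#' @param x A length-1 character vector (taken as UTF-8 bytes) or a raw
#'   vector.
#' @return Lower-case 64-character hex digest.
#' @export
sha256 <- function(x) {
  msg <- if (is.raw(x)) x else charToRaw(enc2utf8(x))
  ml <- length(msg)
  padlen <- (55 - ml) %% 64
  bits <- ml * 8
  lenbytes <- as.raw((bits %/% 256^(7:0)) %% 256)
  buf <- as.numeric(c(msg, as.raw(0x80), rep(as.raw(0), padlen), lenbytes))

  H <- SHA256_H0
  K <- SHA256_K
  for (blk in seq_len(length(buf) %/% 64)) {
    off <- (blk - 1) * 64
    w <- numeric(64)
    for (t in 1:16) {
      b <- buf[off + (4 * t - 3):(4 * t)]
      w[t] <- b[1] * 16777216 + b[2] * 65536 + b[3] * 256 + b[4]
    }
    for (t in 17:64) {
      s0 <- xor32(xor32(rotr32(w[t - 15], 7), rotr32(w[t - 15], 18)),
                  shr32(w[t - 15], 3))
      s1 <- xor32(xor32(rotr32(w[t - 2], 17), rotr32(w[t - 2], 19)),
                  shr32(w[t - 2], 10))
      w[t] <- (w[t - 16] + s0 + w[t - 7] + s1) %% 4294967296
    }
    a <- H[1]; b <- H[2]; cc <- H[3]; d <- H[4]
    e <- H[5]; f <- H[6]; g <- H[7]; h <- H[8]
    for (t in 1:64) {
      S1 <- xor32(xor32(rotr32(e, 6), rotr32(e, 11)), rotr32(e, 25))
      ch <- xor32(and32(e, f), and32(not32(e), g))
      t1 <- (h + S1 + ch + K[t] + w[t]) %% 4294967296
      S0 <- xor32(xor32(rotr32(a, 2), rotr32(a, 13)), rotr32(a, 22))
      maj <- xor32(xor32(and32(a, b), and32(a, cc)), and32(b, cc))
      t2 <- (S0 + maj) %% 4294967296
      h <- g; g <- f; f <- e
      e <- (d + t1) %% 4294967296
      d <- cc; cc <- b; b <- a
      a <- (t1 + t2) %% 4294967296
    }
    H <- (H + c(a, b, cc, d, e, f, g, h)) %% 4294967296
  }
  paste0(sprintf("%04x%04x", H %/% 65536, H %% 65536), collapse = "")
}
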