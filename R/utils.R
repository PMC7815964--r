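# Internal helpers: stable hashing for resample ids and seed derivation.

# FNV-1a 32-bit over the UTF-8 bytes of a string. Pure integer arithmetic in
# doubles (exact below 2^53), so the digest is identical on every platform.
fnv1a32 <- function(x, offset = 2166136261) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- offset
  for (b in bytes) {
    h <- bitwXor32(h, b)
    # h * 16777619 mod 2^32, split to avoid exceeding 2^53
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # bitwXor works on 32-bit signed ints; keep everything in [0, 2^32)
  ah <- a %/% 65536; al <- a %% 65536
  bh <- b %/% 65536; bl <- b %% 65536
  bitwXor(ah, bh) * 65536 + bitwXor(al, bl)
}

# 64-bit-equivalent hex digest from two independent FNV lanes.
stable_digest <- function(x) {
  hex32 <- function(h) sprintf("%04x%04x", as.integer(h %/% 65536),
                               as.integer(h %% 65536))
  paste0(hex32(fnv1a32(x)), hex32(fnv1a32(x, offset = 40389)))
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Work units (one resample, one algorithm, one repeat) draw their own seeds
#' by hashing the master seed together with stable labels, so adding an
#' algorithm or running units in parallel never perturbs another unit's
#' random stream.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the work unit.
#' @return An integer in [0, 2^31 - 1] usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(as.character(master), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  as.integer(fnv1a32(key) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
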