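#' @importFrom stats runif setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded pseudonym generation
#' never disturbs the caller's random stream. A `NULL` seed evaluates the
#' expression against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# 128-bit (by default) random identifiers rendered as lowercase hex.
# Drawn from R's seedable stream so fixtures are reproducible; pseudonyms are
# never derived from record content.
random_hex <- function(n = 1L, bytes = 16L) {
  vapply(seq_len(n), function(i) {
    paste(sprintf("%02x", sample.int(256L, bytes, replace = TRUE) - 1L),
          collapse = "")
  }, character(1))
}

random_raw <- function(bytes) {
  as.raw(sample.int(256L, bytes, replace = TRUE) - 1L)
}

pr_stop <- function(message, class, ...) {
  stop(structure(
    class = c(class, "pseudoreg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

is_pr_error <- function(e, class) inherits(e, class)

sha256_hex <- function(x) {
  if (!is.raw(x)) x <- charToRaw(paste(x, collapse = ""))
  paste(as.character(openssl::sha256(x)), collapse = "")
}

hmac_sha256 <- function(key, data) {
  openssl::sha256(data, key = key)
}

#' URL-safe base64 (RFC 4648 base64url, unpadded)
#' @param x raw vector to encode / character scalar to decode.
#' @return encoded text / decoded raw vector.
#' @keywords internal
#' @noRd
base64url_encode <- function(x) {
  s <- openssl::base64_encode(x)
  s <- chartr("+/", "-_", s)
  gsub("=+$", "", s)
}

base64url_decode <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s)) {
    pr_stop("base64url input must be a single string", "pseudoreg_decode_error")
  }
  if (grepl("[^A-Za-z0-9_-]", s)) {
    pr_stop("input is not base64url text", "pseudoreg_decode_error")
  }
  pad <- (4L - nchar(s) %% 4L) %% 4L
  if (pad == 3L) {
    pr_stop("truncated base64url text", "pseudoreg_decode_error")
  }
  s <- chartr("-_", "+/", s)
  s <- paste0(s, strrep("=", pad))
  openssl::base64_decode(s)
}

to_json_chr <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                                digits = NA))
}

from_json_chr <- function(s) {
  jsonlite::fromJSON(s, simplifyVector = FALSE)
}
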