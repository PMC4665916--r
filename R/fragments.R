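# Request-line fragmentation.
#
# Browsers cap the length of a URL (historically 2083 characters), so an
# encoded token that does not fit is split client-side into multiple
# sub-requests which the server recombines. Each fragment is framed as
#   rid=<16 hex>&idx=<6 digits>&tot=<6 digits>&frag=<chunk>
# so a complete, possibly reordered set reassembles losslessly and incomplete
# or conflicting sets are detected.

FRAGMENT_URL_LIMIT <- 2083L

fragment_overhead <- function() {
  nchar("rid=") + 16L + nchar("&idx=") + 6L + nchar("&tot=") + 6L +
    nchar("&frag=")
}

#' Split an encoded request line into length-bounded sub-requests
#'
#' @param encoded the URL-safe encoded text (see [encode_request_line()]).
#' @param max_len maximum full request-line length per fragment; the default
#'   is the common browser URL limit of 2083 characters.
#' @param rng_seed optional seed for the request id (testing only).
#' @return character vector of framed sub-requests, each of length
#'   `<= max_len`; a text that already fits yields exactly one fragment.
#' @export
fragment_request <- function(encoded, max_len = FRAGMENT_URL_LIMIT,
                             rng_seed = NULL) {
  stopifnot(is.character(encoded), length(encoded) == 1L)
  capacity <- max_len - fragment_overhead()
  if (capacity < 1L) {
    pr_stop(sprintf(
      "max_len %d leaves no room for payload (framing needs %d characters)",
      max_len, fragment_overhead()), "pseudoreg_usage_error")
  }
  rid <- with_seed(rng_seed, random_hex(1L, 8L))
  n <- max(1L, as.integer(ceiling(nchar(encoded) / capacity)))
  starts <- (seq_len(n) - 1L) * capacity + 1L
  chunks <- substring(encoded, starts, pmin(starts + capacity - 1L,
                                            nchar(encoded)))
  sprintf("rid=%s&idx=%06d&tot=%06d&frag=%s", rid, seq_len(n), n, chunks)
}

#' Reassemble fragmented sub-requests into the original text
#'
#' Accepts the fragments in any order. Missing indices are reported by name;
#' duplicate indices with conflicting content raise an error (identical
#' duplicates are tolerated, as retransmissions are harmless).
#'
#' @param fragments character vector of framed sub-requests.
#' @return the reassembled encoded text.
#' @export
reassemble_request <- function(fragments) {
  if (length(fragments) == 0L) {
    pr_stop("no fragments to reassemble", "pseudoreg_fragment_error")
  }
  m <- regmatches(fragments,
                  regexec("^rid=([0-9a-f]{16})&idx=([0-9]{6})&tot=([0-9]{6})&frag=(.*)$",
                          fragments))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    pr_stop("malformed fragment framing", "pseudoreg_fragment_error")
  }
  rid <- vapply(m, `[`, character(1), 2L)
  idx <- as.integer(vapply(m, `[`, character(1), 3L))
  tot <- as.integer(vapply(m, `[`, character(1), 4L))
  chunk <- vapply(m, `[`, character(1), 5L)
  if (length(unique(rid)) != 1L) {
    pr_stop("fragments belong to different requests", "pseudoreg_fragment_error")
  }
  if (length(unique(tot)) != 1L) {
    pr_stop("fragments disagree on total count", "pseudoreg_fragment_error")
  }
  n <- tot[1]
  for (i in unique(idx[duplicated(idx)])) {
    if (length(unique(chunk[idx == i])) > 1L) {
      pr_stop(sprintf("conflicting content for duplicate fragment index %d", i),
              "pseudoreg_fragment_error")
    }
  }
  keep <- !duplicated(idx)
  idx <- idx[keep]
  chunk <- chunk[keep]
  missing <- setdiff(seq_len(n), idx)
  if (length(missing)) {
    pr_stop(sprintf("missing fragment index(es): %s",
                    paste(missing, collapse = ", ")),
            "pseudoreg_fragment_error")
  }
  if (any(idx > n)) {
    pr_stop("fragment index exceeds total count", "pseudoreg_fragment_error")
  }
  paste(chunk[order(idx)], collapse = "")
}
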