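# Sealed two-component access tokens.
#
# A token carries username, password, a per-channel replay counter and
# structured payload data P through the client between backend components.
# It is built of exactly two encrypted components:
#   component 1: the fresh symmetric key K1, encrypted for the receiver with
#                RSA-2048 OAEP (the receiver's public key K2);
#   component 2: the canonical serialization of the token payload, encrypted
#                and integrity protected under K1 (AES-256-CBC with
#                HMAC-SHA256 in encrypt-then-MAC composition; both keys are
#                derived from K1 with domain-separated SHA-256).
# Any single-byte modification of either component is rejected with an
# integrity error, never surfaced as a garbled payload.

CIPHER_SUITE <- "RSA-2048-OAEP/AES-256-CBC/HMAC-SHA256"

#' Generate an asymmetric key pair for a component
#'
#' @param component_id text identifier of the owning component.
#' @param bits RSA modulus size.
#' @return object of class `component_keypair` with the private key and the
#'   shareable public key. The private key is never serialized into tokens or
#'   transcripts.
#' @export
make_keypair <- function(component_id, bits = 2048L) {
  key <- openssl::rsa_keygen(bits)
  structure(list(component_id = component_id, key = key,
                 pubkey = key$pubkey),
            class = "component_keypair")
}

#' Key ring of one component in a peer-to-peer topology
#'
#' Each component manages its own key pair plus the public key of every
#' declared peer; there is no central key authority.
#'
#' @param own a [make_keypair()] result.
#' @param peers named list `component_id -> public key`.
#' @return object of class `component_keyring`.
#' @export
keyring <- function(own, peers = list()) {
  stopifnot(inherits(own, "component_keypair"))
  structure(list(own = own, peers = peers), class = "component_keyring")
}

#' Token payload: credentials, replay counter and content
#'
#' @param username,password end-user credentials travelling inside the sealed
#'   token (non-delegated authentication is re-verified at every receiver).
#' @param counter per sender-to-receiver channel replay counter; a receiver
#'   accepts a token only if its counter is strictly greater than the last
#'   accepted one on that channel.
#' @param payload structured key-value content P (operation name, identifier
#'   mappings, document content, ...).
#' @return object of class `token_payload`.
#' @export
token_payload <- function(username, password, counter, payload = list()) {
  if (!is.numeric(counter) || length(counter) != 1L || counter < 0) {
    pr_stop("counter must be a single non-negative number",
            "pseudoreg_usage_error")
  }
  structure(list(username = username, password = password,
                 counter = as.numeric(counter), payload = payload),
            class = "token_payload")
}

derive_keys <- function(k1) {
  list(enc = openssl::sha256(c(k1, charToRaw("enc"))),
       mac = openssl::sha256(c(k1, charToRaw("mac"))))
}

canonical_payload_bytes <- function(sender_id, receiver_id, payload) {
  # fixed field order so serialization (and hence the MAC) is deterministic
  charToRaw(to_json_chr(list(
    sender = sender_id,
    receiver = receiver_id,
    username = payload$username,
    password = payload$password,
    counter = payload$counter,
    payload = payload$payload
  )))
}

#' Seal a token for a peer component
#'
#' Generates a fresh symmetric key K1 per token, so sealing identical payloads
#' twice yields byte-distinct tokens.
#'
#' @param ring the sender's [keyring()].
#' @param receiver_id peer to seal for; its public key must be on the ring.
#' @param payload a [token_payload()].
#' @param rng_seed optional seed making K1/IV generation reproducible (testing
#'   only); `NULL` uses the OS random source.
#' @return object of class `sealed_token` with `sender_id`, `receiver_id` and
#'   exactly two encrypted `components`.
#' @export
seal_token <- function(ring, receiver_id, payload, rng_seed = NULL) {
  pk <- ring$peers[[receiver_id]]
  if (is.null(pk)) {
    pr_stop(sprintf("no public key for receiver '%s' on the ring", receiver_id),
            "pseudoreg_key_lookup_error")
  }
  rnd <- if (is.null(rng_seed)) {
    list(k1 = openssl::rand_bytes(32L), iv = openssl::rand_bytes(16L))
  } else {
    with_seed(rng_seed, list(k1 = random_raw(32L), iv = random_raw(16L)))
  }
  keys <- derive_keys(rnd$k1)
  pt <- canonical_payload_bytes(ring$own$component_id, receiver_id, payload)
  ct <- openssl::aes_cbc_encrypt(pt, key = keys$enc, iv = rnd$iv)
  body <- c(rnd$iv, unclass(ct))
  mac <- hmac_sha256(keys$mac, body)
  component_2 <- c(body, unclass(mac))
  component_1 <- openssl::rsa_encrypt(rnd$k1, pk)
  structure(list(sender_id = ring$own$component_id,
                 receiver_id = receiver_id,
                 suite = CIPHER_SUITE,
                 components = list(unclass(component_1), component_2)),
            class = "sealed_token")
}

#' @export
print.sealed_token <- function(x, ...) {
  cat(sprintf("<sealed_token %s -> %s, 2 components (%d + %d bytes), %s>\n",
              x$sender_id, x$receiver_id, length(x$components[[1]]),
              length(x$components[[2]]), x$suite))
  invisible(x)
}

#' Per-channel replay state of a receiver
#'
#' Tracks the highest accepted counter per sender; monotonically
#' non-decreasing.
#'
#' @return an environment-backed object of class `replay_state`.
#' @export
replay_state <- function() {
  structure(new.env(parent = emptyenv()), class = "replay_state")
}

replay_last <- function(replay, sender_id) {
  get0(sender_id, envir = replay, ifnotfound = -1)
}

#' Open a sealed token, enforcing integrity and replay protection
#'
#' Checks run in order: the token must be addressed to this ring's component
#' (wrong receiver fails decryption), both components must verify (any
#' tampering raises an integrity error), and the counter must be strictly
#' greater than the last accepted counter from this sender (otherwise a
#' distinct replay rejection is raised). Only after all checks does the replay
#' state advance.
#'
#' @param ring the receiver's [keyring()].
#' @param token a [seal_token()] result.
#' @param replay the receiver's [replay_state()].
#' @return the verified [token_payload()].
#' @export
open_token <- function(ring, token, replay) {
  if (!identical(token$receiver_id, ring$own$component_id)) {
    pr_stop(sprintf("token sealed for '%s' cannot be decrypted by '%s'",
                    token$receiver_id, ring$own$component_id),
            "pseudoreg_decrypt_error")
  }
  k1 <- tryCatch(
    openssl::rsa_decrypt(token$components[[1]], ring$own$key),
    error = function(e) {
      pr_stop("token component 1 failed decryption/integrity check",
              "pseudoreg_integrity_error")
    }
  )
  if (length(k1) != 32L) {
    pr_stop("token component 1 failed decryption/integrity check",
            "pseudoreg_integrity_error")
  }
  comp2 <- token$components[[2]]
  if (length(comp2) < 16L + 32L + 16L) {
    pr_stop("token component 2 truncated", "pseudoreg_integrity_error")
  }
  keys <- derive_keys(k1)
  body <- comp2[seq_len(length(comp2) - 32L)]
  mac <- comp2[(length(comp2) - 31L):length(comp2)]
  expect <- hmac_sha256(keys$mac, body)
  if (!identical(as.raw(mac), as.raw(unclass(expect)))) {
    pr_stop("token component 2 failed integrity check",
            "pseudoreg_integrity_error")
  }
  iv <- body[1:16]
  ct <- body[17:length(body)]
  pt <- tryCatch(
    openssl::aes_cbc_decrypt(ct, key = keys$enc, iv = iv),
    error = function(e) {
      pr_stop("token component 2 failed integrity check",
              "pseudoreg_integrity_error")
    }
  )
  obj <- tryCatch(from_json_chr(rawToChar(pt)), error = function(e) {
    pr_stop("token component 2 failed integrity check",
            "pseudoreg_integrity_error")
  })
  if (!identical(obj$sender, token$sender_id) ||
      !identical(obj$receiver, token$receiver_id)) {
    pr_stop("token envelope does not match sealed addressing",
            "pseudoreg_integrity_error")
  }
  last <- replay_last(replay, token$sender_id)
  if (obj$counter <= last) {
    pr_stop(sprintf(
      "replay rejected: counter %s from '%s' not greater than last accepted %s",
      format(obj$counter), token$sender_id, format(last)),
      "pseudoreg_replay_error")
  }
  assign(token$sender_id, obj$counter, envir = replay)
  token_payload(obj$username, obj$password, obj$counter,
                payload = obj$payload %||% list())
}

#' Encode a sealed token for the HTTP request line
#'
#' Serializes the token and encodes it with unpadded base64url (RFC 4648), so
#' the result contains URL-unreserved characters only.
#' `decode_request_line()` inverts the encoding.
#'
#' @param token a [seal_token()] result.
#' @return a URL-safe character scalar.
#' @export
encode_request_line <- function(token) {
  stopifnot(inherits(token, "sealed_token"))
  json <- to_json_chr(list(
    s = token$sender_id, r = token$receiver_id, v = token$suite,
    c1 = base64url_encode(token$components[[1]]),
    c2 = base64url_encode(token$components[[2]])
  ))
  base64url_encode(charToRaw(json))
}

#' @rdname encode_request_line
#' @param text encoded request-line text.
#' @export
decode_request_line <- function(text) {
  obj <- tryCatch(from_json_chr(rawToChar(base64url_decode(text))),
                  error = function(e) {
                    pr_stop("malformed request-line token encoding",
                            "pseudoreg_decode_error")
                  })
  if (!all(c("s", "r", "c1", "c2") %in% names(obj))) {
    pr_stop("malformed request-line token encoding", "pseudoreg_decode_error")
  }
  structure(list(sender_id = obj$s, receiver_id = obj$r,
                 suite = obj$v %||% CIPHER_SUITE,
                 components = list(base64url_decode(obj$c1),
                                   base64url_decode(obj$c2))),
            class = "sealed_token")
}
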