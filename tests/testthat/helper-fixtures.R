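# Shared fixtures. RSA key generation is comparatively slow, so one set of
# component key pairs is generated per test run and reused; keys are
# deployment material, independent of the data under test.

test_keys <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(primary = make_keypair("primary"),
                     secondary = make_keypair("secondary"),
                     mapping = make_keypair("mapping"))
    }
    cache
  }
})

# a pair of peer keyrings for raw token tests
test_rings <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ka <- make_keypair("alpha")
      kb <- make_keypair("beta")
      cache <<- list(
        alpha = keyring(ka, list(beta = kb$pubkey, alpha = ka$pubkey)),
        beta = keyring(kb, list(alpha = ka$pubkey))
      )
    }
    cache
  }
})

build_test_system <- function(n_subjects = 6L, seed = 11L,
                              mode = "indirect", ...) {
  reg <- generate_registry(generator_spec(n_subjects = n_subjects, seed = seed))
  registry_system(reg, mode = mode, seed = seed, keys = test_keys(), ...)
}

monitor_client <- function(system) {
  registry_client(system, "monitor-1", "pw-monitor-1")
}

# deterministic 32-hex pseudonym-like strings for substring scans
random_hex_for_test <- function(seed) {
  substr(paste(as.character(openssl::sha256(charToRaw(paste0("t", seed)))),
               collapse = ""), 1, 32)
}

# valid base64url text that is not a token serialization
base64url_smoke <- function(text) {
  s <- openssl::base64_encode(charToRaw(text))
  gsub("=+$", "", chartr("+/", "-_", s))
}

# Independent brute-force join oracle: exhaustive double loop over all
# pseudonym pairs, no shared code with integrate_pools().
brute_force_join <- function(master_pool, payload_pool, mapping = NULL) {
  out <- list()
  for (a in names(master_pool$entries)) {
    for (b in names(payload_pool$entries)) {
      linked <- if (is.null(mapping)) {
        identical(a, b)
      } else {
        any(mapping$pairs$pseudonym_a == a & mapping$pairs$pseudonym_b == b)
      }
      if (linked) {
        out[[length(out) + 1L]] <-
          c(master_pool$entries[[a]], payload_pool$entries[[b]])
      }
    }
  }
  out
}

# order-insensitive multiset signature of records given as named lists
record_signatures <- function(records) {
  sort(vapply(records, function(r) {
    r <- r[order(names(r))]
    paste(names(r), vapply(r, as.character, character(1)),
          sep = "=", collapse = ";")
  }, character(1)))
}

dataset_signatures <- function(ds) {
  recs <- lapply(seq_len(nrow(ds$data)), function(i) {
    as.list(ds$data[i, setdiff(names(ds$data), "subject_key"), drop = FALSE])
  })
  record_signatures(recs)
}
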