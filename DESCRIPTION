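Package: pseudoreg
Title: Two-Tier Pseudonymization and Client-Side Joining for Distributed
    Registry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for managing pseudonymized biomedical registry data that is
    split across physically separated backend services. Implements one-tier and
    two-tier separation of identifying (master) and payload (clinical)
    attributes, a trusted mapping service that holds only pseudonym pairs,
    sealed two-component access tokens (hybrid RSA/AES with per-channel replay
    counters) that provide single sign-on and a confidential server-to-server
    channel routed via the client, URL-safe token encoding with request-line
    fragmentation, role-based access control with site filtering and append-only
    audit trails, and client-side join protocols that reconstruct integrated
    per-subject views without any server ever holding the joined data and
    without the client ever seeing internal pseudonyms. Includes a deterministic
    synthetic registry generator and an invariant verifier.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    jsonlite,
    openssl,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
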