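#' @import R6
NULL

# Common machinery of every party in the distributed system: key ring,
# per-channel outbound counters, replay state, user directory with salted
# credential hashes, sessions and an append-only audit trail. Each component
# authenticates and authorizes autonomously (non-delegated): tokens carry the
# user's credentials and every receiver re-verifies them.
ServiceBase <- R6::R6Class("ServiceBase",
  public = list(
    component_id = NULL,
    ring = NULL,
    replay = NULL,

    initialize = function(component_id) {
      self$component_id <- component_id
      self$replay <- replay_state()
      private$counters <- new.env(parent = emptyenv())
      private$sessions <- new.env(parent = emptyenv())
      private$audit_events <- list()
      private$users <- data.frame(username = character(),
                                  salt = character(),
                                  secret_hash = character(),
                                  role = character(), site = character(),
                                  stringsAsFactors = FALSE)
    },

    set_ring = function(ring) {
      stopifnot(inherits(ring, "component_keyring"))
      self$ring <- ring
      invisible(self)
    },

    add_user = function(username, password, role, site) {
      if (username %in% private$users$username) {
        pr_stop(sprintf("user '%s' already exists", username),
                "pseudoreg_usage_error")
      }
      salt <- random_hex(1L, 8L)
      private$users <- rbind(private$users, data.frame(
        username = username, salt = salt,
        secret_hash = sha256_hex(paste0(salt, password)),
        role = role, site = site, stringsAsFactors = FALSE
      ))
      invisible(self)
    },

    user_record = function(username) {
      i <- match(username, private$users$username)
      if (is.na(i)) NULL else as.list(private$users[i, ])
    },

    check_credentials = function(username, password) {
      u <- self$user_record(username)
      !is.null(u) && identical(u$secret_hash, sha256_hex(paste0(u$salt, password)))
    },

    # Interactive login: issues a fresh random session id. Unknown user and
    # wrong secret are indistinguishable denials; every outcome is audited.
    authenticate = function(username, password) {
      if (!self$check_credentials(username, password)) {
        self$audit(username, "login", NA_character_, "denied")
        pr_stop("authentication denied", "pseudoreg_auth_error")
      }
      sid <- random_hex(1L, 16L)
      assign(sid, username, envir = private$sessions)
      self$audit(username, "login", NA_character_, "ok")
      sid
    },

    session_user = function(session_id) {
      u <- get0(session_id, envir = private$sessions, ifnotfound = NULL)
      if (is.null(u)) {
        pr_stop("unknown or expired session", "pseudoreg_auth_error")
      }
      u
    },

    # Credential re-verification for token-borne requests (no session).
    verify_token_user = function(username, password) {
      if (!self$check_credentials(username, password)) {
        self$audit(username, "login", NA_character_, "denied")
        pr_stop("authentication denied", "pseudoreg_auth_error")
      }
      self$audit(username, "login", NA_character_, "ok")
      invisible(username)
    },

    audit = function(actor, operation, target, outcome) {
      private$audit_events[[length(private$audit_events) + 1L]] <- list(
        seq = length(private$audit_events) + 1L,
        actor = actor %||% NA_character_,
        operation = operation,
        target = target %||% NA_character_,
        backend = self$component_id,
        outcome = outcome
      )
      invisible(self)
    },

    audit_log = function() {
      if (!length(private$audit_events)) {
        return(data.frame(seq = integer(), actor = character(),
                          operation = character(), target = character(),
                          backend = character(), outcome = character(),
                          stringsAsFactors = FALSE))
      }
      do.call(rbind, lapply(private$audit_events, function(e) {
        data.frame(seq = e$seq, actor = e$actor, operation = e$operation,
                   target = e$target, backend = e$backend,
                   outcome = e$outcome, stringsAsFactors = FALSE)
      }))
    },

    audit_jsonl = function(path = NULL) {
      lines <- vapply(private$audit_events, to_json_chr, character(1))
      if (is.null(path)) return(lines)
      writeLines(lines, path)
      invisible(lines)
    },

    # Strictly increasing outbound counter per receiver channel.
    next_counter = function(receiver_id) {
      v <- get0(receiver_id, envir = private$counters, ifnotfound = 0) + 1
      assign(receiver_id, v, envir = private$counters)
      v
    },

    seal_for = function(receiver_id, username, password, payload = list()) {
      seal_token(self$ring, receiver_id,
                 token_payload(username, password,
                               self$next_counter(receiver_id), payload))
    },

    open_from = function(token) {
      open_token(self$ring, token, self$replay)
    },

    users_df = function() private$users
  ),
  private = list(
    counters = NULL,
    sessions = NULL,
    audit_events = NULL,
    users = NULL
  )
)

#' Backend data service (primary or secondary)
#'
#' A stateful party holding one of the separated data pools: the primary
#' service stores subject root nodes with master data, the secondary service
#' stores payload documents. Data is modeled as a tree of document nodes
#' keyed by pseudonyms of the service's own namespace; a backend refuses to
#' store data classes outside its declared set, which is what physically
#' enforces separation. Includes per-request authentication, RBAC with site
#' filtering, temporary-identifier issuance, optional encryption of master
#' data at rest, and an append-only audit trail.
#'
#' @export
BackendService <- R6::R6Class("BackendService",
  inherit = ServiceBase,
  public = list(
    namespace = NULL,
    accepted_classes = NULL,
    rbac = NULL,
    site_restricted_roles = NULL,
    encrypt_at_rest = FALSE,
    mutation_count = 0L,
    substitute_temp_ids = TRUE,

    #' @param component_id,namespace identity of the service.
    #' @param accepted_classes data classes this store may hold (e.g.
    #'   `"master"` for the primary, `c("clinical", "specimen")` for the
    #'   secondary).
    #' @param rbac RBAC matrix, see [default_rbac_matrix()].
    #' @param site_restricted_roles see [default_site_restricted_roles()].
    #' @param encrypt_at_rest encrypt master-class attribute values in the
    #'   persistent store.
    #' @param master_data_key 32-byte raw symmetric key; required (startup
    #'   refusal otherwise) when `encrypt_at_rest` is `TRUE`.
    initialize = function(component_id, namespace, accepted_classes,
                          rbac = default_rbac_matrix(),
                          site_restricted_roles = default_site_restricted_roles(),
                          encrypt_at_rest = FALSE, master_data_key = NULL) {
      super$initialize(component_id)
      self$namespace <- namespace
      self$accepted_classes <- accepted_classes
      self$rbac <- rbac
      self$site_restricted_roles <- site_restricted_roles
      self$encrypt_at_rest <- isTRUE(encrypt_at_rest)
      if (self$encrypt_at_rest) {
        if (is.null(master_data_key) || !is.raw(master_data_key) ||
            length(master_data_key) != 32L) {
          pr_stop("encrypt_at_rest requires a 32-byte master data key",
                  "pseudoreg_key_lookup_error")
        }
        private$master_key <- master_data_key
      }
      private$store <- new.env(parent = emptyenv())
      private$temp_map <- new.env(parent = emptyenv())
      private$label_index <- new.env(parent = emptyenv())
    },

    authorize = function(username, operation, data_class,
                         target_site = NA_character_,
                         target = NA_character_) {
      u <- self$user_record(username)
      if (is.null(u)) {
        self$audit(username, operation, target, "denied")
        return(FALSE)
      }
      ok <- rbac_decision(self$rbac, u$role, operation, data_class,
                          user_site = u$site, target_site = target_site,
                          site_restricted_roles = self$site_restricted_roles)
      if (!ok) self$audit(username, operation, target, "denied")
      ok
    },

    has_node = function(node_id) {
      !is.null(get0(node_id, envir = private$store, ifnotfound = NULL))
    },

    node_ids = function() ls(private$store),

    store_size = function() length(ls(private$store)),

    children_of = function(node_id) {
      ids <- ls(private$store)
      ids[vapply(ids, function(i) {
        identical(get(i, envir = private$store)$parent, node_id)
      }, logical(1))]
    },

    # Raw node record (content stays encrypted if encrypted at rest).
    node_record = function(node_id) {
      get0(node_id, envir = private$store, ifnotfound = NULL)
    },

    create_node = function(actor, doc_type, content, site,
                           data_class, parent = NULL, node_id = NULL) {
      if (!data_class %in% self$accepted_classes) {
        pr_stop(sprintf("backend '%s' does not accept data class '%s'",
                        self$component_id, data_class),
                "pseudoreg_separation_error")
      }
      node_id <- node_id %||% random_hex(1L)
      if (self$has_node(node_id)) {
        pr_stop("node id already exists", "pseudoreg_usage_error")
      }
      node <- list(node_id = node_id, parent = parent, doc_type = doc_type,
                   site = site, data_class = data_class)
      node$content <- private$content_at_rest(content, data_class)
      assign(node_id, node, envir = private$store)
      if (!is.null(content$record_label)) {
        assign(content$record_label, node_id, envir = private$label_index)
      }
      self$mutation_count <- self$mutation_count + 1L
      self$audit(actor, "create", node_id, "ok")
      node_id
    },

    read_node = function(actor, node_id, audit = TRUE) {
      node <- self$node_record(node_id)
      if (is.null(node)) {
        pr_stop(sprintf("node '%s' not found", node_id),
                "pseudoreg_not_found_error")
      }
      if (audit) self$audit(actor, "read", node_id, "ok")
      node$content <- private$content_clear(node$content, node$data_class)
      node
    },

    update_node = function(actor, node_id, content) {
      node <- self$node_record(node_id)
      if (is.null(node)) {
        pr_stop(sprintf("node '%s' not found", node_id),
                "pseudoreg_not_found_error")
      }
      node$content <- private$content_at_rest(content, node$data_class)
      assign(node_id, node, envir = private$store)
      self$mutation_count <- self$mutation_count + 1L
      self$audit(actor, "update", node_id, "ok")
      invisible(node_id)
    },

    delete_node = function(actor, node_id, cascade = FALSE) {
      node <- self$node_record(node_id)
      if (is.null(node)) {
        pr_stop(sprintf("node '%s' not found", node_id),
                "pseudoreg_not_found_error")
      }
      kids <- self$children_of(node_id)
      if (length(kids) && !cascade) {
        pr_stop("node has children; deletion requires an explicit cascade flag",
                "pseudoreg_usage_error")
      }
      for (k in kids) self$delete_node(actor, k, cascade = TRUE)
      rm(list = node_id, envir = private$store)
      self$mutation_count <- self$mutation_count + 1L
      self$audit(actor, "delete", node_id, "ok")
      invisible(node_id)
    },

    find_by_label = function(label) {
      id <- get0(label, envir = private$label_index, ifnotfound = NULL)
      if (!is.null(id) && self$has_node(id)) id else NULL
    },

    # Fresh temporary identifiers for internal pseudonyms. Temp ids carry a
    # "tmp-" prefix, so they can never equal an internal pseudonym. In
    # indirect mode the association travels only inside sealed tokens and the
    # server stays stateless; in direct mode it is persisted for later
    # resolution by peers.
    issue_temp_ids = function(ids, mode = c("indirect", "direct")) {
      mode <- match.arg(mode)
      if (!self$substitute_temp_ids) {
        # fault-injection hook for the verifier: internal pseudonyms leak
        temp <- ids
        names(temp) <- ids
        return(temp)
      }
      temp <- paste0("tmp-", random_hex(length(ids)))
      names(temp) <- ids
      if (mode == "direct") {
        for (i in seq_along(ids)) {
          assign(temp[[i]], ids[[i]], envir = private$temp_map)
        }
      }
      temp
    },

    temp_map_size = function() length(ls(private$temp_map)),

    # Direct mode: resolve a persisted temporary mapping; retired on use
    # (delete-on-successful-resolution policy).
    resolve_temp = function(temp_id, retire = TRUE) {
      v <- get0(temp_id, envir = private$temp_map, ifnotfound = NULL)
      if (is.null(v)) {
        pr_stop(sprintf("temporary mapping '%s' absent or already retired",
                        temp_id), "pseudoreg_not_found_error")
      }
      if (retire) rm(list = temp_id, envir = private$temp_map)
      v
    },

    # Persistent serialization of the store (JSON-lines). With encryption at
    # rest enabled, master-class attribute values appear only as ciphertext.
    persist_store = function(path = NULL) {
      lines <- vapply(ls(private$store), function(id) {
        to_json_chr(get(id, envir = private$store))
      }, character(1), USE.NAMES = FALSE)
      if (is.null(path)) return(lines)
      writeLines(lines, path)
      invisible(lines)
    }
  ),
  private = list(
    store = NULL,
    temp_map = NULL,
    label_index = NULL,
    master_key = NULL,

    content_at_rest = function(content, data_class) {
      if (!self$encrypt_at_rest || !identical(data_class, "master")) {
        return(content)
      }
      keys <- derive_keys(private$master_key)
      iv <- openssl::rand_bytes(16L)
      pt <- charToRaw(to_json_chr(content))
      ct <- openssl::aes_cbc_encrypt(pt, key = keys$enc, iv = iv)
      body <- c(iv, unclass(ct))
      list(.enc = base64url_encode(c(body, unclass(hmac_sha256(keys$mac, body)))))
    },

    content_clear = function(content, data_class) {
      if (is.null(content$.enc)) return(content)
      blob <- base64url_decode(content$.enc)
      keys <- derive_keys(private$master_key)
      body <- blob[seq_len(length(blob) - 32L)]
      mac <- blob[(length(blob) - 31L):length(blob)]
      if (!identical(as.raw(mac), as.raw(unclass(hmac_sha256(keys$mac, body))))) {
        pr_stop("master data store failed integrity check",
                "pseudoreg_integrity_error")
      }
      pt <- openssl::aes_cbc_decrypt(body[17:length(body)], key = keys$enc,
                                     iv = body[1:16])
      from_json_chr(rawToChar(pt))
    }
  )
)

#' Trusted mapping service
#'
#' The third party of the two-tier architecture: it stores bare pseudonym
#' pairs linking the primary and secondary namespaces and translates
#' identifiers between them. It holds no attribute values, authenticates end
#' users from token credentials, and audits every translation.
#'
#' @export
MappingService <- R6::R6Class("MappingService",
  inherit = ServiceBase,
  public = list(
    namespace_a = NULL,
    namespace_b = NULL,

    #' @param component_id service identity.
    #' @param namespace_a,namespace_b the linked namespaces.
    initialize = function(component_id, namespace_a, namespace_b) {
      super$initialize(component_id)
      if (identical(namespace_a, namespace_b)) {
        pr_stop("mapping service requires two distinct namespaces",
                "pseudoreg_namespace_error")
      }
      self$namespace_a <- namespace_a
      self$namespace_b <- namespace_b
      private$a_to_b <- new.env(parent = emptyenv())
      private$b_to_a <- new.env(parent = emptyenv())
    },

    add_pair = function(pseudonym_a, pseudonym_b) {
      if (!is.null(get0(pseudonym_a, envir = private$a_to_b, ifnotfound = NULL)) ||
          !is.null(get0(pseudonym_b, envir = private$b_to_a, ifnotfound = NULL))) {
        pr_stop("each pseudonym may appear in at most one pair",
                "pseudoreg_mapping_error")
      }
      assign(pseudonym_a, pseudonym_b, envir = private$a_to_b)
      assign(pseudonym_b, pseudonym_a, envir = private$b_to_a)
      invisible(self)
    },

    load_mapping = function(mapping) {
      stopifnot(inherits(mapping, "mapping_table"))
      for (i in seq_len(nrow(mapping$pairs))) {
        self$add_pair(mapping$pairs$pseudonym_a[i], mapping$pairs$pseudonym_b[i])
      }
      invisible(self)
    },

    lookup_b = function(pseudonym_a) {
      get0(pseudonym_a, envir = private$a_to_b, ifnotfound = NULL)
    },

    lookup_a = function(pseudonym_b) {
      get0(pseudonym_b, envir = private$b_to_a, ifnotfound = NULL)
    },

    # Create a missing counterpart in namespace B (used when a first payload
    # document is created for a subject with no secondary-side pseudonym yet).
    ensure_pair = function(pseudonym_a, actor = NA_character_) {
      b <- self$lookup_b(pseudonym_a)
      if (is.null(b)) {
        b <- random_hex(1L)
        self$add_pair(pseudonym_a, b)
        self$audit(actor, "create", pseudonym_a, "ok")
      }
      b
    },

    n_pairs = function() length(ls(private$a_to_b)),

    as_mapping_table = function() {
      a <- ls(private$a_to_b)
      mapping_table(
        data.frame(pseudonym_a = a,
                   pseudonym_b = vapply(a, function(x) {
                     get(x, envir = private$a_to_b)
                   }, character(1), USE.NAMES = FALSE),
                   stringsAsFactors = FALSE),
        self$namespace_a, self$namespace_b
      )
    },

    # Namespace translation of a batch of (temp_id, pseudonym) associations
    # arriving in a sealed token from the primary. Missing pairs become
    # per-id dangling-link markers, never a hard failure. Audited per id.
    translate_pairs = function(actor, pairs) {
      lapply(pairs, function(p) {
        b <- self$lookup_b(p$pseudonym)
        self$audit(actor, "translate", p$pseudonym,
                   if (is.null(b)) "error" else "ok")
        if (is.null(b)) {
          list(temp_id = p$temp_id, status = "dangling")
        } else {
          list(temp_id = p$temp_id, status = "ok", pseudonym = b)
        }
      })
    }
  ),
  private = list(
    a_to_b = NULL,
    b_to_a = NULL
  )
)
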