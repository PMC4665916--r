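#' Assemble a complete three-party registry system
#'
#' Builds the minimal two-tier deployment: a primary service holding master
#' data (root nodes), a secondary service holding payload documents, and a
#' mapping service holding only the pseudonym pairs that link the two
#' namespaces. The integrated registry is two-tier pseudonymized, distributed
#' over the three parties, user accounts are replicated to every component
#' (each authenticates autonomously), and RSA key pairs are exchanged in a
#' peer-to-peer topology.
#'
#' Each subject root additionally carries a generated client-facing record
#' label (`S0001`, ...) as a master-data attribute, so clients can address
#' subjects without ever touching internal pseudonyms.
#'
#' @param registry output of [generate_registry()] (or a compatible list with
#'   `dataset`, `users`, `documents`).
#' @param mode `"indirect"` (server-to-server messages routed via the client
#'   inside sealed tokens; servers stay stateless) or `"direct"` (peers
#'   synchronize persisted temporary identifiers directly).
#' @param seed integer seed for pseudonym generation.
#' @param encrypt_master encrypt master-data attribute values at rest on the
#'   primary.
#' @param substitute_temp_ids set `FALSE` only for fault-injection testing:
#'   internal pseudonyms then leak to clients and the verifier must flag it.
#' @param keys optional named list of [make_keypair()] objects
#'   (`primary`, `secondary`, `mapping`) to reuse key material.
#' @return an object of class `registry_system`: list with `primary`,
#'   `secondary`, `mapping`, `mode`, `pools` (the pseudonymized pools and
#'   mapping table for oracle comparisons), `labels` (record label ->
#'   subject_key, for test oracles only) and `registry`.
#' @export
registry_system <- function(registry = generate_registry(),
                            mode = c("indirect", "direct"),
                            seed = 1L,
                            encrypt_master = TRUE,
                            substitute_temp_ids = TRUE,
                            keys = NULL) {
  mode <- match.arg(mode)
  dataset <- registry$dataset
  ns_a <- "ns-primary"
  ns_b <- "ns-secondary"

  tiers <- pseudonymize_two_tier(dataset, ns_a, ns_b, rng_seed = seed)

  keys <- keys %||% list(primary = make_keypair("primary"),
                         secondary = make_keypair("secondary"),
                         mapping = make_keypair("mapping"))

  master_key <- if (encrypt_master) {
    with_seed(seed + 1L, random_raw(32L))
  } else NULL

  primary <- BackendService$new("primary", ns_a, accepted_classes = "master",
                                encrypt_at_rest = encrypt_master,
                                master_data_key = master_key)
  secondary <- BackendService$new("secondary", ns_b,
                                  accepted_classes = c("clinical", "specimen"))
  mapping <- MappingService$new("mapping", ns_a, ns_b)

  peers_of <- function(own) {
    ids <- setdiff(c("primary", "secondary", "mapping"), own)
    setNames(lapply(ids, function(i) keys[[i]]$pubkey), ids)
  }
  primary$set_ring(keyring(keys$primary, peers_of("primary")))
  secondary$set_ring(keyring(keys$secondary, peers_of("secondary")))
  mapping$set_ring(keyring(keys$mapping, peers_of("mapping")))

  primary$substitute_temp_ids <- isTRUE(substitute_temp_ids)
  secondary$substitute_temp_ids <- isTRUE(substitute_temp_ids)

  for (i in seq_len(nrow(registry$users))) {
    u <- registry$users[i, ]
    primary$add_user(u$username, u$password, u$role, u$site)
    secondary$add_user(u$username, u$password, u$role, u$site)
    mapping$add_user(u$username, u$password, u$role, u$site)
  }

  # distribute the separated pools over the parties
  recs <- dataset_records(dataset)
  psn_a <- names(tiers$master_pool$entries) %||% character(0)
  psn_b <- names(tiers$payload_pool$entries) %||% character(0)
  labels <- character(0)
  site_col <- if ("site" %in% names(dataset$schema)) "site" else NULL
  key_to_b <- setNames(psn_b, vapply(recs, `[[`, character(1), "subject_key"))
  for (i in seq_along(recs)) {
    label <- sprintf("S%04d", i)
    labels[label] <- recs[[i]]$subject_key
    site <- if (is.null(site_col)) NA_character_ else
      as.character(recs[[i]]$attrs[[site_col]])
    master_content <- c(tiers$master_pool$entries[[psn_a[i]]],
                        list(record_label = label))
    primary$create_node("system", "subject", master_content, site, "master",
                        node_id = psn_a[i])
    secondary$create_node("system", "record",
                          tiers$payload_pool$entries[[psn_b[i]]],
                          site, "clinical", node_id = psn_b[i])
  }
  mapping$load_mapping(tiers$mapping)

  site_of_key <- setNames(
    vapply(recs, function(r) {
      if (is.null(site_col)) NA_character_ else as.character(r$attrs[[site_col]])
    }, character(1)),
    vapply(recs, `[[`, character(1), "subject_key")
  )
  for (doc in registry$documents %||% list()) {
    b <- key_to_b[[doc$subject_key]]
    if (is.null(b)) next
    secondary$create_node("system", doc$doc_type, doc$content,
                          site_of_key[[doc$subject_key]], doc$data_class,
                          parent = b)
  }

  structure(list(primary = primary, secondary = secondary, mapping = mapping,
                 mode = mode, pools = tiers, labels = labels,
                 registry = registry),
            class = "registry_system")
}

#' @export
print.registry_system <- function(x, ...) {
  cat(sprintf(
    "<registry_system mode=%s: primary %d nodes, secondary %d nodes, mapping %d pairs>\n",
    x$mode, x$primary$store_size(), x$secondary$store_size(),
    x$mapping$n_pairs()))
  invisible(x)
}

#' All internal pseudonyms of a system
#'
#' The identifiers that must never be visible to clients: every pseudonym of
#' both backend namespaces, from the stores and the mapping table.
#'
#' @param system a [registry_system()].
#' @return character vector of pseudonym values.
#' @export
internal_pseudonyms <- function(system) {
  mt <- system$mapping$as_mapping_table()
  unique(c(system$primary$node_ids(), system$secondary$node_ids(),
           mt$pairs$pseudonym_a, mt$pairs$pseudonym_b))
}

#' Attempt the forbidden join from a single party's state
#'
#' The separation invariant states that no single component can produce any
#' (identifying, payload) attribute pairing on its own. This function plays
#' the adversary: given one party's complete persistent state, it attempts
#' the join and returns every linked pair it can construct. For a correctly
#' separated system the result has zero rows for every party: the primary
#' holds no payload values, the secondary no identifying values, and the
#' mapping service holds pairs but no attributes at all.
#'
#' @param party a [BackendService] or [MappingService].
#' @return data.frame with columns `identifying_attr`, `identifying_value`,
#'   `payload_attr`, `payload_value` (zero rows when separation holds).
#' @export
adversary_view <- function(party) {
  empty <- data.frame(identifying_attr = character(),
                      identifying_value = character(),
                      payload_attr = character(),
                      payload_value = character(),
                      stringsAsFactors = FALSE)
  if (inherits(party, "MappingService")) {
    # pairs carry no attribute values: nothing to join
    return(empty)
  }
  stopifnot(inherits(party, "BackendService"))
  rows <- list()
  ids <- party$node_ids()
  classify <- function(node) {
    if (identical(node$data_class, "master")) "identifying" else "payload"
  }
  # group nodes by subject linkage visible within this single store:
  # a node and its ancestors belong to the same subject
  root_of <- function(id) {
    node <- party$node_record(id)
    while (!is.null(node$parent) &&
           !is.null(party$node_record(node$parent))) {
      id <- node$parent
      node <- party$node_record(id)
    }
    id
  }
  by_root <- split(ids, vapply(ids, root_of, character(1)))
  for (group in by_root) {
    ident <- list()
    payload <- list()
    for (id in group) {
      node <- party$node_record(id)
      content <- tryCatch(
        party$read_node("adversary", id, audit = FALSE)$content,
        error = function(e) node$content
      )
      if (classify(node) == "identifying") {
        ident <- c(ident, content)
      } else {
        payload <- c(payload, content)
      }
    }
    for (ia in names(ident)) {
      for (pa in names(payload)) {
        rows[[length(rows) + 1L]] <- data.frame(
          identifying_attr = ia,
          identifying_value = as.character(ident[[ia]]),
          payload_attr = pa,
          payload_value = as.character(payload[[pa]]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty
}
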