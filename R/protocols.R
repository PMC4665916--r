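# Client-side orchestration of the join and data-entry flows.
#
# All reconstruction of separated data happens at the client: servers only
# ever see their own pool, temporary identifiers, and sealed tokens. In
# indirect mode every message is routed via the client and the servers stay
# stateless with respect to temporary identifiers; in direct mode the
# backends synchronize persisted temporary mappings peer-to-peer, with the
# answer routed through the mapping service (which performs the namespace
# translation).

#' Open a client session against a registry system
#'
#' Performs the single interactive login at the primary service. The client
#' retains the credentials so later hops can carry them inside sealed tokens
#' (single sign-on: no further interactive authentication, ever).
#'
#' @param system a [registry_system()].
#' @param username,password account credentials.
#' @return an object of class `registry_client`.
#' @export
registry_client <- function(system, username, password) {
  client <- new.env(parent = emptyenv())
  client$system <- system
  client$username <- username
  client$password <- password
  client$sessions <- list(primary = system$primary$authenticate(username,
                                                                password))
  client$interactive_logins <- 1L
  class(client) <- "registry_client"
  client
}

#' @export
print.registry_client <- function(x, ...) {
  cat(sprintf("<registry_client user=%s, %d interactive login(s)>\n",
              x$username, x$interactive_logins))
  invisible(x)
}

integrated_view <- function(rows, unmatched = list()) {
  structure(list(rows = rows, unmatched = unmatched),
            class = "integrated_view")
}

#' @export
print.integrated_view <- function(x, ...) {
  cat(sprintf("<integrated_view: %d rows, %d unmatched>\n",
              length(x$rows), length(x$unmatched)))
  invisible(x)
}

#' Convert an integrated view into an integrated dataset
#'
#' Re-expresses the client-side joined rows as an [integrated_dataset()]
#' (keyed by temporary identifiers) so protocol output can be compared
#' record-by-record against the [integrate_pools()] oracle with
#' [same_records()].
#'
#' @param view an integrated view from one of the join protocols, or a list
#'   of views whose rows are pooled.
#' @return an [integrated_dataset()] (schema categories are not recovered).
#' @export
view_dataset <- function(view) {
  if (inherits(view, "integrated_view")) view <- list(view)
  rows <- do.call(c, c(lapply(view, `[[`, "rows"), list(list())))
  attr_names <- unique(unlist(lapply(rows, function(r) names(r$attrs)),
                              use.names = FALSE))
  df <- data.frame(
    subject_key = vapply(rows, function(r) r$temp_id, character(1)) %||%
      character(0),
    stringsAsFactors = FALSE
  )
  if (length(rows) == 0L) df <- data.frame(subject_key = character(0))
  for (a in attr_names) {
    df[[a]] <- vapply(rows, function(r) {
      v <- r$attrs[[a]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  schema <- setNames(rep("payload", length(attr_names)), attr_names)
  integrated_dataset(df, schema, degenerate = TRUE)
}

#' Oracle integration of a system's separated pools
#'
#' Runs the pure data-layer join ([integrate_pools()]) on the pools the
#' system was built from; join protocols must reproduce this result.
#'
#' @param system a [registry_system()].
#' @return an `integration_result`.
#' @export
oracle_integrate <- function(system) {
  integrate_pools(system$pools$master_pool, system$pools$payload_pool,
                  system$pools$mapping)
}

# ---- primary-service request handlers -------------------------------------

primary_read_subject <- function(system, req, mode) {
  p <- system$primary
  p$verify_token_user(req$username, req$password)
  psn_a <- p$find_by_label(req$label)
  if (is.null(psn_a)) {
    pr_stop(sprintf("no subject with record label '%s'", req$label),
            "pseudoreg_not_found_error")
  }
  node <- p$node_record(psn_a)
  if (!p$authorize(req$username, "read", "master",
                   target_site = node$site, target = psn_a)) {
    return(list(status = "denied"))
  }
  content <- p$read_node(req$username, psn_a)$content
  master <- content[setdiff(names(content), "record_label")]
  temp <- unname(p$issue_temp_ids(psn_a, mode = mode))
  resp <- list(status = "ok", temp_id = temp, label = req$label,
               master = master)
  if (mode == "indirect") {
    tok <- p$seal_for("mapping", req$username, req$password, payload = list(
      op = "translate",
      pairs = list(list(temp_id = temp, pseudonym = psn_a))
    ))
    resp$token <- encode_request_line(tok)
  }
  resp
}

primary_list_subjects <- function(system, req) {
  p <- system$primary
  p$verify_token_user(req$username, req$password)
  rows <- list()
  pairs <- list()
  for (id in p$node_ids()) {
    node <- p$node_record(id)
    if (!p$authorize(req$username, "read", "master",
                     target_site = node$site, target = id)) next
    content <- p$read_node(req$username, id)$content
    temp <- unname(p$issue_temp_ids(id, mode = "indirect"))
    rows[[length(rows) + 1L]] <- list(
      temp_id = temp, label = content$record_label,
      master = content[setdiff(names(content), "record_label")]
    )
    pairs[[length(pairs) + 1L]] <- list(temp_id = temp, pseudonym = id)
  }
  resp <- list(status = "ok", rows = rows)
  if (length(pairs)) {
    tok <- p$seal_for("mapping", req$username, req$password,
                      payload = list(op = "translate", pairs = pairs))
    resp$token <- encode_request_line(tok)
  }
  resp
}

# ---- mapping-service request handlers -------------------------------------

mapping_handle_token <- function(system, encoded_token) {
  ms <- system$mapping
  pl <- ms$open_from(decode_request_line(encoded_token))
  ms$verify_token_user(pl$username, pl$password)
  op <- pl$payload$op
  if (identical(op, "translate") || identical(op, "route_answer")) {
    entries <- ms$translate_pairs(pl$username, pl$payload$pairs)
    out <- ms$seal_for("secondary", pl$username, pl$password,
                       payload = list(op = "resolve", entries = entries))
    list(status = "ok", token = encode_request_line(out))
  } else if (identical(op, "translate_create")) {
    pair <- pl$payload$pairs[[1]]
    b <- ms$ensure_pair(pair$pseudonym, actor = pl$username)
    ms$audit(pl$username, "translate", pair$pseudonym, "ok")
    out <- ms$seal_for("secondary", pl$username, pl$password, payload = list(
      op = "create_doc",
      entry = list(temp_id = pair$temp_id, pseudonym = b),
      doc_type = pl$payload$doc_type, content = pl$payload$content,
      site = pl$payload$site, data_class = pl$payload$data_class
    ))
    list(status = "ok", token = encode_request_line(out))
  } else {
    pr_stop(sprintf("mapping service cannot handle op '%s'", op),
            "pseudoreg_usage_error")
  }
}

#' Translate a sealed token at the mapping service
#'
#' Opens a token from the primary (authentication and replay checks
#' included), translates each `(temp_id, pseudonym)` association into the
#' secondary namespace via the pair table (missing pairs become per-id
#' dangling-link markers), and seals the result for the secondary service.
#'
#' @param system a [registry_system()].
#' @param encoded_token request-line encoded token from the primary.
#' @return list with the outgoing encoded `token`.
#' @export
mapping_translate <- function(system, encoded_token) {
  mapping_handle_token(system, encoded_token)
}

# ---- secondary-service request handlers -----------------------------------

#' Resolve translated identifiers at the secondary service
#'
#' Opens a token from the mapping service, re-authenticates the user from
#' the token credentials, looks up each translated pseudonym and returns the
#' payload content keyed by the temporary identifier only; internal
#' secondary-namespace pseudonyms never appear in the response. Unknown
#' pseudonyms and dangling links yield per-id unmatched markers.
#'
#' @param system a [registry_system()].
#' @param encoded_token request-line encoded token from the mapping service.
#' @param with_documents include per-subject document summaries.
#' @return list with `results`: one entry per temporary identifier.
#' @export
secondary_resolve <- function(system, encoded_token, with_documents = FALSE) {
  s <- system$secondary
  pl <- s$open_from(decode_request_line(encoded_token))
  s$verify_token_user(pl$username, pl$password)
  results <- lapply(pl$payload$entries, function(e) {
    if (!identical(e$status, "ok")) {
      return(list(temp_id = e$temp_id, status = "unmatched"))
    }
    node <- s$node_record(e$pseudonym)
    if (is.null(node)) {
      return(list(temp_id = e$temp_id, status = "unmatched"))
    }
    if (!s$authorize(pl$username, "read", node$data_class,
                     target_site = node$site, target = e$pseudonym)) {
      return(list(temp_id = e$temp_id, status = "denied"))
    }
    content <- s$read_node(pl$username, e$pseudonym)$content
    out <- list(temp_id = e$temp_id, status = "ok", content = content)
    if (with_documents) {
      kids <- s$children_of(e$pseudonym)
      out$documents <- list(
        n = length(kids),
        doc_types = unname(vapply(kids, function(k) {
          s$node_record(k)$doc_type
        }, character(1)))
      )
    }
    out
  })
  list(status = "ok", results = results)
}

secondary_create_doc <- function(system, encoded_token) {
  s <- system$secondary
  pl <- s$open_from(decode_request_line(encoded_token))
  s$verify_token_user(pl$username, pl$password)
  e <- pl$payload$entry
  if (!s$authorize(pl$username, "create", pl$payload$data_class,
                   target_site = pl$payload$site)) {
    return(list(status = "denied"))
  }
  node_id <- s$create_node(pl$username, pl$payload$doc_type,
                           pl$payload$content, pl$payload$site,
                           pl$payload$data_class, parent = e$pseudonym)
  doc_ref <- unname(s$issue_temp_ids(node_id, mode = "indirect"))
  list(status = "ok", temp_id = e$temp_id, doc_ref = doc_ref)
}

# ---- client-side protocol drivers -----------------------------------------

result_row <- function(resp1, res) {
  list(temp_id = resp1$temp_id, label = resp1$label,
       attrs = c(resp1$master, res$content))
}

#' Single-record join with indirect server-to-server communication
#'
#' The six-step flow: (1) client requests a subject from the primary; (2) the
#' primary answers with master data under a fresh temporary identifier plus a
#' sealed token holding the temp-to-internal association; (3) the client
#' forwards the token to the mapping service; (4) the mapping service
#' translates into the secondary namespace and returns a second token; (5)
#' the client forwards it to the secondary; (6) the secondary resolves the
#' payload record and answers keyed by the temporary identifier. Every
#' message is routed via the client and no server persists any temporary
#' mapping.
#'
#' @param client a [registry_client()].
#' @param label client-visible record label of the subject.
#' @param record set `FALSE` to skip transcript recording (bulk runs where
#'   only the view is needed); `transcript` is then `NULL`.
#' @return list with `status`, `view` (an integrated view) and `transcript`.
#' @export
join_indirect_single <- function(client, label, record = TRUE) {
  system <- client$system
  if (!identical(system$mode, "indirect")) {
    pr_stop("system is not in indirect mode", "pseudoreg_usage_error")
  }
  rec <- if (record) new_recorder() else NULL
  req1 <- list(op = "read_subject", label = label,
               username = client$username, password = client$password)
  record_message(rec, "client", "primary", "request", req1)
  resp1 <- primary_read_subject(system, req1, mode = "indirect")
  record_message(rec, "primary", "client", "response", resp1)
  if (!identical(resp1$status, "ok")) {
    return(list(status = "denied", at = "primary", view = NULL,
                transcript = as_transcript(rec)))
  }
  req2 <- list(token = resp1$token)
  record_message(rec, "client", "mapping", "request", req2)
  resp2 <- mapping_translate(system, resp1$token)
  record_message(rec, "mapping", "client", "response", resp2)
  req3 <- list(token = resp2$token)
  record_message(rec, "client", "secondary", "request", req3)
  resp3 <- secondary_resolve(system, resp2$token)
  record_message(rec, "secondary", "client", "response", resp3)

  res <- resp3$results[[1]]
  rows <- list()
  unmatched <- list()
  if (identical(res$status, "ok")) {
    rows <- list(result_row(resp1, res))
  } else {
    unmatched <- list(list(temp_id = res$temp_id, status = res$status))
  }
  list(status = "ok", view = integrated_view(rows, unmatched),
       transcript = as_transcript(rec))
}

#' Single-record join with direct server-to-server communication
#'
#' The nine-step flow: (1) client requests a subject from the primary; (2)
#' the primary persists a temporary mapping locally; (3) it answers with
#' master data under the temporary identifier; (4) the client requests the
#' associated payload from the secondary; (5) the secondary asks the primary
#' to resolve the temporary identifier; (6) the primary looks up and retires
#' the persisted mapping; (7) it routes the answer to the mapping service;
#' (8) which translates it into the secondary namespace and forwards it to
#' the secondary; (9) the secondary delivers the payload to the client. At
#' least seven of the nine steps are message exchanges; steps 5, 7 and 8 are
#' server-to-server and not visible to the client.
#'
#' @inheritParams join_indirect_single
#' @return list with `status`, `view` and `transcript`.
#' @export
join_direct_single <- function(client, label, record = TRUE) {
  system <- client$system
  if (!identical(system$mode, "direct")) {
    pr_stop("system is not in direct mode", "pseudoreg_usage_error")
  }
  p <- system$primary
  s <- system$secondary
  rec <- if (record) new_recorder() else NULL

  req1 <- list(op = "read_subject", label = label,
               username = client$username, password = client$password)
  record_message(rec, "client", "primary", "request", req1)        # step 1
  p$verify_token_user(req1$username, req1$password)
  psn_a <- p$find_by_label(label)
  if (is.null(psn_a)) {
    pr_stop(sprintf("no subject with record label '%s'", label),
            "pseudoreg_not_found_error")
  }
  node <- p$node_record(psn_a)
  if (!p$authorize(req1$username, "read", "master",
                   target_site = node$site, target = psn_a)) {
    record_message(rec, "primary", "client", "response",
                   list(status = "denied"))
    return(list(status = "denied", at = "primary", view = NULL,
                transcript = as_transcript(rec)))
  }
  content <- p$read_node(req1$username, psn_a)$content
  temp <- unname(p$issue_temp_ids(psn_a, mode = "direct"))
  record_local(rec, "primary", "persist temporary mapping")        # step 2
  resp1 <- list(status = "ok", temp_id = temp, label = label,
                master = content[setdiff(names(content), "record_label")])
  record_message(rec, "primary", "client", "response", resp1)      # step 3

  req2 <- list(op = "read_by_temp", temp_id = temp,
               username = client$username, password = client$password)
  record_message(rec, "client", "secondary", "request", req2)      # step 4
  s$verify_token_user(req2$username, req2$password)
  tok_req <- s$seal_for("primary", req2$username, req2$password,
                        payload = list(op = "resolve_temp", temp_id = temp))
  record_message(rec, "secondary", "primary", "request",
                 list(token = encode_request_line(tok_req)),
                 visible_to_client = FALSE)                        # step 5
  pl_req <- p$open_from(tok_req)
  p$verify_token_user(pl_req$username, pl_req$password)
  psn_resolved <- p$resolve_temp(pl_req$payload$temp_id)
  record_local(rec, "primary", "resolve and retire temporary mapping") # 6
  tok_ans <- p$seal_for("mapping", pl_req$username, pl_req$password,
                        payload = list(op = "route_answer",
                                       pairs = list(list(
                                         temp_id = temp,
                                         pseudonym = psn_resolved))))
  record_message(rec, "primary", "mapping", "response",
                 list(token = encode_request_line(tok_ans)),
                 visible_to_client = FALSE)                        # step 7
  resp_ms <- mapping_handle_token(system, encode_request_line(tok_ans))
  record_message(rec, "mapping", "secondary", "response",
                 list(token = resp_ms$token),
                 visible_to_client = FALSE)                        # step 8
  resp3 <- secondary_resolve(system, resp_ms$token)
  record_message(rec, "secondary", "client", "response", resp3)    # step 9

  res <- resp3$results[[1]]
  rows <- list()
  unmatched <- list()
  if (identical(res$status, "ok")) {
    rows <- list(result_row(resp1, res))
  } else {
    unmatched <- list(list(temp_id = res$temp_id, status = res$status))
  }
  list(status = "ok", view = integrated_view(rows, unmatched),
       transcript = as_transcript(rec))
}

#' Batch list-view join
#'
#' One batch round to the primary (all authorized subjects, master rows plus
#' temporary identifiers plus one token), one to the mapping service (batch
#' namespace translation), one to the secondary (batch payload fetch with
#' document summaries); the client then updates its rows in place keyed by
#' the temporary identifiers. An empty authorized set short-circuits after
#' the primary round.
#'
#' @param client a [registry_client()].
#' @return list with `status`, `view` and `transcript`; each view row gains a
#'   `documents` summary (`n`, `doc_types`).
#' @export
list_view_join <- function(client) {
  system <- client$system
  if (!identical(system$mode, "indirect")) {
    pr_stop("list view requires indirect mode", "pseudoreg_usage_error")
  }
  rec <- new_recorder()
  req1 <- list(op = "list", username = client$username,
               password = client$password)
  record_message(rec, "client", "primary", "request", req1)
  resp1 <- primary_list_subjects(system, req1)
  record_message(rec, "primary", "client", "response", resp1)
  if (length(resp1$rows) == 0L) {
    return(list(status = "ok", view = integrated_view(list()),
                transcript = as_transcript(rec)))
  }
  req2 <- list(token = resp1$token)
  record_message(rec, "client", "mapping", "request", req2)
  resp2 <- mapping_translate(system, resp1$token)
  record_message(rec, "mapping", "client", "response", resp2)
  req3 <- list(token = resp2$token)
  record_message(rec, "client", "secondary", "request", req3)
  resp3 <- secondary_resolve(system, resp2$token, with_documents = TRUE)
  record_message(rec, "secondary", "client", "response", resp3)

  by_temp <- list()
  for (res in resp3$results) by_temp[[res$temp_id]] <- res
  rows <- list()
  unmatched <- list()
  for (r in resp1$rows) {
    res <- by_temp[[r$temp_id]]
    if (!is.null(res) && identical(res$status, "ok")) {
      row <- result_row(r, res)
      row$documents <- res$documents
      rows[[length(rows) + 1L]] <- row
    } else {
      unmatched[[length(unmatched) + 1L]] <-
        list(temp_id = r$temp_id, status = res$status %||% "missing")
    }
  }
  list(status = "ok", view = integrated_view(rows, unmatched),
       transcript = as_transcript(rec))
}

#' Create a payload document via the token cascade
#'
#' Single-sign-on data entry: the first request carries the user's
#' credentials to the primary; every further hop carries them only inside
#' sealed tokens. The primary authorizes the operation and issues a
#' temporary identifier; the mapping service translates (creating a new
#' pseudonym pair when the subject has no secondary-side identifier yet);
#' the secondary re-authenticates, re-authorizes, and creates the document
#' node linked to the subject's secondary pseudonym. A denial at any hop
#' aborts with zero state change and is audited where it was denied.
#'
#' @param client a [registry_client()].
#' @param label record label of the subject.
#' @param doc_type document type name (e.g. an eCRF name).
#' @param content named list of field values.
#' @param data_class access-control class of the document
#'   (default `"clinical"`).
#' @return list with `status` (`"ok"` or `"denied"`), `at` (denying hop, when
#'   denied), `doc_ref` (temporary reference of the new document) and
#'   `transcript`.
#' @export
create_ecrf_flow <- function(client, label, doc_type, content,
                             data_class = "clinical") {
  system <- client$system
  p <- system$primary
  rec <- new_recorder()
  req1 <- list(op = "create_doc", label = label, doc_type = doc_type,
               content = content, username = client$username,
               password = client$password)
  record_message(rec, "client", "primary", "request", req1)
  p$verify_token_user(req1$username, req1$password)
  psn_a <- p$find_by_label(label)
  if (is.null(psn_a)) {
    pr_stop(sprintf("no subject with record label '%s'", label),
            "pseudoreg_not_found_error")
  }
  node <- p$node_record(psn_a)
  if (!p$authorize(req1$username, "create", data_class,
                   target_site = node$site, target = psn_a)) {
    record_message(rec, "primary", "client", "response",
                   list(status = "denied"))
    return(list(status = "denied", at = "primary",
                transcript = as_transcript(rec)))
  }
  temp <- unname(p$issue_temp_ids(psn_a, mode = "indirect"))
  tok <- p$seal_for("mapping", req1$username, req1$password, payload = list(
    op = "translate_create",
    pairs = list(list(temp_id = temp, pseudonym = psn_a)),
    doc_type = doc_type, content = content, site = node$site,
    data_class = data_class
  ))
  resp1 <- list(status = "ok", temp_id = temp,
                token = encode_request_line(tok))
  record_message(rec, "primary", "client", "response", resp1)
  req2 <- list(token = resp1$token)
  record_message(rec, "client", "mapping", "request", req2)
  resp2 <- mapping_handle_token(system, resp1$token)
  record_message(rec, "mapping", "client", "response", resp2)
  req3 <- list(token = resp2$token)
  record_message(rec, "client", "secondary", "request", req3)
  resp3 <- secondary_create_doc(system, resp2$token)
  record_message(rec, "secondary", "client", "response", resp3)
  if (!identical(resp3$status, "ok")) {
    return(list(status = "denied", at = "secondary",
                transcript = as_transcript(rec)))
  }
  list(status = "ok", doc_ref = resp3$doc_ref, subject_temp = temp,
       transcript = as_transcript(rec))
}
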