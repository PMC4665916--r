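#' Session-authenticated CRUD on a backend's document tree
#'
#' The generic data-layer operation surface: create, read, update or delete a
#' document node, with authorization evaluated against the backend's RBAC
#' matrix (including the site filter) and exactly one audit event appended
#' per mutation. Deleting a node with children requires an explicit
#' `cascade` flag.
#'
#' @param backend a [BackendService].
#' @param session a session id from `backend$authenticate()`.
#' @param operation one of `"create"`, `"read"`, `"update"`, `"delete"`.
#' @param node a list describing the target: for `create`, elements
#'   `doc_type`, `content`, `site`, `data_class` and optional `parent`; for
#'   the other operations `node_id` (plus `content` for `update`, and
#'   optional `cascade` for `delete`).
#' @return for `create`, the new node id; for `read`, the node (with
#'   decrypted content); for `update`/`delete`, the node id, invisibly.
#' @export
crud <- function(backend, session, operation, node) {
  stopifnot(inherits(backend, "BackendService"))
  operation <- match.arg(operation, c("create", "read", "update", "delete"))
  user <- backend$session_user(session)

  if (operation == "create") {
    ok <- backend$authorize(user, "create", node$data_class,
                            target_site = node$site %||% NA_character_)
    if (!ok) pr_stop("operation denied", "pseudoreg_authz_error")
    return(backend$create_node(user, node$doc_type, node$content,
                               node$site, node$data_class,
                               parent = node$parent %||% NULL))
  }

  existing <- backend$node_record(node$node_id)
  if (is.null(existing)) {
    pr_stop(sprintf("node '%s' not found", node$node_id),
            "pseudoreg_not_found_error")
  }
  ok <- backend$authorize(user, operation, existing$data_class,
                          target_site = existing$site %||% NA_character_,
                          target = node$node_id)
  if (!ok) pr_stop("operation denied", "pseudoreg_authz_error")

  switch(operation,
    read = backend$read_node(user, node$node_id),
    update = backend$update_node(user, node$node_id, node$content),
    delete = backend$delete_node(user, node$node_id,
                                 cascade = isTRUE(node$cascade))
  )
}
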