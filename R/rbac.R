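#' Default role-based access-control matrix
#'
#' Encodes the four standard registry roles. Application administrators may
#' perform all CRUD operations on user accounts but have no access to any
#' research data. Monitors are read-only on research data (quality
#' assurance). Physicians may perform all CRUD operations on master data and
#' clinical data, restricted to subjects of their own site. Lab personnel
#' manage biospecimen registration documents. Additional roles can be added
#' by extending the returned data frame.
#'
#' @return data.frame of allowed (`role`, `operation`, `data_class`) triples.
#' @export
default_rbac_matrix <- function() {
  allow <- function(role, ops, classes) {
    expand.grid(role = role, operation = ops, data_class = classes,
                stringsAsFactors = FALSE)
  }
  rbind(
    allow("administrator", c("create", "read", "update", "delete"), "account"),
    allow("monitor", "read", c("master", "clinical", "specimen")),
    allow("physician", c("create", "read", "update", "delete"),
          c("master", "clinical")),
    allow("lab", c("create", "read", "update", "delete"), "specimen")
  )
}

#' Roles whose research-data access is filtered by site
#'
#' Physicians only access data of subjects recruited at their own
#' institution; monitors audit across all sites by default (configurable).
#'
#' @return character vector of role names.
#' @export
default_site_restricted_roles <- function() "physician"

#' Evaluate an access-control decision against a matrix
#'
#' Pure decision function: a triple outside the matrix denies; for
#' site-restricted roles, subject-linked data of a different site denies.
#' Deny is a value, not an error.
#'
#' @param matrix an RBAC matrix, see [default_rbac_matrix()].
#' @param role,operation,data_class the requested triple.
#' @param user_site,target_site sites of the requesting account and of the
#'   target subject (`NA` when the target is not subject-linked).
#' @param site_restricted_roles roles subject to the site filter.
#' @return `TRUE` (allow) or `FALSE` (deny).
#' @export
rbac_decision <- function(matrix, role, operation, data_class,
                          user_site = NA_character_,
                          target_site = NA_character_,
                          site_restricted_roles = default_site_restricted_roles()) {
  hit <- any(matrix$role == role & matrix$operation == operation &
               matrix$data_class == data_class)
  if (!hit) return(FALSE)
  if (role %in% site_restricted_roles && !is.na(target_site) &&
      data_class %in% c("master", "clinical", "specimen")) {
    if (is.na(user_site) || !identical(user_site, target_site)) return(FALSE)
  }
  TRUE
}
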