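#' Run the full invariant suite against a system
#'
#' Executes the verifiable security properties of the architecture:
#'
#' * **separation** — the adversary-view join from every single party's state
#'   yields zero linked (identifying, payload) attribute pairs;
#' * **confidentiality** — client-visible bytes of the supplied transcripts
#'   contain no internal pseudonym of any namespace;
#' * **replay** — a live probe seals a token between two components, accepts
#'   it once and confirms the identical token is rejected on re-submission;
#' * **audit_completeness** — per backend, the number of executed mutating
#'   operations equals the number of `{create, update, delete}` audit events;
#' * **rbac** — randomized operation fuzzing never produces an allow outside
#'   the declared role matrix (including the site filter).
#'
#' @param system a [registry_system()].
#' @param transcripts list of transcripts from protocol runs (may be empty;
#'   the confidentiality check then passes vacuously).
#' @param n_fuzz number of fuzzed RBAC decisions.
#' @param fuzz_seed seed for the fuzzer.
#' @return data.frame with columns `invariant`, `pass`, `detail`.
#' @export
verify_invariants <- function(system, transcripts = list(), n_fuzz = 1000L,
                              fuzz_seed = 1L) {
  res <- list()
  note <- function(invariant, pass, detail) {
    res[[length(res) + 1L]] <<- data.frame(
      invariant = invariant, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }

  pairs <- vapply(list(system$primary, system$secondary, system$mapping),
                  function(p) nrow(adversary_view(p)), integer(1))
  note("separation", all(pairs == 0L),
       sprintf("linked pairs per party: %s", paste(pairs, collapse = "/")))

  psns <- internal_pseudonyms(system)
  viol <- assert_confidential(transcripts, psns)
  note("confidentiality", nrow(viol) == 0L,
       sprintf("%d pseudonym leak(s) in %d transcript(s)", nrow(viol),
               length(transcripts)))

  replay_ok <- tryCatch({
    user <- system$registry$users[1, ]
    tok <- system$primary$seal_for("mapping", user$username, user$password,
                                   payload = list(op = "noop"))
    system$mapping$open_from(tok)
    second <- tryCatch({
      system$mapping$open_from(tok)
      FALSE
    }, pseudoreg_replay_error = function(e) TRUE)
    second
  }, error = function(e) FALSE)
  note("replay", replay_ok, "replayed token rejected")

  audit_ok <- TRUE
  details <- character(0)
  for (b in list(system$primary, system$secondary)) {
    log <- b$audit_log()
    n_mut <- sum(log$operation %in% c("create", "update", "delete") &
                   log$outcome == "ok")
    audit_ok <- audit_ok && (n_mut == b$mutation_count)
    details <- c(details, sprintf("%s %d/%d", b$component_id, n_mut,
                                  b$mutation_count))
  }
  note("audit_completeness", audit_ok, paste(details, collapse = ", "))

  fuzz <- rbac_fuzz(system$primary, n = n_fuzz, seed = fuzz_seed)
  note("rbac", fuzz$violations == 0L,
       sprintf("%d violation(s) in %d fuzzed decisions", fuzz$violations,
               fuzz$n))

  do.call(rbind, res)
}

#' Fuzz a backend's authorization decisions against the declared matrix
#'
#' Draws random (role, operation, data class, site) requests using accounts
#' present on the backend and compares every live decision with the declared
#' RBAC matrix plus site rule; any allow outside the declaration is a
#' violation.
#'
#' @param backend a [BackendService].
#' @param n number of fuzzed decisions.
#' @param seed RNG seed.
#' @return list with `n`, `violations`, and the `decisions` data.frame.
#' @export
rbac_fuzz <- function(backend, n = 1000L, seed = 1L) {
  users <- backend$users_df()
  ops <- c("create", "read", "update", "delete")
  classes <- c("master", "clinical", "specimen", "account")
  sites <- unique(c(users$site, "site-zz"))
  with_seed(seed, {
    idx <- sample.int(nrow(users), n, replace = TRUE)
    op <- sample(ops, n, replace = TRUE)
    cls <- sample(classes, n, replace = TRUE)
    tsite <- sample(c(sites, NA_character_), n, replace = TRUE)
    got <- logical(n)
    want <- logical(n)
    for (i in seq_len(n)) {
      u <- users[idx[i], ]
      got[i] <- backend$authorize(u$username, op[i], cls[i],
                                  target_site = tsite[i])
      want[i] <- rbac_decision(backend$rbac, u$role, op[i], cls[i],
                               user_site = u$site, target_site = tsite[i],
                               site_restricted_roles =
                                 backend$site_restricted_roles)
    }
    decisions <- data.frame(username = users$username[idx], role =
                              users$role[idx], operation = op,
                            data_class = cls, target_site = tsite,
                            got = got, want = want,
                            stringsAsFactors = FALSE)
    list(n = n, violations = sum(got & !want),
         mismatches = sum(got != want), decisions = decisions)
  })
}
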