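make_backend <- function(encrypt = FALSE, key = NULL) {
  b <- BackendService$new("primary", "ns-a", accepted_classes = "master",
                          encrypt_at_rest = encrypt, master_data_key = key)
  b$add_user("doc1", "pw1", "physician", "site-01")
  b$add_user("doc2", "pw2", "physician", "site-02")
  b$add_user("mon", "pwm", "monitor", "site-01")
  b$add_user("adm", "pwa", "administrator", "site-01")
  b$add_user("lab", "pwl", "lab", "site-01")
  b
}

test_that("authentication issues fresh sessions and audits every outcome", {
  b <- make_backend()
  sid <- b$authenticate("doc1", "pw1")
  log <- b$audit_log()
  expect_equal(sum(log$operation == "login" & log$outcome == "ok"), 1L)
  expect_identical(b$session_user(sid), "doc1")

  expect_error(b$authenticate("doc1", "wrong"), class = "pseudoreg_auth_error")
  bad_known <- tryCatch(b$authenticate("doc1", "wrong"),
                        error = conditionMessage)
  bad_unknown <- tryCatch(b$authenticate("ghost", "x"),
                          error = conditionMessage)
  expect_identical(bad_known, bad_unknown)  # indistinguishable denials

  sids <- vapply(1:1000, function(i) b$authenticate("doc1", "pw1"),
                 character(1))
  expect_equal(length(unique(sids)), 1000L)
})

test_that("authorization follows the declared role matrix", {
  b <- make_backend()
  # monitors: read-only on clinical data
  expect_false(b$authorize("mon", "update", "clinical"))
  expect_true(b$authorize("mon", "read", "clinical"))
  # administrators never touch research data
  expect_false(b$authorize("adm", "read", "master"))
  expect_false(b$authorize("adm", "read", "clinical"))
  expect_false(b$authorize("adm", "read", "specimen"))
  expect_true(b$authorize("adm", "create", "account"))
  # physicians are confined to their own site
  expect_true(b$authorize("doc1", "read", "master", target_site = "site-01"))
  expect_false(b$authorize("doc1", "read", "master", target_site = "site-02"))
  # lab personnel manage specimens only
  expect_true(b$authorize("lab", "update", "specimen"))
  expect_false(b$authorize("lab", "read", "clinical"))
  # denials are audited as values
  expect_gt(sum(b$audit_log()$outcome == "denied"), 0L)
})

test_that("crud round-trips content, audits one event per mutation, and guards roots", {
  b <- make_backend()
  sid <- b$authenticate("doc1", "pw1")
  before <- nrow(b$audit_log())

  id <- crud(b, sid, "create", list(doc_type = "subject",
                                    content = list(name = "Alva"),
                                    site = "site-01", data_class = "master"))
  node <- crud(b, sid, "read", list(node_id = id))
  expect_identical(node$content$name, "Alva")
  crud(b, sid, "update", list(node_id = id, content = list(name = "Runa")))
  expect_identical(crud(b, sid, "read", list(node_id = id))$content$name,
                   "Runa")

  id2 <- crud(b, sid, "create", list(doc_type = "subject",
                                     content = list(name = "Edda"),
                                     site = "site-01", data_class = "master"))
  crud(b, sid, "delete", list(node_id = id2))

  log <- b$audit_log()[-seq_len(before), ]
  expect_equal(sum(log$operation %in% c("create", "update", "delete") &
                     log$outcome == "ok"), 4L)
  expect_equal(b$mutation_count, 4L)
  # gapless sequence numbers
  full <- b$audit_log()
  expect_identical(full$seq, seq_len(nrow(full)))

  # unknown node: not-found, zero state change
  n0 <- b$store_size()
  expect_error(crud(b, sid, "delete", list(node_id = "nope")),
               class = "pseudoreg_not_found_error")
  expect_equal(b$store_size(), n0)

  # a parent with children needs an explicit cascade flag
  kid <- b$create_node("doc1", "note", list(t = "x"), "site-01", "master",
                       parent = id)
  expect_error(b$delete_node("doc1", id), class = "pseudoreg_usage_error")
  b$delete_node("doc1", id, cascade = TRUE)
  expect_false(b$has_node(kid))

  # a backend refuses data classes outside its pool
  expect_error(b$create_node("doc1", "ecrf", list(x = 1), "site-01",
                             "clinical"),
               class = "pseudoreg_separation_error")
})

test_that("temporary identifiers never equal internal pseudonyms; persistence depends on mode", {
  b <- make_backend()
  ids <- vapply(1:5, function(i) {
    b$create_node("doc1", "subject", list(n = i), "site-01", "master")
  }, character(1))

  t_ind <- b$issue_temp_ids(ids, mode = "indirect")
  expect_length(intersect(t_ind, ids), 0L)
  expect_equal(b$temp_map_size(), 0L)  # servers stay stateless

  t_dir <- b$issue_temp_ids(ids, mode = "direct")
  expect_equal(b$temp_map_size(), 5L)
  expect_identical(unname(b$resolve_temp(t_dir[[1]])), ids[1])
  # delete-on-use: a second resolution of the same temp mapping fails
  expect_error(b$resolve_temp(t_dir[[1]]),
               class = "pseudoreg_not_found_error")
  expect_equal(b$temp_map_size(), 4L)
})

test_that("master data is encrypted at rest and transparently decrypted on read", {
  key <- openssl::rand_bytes(32)
  b <- make_backend(encrypt = TRUE, key = key)
  id <- b$create_node("doc1", "subject",
                      list(given_name = "Quirin", family_name = "Jelinek"),
                      "site-01", "master")
  dump <- paste(b$persist_store(), collapse = "")
  expect_false(grepl("Quirin", dump, fixed = TRUE))
  expect_false(grepl("Jelinek", dump, fixed = TRUE))
  expect_identical(b$read_node("doc1", id)$content$given_name, "Quirin")

  # startup refusal without a key
  expect_error(
    BackendService$new("primary", "ns-a", accepted_classes = "master",
                       encrypt_at_rest = TRUE),
    class = "pseudoreg_key_lookup_error"
  )

  # the payload backend is unaffected by the flag
  s <- BackendService$new("secondary", "ns-b",
                          accepted_classes = c("clinical", "specimen"))
  s$add_user("doc1", "pw1", "physician", "site-01")
  sid <- s$create_node("doc1", "baseline", list(diagnosis = "MT-DX-01"),
                       "site-01", "clinical")
  expect_true(grepl("MT-DX-01", paste(s$persist_store(), collapse = "")))
})

test_that("the mapping service stores bare pairs and translates with dangling markers", {
  ms <- MappingService$new("mapping", "ns-a", "ns-b")
  ms$add_user("doc1", "pw1", "physician", "site-01")
  ms$add_pair("aaaa", "bbbb")
  expect_error(ms$add_pair("aaaa", "cccc"), class = "pseudoreg_mapping_error")
  expect_identical(ms$lookup_b("aaaa"), "bbbb")
  expect_identical(ms$lookup_a("bbbb"), "aaaa")

  out <- ms$translate_pairs("doc1", list(
    list(temp_id = "t1", pseudonym = "aaaa"),
    list(temp_id = "t2", pseudonym = "zzzz")
  ))
  expect_identical(out[[1]]$status, "ok")
  expect_identical(out[[1]]$pseudonym, "bbbb")
  expect_identical(out[[2]]$status, "dangling")
  log <- ms$audit_log()
  expect_equal(sum(log$operation == "translate"), 2L)

  # ensure_pair creates a fresh secondary-side pseudonym exactly once
  b1 <- ms$ensure_pair("new-a", actor = "doc1")
  b2 <- ms$ensure_pair("new-a", actor = "doc1")
  expect_identical(b1, b2)
  expect_equal(ms$n_pairs(), 2L)
})

test_that("replayed tokens are rejected at service level", {
  sys <- build_test_system(n_subjects = 2L, seed = 21L)
  u <- sys$registry$users[1, ]
  tok <- sys$primary$seal_for("mapping", u$username, u$password,
                              payload = list(op = "noop"))
  sys$mapping$open_from(tok)
  expect_error(sys$mapping$open_from(tok), class = "pseudoreg_replay_error")
})
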