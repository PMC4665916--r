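test_that("indirect single-record join runs in six client-routed steps and matches the oracle", {
  sys <- build_test_system(n_subjects = 3L, seed = 5L)
  cl <- monitor_client(sys)
  r <- join_indirect_single(cl, "S0001")
  expect_identical(r$status, "ok")
  expect_equal(transcript_steps(r$transcript), 6L)
  expect_equal(transcript_messages(r$transcript), 6L)
  expect_true(all(r$transcript$steps$visible_to_client))
  expect_identical(r$transcript$steps$from,
                   c("client", "primary", "client", "mapping", "client",
                     "secondary"))

  # no server persisted any temporary mapping
  expect_equal(sys$primary$temp_map_size(), 0L)
  expect_equal(sys$secondary$temp_map_size(), 0L)

  # single-row view equals the corresponding oracle record
  orc <- oracle_integrate(sys)
  key <- sys$labels[["S0001"]]
  expected <- sys$registry$dataset$data[
    sys$registry$dataset$data$subject_key == key, ]
  attrs <- r$view$rows[[1]]$attrs
  for (a in names(sys$registry$dataset$schema)) {
    expect_identical(as.character(attrs[[a]]), as.character(expected[[a]]))
  }
  expect_equal(nrow(orc$unmatched), 0L)
})

test_that("direct single-record join: nine steps, at least seven messages, mapping retired", {
  sys <- build_test_system(n_subjects = 3L, seed = 5L, mode = "direct")
  cl <- monitor_client(sys)
  r <- join_direct_single(cl, "S0002")
  expect_identical(r$status, "ok")
  expect_equal(transcript_steps(r$transcript), 9L)
  expect_gte(transcript_messages(r$transcript), 7L)
  expect_equal(sum(r$transcript$steps$kind == "local"), 2L)

  # server-to-server answer is routed through the mapping service, never
  # primary -> secondary directly
  st <- r$transcript$steps
  s2s <- st[!st$visible_to_client & st$kind != "local", ]
  expect_false(any(s2s$from == "primary" & s2s$to == "secondary"))
  expect_true(any(s2s$from == "primary" & s2s$to == "mapping"))
  expect_true(any(s2s$from == "mapping" & s2s$to == "secondary"))

  # the persisted temporary mapping was created and then retired
  expect_equal(sys$primary$temp_map_size(), 0L)

  # view equality with the pure data-layer oracle
  key <- sys$labels[["S0002"]]
  expected <- sys$registry$dataset$data[
    sys$registry$dataset$data$subject_key == key, ]
  for (a in names(sys$registry$dataset$schema)) {
    expect_identical(as.character(r$view$rows[[1]]$attrs[[a]]),
                     as.character(expected[[a]]))
  }
})

test_that("both protocols reproduce the integrate oracle over whole registries", {
  for (seed in c(13L, 27L)) {
    reg <- generate_registry(generator_spec(n_subjects = 8L, seed = seed))
    sys <- registry_system(reg, mode = "indirect", seed = seed,
                           keys = test_keys())
    orc <- oracle_integrate(sys)
    cl <- monitor_client(sys)
    vi <- lapply(names(sys$labels), function(l) {
      join_indirect_single(cl, l, record = FALSE)$view
    })
    expect_true(same_records(view_dataset(vi), orc$dataset))

    sysd <- registry_system(reg, mode = "direct", seed = seed,
                            keys = test_keys())
    cld <- monitor_client(sysd)
    vd <- lapply(names(sysd$labels), function(l) {
      join_direct_single(cld, l, record = FALSE)$view
    })
    expect_true(same_records(view_dataset(vd), orc$dataset))
  }
})

test_that("list view joins in three batch rounds with site-filtered row counts", {
  sys <- build_test_system(n_subjects = 10L, seed = 8L)
  cl <- monitor_client(sys)
  r <- list_view_join(cl)
  expect_length(r$view$rows, 10L)
  expect_equal(transcript_messages(r$transcript), 6L)
  expect_true(all(r$transcript$steps$visible_to_client))
  expect_true(same_records(view_dataset(r$view),
                           oracle_integrate(sys)$dataset))
  # document summaries ride along without disturbing the record attributes
  expect_true(all(vapply(r$view$rows, function(x) !is.null(x$documents),
                         logical(1))))

  # physician: only own-site subjects (round-robin: 4 of 10 at site-01)
  clp <- registry_client(sys, "phys-site-01", "pw-phys-site-01")
  rp <- list_view_join(clp)
  expect_length(rp$view$rows, 4L)

  # empty registry short-circuits after the primary round
  sys0 <- registry_system(generate_registry(generator_spec(n_subjects = 0L,
                                                           seed = 1L)),
                          keys = test_keys())
  r0 <- list_view_join(monitor_client(sys0))
  expect_length(r0$view$rows, 0L)
  expect_equal(transcript_messages(r0$transcript), 2L)
})

test_that("document creation cascades tokens, grows state by one node, and achieves SSO", {
  sys <- build_test_system(n_subjects = 4L, seed = 9L)
  clp <- registry_client(sys, "phys-site-01", "pw-phys-site-01")
  n0 <- sys$secondary$store_size()
  p0 <- sys$mapping$n_pairs()

  r <- create_ecrf_flow(clp, "S0001", "followup",
                        list(visit_date = "2025-03-01", severity_score = "4"))
  expect_identical(r$status, "ok")
  expect_equal(sys$secondary$store_size() - n0, 1L)
  expect_lte(sys$mapping$n_pairs() - p0, 1L)
  expect_match(r$doc_ref, "^tmp-")
  expect_equal(clp$interactive_logins, 1L)

  # credentials travel in clear only in the first request; afterwards only
  # inside sealed tokens
  bodies <- r$transcript$bodies
  expect_true(grepl("pw-phys-site-01", bodies[1], fixed = TRUE))
  for (i in 2:length(bodies)) {
    expect_false(grepl("pw-phys-site-01", bodies[i], fixed = TRUE))
  }

  # a monitor is denied at the primary with zero state change anywhere
  clm <- monitor_client(sys)
  n1 <- sys$secondary$store_size()
  p1 <- sys$mapping$n_pairs()
  rm <- create_ecrf_flow(clm, "S0001", "followup", list(x = "y"))
  expect_identical(rm$status, "denied")
  expect_identical(rm$at, "primary")
  expect_equal(sys$secondary$store_size(), n1)
  expect_equal(sys$mapping$n_pairs(), p1)
})

test_that("client-visible bytes never contain internal pseudonyms; fault injection is caught", {
  sys <- build_test_system(n_subjects = 5L, seed = 14L)
  cl <- monitor_client(sys)
  transcripts <- list(
    join_indirect_single(cl, "S0001")$transcript,
    list_view_join(cl)$transcript,
    create_ecrf_flow(registry_client(sys, "phys-site-01", "pw-phys-site-01"),
                     "S0002", "baseline",
                     list(diagnosis = "MT-DX-03", onset_age = "9"))$transcript
  )
  psns <- internal_pseudonyms(sys)
  expect_gt(length(psns), 0L)
  expect_equal(nrow(assert_confidential(transcripts, psns)), 0L)

  # empty transcript: empty report
  expect_equal(nrow(assert_confidential(list(), psns)), 0L)

  # disabling temp-id substitution leaks pseudonyms and must be detected
  sysf <- registry_system(sys$registry, seed = 14L, keys = test_keys(),
                          substitute_temp_ids = FALSE)
  rf <- join_indirect_single(monitor_client(sysf), "S0001")
  expect_gt(nrow(assert_confidential(rf$transcript,
                                     internal_pseudonyms(sysf))), 0L)
})

test_that("replaying a translation token is rejected", {
  sys <- build_test_system(n_subjects = 2L, seed = 17L)
  cl <- monitor_client(sys)
  req <- list(op = "read_subject", label = "S0001",
              username = cl$username, password = cl$password)
  resp <- pseudoreg:::primary_read_subject(sys, req, mode = "indirect")
  mapping_translate(sys, resp$token)
  expect_error(mapping_translate(sys, resp$token),
               class = "pseudoreg_replay_error")
})

test_that("dangling mapping links surface as unmatched markers downstream", {
  sys <- build_test_system(n_subjects = 3L, seed = 19L)
  # remove one pair at the mapping service by rebuilding without it
  reg <- sys$registry
  sys2 <- registry_system(reg, seed = 19L, keys = test_keys())
  psn_a <- sys2$primary$find_by_label("S0003")
  # rebuild the mapping service without the pair of this subject
  mt <- sys2$mapping$as_mapping_table()
  keep <- mt$pairs[mt$pairs$pseudonym_a != psn_a, ]
  ms2 <- MappingService$new("mapping", "ns-primary", "ns-secondary")
  for (i in seq_len(nrow(sys2$registry$users))) {
    u <- sys2$registry$users[i, ]
    ms2$add_user(u$username, u$password, u$role, u$site)
  }
  ms2$set_ring(sys2$mapping$ring)
  ms2$load_mapping(mapping_table(keep, "ns-primary", "ns-secondary"))
  sys2$mapping <- ms2

  cl <- monitor_client(sys2)
  r <- join_indirect_single(cl, "S0003")
  expect_length(r$view$rows, 0L)
  expect_length(r$view$unmatched, 1L)
  expect_identical(r$view$unmatched[[1]]$status, "unmatched")
})
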