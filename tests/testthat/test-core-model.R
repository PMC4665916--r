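test_that("dataset construction enforces declared categories and unique keys", {
  df <- data.frame(subject_key = c("p1", "p2"), name = c("A", "B"),
                   dx = c("D", "E"), stringsAsFactors = FALSE)
  d <- integrated_dataset(df, c(name = "identifying", dx = "payload"))
  expect_equal(n_records(d), 2L)

  expect_error(
    integrated_dataset(df, c(name = "identifying", dx = "clinical")),
    class = "pseudoreg_schema_error"
  )
  expect_error(
    integrated_dataset(df, c(name = "identifying")),
    class = "pseudoreg_schema_error"
  )
  expect_error(
    integrated_dataset(rbind(df, df), c(name = "identifying", dx = "payload")),
    class = "pseudoreg_duplicate_key_error"
  )
  # no guessing: both categories must be present unless declared degenerate
  expect_error(
    integrated_dataset(df[, c("subject_key", "name")],
                       c(name = "identifying")),
    class = "pseudoreg_schema_error"
  )
  expect_s3_class(
    integrated_dataset(df[, c("subject_key", "name")],
                       c(name = "identifying"), degenerate = TRUE),
    "integrated_dataset"
  )
})

test_that("one-tier separation shares a single pseudonym per record and drops subject keys", {
  d <- example_integrated_dataset()
  tier <- pseudonymize_one_tier(d, "ns1", rng_seed = 3)
  expect_identical(sort(names(tier$master_pool$entries)),
                   sort(names(tier$payload_pool$entries)))
  expect_length(tier$master_pool$entries, 3L)

  # the A-D, B-E, C-F pairing of the worked example is preserved
  for (psn in names(tier$master_pool$entries)) {
    a <- tier$master_pool$entries[[psn]]$attr1
    b <- tier$payload_pool$entries[[psn]]$attr2
    expect_equal(match(b, c("D", "E", "F")), match(a, c("A", "B", "C")))
  }

  # serialized pools contain neither subject keys nor the other category
  master_bytes <- paste(write_pool_jsonl(tier$master_pool), collapse = "")
  payload_bytes <- paste(write_pool_jsonl(tier$payload_pool), collapse = "")
  for (key in d$data$subject_key) {
    expect_false(grepl(key, master_bytes, fixed = TRUE))
    expect_false(grepl(key, payload_bytes, fixed = TRUE))
  }
  for (v in c("D", "E", "F")) {
    expect_false(grepl(sprintf('"%s"', v), master_bytes, fixed = TRUE))
  }
  for (v in c("A", "B", "C")) {
    expect_false(grepl(sprintf('"%s"', v), payload_bytes, fixed = TRUE))
  }

  # empty dataset -> two empty pools
  empty <- integrated_dataset(
    data.frame(subject_key = character(), x = character(), y = character()),
    c(x = "identifying", y = "payload")
  )
  te <- pseudonymize_one_tier(empty, "ns1", rng_seed = 1)
  expect_length(te$master_pool$entries, 0L)
  expect_length(te$payload_pool$entries, 0L)
})

test_that("two-tier separation yields disjoint namespaces linked only by the mapping table", {
  d <- example_integrated_dataset()
  expect_error(pseudonymize_two_tier(d, "same", "same", rng_seed = 1),
               class = "pseudoreg_namespace_error")

  tier <- pseudonymize_two_tier(d, "ns-a", "ns-b", rng_seed = 5)
  expect_equal(nrow(tier$mapping$pairs), 3L)
  expect_length(intersect(names(tier$master_pool$entries),
                          names(tier$payload_pool$entries)), 0L)

  # singleton dataset
  d1 <- integrated_dataset(
    data.frame(subject_key = "p", x = "ID", y = "PL"),
    c(x = "identifying", y = "payload")
  )
  t1 <- pseudonymize_two_tier(d1, "a", "b", rng_seed = 1)
  expect_equal(nrow(t1$mapping$pairs), 1L)
  expect_length(t1$master_pool$entries, 1L)
  expect_length(t1$payload_pool$entries, 1L)

  # removing the mapping removes all linkage (brute-force oracle)
  none <- mapping_table(namespace_a = "ns-a", namespace_b = "ns-b")
  expect_length(brute_force_join(tier$master_pool, tier$payload_pool, none),
                0L)
})

test_that("integration reproduces the source records and matches the brute-force oracle", {
  for (seed in c(2L, 9L, 31L)) {
    reg <- generate_registry(generator_spec(n_subjects = 7L, seed = seed))
    d <- reg$dataset

    t1 <- pseudonymize_one_tier(d, "ns", rng_seed = seed)
    r1 <- integrate_pools(t1$master_pool, t1$payload_pool)
    expect_true(same_records(r1$dataset, d))
    expect_equal(nrow(r1$unmatched), 0L)
    expect_identical(dataset_signatures(r1$dataset),
                     record_signatures(brute_force_join(t1$master_pool,
                                                        t1$payload_pool)))

    t2 <- pseudonymize_two_tier(d, "a", "b", rng_seed = seed)
    r2 <- integrate_pools(t2$master_pool, t2$payload_pool, t2$mapping)
    expect_true(same_records(r2$dataset, d))
    expect_identical(dataset_signatures(r2$dataset),
                     record_signatures(brute_force_join(t2$master_pool,
                                                        t2$payload_pool,
                                                        t2$mapping)))
  }
})

test_that("unmatched entries are reported, never silently dropped", {
  d <- example_integrated_dataset()
  tier <- pseudonymize_two_tier(d, "a", "b", rng_seed = 8)

  # remove one pair: 2 integrated records + 2 unmatched pool entries
  cut <- mapping_table(tier$mapping$pairs[-2, ], "a", "b")
  r <- integrate_pools(tier$master_pool, tier$payload_pool, cut)
  expect_equal(n_records(r$dataset), 2L)
  expect_equal(sum(r$unmatched$reason == "no_pair"), 2L)

  # a pair referencing an absent entry is reported as a dangling link
  broken <- tier$mapping$pairs
  broken$pseudonym_b[1] <- "feedfeedfeedfeedfeedfeedfeedfeed"
  rb <- integrate_pools(tier$master_pool, tier$payload_pool,
                        mapping_table(broken, "a", "b"))
  expect_equal(n_records(rb$dataset), 2L)
  expect_true("dangling_link" %in% rb$unmatched$reason)
})

test_that("pseudonyms are not content-derived: identical values, different seeds, different ids", {
  d <- example_integrated_dataset()
  a <- pseudonymize_one_tier(d, "ns", rng_seed = 1)
  b <- pseudonymize_one_tier(d, "ns", rng_seed = 2)
  expect_length(intersect(names(a$master_pool$entries),
                          names(b$master_pool$entries)), 0L)
  # same seed reproduces the same pseudonyms
  a2 <- pseudonymize_one_tier(d, "ns", rng_seed = 1)
  expect_identical(names(a$master_pool$entries),
                   names(a2$master_pool$entries))
})

test_that("CSV + schema and JSON-lines serializations round-trip", {
  dir <- withr::local_tempdir()
  reg <- generate_registry(generator_spec(n_subjects = 4L, seed = 7L))
  csv <- file.path(dir, "d.csv")
  sch <- file.path(dir, "d.schema")
  write_integrated_csv(reg$dataset, csv, sch)
  back <- read_integrated_csv(csv, sch)
  expect_identical(back$schema, reg$dataset$schema)
  expect_true(same_records(back, reg$dataset))

  tier <- pseudonymize_two_tier(reg$dataset, "a", "b", rng_seed = 7)
  pf <- file.path(dir, "pool.jsonl")
  write_pool_jsonl(tier$master_pool, pf)
  pool2 <- read_pool_jsonl(pf)
  expect_identical(pool2$namespace, "a")
  expect_setequal(names(pool2$entries), names(tier$master_pool$entries))

  mf <- file.path(dir, "map.jsonl")
  write_mapping_jsonl(tier$mapping, mf)
  m2 <- read_mapping_jsonl(mf, "a", "b")
  expect_identical(m2$pairs[order(m2$pairs$pseudonym_a), ],
                   tier$mapping$pairs[order(tier$mapping$pairs$pseudonym_a), ],
                   ignore_attr = TRUE)
})
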