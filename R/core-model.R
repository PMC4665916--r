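#' Integrated per-subject dataset
#'
#' The logical global record set of a registry before separation (and after
#' authorized client-side reconstruction). Every non-key column must carry an
#' explicit category declaration: `"identifying"` (master data: name, birth
#' date, institution, ...) or `"payload"` (substantive research content).
#' Categories are declared, never inferred: which attributes may safely stay
#' in the payload pool is an open question in pseudonymization practice, so
#' the package refuses to guess.
#'
#' @param data a `data.frame` with a unique `subject_key` column plus one
#'   column per declared attribute.
#' @param schema named character vector mapping every non-key column to
#'   `"identifying"` or `"payload"`.
#' @param degenerate set `TRUE` to allow datasets lacking one of the two
#'   categories (used for edge-case testing only).
#' @return an object of class `integrated_dataset` with elements `data` and
#'   `schema`.
#' @examples
#' d <- integrated_dataset(
#'   data.frame(subject_key = c("p1", "p2"),
#'              name = c("A", "B"), dx = c("D", "E")),
#'   schema = c(name = "identifying", dx = "payload")
#' )
#' n_records(d)
#' @export
integrated_dataset <- function(data, schema, degenerate = FALSE) {
  if (!is.data.frame(data)) {
    pr_stop("`data` must be a data.frame", "pseudoreg_schema_error")
  }
  if (!"subject_key" %in% names(data)) {
    pr_stop("`data` must contain a `subject_key` column",
            "pseudoreg_schema_error")
  }
  keys <- as.character(data$subject_key)
  if (anyDuplicated(keys)) {
    pr_stop("duplicate subject_key values in dataset",
            "pseudoreg_duplicate_key_error")
  }
  attrs <- setdiff(names(data), "subject_key")
  schema <- unlist(schema)
  if (!setequal(names(schema), attrs)) {
    pr_stop(sprintf(
      "schema must declare exactly the dataset attributes (missing: %s; extra: %s)",
      paste(setdiff(attrs, names(schema)), collapse = ", "),
      paste(setdiff(names(schema), attrs), collapse = ", ")
    ), "pseudoreg_schema_error")
  }
  bad <- !schema %in% c("identifying", "payload")
  if (any(bad)) {
    pr_stop(sprintf("undeclared attribute category for: %s",
                    paste(names(schema)[bad], collapse = ", ")),
            "pseudoreg_schema_error")
  }
  if (!degenerate && nrow(data) > 0 &&
      (!any(schema == "identifying") || !any(schema == "payload"))) {
    pr_stop("dataset must have at least one identifying and one payload attribute",
            "pseudoreg_schema_error")
  }
  structure(
    list(data = data, schema = schema[attrs]),
    class = "integrated_dataset"
  )
}

#' @export
print.integrated_dataset <- function(x, ...) {
  cat(sprintf("<integrated_dataset: %d records, %d identifying + %d payload attributes>\n",
              nrow(x$data), sum(x$schema == "identifying"),
              sum(x$schema == "payload")))
  invisible(x)
}

#' Number of records in an integrated dataset
#' @param x an `integrated_dataset`.
#' @return integer record count.
#' @export
n_records <- function(x) nrow(x$data)

# one record -> named list of attribute values (subject_key excluded)
dataset_records <- function(ds) {
  attrs <- names(ds$schema)
  lapply(seq_len(nrow(ds$data)), function(i) {
    vals <- lapply(attrs, function(a) ds$data[[a]][i])
    names(vals) <- attrs
    list(subject_key = as.character(ds$data$subject_key[i]), attrs = vals)
  })
}

record_attrs_by_category <- function(ds, record, category) {
  record$attrs[names(ds$schema)[ds$schema == category]]
}

#' Attribute pool of a single category
#'
#' One of the two separated persistent stores produced by pseudonymization:
#' either a master-data pool or a payload pool, keyed by opaque pseudonyms of
#' a single namespace. A pool never contains subject keys nor attributes of
#' the other category.
#'
#' @param namespace text label of the owning component's identifier namespace.
#' @param category `"identifying"` or `"payload"`.
#' @param entries named list: pseudonym value -> named list of attribute values.
#' @return an object of class `pseudonym_pool`.
#' @export
pseudonym_pool <- function(namespace, category, entries = list()) {
  stopifnot(is.character(namespace), length(namespace) == 1L,
            category %in% c("identifying", "payload"))
  structure(list(namespace = namespace, category = category,
                 entries = entries),
            class = "pseudonym_pool")
}

#' @export
print.pseudonym_pool <- function(x, ...) {
  cat(sprintf("<pseudonym_pool ns=%s category=%s entries=%d>\n",
              x$namespace, x$category, length(x$entries)))
  invisible(x)
}

#' Pseudonym pair table of a mapping service
#'
#' Links identifiers of two distinct namespaces through bare
#' (pseudonym_a, pseudonym_b) pairs; it carries no attribute values and each
#' pseudonym appears in at most one pair.
#'
#' @param pairs data.frame with columns `pseudonym_a`, `pseudonym_b`.
#' @param namespace_a,namespace_b the two distinct namespaces being linked.
#' @return an object of class `mapping_table`.
#' @export
mapping_table <- function(pairs = data.frame(pseudonym_a = character(),
                                             pseudonym_b = character(),
                                             stringsAsFactors = FALSE),
                          namespace_a, namespace_b) {
  if (identical(namespace_a, namespace_b)) {
    pr_stop("the two namespaces of a mapping table must differ",
            "pseudoreg_namespace_error")
  }
  pairs <- data.frame(pseudonym_a = as.character(pairs$pseudonym_a),
                      pseudonym_b = as.character(pairs$pseudonym_b),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(pairs$pseudonym_a) || anyDuplicated(pairs$pseudonym_b)) {
    pr_stop("each pseudonym may appear in at most one pair",
            "pseudoreg_mapping_error")
  }
  structure(list(pairs = pairs, namespace_a = namespace_a,
                 namespace_b = namespace_b),
            class = "mapping_table")
}

#' @export
print.mapping_table <- function(x, ...) {
  cat(sprintf("<mapping_table %s<->%s pairs=%d>\n",
              x$namespace_a, x$namespace_b, nrow(x$pairs)))
  invisible(x)
}

#' One-tier pseudonymization
#'
#' Separates an integrated dataset into a master pool and a payload pool that
#' share a single pseudonym per record (one namespace). The subject key
#' appears in neither pool; pseudonyms are random 128-bit values, independent
#' of record content.
#'
#' @param dataset an [integrated_dataset()].
#' @param ns namespace label for both pools.
#' @param rng_seed integer seed for reproducible pseudonym generation, or
#'   `NULL` to draw from the current RNG stream.
#' @return list with elements `master_pool` and `payload_pool`.
#' @export
pseudonymize_one_tier <- function(dataset, ns, rng_seed = NULL) {
  stopifnot(inherits(dataset, "integrated_dataset"))
  recs <- dataset_records(dataset)
  psn <- with_seed(rng_seed, unique_hex_ids(length(recs)))
  master <- payload <- list()
  for (i in seq_along(recs)) {
    master[[psn[i]]] <- record_attrs_by_category(dataset, recs[[i]], "identifying")
    payload[[psn[i]]] <- record_attrs_by_category(dataset, recs[[i]], "payload")
  }
  list(master_pool = pseudonym_pool(ns, "identifying", master),
       payload_pool = pseudonym_pool(ns, "payload", payload))
}

#' Two-tier pseudonymization
#'
#' Separates an integrated dataset into a master pool keyed by pseudonyms of
#' namespace `ns_a` and a payload pool keyed by pseudonyms of the distinct
#' namespace `ns_b`; the pools are linked only through a mapping table of
#' cascading identifier pairs, so no single store can reproduce the join.
#'
#' @inheritParams pseudonymize_one_tier
#' @param ns_a namespace of the master pool.
#' @param ns_b namespace of the payload pool; must differ from `ns_a`.
#' @return list with elements `master_pool`, `payload_pool`, `mapping`.
#' @export
pseudonymize_two_tier <- function(dataset, ns_a, ns_b, rng_seed = NULL) {
  stopifnot(inherits(dataset, "integrated_dataset"))
  if (identical(ns_a, ns_b)) {
    pr_stop("two-tier pseudonymization requires two distinct namespaces",
            "pseudoreg_namespace_error")
  }
  recs <- dataset_records(dataset)
  n <- length(recs)
  ids <- with_seed(rng_seed, unique_hex_ids(2L * n))
  psn_a <- ids[seq_len(n)]
  psn_b <- ids[n + seq_len(n)]
  master <- payload <- list()
  for (i in seq_along(recs)) {
    master[[psn_a[i]]] <- record_attrs_by_category(dataset, recs[[i]], "identifying")
    payload[[psn_b[i]]] <- record_attrs_by_category(dataset, recs[[i]], "payload")
  }
  list(
    master_pool = pseudonym_pool(ns_a, "identifying", master),
    payload_pool = pseudonym_pool(ns_b, "payload", payload),
    mapping = mapping_table(
      data.frame(pseudonym_a = psn_a, pseudonym_b = psn_b,
                 stringsAsFactors = FALSE),
      namespace_a = ns_a, namespace_b = ns_b
    )
  )
}

# hex ids guaranteed unique within one call (collision among 128-bit values is
# negligible, but uniqueness is an invariant, so it is enforced)
unique_hex_ids <- function(n) {
  ids <- random_hex(n)
  while (anyDuplicated(ids)) {
    dup <- duplicated(ids)
    ids[dup] <- random_hex(sum(dup))
  }
  ids
}

#' Reconstruct an integrated dataset from separated pools
#'
#' De-pseudonymization: joins a master pool and a payload pool back into
#' per-subject records. For one-tier pools (shared namespace) no mapping is
#' needed; for two-tier pools the mapping table drives the join. Entries that
#' cannot be linked (missing pair, or a pair pointing at an absent pool entry,
#' i.e. a dangling link) are never silently dropped: they are returned in the
#' `unmatched` report so partial de-pseudonymization remains representable.
#'
#' @param master_pool,payload_pool the separated pools.
#' @param mapping a [mapping_table()] for two-tier pools, or `NULL` for
#'   one-tier pools sharing a namespace.
#' @return an object of class `integration_result`: list with `dataset` (an
#'   [integrated_dataset()] keyed by the master-side pseudonym) and
#'   `unmatched` (data.frame `namespace`, `pseudonym`, `reason`).
#' @export
integrate_pools <- function(master_pool, payload_pool, mapping = NULL) {
  stopifnot(inherits(master_pool, "pseudonym_pool"),
            inherits(payload_pool, "pseudonym_pool"))
  unmatched <- list()
  note_unmatched <- function(ns, psn, reason) {
    unmatched[[length(unmatched) + 1L]] <<-
      data.frame(namespace = ns, pseudonym = psn, reason = reason,
                 stringsAsFactors = FALSE)
  }
  records <- list()
  if (is.null(mapping)) {
    if (!identical(master_pool$namespace, payload_pool$namespace)) {
      pr_stop("one-tier integration requires pools sharing one namespace",
              "pseudoreg_namespace_error")
    }
    keys_m <- names(master_pool$entries)
    keys_p <- names(payload_pool$entries)
    for (k in intersect(keys_m, keys_p)) {
      records[[k]] <- c(master_pool$entries[[k]], payload_pool$entries[[k]])
    }
    for (k in setdiff(keys_m, keys_p)) {
      note_unmatched(master_pool$namespace, k, "no_counterpart")
    }
    for (k in setdiff(keys_p, keys_m)) {
      note_unmatched(payload_pool$namespace, k, "no_counterpart")
    }
  } else {
    stopifnot(inherits(mapping, "mapping_table"))
    pairs <- mapping$pairs
    linked_a <- character(0)
    linked_b <- character(0)
    for (i in seq_len(nrow(pairs))) {
      a <- pairs$pseudonym_a[i]
      b <- pairs$pseudonym_b[i]
      has_a <- a %in% names(master_pool$entries)
      has_b <- b %in% names(payload_pool$entries)
      if (has_a && has_b) {
        records[[a]] <- c(master_pool$entries[[a]], payload_pool$entries[[b]])
        linked_a <- c(linked_a, a)
        linked_b <- c(linked_b, b)
      } else {
        if (!has_a) note_unmatched(master_pool$namespace, a, "dangling_link")
        if (!has_b) note_unmatched(payload_pool$namespace, b, "dangling_link")
        if (has_a) note_unmatched(master_pool$namespace, a, "counterpart_missing")
        if (has_b) note_unmatched(payload_pool$namespace, b, "counterpart_missing")
      }
    }
    for (k in setdiff(names(master_pool$entries), pairs$pseudonym_a)) {
      note_unmatched(master_pool$namespace, k, "no_pair")
    }
    for (k in setdiff(names(payload_pool$entries), pairs$pseudonym_b)) {
      note_unmatched(payload_pool$namespace, k, "no_pair")
    }
  }
  dataset <- records_to_dataset(records, master_pool, payload_pool)
  unmatched <- if (length(unmatched)) {
    do.call(rbind, unmatched)
  } else {
    data.frame(namespace = character(), pseudonym = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  structure(list(dataset = dataset, unmatched = unmatched),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("<integration_result: %d records, %d unmatched entries>\n",
              n_records(x$dataset), nrow(x$unmatched)))
  invisible(x)
}

records_to_dataset <- function(records, master_pool, payload_pool) {
  attr_names <- unique(c(
    unlist(lapply(master_pool$entries, names), use.names = FALSE),
    unlist(lapply(payload_pool$entries, names), use.names = FALSE)
  ))
  m_names <- unique(unlist(lapply(master_pool$entries, names),
                           use.names = FALSE))
  schema <- ifelse(attr_names %in% m_names, "identifying", "payload")
  names(schema) <- attr_names
  cols <- lapply(attr_names, function(a) {
    if (length(records) == 0L) return(character(0))
    vals <- lapply(records, function(r) r[[a]] %||% NA)
    unlist(vals, use.names = FALSE)
  })
  names(cols) <- attr_names
  df <- data.frame(subject_key = names(records) %||% character(0),
                   stringsAsFactors = FALSE)
  for (a in attr_names) df[[a]] <- cols[[a]]
  integrated_dataset(df, schema, degenerate = TRUE)
}

#' Order-insensitive record equality between integrated datasets
#'
#' Compares two datasets as multisets of attribute maps, ignoring subject keys
#' and row/column order (pseudonymization intentionally discards subject keys,
#' and no ordering of records is guaranteed by the separation model).
#'
#' @param a,b `integrated_dataset` objects.
#' @return `TRUE` if the record multisets match.
#' @export
same_records <- function(a, b) {
  sig <- function(ds) {
    recs <- dataset_records(ds)
    sort(vapply(recs, function(r) {
      vals <- r$attrs[order(names(r$attrs))]
      to_json_chr(lapply(vals, as.character))
    }, character(1)))
  }
  identical(sig(a), sig(b))
}
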