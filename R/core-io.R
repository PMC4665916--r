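#' Read an integrated dataset from CSV plus a schema file
#'
#' The CSV (UTF-8, header row) must contain a `subject_key` column; the schema
#' file declares one `name = category` line per remaining column, with
#' category `identifying` or `payload`. Blank lines and `#` comments are
#' ignored.
#'
#' @param csv_path path to the delimited dataset.
#' @param schema_path path to the key-value schema file.
#' @return an [integrated_dataset()].
#' @export
read_integrated_csv <- function(csv_path, schema_path) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  integrated_dataset(df, read_schema_file(schema_path))
}

read_schema_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^=]+)=(.+)$", lines))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    pr_stop(sprintf("malformed schema line: %s", lines[bad][1]),
            "pseudoreg_schema_error")
  }
  schema <- vapply(m, function(x) trimws(x[3]), character(1))
  names(schema) <- vapply(m, function(x) trimws(x[2]), character(1))
  schema
}

#' Write an integrated dataset as CSV plus a schema file
#' @param dataset an [integrated_dataset()].
#' @param csv_path,schema_path output paths.
#' @return invisibly, the dataset.
#' @export
write_integrated_csv <- function(dataset, csv_path, schema_path) {
  stopifnot(inherits(dataset, "integrated_dataset"))
  write.csv(dataset$data, csv_path, row.names = FALSE)
  writeLines(sprintf("%s = %s", names(dataset$schema), dataset$schema),
             schema_path)
  invisible(dataset)
}

#' Serialize a pseudonym pool to JSON-lines
#'
#' One entry per line with stable field names `namespace`, `pseudonym`,
#' `attributes`. `read_pool_jsonl()` reverses the operation.
#'
#' @param pool a [pseudonym_pool()].
#' @param path output file; if `NULL` the lines are returned as a character
#'   vector.
#' @return the JSON lines, invisibly when written to a file.
#' @export
write_pool_jsonl <- function(pool, path = NULL) {
  stopifnot(inherits(pool, "pseudonym_pool"))
  lines <- vapply(names(pool$entries), function(p) {
    to_json_chr(list(namespace = pool$namespace, category = pool$category,
                     pseudonym = p, attributes = pool$entries[[p]]))
  }, character(1), USE.NAMES = FALSE)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_pool_jsonl
#' @param namespace,category pool identity, required when reading an empty
#'   file; otherwise taken from the first line.
#' @export
read_pool_jsonl <- function(path, namespace = NULL, category = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  entries <- list()
  for (ln in lines) {
    obj <- from_json_chr(ln)
    namespace <- namespace %||% obj$namespace
    category <- category %||% obj$category
    entries[[obj$pseudonym]] <- obj$attributes
  }
  if (is.null(namespace) || is.null(category)) {
    pr_stop("empty pool file needs explicit namespace and category",
            "pseudoreg_schema_error")
  }
  pseudonym_pool(namespace, category, entries)
}

#' Serialize a mapping table to JSON-lines
#'
#' One pair per line with stable field names `pseudonym_a`, `pseudonym_b`.
#'
#' @param mapping a [mapping_table()].
#' @param path output file; `NULL` returns the lines.
#' @return the JSON lines, invisibly when written to a file.
#' @export
write_mapping_jsonl <- function(mapping, path = NULL) {
  stopifnot(inherits(mapping, "mapping_table"))
  lines <- vapply(seq_len(nrow(mapping$pairs)), function(i) {
    to_json_chr(list(pseudonym_a = mapping$pairs$pseudonym_a[i],
                     pseudonym_b = mapping$pairs$pseudonym_b[i]))
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_mapping_jsonl
#' @param namespace_a,namespace_b namespaces of the reconstructed table.
#' @export
read_mapping_jsonl <- function(path, namespace_a, namespace_b) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  pairs <- if (length(lines)) {
    do.call(rbind, lapply(lines, function(ln) {
      obj <- from_json_chr(ln)
      data.frame(pseudonym_a = obj$pseudonym_a, pseudonym_b = obj$pseudonym_b,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(pseudonym_a = character(), pseudonym_b = character(),
               stringsAsFactors = FALSE)
  }
  mapping_table(pairs, namespace_a, namespace_b)
}
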