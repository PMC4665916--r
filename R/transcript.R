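# Ordered protocol trace. Message exchanges and local server-side actions are
# recorded as numbered steps; only messages count towards message_count, and
# every message routed via the client keeps its full on-wire body so
# confidentiality assertions can scan the bytes a client actually saw.

new_recorder <- function() {
  env <- new.env(parent = emptyenv())
  env$steps <- list()
  env
}

record_message <- function(rec, from, to, kind, body,
                           visible_to_client = TRUE) {
  if (is.null(rec)) return(invisible(body))
  body_json <- to_json_chr(body)
  rec$steps[[length(rec$steps) + 1L]] <- list(
    step_no = length(rec$steps) + 1L,
    from = from, to = to, kind = kind,
    visible_to_client = isTRUE(visible_to_client),
    body_digest = sha256_hex(body_json),
    body = if (isTRUE(visible_to_client)) body_json else NA_character_
  )
  invisible(body)
}

record_local <- function(rec, at, action) {
  if (is.null(rec)) return(invisible(action))
  rec$steps[[length(rec$steps) + 1L]] <- list(
    step_no = length(rec$steps) + 1L,
    from = at, to = at, kind = "local",
    visible_to_client = FALSE,
    body_digest = sha256_hex(action),
    body = NA_character_
  )
  invisible(action)
}

as_transcript <- function(rec) {
  if (is.null(rec)) return(NULL)
  field <- function(name, type) {
    vapply(rec$steps, function(s) s[[name]], type)
  }
  steps <- data.frame(
    step_no = field("step_no", integer(1)),
    from = field("from", character(1)),
    to = field("to", character(1)),
    kind = field("kind", character(1)),
    visible_to_client = field("visible_to_client", logical(1)),
    body_digest = field("body_digest", character(1)),
    stringsAsFactors = FALSE
  )
  structure(list(
    steps = steps,
    bodies = vapply(rec$steps, function(s) s$body, character(1)),
    message_count = sum(steps$kind != "local")
  ), class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript: %d steps, %d messages>\n",
              nrow(x$steps), x$message_count))
  if (nrow(x$steps)) {
    print(x$steps[, c("step_no", "from", "to", "kind", "visible_to_client")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Number of steps / messages in a transcript
#' @param transcript a transcript as returned by the join protocols.
#' @return integer.
#' @export
transcript_steps <- function(transcript) nrow(transcript$steps)

#' @rdname transcript_steps
#' @export
transcript_messages <- function(transcript) transcript$message_count

#' Write a transcript as JSON-lines
#' @param transcript a transcript.
#' @param path output file.
#' @return invisibly, the lines written.
#' @export
write_transcript_jsonl <- function(transcript, path) {
  lines <- vapply(seq_len(nrow(transcript$steps)), function(i) {
    s <- transcript$steps[i, ]
    to_json_chr(list(step_no = s$step_no, from = s$from, to = s$to,
                     kind = s$kind, visible_to_client = s$visible_to_client,
                     body_digest = s$body_digest))
  }, character(1))
  writeLines(lines, path)
  invisible(lines)
}

#' Scan client-visible transcript bytes for internal pseudonyms
#'
#' Confidentiality check: concatenated over every message body the client
#' could see, no internal pseudonym of any namespace may occur as a
#' substring. Sealed tokens hide pseudonyms by encryption; temporary
#' identifiers hide them in responses.
#'
#' @param transcript a transcript (or list of transcripts).
#' @param pseudonyms character vector of internal pseudonym values, e.g.
#'   [internal_pseudonyms()].
#' @return data.frame of violations (`step_no`, `pseudonym`); zero rows when
#'   confidentiality holds.
#' @export
assert_confidential <- function(transcript, pseudonyms) {
  if (inherits(transcript, "transcript")) transcript <- list(transcript)
  out <- list()
  for (tr in transcript) {
    vis <- which(tr$steps$visible_to_client)
    for (i in vis) {
      body <- tr$bodies[i]
      if (is.na(body)) next
      hit <- pseudonyms[vapply(pseudonyms, function(p) {
        grepl(p, body, fixed = TRUE)
      }, logical(1))]
      for (p in hit) {
        out[[length(out) + 1L]] <- data.frame(
          step_no = tr$steps$step_no[i], pseudonym = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(step_no = integer(), pseudonym = character(),
               stringsAsFactors = FALSE)
}
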