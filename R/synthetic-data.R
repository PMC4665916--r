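# Synthetic fake-name word lists. All values are invented; no real-person
# data ships with the package.
.given_names <- c(
  "Alva", "Boris", "Carla", "Dario", "Edda", "Falko", "Greta", "Hanno",
  "Ilka", "Jonas", "Katja", "Lennart", "Mira", "Nuno", "Odile", "Pavel",
  "Quirin", "Runa", "Sören", "Talia"
)
.family_names <- c(
  "Achterberg", "Brenner", "Cervantes", "Dahlke", "Eriksson", "Fontaine",
  "Grünwald", "Haverkamp", "Ivarsson", "Jelinek", "Kowalczyk", "Lindqvist",
  "Moreau", "Novak", "Oliveira", "Petrov", "Quast", "Rasmussen", "Steiner",
  "Tanaka"
)
.diagnoses <- c("MT-DX-01", "MT-DX-02", "MT-DX-03", "MT-DX-04", "MT-DX-05")

#' Default document-type schemas for the synthetic registry
#'
#' Three eCRF-like document types: a clinical baseline form, a clinical
#' follow-up form and a biospecimen registration form. Each entry declares its
#' payload fields and its access-control data class.
#'
#' @return named list of `list(fields, data_class)`.
#' @export
default_doc_types <- function() {
  list(
    baseline = list(fields = c("diagnosis", "onset_age"),
                    data_class = "clinical"),
    followup = list(fields = c("visit_date", "severity_score"),
                    data_class = "clinical"),
    specimen = list(fields = c("sample_type", "kit_id"),
                    data_class = "specimen")
  )
}

#' Specification for the synthetic registry generator
#'
#' Defaults describe a small multi-site rare-disease registry: 10 subjects
#' over 3 sites, one to three documents per subject drawn from the default
#' eCRF schemas. The same spec and seed always reproduce a byte-identical
#' registry.
#'
#' @param n_subjects number of subjects (0 allowed: empty registry).
#' @param n_sites number of recruiting sites; subjects are assigned
#'   round-robin.
#' @param docs_per_subject integer range `c(min, max)` of payload documents
#'   per subject.
#' @param doc_types document-type schemas, see [default_doc_types()].
#' @param seed integer seed controlling every random draw.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects = 10L, n_sites = 3L,
                           docs_per_subject = c(1L, 3L),
                           doc_types = default_doc_types(), seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L ||
      is.na(n_subjects) || n_subjects < 0) {
    pr_stop("n_subjects must be a non-negative integer",
            "pseudoreg_spec_error")
  }
  if (!is.numeric(n_sites) || n_sites < 1) {
    pr_stop("n_sites must be a positive integer", "pseudoreg_spec_error")
  }
  if (length(docs_per_subject) != 2L || any(docs_per_subject < 0) ||
      docs_per_subject[1] > docs_per_subject[2]) {
    pr_stop("docs_per_subject must be an increasing non-negative range",
            "pseudoreg_spec_error")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sites = as.integer(n_sites),
                 docs_per_subject = as.integer(docs_per_subject),
                 doc_types = doc_types, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic integrated registry
#'
#' Produces a deterministic integrated dataset (identifying attributes:
#' synthetic name, birth date, site; payload attributes: record-level clinical
#' summary), a user directory (one physician per site plus a monitor, an
#' administrator and a lab account; passwords are fixed synthetic strings
#' `pw-<username>`), per-subject payload documents per the doc-type schemas,
#' and the round-robin site assignment.
#'
#' @param spec a [generator_spec()].
#' @return list with elements `dataset`, `users`, `documents`, `sites`,
#'   `spec`. `users` is a data.frame (`username`, `password`, `role`, `site`);
#'   `documents` is a list of `list(subject_key, doc_type, data_class, content)`.
#' @export
generate_registry <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    sites <- sprintf("site-%02d", seq_len(spec$n_sites))
    site_of <- rep_len(sites, n)
    keys <- sprintf("SUBJ-%04d", seq_len(n))
    df <- data.frame(
      subject_key = keys,
      given_name = if (n) sample(.given_names, n, replace = TRUE) else character(0),
      family_name = if (n) sample(.family_names, n, replace = TRUE) else character(0),
      birth_date = if (n) {
        format(as.Date("1950-01-01") + sample.int(20000L, n, replace = TRUE),
               "%Y-%m-%d")
      } else character(0),
      site = site_of,
      diagnosis = if (n) sample(.diagnoses, n, replace = TRUE) else character(0),
      onset_age = if (n) as.character(sample(1:70, n, replace = TRUE)) else character(0),
      stringsAsFactors = FALSE
    )
    schema <- c(given_name = "identifying", family_name = "identifying",
                birth_date = "identifying", site = "identifying",
                diagnosis = "payload", onset_age = "payload")
    dataset <- integrated_dataset(df, schema)

    documents <- list()
    type_names <- names(spec$doc_types)
    for (i in seq_len(n)) {
      range_k <- seq(spec$docs_per_subject[1], spec$docs_per_subject[2])
      k <- range_k[sample.int(length(range_k), 1L)]
      for (j in seq_len(k)) {
        tn <- sample(type_names, 1L)
        tp <- spec$doc_types[[tn]]
        content <- lapply(tp$fields, function(f) synth_field_value(f))
        names(content) <- tp$fields
        documents[[length(documents) + 1L]] <- list(
          subject_key = keys[i], doc_type = tn,
          data_class = tp$data_class, content = content
        )
      }
    }

    users <- data.frame(
      username = c(sprintf("phys-%s", sites), "monitor-1", "admin-1", "lab-1"),
      role = c(rep("physician", length(sites)), "monitor", "administrator",
               "lab"),
      site = c(sites, sites[1], sites[1], sites[1]),
      stringsAsFactors = FALSE
    )
    users$password <- sprintf("pw-%s", users$username)

    list(dataset = dataset, users = users, documents = documents,
         sites = sites, spec = spec)
  })
}

synth_field_value <- function(field) {
  switch(field,
    diagnosis = sample(.diagnoses, 1L),
    onset_age = as.character(sample(1:70, 1L)),
    visit_date = format(as.Date("2024-01-01") + sample.int(700L, 1L),
                        "%Y-%m-%d"),
    severity_score = as.character(sample(0:10, 1L)),
    sample_type = sample(c("EDTA-blood", "serum", "fibroblast"), 1L),
    kit_id = sprintf("KIT-%05d", sample.int(99999L, 1L)),
    random_hex(1L, 4L)
  )
}

#' Three-record worked example dataset
#'
#' The canonical miniature registry used throughout the documentation and
#' tests: three records with one identifying attribute (values `A`, `B`, `C`)
#' and one payload attribute (values `D`, `E`, `F`), paired in order.
#'
#' @return an [integrated_dataset()] with 3 records and 2 attributes.
#' @export
example_integrated_dataset <- function() {
  integrated_dataset(
    data.frame(subject_key = c("p1", "p2", "p3"),
               attr1 = c("A", "B", "C"),
               attr2 = c("D", "E", "F"),
               stringsAsFactors = FALSE),
    schema = c(attr1 = "identifying", attr2 = "payload")
  )
}
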