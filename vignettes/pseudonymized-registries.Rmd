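---
title: "Managing pseudonymized registry data with separated backends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Managing pseudonymized registry data with separated backends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoreg)
```

## The problem

Multi-site biomedical registries collect sensitive person-related data
prospectively, often over many years. Data-protection law requires that data
enabling the identification of a subject be *kept separately* from the
substantive research content, linked only through arbitrary codes —
pseudonyms. `pseudoreg` implements a complete, testable model of such a
system: how an integrated per-subject record set is separated into pools,
how the pools are distributed over mutually distrusting services, and how an
authorized client reconstructs integrated views without any server ever
holding the joined data and without the client ever learning the internal
pseudonyms the servers use.

The package is a reference implementation for method development and
teaching, not a deployment: transport is an in-process message bus that
models request/response routing one-to-one (an HTTP deployment maps each
message to one request), and storage is in-memory with JSON-lines
persistence. The protocols are defined by message content and routing, which
is exactly what the package makes observable through transcripts.

## The data model: declared separation

An *integrated dataset* is a set of per-subject records whose attributes are
partitioned into two categories:

* **identifying** (master data): name, birth date, recruiting institution;
* **payload**: substantive research content (clinical record summaries,
  eCRF documents, biospecimen registrations).

Which attributes can safely remain in the payload pool is an unresolved
question in pseudonymization practice — diagnosis codes, for instance, can
themselves be re-identifying. The package therefore requires an explicit
per-attribute declaration in the dataset schema and refuses to infer
categories. Statistical re-identification risk of the payload pool is out of
scope.

Two separation schemes are provided:

* **one-tier**: both pools are keyed by the *same* pseudonym per record.
  Whoever obtains both pools can join them directly.
* **two-tier**: each pool is keyed in its *own namespace*, and the only link
  is a table of bare `(pseudonym_a, pseudonym_b)` pairs held by a dedicated
  mapping service. Compromising any single store — including the mapping
  service, which holds no attribute values — yields no
  (identifying, payload) pairing.

```{r}
d <- example_integrated_dataset()
d$data

tier <- pseudonymize_two_tier(d, "ns-a", "ns-b", rng_seed = 1)
tier$mapping$pairs
```

Pseudonyms are 128-bit random values rendered as lowercase hex, drawn from a
seedable stream for reproducibility and never derived from record content,
so identical attribute values under different seeds yield unrelated
pseudonyms. De-pseudonymization is the inverse join:

```{r}
r <- integrate_pools(tier$master_pool, tier$payload_pool, tier$mapping)
r$dataset$data
```

Entries that cannot be linked (a deleted pair, or a pair pointing at an
absent entry) are returned in a side report rather than raised as an error,
because partial de-pseudonymization is a legitimate state in exception
workflows. Record comparison throughout the package is order-insensitive:
the separation model guarantees no ordering.

## Sealed tokens

The services authenticate users themselves (non-delegated: every
token-bearing request is re-verified) and communicate through the client via
*sealed tokens*. A token carries the username, password, a replay counter
and structured payload data, and is built of exactly two encrypted
components: the fresh per-token symmetric key K1 sealed for the receiver
with RSA-2048 OAEP, and the canonical payload serialization encrypted and
integrity-protected under K1. The symmetric layer is an encrypt-then-MAC
composition (AES-256-CBC with HMAC-SHA256, both keys derived from K1 with
domain-separated SHA-256), chosen so that *every* single-byte modification
of either component is rejected with an integrity error and can never
surface as a garbled payload; OAEP's padding check provides the same
guarantee for the key component. The suite is named in each token
(`RSA-2048-OAEP/AES-256-CBC/HMAC-SHA256`) so that equivalent KEM/AEAD pairs
can be substituted without changing the token format.

Replay protection is a per-channel counter: each receiver records the
highest counter accepted from each sender and accepts only strictly greater
values. The scope is the sender-to-receiver channel (not global, which
would require coordination across parties, and not per-session — the
binding to sessions is left open here and documented as such); there is no
acceptance window. Keys are distributed peer-to-peer: every component holds
the public key of every other component, with no central key authority.

Tokens travel in the HTTP request line, encoded with unpadded base64url.
Since browsers cap URL length (historically 2083 characters), over-long
encodings are fragmented into framed sub-requests
(`rid`/`idx`/`tot`/`frag`) that reassemble losslessly under arbitrary
reordering, with missing indices reported by name and conflicting
duplicates rejected.

```{r}
ka <- make_keypair("a"); kb <- make_keypair("b")
ring_a <- keyring(ka, list(b = kb$pubkey))
ring_b <- keyring(kb, list(a = ka$pubkey))
tok <- seal_token(ring_a, "b", token_payload("alice", "pw", 1,
                                             list(op = "translate")))
tok
enc <- encode_request_line(tok)
length(fragment_request(enc, max_len = 300))
```

## The three parties and their joins

A minimal deployment has three services, each with its own namespace, user
directory, RBAC matrix, replay state and append-only audit trail:

* **primary**: subject root nodes with master data (optionally encrypted at
  rest with a dedicated symmetric key);
* **secondary**: payload documents, modeled as a tree under each subject's
  secondary-namespace pseudonym;
* **mapping service**: bare pseudonym pairs only. It stores nothing beyond
  the pairs — whether it may hold, say, timestamps is left open by current
  practice; this implementation deliberately stores the minimum.

A backend refuses to store data classes outside its declared set; that
refusal, not convention, is what enforces separation. One deliberate
reading: the "roots live on the primary" rule is enforced by *data class*
(master-class content is rejected outside the primary), because the
secondary necessarily holds parentless payload records keyed by its own
subject pseudonyms. Payload nodes carry a site tag so the enforcing backend
can apply the site filter; the tag is infrastructure metadata, not an
identifying attribute.

Clients never see internal pseudonyms (they see generated record labels and
single-use temporary identifiers), and reconstruction happens only at the
client. Two join choreographies are implemented:

```{r}
reg <- generate_registry(generator_spec(n_subjects = 4, seed = 7))
sys <- registry_system(reg, mode = "indirect", seed = 7)
cl <- registry_client(sys, "monitor-1", "pw-monitor-1")
run <- join_indirect_single(cl, "S0001")
run$transcript
```

* **indirect** (six steps, all routed via the client, servers stateless):
  the primary answers with master data under a fresh temporary identifier
  plus a sealed token holding the temp-to-internal association; the mapping
  service translates the association into the secondary namespace and
  re-seals; the secondary resolves and answers keyed by the temporary
  identifier.
* **direct** (nine steps, at least seven messages): the primary *persists*
  the temporary mapping; the secondary later asks the primary to resolve
  it, and the answer is routed through the mapping service — it has to be,
  because the mapping service is the only party able to translate the
  identifier into the secondary's namespace. When the request path of that
  resolution is itself routed is ambiguous in practice; here the request
  goes secondary-to-primary directly and only the answer cascades through
  the mapping service, matching the enumerated step count. Persisted
  temporary mappings are retired on successful resolution
  (delete-on-use), the pragmatic answer to the open question of when such
  state may be deleted.

The batch *list view* amortizes the same indirect pattern over all
authorized subjects in three rounds (primary, mapping service, secondary),
and the *document-creation cascade* implements single sign-on data entry:
credentials appear in clear only in the client's first request and
afterwards travel exclusively inside sealed tokens; the mapping service
creates a missing pseudonym pair on the fly, and the new document node
references the subject's secondary pseudonym as parent directly, so the
secondary store grows by exactly one node per document.

## Access control and audit

Four roles are encoded by default: application administrators (full CRUD on
user accounts, no access to any research data), monitors (read-only on
research data, across sites — quality assurance needs the full picture, so
site restriction for monitors is configurable rather than default),
physicians (full CRUD on master and clinical data, restricted to subjects
of their own site) and lab personnel (biospecimen registration documents;
modeled as site-unrestricted because specimen processing is centralized).
Denials are values, not exceptions, and every denial is audited — this is
what makes randomized authorization fuzzing countable. Each backend keeps a
gapless append-only audit log; for every reachable state the number of
executed mutating operations equals the number of create/update/delete
audit events.

## What the verifier checks

`verify_invariants()` executes the security properties as measurements:

* *separation*: `adversary_view()` attempts the forbidden join from each
  single party's state and must return zero linked pairs;
* *confidentiality*: the concatenated client-visible transcript bytes
  contain no internal pseudonym of any namespace (tested positively via a
  fault-injection switch that disables temporary-identifier substitution —
  the verifier must then flag the run);
* *replay*: a live probe replays an accepted token;
* *audit completeness* and *RBAC conformance* as above.

## The synthetic generator, and what passing tests do not show

`generate_registry()` produces a deterministic multi-site rare-disease-style
registry: invented names from a bundled synthetic word list (no real-person
data ships with the package), round-robin site assignment, a record-level
clinical summary per subject and one to three eCRF-like documents drawn
from three default schemas (baseline, follow-up, specimen registration).
Defaults are 10 subjects over 3 sites — the scale of the worked examples —
and the property suites use 100 registries of 10–200 subjects, chosen as
a realistic span for rare-disease site counts while keeping the full
protocol sweep (every subject joined under both choreographies, roughly
twenty thousand joins) tractable on one CPU.

The generator emulates structure, not clinical realism: attribute values
are uniform draws, documents are independent of one another, and there is
no missingness, no record-linkage noise, and no longitudinal correlation.
Passing tests therefore demonstrate the correctness of separation, token
security and join choreography — they say nothing about re-identification
risk of real payload distributions, which is explicitly out of scope.

## Numerical and degenerate-input choices

* Pseudonyms and temporary identifiers are uniform 128-bit values;
  uniqueness is nonetheless enforced, not assumed. Temporary identifiers
  carry a `tmp-` prefix so they can never collide with internal pseudonyms.
* Empty registries are legal everywhere: empty pools, an empty list view
  (which short-circuits after the primary round), and a zero-exit CLI run.
* Duplicate subject keys, undeclared attribute categories, and same-namespace
  two-tier requests are rejected at construction.
* Passwords are stored as salted SHA-256 hashes on every service; unknown
  users and wrong passwords are indistinguishable on denial.
* Fragment framing fixes six-digit index/total fields; the framing overhead
  is 48 characters, and a limit too small to carry one payload character is
  rejected rather than looped on.

## Limitations

Browser mechanics (frames, cross-origin policy, redirects), TLS deployment,
two-factor authentication and biosample logistics are intentionally out of
scope; the package models their net effect — client-side-only joining — not
their implementation. The mapping service authenticates end users as well
as peers (credentials travel in every token); deployments that want the
mapping service blind to user identities would need a different token
payload. A single mapping service links exactly two namespaces; chaining
more tiers is possible by composition but not packaged.
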