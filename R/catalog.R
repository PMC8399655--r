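# Reference catalogue of PKS cluster components and cluster templates.
# The shipped default mirrors the conserved Bacillus pks/bae operon
# (18 slots, PksA..PksS) plus keyword/synonym-driven macrolactin (mln) and
# difficidin (dfn) templates.

#' Construct a catalogue entry
#'
#' @param component_id Canonical component name (unique within a catalogue).
#' @param description Enzyme description text.
#' @param ec_numbers Character vector of EC numbers (may be empty; `-`
#'   wildcards allowed).
#' @param keywords List/vector of token patterns; a pattern matches a product
#'   string when *all* of its (lower-cased, punctuation-stripped) tokens occur
#'   in the product.
#' @param gene_synonyms Gene-name strings matched case-insensitively.
#' @param reference_proteins Named character vector of amino-acid sequences
#'   (label -> sequence); may be empty.
#' @param core Does this slot count toward cluster completeness thresholds?
#'   (`FALSE` only for regulator and hypothetical slots.)
#' @return An object of class `catalog_entry`.
#' @export
catalog_entry <- function(component_id, description, ec_numbers = character(),
                          keywords = list(description), gene_synonyms = character(),
                          reference_proteins = character(), core = TRUE) {
  if (!nzchar(component_id))
    pks_abort("component_id must be non-empty", "pks_validation_error")
  keywords <- as.list(as.character(unlist(keywords)))
  if (length(keywords) && any(!nzchar(unlist(keywords))))
    pks_abort(sprintf("empty keyword pattern in %s", component_id), "pks_validation_error")
  ec_numbers <- as.character(ec_numbers)
  bad <- ec_numbers[!vapply(ec_numbers, is_valid_ec, logical(1))]
  if (length(bad))
    pks_abort(sprintf("%s: invalid EC number(s) %s", component_id,
                      paste(bad, collapse = ", ")), "pks_validation_error")
  rp <- as.character(reference_proteins)
  names(rp) <- names(reference_proteins)
  structure(list(
    component_id = component_id, description = description,
    ec_numbers = ec_numbers, keywords = keywords,
    gene_synonyms = as.character(gene_synonyms),
    reference_proteins = rp, core = isTRUE(core)
  ), class = "catalog_entry")
}

#' Construct a cluster template
#'
#' @param template_id Short cluster id (e.g. `"bae"`).
#' @param product_name Metabolite name (e.g. `"bacillaene"`).
#' @param components Ordered character vector of component ids.
#' @param max_gap_bp Maximum genomic gap (bp) between successive hits chained
#'   into one cluster call.
#' @param complete_max_missing A call is `complete` when at most this many
#'   template components are missing.
#' @param partial_min_hits Minimum hits for a `partial` (rather than `absent`)
#'   genome call.
#' @return An object of class `cluster_template`.
#' @export
cluster_template <- function(template_id, product_name, components,
                             max_gap_bp = 20000L, complete_max_missing = 3L,
                             partial_min_hits = 1L) {
  components <- as.character(components)
  if (!length(components))
    pks_abort(sprintf("template %s has no components", template_id),
              "pks_validation_error")
  if (complete_max_missing >= length(components))
    pks_abort(sprintf("template %s: complete_max_missing must be < number of components",
                      template_id), "pks_validation_error")
  if (partial_min_hits < 1L)
    pks_abort(sprintf("template %s: partial_min_hits must be >= 1", template_id),
              "pks_validation_error")
  structure(list(
    template_id = template_id, product_name = product_name,
    components = components,
    max_gap_bp = as.integer(max_gap_bp),
    complete_max_missing = as.integer(complete_max_missing),
    partial_min_hits = as.integer(partial_min_hits)
  ), class = "cluster_template")
}

#' Assemble a catalogue from entries and templates
#'
#' Validates uniqueness of component ids and referential integrity (every
#' component referenced by a template exists among the entries).
#'
#' @param entries List of [catalog_entry()] objects.
#' @param templates List of [cluster_template()] objects.
#' @param metadata Named list of free-form catalogue metadata.
#' @return An object of class `pks_catalog` with named elements `entries`,
#'   `templates`, `metadata`.
#' @export
pks_catalog <- function(entries, templates, metadata = list()) {
  ids <- vapply(entries, `[[`, character(1), "component_id")
  if (anyDuplicated(ids))
    pks_abort(sprintf("duplicate component_id: %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "pks_validation_error")
  names(entries) <- ids
  tids <- vapply(templates, `[[`, character(1), "template_id")
  names(templates) <- tids
  for (tmpl in templates) {
    missing <- setdiff(tmpl$components, ids)
    if (length(missing))
      pks_abort(sprintf("template %s references unknown component(s): %s",
                        tmpl$template_id, paste(missing, collapse = ", ")),
                "pks_validation_error")
  }
  structure(list(entries = entries, templates = templates, metadata = metadata),
            class = "pks_catalog")
}

#' @export
print.pks_catalog <- function(x, ...) {
  cat(sprintf("<pks_catalog> %d components, %d templates (%s)\n",
              length(x$entries), length(x$templates),
              paste(names(x$templates), collapse = ", ")))
  invisible(x)
}

#' The shipped default PKS catalogue
#'
#' Eighteen bacillaene (bae/pks) operon slots in operon order — PksA, a second
#' hypothetical slot (Hyp2), the TetR-family regulator, PksB..PksS — with the
#' enzyme descriptions and EC numbers of the conserved Bacillus macrocluster,
#' plus synonym-driven macrolactin (MlnA–I) and difficidin (DfnA–M) slots.
#' The two "SDR family NAD(P) dependent oxidoreductase" slots are named PksL
#' and PksM (the known B. subtilis operon order is pksJ-L-M-N-R-S); both carry
#' the same printed description. Non-core slots (not counted against
#' completeness thresholds by convention, though thresholds operate on all
#' slots): PksA, Hyp2, Regulator.
#'
#' Defaults: `max_gap_bp = 20000`, `complete_max_missing = 3`,
#' `partial_min_hits = 1` for every template.
#'
#' @return A [pks_catalog()].
#' @export
default_catalog <- function() {
  e <- function(...) catalog_entry(...)
  bae <- list(
    e("PksA", "Hypothetical protein", "3.1.2.6", gene_synonyms = "pksA", core = FALSE),
    e("Hyp2", "Hypothetical protein", "3.1.2.6", gene_synonyms = "hyp2", core = FALSE),
    e("Regulator", "TetR family transcriptional regulator C terminal",
      gene_synonyms = "tetR", core = FALSE),
    e("PksB", "MBL fold metallo hydrolase", "2.3.1.39", gene_synonyms = "pksB"),
    e("PksC", "ACP S malonyltransferase", "2.3.1.51", gene_synonyms = "pksC"),
    e("PksD", "Acyltransferase domain containing protein", "2.3.1.39",
      gene_synonyms = "pksD"),
    e("PksE", "ACP S malonyltransferase", c("1.3.1.9", "1.3.1.10"),
      gene_synonyms = "pksE"),
    e("AcpK", "Acyl carrier protein", "2.3.3.10", gene_synonyms = "acpK"),
    e("PksF", "Polyketide beta ketoacyl ACP synthase", "4.2.1.17",
      gene_synonyms = "pksF"),
    e("PksG", "Hydroxymethylglutaryl CoA synthase family", "4.2.1.17",
      gene_synonyms = "pksG"),
    e("PksH", "Enoyl CoA hydratase isomerase", gene_synonyms = "pksH"),
    e("PksI", "enoyl CoA hydratase isomerase family protein", gene_synonyms = "pksI"),
    e("PksJ", "Non ribosomal peptide synthetase", gene_synonyms = "pksJ"),
    e("PksL", "SDR family NAD(P) dependent oxidoreductase", "1.6.5.2",
      gene_synonyms = "pksL"),
    e("PksM", "SDR family NAD(P) dependent oxidoreductase", "1.6.5.2",
      gene_synonyms = "pksM"),
    e("PksN", "Non ribosomal peptide synthetase", gene_synonyms = "pksN"),
    e("PksR", "Polyketide synthase dehydratase domain", "2.1.1.-",
      gene_synonyms = "pksR"),
    e("PksS", "Cytochrome P450", "1.14.14.-", gene_synonyms = "pksS")
  )
  mln <- lapply(LETTERS[1:9], function(x) {
    e(paste0("Mln", x), sprintf("macrolactin trans-AT polyketide synthase Mln%s", x),
      keywords = list("macrolactin"), gene_synonyms = paste0("mln", tolower(x)))
  })
  dfn <- lapply(LETTERS[1:13], function(x) {
    e(paste0("Dfn", x), sprintf("difficidin polyketide synthase Dfn%s", x),
      keywords = list("difficidin"), gene_synonyms = paste0("dfn", tolower(x)))
  })
  templates <- list(
    cluster_template("bae", "bacillaene",
                     vapply(bae, `[[`, character(1), "component_id")),
    cluster_template("mln", "macrolactin",
                     vapply(mln, `[[`, character(1), "component_id")),
    cluster_template("dfn", "difficidin",
                     vapply(dfn, `[[`, character(1), "component_id"))
  )
  pks_catalog(c(bae, mln, dfn), templates, metadata = list(
    name = "pksminer-default",
    version = "1",
    notes = paste("Second oxidoreductase slot named PksL to avoid a duplicate",
                  "PksM key; printed description retained for both slots.")
  ))
}

# ---------------------------------------------------------------------------
# JSON (de)serialization

#' Save a catalogue as JSON
#'
#' @param catalog A [pks_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_catalog <- function(catalog, path) {
  x <- list(
    metadata = catalog$metadata,
    entries = lapply(unname(catalog$entries), function(en) {
      list(component_id = en$component_id, description = en$description,
           ec_numbers = as.list(en$ec_numbers), keywords = en$keywords,
           gene_synonyms = as.list(en$gene_synonyms),
           reference_proteins = as.list(en$reference_proteins),
           core = en$core)
    }),
    templates = lapply(unname(catalog$templates), function(t) {
      list(template_id = t$template_id, product_name = t$product_name,
           components = as.list(t$components), max_gap_bp = t$max_gap_bp,
           complete_max_missing = t$complete_max_missing,
           partial_min_hits = t$partial_min_hits)
    })
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a catalogue from JSON
#'
#' @param path Path to a JSON file written by [save_catalog()] (or following
#'   the same schema).
#' @return A validated [pks_catalog()].
#' @export
load_catalog <- function(path) {
  if (!file.exists(path))
    pks_abort(sprintf("catalogue file not found: %s", path), "pks_input_error")
  x <- jsonlite::read_json(path)
  if (is.null(x$entries) || is.null(x$templates))
    pks_abort("catalogue schema violation: top-level 'entries' and 'templates' required",
              "pks_validation_error")
  need <- function(obj, field, where) {
    if (is.null(obj[[field]]))
      pks_abort(sprintf("catalogue schema violation: missing '%s' in %s", field, where),
                "pks_validation_error")
    obj[[field]]
  }
  entries <- lapply(x$entries, function(en) {
    catalog_entry(
      component_id = need(en, "component_id", "entry"),
      description = need(en, "description", "entry"),
      ec_numbers = unlist(en$ec_numbers) %||% character(),
      keywords = en$keywords %||% list(),
      gene_synonyms = unlist(en$gene_synonyms) %||% character(),
      reference_proteins = unlist(en$reference_proteins) %||% character(),
      core = en$core %||% TRUE
    )
  })
  templates <- lapply(x$templates, function(t) {
    cluster_template(
      template_id = need(t, "template_id", "template"),
      product_name = t$product_name %||% "",
      components = unlist(need(t, "components", paste0("template ", t$template_id %||% "?"))),
      max_gap_bp = t$max_gap_bp %||% 20000L,
      complete_max_missing = t$complete_max_missing %||% 3L,
      partial_min_hits = t$partial_min_hits %||% 1L
    )
  })
  pks_catalog(entries, templates, metadata = x$metadata %||% list())
}

#' Attach reference proteins from a FASTA file to catalogue entries
#'
#' Sequence names must be `<component_id>` or `<component_id>|<label>`;
#' sequences are attached to the matching entry for use by homology mode.
#'
#' @param catalog A [pks_catalog()].
#' @param fasta_path Path to an amino-acid FASTA file.
#' @return The updated catalogue.
#' @export
load_reference_proteins <- function(catalog, fasta_path) {
  seqs <- read_fasta(fasta_path)
  for (nm in names(seqs)) {
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    cid <- parts[1]
    label <- if (length(parts) > 1L) parts[2] else cid
    if (is.null(catalog$entries[[cid]]))
      pks_abort(sprintf("reference protein '%s' names unknown component %s", nm, cid),
                "pks_validation_error")
    if (!is_valid_protein(seqs[[nm]]))
      pks_abort(sprintf("reference protein '%s' has invalid residues", nm),
                "pks_alphabet_error")
    rp <- catalog$entries[[cid]]$reference_proteins
    rp[[label]] <- toupper(seqs[[nm]])
    catalog$entries[[cid]]$reference_proteins <- rp
  }
  catalog
}
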