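# Cluster mining: match genome features to catalogue components, chain hits
# into candidate clusters, score completeness, classify genomes and label
# clusters.

#' Mining run configuration
#'
#' @param max_gap_bp Override the per-template chaining gap (bp); `NULL`
#'   keeps each template's own value.
#' @param complete_max_missing Override per-template completeness threshold;
#'   `NULL` keeps template values.
#' @param partial_min_hits Override per-template partial threshold.
#' @param modes Annotation match modes to use, in precedence order (subset of
#'   `c("gene_name", "ec", "keyword")`).
#' @param homology Enable homology fallback for features unmatched by
#'   annotation (requires catalogue reference proteins and CDS translations).
#' @param min_identity,min_coverage Homology acceptance thresholds
#'   (identity and reference coverage fractions).
#' @param exclude_compound Drop features whose annotated location was a
#'   join/order compound (e.g. pseudo-gene fragments).
#' @return An object of class `run_config`.
#' @export
run_config <- function(max_gap_bp = NULL, complete_max_missing = NULL,
                       partial_min_hits = NULL,
                       modes = c("gene_name", "ec", "keyword"),
                       homology = FALSE, min_identity = 0.4, min_coverage = 0.7,
                       exclude_compound = FALSE) {
  modes <- match.arg(modes, c("gene_name", "ec", "keyword"), several.ok = TRUE)
  chk01 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1)
      pks_abort(sprintf("%s must be in (0, 1]", nm), "pks_config_error")
  }
  chk01(min_identity, "min_identity"); chk01(min_coverage, "min_coverage")
  if (!is.null(max_gap_bp) && (!is.numeric(max_gap_bp) || max_gap_bp < 0))
    pks_abort("max_gap_bp must be >= 0", "pks_config_error")
  if (!is.null(complete_max_missing) && complete_max_missing < 0)
    pks_abort("complete_max_missing must be >= 0", "pks_config_error")
  if (!is.null(partial_min_hits) && partial_min_hits < 1)
    pks_abort("partial_min_hits must be >= 1", "pks_config_error")
  structure(list(
    max_gap_bp = max_gap_bp, complete_max_missing = complete_max_missing,
    partial_min_hits = partial_min_hits, modes = modes, homology = homology,
    min_identity = min_identity, min_coverage = min_coverage,
    exclude_compound = isTRUE(exclude_compound)
  ), class = "run_config")
}

# Apply config threshold overrides to one template.
effective_template <- function(template, config) {
  if (!is.null(config$max_gap_bp)) template$max_gap_bp <- as.integer(config$max_gap_bp)
  if (!is.null(config$complete_max_missing))
    template$complete_max_missing <- as.integer(config$complete_max_missing)
  if (!is.null(config$partial_min_hits))
    template$partial_min_hits <- as.integer(config$partial_min_hits)
  template
}

MODE_PRECEDENCE <- c(gene_name = 1L, ec = 2L, keyword = 3L, homology = 4L)

# Best annotation match of one feature against one entry, or NULL.
# Returns mode, score, and keyword specificity (matched-pattern token count)
# used as a late tie-breaker.
match_one <- function(feature, entry, modes) {
  if ("gene_name" %in% modes && nzchar(feature$gene) &&
      tolower(feature$gene) %in% tolower(entry$gene_synonyms))
    return(list(mode = "gene_name", score = 1.0, specificity = 0L))
  if ("ec" %in% modes && length(feature$ec_numbers) && length(entry$ec_numbers)) {
    for (fe in feature$ec_numbers) for (ee in entry$ec_numbers)
      if (ec_matches(fe, ee))
        return(list(mode = "ec", score = 1.0, specificity = 0L))
  }
  if ("keyword" %in% modes && nzchar(feature$product) && length(entry$keywords)) {
    ptoks <- text_tokens(feature$product)
    best_spec <- -1L
    for (pat in entry$keywords) {
      ktoks <- text_tokens(pat)
      if (length(ktoks) && all(ktoks %in% ptoks))
        best_spec <- max(best_spec, length(ktoks))
    }
    if (best_spec >= 0L)
      return(list(mode = "keyword", score = 1.0, specificity = best_spec))
  }
  NULL
}

#' Match genome features against catalogue components
#'
#' Each feature yields at most one hit: candidate (feature, component)
#' matches are ranked by mode precedence (`gene_name > ec > keyword >
#' homology`), then higher score, then (for keyword ties) the more specific
#' pattern, then catalogue order. Deterministic given its inputs.
#'
#' @param record A [genome_record()].
#' @param catalog A [pks_catalog()] (its `entries` are used).
#' @param config A [run_config()].
#' @return A list of `component_hit` objects (fields `component_id`,
#'   `feature`, `mode`, `score`, and `alignment` for homology hits).
#' @export
match_features <- function(record, catalog, config = run_config()) {
  entries <- catalog$entries
  hits <- list()
  for (feature in record$features) {
    if (config$exclude_compound && feature$compound) next
    best <- NULL
    for (ei in seq_along(entries)) {
      entry <- entries[[ei]]
      m <- match_one(feature, entry, config$modes)
      cand <- NULL
      if (!is.null(m)) {
        cand <- list(component_id = entry$component_id, mode = m$mode,
                     score = m$score, specificity = m$specificity,
                     order = ei, alignment = NULL)
      } else if (config$homology && nzchar(feature$translation) &&
                 length(entry$reference_proteins)) {
        hm <- best_reference_alignment(feature$translation, entry,
                                       config$min_identity, config$min_coverage)
        if (!is.null(hm))
          cand <- list(component_id = entry$component_id, mode = "homology",
                       score = hm$score, specificity = 0L, order = ei,
                       alignment = hm$alignment)
      }
      if (is.null(cand)) next
      if (is.null(best) || better_candidate(cand, best)) best <- cand
    }
    if (!is.null(best)) {
      hits[[length(hits) + 1L]] <- structure(list(
        component_id = best$component_id, feature = feature,
        mode = best$mode, score = best$score, alignment = best$alignment
      ), class = "component_hit")
    }
  }
  hits
}

better_candidate <- function(a, b) {
  pa <- MODE_PRECEDENCE[[a$mode]]; pb <- MODE_PRECEDENCE[[b$mode]]
  if (pa != pb) return(pa < pb)
  if (a$score != b$score) return(a$score > b$score)
  if (a$specificity != b$specificity) return(a$specificity > b$specificity)
  a$order < b$order
}

#' Chain component hits into cluster calls
#'
#' Hits are sorted by feature start; maximal runs in which the genomic gap
#' between successive hit features (`start_next - end_prev`) stays at or
#' below the template's `max_gap_bp` become one cluster call each.
#'
#' @param hits List of component hits from one genome record (any template's
#'   components; filtering to the template is done here).
#' @param template A [cluster_template()].
#' @return List of `cluster_call` objects (fields `template_id`, `hits`,
#'   `span`, `completeness`, `missing`, `status`, `label`).
#' @export
assemble_clusters <- function(hits, template) {
  hits <- hits[vapply(hits, function(h) h$component_id %in% template$components,
                      logical(1))]
  if (!length(hits)) return(list())
  starts <- vapply(hits, function(h) h$feature$start, integer(1))
  hits <- hits[order(starts)]
  starts <- sort(starts)
  ends <- vapply(hits, function(h) h$feature$end, integer(1))
  chains <- list()
  current <- 1L
  for (i in seq_along(hits)[-1]) {
    if (starts[i] - ends[i - 1L] > template$max_gap_bp) {
      chains[[length(chains) + 1L]] <- current
      current <- i
    } else {
      current <- c(current, i)
    }
  }
  chains[[length(chains) + 1L]] <- current
  lapply(chains, function(idx) new_cluster_call(hits[idx], template))
}

new_cluster_call <- function(hits, template, absent = FALSE) {
  if (absent || !length(hits)) {
    return(structure(list(
      template_id = template$template_id, hits = list(), span = NULL,
      completeness = 0, missing = template$components, status = "absent",
      label = "unknown"
    ), class = "cluster_call"))
  }
  comps <- unique(vapply(hits, `[[`, character(1), "component_id"))
  missing <- setdiff(template$components, comps)
  status <- if (length(missing) <= template$complete_max_missing) "complete"
            else if (length(hits) >= template$partial_min_hits) "partial"
            else "absent"
  structure(list(
    template_id = template$template_id, hits = hits,
    span = c(min(vapply(hits, function(h) h$feature$start, integer(1))),
             max(vapply(hits, function(h) h$feature$end, integer(1)))),
    completeness = length(comps) / length(template$components),
    missing = missing, status = status, label = template$template_id
  ), class = "cluster_call")
}

#' @export
print.cluster_call <- function(x, ...) {
  if (x$status == "absent") {
    cat(sprintf("<cluster_call> %s: absent (PKs Loci was not found)\n", x$template_id))
  } else {
    cat(sprintf("<cluster_call> %s: %s, %d hits, span %d..%d, completeness %.2f, missing: %s\n",
                x$template_id, x$status, length(x$hits), x$span[1], x$span[2],
                x$completeness,
                if (length(x$missing)) paste(x$missing, collapse = ",") else "none"))
  }
  invisible(x)
}

#' Classify a genome against every catalogue template
#'
#' Runs annotation (and optionally homology) matching, chains hits per
#' template, and keeps the best call per template (highest completeness,
#' ties broken by longer span). Templates without any hit yield an `absent`
#' call — reported downstream with the phrase "PKs Loci was not found".
#'
#' @param record A [genome_record()].
#' @param catalog A [pks_catalog()].
#' @param config A [run_config()].
#' @return Named list (by template id) of `cluster_call` objects.
#' @export
classify_genome <- function(record, catalog, config = run_config()) {
  hits <- match_features(record, catalog, config)
  out <- list()
  for (template in catalog$templates) {
    template <- effective_template(template, config)
    calls <- assemble_clusters(hits, template)
    if (!length(calls)) {
      out[[template$template_id]] <- new_cluster_call(list(), template, absent = TRUE)
      next
    }
    comp <- vapply(calls, `[[`, numeric(1), "completeness")
    spanlen <- vapply(calls, function(cl) diff(cl$span) + 1L, integer(1))
    best <- order(-comp, -spanlen)[1]
    out[[template$template_id]] <- calls[[best]]
  }
  out
}

#' Label a cluster call by majority template membership
#'
#' Counts, per template, how many of the call's hits match that template's
#' components; the label is the template holding a strict majority of the
#' hits, or `"unknown"` when no template does.
#'
#' @param call A non-absent `cluster_call`.
#' @param templates List of [cluster_template()]s (e.g.
#'   `default_catalog()$templates`).
#' @return Character label (`"bae"`, `"mln"`, `"dfn"`, ... or `"unknown"`).
#' @export
label_cluster <- function(call, templates) {
  if (call$status == "absent" || !length(call$hits))
    pks_abort("cannot label an absent cluster call", "pks_usage_error")
  comps <- vapply(call$hits, `[[`, character(1), "component_id")
  counts <- vapply(templates, function(t) sum(comps %in% t$components), integer(1))
  names(counts) <- vapply(templates, `[[`, character(1), "template_id")
  top <- max(counts)
  winners <- names(counts)[counts == top]
  if (length(winners) != 1L || top * 2L <= length(comps)) return("unknown")
  winners
}

# ---------------------------------------------------------------------------
# Reporting

#' Cross-genome component matrix (Table-style report)
#'
#' Rows are the components of one template (catalogue order), columns are
#' genomes; a cell is `"<protein_id> <start>..<end>"` for the component's hit
#' in that genome's best call, `"-"` otherwise. Genomes whose call is absent
#' are listed in a `footnotes` attribute with the phrase
#' `"PKs Loci was not found"`.
#'
#' @param results Named list (by genome accession) of [classify_genome()]
#'   outputs.
#' @param catalog The catalogue used.
#' @param template_id Which template's components form the rows.
#' @return A character matrix with a `footnotes` attribute.
#' @export
report_matrix <- function(results, catalog, template_id = "bae") {
  template <- catalog$templates[[template_id]]
  if (is.null(template))
    pks_abort(sprintf("unknown template: %s", template_id), "pks_usage_error")
  genomes <- names(results)
  m <- matrix("-", nrow = length(template$components), ncol = length(genomes),
              dimnames = list(template$components, genomes))
  footnotes <- character()
  for (g in genomes) {
    call <- results[[g]][[template_id]]
    if (is.null(call) || call$status == "absent") {
      footnotes <- c(footnotes, sprintf("%s PKs Loci was not found", g))
      next
    }
    for (h in call$hits) {
      id <- if (nzchar(h$feature$protein_id)) h$feature$protein_id
            else if (nzchar(h$feature$locus_tag)) h$feature$locus_tag else "-"
      cell <- sprintf("%s %d..%d", id, h$feature$start, h$feature$end)
      if (m[h$component_id, g] == "-") m[h$component_id, g] <- cell
    }
  }
  attr(m, "footnotes") <- footnotes
  m
}
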