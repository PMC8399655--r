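# Annotated-genome model: GenBank flat-file parsing, writing, and
# coordinate/neighbourhood queries. Coordinates are 1-based inclusive
# throughout (GenBank convention).

#' Construct a gene feature
#'
#' A single protein-coding feature of an annotated replicon. Coordinates are
#' 1-based inclusive; compound (join/complement-join) locations are collapsed
#' to their envelope span with `compound = TRUE`.
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param strand `"+"` (forward) or `"-"` (reverse).
#' @param locus_tag,gene,product,protein_id Annotation strings (may be `""`).
#' @param ec_numbers Character vector of EC numbers (`d.d.d.d`, `-` wildcards
#'   allowed).
#' @param translation Amino-acid string (20 letters plus `X`) or `""`.
#' @param compound `TRUE` when the annotated location was a join/order
#'   compound collapsed to its envelope.
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(start, end, strand = "+", locus_tag = "", gene = "",
                         product = "", protein_id = "", ec_numbers = character(),
                         translation = "", compound = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start)
    pks_abort(sprintf("invalid feature span %s..%s", start, end), "pks_coordinate_error")
  if (!strand %in% c("+", "-"))
    pks_abort("strand must be '+' or '-'", "pks_value_error")
  ec_numbers <- as.character(ec_numbers)
  bad <- ec_numbers[!vapply(ec_numbers, is_valid_ec, logical(1))]
  if (length(bad))
    pks_abort(sprintf("invalid EC number(s): %s", paste(bad, collapse = ", ")),
              "pks_value_error")
  if (nzchar(translation) && !is_valid_protein(translation))
    pks_abort(sprintf("invalid residues in translation of %s",
                      if (nzchar(locus_tag)) locus_tag else "feature"),
              "pks_alphabet_error")
  structure(list(
    start = start, end = end, strand = strand,
    locus_tag = locus_tag, gene = gene, product = product,
    protein_id = protein_id, ec_numbers = ec_numbers,
    translation = toupper(translation), compound = isTRUE(compound)
  ), class = "gene_feature")
}

#' Construct a genome record
#'
#' @param accession Record accession (LOCUS/ACCESSION name).
#' @param length Replicon length in base pairs.
#' @param features List of [gene_feature()] objects; stored sorted by
#'   (start, end).
#' @param organism Organism name.
#' @param topology `"linear"` or `"circular"`.
#' @param definition Free-text definition line.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(accession, length, features = list(),
                          organism = "", topology = "linear", definition = "") {
  length <- as.integer(length)
  if (is.na(length) || length < 1L)
    pks_abort("record length must be a positive integer", "pks_value_error")
  if (!topology %in% c("linear", "circular"))
    pks_abort("topology must be 'linear' or 'circular'", "pks_value_error")
  for (f in features) {
    if (!inherits(f, "gene_feature"))
      pks_abort("features must be gene_feature objects", "pks_value_error")
    if (f$end > length)
      pks_abort(sprintf("feature %s ends beyond record length (%d > %d)",
                        if (nzchar(f$locus_tag)) f$locus_tag else "<unnamed>",
                        f$end, length),
                "pks_coordinate_error")
  }
  ord <- order(vapply(features, `[[`, integer(1), "start"),
               vapply(features, `[[`, integer(1), "end"))
  structure(list(
    accession = accession, organism = organism, length = length,
    topology = topology, definition = definition, features = features[ord]
  ), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s), %d bp %s, %d CDS features\n",
              x$accession, if (nzchar(x$organism)) x$organism else "unknown organism",
              x$length, x$topology, length(x$features)))
  invisible(x)
}

#' Tabulate the features of a genome record
#'
#' @param record A [genome_record()].
#' @return A data frame with one row per feature.
#' @export
features_table <- function(record) {
  f <- record$features
  data.frame(
    locus_tag = vapply(f, `[[`, character(1), "locus_tag"),
    gene = vapply(f, `[[`, character(1), "gene"),
    start = vapply(f, `[[`, integer(1), "start"),
    end = vapply(f, `[[`, integer(1), "end"),
    strand = vapply(f, `[[`, character(1), "strand"),
    product = vapply(f, `[[`, character(1), "product"),
    protein_id = vapply(f, `[[`, character(1), "protein_id"),
    ec_numbers = vapply(f, function(x) paste(x$ec_numbers, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# GenBank flat-file parsing

#' Parse GenBank flat-file text into genome records
#'
#' Reads one or more LOCUS records from a GenBank flat file (plain or gzip).
#' Every CDS feature becomes a [gene_feature()]; join/complement locations are
#' reduced to their envelope (min start, max end) with strand taken from the
#' complement flag and `compound = TRUE` recorded. Non-CDS features are
#' ignored unless listed in `include_features`.
#'
#' @param path Path to a `.gb`/`.gbk`/`.gbff` file (optionally gzipped), or
#'   `NULL` when `text` is given.
#' @param text Character vector of GenBank lines (alternative to `path`).
#' @param include_features Feature keys to retain (default `"CDS"`).
#' @return A list of [genome_record()] objects, one per LOCUS.
#' @export
read_genbank <- function(path = NULL, text = NULL, include_features = "CDS") {
  if (is.null(text)) {
    if (is.null(path) || !file.exists(path))
      pks_abort(sprintf("cannot read GenBank file: %s", path %||% "<NULL>"),
                "pks_input_error")
    con <- gzfile(path, open = "rt")  # gzfile reads plain text transparently
    on.exit(close(con))
    text <- readLines(con, warn = FALSE)
  }
  locus_idx <- grep("^LOCUS", text)
  if (!length(locus_idx))
    pks_abort("no LOCUS line found in GenBank input", "pks_parse_error")
  end_idx <- c(locus_idx[-1] - 1L, length(text))
  lapply(seq_along(locus_idx), function(i) {
    parse_one_record(text[locus_idx[i]:end_idx[i]], locus_idx[i], include_features)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_one_record <- function(lines, line_offset, include_features) {
  m <- regmatches(lines[1],
                  regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp(?:\\s+\\S+)?(?:\\s+(linear|circular))?",
                          lines[1]))[[1]]
  if (length(m) < 3L || !nzchar(m[2]) || !nzchar(m[3]))
    pks_abort(sprintf("malformed LOCUS line at line %d: %s", line_offset, lines[1]),
              "pks_parse_error")
  name <- m[2]
  len <- as.integer(m[3])
  topology <- if (length(m) >= 4L && nzchar(m[4])) m[4] else "linear"

  definition <- sub("^DEFINITION\\s+", "", grep("^DEFINITION", lines, value = TRUE)[1])
  if (is.na(definition)) definition <- ""
  acc_line <- grep("^ACCESSION", lines, value = TRUE)[1]
  accession <- if (!is.na(acc_line)) sub("^ACCESSION\\s+", "", acc_line) else name
  accession <- strsplit(trimws(accession), "\\s+")[[1]][1]
  if (is.na(accession) || !nzchar(accession)) accession <- name
  org_line <- grep("^  ORGANISM", lines, value = TRUE)[1]
  organism <- if (!is.na(org_line)) trimws(sub("^  ORGANISM\\s+", "", org_line)) else ""

  feat_start <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_start)) {
    stop_idx <- grep("^(ORIGIN|CONTIG|BASE COUNT)", lines)
    stop_idx <- stop_idx[stop_idx > feat_start[1]]
    feat_end <- if (length(stop_idx)) stop_idx[1] - 1L else length(lines)
    fl <- lines[(feat_start[1] + 1L):feat_end]
    fl <- fl[nzchar(trimws(fl))]
    features <- parse_feature_table(fl, include_features, len)
  }
  genome_record(accession = accession, length = len, features = features,
                organism = organism, topology = topology, definition = definition)
}

parse_feature_table <- function(lines, include_features, record_length) {
  is_key <- grepl("^ {5}\\S", lines)
  key_pos <- which(is_key)
  features <- list()
  for (ki in seq_along(key_pos)) {
    first <- key_pos[ki]
    last <- if (ki < length(key_pos)) key_pos[ki + 1L] - 1L else length(lines)
    block <- lines[first:last]
    key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
    if (!key %in% include_features) next
    body <- c(sub("^ {5}\\S+\\s+", "", block[1]), trimws(block[-1]))
    qual_start <- grep("^/", body)
    loc_lines <- if (length(qual_start)) body[seq_len(qual_start[1] - 1L)] else body
    location <- paste(loc_lines, collapse = "")
    quals <- parse_qualifiers(if (length(qual_start)) body[qual_start[1]:length(body)] else character())
    loc <- parse_location(location)
    feat <- gene_feature(
      start = loc$start, end = loc$end, strand = loc$strand,
      locus_tag = quals$locus_tag %||% "",
      gene = quals$gene %||% "",
      product = quals$product %||% "",
      protein_id = quals$protein_id %||% "",
      ec_numbers = quals$EC_number %||% character(),
      translation = quals$translation %||% "",
      compound = loc$compound
    )
    if (feat$end > record_length)
      pks_abort(sprintf("CDS %s ends beyond record length (%d > %d)",
                        if (nzchar(feat$locus_tag)) feat$locus_tag else location,
                        feat$end, record_length),
                "pks_coordinate_error")
    features[[length(features) + 1L]] <- feat
  }
  features
}

# Qualifier lines: continuation of /translation concatenates without spaces,
# everything else re-joins with a single space.
parse_qualifiers <- function(lines) {
  quals <- list()
  current <- NULL
  flush <- function() {
    if (is.null(current)) return()
    val <- current$value
    if (grepl('^"', val)) val <- gsub('"', "", val)
    quals[[current$name]] <<- c(quals[[current$name]], val)
    current <<- NULL
  }
  for (ln in lines) {
    if (grepl("^/", ln)) {
      flush()
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        current <- list(name = substring(ln, 2L, eq - 1L),
                        value = substring(ln, eq + 1L))
      } else {
        current <- list(name = substring(ln, 2L), value = "true")
      }
    } else if (!is.null(current)) {
      sep <- if (current$name == "translation") "" else " "
      current$value <- paste(current$value, ln, sep = sep)
    }
  }
  flush()
  quals
}

# Collapse any GenBank location string to (start, end, strand, compound).
parse_location <- function(location) {
  strand <- if (grepl("complement", location)) "-" else "+"
  compound <- grepl("join|order", location)
  nums <- regmatches(location, gregexpr("[0-9]+", location))[[1]]
  if (!length(nums))
    pks_abort(sprintf("cannot parse feature location: %s", location), "pks_parse_error")
  nums <- as.numeric(nums)
  list(start = min(nums), end = max(nums), strand = strand, compound = compound)
}

# ---------------------------------------------------------------------------
# GenBank writing (round-trip safe for the fields the model retains)

#' Write genome records as GenBank flat-file text
#'
#' Emits the minimal mandatory GenBank structure for each record (LOCUS,
#' DEFINITION, ACCESSION, SOURCE/ORGANISM, FEATURES, empty ORIGIN). The
#' output is deterministic (fixed timestamp) and round-trips through
#' [read_genbank()] for all fields the model retains.
#'
#' @param records A [genome_record()] or list of them.
#' @param path Output path, or `NULL` to return the text invisibly only.
#' @return (Invisibly) the character vector of lines written.
#' @export
write_genbank <- function(records, path = NULL) {
  if (inherits(records, "genome_record")) records <- list(records)
  out <- unlist(lapply(records, format_one_record))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

format_one_record <- function(rec) {
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     %-8s BCT 01-JAN-2000",
            rec$accession, rec$length, rec$topology),
    sprintf("DEFINITION  %s", if (nzchar(rec$definition)) rec$definition else "."),
    sprintf("ACCESSION   %s", rec$accession),
    "SOURCE      .",
    sprintf("  ORGANISM  %s", if (nzchar(rec$organism)) rec$organism else "."),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", rec$length)
  )
  for (f in rec$features) lines <- c(lines, format_one_feature(f))
  c(lines, "ORIGIN", "//")
}

format_one_feature <- function(f) {
  span <- sprintf("%d..%d", f$start, f$end)
  loc <- if (f$strand == "-") sprintf("complement(%s)", span) else span
  lines <- sprintf("     %-16s%s", "CDS", loc)
  qual <- function(name, value, quote = TRUE) {
    if (!length(value) || !any(nzchar(value))) return(character())
    unlist(lapply(value, function(v) {
      txt <- if (quote) sprintf("/%s=\"%s\"", name, v) else sprintf("/%s=%s", name, v)
      # translations wrap at fixed width (re-joined without spaces on parse);
      # other qualifiers wrap at word boundaries (re-joined with one space)
      wrapped <- if (name == "translation") wrap_fixed(txt, 58L)
                 else wrap_words(txt, 58L)
      paste0(strrep(" ", 21), wrapped)
    }))
  }
  c(lines,
    qual("locus_tag", f$locus_tag),
    qual("gene", f$gene),
    qual("product", f$product),
    qual("EC_number", f$ec_numbers),
    qual("protein_id", f$protein_id),
    qual("translation", f$translation))
}

# ---------------------------------------------------------------------------
# Neighbourhood queries

#' Genes flanking a genomic span
#'
#' Returns up to `k` genes strictly upstream (ending before the span starts)
#' and up to `k` strictly downstream (starting after the span ends), each
#' ordered nearest-first. Fewer than `k` are returned at replicon edges.
#'
#' @param record A [genome_record()].
#' @param span Numeric `c(start, end)` within the replicon (1-based inclusive).
#' @param k Maximum number of genes on each side (`k >= 0`).
#' @return An object of class `neighborhood_report` with elements `upstream`,
#'   `downstream` (lists of [gene_feature()]s, nearest first) and
#'   `anchor_span`.
#' @export
neighborhood <- function(record, span, k = 5L) {
  k <- as.integer(k)
  if (is.na(k) || k < 0L) pks_abort("k must be >= 0", "pks_value_error")
  span <- as.integer(span)
  if (length(span) != 2L || anyNA(span) || span[1] > span[2] ||
      span[1] < 1L || span[2] > record$length)
    pks_abort(sprintf("span must lie within [1, %d]", record$length),
              "pks_bounds_error")
  ends <- vapply(record$features, `[[`, integer(1), "end")
  starts <- vapply(record$features, `[[`, integer(1), "start")
  up <- record$features[ends < span[1]]
  up <- up[order(vapply(up, `[[`, integer(1), "end"), decreasing = TRUE)]
  down <- record$features[starts > span[2]]
  down <- down[order(vapply(down, `[[`, integer(1), "start"))]
  structure(list(
    upstream = head(up, k), downstream = head(down, k),
    anchor_span = span
  ), class = "neighborhood_report")
}

#' @export
print.neighborhood_report <- function(x, ...) {
  cat(sprintf("Neighborhood of %d..%d\n", x$anchor_span[1], x$anchor_span[2]))
  show <- function(side, feats) {
    cat(sprintf("%s (%d):\n", side, length(feats)))
    for (f in feats)
      cat(sprintf("  %s %d..%d (%s) %s\n",
                  if (nzchar(f$locus_tag)) f$locus_tag else "<unnamed>",
                  f$start, f$end, f$strand, f$product))
  }
  show("upstream", x$upstream)
  show("downstream", x$downstream)
  invisible(x)
}
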