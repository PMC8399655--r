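# Annotation-independent fallback: Smith-Waterman local alignment of CDS
# translations against catalogue reference proteins (Gotoh affine-gap DP).
#
# Gap convention: a gap of length L costs gap_open + L * gap_extend (both
# penalties are negative numbers), i.e. the first gapped column costs
# gap_open + gap_extend. This matches Biostrings::pairwiseAlignment with
# gapOpening = -gap_open, gapExtension = -gap_extend.

#' Scoring scheme for protein alignment
#'
#' @param matrix Either a square numeric substitution matrix with residue
#'   dimnames, or `"unit"` (match `match`, mismatch `mismatch`), or
#'   `"BLOSUM62"`.
#' @param gap_open Gap-opening penalty (negative; default -11).
#' @param gap_extend Per-column gap-extension penalty (negative; default -1).
#' @param match,mismatch Scores used when `matrix = "unit"`.
#' @return A list with elements `matrix`, `gap_open`, `gap_extend`.
#' @export
alignment_scoring <- function(matrix = "BLOSUM62", gap_open = -11, gap_extend = -1,
                              match = 1, mismatch = -1) {
  if (is.character(matrix) && identical(matrix, "BLOSUM62")) {
    env <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = env)
    matrix <- env$BLOSUM62
  } else if (is.character(matrix) && identical(matrix, "unit")) {
    letters22 <- c(AA_LETTERS, "X", "*")
    matrix <- base::matrix(mismatch, length(letters22), length(letters22),
                           dimnames = list(letters22, letters22))
    diag(matrix) <- match
  }
  if (!is.matrix(matrix) || is.null(dimnames(matrix)))
    pks_abort("substitution matrix must have residue dimnames", "pks_config_error")
  if (gap_open > 0 || gap_extend > 0)
    pks_abort("gap penalties must be <= 0", "pks_config_error")
  list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps (Gotoh). The traceback is deterministic:
#' ties prefer the diagonal move, then the gap in the reference (up), then
#' the gap in the query (left); the best cell is the first maximal cell in
#' row-major order.
#'
#' @param query,ref Amino-acid strings (20 letters plus X).
#' @param scoring An [alignment_scoring()] list.
#' @return An `alignment_result`: `score`, `identity` (identical columns /
#'   alignment columns), `query_coverage`, `ref_coverage`, `aligned_pairs`
#'   (two-column matrix of 1-based query/ref indices of aligned residue
#'   pairs), and the aligned strings `query_aln`, `ref_aln`.
#' @export
align_local <- function(query, ref, scoring = alignment_scoring()) {
  q <- toupper(query); r <- toupper(ref)
  if (!nzchar(q) || !nzchar(r))
    pks_abort("sequences must be non-empty", "pks_value_error")
  if (!is_valid_protein(q) || !is_valid_protein(r))
    pks_abort("invalid residue in input sequence", "pks_alphabet_error")
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  bad <- setdiff(c(qs, rs), rownames(scoring$matrix))
  if (length(bad))
    pks_abort(sprintf("residue(s) not in substitution matrix: %s",
                      paste(bad, collapse = ",")), "pks_alphabet_error")
  n <- length(qs); m <- length(rs)
  go <- scoring$gap_open; ge <- scoring$gap_extend
  sub <- scoring$matrix[qs, rs, drop = FALSE]

  NEG <- -Inf
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L)   # gap in query (left moves)
  F <- matrix(NEG, n + 1L, m + 1L)   # gap in ref (up moves)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] + go + ge, E[i + 1L, j] + ge)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] + go + ge, F[i, j + 1L] + ge)
      h <- max(0, H[i, j] + sub[i, j], F[i + 1L, j + 1L], E[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) { best <- h; bi <- i; bj <- j }
    }
  }

  if (best <= 0) {
    return(structure(list(
      score = 0, identity = 0, query_coverage = 0, ref_coverage = 0,
      aligned_pairs = matrix(integer(), 0L, 2L,
                             dimnames = list(NULL, c("query", "ref"))),
      query_aln = "", ref_aln = ""
    ), class = "alignment_result"))
  }

  # Traceback from (bi, bj); state "H"/"E"/"F"; ties prefer diagonal, up, left.
  i <- bi; j <- bj; state <- "H"
  qa <- character(); ra <- character(); pairs <- list()
  repeat {
    if (state == "H") {
      h <- H[i + 1L, j + 1L]
      if (h == 0) break
      if (i >= 1L && j >= 1L && h == H[i, j] + sub[i, j]) {
        qa <- c(qs[i], qa); ra <- c(rs[j], ra)
        pairs[[length(pairs) + 1L]] <- c(i, j)
        i <- i - 1L; j <- j - 1L
      } else if (h == F[i + 1L, j + 1L]) {
        state <- "F"
      } else if (h == E[i + 1L, j + 1L]) {
        state <- "E"
      } else break
    } else if (state == "F") {  # gap in ref: consume query residue
      qa <- c(qs[i], qa); ra <- c("-", ra)
      from_open <- H[i, j + 1L] + go + ge
      f_here <- F[i + 1L, j + 1L]
      i <- i - 1L
      # Prefer closing the gap when both origins tie (shorter gaps first).
      state <- if (f_here == from_open) "H" else "F"
    } else {  # E: gap in query, consume ref residue
      qa <- c("-", qa); ra <- c(rs[j], ra)
      from_open <- H[i + 1L, j] + go + ge
      e_here <- E[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (e_here == from_open) "H" else "E"
    }
  }
  pairs <- if (length(pairs)) {
    do.call(rbind, rev(pairs))
  } else matrix(integer(), 0L, 2L)
  dimnames(pairs) <- list(NULL, c("query", "ref"))
  ncol_aln <- length(qa)
  ident <- sum(qa == ra & qa != "-")
  structure(list(
    score = best,
    identity = if (ncol_aln) ident / ncol_aln else 0,
    query_coverage = sum(qa != "-") / n,
    ref_coverage = sum(ra != "-") / m,
    aligned_pairs = pairs,
    query_aln = paste(qa, collapse = ""), ref_aln = paste(ra, collapse = "")
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> score %.1f, identity %.2f, qcov %.2f, rcov %.2f\n",
              x$score, x$identity, x$query_coverage, x$ref_coverage))
  if (nzchar(x$query_aln)) cat(" ", x$query_aln, "\n ", x$ref_aln, "\n", sep = "")
  invisible(x)
}

# Best reference alignment of a translation against one entry's references;
# NULL unless identity >= min_identity and ref_coverage >= min_coverage.
best_reference_alignment <- function(translation, entry, min_identity,
                                     min_coverage,
                                     scoring = alignment_scoring()) {
  best <- NULL
  for (ref in entry$reference_proteins) {
    aln <- align_local(translation, ref, scoring)
    if (aln$identity < min_identity || aln$ref_coverage < min_coverage) next
    sc <- aln$identity * aln$ref_coverage
    if (is.null(best) || sc > best$score) best <- list(score = sc, alignment = aln)
  }
  best
}

#' Homology match of one feature against the catalogue
#'
#' Aligns the feature's translation against every reference protein of every
#' entry; returns a `component_hit` (mode `"homology"`, score = identity x
#' reference coverage) for the best entry passing both thresholds, or `NULL`.
#' Ties between entries are broken by catalogue order.
#'
#' @param feature A [gene_feature()] with a non-empty translation.
#' @param catalog A [pks_catalog()].
#' @param min_identity,min_coverage Acceptance thresholds (defaults 0.4, 0.7).
#' @param scoring An [alignment_scoring()] list.
#' @return A `component_hit` or `NULL`.
#' @export
homology_match <- function(feature, catalog, min_identity = 0.4,
                           min_coverage = 0.7, scoring = alignment_scoring()) {
  if (!nzchar(feature$translation))
    pks_abort("feature has no translation", "pks_usage_error")
  best <- NULL
  for (entry in catalog$entries) {
    hm <- best_reference_alignment(feature$translation, entry, min_identity,
                                   min_coverage, scoring)
    if (!is.null(hm) && (is.null(best) || hm$score > best$hm$score))
      best <- list(entry = entry, hm = hm)
  }
  if (is.null(best)) return(NULL)
  structure(list(
    component_id = best$entry$component_id, feature = feature,
    mode = "homology", score = best$hm$score, alignment = best$hm$alignment
  ), class = "component_hit")
}
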