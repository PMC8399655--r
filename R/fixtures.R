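# Synthetic annotated-genome fixtures with ground truth, plus a K2P sequence
# simulator. Everything is deterministic for a given seed (byte-identical
# GenBank output), so every other module is testable without downloads.

# Nominal gene lengths (bp) for the bae macrocluster slots, about the scale
# of the conserved B. subtilis operon (two giant NRPS/PKS megagenes, small
# ACP, etc.). Components without an entry here get a seeded random length.
BAE_NOMINAL_LENGTHS <- c(
  PksA = 678, Hyp2 = 267, Regulator = 618, PksB = 678, PksC = 867, PksD = 975,
  PksE = 2304, AcpK = 249, PksF = 1248, PksG = 1263, PksH = 780, PksI = 750,
  PksJ = 15132, PksL = 12789, PksM = 16467, PksN = 7632, PksR = 13617,
  PksS = 1218
)

DEFAULT_DECOY_VOCABULARY <- c(
  "DNA gyrase subunit alpha",
  "ribosome maturation GTPase",
  "cell division septum formation initiator",
  "ABC transporter permease",
  "RNA polymerase sigma factor RpoD",
  "phosphate import ATPase",
  "flagellar hook assembly scaffold",
  "sporulation histidine kinase KinA",
  "teichoic acid export permease",
  "chaperonin GroEL cochaperone GroES",
  "glycine cleavage system aminomethyltransferase",
  "two component response element YycF"
)

# Near-miss products sharing tokens with catalogue patterns but never
# covering a full pattern, for precision testing.
ADVERSARIAL_DECOY_VOCABULARY <- c(
  "malonate transporter",
  "acyl CoA dehydrogenase",
  "LacI family transcriptional regulator",
  "polyketide cyclase like lipocalin",
  "3-oxoacyl ACP reductase FabG",
  "hypothetical membrane spanning exporter",
  "NAD dependent epimerase",
  "peptide ABC transporter substrate binding protein"
)

#' Specification of a synthetic annotated genome
#'
#' @param seed Integer RNG seed; the generated GenBank text is byte-identical
#'   for the same spec.
#' @param n_background Number of decoy (non-catalogue) genes, split between
#'   the flanks of the planted cluster.
#' @param template_id Which cluster template to plant (default `"bae"`).
#' @param deleted_components Component ids removed from the planted cluster.
#' @param shuffle Permute the order of the planted component genes.
#' @param gap_scale_bp Mean intergenic gap (bp) inside the planted cluster
#'   (exponentially distributed).
#' @param strand_flip_prob Probability a planted gene sits on the reverse
#'   strand.
#' @param decoy_vocabulary Product strings decoy genes are sampled from
#'   (default is token-disjoint from every catalogue keyword pattern).
#' @param adversarial Add near-miss decoy products that share tokens with
#'   catalogue patterns without fully matching any.
#' @param mutation_rate Per-residue substitution rate applied to catalogue
#'   reference proteins when deriving planted translations.
#' @param expect_status Optional declared expectation for the planted
#'   template's status; [generate_genome()] errors if the realized layout
#'   contradicts it (spec-inconsistency guard).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, n_background = 30L, template_id = "bae",
                         deleted_components = character(), shuffle = FALSE,
                         gap_scale_bp = 200, strand_flip_prob = 0,
                         decoy_vocabulary = DEFAULT_DECOY_VOCABULARY,
                         adversarial = FALSE, mutation_rate = 0,
                         expect_status = NULL) {
  if (gap_scale_bp < 0) pks_abort("gap_scale_bp must be >= 0", "pks_value_error")
  if (strand_flip_prob < 0 || strand_flip_prob > 1)
    pks_abort("strand_flip_prob must be in [0,1]", "pks_value_error")
  structure(list(
    seed = as.integer(seed), n_background = as.integer(n_background),
    template_id = template_id,
    deleted_components = as.character(deleted_components),
    shuffle = isTRUE(shuffle), gap_scale_bp = gap_scale_bp,
    strand_flip_prob = strand_flip_prob,
    decoy_vocabulary = as.character(decoy_vocabulary),
    adversarial = isTRUE(adversarial), mutation_rate = mutation_rate,
    expect_status = expect_status
  ), class = "fixture_spec")
}

random_protein <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  chars[hit] <- sample(AA_LETTERS, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

#' Generate a synthetic annotated genome with ground truth
#'
#' Plants the template's component genes (products, gene names and EC
#' numbers copied from the catalogue; translations derived from catalogue
#' reference proteins where present, else seeded random) on a linear
#' replicon, interleaved with decoy genes on both flanks, then derives a
#' ground-truth table including the status the miner is expected to call at
#' the template's thresholds.
#'
#' @param spec A [fixture_spec()].
#' @param catalog A [pks_catalog()] (default [default_catalog()]).
#' @return List with `record` (a [genome_record()]), `genbank` (character
#'   vector of GenBank lines), and `truth` (list: `components` data frame,
#'   `expected_status` named by template id, `spec`).
#' @export
generate_genome <- function(spec, catalog = default_catalog()) {
  template <- catalog$templates[[spec$template_id]]
  if (is.null(template))
    pks_abort(sprintf("unknown template: %s", spec$template_id), "pks_value_error")
  unknown <- setdiff(spec$deleted_components, template$components)
  if (length(unknown))
    pks_abort(sprintf("deleted_components not in template: %s",
                      paste(unknown, collapse = ", ")), "pks_spec_error")

  with_rng_seed(spec$seed, {
    planted_ids <- setdiff(template$components, spec$deleted_components)
    if (spec$shuffle) planted_ids <- sample(planted_ids)

    vocab <- spec$decoy_vocabulary
    if (spec$adversarial) vocab <- c(vocab, ADVERSARIAL_DECOY_VOCABULARY)
    n_up <- ceiling(spec$n_background / 2)
    n_down <- spec$n_background - n_up

    genes <- list()   # list of (kind, component, length, product, ...)
    add_decoy <- function() {
      list(kind = "decoy", component = NA_character_,
           length = sample(300:1800, 1L) %/% 3L * 3L,
           product = sample(vocab, 1L))
    }
    for (i in seq_len(n_up)) genes[[length(genes) + 1L]] <- add_decoy()
    for (cid in planted_ids) {
      len <- if (cid %in% names(BAE_NOMINAL_LENGTHS)) BAE_NOMINAL_LENGTHS[[cid]]
             else sample(200:600, 1L) * 3L
      genes[[length(genes) + 1L]] <- list(kind = "component", component = cid,
                                          length = as.integer(len), product = NULL)
    }
    for (i in seq_len(n_down)) genes[[length(genes) + 1L]] <- add_decoy()

    # Lay out left to right. Decoy flanks use a fixed 400 bp mean gap;
    # intra-cluster gaps use gap_scale_bp.
    cursor <- 101L
    feats <- list()
    truth_rows <- list()
    idx <- 0L
    for (g in genes) {
      idx <- idx + 1L
      gap_mean <- if (g$kind == "component") spec$gap_scale_bp else 400
      gap <- if (gap_mean > 0) as.integer(round(rexp(1L, 1 / gap_mean))) else 0L
      start <- cursor + gap
      end <- start + g$length - 1L
      cursor <- end + 2L
      strand <- if (runif(1L) < spec$strand_flip_prob) "-" else "+"
      locus_tag <- sprintf("FIX_%04d", idx)
      protein_id <- sprintf("FIXP_%04d", idx)
      if (g$kind == "component") {
        entry <- catalog$entries[[g$component]]
        translation <- if (length(entry$reference_proteins)) {
          mutate_protein(entry$reference_proteins[[1]], spec$mutation_rate)
        } else random_protein(max(10L, g$length %/% 3L - 1L))
        feats[[idx]] <- gene_feature(
          start, end, strand, locus_tag = locus_tag,
          gene = if (length(entry$gene_synonyms)) entry$gene_synonyms[[1]] else "",
          product = entry$description, protein_id = protein_id,
          ec_numbers = entry$ec_numbers, translation = translation
        )
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          component = g$component, present = TRUE, start = start, end = end,
          strand = strand, stringsAsFactors = FALSE)
      } else {
        feats[[idx]] <- gene_feature(
          start, end, strand, locus_tag = locus_tag, product = g$product,
          protein_id = protein_id,
          translation = random_protein(max(10L, g$length %/% 3L - 1L))
        )
      }
    }
    for (cid in spec$deleted_components)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        component = cid, present = FALSE, start = NA_integer_, end = NA_integer_,
        strand = NA_character_, stringsAsFactors = FALSE)

    record <- genome_record(
      accession = sprintf("SYNB%06d", spec$seed %% 1000000L),
      length = cursor + 200L, features = feats,
      organism = "synthetic Bacillus fixture",
      definition = sprintf("synthetic %s-template fixture (seed %d)",
                           spec$template_id, spec$seed)
    )
    truth_components <- do.call(rbind, truth_rows)
    expected <- expected_statuses(truth_components, catalog, spec$template_id)
    if (!is.null(spec$expect_status) &&
        !identical(expected[[spec$template_id]], spec$expect_status))
      pks_abort(sprintf(
        "fixture spec inconsistency: declared status '%s' but layout yields '%s'",
        spec$expect_status, expected[[spec$template_id]]), "pks_spec_error")

    list(record = record, genbank = write_genbank(record),
         truth = list(components = truth_components,
                      expected_status = expected, spec = spec))
  })
}

# Independent (straightforward arithmetic) derivation of the status each
# template should receive from the planted coordinates and thresholds.
expected_statuses <- function(truth_components, catalog, planted_template) {
  out <- list()
  present <- truth_components[truth_components$present, , drop = FALSE]
  for (template in catalog$templates) {
    tid <- template$template_id
    rows <- present[present$component %in% template$components, , drop = FALSE]
    if (!nrow(rows)) { out[[tid]] <- "absent"; next }
    rows <- rows[order(rows$start), , drop = FALSE]
    # chain by the gap rule, keep chain with most distinct components
    chain_sizes <- integer(); chain <- character()
    best <- character()
    for (i in seq_len(nrow(rows))) {
      if (i > 1L && rows$start[i] - rows$end[i - 1L] > template$max_gap_bp) {
        if (length(unique(chain)) > length(unique(best))) best <- chain
        chain <- character()
      }
      chain <- c(chain, rows$component[i])
    }
    if (length(unique(chain)) > length(unique(best))) best <- chain
    missing <- length(template$components) - length(unique(best))
    out[[tid]] <- if (missing <= template$complete_max_missing) "complete"
                  else if (length(best) >= template$partial_min_hits) "partial"
                  else "absent"
  }
  out
}

#' Write a fixture's truth table as JSON
#'
#' @param truth The `truth` element of a [generate_genome()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_truth <- function(truth, path) {
  jsonlite::write_json(list(
    components = truth$components,
    expected_status = truth$expected_status,
    spec = unclass(truth$spec)
  ), path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}

# ---------------------------------------------------------------------------
# K2P sequence simulation

#' Simulate aligned sequences under the Kimura 2-parameter process
#'
#' Evolves a uniform-random root sequence site-independently along a tree
#' with branch lengths in substitutions/site. `kappa` is the
#' transition/transversion *rate ratio* alpha/(2*beta): `kappa = 0.5` makes
#' all three substitution types equally likely ("unbiased"), typical 16S
#' data sit near 2.
#'
#' @param tree A `phylo` object with branch lengths, or a Newick string.
#' @param L Number of sites (`L >= 1`).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer seed for reproducibility.
#' @return Named character vector of aligned sequences (tip labels).
#' @export
simulate_k2p_alignment <- function(tree, L, kappa = 2, seed = NULL) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  L <- as.integer(L)
  if (is.na(L) || L < 1L) pks_abort("L must be >= 1", "pks_value_error")
  if (kappa <= 0) pks_abort("kappa must be > 0", "pks_value_error")
  run <- function() {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- sample(VALID_BASES, L, replace = TRUE)
    # preorder edge traversal
    ord <- order(tree$edge[, 1])
    edges <- tree$edge[ord, , drop = FALSE]
    lens <- tree$edge.length[ord]
    # simple BFS from root over the edge list
    queue <- root
    while (length(queue)) {
      parent <- queue[[1]]; queue <- queue[-1]
      kids <- which(edges[, 1] == parent)
      for (k in kids) {
        child <- edges[k, 2]
        seqs[[child]] <- evolve_k2p(seqs[[parent]], lens[k], kappa)
        if (child > n_tip) queue <- c(queue, child)
      }
    }
    out <- vapply(seq_len(n_tip), function(i) paste(seqs[[i]], collapse = ""),
                  character(1))
    names(out) <- tree$tip.label
    out
  }
  if (is.null(seed)) run() else with_rng_seed(seed, run())
}

# One branch of the K2P process: substitution probabilities from the closed
# form of the K80 transition matrix with total rate 1 (branch length =
# expected substitutions/site).
evolve_k2p <- function(seq_chars, d, kappa) {
  if (d <= 0) return(seq_chars)
  beta <- 1 / (2 * (kappa + 1))
  alpha <- 2 * kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1          # each of the two transversion targets
  u <- runif(length(seq_chars))
  out <- seq_chars
  ts_idx <- u < p_ts
  out[ts_idx] <- TRANSITION_PARTNER[seq_chars[ts_idx]]
  tv1 <- u >= p_ts & u < p_ts + p_tv
  tv2 <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  tv_targets <- list(A = c("C", "T"), G = c("C", "T"),
                     C = c("A", "G"), T = c("A", "G"))
  out[tv1] <- vapply(seq_chars[tv1], function(b) tv_targets[[b]][1], character(1))
  out[tv2] <- vapply(seq_chars[tv2], function(b) tv_targets[[b]][2], character(1))
  out
}
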