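# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the implementation paths they check.

# --- tiny record builder ----------------------------------------------------

make_record <- function(spans, length = NULL, ...) {
  feats <- lapply(seq_len(nrow(spans)), function(i) {
    args <- lapply(spans, function(col) col[i])
    do.call(gene_feature, args)
  })
  genome_record(accession = "TEST", features = feats,
                length = length %||% (max(spans$end) + 100L), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- neighborhood oracle: exhaustive scan over all features -----------------

oracle_neighborhood <- function(record, span, k) {
  up <- list(); down <- list()
  for (f in record$features) {
    if (f$end < span[1]) up[[length(up) + 1L]] <- f
    if (f$start > span[2]) down[[length(down) + 1L]] <- f
  }
  up <- up[order(sapply(up, `[[`, "end"), decreasing = TRUE)]
  down <- down[order(sapply(down, `[[`, "start"))]
  list(upstream = head(up, k), downstream = head(down, k))
}

# --- keyword-match oracle: exhaustive pairwise token check ------------------

oracle_keyword_matches <- function(product, catalog) {
  toks <- tolower(strsplit(gsub("[^a-zA-Z0-9]+", " ", product), " +")[[1]])
  toks <- toks[nzchar(toks)]
  hits <- character()
  for (entry in catalog$entries) {
    for (pat in entry$keywords) {
      ktoks <- tolower(strsplit(gsub("[^a-zA-Z0-9]+", " ", pat), " +")[[1]])
      ktoks <- ktoks[nzchar(ktoks)]
      if (length(ktoks) && all(ktoks %in% toks)) {
        hits <- c(hits, entry$component_id); break
      }
    }
  }
  hits
}

# --- chaining oracle: greedy split on the gap rule --------------------------

oracle_chains <- function(starts, ends, max_gap) {
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  groups <- list(); cur <- ord[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - ends[i - 1L] > max_gap) {
      groups[[length(groups) + 1L]] <- cur; cur <- ord[i]
    } else cur <- c(cur, ord[i])
  }
  groups[[length(groups) + 1L]] <- cur
  groups
}

# --- exhaustive local-alignment enumeration (tiny sequences) ----------------
# Recursively enumerates every gapped alignment of every substring pair;
# affine gaps cost gap_open + L * gap_extend.

oracle_local_score <- function(q, r, scoring) {
  qs <- strsplit(q, "")[[1]]; rs <- strsplit(r, "")[[1]]
  sub <- scoring$matrix
  go <- scoring$gap_open; ge <- scoring$gap_extend
  enum_global <- function(qi, ri, last) {
    nq <- length(qi); nr <- length(ri)
    if (!nq && !nr) return(0)
    cands <- c()
    if (nq && nr)
      cands <- c(cands, sub[qi[1], ri[1]] +
                   enum_global(qi[-1], ri[-1], "M"))
    if (nq)
      cands <- c(cands, (if (identical(last, "X")) ge else go + ge) +
                   enum_global(qi[-1], ri, "X"))
    if (nr)
      cands <- c(cands, (if (identical(last, "Y")) ge else go + ge) +
                   enum_global(qi, ri[-1], "Y"))
    max(cands)
  }
  best <- 0
  for (i1 in seq_along(qs)) for (i2 in i1:length(qs))
    for (j1 in seq_along(rs)) for (j2 in j1:length(rs))
      best <- max(best, enum_global(qs[i1:i2], rs[j1:j2], ""))
  best
}

# --- all-topology least-squares oracle for 4-taxon NJ -----------------------
# Fits branch lengths by least squares for each of the three unrooted
# quartet topologies; returns the best topology (as a bipartition string)
# and its fitted distances.

oracle_quartet <- function(d) {
  taxa <- rownames(d)
  pairings <- list(c(1, 2), c(1, 3), c(1, 4))  # partner of taxon 1
  fits <- lapply(pairings, function(p) {
    a <- 1; b <- p[2]; cd <- setdiff(1:4, c(a, b))
    # branch order: la, lb, lc, ld, internal
    rows <- list(); y <- c()
    pair_idx <- list(c(a, b), c(a, cd[1]), c(a, cd[2]),
                     c(b, cd[1]), c(b, cd[2]), c(cd[1], cd[2]))
    X <- matrix(0, 6, 5)
    for (k in seq_along(pair_idx)) {
      i <- pair_idx[[k]][1]; j <- pair_idx[[k]][2]
      y[k] <- d[i, j]
      X[k, i] <- 1; X[k, j] <- 1
      same_side <- (i %in% c(a, b)) == (j %in% c(a, b))
      if (!same_side) X[k, 5] <- 1
    }
    fit <- lm.fit(X, y)
    sig <- paste(sort(taxa[c(a, b)]), collapse = "|")
    # canonical signature = side without the alphabetically first taxon
    first <- sort(taxa)[1]
    side <- if (first %in% taxa[c(a, b)]) taxa[cd] else taxa[c(a, b)]
    list(rss = sum(fit$residuals^2), coef = fit$coefficients,
         sig = paste(sort(side), collapse = "|"))
  })
  best <- which.min(sapply(fits, `[[`, "rss"))
  fits[[best]]
}

# --- K2P sampling variance (delta method) -----------------------------------

k2p_stderr <- function(P, Q, L) {
  c1 <- 1 / (1 - 2 * P - Q)
  c2 <- 1 / (1 - 2 * Q)
  c3 <- (c1 + c2) / 2
  sqrt((c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / L)
}

# --- Table-style AM1 emulation ----------------------------------------------
# Exact coordinates and protein ids of the bacillaene macrocluster of the
# Bacillus sp. AM1 genome record (synthetic stand-in for the real record,
# which cannot be downloaded offline).

am1_loci <- function() {
  data.frame(
    component = c("PksA", "PksB", "PksC", "PksD", "PksE", "AcpK", "PksG",
                  "PksH", "PksI", "PksJ", "PksL", "PksM", "PksN", "PksR", "PksS"),
    protein_id = sprintf("QHJ%05d.1", 3379:3393),
    start = c(1787442L, 1788295L, 1789287L, 1790293L, 1791269L, 1793575L,
              1793875L, 1795134L, 1795917L, 1796706L, 1811659L, 1825104L,
              1835629L, 1851944L, 1859536L),
    end = c(1787651L, 1788972L, 1790156L, 1791267L, 1793509L, 1793823L,
            1795137L, 1795907L, 1796666L, 1811657L, 1825086L, 1835639L,
            1851930L, 1859401L, 1860747L),
    stringsAsFactors = FALSE
  )
}

am1_record <- function(catalog = default_catalog()) {
  loci <- am1_loci()
  feats <- lapply(seq_len(nrow(loci)), function(i) {
    entry <- catalog$entries[[loci$component[i]]]
    gene_feature(loci$start[i], loci$end[i], "+",
                 locus_tag = sprintf("AM1_%04d", i),
                 gene = if (length(entry$gene_synonyms)) entry$gene_synonyms[1] else "",
                 product = entry$description,
                 protein_id = loci$protein_id[i],
                 ec_numbers = entry$ec_numbers)
  })
  genome_record("CP047644", length = 2000000L, features = feats,
                organism = "Bacillus sp. AM1 (synthetic emulation)")
}
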