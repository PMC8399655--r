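# Feature matching, cluster chaining, genome classification and labelling.

cat_ <- default_catalog()

test_that("annotation matching follows mode precedence", {
  # EC beats keyword; the printed PksC annotation maps to PksC via EC
  f <- gene_feature(100, 900, product = "ACP S malonyltransferase",
                    ec_numbers = "2.3.1.51")
  rec <- genome_record("T", 2000, list(f))
  hits <- match_features(rec, cat_)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$component_id, "PksC")
  expect_equal(hits[[1]]$mode, "ec")
  expect_equal(hits[[1]]$score, 1.0)

  # gene name beats EC: same EC but gene says pksE
  f2 <- gene_feature(100, 900, gene = "pksE",
                     product = "ACP S malonyltransferase", ec_numbers = "2.3.1.51")
  hits2 <- match_features(genome_record("T", 2000, list(f2)), cat_)
  expect_equal(hits2[[1]]$component_id, "PksE")
  expect_equal(hits2[[1]]$mode, "gene_name")

  # keyword only
  f3 <- gene_feature(100, 900, product = "Hydroxymethylglutaryl CoA synthase family protein")
  hits3 <- match_features(genome_record("T", 2000, list(f3)), cat_)
  expect_equal(hits3[[1]]$component_id, "PksG")
  expect_equal(hits3[[1]]$mode, "keyword")

  # the more specific keyword pattern wins the PksH/PksI token-subset tie
  f4 <- gene_feature(100, 900, product = "enoyl CoA hydratase/isomerase family protein")
  expect_equal(match_features(genome_record("T", 2000, list(f4)), cat_)[[1]]$component_id,
               "PksI")
  f5 <- gene_feature(100, 900, product = "Enoyl CoA hydratase/isomerase")
  expect_equal(match_features(genome_record("T", 2000, list(f5)), cat_)[[1]]$component_id,
               "PksH")

  # EC wildcards match annotated sub-numbers
  f6 <- gene_feature(100, 900, product = "unrelated oxidase", ec_numbers = "1.14.14.9")
  expect_equal(match_features(genome_record("T", 2000, list(f6)), cat_)[[1]]$component_id,
               "PksS")
})

test_that("zero features and decoy products yield no hits (keyword oracle agrees)", {
  expect_length(match_features(genome_record("E", 1000, list()), cat_), 0L)

  decoys <- c("malonate transporter", "acyl CoA dehydrogenase",
              "DNA gyrase subunit alpha", "polyketide cyclase like lipocalin")
  for (p in decoys) {
    f <- gene_feature(10, 500, product = p)
    got <- match_features(genome_record("D", 1000, list(f)), cat_)
    want <- oracle_keyword_matches(p, cat_)
    expect_equal(length(got) > 0, length(want) > 0, label = p)
    expect_length(got, 0L)
  }
})

test_that("matching equals the exhaustive (feature, entry) oracle on random products", {
  set.seed(99)
  vocab <- c(unlist(lapply(cat_$entries, `[[`, "description")),
             "malonate transporter", "ribosome maturation GTPase",
             "Acyl carrier protein", "Cytochrome P450 monooxygenase")
  for (rep in 1:50) {
    p <- sample(vocab, 1)
    f <- gene_feature(10, 500, product = p)
    got <- match_features(genome_record("R", 1000, list(f)), cat_,
                          run_config(modes = "keyword"))
    want <- oracle_keyword_matches(p, cat_)
    if (length(want)) {
      expect_length(got, 1L)
      expect_true(got[[1]]$component_id %in% want)
    } else {
      expect_length(got, 0L)
    }
  }
})

test_that("chaining matches the brute-force gap oracle", {
  tmpl <- cat_$templates$bae
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:40, 1)
    starts <- sort(sample.int(500000, n))
    ends <- starts + sample(200:2000, n, replace = TRUE)
    comps <- sample(tmpl$components, n, replace = TRUE)
    hits <- lapply(seq_len(n), function(i) {
      structure(list(component_id = comps[i],
                     feature = gene_feature(starts[i], ends[i]),
                     mode = "gene_name", score = 1, alignment = NULL),
                class = "component_hit")
    })
    calls <- assemble_clusters(hits, tmpl)
    want <- oracle_chains(starts, ends, tmpl$max_gap_bp)
    expect_length(calls, length(want))
    got_sizes <- sapply(calls, function(cl) length(cl$hits))
    expect_equal(got_sizes, sapply(want, length))
  }
})

test_that("a far-away hit is split into its own call", {
  tmpl <- cat_$templates$bae
  starts <- c(seq(1000, by = 2000, length.out = 16), 800000L)
  ends <- starts + 1500L
  comps <- c(tmpl$components[1:16], "PksS")
  hits <- lapply(seq_along(starts), function(i)
    structure(list(component_id = comps[i],
                   feature = gene_feature(starts[i], ends[i]),
                   mode = "gene_name", score = 1, alignment = NULL),
              class = "component_hit"))
  calls <- assemble_clusters(hits, tmpl)
  expect_length(calls, 2L)
  expect_equal(sort(sapply(calls, function(cl) length(cl$hits))), c(1L, 16L))
  expect_length(assemble_clusters(list(), tmpl), 0L)
})

test_that("classification reproduces complete / partial / absent patterns", {
  # full template in order -> completeness 1.0, complete
  fx <- generate_genome(fixture_spec(seed = 1, n_background = 0))
  expect_equal(length(fx$record$features), 18L)
  call <- classify_genome(fx$record, cat_)$bae
  expect_equal(call$completeness, 1.0)
  expect_equal(call$status, "complete")

  # B. amyloliquefaciens pattern: Regulator, PksF, PksN deleted -> still complete
  fx2 <- generate_genome(fixture_spec(seed = 2,
                                      deleted_components = c("Regulator", "PksF", "PksN")))
  call2 <- classify_genome(fx2$record, cat_)$bae
  expect_equal(call2$status, "complete")
  expect_equal(sort(call2$missing), c("PksF", "PksN", "Regulator"))
  expect_equal(call2$completeness, 15 / 18)

  # only 4 scattered components -> partial; none -> absent
  keep <- c("PksC", "PksG", "PksJ", "PksS")
  fx3 <- generate_genome(fixture_spec(
    seed = 3, deleted_components = setdiff(cat_$templates$bae$components, keep)))
  expect_equal(classify_genome(fx3$record, cat_)$bae$status, "partial")
  fx4 <- generate_genome(fixture_spec(
    seed = 4, deleted_components = cat_$templates$bae$components))
  call4 <- classify_genome(fx4$record, cat_)$bae
  expect_equal(call4$status, "absent")
  expect_length(call4$hits, 0L)
})

test_that("exactly one status per template and determinism across runs", {
  fx <- generate_genome(fixture_spec(seed = 10, n_background = 20,
                                     deleted_components = c("PksF", "PksN")))
  res1 <- classify_genome(fx$record, cat_)
  res2 <- classify_genome(fx$record, cat_)
  expect_identical(res1, res2)
  for (call in res1)
    expect_true(call$status %in% c("complete", "partial", "absent"))
  m1 <- report_matrix(list(G = res1), cat_)
  m2 <- report_matrix(list(G = res2), cat_)
  expect_identical(m1, m2)
})

test_that("deleting components never raises completeness; decoys never change it", {
  tmpl_comps <- cat_$templates$bae$components
  set.seed(5)
  for (rep in 1:8) {
    del_small <- sample(tmpl_comps, sample(0:5, 1))
    del_big <- unique(c(del_small, sample(setdiff(tmpl_comps, del_small),
                                          sample(1:6, 1))))
    seed <- sample.int(10000, 1)
    c_small <- classify_genome(generate_genome(
      fixture_spec(seed = seed, deleted_components = del_small))$record, cat_)$bae
    c_big <- classify_genome(generate_genome(
      fixture_spec(seed = seed, deleted_components = del_big))$record, cat_)$bae
    expect_lte(c_big$completeness, c_small$completeness)

    c_deco <- classify_genome(generate_genome(
      fixture_spec(seed = seed, deleted_components = del_small,
                   n_background = 40))$record, cat_)$bae
    expect_equal(c_deco$completeness, c_small$completeness)
    expect_equal(c_deco$status, c_small$status)
  }
})

test_that("labelling follows the strict-majority rule", {
  # all-bae call
  fx <- generate_genome(fixture_spec(seed = 6, n_background = 0))
  call <- classify_genome(fx$record, cat_)$bae
  expect_equal(label_cluster(call, cat_$templates), "bae")

  mixed_call <- function(n_mln, n_dfn) {
    comps <- c(paste0("Mln", LETTERS[seq_len(n_mln)]),
               paste0("Dfn", LETTERS[seq_len(n_dfn)]))
    hits <- lapply(seq_along(comps), function(i)
      structure(list(component_id = comps[i],
                     feature = gene_feature(i * 1000L, i * 1000L + 500L),
                     mode = "gene_name", score = 1, alignment = NULL),
                class = "component_hit"))
    mix <- cluster_template("mix", "mixed", c(paste0("Mln", LETTERS[1:9]),
                                              paste0("Dfn", LETTERS[1:13])))
    assemble_clusters(hits, mix)[[1]]
  }
  expect_equal(label_cluster(mixed_call(5, 2), cat_$templates), "mln")
  expect_equal(label_cluster(mixed_call(3, 3), cat_$templates), "unknown")

  absent <- classify_genome(generate_genome(fixture_spec(
    seed = 7, deleted_components = cat_$templates$bae$components))$record, cat_)$bae
  expect_error(label_cluster(absent, cat_$templates), class = "pks_usage_error")
})

test_that("mln and dfn clusters are found and labelled from gene names", {
  mln_genes <- paste0("mln", tolower(LETTERS[1:9]))
  feats <- lapply(seq_along(mln_genes), function(i)
    gene_feature(i * 3000L, i * 3000L + 2000L, gene = mln_genes[i],
                 product = sprintf("macrolactin synthase %s", LETTERS[i])))
  rec <- genome_record("MLN", 60000L, feats)
  res <- classify_genome(rec, cat_)
  expect_equal(res$mln$status, "complete")
  expect_equal(res$mln$completeness, 1.0)
  expect_equal(res$bae$status, "absent")
  expect_equal(label_cluster(res$mln, cat_$templates), "mln")
})

test_that("report matrix mirrors the table cell format", {
  loci <- am1_loci()
  rec <- am1_record(cat_)
  res <- list()
  res[[rec$accession]] <- classify_genome(rec, cat_)
  m <- report_matrix(res, cat_)
  expect_equal(m["PksC", "CP047644"], "QHJ03381.1 1789287..1790156")
  expect_equal(m["Regulator", "CP047644"], "-")
  # empty genome gets a footnote with the canonical phrase
  res$EMPTY <- classify_genome(genome_record("EMPTY", 1000L, list()), cat_)
  m2 <- report_matrix(res, cat_)
  expect_true(any(grepl("EMPTY PKs Loci was not found", attr(m2, "footnotes"))))
})
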