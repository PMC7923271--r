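test_that("base_stats matches direct letter counting", {
  expect_equal(base_stats("AATT")$at_skew, 0)
  expect_equal(base_stats("AAAT")$at_skew, 0.5)  # (3 - 1) / 4
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 1000, replace = TRUE,
                    prob = c(.3, .2, .2, .25, .05)), collapse = "")
  ch <- strsplit(s, "")[[1]]
  a <- sum(ch == "A"); t <- sum(ch == "T"); gg <- sum(ch == "G"); cc <- sum(ch == "C")
  bs <- base_stats(s)
  expect_equal(bs$at_skew, (a - t) / (a + t))
  expect_equal(bs$gc_skew, (gg - cc) / (gg + cc))
  expect_equal(bs$at_percent, 100 * (a + t) / (a + t + gg + cc))
  expect_equal(bs$n_sites, a + t + gg + cc)  # ambiguity codes excluded
})

test_that("base_stats handles degenerate input and reverse complement", {
  empty <- base_stats("NNN-")
  expect_true(is.na(empty$at_percent) && is.na(empty$at_skew))
  expect_true(is.na(base_stats("GGCC")$at_skew))
  # reverse complement negates both skews, preserves AT percent
  set.seed(7)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    fwd <- base_stats(s); rev <- base_stats(revcomp(s))
    expect_equal(rev$at_skew, -fwd$at_skew)
    expect_equal(rev$gc_skew, -fwd$gc_skew)
    expect_equal(rev$at_percent, fwd$at_percent)
  }
})

cfg <- sim_config(seed = 202)
toy <- generate_toy_mitogenome(cfg)
g <- toy$genome

test_that("partitioned composition covers genome, genes, codon positions and pools", {
  structures <- lapply(
    stats::setNames(nm = grep("^trn", gene_tokens(), value = TRUE)),
    function(f) {
      if (f %in% c("trnS1", "trnV")) cloverleaf_template(f, d_pairs = 0)
      else cloverleaf_template(f)
    })
  rep <- partitioned_composition(g, structures = structures)
  expect_equal(sum(rep$partition_type == "genome"), 1)
  expect_equal(sum(rep$partition_type == "gene"), 37)
  expect_equal(sum(rep$partition_type == "codon_position"), 6)  # 3 positions x 2 strands
  expect_equal(sum(rep$partition_type == "control_region"), 2)
  # stems vs loops: exactly two rows
  expect_equal(rep$partition[rep$partition_type == "trna_structure"],
               c("stems", "loops"))
  # letter-count conservation: gene + CR partitions tile the genome
  parts <- rep[rep$partition_type %in% c("gene", "control_region"), ]
  expect_equal(sum(parts$n_sites),
               rep$n_sites[rep$partition_type == "genome"])
  # stems + loops tile the tRNA pool
  expect_equal(sum(rep$n_sites[rep$partition_type == "trna_structure"]),
               rep$n_sites[rep$partition == "tRNA"])
})

test_that("an all-AT third position yields 100 percent AT at position 3", {
  f <- tibble::tibble(token = "atp8", start = 0L, end = 12L, strand = "+",
                      kind = "PCG", wrap = FALSE)
  gg <- mitogenome("x", "ATGCCTGGATAA", f)  # third positions G,T,A,A -> not all AT
  gg2 <- mitogenome("y", "ATACCTGGATAA", f) # third positions A,T,A,A
  rep2 <- partitioned_composition(gg2)
  pos3 <- rep2[rep2$partition == "pos3" & rep2$strand == "+", ]
  expect_equal(pos3$at_percent, 100)
})

test_that("ENC attains its limits and matches an independent implementation", {
  sense <- sense_codons(5)
  uniform <- stats::setNames(rep(10L, length(sense)), sense)
  expect_equal(enc(uniform), 62)  # all codons equally used
  # one codon per family: maximal bias, ENC = number of families
  tbl <- codon_table(5)
  one_per <- stats::setNames(rep(0L, length(sense)), sense)
  for (a in unique(tbl[sense])) {
    one_per[names(which(tbl[sense] == a))[1]] <- 50L
  }
  n_fam <- length(unique(tbl[sense]))
  expect_equal(enc(one_per), n_fam)
  expect_true(is.na(enc(stats::setNames(rep(0L, 62), sense))))
  # random tables agree with the straight-formula oracle
  set.seed(11)
  for (i in 1:10) {
    counts <- stats::setNames(rpois(62, lambda = sample(c(2, 5, 20), 1)), sense)
    expect_equal(enc(counts), oracle_enc(counts), tolerance = 1e-10)
  }
})

test_that("ENC decreases as within-family usage concentrates", {
  sense <- sense_codons(5)
  tbl <- codon_table(5)
  concentrate <- function(bias) {
    counts <- stats::setNames(numeric(length(sense)), sense)
    for (a in unique(tbl[sense])) {
      fam <- names(which(tbl[sense] == a))
      w <- (1 - bias) / length(fam) + bias * (seq_along(fam) == 1)
      counts[fam] <- round(600 * w)
    }
    counts
  }
  encs <- vapply(seq(0, 1, by = 0.2), function(b) enc(concentrate(b)), 0)
  expect_true(all(diff(encs) <= 1e-9))
})

test_that("MILC matches its formula and is ~0.5 under uniform usage", {
  sense <- sense_codons(5)
  set.seed(3)
  counts <- stats::setNames(rpois(62, 30), sense)
  expect_equal(milc(counts), oracle_milc(counts), tolerance = 1e-12)
  # usage equal to expectation: sum of M_a is 0, MILC = 0.5 - sum(r-1)/L
  uniform <- stats::setNames(rep(100L, 62), sense)
  fam_sizes <- table(codon_table(5)[sense])
  L <- sum(uniform)
  expect_equal(milc(uniform), 0.5 - sum(fam_sizes - 1) / L)
  expect_equal(milc(uniform), 0.5, tolerance = 0.02)
  # single amino-acid family with o = g exactly: M contribution zero
  lys <- stats::setNames(rep(0L, 62), sense)
  lys[c("AAA", "AAG")] <- 50L
  expect_equal(milc(lys), 0.5 - 1 / 100)
})

test_that("MILC supports a background expected distribution", {
  sense <- sense_codons(5)
  set.seed(8)
  bg <- stats::setNames(runif(62, 0.5, 2), sense)
  counts <- stats::setNames(rpois(62, 20), sense)
  m1 <- milc(counts, expected = bg)
  expect_true(is.finite(m1))
  # expected must not be zero where observed is positive
  bg0 <- bg; bg0["AAA"] <- 0
  counts["AAA"] <- 5
  expect_error(milc(counts, expected = bg0), class = "mito_data_error")
})

test_that("GC3 at fourfold-degenerate sites hits its bounds", {
  # GCx encodes Ala (fourfold) under code 5
  expect_equal(gc3_fourfold("GCTGCAGCT"), 0)
  expect_equal(gc3_fourfold("GCGGCCGCG"), 1)
  # AAA (Lys) is not fourfold: no qualifying codons
  expect_true(is.na(gc3_fourfold("AAA")))
})

test_that("amino-acid frequencies equal a translate-and-count oracle", {
  cds <- tibble::tibble(gene = "x", strand = "+", seq = "TTATTA")
  f <- aa_frequencies(cds)
  expect_equal(f$freq[f$strand == "all" & f$aa == "L"], 1)
  set.seed(5)
  cds2 <- extract_cds(generate_toy_mitogenome(sim_config(seed = 5))$genome)
  freqs <- aa_frequencies(cds2)
  for (cl in c("+", "-", "all")) {
    expect_equal(sum(freqs$freq[freqs$strand == cl]), 1)
  }
  # oracle: seqinr translation, pooled
  aa <- unlist(lapply(cds2$seq, function(s) {
    seqinr::translate(strsplit(s, "")[[1]], numcode = 5)
  }))
  aa <- aa[aa != "*"]
  leu <- mean(aa == "L")
  expect_equal(freqs$freq[freqs$strand == "all" & freqs$aa == "L"], leu)
})

test_that("ENC-GC3 and MILC respond monotonically to the composition bias", {
  # sweep the generator's GC3 parameter; stronger AT bias (lower GC3) must
  # give lower ENC and higher MILC on pooled counts
  gc3s <- c(0.08, 0.2, 0.35, 0.5)
  res <- vapply(seq_along(gc3s), function(i) {
    cc <- sim_config(seed = 300 + i, gc3 = gc3s[i])
    sc <- simulate_cds(cc)
    counts <- codon_counts(sc$cds)
    pooled <- tapply(counts$count, counts$codon, sum)
    c(enc = enc(pooled), milc = milc(pooled))
  }, c(enc = 0, milc = 0))
  expect_gt(cor(gc3s, res["enc", ], method = "spearman"), 0)
  expect_lt(cor(gc3s, res["milc", ], method = "spearman"), 0)
})
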