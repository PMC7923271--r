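test_that("pair stability is a pure function of the duple", {
  expect_equal(pair_stability(c("AU", "UA", "GC", "CG")), rep("WC", 4))
  expect_equal(pair_stability(c("GU", "UG")), rep("wobble", 2))
  expect_equal(pair_stability(c("AC", "UU", "GA")), rep("mismatch", 3))
  expect_equal(pair_stability(c("A-", "--")), rep("gapped", 2))
  # only 6 of the 16 pairings are stable
  all16 <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  expect_equal(sum(pair_stability(all16) %in% c("WC", "wobble")), 6)
})

test_that("pair-change classification follows the FCBC/HCBC/indel partition", {
  # full compensatory Watson-Crick switch
  cls <- classify_pair_change("AU", "GC")
  expect_equal(cls$category, "FCBC")
  expect_equal(cls$subtype, "WC_switch")
  expect_equal(cls$change, "AU->GC")
  # hemi change to a wobble pair
  cls <- classify_pair_change("AU", "GU")
  expect_equal(cls$category, "HCBC")
  expect_equal(cls$subtype, "result_wobble")
  expect_equal(cls$change, "A->G vs U")
  # hemi change producing a mismatch stays an HCBC with its subtype
  cls <- classify_pair_change("AU", "AC")
  expect_equal(cls$category, "HCBC")
  expect_equal(cls$subtype, "result_mismatch")
  # no change
  expect_equal(classify_pair_change("AU", "AU")$category, "none")
  # gaps are indels, never compensatory
  expect_equal(classify_pair_change("AU", "A-")$category, "indel")
  expect_equal(classify_pair_change("-U", "GU")$category, "indel")
  # double change resolving a mismatch
  expect_equal(classify_pair_change("AC", "GC")$category, "HCBC")
  expect_equal(classify_pair_change("AA", "GC")$subtype, "mismatch_to_match")
  expect_equal(classify_pair_change("GC", "AA")$subtype, "match_to_mismatch")
})

test_that("classification category is symmetric under direction reversal", {
  states <- c("AU", "UA", "GC", "CG", "GU", "AC", "UU", "A-", "--")
  for (p in states) for (k in states) {
    fwd <- classify_pair_change(p, k)$category
    bwd <- classify_pair_change(k, p)$category
    expect_equal(fwd, bwd)
  }
})

test_that("cloverleaf templates honour the forced stem sizes", {
  tmpl <- cloverleaf_template("trnA")
  expect_equal(sum(tmpl$pairs$arm == "acceptor"), 7)
  expect_equal(sum(tmpl$pairs$arm == "anticodon"), 5)
  expect_true(all(tmpl$pairs$pos5 < tmpl$pairs$pos3))
  expect_equal(anyDuplicated(c(tmpl$pairs$pos5, tmpl$pairs$pos3)), 0)
  armless <- cloverleaf_template("trnS1", d_pairs = 0)
  expect_false(armless$d_arm)
  expect_lt(armless$n_col, tmpl$n_col)
  expect_error(cloverleaf_template("trnX", d_pairs = 5))
})

test_that("consensus structure follows the majority layout", {
  cfg <- sim_config(seed = 31)
  tree <- simulate_tree(cfg)
  tmpl <- cloverleaf_template("trnA")
  sim <- simulate_trna(cfg, tree, tmpl)
  map <- build_consensus_structure(sim$alignment, tmpl)
  expect_equal(map$pairs$arm, tmpl$pairs$arm)
  expect_true(map$d_arm)
  # D-armless family: flag absent
  tmpl2 <- cloverleaf_template("trnS1", d_pairs = 0)
  sim2 <- simulate_trna(cfg, tree, tmpl2, seed = 32)
  map2 <- build_consensus_structure(sim2$alignment, tmpl2)
  expect_false(map2$d_arm)
  # 60/40 mixture of D-arm and D-armless layouts: majority wins
  full <- cloverleaf_template("trnA")
  armless <- cloverleaf_template("trnA", d_pairs = 0)
  n_full <- 6; n_arm <- 4
  width <- full$n_col
  rows <- matrix("-", n_full + n_arm, width)
  set.seed(9)
  for (i in seq_len(n_full)) rows[i, ] <- sample(c("A", "C", "G", "T"), width, TRUE)
  # armless rows occupy a fixed subset of columns (the first armless$n_col)
  sub_cols <- seq_len(armless$n_col)
  for (i in n_full + seq_len(n_arm)) {
    rows[i, sub_cols] <- sample(c("A", "C", "G", "T"), armless$n_col, TRUE)
  }
  rownames(rows) <- paste0("s", seq_len(nrow(rows)))
  map_mix <- build_consensus_structure(rows, full)
  expect_true(map_mix$d_arm)  # 60% majority carries the full layout
  # flipped majority: armless layout wins
  rows2 <- rows[c(7:10, 1:2, 7:10), , drop = FALSE]
  rownames(rows2) <- paste0("s", 1:10)
  map_mix2 <- build_consensus_structure(rows2, full)
  expect_false(map_mix2$d_arm)
})

test_that("pairwise CBC matrix matches the per-column oracle", {
  tmpl <- cloverleaf_template("trnA")
  cfg <- sim_config(seed = 77)
  tree <- simulate_tree(cfg)
  sim <- simulate_trna(cfg, tree, tmpl)
  alns <- list(trnA = sim$alignment)
  maps <- list(trnA = tmpl)
  cm <- pairwise_cbc_matrix(alns, maps, exclude = character(0))
  expect_true(isSymmetric(cm$total))
  expect_true(all(diag(cm$total) == 0))
  # brute-force per-pair, per-column oracle
  taxa <- rownames(sim$alignment)
  stable6 <- c("AT", "TA", "GC", "CG", "GT", "TG")
  for (i in 1:4) for (j in 5:8) {
    cnt <- 0
    for (p in seq_len(nrow(tmpl$pairs))) {
      d1 <- paste0(sim$alignment[i, tmpl$pairs$pos5[p]],
                   sim$alignment[i, tmpl$pairs$pos3[p]])
      d2 <- paste0(sim$alignment[j, tmpl$pairs$pos5[p]],
                   sim$alignment[j, tmpl$pairs$pos3[p]])
      if (d1 %in% stable6 && d2 %in% stable6 &&
          substr(d1, 1, 1) != substr(d2, 1, 1) &&
          substr(d1, 2, 2) != substr(d2, 2, 2)) cnt <- cnt + 1
    }
    expect_equal(cm$total[taxa[i], taxa[j]], cnt)
  }
})

test_that("pairwise CBC matrix: identity pairs, engineered FCBC, added taxon", {
  tmpl <- cloverleaf_template("trnA")
  base <- paste(rep("A", tmpl$n_col), collapse = "")
  s <- strsplit(base, "")[[1]]
  s[tmpl$pairs$pos5] <- "A"; s[tmpl$pairs$pos3] <- "T"
  s2 <- s
  s2[tmpl$pairs$pos5[1]] <- "G"; s2[tmpl$pairs$pos3[1]] <- "C"
  aln <- rbind(x = s, y = s2, z = s)
  cm <- pairwise_cbc_matrix(list(trnA = aln), list(trnA = tmpl),
                            exclude = character(0))
  expect_equal(cm$total["x", "y"], 1)  # one engineered AU/GC swap
  expect_equal(cm$total["x", "z"], 0)  # identical sequences
  # the duplicated taxon z contributes a zero row against x
  expect_equal(cm$total["z", "x"], 0)
})

test_that("tRNA families C, Y, M are excluded by default", {
  tmpl <- cloverleaf_template("trnA")
  aln <- matrix("A", 3, tmpl$n_col, dimnames = list(c("x", "y", "z"), NULL))
  alns <- list(trnA = aln, trnC = aln, trnY = aln, trnM = aln)
  maps <- list(trnA = tmpl, trnC = tmpl, trnY = tmpl, trnM = tmpl)
  cm <- pairwise_cbc_matrix(alns, maps)
  expect_equal(names(cm$per_trna), "trnA")
})

test_that("stem/loop composition agrees with base_stats on the sub-sequences", {
  cfg <- sim_config(seed = 55)
  tree <- simulate_tree(cfg)
  sim <- simulate_trna_set(cfg, tree, families = c("trnA", "trnF"))
  st <- stem_loop_stats(sim$alignments, sim$maps)
  expect_equal(st$partition, c("stems", "loops"))
  # oracle: extract and pool the sub-sequences by hand
  stems <- loops <- character(0)
  for (f in c("trnA", "trnF")) {
    m <- sim$alignments[[f]]
    paired <- c(sim$maps[[f]]$pairs$pos5, sim$maps[[f]]$pairs$pos3)
    stems <- c(stems, as.vector(m[, paired]))
    loops <- c(loops, as.vector(m[, -paired]))
  }
  expect_equal(st$at_percent[1], base_stats(paste(stems, collapse = ""))$at_percent)
  expect_equal(st$at_percent[2], base_stats(paste(loops, collapse = ""))$at_percent)
  # the generator's AT-rich loops show up as higher loop AT content
  expect_gt(st$at_percent[2], st$at_percent[1])
})

test_that("CBC tallies are exhaustive, exclusive and zero without change", {
  cfg0 <- sim_config(seed = 66, fcbc_rate = 0, hcbc_rate = 0,
                     mismatch_rate = 0, indel_rate = 0, loop_rate = 0)
  tree <- simulate_tree(cfg0)
  sim <- simulate_trna_set(cfg0, tree, families = c("trnA", "trnD"))
  expect_equal(nrow(sim$truth), 0)
  expect_true(all(apply(sim$alignments$trnA, 2, function(x) length(unique(x)) == 1)))
  anc <- lapply(sim$alignments, function(a) fitch_ancestral(a, tree))
  tl <- tally_cbc(anc, sim$maps)
  expect_equal(nrow(tl$records), 0)
  expect_equal(tl$stem_loop$events, c(0, 0))
  # with events: every changed stem pair lands in exactly one category
  cfg <- sim_config(seed = 67)
  sim <- simulate_trna_set(cfg, tree, families = c("trnA", "trnD"))
  anc <- lapply(sim$alignments, function(a) fitch_ancestral(a, tree))
  tl <- tally_cbc(anc, sim$maps)
  recs <- tl$records
  expect_true(all(recs$category %in% c("FCBC", "HCBC", "indel")))
  expect_equal(sum(tl$category$events), nrow(recs))
  # FCBC convenience column counts both bases of the pair
  fc <- tl$category[tl$category$category == "FCBC", ]
  expect_equal(fc$changes, 2L * fc$events)
})

test_that("near-zero HCBC is reported when the HCBC rate is zero", {
  cfg <- sim_config(seed = 68, hcbc_rate = 0, mismatch_rate = 0)
  tree <- simulate_tree(cfg)
  sim <- simulate_trna_set(cfg, tree)
  anc <- lapply(sim$alignments, function(a) fitch_ancestral(a, tree))
  g <- glance(tally_cbc(anc, sim$maps))
  fc <- g$fcbc_external + g$fcbc_internal
  hc <- g$hcbc_external + g$hcbc_internal
  expect_gt(fc, 0)
  expect_lte(hc, 0.05 * fc + 1)  # parsimony misassignment is bounded
})
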