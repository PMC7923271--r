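# Nucleotide composition, strand skews and codon-usage statistics.
#
# AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C); ambiguity codes and
# gaps never enter any count. Minus-strand genes are always summarised on
# their sense (coding) strand, the whole genome on the plus strand.

#' Base composition and strand skews of a sequence
#'
#' @param seq Nucleotide string (DNA or RNA; `U` is counted with `T`).
#' @return One-row tibble: `at_percent`, `at_skew`, `gc_skew`, `n_sites`.
#'   Skews are `NA` when their denominator is zero; all fields are `NA`
#'   for an empty effective sequence.
#' @export
#' @examples
#' base_stats("AAAT")$at_skew  # (3 - 1) / 4 = 0.5
base_stats <- function(seq) {
  s <- seq_chars(chartr("U", "T", toupper(seq)))
  a <- sum(s == "A"); c_ <- sum(s == "C"); g <- sum(s == "G"); t <- sum(s == "T")
  n <- a + c_ + g + t
  tibble::tibble(
    at_percent = if (n > 0) 100 * (a + t) / n else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_,
    n_sites = n)
}

#' Partitioned composition report for a mitogenome
#'
#' One row per partition: the whole genome (plus strand); every gene on its
#' sense strand; codon positions 1/2/3 pooled across the protein-coding
#' genes, separately for plus- and minus-strand genes; the rRNA and tRNA
#' pools; tRNA stems vs loops when cloverleaf structures are supplied; and
#' each control region.
#'
#' @param g A [mitogenome()].
#' @param structures Optional named list (by tRNA token) of
#'   [cloverleaf_template()] layouts used to split tRNA genes into stem and
#'   loop sites; a tRNA whose length does not match its template is pooled
#'   but not split.
#' @param code Translation table for framing checks.
#' @return Tibble with columns `partition_type`, `partition`, `strand` and
#'   the [base_stats()] fields.
#' @export
partitioned_composition <- function(g, structures = NULL, code = 5) {
  reports <- list(
    dplyr::mutate(base_stats(g$sequence), partition_type = "genome",
                  partition = "complete", strand = "+"))
  f <- g$features
  # per-gene, sense strand
  for (i in seq_len(nrow(f))) {
    row <- f[i, ]
    reports[[length(reports) + 1]] <- dplyr::mutate(
      base_stats(feature_seq(g, row)),
      partition_type = ifelse(row$kind == "CR", "control_region", "gene"),
      partition = row$token, strand = row$strand)
  }
  # codon positions by strand class, pooled over framed PCGs
  cds <- extract_cds(g, code)
  for (str in c("+", "-")) {
    sub <- cds[cds$strand == str, ]
    if (!nrow(sub)) next
    pooled <- lapply(1:3, function(p) character(0))
    for (s in sub$seq) {
      ch <- seq_chars(s)
      n3 <- (length(ch) %/% 3) * 3
      if (n3 == 0) next
      pos <- rep(1:3, length.out = n3)
      for (p in 1:3) pooled[[p]] <- c(pooled[[p]], ch[seq_len(n3)][pos == p])
    }
    for (p in 1:3) {
      reports[[length(reports) + 1]] <- dplyr::mutate(
        base_stats(paste(pooled[[p]], collapse = "")),
        partition_type = "codon_position", partition = paste0("pos", p),
        strand = str)
    }
  }
  # region-class pools
  for (kind in c("rRNA", "tRNA")) {
    sub <- f[f$kind == kind, ]
    if (!nrow(sub)) next
    seqs <- vapply(seq_len(nrow(sub)), function(i) feature_seq(g, sub[i, ]), "")
    reports[[length(reports) + 1]] <- dplyr::mutate(
      base_stats(paste(seqs, collapse = "")),
      partition_type = "region_class", partition = kind, strand = "sense")
  }
  # tRNA stems vs loops from supplied cloverleaf layouts
  if (!is.null(structures)) {
    stem <- character(0); loop <- character(0)
    sub <- f[f$kind == "tRNA", ]
    for (i in seq_len(nrow(sub))) {
      tmpl <- structures[[sub$token[i]]]
      if (is.null(tmpl)) next
      s <- seq_chars(feature_seq(g, sub[i, ]))
      if (length(s) != tmpl$n_col) next
      paired <- c(tmpl$pairs$pos5, tmpl$pairs$pos3)
      stem <- c(stem, s[paired])
      loop <- c(loop, s[-paired])
    }
    reports[[length(reports) + 1]] <- dplyr::mutate(
      base_stats(paste(stem, collapse = "")),
      partition_type = "trna_structure", partition = "stems", strand = "sense")
    reports[[length(reports) + 1]] <- dplyr::mutate(
      base_stats(paste(loop, collapse = "")),
      partition_type = "trna_structure", partition = "loops", strand = "sense")
  }
  dplyr::bind_rows(reports) %>%
    dplyr::select("partition_type", "partition", "strand", dplyr::everything())
}

# ------------------------------------------------------------- codon usage

#' Codon counts of a CDS set
#'
#' @param cds Tibble from [extract_cds()] (or any tibble with `gene`,
#'   `seq`). Stop codons and codons containing ambiguity codes are excluded.
#' @param code Translation table.
#' @return Tibble `gene`, `codon`, `aa`, `count` over the sense codons.
#' @export
codon_counts <- function(cds, code = 5) {
  tbl <- codon_table(code)
  sense <- sense_codons(code)
  purrr::map2(cds$gene, cds$seq, function(gene, seq) {
    cods <- split_codons(seq)
    cods <- cods[cods %in% sense]
    cnt <- table(factor(cods, levels = sense))
    tibble::tibble(gene = gene, codon = sense, aa = unname(tbl[sense]),
                   count = as.integer(cnt))
  }) %>% dplyr::bind_rows()
}

#' Effective number of codons (Wright's ENC)
#'
#' Wright's statistic generalized to an arbitrary genetic code: for each
#' amino-acid family with at least two observations and family size
#' \eqn{r \ge 2}, the homozygosity is
#' \eqn{\hat F = (n \sum_i p_i^2 - 1)/(n - 1)}; ENC sums, over family-size
#' classes, the number of families in the class divided by the mean
#' \eqn{\hat F} of the class, plus one for every single-codon family.
#' A class with no informative family is imputed from the neighbouring
#' classes (Wright's convention). The result is capped at the number of
#' sense codons (62 for the invertebrate mitochondrial code).
#'
#' @param counts Named integer vector of codon counts (names = codons), or
#'   a tibble with `codon` and `count` columns.
#' @param code Translation table.
#' @return ENC as a single double; `NA` for an all-zero table.
#' @export
enc <- function(counts, code = 5) {
  counts <- as_codon_vector(counts, code)
  if (sum(counts) == 0) return(NA_real_)
  tbl <- codon_table(code)
  fam <- split(counts, tbl[names(counts)])
  sizes <- vapply(fam, length, 0L)
  F_hat <- vapply(fam, function(x) {
    n <- sum(x)
    if (n < 2) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }, 0)
  n_single <- sum(sizes == 1)
  out <- n_single
  size_classes <- sort(unique(sizes[sizes >= 2]))
  class_means <- vapply(size_classes, function(s) {
    v <- F_hat[sizes == s]
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  for (k in seq_along(size_classes)) {
    m <- class_means[k]
    if (is.na(m)) {
      # impute from the mean of the available neighbouring classes
      avail <- class_means[!is.na(class_means)]
      if (!length(avail)) return(NA_real_)
      m <- mean(avail)
    }
    out <- out + sum(sizes == size_classes[k]) / m
  }
  min(out, length(counts))
}

#' MILC codon-usage statistic
#'
#' Measure Independent of Length and Composition: per amino acid,
#' \eqn{M_a = 2 \sum_c o_c \ln(f_c / g_c)} over its codons (observed counts
#' \eqn{o}, observed within-family frequencies \eqn{f}, expected
#' within-family frequencies \eqn{g}); then
#' \eqn{\mathrm{MILC} = \sum_a M_a / L - C} with the correction
#' \eqn{C = \sum_a (r_a - 1)/L - 0.5} over the amino acids observed, where
#' \eqn{L} is the total codon count. Under usage equal to the expectation
#' the statistic is close to 0.5 for long genes.
#'
#' @inheritParams enc
#' @param expected `"uniform"` (equal use within each family, the default)
#'   or a named numeric vector of expected codon frequencies (e.g. the
#'   genome-wide codon distribution) used as the background.
#' @return MILC as a single double; `NA` when no codons are observed.
#' @export
milc <- function(counts, expected = "uniform", code = 5) {
  counts <- as_codon_vector(counts, code)
  L <- sum(counts)
  if (L == 0) return(NA_real_)
  tbl <- codon_table(code)
  aa <- tbl[names(counts)]
  if (identical(expected, "uniform")) {
    g_all <- stats::ave(rep(1, length(counts)), aa, FUN = function(x) x / length(x))
    names(g_all) <- names(counts)
  } else {
    g_all <- expected[names(counts)]
    tot <- stats::ave(g_all, aa, FUN = sum)
    g_all <- g_all / tot
  }
  if (any(counts > 0 & (is.na(g_all) | g_all == 0))) {
    abort("observed codon with zero expected frequency", class = "mito_data_error")
  }
  M_sum <- 0; r_sum <- 0
  for (a in unique(aa)) {
    sel <- aa == a
    o <- counts[sel]
    n <- sum(o)
    if (n == 0) next
    f <- o / n
    g <- g_all[sel]
    pos <- o > 0
    M_sum <- M_sum + 2 * sum(o[pos] * log(f[pos] / g[pos]))
    r_sum <- r_sum + (sum(sel) - 1)
  }
  M_sum / L - (r_sum / L - 0.5)
}

as_codon_vector <- function(counts, code = 5) {
  sense <- sense_codons(code)
  if (is.data.frame(counts)) counts <- stats::setNames(counts$count, counts$codon)
  out <- stats::setNames(rep(0, length(sense)), sense)
  keep <- intersect(names(counts), sense)
  out[keep] <- counts[keep]
  out
}

#' G+C at third positions of fourfold-degenerate codons
#'
#' The fraction of G or C among third codon positions of codons belonging to
#' a fourfold-degenerate quartet (all four third bases code the same amino
#' acid) under the chosen code.
#'
#' @param cds Tibble with a `seq` column of in-frame coding sequences, or a
#'   character vector of sequences.
#' @param code Translation table.
#' @return Fraction in \[0, 1\]; `NA` when no qualifying codons exist.
#' @export
gc3_fourfold <- function(cds, code = 5) {
  seqs <- if (is.data.frame(cds)) cds$seq else cds
  tbl <- codon_table(code)
  quartet <- vapply(names(tbl), function(cdn) {
    pre <- substr(cdn, 1, 2)
    alt <- paste0(pre, c("A", "C", "G", "T"))
    all(tbl[alt] == tbl[cdn]) && tbl[cdn] != "*"
  }, TRUE)
  four <- names(tbl)[quartet]
  third <- unlist(lapply(seqs, function(s) {
    cods <- split_codons(s)
    substr(cods[cods %in% four], 3, 3)
  }))
  if (!length(third)) return(NA_real_)
  mean(third %in% c("G", "C"))
}

#' Amino-acid frequencies of a CDS set, by coding strand
#'
#' Translates each gene under the chosen code, drops stops and ambiguous
#' codons, and reports frequencies per strand class plus pooled.
#'
#' @param cds Tibble from [extract_cds()] (`gene`, `strand`, `seq`).
#' @param code Translation table.
#' @return Tibble `strand` (`+`, `-`, `all`), `aa`, `freq`; frequencies sum
#'   to 1 within each strand class.
#' @export
aa_frequencies <- function(cds, code = 5) {
  aas <- purrr::map2(cds$strand, cds$seq, function(str, s) {
    aa <- translate_cds(s, code)
    aa <- aa[!aa %in% c("*", "X")]
    tibble::tibble(strand = str, aa = aa)
  }) %>% dplyr::bind_rows()
  lvls <- sort(unique(unname(codon_table(code))))
  lvls <- setdiff(lvls, "*")
  one <- function(x, label) {
    tb <- table(factor(x, levels = lvls))
    tibble::tibble(strand = label, aa = lvls, freq = as.numeric(tb) / sum(tb))
  }
  dplyr::bind_rows(
    if (any(aas$strand == "+")) one(aas$aa[aas$strand == "+"], "+"),
    if (any(aas$strand == "-")) one(aas$aa[aas$strand == "-"], "-"),
    one(aas$aa, "all"))
}

#' Per-gene codon-usage summary
#'
#' Convenience wrapper combining [codon_counts()], [enc()], [milc()] and
#' [gc3_fourfold()] per gene.
#'
#' @inheritParams codon_counts
#' @param expected Passed to [milc()].
#' @return Tibble `gene`, `n_codons`, `enc`, `milc`, `gc3_4fold`.
#' @export
codon_usage <- function(cds, expected = "uniform", code = 5) {
  cc <- codon_counts(cds, code)
  cc %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(
      n_codons = sum(.data$count),
      enc = enc(stats::setNames(.data$count, .data$codon), code),
      milc = milc(stats::setNames(.data$count, .data$codon), expected, code),
      .groups = "drop") %>%
    dplyr::left_join(
      cds %>% dplyr::group_by(.data$gene) %>%
        dplyr::summarise(gc3_4fold = gc3_fourfold(.data$seq, code),
                         .groups = "drop"),
      by = "gene")
}
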