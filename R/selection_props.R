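# Physicochemical-property selection scan (TREESAAP-style magnitude
# categories and Z-scores) and a Nei-Gojobori counting dN/dS.

#' Amino-acid physicochemical property table
#'
#' Numeric values of seven physicochemical properties for the 20 amino
#' acids, drawn at runtime from the AAindex compilation distributed with the
#' seqinr package. The shipped set mirrors the properties commonly reported
#' in destabilizing-selection scans of mitochondrial proteins:
#'
#' * `pK_COOH` — equilibrium constant, ionization of COOH (AAindex
#'   JOND750102, Jones 1975)
#' * `solvent_reduction_ratio` — solvent accessibility reduction ratio
#'   (PONP800107, Ponnuswamy et al. 1980)
#' * `buriedness` — proportion of residues 95% buried (CHOC760103,
#'   Chothia 1976)
#' * `isoelectric_point` — (ZIMJ680104, Zimmerman et al. 1968)
#' * `surrounding_hydrophobicity` — in folded form (PONP800101,
#'   Ponnuswamy et al. 1980)
#' * `total_nonbonded_energy` — average non-bonded energy per residue
#'   (OOBM770104, Oobatake & Ooi 1977)
#' * `surrounding_residues` — average number of surrounding residues
#'   (PONP800108, Ponnuswamy et al. 1980)
#'
#' @param properties Optional subset of property names.
#' @return Tibble `property`, `aa` (one-letter), `value`; every property
#'   covers all 20 amino acids.
#' @export
aa_property_table <- function(properties = NULL) {
  acc <- c(pK_COOH = "JOND750102",
           solvent_reduction_ratio = "PONP800107",
           buriedness = "CHOC760103",
           isoelectric_point = "ZIMJ680104",
           surrounding_hydrophobicity = "PONP800101",
           total_nonbonded_energy = "OOBM770104",
           surrounding_residues = "PONP800108")
  if (!is.null(properties)) acc <- acc[properties]
  aaidx <- get_aaindex()
  three <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
             E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
             M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
             Y = "Tyr", V = "Val")
  purrr::imap(acc, function(a, nm) {
    v <- aaidx[[a]]$I
    tibble::tibble(property = nm, aa = names(three), value = unname(v[three]))
  }) %>% dplyr::bind_rows()
}

get_aaindex <- function() {
  if (is.null(the$aaindex)) {
    e <- new.env()
    utils::data("aaindex", package = "seqinr", envir = e)
    the$aaindex <- e$aaindex
  }
  the$aaindex
}

#' Magnitude model for amino-acid property changes
#'
#' Enumerates, with equal weight, every nonsynonymous (codon, single-
#' nucleotide mutant codon) pair under the genetic code, and bins the
#' absolute property change of each replacement into 8 equal-width
#' categories spanning the enumerated range. The category probabilities
#' `p_k` form the neutral baseline the Z-scan tests against; categories 7-8
#' are the "radical" changes.
#'
#' @param props Property table from [aa_property_table()].
#' @param code Translation table (5 = invertebrate mitochondrial).
#' @param n_cat Number of magnitude categories.
#' @return A `magnitude_model`: per property a list with `breaks` (length
#'   `n_cat + 1`) and `p` (baseline category probabilities summing to 1).
#' @export
build_magnitude_model <- function(props = aa_property_table(), code = 5,
                                  n_cat = 8) {
  tbl <- codon_table(code)
  pairs <- codon_mutant_pairs(code)
  by_prop <- split(props, props$property)
  model <- purrr::map(by_prop, function(pt) {
    if (length(unique(pt$aa)) < 20 || any(is.na(pt$value))) {
      abort("property table must cover all 20 amino acids", class = "mito_data_error")
    }
    val <- stats::setNames(pt$value, pt$aa)
    d <- abs(val[pairs$aa_to] - val[pairs$aa_from])
    rng <- range(d)
    if (diff(rng) == 0) {
      breaks <- c(rng[1], rng[2] + seq_len(n_cat))  # degenerate: all in cat 1
      p <- c(1, rep(0, n_cat - 1))
    } else {
      breaks <- seq(rng[1], rng[2], length.out = n_cat + 1)
      k <- magnitude_category(d, breaks)
      p <- as.numeric(table(factor(k, levels = seq_len(n_cat)))) / length(d)
    }
    list(breaks = breaks, p = p)
  })
  structure(list(properties = model, n_cat = n_cat, code = code),
            class = "magnitude_model")
}

# all single-nucleotide nonsynonymous codon pairs (both non-stop)
codon_mutant_pairs <- function(code = 5) {
  key <- paste0("mutpairs", code)
  if (!is.null(the[[key]])) return(the[[key]])
  tbl <- codon_table(code)
  sense <- sense_codons(code)
  from <- character(0); to <- character(0)
  for (cdn in sense) {
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cdn, pos, pos))) {
        mut <- cdn
        substr(mut, pos, pos) <- b
        if (tbl[mut] != "*" && tbl[mut] != tbl[cdn]) {
          from <- c(from, cdn); to <- c(to, mut)
        }
      }
    }
  }
  out <- tibble::tibble(from = from, to = to,
                        aa_from = unname(tbl[from]), aa_to = unname(tbl[to]))
  the[[key]] <- out
  out
}

magnitude_category <- function(d, breaks) {
  k <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  pmin(pmax(k, 1L), length(breaks) - 1L)
}

#' @export
print.magnitude_model <- function(x, ...) {
  cat(sprintf("<magnitude_model> %d properties, %d categories, code %d\n",
              length(x$properties), x$n_cat, x$code))
  invisible(x)
}

#' Per-branch amino-acid replacements from a codon alignment
#'
#' Reconstructs ancestral codons by nucleotide-level Fitch parsimony
#' ([fitch_ancestral()]) and lists the nonsynonymous parent-to-child
#' replacements on every branch. A codon differing at several positions is
#' decomposed along minimal single-step mutational paths; paths through
#' stop codons are avoided (used only if unavoidable) and ties are averaged,
#' so replacement weights may be fractional.
#'
#' @param codon_aln In-frame codon alignment (character matrix, columns a
#'   multiple of 3, rows = leaf labels).
#' @param tree Rooted `phylo`.
#' @param code Translation table.
#' @return Tibble `branch`, `branch_class`, `codon_site`, `aa_from`,
#'   `aa_to`, `weight`.
#' @export
branch_aa_substitutions <- function(codon_aln, tree, code = 5) {
  m <- as_aln_matrix(codon_aln)
  if (ncol(m) %% 3 != 0) {
    abort("codon alignment length is not a multiple of 3", class = "mito_data_error")
  }
  aa <- fitch_ancestral(m, tree)
  full <- aa$alignment
  bt <- branch_table(tree)
  tbl <- codon_table(code)
  rows <- list()
  n_sites <- ncol(m) / 3
  for (b in seq_len(nrow(bt))) {
    pl <- node_label(tree, bt$parent[b])
    cl <- bt$child_label[b]
    ps <- full[pl, ]; cs <- full[cl, ]
    changed_sites <- unique((which(ps != cs) - 1) %/% 3 + 1)
    for (site in changed_sites) {
      idx <- (site - 1) * 3 + 1:3
      pc <- paste(ps[idx], collapse = ""); cc <- paste(cs[idx], collapse = "")
      if (grepl("-", paste0(pc, cc), fixed = TRUE)) next
      steps <- codon_path_steps(pc, cc, tbl)
      if (!nrow(steps)) next
      rows[[length(rows) + 1]] <- dplyr::mutate(
        steps, branch = bt$child[b], branch_class = bt$class[b],
        codon_site = site)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(branch = integer(), branch_class = character(),
                          codon_site = integer(), aa_from = character(),
                          aa_to = character(), weight = double()))
  }
  out[, c("branch", "branch_class", "codon_site", "aa_from", "aa_to", "weight")]
}

# nonsynonymous steps along minimal mutational paths between two codons,
# averaged over admissible paths (those avoiding stop codons when possible)
codon_path_steps <- function(from, to, tbl) {
  diffs <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  empty <- tibble::tibble(aa_from = character(), aa_to = character(),
                          weight = double())
  if (!length(diffs)) return(empty)
  perms <- all_perms(diffs)
  paths <- purrr::map(perms, function(ord) {
    cur <- from
    codons <- character(length(ord))
    for (i in seq_along(ord)) {
      substr(cur, ord[i], ord[i]) <- substr(to, ord[i], ord[i])
      codons[i] <- cur
    }
    codons
  })
  ok <- vapply(paths, function(p) all(tbl[utils::head(c(from, p), -1)] != "*" &
                                        tbl[p] != "*"), TRUE)
  if (any(ok)) paths <- paths[ok]
  w <- 1 / length(paths)
  steps <- purrr::map(paths, function(p) {
    chain <- c(from, p)
    a <- tbl[chain]
    ns <- which(a[-1] != a[-length(a)] & a[-1] != "*" & a[-length(a)] != "*")
    if (!length(ns)) return(NULL)
    tibble::tibble(aa_from = unname(a[ns]), aa_to = unname(a[ns + 1]), weight = w)
  })
  out <- dplyr::bind_rows(steps)
  if (!nrow(out)) return(empty)
  out %>%
    dplyr::group_by(.data$aa_from, .data$aa_to) %>%
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
}

all_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  }
  out
}

#' Z-score scan of property-change categories
#'
#' Gene-level test per property and magnitude category:
#' \eqn{z_k = (o_k - N p_k) / \sqrt{N p_k (1 - p_k)}} with `N` the total
#' replacement weight and `p_k` the neutral baseline from
#' [build_magnitude_model()]; a positive selection flag is raised when
#' `z > threshold` in a radical category (7 or 8 of 8). A per-site track is
#' computed with the same statistic inside a sliding window of codon sites.
#'
#' @param subs Replacements from [branch_aa_substitutions()].
#' @param model A `magnitude_model`.
#' @param props Property table used to score each replacement (must match
#'   the model).
#' @param window Sliding-window width in codon sites.
#' @param threshold Significance threshold on z (3.09 is the one-sided
#'   normal 0.001 point).
#' @return A `z_report`: list with `gene` (tibble `property`, `category`,
#'   `observed`, `expected`, `z`, `radical`, `significant`) and `site`
#'   (windowed track for the radical categories), plus the inputs' `n`.
#' @export
z_scan <- function(subs, model, props = aa_property_table(), window = 20,
                   threshold = 3.09) {
  n_cat <- model$n_cat
  radical <- c(n_cat - 1, n_cat)
  if (!nrow(subs)) {
    return(structure(list(
      gene = tibble::tibble(property = character(), category = integer(),
                            observed = double(), expected = double(),
                            z = double(), radical = logical(),
                            significant = logical()),
      site = tibble::tibble(property = character(), category = integer(),
                            site = integer(), z = double(),
                            significant = logical()),
      n = 0, threshold = threshold), class = "z_report"))
  }
  val_tbl <- split(props, props$property)
  gene_rows <- list(); site_rows <- list()
  N <- sum(subs$weight)
  for (nm in names(model$properties)) {
    pm <- model$properties[[nm]]
    val <- stats::setNames(val_tbl[[nm]]$value, val_tbl[[nm]]$aa)
    d <- abs(val[subs$aa_to] - val[subs$aa_from])
    k <- magnitude_category(d, pm$breaks)
    o <- vapply(seq_len(n_cat), function(i) sum(subs$weight[k == i]), 0)
    expd <- N * pm$p
    z <- ifelse(pm$p > 0 & pm$p < 1,
                (o - expd) / sqrt(N * pm$p * (1 - pm$p)), 0)
    z[o == expd] <- 0
    gene_rows[[nm]] <- tibble::tibble(
      property = nm, category = seq_len(n_cat), observed = o, expected = expd,
      z = z, radical = seq_len(n_cat) %in% radical,
      significant = seq_len(n_cat) %in% radical & z > threshold)
    # sliding-window site track for radical categories
    max_site <- max(subs$codon_site)
    if (max_site >= 1) {
      starts <- seq_len(max(1, max_site - window + 1))
      for (cat in radical) {
        if (pm$p[cat] <= 0 || pm$p[cat] >= 1) next
        zs <- vapply(starts, function(s) {
          inw <- subs$codon_site >= s & subs$codon_site < s + window
          nw <- sum(subs$weight[inw])
          if (nw == 0) return(0)
          ow <- sum(subs$weight[inw & k == cat])
          (ow - nw * pm$p[cat]) / sqrt(nw * pm$p[cat] * (1 - pm$p[cat]))
        }, 0)
        site_rows[[paste(nm, cat)]] <- tibble::tibble(
          property = nm, category = cat, site = starts, z = zs,
          significant = zs > threshold)
      }
    }
  }
  structure(list(gene = dplyr::bind_rows(gene_rows),
                 site = dplyr::bind_rows(site_rows),
                 n = N, threshold = threshold),
            class = "z_report")
}

#' @export
print.z_report <- function(x, ...) {
  cat(sprintf("<z_report> N = %.5g replacements, threshold z > %.3g\n",
              x$n, x$threshold))
  sig <- x$gene[x$gene$significant, ]
  if (nrow(sig)) {
    cat("properties with radical categories above threshold:\n")
    print(sig)
  } else cat("no radical category exceeds the threshold\n")
  invisible(x)
}

#' @export
#' @method tidy z_report
tidy.z_report <- function(x, ...) x$gene

#' @export
#' @method glance z_report
glance.z_report <- function(x, ...) {
  tibble::tibble(n_replacements = x$n,
                 n_properties = length(unique(x$gene$property)),
                 n_significant = sum(x$gene$significant),
                 threshold = x$threshold)
}

# ------------------------------------------------------------------ dN/dS

#' Nei-Gojobori (1986) counting dN/dS for a codon sequence pair
#'
#' Classic counting method: per-codon synonymous/nonsynonymous site
#' fractions (changes to stop codons count as nonsynonymous sites),
#' pathway-averaged synonymous/nonsynonymous differences (pathways through
#' stop codons avoided when possible), and the Jukes-Cantor correction
#' \eqn{d = -3/4 \log(1 - 4p/3)}. Codons with a gap or ambiguity in either
#' sequence are dropped pairwise.
#'
#' @param seq_a,seq_b Equal-length in-frame codon sequences.
#' @param code Translation table.
#' @return A `dnds` object: list with `omega`, `dn`, `ds`, `pn`, `ps`,
#'   `n_sites`, `s_sites`, `n_diff`, `s_diff`, `n_codons`. `omega` is `NA`
#'   when `ds` is 0; saturated distances (p >= 3/4) give `NA` estimates.
#' @export
ng86_dnds <- function(seq_a, seq_b, code = 5) {
  tbl <- codon_table(code)
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  if (length(ca) != length(cb)) {
    abort("sequences differ in codon length", class = "mito_data_error")
  }
  valid <- function(x) x %in% names(tbl) & tbl[x] != "*"
  keep <- valid(ca) & valid(cb) & !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (!length(ca)) abort("no comparable codons", class = "mito_data_error")
  syn_frac <- ng86_site_fractions(code)
  S <- sum(syn_frac[ca] + syn_frac[cb]) / 2
  N <- 3 * length(ca) - S
  dif <- purrr::map2(ca, cb, function(x, y) ng86_codon_diffs(x, y, tbl))
  Sd <- sum(vapply(dif, `[[`, 0, "s"))
  Nd <- sum(vapply(dif, `[[`, 0, "n"))
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) {
    if (is.nan(p) || p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3) + 0  # +0 avoids signed negative zero
  }
  ds <- jc(ps); dn <- jc(pn)
  omega <- if (is.na(ds) || is.na(dn) || ds == 0) NA_real_ else dn / ds
  structure(list(omega = omega, dn = dn, ds = ds, pn = pn, ps = ps,
                 n_sites = N, s_sites = S, n_diff = Nd, s_diff = Sd,
                 n_codons = length(ca)),
            class = "dnds")
}

# per-codon synonymous site fraction: for each position, the fraction of
# the three alternative bases giving a synonymous non-stop codon
ng86_site_fractions <- function(code = 5) {
  key <- paste0("ngsites", code)
  if (!is.null(the[[key]])) return(the[[key]])
  tbl <- codon_table(code)
  sense <- sense_codons(code)
  out <- vapply(sense, function(cdn) {
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cdn, pos, pos))) {
        mut <- cdn
        substr(mut, pos, pos) <- b
        if (tbl[mut] == tbl[cdn]) s <- s + 1 / 3
      }
    }
    s
  }, 0)
  the[[key]] <- out
  out
}

# pathway-averaged synonymous/nonsynonymous differences between two codons
ng86_codon_diffs <- function(a, b, tbl) {
  if (a == b) return(list(s = 0, n = 0))
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  perms <- all_perms(diffs)
  paths <- purrr::map(perms, function(ord) {
    cur <- a
    codons <- character(length(ord))
    for (i in seq_along(ord)) {
      substr(cur, ord[i], ord[i]) <- substr(b, ord[i], ord[i])
      codons[i] <- cur
    }
    codons
  })
  ok <- vapply(paths, function(p) all(tbl[p] != "*"), TRUE)
  if (any(ok)) paths <- paths[ok]
  s <- 0; n <- 0
  for (p in paths) {
    chain <- c(a, p)
    aa <- tbl[chain]
    syn <- aa[-1] == aa[-length(aa)]
    s <- s + sum(syn) / length(paths)
    n <- n + sum(!syn) / length(paths)
  }
  list(s = s, n = n)
}

#' @export
print.dnds <- function(x, ...) {
  cat(sprintf("<dnds> omega = %s (dN = %.4g, dS = %.4g; %d codons)\n",
              if (is.na(x$omega)) "undefined" else sprintf("%.4g", x$omega),
              x$dn, x$ds, x$n_codons))
  invisible(x)
}

#' @export
#' @method tidy dnds
tidy.dnds <- function(x, ...) {
  tibble::tibble(term = c("omega", "dN", "dS"),
                 estimate = c(x$omega, x$dn, x$ds))
}

#' @export
#' @method glance dnds
glance.dnds <- function(x, ...) {
  tibble::tibble(omega = x$omega, dn = x$dn, ds = x$ds, pn = x$pn, ps = x$ps,
                 n_sites = x$n_sites, s_sites = x$s_sites,
                 n_diff = x$n_diff, s_diff = x$s_diff, n_codons = x$n_codons)
}
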