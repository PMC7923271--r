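# Cloverleaf stem maps over tRNA alignments and classification of stem-pair
# changes into full (FCBC) and hemi (HCBC) compensatory base changes,
# mismatch outcomes and indels.
#
# Stable pairings are the Watson-Crick AU, UA, GC, CG and the wobble GU/UG;
# the remaining 10 duples are mismatches. An FCBC changes both bases of a
# pair, an HCBC exactly one; any gap involvement is an indel.

STABLE_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")
WC_PAIRS <- c("AT", "TA", "GC", "CG")

#' Stability class of a stem base pair
#'
#' @param duple Character vector of 2-character pair states (e.g. `"AU"`,
#'   `"G-"`); `T` and `U` are interchangeable.
#' @return `"WC"`, `"wobble"`, `"mismatch"` or `"gapped"`.
#' @export
pair_stability <- function(duple) {
  d <- chartr("U", "T", toupper(duple))
  dplyr::case_when(
    grepl("-", d, fixed = TRUE) ~ "gapped",
    d %in% WC_PAIRS ~ "WC",
    d %in% STABLE_PAIRS ~ "wobble",
    TRUE ~ "mismatch")
}

# render a duple in RNA letters for reporting
rna_pair <- function(duple) chartr("T", "U", toupper(duple))

#' Cloverleaf layout template for a tRNA family
#'
#' Builds the canonical cloverleaf coordinate layout: acceptor stem (always
#' 7 pairs), D-arm (0-4 pairs; 0 models D-armless families such as tRNA-S1
#' and tRNA-V), anticodon stem (always 5 pairs) and T-arm (0-4 pairs), with
#' the connecting loops. Positions are 1-based over the ungapped sequence.
#'
#' @param trna Family token (`trnA` ... `trnY`).
#' @param d_pairs,t_pairs Stem sizes of the D- and T-arms.
#' @param d_loop,ac_loop,var_loop,t_loop Loop lengths; when an arm has zero
#'   pairs its stem+loop region collapses to a short replacement loop.
#' @return A `cloverleaf_map`: list with `trna`, `pairs` (tibble `pos5`,
#'   `pos3`, `arm`), `anticodon` (3 positions), arm flags and `n_col`.
#' @export
cloverleaf_template <- function(trna, d_pairs = 4, t_pairs = 4, d_loop = 7,
                                ac_loop = 7, var_loop = 4, t_loop = 7) {
  stopifnot(d_pairs >= 0, d_pairs <= 4, t_pairs >= 0, t_pairs <= 4)
  if (d_pairs == 0) d_loop <- 4
  if (t_pairs == 0) t_loop <- 4
  seg <- c(
    rep("acc5", 7), rep("spacer", 2),
    rep("d5", d_pairs), rep("d_loop", d_loop), rep("d3", d_pairs),
    "spacer",
    rep("ac5", 5), rep("ac_loop", ac_loop), rep("ac3", 5),
    rep("var", var_loop),
    rep("t5", t_pairs), rep("t_loop", t_loop), rep("t3", t_pairs),
    rep("acc3", 7))
  n <- length(seg)
  stem_pairs <- function(arm5, arm3, arm) {
    p5 <- which(seg == arm5); p3 <- which(seg == arm3)
    if (!length(p5)) return(NULL)
    tibble::tibble(pos5 = p5, pos3 = rev(p3), arm = arm)
  }
  pairs <- dplyr::bind_rows(
    stem_pairs("acc5", "acc3", "acceptor"),
    stem_pairs("d5", "d3", "D"),
    stem_pairs("ac5", "ac3", "anticodon"),
    stem_pairs("t5", "t3", "T"))
  acl <- which(seg == "ac_loop")
  anticodon <- acl[ceiling(length(acl) / 2) + (-1:1)]
  new_cloverleaf_map(trna, pairs, anticodon, n, segments = seg)
}

new_cloverleaf_map <- function(trna, pairs, anticodon, n_col, segments = NULL) {
  stopifnot(sum(pairs$arm == "acceptor") == 7,
            sum(pairs$arm == "anticodon") == 5,
            all(pairs$pos5 < pairs$pos3),
            !anyDuplicated(c(pairs$pos5, pairs$pos3)))
  structure(
    list(trna = trna, pairs = pairs, anticodon = anticodon,
         d_arm = any(pairs$arm == "D"), t_arm = any(pairs$arm == "T"),
         n_col = as.integer(n_col), segments = segments),
    class = "cloverleaf_map")
}

#' @export
print.cloverleaf_map <- function(x, ...) {
  cat(sprintf("<cloverleaf_map> %s: %d columns, %d pairs (acceptor 7, D %d, anticodon 5, T %d)%s\n",
              x$trna, x$n_col, nrow(x$pairs), sum(x$pairs$arm == "D"),
              sum(x$pairs$arm == "T"),
              if (!x$d_arm) ", D-arm absent" else ""))
  invisible(x)
}

#' Majority-rule consensus cloverleaf over a tRNA alignment
#'
#' Columns occupied (non-gap) in at least half of the sequences define the
#' consensus layout; the acceptor and anticodon stems are forced to 7 and 5
#' pairs at the template positions, while the D- and T-arms follow the
#' layout shared by the majority (an arm is dropped when the majority lacks
#' its columns, as in D-armless tRNA-S1/tRNA-V).
#'
#' @param aln Character matrix (or `DNAbin`) alignment of one tRNA family.
#' @param template [cloverleaf_template()] for the family.
#' @return A `cloverleaf_map` whose positions are alignment columns.
#' @export
build_consensus_structure <- function(aln, template) {
  m <- as_aln_matrix(aln)
  present <- which(colMeans(m != "-") >= 0.5)
  candidates <- list(template)
  if (template$d_arm) {
    candidates <- c(candidates, list(cloverleaf_template(template$trna, d_pairs = 0,
                                                         t_pairs = sum(template$pairs$arm == "T"))))
  }
  if (template$t_arm) {
    candidates <- c(candidates, list(cloverleaf_template(template$trna, t_pairs = 0,
                                                         d_pairs = sum(template$pairs$arm == "D"))))
  }
  fit <- purrr::detect(candidates, function(cand) cand$n_col == length(present))
  if (is.null(fit)) {
    abort(sprintf(
      "%s: consensus layout (%d present columns) matches no cloverleaf variant of the template",
      template$trna, length(present)), class = "mito_data_error")
  }
  pairs <- fit$pairs
  pairs$pos5 <- present[pairs$pos5]
  pairs$pos3 <- present[pairs$pos3]
  new_cloverleaf_map(template$trna, pairs, present[fit$anticodon], ncol(m))
}

#' Classify a stem-pair change
#'
#' Categories follow the compensatory-change framework: `FCBC` when both
#' bases of the pair changed (no gaps), `HCBC` when exactly one changed (no
#' gaps), `indel` when a gap is involved, `none` when the pair states are
#' equal. FCBC subtypes separate Watson-Crick switches (e.g. AU -> GC) from
#' mismatch-resolving or mismatch-creating double changes; HCBC subtypes
#' record the stability of the resulting pair (an HCBC producing a mismatch,
#' e.g. AU -> AC, stays an HCBC with subtype `result_mismatch`).
#'
#' @param parent,child 2-character pair states over `A,C,G,U/T,-`.
#' @return One-row tibble: `category`, `subtype`, `change` (rendered like
#'   `"AU->GC"` for FCBCs, `"A->G vs U"` for HCBCs).
#' @export
classify_pair_change <- function(parent, child) {
  p <- chartr("U", "T", toupper(parent))
  k <- chartr("U", "T", toupper(child))
  if (p == k) {
    return(tibble::tibble(category = "none", subtype = NA_character_,
                          change = NA_character_))
  }
  p1 <- substr(p, 1, 1); p2 <- substr(p, 2, 2)
  c1 <- substr(k, 1, 1); c2 <- substr(k, 2, 2)
  if (grepl("-", paste0(p, k), fixed = TRUE)) {
    return(tibble::tibble(category = "indel", subtype = NA_character_,
                          change = paste0(rna_pair(p), "->", rna_pair(k))))
  }
  n_changed <- (p1 != c1) + (p2 != c2)
  ps <- pair_stability(p); cs <- pair_stability(k)
  if (n_changed == 2) {
    subtype <- if (ps %in% c("WC", "wobble") && cs %in% c("WC", "wobble")) {
      if (ps == "WC" && cs == "WC") "WC_switch" else "stable_switch"
    } else if (cs %in% c("WC", "wobble")) "mismatch_to_match"
    else if (ps %in% c("WC", "wobble")) "match_to_mismatch"
    else "mismatch_to_mismatch"
    tibble::tibble(category = "FCBC", subtype = subtype,
                   change = paste0(rna_pair(p), "->", rna_pair(k)))
  } else {
    subtype <- switch(cs, WC = "result_WC", wobble = "result_wobble",
                      "result_mismatch")
    change <- if (p1 != c1) {
      paste0(rna_pair(p1), "->", rna_pair(c1), " vs ", rna_pair(p2))
    } else {
      paste0(rna_pair(p2), "->", rna_pair(c2), " vs ", rna_pair(p1))
    }
    tibble::tibble(category = "HCBC", subtype = subtype, change = change)
  }
}

#' Stem-pair change records along the branches of a reconstruction
#'
#' Walks every branch of the ancestral reconstruction and every stem pair of
#' the cloverleaf map, classifying each changed pair exactly once.
#'
#' @param aa An `ancestral_alignment` of one tRNA family alignment.
#' @param map The family's consensus `cloverleaf_map` (alignment columns).
#' @return Tibble: `trna`, `branch`, `branch_class`, `arm`, `pos5`, `pos3`,
#'   `parent_pair`, `child_pair`, `category`, `subtype`, `change`.
#' @export
cbc_changes <- function(aa, map) {
  tree <- aa$tree
  m <- aa$alignment
  bt <- branch_table(tree)
  rows <- list()
  for (b in seq_len(nrow(bt))) {
    pl <- node_label(tree, bt$parent[b])
    cl <- bt$child_label[b]
    pp <- paste0(m[pl, map$pairs$pos5], m[pl, map$pairs$pos3])
    cp <- paste0(m[cl, map$pairs$pos5], m[cl, map$pairs$pos3])
    d <- which(pp != cp)
    for (i in d) {
      cls <- classify_pair_change(pp[i], cp[i])
      rows[[length(rows) + 1]] <- tibble::tibble(
        trna = map$trna, branch = bt$child[b], branch_class = bt$class[b],
        arm = map$pairs$arm[i], pos5 = map$pairs$pos5[i],
        pos3 = map$pairs$pos3[i],
        parent_pair = rna_pair(chartr("U", "T", pp[i])),
        child_pair = rna_pair(chartr("U", "T", cp[i])),
        category = cls$category, subtype = cls$subtype, change = cls$change)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(trna = character(), branch = integer(),
                          branch_class = character(), arm = character(),
                          pos5 = integer(), pos3 = integer(),
                          parent_pair = character(), child_pair = character(),
                          category = character(), subtype = character(),
                          change = character()))
  }
  dplyr::bind_rows(rows)
}

#' Tally compensatory changes across tRNA families
#'
#' Aggregates [cbc_changes()] records over a set of family reconstructions:
#' category by branch class (with a `changes` column equal to 2 x events
#' for FCBCs, since both bases of the pair are affected), arm by branch
#' class, substitution type by branch class, and stem vs loop change
#' totals (substitutions at unpaired columns count as loop changes).
#'
#' @param anc Named list (by tRNA token) of `ancestral_alignment`s.
#' @param maps Named list of matching `cloverleaf_map`s.
#' @return A `cbc_tally`: list of tibbles `records`, `category`, `arm`,
#'   `type`, `stem_loop`.
#' @export
tally_cbc <- function(anc, maps) {
  fams <- intersect(names(anc), names(maps))
  records <- dplyr::bind_rows(lapply(fams, function(f) cbc_changes(anc[[f]], maps[[f]])))
  loops <- dplyr::bind_rows(lapply(fams, function(f) {
    subs <- branch_substitutions(anc[[f]])
    paired <- c(maps[[f]]$pairs$pos5, maps[[f]]$pairs$pos3)
    subs <- subs[!subs$column %in% paired, ]
    if (nrow(subs)) dplyr::mutate(subs, trna = f) else NULL
  }))
  events <- records[records$category != "none", ]
  category <- events %>%
    dplyr::count(.data$category, .data$branch_class, name = "events") %>%
    dplyr::mutate(changes = ifelse(.data$category == "FCBC",
                                   2L * .data$events, .data$events))
  arm <- events %>% dplyr::count(.data$arm, .data$branch_class, name = "events")
  type <- events %>%
    dplyr::count(.data$category, .data$change, .data$branch_class,
                 name = "events") %>%
    dplyr::arrange(.data$category, dplyr::desc(.data$events))
  stem_loop <- tibble::tibble(
    region = c("stems", "loops"),
    events = c(nrow(events), nrow(loops)))
  structure(list(records = records, category = category, arm = arm,
                 type = type, stem_loop = stem_loop, loop_records = loops),
            class = "cbc_tally")
}

#' @export
print.cbc_tally <- function(x, ...) {
  cat("<cbc_tally>\n")
  print(x$category)
  invisible(x)
}

#' @export
#' @method tidy cbc_tally
tidy.cbc_tally <- function(x, ...) x$records

#' @export
#' @method glance cbc_tally
glance.cbc_tally <- function(x, ...) {
  g <- function(cat, cls) {
    v <- x$category$events[x$category$category == cat &
                             x$category$branch_class == cls]
    if (length(v)) v else 0L
  }
  tibble::tibble(
    fcbc_external = g("FCBC", "external"), fcbc_internal = g("FCBC", "internal"),
    hcbc_external = g("HCBC", "external"), hcbc_internal = g("HCBC", "internal"),
    indel_events = sum(x$category$events[x$category$category == "indel"]),
    stem_events = x$stem_loop$events[1], loop_events = x$stem_loop$events[2])
}

#' Pairwise compensatory-change matrix across taxa
#'
#' Tree-free pairwise counting over extant sequences: for every taxon pair
#' and every stem pair, a count of 1 when both positions differ between the
#' two sequences and both duples are stable pairings (no gaps). With
#' `fcbc_only = FALSE`, changes at one position (hemi changes between two
#' stable duples) are counted as well.
#'
#' @param alns Named list (by tRNA token) of family alignments (character
#'   matrices over common taxa).
#' @param maps Named list of matching `cloverleaf_map`s.
#' @param fcbc_only Count only full compensatory differences.
#' @param exclude tRNA families left out (default C, Y, M, which are prone
#'   to missing data next to repetitive control regions).
#' @return A `cbc_matrix`: list with `total` (taxa x taxa symmetric count
#'   matrix) and `per_trna` (named list of matrices).
#' @export
pairwise_cbc_matrix <- function(alns, maps, fcbc_only = TRUE,
                                exclude = c("trnC", "trnY", "trnM")) {
  fams <- setdiff(intersect(names(alns), names(maps)), exclude)
  if (!length(fams)) abort("no tRNA families to analyze", class = "mito_data_error")
  taxa <- Reduce(intersect, lapply(alns[fams], rownames))
  per <- lapply(fams, function(f) {
    m <- as_aln_matrix(alns[[f]])[taxa, , drop = FALSE]
    p <- maps[[f]]$pairs
    out <- matrix(0L, length(taxa), length(taxa), dimnames = list(taxa, taxa))
    for (i in seq_along(taxa)) {
      di <- paste0(m[i, p$pos5], m[i, p$pos3])
      for (j in seq_along(taxa)) {
        if (j <= i) next
        dj <- paste0(m[j, p$pos5], m[j, p$pos3])
        stable <- pair_stability(di) %in% c("WC", "wobble") &
          pair_stability(dj) %in% c("WC", "wobble")
        b1 <- substr(di, 1, 1) != substr(dj, 1, 1)
        b2 <- substr(di, 2, 2) != substr(dj, 2, 2)
        hit <- if (fcbc_only) stable & b1 & b2 else stable & (b1 | b2)
        out[i, j] <- out[j, i] <- sum(hit)
      }
    }
    out
  })
  names(per) <- fams
  total <- Reduce(`+`, per)
  structure(list(total = total, per_trna = per, fcbc_only = fcbc_only),
            class = "cbc_matrix")
}

#' @export
print.cbc_matrix <- function(x, ...) {
  cat(sprintf("<cbc_matrix> %d taxa, %d tRNA families, %s counts\n",
              nrow(x$total), length(x$per_trna),
              if (x$fcbc_only) "FCBC" else "all-CBC"))
  print(x$total)
  invisible(x)
}

#' @export
#' @method tidy cbc_matrix
tidy.cbc_matrix <- function(x, ...) {
  df <- as.data.frame(as.table(x$total), stringsAsFactors = FALSE)
  names(df) <- c("taxon1", "taxon2", "count")
  tibble::as_tibble(df[df$taxon1 < df$taxon2, ])
}

#' Pooled stem vs loop composition of tRNA alignments
#'
#' @inheritParams pairwise_cbc_matrix
#' @return Tibble of two [base_stats()] rows, `partition` = stems / loops
#'   (gaps excluded from all counts).
#' @export
stem_loop_stats <- function(alns, maps, exclude = character(0)) {
  fams <- setdiff(intersect(names(alns), names(maps)), exclude)
  stem <- character(0); loop <- character(0)
  for (f in fams) {
    m <- as_aln_matrix(alns[[f]])
    paired <- c(maps[[f]]$pairs$pos5, maps[[f]]$pairs$pos3)
    stem <- c(stem, as.vector(m[, paired]))
    loop <- c(loop, as.vector(m[, -paired]))
  }
  dplyr::bind_rows(
    dplyr::mutate(base_stats(paste(stem, collapse = "")), partition = "stems"),
    dplyr::mutate(base_stats(paste(loop, collapse = "")), partition = "loops")) %>%
    dplyr::select("partition", dplyr::everything())
}
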