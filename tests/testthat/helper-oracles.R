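# Independent oracle implementations used to cross-check the package.
# Each is written from the defining formula or by exhaustive enumeration,
# deliberately not sharing code with the implementation under test.

# ---- exhaustive Fitch parsimony (minimum over all internal labelings) ----
oracle_parsimony_score <- function(states, tree, alphabet = c("A", "C", "G", "T", "-")) {
  # states: named character vector of leaf states (one column)
  n_tip <- length(tree$tip.label)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  grids <- rep(list(alphabet), length(internal))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- character(n_tip + tree$Nnode)
    lab[seq_len(n_tip)] <- states[tree$tip.label]
    lab[internal] <- unlist(combos[r, ])
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (cost < best) best <- cost
  }
  best
}

# ---- circular signed adjacency breakpoints, independent formulation ----
oracle_breakpoints <- function(tok_a, sgn_a, tok_b, sgn_b) {
  # adjacency multiset as unordered-strand-aware keys
  adj <- function(tok, sgn) {
    n <- length(tok)
    sapply(seq_len(n), function(i) {
      j <- if (i == n) 1 else i + 1
      x <- paste0(ifelse(sgn[i] < 0, "-", ""), tok[i])
      y <- paste0(ifelse(sgn[j] < 0, "-", ""), tok[j])
      xr <- paste0(ifelse(sgn[j] < 0, "", "-"), tok[j])
      yr <- paste0(ifelse(sgn[i] < 0, "", "-"), tok[i])
      paste(sort(c(paste(x, y), paste(xr, yr)))[1])
    })
  }
  sum(!adj(tok_a, sgn_a) %in% adj(tok_b, sgn_b))
}

# ---- conserved signed intervals by direct arc enumeration ----
oracle_blocks <- function(tok_a, sgn_a, tok_b, sgn_b) {
  n <- length(tok_a)
  arcs <- list()
  is_conserved <- function(idx) {
    # idx: positions in a (circular run). check contiguity + orientation in b
    toks <- tok_a[idx]
    pb <- match(toks, tok_b)
    if (length(idx) == 1) return(TRUE)
    dfwd <- all(diff(pb) %% n == 1) && all(sgn_b[pb] == sgn_a[idx])
    dbwd <- all(-diff(pb) %% n == 1) && all(sgn_b[pb] == -sgn_a[idx])
    dfwd || dbwd
  }
  if (is_conserved(seq_len(n))) return(list(seq_len(n)))
  for (s in seq_len(n)) {
    for (l in seq_len(n - 1)) {
      idx <- ((s - 1 + 0:(l - 1)) %% n) + 1
      if (is_conserved(idx)) arcs[[length(arcs) + 1]] <- idx else break
    }
  }
  # keep maximal arcs only
  keep <- vapply(seq_along(arcs), function(i) {
    !any(vapply(seq_along(arcs), function(j) {
      i != j && length(arcs[[j]]) > length(arcs[[i]]) &&
        all(arcs[[i]] %in% arcs[[j]])
    }, TRUE))
  }, TRUE)
  arcs <- arcs[keep]
  arcs[!duplicated(vapply(arcs, function(a) paste(sort(a), collapse = ","), ""))]
}

# ---- Wright's ENC, straight transcription of the formula ----
oracle_enc <- function(counts, code = 5) {
  tbl <- mitocomp::codon_table(code)
  aa_of <- tbl[names(counts)]
  fams <- split(counts, aa_of)
  Fhat <- list()
  for (a in names(fams)) {
    x <- fams[[a]]
    n <- sum(x)
    if (length(x) >= 2 && n >= 2) {
      Fhat[[a]] <- (n * sum((x / n)^2) - 1) / (n - 1)
    }
  }
  sizes <- vapply(fams, length, 0L)
  total <- sum(sizes == 1)
  for (s in sort(unique(sizes[sizes >= 2]))) {
    fam_names <- names(sizes)[sizes == s]
    vals <- unlist(Fhat[fam_names])
    vals <- vals[vals > 0]
    m <- if (length(vals)) mean(vals) else {
      all_vals <- unlist(Fhat)
      mean(all_vals[all_vals > 0])
    }
    total <- total + sum(sizes == s) / m
  }
  min(total, length(counts))
}

# ---- MILC from its defining formula ----
oracle_milc <- function(counts, code = 5) {
  tbl <- mitocomp::codon_table(code)
  aa_of <- tbl[names(counts)]
  L <- sum(counts)
  Ma_sum <- 0
  r_sum <- 0
  for (a in unique(aa_of)) {
    o <- counts[aa_of == a]
    if (sum(o) == 0) next
    f <- o / sum(o)
    g <- rep(1 / length(o), length(o))
    Ma_sum <- Ma_sum + 2 * sum(o[o > 0] * log(f[o > 0] / g[o > 0]))
    r_sum <- r_sum + length(o) - 1
  }
  Ma_sum / L - (r_sum / L - 0.5)
}

# ---- NG86 dN/dS, second implementation (loop-based, shared nothing) ----
oracle_ng86 <- function(a, b, code = 5) {
  tbl <- mitocomp::codon_table(code)
  cods_a <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cods_b <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  keep <- tbl[cods_a] != "*" & tbl[cods_b] != "*" &
    !is.na(tbl[cods_a]) & !is.na(tbl[cods_b])
  cods_a <- cods_a[keep]; cods_b <- cods_b[keep]
  syn_sites <- function(cdn) {
    s <- 0
    for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
      if (nt == substr(cdn, pos, pos)) next
      mut <- cdn; substr(mut, pos, pos) <- nt
      if (tbl[mut] == tbl[cdn]) s <- s + 1 / 3
    }
    s
  }
  S <- mean(c(sum(sapply(cods_a, syn_sites)), sum(sapply(cods_b, syn_sites))))
  N <- 3 * length(cods_a) - S
  oracle_perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(oracle_perms(v[-i]), function(rest) c(v[i], rest))
    }), recursive = FALSE)
  }
  path_diffs <- function(x, y) {
    d <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (!length(d)) return(c(0, 0))
    perms <- oracle_perms(d)
    step_counts <- lapply(perms, function(ord) {
      cur <- x; sy <- 0; ns <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; substr(nxt, p, p) <- substr(y, p, p)
        if (tbl[nxt] == "*") ok <- FALSE
        if (tbl[nxt] == tbl[cur]) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      list(s = sy, n = ns, ok = ok)
    })
    usable <- Filter(function(z) z$ok, step_counts)
    if (!length(usable)) usable <- step_counts
    c(mean(sapply(usable, `[[`, "s")), mean(sapply(usable, `[[`, "n")))
  }
  sd_nd <- rowSums(mapply(path_diffs, cods_a, cods_b))
  ps <- sd_nd[1] / S; pn <- sd_nd[2] / N
  jc <- function(p) if (p >= 0.75) NA else -3 / 4 * log(1 - 4 * p / 3)
  list(ds = jc(ps), dn = jc(pn), S = S, N = N, Sd = sd_nd[1], Nd = sd_nd[2])
}

# ---- magnitude-model baseline by independent enumeration ----
oracle_magnitude_p <- function(values, code = 5, n_cat = 8) {
  # values: named numeric over one-letter amino acids
  tbl <- mitocomp::codon_table(code)
  bases <- c("A", "C", "G", "T")
  deltas <- c()
  for (c1 in names(tbl)) {
    if (tbl[c1] == "*") next
    sp <- strsplit(c1, "")[[1]]
    for (pos in 1:3) for (nt in bases) {
      if (nt == sp[pos]) next
      c2 <- c1; substr(c2, pos, pos) <- nt
      if (tbl[c2] == "*" || tbl[c2] == tbl[c1]) next
      deltas <- c(deltas, abs(values[tbl[c2]] - values[tbl[c1]]))
    }
  }
  br <- seq(min(deltas), max(deltas), length.out = n_cat + 1)
  # left-closed bins [a, b), last bin closed, matching the stated convention
  k <- cut(deltas, breaks = br, right = FALSE, include.lowest = TRUE,
           labels = FALSE)
  as.numeric(table(factor(k, levels = 1:n_cat))) / length(deltas)
}

# ---- Spearman-by-hand Baker's gamma for tiny trees ----
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# ---- misc fixture builders ----
random_signed_order <- function(n, seed) {
  set.seed(seed)
  toks <- gene_tokens()[seq_len(n)]
  mitocomp:::new_gene_order(sample(toks), sample(c(-1L, 1L), n, replace = TRUE))
}

tiny_alignment <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(rows)
  m
}
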