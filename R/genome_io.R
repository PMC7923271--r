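# Reading, writing and dissecting annotated mitogenomes.
#
# Coordinates are 0-based half-open internally; GenBank and feature-table
# input/output are 1-based inclusive. A feature crossing the origin of the
# circular molecule keeps start > end and carries wrap = TRUE.

#' Construct an annotated mitogenome
#'
#' @param id Accession or sample code.
#' @param sequence IUPAC nucleotide string (plus strand).
#' @param features Data frame with columns `token`, `start`, `end`, `strand`
#'   (`+`/`-`), and optionally `kind` and `wrap`. Coordinates 0-based
#'   half-open on the plus strand; origin-wrapping features have
#'   `start > end` and `wrap = TRUE`.
#' @param taxon Free-text taxon name.
#' @param circular Is the molecule circular?
#' @param complete If `NULL`, inferred as "all 37 tokens present".
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(id, sequence, features, taxon = "", circular = TRUE,
                       complete = NULL) {
  features <- tibble::as_tibble(features)
  if (!"kind" %in% names(features)) features$kind <- token_kind(features$token)
  if (!"wrap" %in% names(features)) features$wrap <- features$start > features$end
  features <- features[, c("token", "start", "end", "strand", "kind", "wrap")]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  g <- structure(
    list(id = id, taxon = taxon, sequence = toupper(sequence),
         circular = circular, complete = FALSE, features = features),
    class = "mitogenome")
  g$complete <- if (is.null(complete)) {
    all(gene_tokens() %in% features$token)
  } else complete
  validate_mitogenome(g)
  g
}

validate_mitogenome <- function(g) {
  if (!nzchar(g$sequence)) abort("mitogenome sequence is empty", class = "mito_data_error")
  L <- nchar(g$sequence)
  f <- g$features
  bad <- (!f$wrap & !(f$start >= 0 & f$start < f$end & f$end <= L)) |
    (f$wrap & !(f$start >= 0 & f$start <= L & f$end >= 0 & f$end <= L))
  if (any(bad)) {
    abort(paste0("feature(s) out of bounds: ",
                 paste(f$token[bad], collapse = ", ")),
          class = "mito_data_error")
  }
  dup <- f$token[duplicated(f$token) & f$kind != "CR"]
  if (length(dup)) {
    abort(paste0("duplicate non-CR feature token(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "mito_data_error")
  }
  if (sum(f$kind == "CR") > 2) {
    abort("more than two control regions", class = "mito_data_error")
  }
  invisible(g)
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s (%s), %d bp, %s, %d features%s\n",
              x$id, if (nzchar(x$taxon)) x$taxon else "unnamed taxon",
              nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              nrow(x$features),
              if (x$complete) ", complete gene set" else ""))
  invisible(x)
}

#' @export
#' @method tidy mitogenome
tidy.mitogenome <- function(x, ...) {
  dplyr::mutate(x$features, id = x$id, taxon = x$taxon, .before = 1)
}

# sense-strand sequence of one feature row (handles wrap + minus strand)
feature_seq <- function(g, row) {
  L <- nchar(g$sequence)
  s <- if (row$wrap) {
    paste0(substr(g$sequence, row$start + 1, L), substr(g$sequence, 1, row$end))
  } else {
    substr(g$sequence, row$start + 1, row$end)
  }
  if (row$strand == "-") revcomp(s) else s
}

feature_length <- function(f, L) {
  ifelse(f$wrap, (L - f$start) + f$end, f$end - f$start)
}

# ---------------------------------------------------------------- synonyms

#' Gene-name synonym table
#'
#' Maps the annotation vocabulary found in GenBank records (e.g. `COI`,
#' `16S`, `tRNA-Leu (UUR)`) onto the standard tokens of [gene_tokens()].
#' The table ships as an editable TSV under `inst/extdata`; pass `path` to
#' use a custom table.
#'
#' @param path Optional path to a two-column TSV (`synonym`, `token`).
#' @return Tibble with columns `synonym` (normalized) and `token`.
#' @export
gene_synonyms <- function(path = NULL) {
  default <- is.null(path)
  if (default) {
    if (!is.null(the$synonyms)) return(the$synonyms)
    path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp")
  }
  tbl <- tibble::as_tibble(read.delim(path, stringsAsFactors = FALSE))
  tbl$synonym <- normalize_gene_name(tbl$synonym)
  if (default) the$synonyms <- tbl
  tbl
}

normalize_gene_name <- function(x) gsub("[^A-Z0-9]", "", toupper(x))

# map raw annotation names to standard tokens; NA when unmappable
map_gene_name <- function(x, synonyms = gene_synonyms()) {
  key <- normalize_gene_name(x)
  synonyms$token[match(key, synonyms$synonym)]
}

# ---------------------------------------------------------------- GenBank

#' Read mitogenomes from a GenBank flat file
#'
#' A minimal flat-file reader for annotated mitochondrial records: LOCUS,
#' DEFINITION, the FEATURES table (CDS/tRNA/rRNA/misc_feature/D-loop with
#' `/gene` and `/product` qualifiers, `complement()` and origin-spanning
#' `join()` locations) and ORIGIN. Feature names are mapped to the standard
#' token vocabulary via [gene_synonyms()]; unmappable features are kept
#' under their raw name with the kind inferred from the feature key, and
#' reported with a warning.
#'
#' @param path GenBank flat file (one or more records).
#' @param synonyms Synonym table, see [gene_synonyms()].
#' @return List of [mitogenome()] objects.
#' @export
read_genbank <- function(path, synonyms = gene_synonyms()) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines))) {
    abort("not a GenBank flat file (no LOCUS line)", class = "mito_format_error")
  }
  starts <- grep("^LOCUS", lines)
  ends <- c(starts[-1] - 1, length(lines))
  purrr::map2(starts, ends, function(a, b) {
    parse_genbank_record(lines[a:b], synonyms)
  })
}

parse_genbank_record <- function(rec, synonyms) {
  locus <- rec[grepl("^LOCUS", rec)][1]
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(grepl("circular", locus))
  taxon <- ""
  defn <- grep("^DEFINITION", rec, value = TRUE)
  if (length(defn)) taxon <- sub("\\.?$", "", sub("^DEFINITION\\s+", "", defn[1]))

  # sequence
  o <- grep("^ORIGIN", rec)
  seqs <- ""
  if (length(o)) {
    body <- rec[(o[1] + 1):length(rec)]
    body <- body[!grepl("^//", body)]
    seqs <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  if (!nzchar(seqs)) abort("zero-length GenBank record", class = "mito_data_error")
  L <- nchar(seqs)

  # features
  fstart <- grep("^FEATURES", rec)
  fend <- if (length(o)) o[1] - 1 else length(rec)
  feats <- list()
  if (length(fstart)) {
    flines <- rec[(fstart[1] + 1):fend]
    is_key <- grepl("^\\s{5}\\S", flines) & !grepl("^\\s{6,}", flines)
    idx <- which(is_key)
    for (k in seq_along(idx)) {
      block <- flines[idx[k]:(if (k < length(idx)) idx[k + 1] - 1 else length(flines))]
      head_toks <- strsplit(trimws(block[1]), "\\s+")[[1]]
      key <- head_toks[1]
      if (key %in% c("source", "gene")) next
      loc <- paste0(head_toks[-1], collapse = "")
      # continuation lines before the first qualifier extend the location
      qual_at <- grep("^\\s+/", block)
      first_q <- if (length(qual_at)) min(qual_at) else length(block) + 1
      if (first_q > 2) {
        loc <- paste0(loc, paste0(trimws(block[2:(first_q - 1)]), collapse = ""))
      }
      quals <- parse_qualifiers(block[qual_at])
      feats[[length(feats) + 1]] <- c(list(key = key, loc = loc), quals)
    }
  }
  features <- genbank_features_to_table(feats, L, synonyms)
  mitogenome(id = id, sequence = seqs, features = features, taxon = taxon,
             circular = circular)
}

parse_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  txt <- trimws(lines)
  out <- list()
  for (l in txt) {
    m <- regmatches(l, regexec('^/([A-Za-z_]+)=?"?([^"]*)"?', l))[[1]]
    if (length(m) == 3) out[[m[2]]] <- m[3]
  }
  out
}

parse_location <- function(loc, L) {
  strand <- if (grepl("complement", loc)) "-" else "+"
  nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
  if (length(nums) < 2) abort(paste("bad location:", loc), class = "mito_format_error")
  if (length(nums) >= 4 && grepl("join", loc)) {
    # origin-spanning join(a..L,1..b)
    list(start = nums[1] - 1, end = nums[4], strand = strand, wrap = TRUE)
  } else {
    list(start = nums[1] - 1, end = nums[2], strand = strand, wrap = FALSE)
  }
}

genbank_features_to_table <- function(feats, L, synonyms) {
  rows <- list()
  n_cr <- 0
  unmapped <- character(0)
  for (f in feats) {
    locp <- parse_location(f$loc, L)
    name <- f$gene %||% f$product %||% f$note %||% ""
    is_cr <- f$key %in% c("D-loop") ||
      grepl("control region|D-loop|AT-rich", paste(f$product %||% "", f$note %||% ""),
            ignore.case = TRUE)
    if (is_cr) {
      n_cr <- n_cr + 1
      num <- regmatches(name, regexpr("[0-9]+", name))
      token <- if (length(num) && nzchar(num)) paste0("CR", num)
               else paste0("CR", n_cr)
      kind <- "CR"
    } else {
      token <- map_gene_name(name, synonyms)
      if (is.na(token)) {
        token <- if (nzchar(name)) name else paste0("unknown_", length(rows) + 1)
        unmapped <- c(unmapped, token)
        kind <- switch(f$key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "PCG")
      } else {
        kind <- token_kind(token)
      }
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      token = token, start = locp$start, end = locp$end,
      strand = locp$strand, kind = kind, wrap = locp$wrap)
  }
  if (length(unmapped)) {
    warn(paste0("unmappable feature name(s) kept verbatim: ",
                paste(unique(unmapped), collapse = ", ")))
  }
  if (!length(rows)) return(tibble::tibble(
    token = character(), start = integer(), end = integer(),
    strand = character(), kind = character(), wrap = logical()))
  dplyr::bind_rows(rows)
}

#' Write mitogenomes to a GenBank flat file
#'
#' Emits the minimal record structure [read_genbank()] parses, so that
#' write-then-read round trips preserve the object.
#'
#' @param genomes A `mitogenome` or list of them.
#' @param path Output file.
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    L <- nchar(g$sequence)
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                       g$id, L, if (g$circular) "circular" else "linear"), con)
    if (nzchar(g$taxon)) writeLines(sprintf("DEFINITION  %s.", g$taxon), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", L), con)
    for (i in seq_len(nrow(g$features))) {
      f <- g$features[i, ]
      key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                    CR = "misc_feature", "misc_feature")
      loc <- if (f$wrap) {
        sprintf("join(%d..%d,1..%d)", f$start + 1, L, f$end)
      } else {
        sprintf("%d..%d", f$start + 1, f$end)
      }
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", key, loc), con)
      if (f$kind == "CR") {
        writeLines(sprintf('                     /note="control region %s"',
                           sub("^CR", "", f$token)), con)
      } else {
        writeLines(sprintf('                     /gene="%s"', f$token), con)
      }
    }
    writeLines("ORIGIN", con)
    pos <- seq(1, L, by = 60)
    for (p in pos) {
      chunk <- substr(g$sequence, p, min(p + 59, L))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# ------------------------------------------------------- FASTA + feature table

#' Read a mitogenome from FASTA plus a tab-separated feature table
#'
#' The feature table carries columns `token`, `start`, `end`, `strand`,
#' `kind` with 1-based inclusive coordinates; a control region wrapping the
#' origin is given with `start > end`.
#'
#' @param fasta Single-record FASTA file with the plus-strand sequence.
#' @param table TSV feature table.
#' @param circular Is the molecule circular?
#' @return A [mitogenome()].
#' @export
read_fasta_features <- function(fasta, table, circular = TRUE) {
  fa <- seqinr::read.fasta(fasta, as.string = TRUE, forceDNAtolower = FALSE)
  id <- names(fa)[1]
  seqs <- toupper(as.character(fa[[1]]))
  ann <- attr(fa[[1]], "Annot")
  taxon <- trimws(sub("^>\\S*\\s*", "", ann %||% ""))
  tbl <- read.delim(table, stringsAsFactors = FALSE)
  L <- nchar(seqs)
  if (any(tbl$start < 1 | tbl$start > L | tbl$end < 1 | tbl$end > L)) {
    abort("feature coordinates out of sequence bounds", class = "mito_data_error")
  }
  wrap <- tbl$start > tbl$end
  features <- tibble::tibble(
    token = tbl$token, start = tbl$start - 1L, end = as.integer(tbl$end),
    strand = tbl$strand, kind = tbl$kind, wrap = wrap)
  mitogenome(id = id, sequence = seqs, features = features, taxon = taxon,
             circular = circular)
}

#' Write a mitogenome as FASTA plus a feature table
#'
#' @param g A [mitogenome()].
#' @param fasta,table Output paths.
#' @export
write_fasta_features <- function(g, fasta, table) {
  seqinr::write.fasta(g$sequence, names = paste(g$id, g$taxon), file.out = fasta)
  out <- g$features
  out$start <- out$start + 1L
  write.table(out[, c("token", "start", "end", "strand", "kind")],
              table, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(g)
}

# ------------------------------------------------------------- gene orders

#' Extract the circular signed gene order of a mitogenome
#'
#' Tokens are listed in ascending plus-strand start order around the circle,
#' with sign encoding the coding strand, and the order is rotated to the
#' canonical frame (see [canonicalize_order()]).
#'
#' @param g A [mitogenome()].
#' @param include_cr Keep control-region tokens in the order.
#' @return A `gene_order` object (tibble of `token`, `sign`).
#' @export
extract_gene_order <- function(g, include_cr = FALSE) {
  f <- g$features
  if (!include_cr) f <- f[f$kind != "CR", ]
  if (nrow(f) < 1) abort("no features to order", class = "mito_data_error")
  f <- f[order(f$start), ]
  new_gene_order(f$token, ifelse(f$strand == "+", 1L, -1L))
}

new_gene_order <- function(tokens, signs, canonical = TRUE) {
  if (anyDuplicated(tokens)) {
    abort("duplicate token in gene order", class = "mito_data_error")
  }
  ord <- structure(tibble::tibble(token = tokens, sign = as.integer(signs)),
                   class = c("gene_order", "tbl_df", "tbl", "data.frame"))
  if (canonical) canonicalize_order(ord) else ord
}

#' Canonical rotation of a circular signed gene order
#'
#' Rotates the circle so that the anchor gene (`cox1` when present,
#' otherwise the first vocabulary token present) comes first with positive
#' sign. When the anchor lies on the minus strand the circle is first read
#' from the opposite strand (order reversed, all signs flipped), which makes
#' the representation invariant to reverse-complementing the genome.
#'
#' @param ord A `gene_order`.
#' @param anchor Anchor token; default `cox1`.
#' @return The canonical `gene_order`.
#' @export
canonicalize_order <- function(ord, anchor = "cox1") {
  tokens <- ord$token; signs <- ord$sign
  if (!anchor %in% tokens) {
    anchor <- intersect(gene_tokens(TRUE), tokens)[1]
    if (is.na(anchor)) anchor <- tokens[1]
  }
  i <- match(anchor, tokens)
  if (signs[i] < 0) {
    tokens <- rev(tokens); signs <- rev(-signs)
    i <- match(anchor, tokens)
  }
  if (i > 1) {
    idx <- c(i:length(tokens), seq_len(i - 1))
    tokens <- tokens[idx]; signs <- signs[idx]
  }
  structure(tibble::tibble(token = tokens, sign = signs),
            class = c("gene_order", "tbl_df", "tbl", "data.frame"))
}

#' @export
format.gene_order <- function(x, ...) {
  paste(ifelse(x$sign < 0, paste0("-", x$token), x$token), collapse = " ")
}

#' @export
print.gene_order <- function(x, ...) {
  cat("<gene_order> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Write signed gene orders to a text file
#'
#' One line per genome: an identifier followed by the signed tokens,
#' space-separated, a leading `-` marking the minus strand.
#'
#' @param orders Named list of `gene_order` objects.
#' @param path Output file.
#' @export
write_gene_orders <- function(orders, path) {
  lines <- purrr::imap_chr(orders, function(o, nm) paste(nm, format(o)))
  writeLines(lines, path)
  invisible(path)
}

#' Read signed gene orders from a text file
#' @param path File written by [write_gene_orders()].
#' @return Named list of `gene_order` objects.
#' @export
read_gene_orders <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    toks <- strsplit(trimws(l), "\\s+")[[1]]
    body <- toks[-1]
    new_gene_order(sub("^-", "", body), ifelse(grepl("^-", body), -1L, 1L))
  })
  names(out) <- vapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]][1], "")
  out
}

# ------------------------------------------------------------------ CDS

#' Extract framed coding sequences from an annotated mitogenome
#'
#' Minus-strand genes are reverse-complemented to their sense strand. A
#' length not divisible by 3 marks a truncated (incomplete) stop codon; an
#' in-frame stop before the final codon is flagged, not fatal.
#'
#' @param g A [mitogenome()].
#' @param code NCBI translation table (5 = invertebrate mitochondrial).
#' @return Tibble with one row per protein-coding gene: `taxon`, `gene`,
#'   `strand`, `seq`, `n_codons`, `truncated`, `internal_stop`.
#' @export
extract_cds <- function(g, code = 5) {
  f <- g$features[g$features$kind == "PCG", ]
  rows <- purrr::map(seq_len(nrow(f)), function(i) {
    row <- f[i, ]
    s <- feature_seq(g, row)
    aa <- translate_cds(s, code)
    n_codons <- length(aa)
    internal <- n_codons > 1 && any(aa[seq_len(n_codons - 1)] == "*")
    tibble::tibble(
      taxon = if (nzchar(g$taxon)) g$taxon else g$id, gene = row$token,
      strand = row$strand, seq = s, n_codons = n_codons,
      truncated = nchar(s) %% 3 != 0, internal_stop = internal)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$internal_stop)) {
    warn(paste0("internal stop codon(s) in: ",
                paste(out$gene[out$internal_stop], collapse = ", ")))
  }
  out
}

#' Audit start and stop codons of a CDS set
#'
#' Canonical starts are ATG/ATA; the recognized alternatives (ATT, ATC,
#' GTG, TTG, CTG, GTA) are reported verbatim. Stops are TAA/TAG, or the
#' truncated forms T/TA completed by polyadenylation.
#'
#' @param cds Tibble from [extract_cds()] (columns `gene`, `taxon`, `seq`).
#' @return Tibble of `gene`, `taxon`, `start_codon`, `stop_codon`,
#'   `canonical_start`, `canonical_stop`, `truncated`.
#' @export
audit_start_stop_codons <- function(cds) {
  purrr::pmap(cds[, c("gene", "taxon", "seq")], function(gene, taxon, seq) {
    s <- toupper(seq)
    n <- nchar(s)
    start <- substr(s, 1, 3)
    rem <- n %% 3
    stop <- if (rem == 0) substr(s, n - 2, n) else substr(s, n - rem + 1, n)
    tibble::tibble(
      gene = gene, taxon = taxon, start_codon = start, stop_codon = stop,
      canonical_start = start %in% c("ATG", "ATA"),
      canonical_stop = stop %in% c("TAA", "TAG"),
      truncated = rem != 0)
  }) %>% dplyr::bind_rows()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
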