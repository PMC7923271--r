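# Fixed 37-gene vocabulary of the metazoan mitogenome plus control regions,
# and the genetic-code machinery shared across modules.

#' Standard mitochondrial gene tokens
#'
#' The fixed vocabulary of the 37 genes of the typical metazoan mitochondrial
#' genome (13 protein-coding genes, 22 tRNAs, 2 rRNAs), optionally extended
#' with up to two control-region tokens (`CR1`, `CR2`).
#'
#' @param include_cr Append the control-region tokens.
#' @return Character vector of gene tokens.
#' @export
#' @examples
#' length(gene_tokens())        # 37
#' tail(gene_tokens(TRUE), 2)   # CR1 CR2
gene_tokens <- function(include_cr = FALSE) {
  pcg <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
           "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
  trn <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI",
           "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP", "trnQ", "trnR",
           "trnS1", "trnS2", "trnT", "trnV", "trnW", "trnY")
  out <- c(pcg, trn, "rrnS", "rrnL")
  if (include_cr) out <- c(out, "CR1", "CR2")
  out
}

#' Kind (feature class) of a gene token
#'
#' @param token Character vector of tokens from [gene_tokens()].
#' @return Character vector over `PCG`, `tRNA`, `rRNA`, `CR`.
#' @export
token_kind <- function(token) {
  dplyr::case_when(
    grepl("^trn", token) ~ "tRNA",
    grepl("^rrn", token) ~ "rRNA",
    grepl("^CR", token)  ~ "CR",
    TRUE                 ~ "PCG"
  )
}

#' Codon-to-amino-acid table for a genetic code
#'
#' Returns the 64-codon translation table as a named character vector
#' (names are DNA codons, values one-letter amino acids, `*` for stops).
#' Tables are produced by seqinr's NCBI genetic-code machinery and cached.
#'
#' @param code NCBI translation table number; 5 is the invertebrate
#'   mitochondrial code used throughout.
#' @return Named character vector of length 64.
#' @export
#' @examples
#' codon_table(5)[["TGA"]]  # "W" in the invertebrate mitochondrial code
codon_table <- function(code = 5) {
  key <- paste0("code", code)
  if (!is.null(the[[key]])) return(the[[key]])
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  codons <- sort(codons)
  aa <- vapply(codons, function(cdn) {
    seqinr::translate(strsplit(cdn, "")[[1]], numcode = code)
  }, character(1))
  tbl <- stats::setNames(aa, codons)
  the[[key]] <- tbl
  tbl
}

#' Sense codons of a genetic code
#' @inheritParams codon_table
#' @return Character vector of non-stop codons (62 for code 5).
#' @export
sense_codons <- function(code = 5) {
  tbl <- codon_table(code)
  names(tbl)[tbl != "*"]
}

# synonymous family sizes, named by amino acid
codon_families <- function(code = 5) {
  tbl <- codon_table(code)
  table(tbl[tbl != "*"])
}

#' Reverse complement of a DNA sequence
#' @param seq Character scalar (IUPAC DNA).
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence into a character vector of single bases
seq_chars <- function(seq) strsplit(toupper(seq), "")[[1]]

# split an in-frame CDS into codons (drops a trailing partial codon)
split_codons <- function(seq) {
  s <- seq_chars(seq)
  n <- length(s) %/% 3
  if (n == 0) return(character(0))
  apply(matrix(s[seq_len(3 * n)], nrow = 3), 2, paste, collapse = "")
}

#' Translate an in-frame coding sequence
#' @param seq Character scalar, in-frame DNA.
#' @inheritParams codon_table
#' @return Character vector of one-letter amino acids (`*` = stop, `X` =
#'   ambiguous codon).
#' @export
translate_cds <- function(seq, code = 5) {
  cods <- split_codons(seq)
  tbl <- codon_table(code)
  aa <- unname(tbl[cods])
  aa[is.na(aa)] <- "X"
  aa
}
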