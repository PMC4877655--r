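#' Read sequences from a FASTA file
#'
#' Reads protein or nucleotide sequences and validates them against the
#' pipeline's restricted alphabets. Protein sequences may use the 20 canonical
#' residues plus `X`; nucleotide sequences may use `ACGTN` and the gap
#' character `-`. A trailing `*` (stop) is stripped from nucleotide coding
#' sequences. Record ids (first whitespace-delimited token of the header) must
#' be unique.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param allow_gaps Permit `-` in protein sequences (for pre-aligned input).
#' @return A `data.frame` with columns `id` and `sequence`, one row per record.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide"),
                       allow_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (alphabet == "nucleotide") seqs <- sub("\\*+$", "", seqs)
  ok <- switch(alphabet,
               protein = "ACDEFGHIKLMNPQRSTVWYX",
               nucleotide = "ACGTN-")
  if (alphabet == "protein" && allow_gaps) ok <- paste0(ok, "-")
  for (k in seq_along(seqs)) {
    if (!nzchar(seqs[k])) stop("empty sequence for record '", ids[k], "'")
    bad <- regexpr(sprintf("[^%s]", ok), seqs[k])
    if (bad > 0L) {
      stop("illegal character '", substr(seqs[k], bad, bad),
           "' in record '", ids[k], "' at position ", bad)
    }
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param records `data.frame` with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a CA trace
#'
#' A CA trace is the ordered list of alpha-carbon positions of one chain:
#' residue numbers (strictly increasing), one-letter residue codes, and an
#' `n x 3` coordinate matrix in Angstroms.
#'
#' @param id Trace identifier.
#' @param resno Integer residue numbers, strictly increasing.
#' @param aa One-letter residue codes, same length as `resno`.
#' @param xyz Numeric matrix `n x 3` of coordinates.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(id, resno, aa, xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(length(resno) == nrow(xyz), length(aa) == nrow(xyz), ncol(xyz) == 3L)
  if (any(diff(resno) <= 0L)) stop("residue indices must be strictly increasing")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  structure(list(id = id, resno = as.integer(resno), aa = as.character(aa),
                 xyz = unname(xyz)),
            class = "ca_trace")
}

#' @exportS3Method base::print
print.ca_trace <- function(x, ...) {
  cat("CA trace '", x$id, "': ", length(x$resno), " residues\n", sep = "")
  invisible(x)
}

#' Read the CA trace of one chain from a PDB file
#'
#' Keeps only CA atoms of the requested chain; where alternate locations are
#' present, the first record per residue number is kept. Residues are returned
#' ordered by residue number.
#'
#' @param path Path to a PDB file with ATOM records.
#' @param chain Chain identifier (single character).
#' @return A [ca_trace()] object.
#' @export
read_ca_trace <- function(path, chain) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  if (!any(at$chain == chain, na.rm = TRUE)) {
    stop("chain '", chain, "' not present in ", path)
  }
  ca <- at[at$chain == chain & at$elety == "CA" & at$type == "ATOM", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms for chain '", chain, "' in ", path)
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]  # first altLoc wins
  ca <- ca[order(ca$resno), , drop = FALSE]
  aa1 <- bio3d::aa321(ca$resid)
  aa1[is.na(aa1) | aa1 == ""] <- "X"
  ca_trace(id = paste0(basename(path), "_", chain),
           resno = ca$resno, aa = aa1,
           xyz = cbind(ca$x, ca$y, ca$z))
}

#' Write a CA trace as a minimal PDB file
#'
#' @param trace A [ca_trace()] object.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_ca_trace <- function(trace, path, chain = "A") {
  stopifnot(inherits(trace, "ca_trace"))
  aa3 <- bio3d::aa123(trace$aa)
  aa3[is.na(aa3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(trace$resno), aa3, chain, trace$resno,
    trace$xyz[, 1], trace$xyz[, 2], trace$xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Construct a multiple protein alignment
#'
#' @param ids Character vector of unique row ids.
#' @param seqs Character vector of aligned sequences (equal lengths, gap `-`).
#' @return An object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) < 2L) stop("an alignment needs at least 2 rows")
  if (anyDuplicated(ids)) stop("duplicate alignment row ids")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("alignment rows differ in length")
  if (any(grepl("[.,]", seqs))) stop("only '-' is accepted as the gap character")
  structure(list(ids = as.character(ids), seqs = toupper(as.character(seqs)),
                 ncol = w),
            class = "multiple_alignment")
}

#' Read a multiple protein alignment from FASTA
#'
#' @param path Path to an aligned FASTA file (gap character `-`).
#' @return A [multiple_alignment()] object.
#' @export
read_alignment <- function(path) {
  rec <- read_fasta(path, "protein", allow_gaps = TRUE)
  multiple_alignment(rec$id, rec$sequence)
}

#' @exportS3Method base::print
print.multiple_alignment <- function(x, ...) {
  cat("multiple_alignment: ", length(x$ids), " rows x ", x$ncol, " columns\n",
      sep = "")
  invisible(x)
}

# alignment as a character matrix (rows = sequences)
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

#' Serialize a phylogenetic tree to newick
#'
#' Labels containing newick metacharacters (`():,;` or whitespace) are
#' single-quoted so they survive a round-trip through [read_newick()].
#'
#' @param tree An `ape::phylo` tree.
#' @return A single newick string with branch lengths.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  special <- grepl("[():,;[:space:]]", labs)
  placeholder <- sprintf("QLBL%dQL", seq_along(labs))
  tree$tip.label <- ifelse(special, placeholder, labs)
  out <- ape::write.tree(tree)
  for (i in which(special)) {
    out <- sub(placeholder[i], paste0("'", labs[i], "'"), out, fixed = TRUE)
  }
  out
}

#' Parse a newick string into a tree
#'
#' Single-quoted labels are unquoted.
#'
#' @param text Newick string.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(text) {
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick string")
  tr$tip.label <- sub("^'(.*)'$", "\\1", tr$tip.label)
  tr
}

#' Validate a labeled distance matrix
#'
#' Checks symmetry (within 1e-9), a zero diagonal, non-negativity and row
#' labels, returning the matrix with labels attached.
#'
#' @param d Square numeric matrix with row/column names.
#' @return The validated matrix.
#' @export
distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix needs labels")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix is not symmetric")
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be 0")
  if (any(d < 0)) stop("distances must be nonnegative")
  colnames(d) <- rownames(d)
  d
}

# shared TSV writer: stable formatting so reruns are byte-identical
write_tsv_report <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "NA", formatC(x, format = "g", digits = 10))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
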