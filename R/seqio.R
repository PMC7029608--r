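#' @keywords internal
RNA_ALPHABET <- c("A", "C", "G", "U")

#' PSI-BLAST amino-acid column order
#'
#' The fixed 20-letter amino-acid ordering used for every position weight
#' matrix in the package. It matches the column order of PSI-BLAST ASCII
#' PSSM files (`-out_ascii_pssm`).
#' @export
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a FASTA file of RNA or protein sequences
#'
#' Sequences are case-folded to upper case. For `alphabet = "rna"`, `T` is
#' mapped to `U` (so DNA-alphabet transcripts are accepted); any residual
#' non-ACGU letters are kept and later skipped by the k-mer encoder. For
#' `alphabet = "protein"`, non-standard amino-acid letters (`B`, `J`, `O`,
#' `U`, `Z`, `*` and anything else outside the 20-letter alphabet) are
#' mapped to `X`.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"rna"` or `"protein"`.
#' @return named character vector of sequences (names are record ids, first
#'   whitespace-delimited token of each header), in file order.
#' @export
read_fasta <- function(path, alphabet = c("rna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (alphabet == "rna") {
    seqs <- gsub("T", "U", seqs, fixed = TRUE)
  } else {
    seqs <- gsub(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")),
                 "X", seqs)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Filter proteins by minimum sequence length
#'
#' The position-weight-matrix representation requires protein sequences
#' longer than 50 residues; shorter sequences are removed. Sequences of
#' length exactly 50 sit on the boundary and are dropped by the default
#' threshold (`min_len = 51`, i.e. keep length > 50); the message reports
#' them separately so the boundary behaviour is visible.
#'
#' @param seqs named character vector of protein sequences.
#' @param min_len minimum length kept (default 51).
#' @return list with `kept` (named character vector) and `dropped_ids`.
#' @export
filter_proteins <- function(seqs, min_len = 51L) {
  lens <- nchar(seqs)
  keep <- lens >= min_len
  dropped <- names(seqs)[!keep]
  if (length(dropped)) {
    n50 <- sum(lens[!keep] == min_len - 1L)
    message(sprintf("filter_proteins: dropped %d protein(s) shorter than %d%s",
                    length(dropped), min_len,
                    if (n50 > 0)
                      sprintf(" (%d of length exactly %d)", n50, min_len - 1L)
                    else ""))
  }
  if (!any(keep)) warning("filter_proteins: no proteins passed the length filter")
  list(kept = seqs[keep], dropped_ids = dropped)
}

#' Read a labeled RNA-protein pair list
#'
#' The file is tab-separated with three columns: `protein_id`, `rna_id`,
#' `label` (0 = non-interacting, 1 = interacting). Pairs whose protein was
#' removed by the length filter are excluded with a warning; ids that are
#' neither loaded nor known-dropped raise an error.
#'
#' @param path path to the tab-separated pair list (no header).
#' @param proteins named character vector of loaded (filtered) proteins.
#' @param rnas named character vector of loaded RNAs.
#' @param dropped_proteins ids removed by [filter_proteins()]; pairs that
#'   reference them are silently excluded (with a count in a warning).
#' @return data.frame with columns `protein_id`, `rna_id`, `label`.
#' @export
read_pairs <- function(path, proteins, rnas, dropped_proteins = character()) {
  if (!file.exists(path)) stop("pair list not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("protein_id", "rna_id", "label"),
                   colClasses = c("character", "character", "character"),
                   quote = "", comment.char = "")
  lab <- df$label
  bad <- !(lab %in% c("0", "1"))
  if (any(bad)) {
    stop("invalid label(s) in pair list (must be 0 or 1): ",
         paste(unique(lab[bad]), collapse = ", "))
  }
  df$label <- as.integer(lab)
  unknown_rna <- setdiff(df$rna_id, names(rnas))
  if (length(unknown_rna)) {
    stop("pair list references unknown RNA id(s): ",
         paste(head(unknown_rna, 5L), collapse = ", "))
  }
  known_prot <- c(names(proteins), dropped_proteins)
  unknown_prot <- setdiff(df$protein_id, known_prot)
  if (length(unknown_prot)) {
    stop("pair list references unknown protein id(s): ",
         paste(head(unknown_prot, 5L), collapse = ", "))
  }
  drop <- df$protein_id %in% dropped_proteins
  if (any(drop)) {
    warning(sprintf("read_pairs: excluded %d pair(s) whose protein failed the length filter",
                    sum(drop)))
    df <- df[!drop, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write a labeled pair list
#'
#' @param pairs data.frame with columns `protein_id`, `rna_id`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs[, c("protein_id", "rna_id", "label")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
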