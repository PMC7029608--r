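.pkg_env <- new.env(parent = emptyenv())

# BLOSUM62 substitution matrix restricted to the 20 standard amino acids,
# columns in PSI-BLAST order; cached after first use.
.blosum62_20 <- function() {
  if (is.null(.pkg_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkg_env$blosum62 <- e$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
  }
  .pkg_env$blosum62
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the position-specific scoring matrix produced by PSI-BLAST's
#' `-out_ascii_pssm` option. Only the first 20 numeric columns (the
#' log-odds block) are retained; the weighted-percentage block and the
#' trailing information/weight columns are ignored.
#'
#' @param path path to the ASCII PSSM file.
#' @return list with `scores` (integer matrix, one row per query residue,
#'   20 columns named in PSI-BLAST amino-acid order) and `query` (the query
#'   sequence reconstructed from the residue column).
#' @export
parse_ascii_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header_i <- 0L
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) >= 20L && all(nchar(toks) == 1L) &&
        identical(toks[1:20], AA_ALPHABET20)) {
      header_i <- i
      break
    }
  }
  if (header_i == 0L) {
    stop("parse_ascii_pssm: no amino-acid column header found in '", path,
         "' (not a PSI-BLAST ASCII PSSM?)")
  }
  rows <- list()
  residues <- character()
  for (i in seq((header_i + 1L), length(lines))) {
    ln <- lines[i]
    if (!grepl("^\\s*\\d+\\s+[A-Za-z*]", ln)) break  # footer or blank ends body
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(toks) < 22L) {
      stop("parse_ascii_pssm: line ", i, ": expected at least 22 columns, got ",
           length(toks))
    }
    pos <- suppressWarnings(as.integer(toks[1L]))
    scores <- suppressWarnings(as.numeric(toks[3:22]))
    if (is.na(pos) || anyNA(scores)) {
      stop("parse_ascii_pssm: line ", i, ": non-numeric cell in log-odds block")
    }
    if (pos != length(rows) + 1L) {
      stop("parse_ascii_pssm: line ", i, ": position ", pos,
           " out of order (expected ", length(rows) + 1L, ")")
    }
    rows[[pos]] <- scores
    residues[pos] <- toupper(toks[2L])
  }
  if (length(rows) == 0L) stop("parse_ascii_pssm: no matrix body found in '", path, "'")
  scores <- do.call(rbind, rows)
  colnames(scores) <- AA_ALPHABET20
  list(scores = scores, query = paste(residues, collapse = ""))
}

#' Write a PSSM in PSI-BLAST ASCII layout
#'
#' Emits the `-out_ascii_pssm` layout (header, 40-column body with the
#' log-odds block first, footer). The percentage block is filled with
#' zeros: only the log-odds block is meaningful for fixtures written by
#' this function.
#'
#' @param scores numeric matrix, l x 20, columns in PSI-BLAST order.
#' @param query query sequence of length `nrow(scores)`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(scores, query, path) {
  stopifnot(ncol(scores) == 20L, nchar(query) == nrow(scores))
  res <- strsplit(query, "", fixed = TRUE)[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    paste("Last position-specific scoring matrix computed, weighted observed",
          "percentages rounded down, information per position, and relative",
          "weight of gapless real matches to pseudocounts")), con)
  writeLines(paste0("           ",
                    paste(sprintf("%3s", c(AA_ALPHABET20, AA_ALPHABET20)),
                          collapse = " ")), con)
  for (i in seq_len(nrow(scores))) {
    writeLines(paste0(sprintf("%5d %s  ", i, res[i]),
                      paste(sprintf("%3d", as.integer(scores[i, ])), collapse = " "),
                      " ",
                      paste(sprintf("%3d", integer(20L)), collapse = " "),
                      sprintf("  %4.2f %8.4f", 0, 0)), con)
  }
  writeLines(c("", "                      K         Lambda",
               "Standard Ungapped    0.1347     0.3179"), con)
  invisible(path)
}

#' Substitution-score pseudo-PWM for a protein sequence
#'
#' When no PSI-BLAST profile is available, row i of the raw score matrix is
#' the BLOSUM62 substitution-score row of residue i (columns in PSI-BLAST
#' amino-acid order); unknown residues (`X`) get an all-zero row, which
#' normalizes to the uninformative value 0.5.
#'
#' @param seq protein sequence.
#' @return numeric matrix, `nchar(seq)` x 20.
#' @export
fallback_pwm <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  b <- .blosum62_20()
  m <- match(chars, AA_ALPHABET20)
  out <- matrix(0, nrow = length(chars), ncol = 20L,
                dimnames = list(NULL, AA_ALPHABET20))
  ok <- !is.na(m)
  out[ok, ] <- b[m[ok], , drop = FALSE]
  out
}

#' Normalize raw profile scores into a position weight matrix
#'
#' Squashes raw (log-odds) scores entrywise into the open interval (0, 1)
#' so the matrix can serve as a bounded intensity function for Legendre
#' moments. `"logistic"` (default) applies `1 / (1 + exp(-s))`;
#' `"minmax"` rescales linearly to (0, 1) (with a small guard keeping the
#' interval open; a constant matrix maps to 0.5).
#'
#' @param scores numeric matrix of finite raw scores (l x 20).
#' @param method `"logistic"` or `"minmax"`.
#' @param protein_id optional id carried on the result.
#' @param source `"psiblast"` or `"fallback"` provenance tag.
#' @return object of class `pwm_profile`: list with `matrix` (l x 20 in
#'   (0,1)), `protein_id`, `source`.
#' @export
normalize_pwm <- function(scores, method = c("logistic", "minmax"),
                          protein_id = NA_character_,
                          source = c("fallback", "psiblast")) {
  method <- match.arg(method)
  source <- match.arg(source)
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("normalize_pwm: non-finite score(s)")
  if (nrow(scores) == 0L || ncol(scores) != 20L) {
    stop("normalize_pwm: expected a non-empty l x 20 score matrix")
  }
  if (method == "logistic") {
    w <- plogis(scores)
  } else {
    rng <- range(scores)
    if (rng[1] == rng[2]) {
      w <- matrix(0.5, nrow(scores), ncol(scores))
    } else {
      eps <- 1e-6
      w <- (scores - rng[1]) / (rng[2] - rng[1]) * (1 - 2 * eps) + eps
    }
  }
  dimnames(w) <- list(NULL, AA_ALPHABET20)
  structure(list(matrix = w, protein_id = protein_id, source = source),
            class = "pwm_profile")
}

#' @export
print.pwm_profile <- function(x, ...) {
  cat(sprintf("pwm_profile '%s': %d x 20 (%s)\n",
              x$protein_id, nrow(x$matrix), x$source))
  invisible(x)
}

#' Build position weight matrices for a set of proteins
#'
#' For each protein, uses `<pssm_dir>/<id>.pssm` (PSI-BLAST ASCII layout)
#' when present, otherwise falls back to BLOSUM62 substitution scores; raw
#' scores are normalized into (0, 1). A message reports how many proteins
#' used the fallback.
#'
#' @param seqs named character vector of protein sequences.
#' @param pssm_dir directory of per-protein `.pssm` files, or `NULL` to use
#'   the fallback for all proteins.
#' @param method normalization passed to [normalize_pwm()].
#' @return named list of `pwm_profile` objects.
#' @export
protein_profiles <- function(seqs, pssm_dir = NULL,
                             method = c("logistic", "minmax")) {
  method <- match.arg(method)
  n_fallback <- 0L
  out <- vector("list", length(seqs))
  names(out) <- names(seqs)
  for (id in names(seqs)) {
    f <- if (is.null(pssm_dir)) "" else file.path(pssm_dir, paste0(id, ".pssm"))
    if (nzchar(f) && file.exists(f)) {
      p <- parse_ascii_pssm(f)
      if (nchar(p$query) != nchar(seqs[[id]])) {
        warning("protein_profiles: PSSM query length mismatch for '", id,
                "', using fallback")
        out[[id]] <- normalize_pwm(fallback_pwm(seqs[[id]]), method,
                                   protein_id = id, source = "fallback")
        n_fallback <- n_fallback + 1L
      } else {
        out[[id]] <- normalize_pwm(p$scores, method,
                                   protein_id = id, source = "psiblast")
      }
    } else {
      out[[id]] <- normalize_pwm(fallback_pwm(seqs[[id]]), method,
                                 protein_id = id, source = "fallback")
      n_fallback <- n_fallback + 1L
    }
  }
  if (n_fallback > 0L) {
    message(sprintf("protein_profiles: %d/%d profile(s) from substitution-score fallback",
                    n_fallback, length(seqs)))
  }
  out
}
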