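#' Configuration for the synthetic ncRPI benchmark generator
#'
#' Describes a desk-scale labeled RNA-protein pair dataset with a planted,
#' learnable interaction rule: interacting pairs tend to carry clustered
#' binding regions -- the RNA 6-mer motif at roughly one copy per 60
#' nucleotides, the protein 5-mer motif at roughly one copy per 50
#' residues, mimicking the clustered binding elements of real
#' RNA-protein interactions (multi-copy RNA sites; repeated protein
#' binding modules) -- while non-interacting pairs tend not to. Each
#' molecule of a positive pair receives its binding region independently
#' with probability `beta`; molecules of negative pairs with probability
#' `1 - beta`. At `beta = 0.5` the motifs carry no label information (null
#' configuration); at the default `beta = 0.9` the signal is strong but not
#' deterministic.
#'
#' @param n_pairs number of labeled pairs (default 600).
#' @param rna_len length range of RNA sequences (default 80-200).
#' @param prot_len length range of protein sequences (default 60-300; the
#'   minimum must exceed 50 so all proteins pass the length filter).
#' @param rna_motif planted RNA motif (6-mer over ACGU).
#' @param prot_motif planted protein motif (5-mer over the 20 amino acids).
#' @param beta motif-label coupling strength in `[0, 1]` (default 0.9).
#' @param balance fraction of interacting pairs (default 0.5).
#' @param seed RNG seed; every generated artifact is reproducible from it.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_pairs = 600L, rna_len = c(80L, 200L),
                         prot_len = c(60L, 300L),
                         rna_motif = "GCAUCG", prot_motif = "HKWYR",
                         beta = 0.9, balance = 0.5, seed = 1L) {
  stopifnot(n_pairs >= 2L, length(rna_len) == 2L, length(prot_len) == 2L,
            beta >= 0, beta <= 1, balance > 0, balance < 1)
  if (prot_len[1] <= 50L) stop("synth_config: minimum protein length must exceed 50")
  if (nchar(rna_motif) > rna_len[1] || nchar(prot_motif) > prot_len[1]) {
    stop("synth_config: motif longer than the minimum sequence length")
  }
  if (grepl("[^ACGU]", rna_motif)) stop("synth_config: RNA motif must be over ACGU")
  structure(list(n_pairs = as.integer(n_pairs), rna_len = as.integer(rna_len),
                 prot_len = as.integer(prot_len), rna_motif = rna_motif,
                 prot_motif = prot_motif, beta = beta, balance = balance,
                 seed = as.integer(seed)),
            class = "synth_config")
}

.random_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# plant a clustered binding region: one motif copy per `density` letters,
# each at a random offset within its segment (copies never overlap).
# Mimics the clustered binding elements of real interactions -- repeated
# protein binding modules (RGG boxes, RRM arrays) and multi-copy RNA
# binding sites -- and keeps the motif fraction of the sequence roughly
# length-constant, so the signal survives global summaries (k-mer counts,
# moments) rather than vanishing as 1/length.
.plant_clustered <- function(seq, motif, density) {
  L <- nchar(seq)
  w <- nchar(motif)
  n_copies <- max(1L, L %/% density)
  bounds <- floor(seq(0L, L, length.out = n_copies + 1L))
  for (i in seq_len(n_copies)) {
    lo <- bounds[i] + 1L
    hi <- bounds[i + 1L] - w + 1L
    if (hi < lo) next
    start <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    seq <- paste0(substring(seq, 1L, start - 1L), motif,
                  substring(seq, start + w, L))
  }
  seq
}

#' Generate a synthetic labeled ncRPI benchmark
#'
#' Draws one RNA and one protein per pair (uniform letters over the
#' respective alphabet), plants the interaction motifs according to the
#' label coupling in `config`, and optionally writes the dataset to disk as
#' two FASTA files, a tab-separated pair list, and a directory of fixture
#' PSSM files in PSI-BLAST ASCII layout (substitution-score profile plus
#' small seeded integer noise).
#'
#' @param config a [synth_config()].
#' @param out_dir optional output directory; created if missing. When given,
#'   writes `rnas.fa`, `proteins.fa`, `pairs.tsv` and `pssms/<id>.pssm`.
#' @param write_pssms write the fixture PSSM directory (default `TRUE` when
#'   `out_dir` is given; writing one file per protein is the slowest step).
#' @return list with `rnas`, `proteins` (named character vectors), `pairs`
#'   (data.frame `protein_id`, `rna_id`, `label`), `config`, and `paths`
#'   (when written).
#' @export
synth_generate <- function(config = synth_config(), out_dir = NULL,
                           write_pssms = !is.null(out_dir)) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_pairs
  n_pos <- round(config$balance * n)
  labels <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  pad <- nchar(as.character(n))
  rna_ids <- sprintf("rna_%0*d", pad, seq_len(n))
  prot_ids <- sprintf("prot_%0*d", pad, seq_len(n))
  rnas <- character(n)
  prots <- character(n)
  for (i in seq_len(n)) {
    p_have <- if (labels[i] == 1L) config$beta else 1 - config$beta
    r <- .random_seq(sample(config$rna_len[1]:config$rna_len[2], 1L),
                     RNA_ALPHABET)
    if (runif(1) < p_have) r <- .plant_clustered(r, config$rna_motif, 60L)
    p <- .random_seq(sample(config$prot_len[1]:config$prot_len[2], 1L),
                     AA_ALPHABET20)
    if (runif(1) < p_have) p <- .plant_clustered(p, config$prot_motif, 50L)
    rnas[i] <- r
    prots[i] <- p
  }
  names(rnas) <- rna_ids
  names(prots) <- prot_ids
  pairs <- data.frame(protein_id = prot_ids, rna_id = rna_ids, label = labels)
  out <- list(rnas = rnas, proteins = prots, pairs = pairs, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(rna_fasta = file.path(out_dir, "rnas.fa"),
                  protein_fasta = file.path(out_dir, "proteins.fa"),
                  pairs = file.path(out_dir, "pairs.tsv"),
                  pssm_dir = file.path(out_dir, "pssms"))
    write_fasta(rnas, paths$rna_fasta)
    write_fasta(prots, paths$protein_fasta)
    write_pairs(pairs, paths$pairs)
    if (write_pssms) {
      dir.create(paths$pssm_dir, showWarnings = FALSE)
      for (id in prot_ids) {
        raw <- fallback_pwm(prots[[id]])
        noise <- matrix(sample(-2:2, length(raw), replace = TRUE), nrow(raw))
        write_ascii_pssm(raw + noise, prots[[id]],
                         file.path(paths$pssm_dir, paste0(id, ".pssm")))
      }
    } else {
      paths$pssm_dir <- NULL
    }
    out$paths <- paths
  }
  out
}
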